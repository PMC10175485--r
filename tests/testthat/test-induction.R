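mk_track <- function(df, condition = "cellular") {
  uvhotspot:::new_lesion_track(df, condition = condition)
}

test_that("naked-DNA scaling equalizes dipyrimidine read totals", {
  regions <- data.frame(contig = "c", start = 0L, end = 100L)
  cell <- mk_track(data.frame(contig = "c", strand = "+", pos = 0:99,
                              count = rep(20, 100)))   # 1000 reads
  nak <- mk_track(data.frame(contig = "c", strand = "+", pos = 0:99,
                             count = rep(10, 100)))    # 500 reads
  sc <- scale_naked(cell, nak, regions)
  expect_equal(sc$scale_factor, 2.0)
  expect_equal(sum(sc$track$count) / 2, sc$cellular_total, tolerance = 1e-9)

  ## equal totals: scaling is the identity
  sc2 <- scale_naked(cell, cell, regions)
  expect_equal(sc2$scale_factor, 1.0)
  expect_equal(sc2$track$count, cell$count)

  ## 1000 vs 400 -> every count x2.5
  nak2 <- mk_track(data.frame(contig = "c", strand = "+", pos = 0:99,
                              count = rep(8, 100)))
  sc3 <- scale_naked(cell, nak2, regions)
  expect_equal(sc3$scale_factor, 2.5)
  expect_equal(sum(sc3$track$count) / 2, 1000)

  empty <- mk_track(data.frame(contig = character(), strand = character(),
                               pos = integer(), count = numeric()))
  expect_error(scale_naked(cell, empty, regions), "track")
})

test_that("global induction sums to zero after scaling", {
  co <- small_cohort()
  key_c <- paste(co$cellular$contig, co$cellular$strand, co$cellular$pos)
  key_n <- paste(co$scaled_naked$contig, co$scaled_naked$strand,
                 co$scaled_naked$pos)
  tot <- sum(co$cellular$count) - sum(co$scaled_naked$count)
  expect_equal(tot / sum(co$cellular$count), 0, tolerance = 1e-9)
})

test_that("motif profiles are strand-oriented averages", {
  sites <- data.frame(contig = "c", midpoint = 50L, strand = "+",
                      stringsAsFactors = FALSE)
  tr <- mk_track(data.frame(contig = "c", strand = "-", pos = 47L, count = 5))
  prof <- motif_profile(tr, sites, halfwidth = 10)
  expect_equal(prof$mean_count[prof$offset == -3], 5)
  expect_equal(sum(prof$mean_count), 5)

  ## minus-strand site: the genomic left flank maps to positive offsets
  sites_m <- data.frame(contig = "c", midpoint = 50L, strand = "-",
                        stringsAsFactors = FALSE)
  prof_m <- motif_profile(tr, sites_m, halfwidth = 10)
  expect_equal(prof_m$mean_count[prof_m$offset == 3], 5)
  expect_error(motif_profile(tr, sites[0, ]), "empty")
})

test_that("variant-site profiles peak at the -4/-3 hotspot", {
  co <- small_cohort()
  prof <- motif_profile(co$cellular, variant_sites(co))
  top <- prof$offset[order(-prof$mean_count)][1:2]
  expect_setequal(top, c(-4, -3))
})

test_that("the capture-efficiency filter thresholds flank coverage per bp", {
  ## 350 flanking bp (window 6..180 both sides), 200 total counts -> 0.571
  sites <- data.frame(contig = "c", midpoint = 200L, strand = "+",
                      stringsAsFactors = FALSE)
  flank_pos <- c(200 - (6:180), 200 + (6:180))
  low <- mk_track(data.frame(contig = "c", strand = "+", pos = flank_pos,
                             count = 200 / 350))
  expect_false(capture_filter(sites, low))
  high <- mk_track(data.frame(contig = "c", strand = "+", pos = flank_pos,
                              count = 400 / 350))
  expect_true(capture_filter(sites, high))
  none <- mk_track(data.frame(contig = "c", strand = "+", pos = 1L, count = 1))
  expect_false(capture_filter(sites, none))
})

test_that("the induction matrix is filtered, ordered, and order-invariant", {
  co <- small_cohort()
  vs <- variant_sites(co)
  m1 <- induction_matrix(co$cellular, co$scaled_naked, vs, co$genome$regions)
  keep <- capture_filter(vs, co$cellular, co$genome$regions)
  expect_equal(nrow(m1), sum(keep))
  expect_true(!is.unsorted(attr(m1, "order_key")))
  ## shuffling the input site order leaves the sorted matrix unchanged
  set.seed(1)
  m2 <- induction_matrix(co$cellular, co$scaled_naked,
                         vs[sample(nrow(vs)), ], co$genome$regions)
  expect_equal(m1[order(rownames(m1)), ], m2[order(rownames(m2)), ])

  ## identical tracks -> all-zero matrix
  m0 <- induction_matrix(co$cellular, co$cellular, vs, co$genome$regions)
  expect_true(all(m0 == 0))
})

test_that("Z-scores follow the flank-null arithmetic", {
  null <- structure(list(mu_flank = -1.5, sigma_flank = 27,
                         n_positions = 1000L, window = c(6, 180)),
                    class = "flank_null")
  expect_equal(induction_z(-1.5, null), 0)
  expect_equal(induction_z(-1.5 + 27, null), 1)
  expect_equal(induction_z(79.5, null), 3)
})

test_that("flank-null Z-scores of the flanking positions standardize exactly", {
  co <- small_cohort()
  vs <- variant_sites(co)
  fn <- flank_null(co$cellular, co$scaled_naked, vs, co$genome$genome)
  expect_gte(fn$n_positions, 100)
  expect_gt(fn$sigma_flank, 0)
  ## recompute the flank inductions and standardize with the null
  pts <- unique(uvhotspot:::flank_positions(vs, c(6, 180)))
  chars <- uvhotspot:::genome_chars(co$genome$genome)
  keep <- logical(nrow(pts))
  for (ctg in unique(pts$contig)) {
    ii <- pts$contig == ctg
    keep[ii] <- pts$pos[ii] >= 0 & pts$pos[ii] < length(chars[[ctg]]) &
      uvhotspot:::cpd_forming(chars[[ctg]], pts$pos[ii])
  }
  pts <- pts[keep, ]
  d <- uvhotspot:::track_values(co$cellular, pts$contig, pts$pos) -
    uvhotspot:::track_values(co$scaled_naked, pts$contig, pts$pos)
  z <- induction_z(d, fn)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})
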