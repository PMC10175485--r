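test_that("make_genome records planted motifs in the truth table", {
  pm <- data.frame(region = 1L, offset = 300L, kind = "ETS_variant", bound = TRUE)
  gen <- make_genome(genome_spec(1, 720, pm, seed = 1))
  expect_equal(nrow(gen$sites), 1L)
  expect_true(gen$sites$variant)
  expect_equal(gen$sites$midpoint, 300L)
})

test_that("planted variant contexts are recovered by the motif scanner", {
  ## the planted variant context carries the STK19-style pyrimidine-strand
  ## core ...TCTTCCG... with a TC dipyrimidine at -4/-3
  pm <- data.frame(region = 1L, offset = 100L, kind = "ETS_variant",
                   bound = TRUE, strand = "+")
  gen <- make_genome(genome_spec(1, 200, pm, seed = 8))
  expect_equal(substr(gen$genome[[1]], 100 - 3, 100 + 4), "TCTTCCGG")
  sc <- scan_ets(gen$genome[[1]], "region_0001")
  hit <- sc[sc$midpoint == 100L, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$variant)
})

test_that("generation is byte-identical under a fixed seed", {
  pm <- data.frame(region = c(1L, 2L), offset = c(60L, 80L),
                   kind = c("ETS_variant", "NFY"), bound = c(TRUE, FALSE))
  spec <- genome_spec(2, 160, pm, seed = 99)
  g1 <- make_genome(spec); g2 <- make_genome(spec)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$sites, g2$sites)
  params <- damage_params(sequencing_depth = 500, seed = 7)
  r1 <- simulate_reads(g1, params, "cellular")
  r2 <- simulate_reads(g2, params, "cellular")
  expect_identical(r1$start, r2$start)
  expect_identical(r1$strand, r2$strand)
})

test_that("overlapping planted motifs are rejected", {
  pm <- data.frame(region = c(1L, 1L), offset = c(60L, 65L),
                   kind = "ETS_variant", bound = TRUE)
  expect_error(genome_spec(1, 160, pm, seed = 1), "overlap")
})

test_that("read counts at a lone dipyrimidine follow the Poisson mean", {
  ## genome with a single TT step and no other dipyrimidines on either
  ## strand: alternating purine/pyrimidine elsewhere
  base <- paste(rep("AC", 30), collapse = "")
  seq <- paste0(substr(base, 1, 28), "TT", substr(base, 31, 60))
  gen <- structure(list(
    genome = c(ctg = seq),
    regions = data.frame(contig = "ctg", start = 0L, end = 60L,
                         name = "ctg", class = "coding",
                         stringsAsFactors = FALSE),
    sites = data.frame(contig = character(), midpoint = integer(),
                       strand = character(), kind = character(),
                       variant = logical(), bound = logical(),
                       site_id = character(), stringsAsFactors = FALSE),
    spec = NULL), class = "uv_genome")
  params <- damage_params(sequencing_depth = 200, background_rate = 0,
                          efficiency_sdlog = 0, library_sdlog = 0,
                          base_rate = c(TT = 1, TC = 0, CT = 0, CC = 0),
                          seed = 13)
  counts <- vapply(1:200, function(i) {
    params$seed <- i
    nrow(simulate_reads(gen, params, "naked"))
  }, numeric(1))
  ## all rate mass sits on the one TT step -> expected reads = depth
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 200))
})

test_that("bound-site induction factors produce the configured cellular:naked ratio", {
  ## Monte-Carlo check of the generative expectation at the -4/-3 step
  pm <- data.frame(region = 1:40, offset = 60L, kind = "ETS_variant",
                   bound = TRUE)
  gen <- make_genome(genome_spec(40, 120, pm, seed = 17))
  params <- damage_params(sequencing_depth = 3000, background_rate = 0,
                          efficiency_sdlog = 0, library_sdlog = 0, seed = 23)
  cell <- call_lesions(simulate_reads(gen, params, "cellular"), gen$genome)
  nak <- call_lesions(simulate_reads(gen, params, "naked"), gen$genome)
  C <- sum(site_lesion_sums(cell, gen$sites, offsets = c(-4, -3)))
  N <- sum(site_lesion_sums(nak, gen$sites, offsets = c(-4, -3)))
  f <- params$induction$ETS_variant[["-4"]]
  ## analytic expectation: the TC step at -4/-3 is boosted by f, and the
  ## -3 position also collects the suppressed (x0.3) CT step
  exp_ratio <- (0.5 * 2 * f + 0.2 * 0.3) / (0.5 * 2 + 0.2)
  expect_equal(C / N, exp_ratio, tolerance = 0.1)
})

test_that("cellular and naked libraries agree away from bound motifs", {
  pm <- data.frame(region = 1:10, offset = 360L, kind = "ETS_variant",
                   bound = TRUE)
  gen <- make_genome(genome_spec(10, 720, pm, seed = 31))
  params <- damage_params(efficiency_sdlog = 0, library_sdlog = 0,
                          background_rate = 0, seed = 37)
  cell <- call_lesions(simulate_reads(gen, params, "cellular"), gen$genome)
  nak <- call_lesions(simulate_reads(gen, params, "naked"), gen$genome)
  ## positions > 20 bp from any midpoint carry no induction factor
  far <- abs(cell$pos - 360L) > 20
  key <- paste(cell$contig, cell$strand, cell$pos)
  nkey <- paste(nak$contig, nak$strand, nak$pos)
  nval <- nak$count[match(key, nkey)]
  nval[is.na(nval)] <- 0
  cc <- cell$count[far]; nn <- nval[far]
  ## per-position two-sample Poisson comparison via binomial share
  idx <- which(cc + nn >= 10)
  p <- vapply(idx, function(i) {
    binom.test(round(cc[i]), round(cc[i] + nn[i]), 0.5)$p.value
  }, numeric(1))
  q <- p.adjust(p, "BH")
  expect_equal(sum(q < 0.01), 0L)
})

test_that("mutation counts follow the log-linear model in degenerate cases", {
  sites <- data.frame(contig = "ctg", midpoint = c(30L, 70L), strand = "+",
                      kind = "ETS_variant", variant = TRUE, bound = TRUE,
                      site_id = c("s1", "s2"), stringsAsFactors = FALSE)
  gen <- structure(list(
    genome = c(ctg = paste(rep("ACGT", 30), collapse = "")),
    regions = data.frame(contig = "ctg", start = 0L, end = 120L,
                         name = "ctg", class = "coding", stringsAsFactors = FALSE),
    sites = sites, spec = NULL), class = "uv_genome")
  empty <- uvhotspot:::new_lesion_track(
    data.frame(contig = character(), strand = character(), pos = integer(),
               count = numeric(), stringsAsFactors = FALSE))
  ## all counts zero and b_cell = b_naked = 0, b0 = log 2 -> Poisson(2)
  ys <- vapply(1:300, function(i) {
    params <- damage_params(glm_beta0 = log(2), glm_beta_cell = 0,
                            glm_beta_naked = 0, background_mut_rate = 0,
                            seed = i)
    cat_i <- suppressWarnings(
      simulate_mutations(empty, empty, sites, params, gen))
    sum(attr(cat_i, "site_counts")$y)
  }, numeric(1))
  expect_lt(abs(mean(ys) / 2 - 2), 3 * sqrt(2 / 300))
  expect_warning(
    simulate_mutations(empty, empty, sites,
                       damage_params(background_mut_rate = 0, seed = 1), gen),
    "treated as 0")
})

test_that("accessibility simulation hits its correlation target", {
  set.seed(4)
  ind <- rlnorm(100, 4, 1)
  d1 <- simulate_dnase(ind, target_rho = 1, seed = 5)
  ## a monotone transform of induction: Spearman exactly 1
  expect_equal(cor(attr(d1, "total"), ind, method = "spearman"), 1)
  d2 <- simulate_dnase(ind, target_rho = 0.41, seed = 6)
  d3 <- simulate_dnase(ind, target_rho = 0.41, seed = 7)
  expect_false(identical(d2$rep1, d3$rep1))
  expect_error(simulate_dnase(ind[1:5], 0.41, 1), "fewer than 10")
  expect_error(simulate_dnase(ind, 1.2, 1), "target_rho")
  ## replicate decomposition preserves the per-site total
  expect_equal(rowSums(as.matrix(d2)), attr(d2, "total"))
})
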