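test_that("the read-to-lesion offset convention is applied on both strands", {
  g <- c(chr = "AAGGAACC")
  ## plus-strand read, leftmost position 4 -> candidate at (2,3) on minus
  ## strand; plus bases G,G host a minus-strand CC -> retained
  t1 <- call_lesions(
    data.frame(chrom = "chr", start = 4L, end = 8L, strand = "+"), g)
  expect_equal(t1$pos, c(2L, 3L))
  expect_equal(t1$strand, c("-", "-"))
  expect_equal(t1$count, c(1, 1))

  ## minus-strand read, rightmost position 5 -> candidate (6,7) on plus (CC)
  t2 <- call_lesions(
    data.frame(chrom = "chr", start = 2L, end = 6L, strand = "-"), g)
  expect_equal(t2$pos, c(6L, 7L))
  expect_equal(t2$strand, c("+", "+"))

  ## candidate bases A,A on the minus strand are purines -> dropped
  t3 <- call_lesions(
    data.frame(chrom = "chr", start = 4L, end = 8L, strand = "+"),
    c(chr = "AATTCGGA"))
  expect_equal(attr(t3, "total_dipyrimidine_reads"), 0L)
  expect_equal(attr(t3, "dropped_nonpyr"), 1L)
})

test_that("input reads are conserved across retained/dropped/off-contig", {
  g <- random_genome(3, 80, seed = 5)
  reads <- random_reads(g, 400, seed = 6)
  tr <- call_lesions(reads, g)
  expect_equal(attr(tr, "total_dipyrimidine_reads") +
               attr(tr, "dropped_nonpyr") + attr(tr, "dropped_off_contig"),
               nrow(reads))
  ## each retained read contributes exactly two position counts
  expect_equal(sum(tr$count), 2 * attr(tr, "total_dipyrimidine_reads"))
  ## every counted position is a dipyrimidine base on its strand
  for (i in seq_len(nrow(tr))) {
    base <- substr(g[[tr$contig[i]]], tr$pos[i] + 1, tr$pos[i] + 1)
    if (tr$strand[i] == "+") expect_true(base %in% c("C", "T"))
    else expect_true(base %in% c("A", "G"))
  }
})

test_that("calling matches a brute-force dipyrimidine scanner on small genomes", {
  for (seed in 1:4) {
    g <- random_genome(2, 100 + 25 * seed, seed = seed)
    reads <- random_reads(g, 300, seed = seed + 50)
    fast <- as.data.frame(call_lesions(reads, g))[, c("contig", "strand", "pos", "count")]
    slow <- brute_force_track(reads, g)
    rownames(fast) <- rownames(slow) <- NULL
    expect_equal(fast, slow)
  }
})

test_that("calling is symmetric under genome reverse complement", {
  g <- random_genome(2, 150, seed = 9)
  reads <- random_reads(g, 500, seed = 10)
  cols <- c("contig", "strand", "pos", "count")
  tr <- as.data.frame(call_lesions(reads, g))[, cols]
  mtr <- as.data.frame(call_lesions(mirror_reads(reads, g), revcomp_genome(g)))[, cols]
  ## mirrored track: position L-1-pos, strand flipped
  mirrored <- data.frame(
    contig = tr$contig,
    strand = ifelse(tr$strand == "+", "-", "+"),
    pos = nchar(g)[tr$contig] - 1L - tr$pos,
    count = tr$count, stringsAsFactors = FALSE
  )
  mirrored <- mirrored[order(mirrored$contig, mirrored$strand, mirrored$pos), ]
  rownames(mirrored) <- rownames(mtr) <- NULL
  expect_equal(mtr, mirrored)
})

test_that("errors name missing contigs and malformed strands", {
  g <- c(chr = "ACGTACGT")
  expect_error(call_lesions(
    data.frame(chrom = "chrX", start = 2L, end = 5L, strand = "+"), g), "chrX")
  expect_error(call_lesions(
    data.frame(chrom = "chr", start = 2L, end = 5L, strand = "*"), g),
    "strand")
})

test_that("dinucleotide fractions classify candidates on the lesion strand", {
  ## every read's candidate is a TT (plus strand "AA" hosts minus "TT")
  g <- c(chr = "CCAAGG")
  reads <- data.frame(chrom = "chr", start = c(4L, 4L, 4L), end = 6L,
                      strand = "+")
  fr <- dinucleotide_fractions(reads, g)
  expect_equal(unname(fr["TT"]), 1)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_error(dinucleotide_fractions(reads[0, ], g), "empty")
})

test_that("no-UV libraries have background-level dipyrimidine fractions", {
  co <- small_cohort()
  nouv <- simulate_reads(co$genome, co$params, "no_uv")
  fr <- dinucleotide_fractions(nouv, co$genome$genome)
  ## exhaustive count of dipyrimidine candidate pairs in the genome:
  ## a uniform read position is a dipyrimidine candidate with probability
  ## (number of dipyrimidine steps on both strands) / (2 * positions)
  fg <- uvhotspot:::flat_genome(co$genome$genome)
  steps <- sum(fg$is_pyr[-length(fg$is_pyr)] & fg$is_pyr[-1]) +
    sum(fg$is_pur[-length(fg$is_pur)] & fg$is_pur[-1])
  expected <- steps / (2 * fg$total)
  expect_equal(sum(fr[c("TT", "TC", "CT", "CC")]), expected, tolerance = 0.02)
})

test_that("cellular libraries without background noise have no 'other' reads", {
  pm <- data.frame(region = 1, offset = 60L, kind = "ETS_variant", bound = TRUE)
  gen <- make_genome(genome_spec(1, 120, pm, seed = 2))
  params <- damage_params(sequencing_depth = 2000, background_rate = 0, seed = 4)
  rd <- simulate_reads(gen, params, "cellular")
  fr <- dinucleotide_fractions(rd, gen$genome)
  expect_equal(unname(fr["other"]), 0)
})

test_that("region density profiles average counts around region centers", {
  g <- c(r1 = paste(rep("A", 101), collapse = ""))
  regions <- data.frame(contig = "r1", start = 0L, end = 101L, class = "ETS")
  tr <- uvhotspot:::new_lesion_track(
    data.frame(contig = "r1", strand = "-", pos = 50L, count = 3,
               stringsAsFactors = FALSE))
  prof <- region_density_profile(tr, regions, halfwidth = 20)
  expect_equal(prof$mean_count[prof$offset == 0], 3)
  expect_equal(sum(prof$mean_count), 3)

  empty <- uvhotspot:::new_lesion_track(
    data.frame(contig = character(), strand = character(), pos = integer(),
               count = numeric(), stringsAsFactors = FALSE))
  prof0 <- region_density_profile(empty, regions, halfwidth = 20)
  expect_true(all(prof0$mean_count == 0))
})

test_that("planted ETS regions show a central damage peak absent from background", {
  co <- cached("profile_cohort", function() {
    simulate_cohort(n_sites = 15, seed = 21, n_background = 15)
  })
  prof <- region_density_profile(co$cellular, co$genome$regions, halfwidth = 300)
  ets <- prof[prof$class == "ETS", ]
  bg <- prof[prof$class == "coding", ]
  center <- abs(ets$offset) <= 5
  flank <- abs(ets$offset) > 50
  expect_gt(mean(ets$mean_count[center]), 1.5 * mean(ets$mean_count[flank]))
  expect_lt(mean(bg$mean_count[abs(bg$offset) <= 5]),
            1.5 * mean(bg$mean_count[abs(bg$offset) > 50]))
})
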