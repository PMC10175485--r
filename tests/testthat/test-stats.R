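test_that("trinucleotide enrichment reproduces hand arithmetic on a toy table", {
  ## background: 100 TCA occurrences with 10 mutations (rate 0.1); the two
  ## query TCA positions carry 6 mutations -> fold = 6 / (2 * 0.1) = 30.
  ## Build a genome of spaced TCA triplets: "TCAG" repeated.
  g <- c(chr = paste(rep("TCAG", 102), collapse = ""))
  ## central positions of TCA triplets are 1, 5, 9, ... (0-based)
  centers <- seq(1L, by = 4L, length.out = 102)
  query <- data.frame(contig = "chr", pos = centers[1:2])
  bg_regions <- data.frame(contig = "chr", start = 0L, end = nchar(g[[1]]))
  catalog <- data.frame(
    contig = "chr",
    position = c(centers[1:2], centers[3:12]),
    tumor_count = c(3L, 3L, rep(1L, 10)),
    stringsAsFactors = FALSE
  )
  enr <- trinuc_enrichment(catalog, g, query, bg_regions, exclude_query = TRUE)
  expect_equal(enr$observed, 6)
  expect_equal(enr$fold, 30, tolerance = 1e-9)
})

test_that("uniform mutations over one context give fold 1", {
  g <- c(chr = paste(rep("TCAG", 50), collapse = ""))
  centers <- seq(1L, by = 4L, length.out = 50)
  catalog <- data.frame(contig = "chr", position = centers,
                        tumor_count = 1L, stringsAsFactors = FALSE)
  query <- data.frame(contig = "chr", pos = centers[1:10])
  enr <- trinuc_enrichment(catalog, g, query,
                           data.frame(contig = "chr", start = 0L,
                                      end = nchar(g[[1]])),
                           exclude_query = FALSE)
  expect_equal(enr$fold, 1, tolerance = 1e-9)
})

test_that("a query context absent from the background is an error naming it", {
  g <- c(chr = "AAAAATCAAAAA")
  catalog <- data.frame(contig = "chr", position = 2L, tumor_count = 1L)
  query <- data.frame(contig = "chr", pos = 6L)  # TCA context
  bg <- data.frame(contig = "chr", start = 0L, end = 4L)
  expect_error(trinuc_enrichment(catalog, g, query, bg), "TCA")
})

test_that("subsampled query positions are unenriched in expectation", {
  set.seed(31)
  g <- random_genome(3, 500, seed = 61)
  bg <- data.frame(contig = names(g), start = 0L, end = 500L)
  folds <- replicate(60, {
    positions <- do.call(rbind, lapply(names(g), function(ctg) {
      data.frame(contig = ctg, position = sample(1:498, 60),
                 stringsAsFactors = FALSE)
    }))
    positions$tumor_count <- 1L
    ## query = uniform subsample of background positions, independent of
    ## where the mutations landed
    q <- data.frame(contig = sample(names(g), 300, replace = TRUE),
                    pos = sample(1:498, 300, replace = TRUE))
    trinuc_enrichment(positions, g, q, bg, exclude_query = FALSE)$fold
  })
  expect_lt(abs(mean(folds) - 1), 3 * sd(folds) / sqrt(length(folds)))
})

test_that("accessibility density averages bedGraph windows correctly", {
  sites <- data.frame(contig = "c", midpoint = 100L)
  track <- data.frame(contig = "c", start = 0L, end = 300L, value = 2.5)
  expect_equal(dnase_density(list(track), sites, halfwidth = 50), 2.5)
  ## three identical datasets sum their averages
  expect_equal(dnase_density(list(track, track, track), sites, 50), 7.5)
})

test_that("spearman_ci matches the published interval arithmetic", {
  ## rho = 0.41 on n = 324 gives the published CI (0.3140, 0.5007)
  ## under the Fisher-z transform with se = 1/sqrt(n-3)
  z <- atanh(0.41); half <- qnorm(0.975) / sqrt(324 - 3)
  expect_equal(tanh(z - half), 0.3140, tolerance = 5e-3)
  set.seed(5)
  x <- rnorm(324); y <- 0.45 * x + rnorm(324)
  ct <- spearman_ci(x, y)
  expect_equal(ct$rho, cor(x, y, method = "spearman"))
  expect_true(ct$ci[1] < ct$rho && ct$rho < ct$ci[2])
  ## perfect rank agreement
  expect_equal(spearman_ci(1:20, (1:20)^3)$rho, 1)
})

test_that("Mann-Whitney matches full enumeration and handles ties", {
  ## {1,2} vs {3,4}: U = 0; 2 of the 6 orderings are as or more extreme
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-9)
  expect_equal(mw$method, "exact")

  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$U, 4.5)
  expect_equal(ident$p, 1, tolerance = 0.01)

  shifted <- mann_whitney(11:20, 1:10)
  expect_lt(shifted$p, 0.01)

  ## exact and approximate branches agree on tie-free n = 10 + 10
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    exact_p <- mann_whitney(a, b)$p
    approx_p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})
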