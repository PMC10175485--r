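#' Trinucleotide-context mutation enrichment
#'
#' Compares the observed mutation count at query positions with the count
#' expected from the pyrimidine-strand trinucleotide context of each query
#' position, where context rates are estimated from background regions.
#' By default the query positions themselves are excluded from the
#' background tally, so hotspot mutations do not inflate their own
#' expectation.
#'
#' @param catalog mutation data frame (`contig, position, tumor_count`).
#' @param genome named character vector of contig sequences.
#' @param query data frame of query positions (`contig, pos`).
#' @param background_regions regions (`contig, start, end`) whose positions
#'   define the context background.
#' @param exclude_query drop query positions from the background.
#' @return list of class `trinuc_enrichment`: `observed`, `expected`,
#'   `fold`, and `per_context` (context occurrences, mutations and rates).
#' @export
trinuc_enrichment <- function(catalog, genome, query, background_regions,
                              exclude_query = TRUE) {
  genome <- check_genome(genome)
  chars <- genome_chars(genome)

  ## background positions and contexts
  bg <- do.call(rbind, lapply(seq_len(nrow(background_regions)), function(i) {
    ctg <- background_regions$contig[i]
    lo <- max(1L, background_regions$start[i])
    hi <- min(length(chars[[ctg]]) - 2L, background_regions$end[i] - 1L)
    if (hi < lo) return(NULL)
    data.frame(contig = ctg, pos = seq(lo, hi), stringsAsFactors = FALSE)
  }))
  if (exclude_query) {
    bg <- bg[!paste(bg$contig, bg$pos) %in% paste(query$contig, query$pos), ,
             drop = FALSE]
  }
  bg$ctx <- NA_character_
  for (ctg in unique(bg$contig)) {
    ii <- bg$contig == ctg
    bg$ctx[ii] <- context_at(chars[[ctg]], bg$pos[ii])
  }
  bg <- bg[!is.na(bg$ctx), , drop = FALSE]

  ## background mutation counts per context
  mut_key <- paste(catalog$contig, catalog$position)
  bg_mut <- catalog$tumor_count[match(paste(bg$contig, bg$pos), mut_key)]
  bg_mut[is.na(bg_mut)] <- 0
  occ <- table(bg$ctx)
  muts <- tapply(bg_mut, bg$ctx, sum)
  per_context <- data.frame(
    context = names(occ),
    occurrences = as.integer(occ),
    mutations = as.numeric(muts[names(occ)]),
    stringsAsFactors = FALSE
  )
  per_context$rate <- per_context$mutations / per_context$occurrences

  ## query contexts
  qctx <- character(nrow(query))
  for (ctg in unique(query$contig)) {
    ii <- query$contig == ctg
    qctx[ii] <- context_at(chars[[ctg]], query$pos[ii])
  }
  missing_ctx <- setdiff(unique(qctx), per_context$context)
  if (length(missing_ctx)) {
    stop("context(s) absent from background: ", paste(missing_ctx, collapse = ", "))
  }
  expected <- sum(per_context$rate[match(qctx, per_context$context)])
  observed <- sum(catalog$tumor_count[match(paste(query$contig, query$pos),
                                            mut_key)], na.rm = TRUE)
  if (expected <= 0) stop("expected mutation count is zero; background too sparse")
  structure(list(observed = observed, expected = expected,
                 fold = observed / expected, n_query = nrow(query),
                 per_context = per_context),
            class = "trinuc_enrichment")
}

#' @export
print.trinuc_enrichment <- function(x, ...) {
  cat(sprintf("trinucleotide enrichment: observed %.4g vs expected %.4g over %d positions (fold = %.3g)\n",
              x$observed, x$expected, x$n_query, x$fold))
  invisible(x)
}

#' Accessibility read density around binding-site midpoints
#'
#' For each dataset, the mean per-bp track value within `halfwidth` bp of
#' each site midpoint; the per-dataset means are summed across datasets.
#'
#' @param tracks list of bedGraph-style interval data frames
#'   (`contig, start, end, value`, 0-based half-open), one per dataset.
#' @param sites site table (`contig, midpoint`).
#' @param halfwidth window half-width in bp.
#' @return numeric vector: summed mean density per site.
#' @export
dnase_density <- function(tracks, sites, halfwidth = 50) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  dens <- numeric(nrow(sites))
  win <- 2 * halfwidth + 1
  for (tr in tracks) {
    for (i in seq_len(nrow(sites))) {
      lo <- sites$midpoint[i] - halfwidth
      hi <- sites$midpoint[i] + halfwidth + 1L  # half-open
      sub <- tr[tr$contig == sites$contig[i] & tr$start < hi & tr$end > lo, ,
                drop = FALSE]
      if (!nrow(sub)) next
      ov <- pmin(sub$end, hi) - pmax(sub$start, lo)
      dens[i] <- dens[i] + sum(sub$value * ov) / win
    }
  }
  dens
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors.
#' @param conf_level confidence level.
#' @return list: `rho`, `ci` (length 2), `n`, `p` (asymptotic, two-sided).
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  rho <- cor(x, y, method = "spearman")
  n <- length(x)
  z <- atanh(rho)
  zq <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  ci <- tanh(c(z - zq, z + zq))
  p <- stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  list(rho = rho, ci = ci, n = n, p = p)
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when the combined sample size is at most 20 and the
#' data are tie-free; otherwise the normal approximation with mid-ranks,
#' tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors.
#' @return list: `U` (for group `a`), `p` (two-sided), `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
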