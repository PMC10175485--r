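#' Configuration for the elevated-CPD classifier
#'
#' A mutation site counts as having significantly elevated CPDs when its
#' cellular count is at least `fold_threshold` times the scaled naked
#' count AND exceeds it by at least `abs_threshold` reads (both bounds
#' inclusive).
#'
#' @param fold_threshold minimum cellular:scaled-naked fold.
#' @param abs_threshold minimum absolute cellular-minus-naked difference.
#' @param window window (bp) around the mutation base over which counts
#'   are summed; default a single base.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(fold_threshold = 2.0, abs_threshold = 50,
                              window = 1) {
  stopifnot(fold_threshold > 0, abs_threshold > 0, window >= 1)
  structure(list(fold_threshold = fold_threshold,
                 abs_threshold = abs_threshold, window = as.integer(window)),
            class = "classifier_config")
}

#' Elevated-CPD flag for a mutation site
#'
#' @param cellular,scaled_naked counts at the site.
#' @param config a [classifier_config()].
#' @return logical vector.
#' @export
elevated_cpd <- function(cellular, scaled_naked, config = classifier_config()) {
  cellular >= config$fold_threshold * scaled_naked &
    (cellular - scaled_naked) >= config$abs_threshold
}

site_window_counts <- function(track, contig, position, window) {
  half <- (window - 1L) %/% 2L
  tot <- numeric(length(position))
  for (d in seq(-half, half)) {
    tot <- tot + track_values(track, contig, position + d)
  }
  tot
}

#' Classify recurrent mutation sites as likely passengers or candidate drivers
#'
#' Reads both-strand-summed CPD counts at each mutation position from the
#' cellular and scaled naked tracks, applies the elevated-CPD rule, and
#' combines it with ETS-motif overlap: elevated + ETS = likely passenger
#' (recurrence explained by binding-induced damage); not elevated =
#' candidate driver; elevated without an ETS motif = ambiguous.  Mutations
#' outside every capture region are reported as uncovered and excluded
#' from the summary fractions.
#'
#' @param catalog annotated mutation data frame (needs `ets_overlap`; see
#'   [annotate_mutations()]).
#' @param cellular,scaled_naked [lesion_track]s.
#' @param config a [classifier_config()].
#' @param regions capture regions; `NULL` treats every site as covered.
#' @return data frame of site calls with a `summary` attribute (per-class
#'   counts and fractions).
#' @export
classify_sites <- function(catalog, cellular, scaled_naked,
                           config = classifier_config(), regions = NULL) {
  stopifnot("ets_overlap" %in% names(catalog))
  covered <- rep(TRUE, nrow(catalog))
  if (!is.null(regions)) {
    covered <- rep(FALSE, nrow(catalog))
    for (i in seq_len(nrow(regions))) {
      covered <- covered | (catalog$contig == regions$contig[i] &
                            catalog$position >= regions$start[i] &
                            catalog$position < regions$end[i])
    }
  }
  cc <- site_window_counts(cellular, catalog$contig, catalog$position,
                           config$window)
  nc <- site_window_counts(scaled_naked, catalog$contig, catalog$position,
                           config$window)
  elevated <- elevated_cpd(cc, nc, config)
  call <- ifelse(!elevated, "candidate_driver",
                 ifelse(catalog$ets_overlap, "likely_passenger", "ambiguous"))
  call[!covered] <- "uncovered"
  out <- cbind(catalog,
               data.frame(cellular = cc, scaled_naked = nc,
                          induction = cc - nc, elevated = elevated,
                          covered = covered, call = call,
                          stringsAsFactors = FALSE))
  cov <- out[out$covered, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(cov, cov$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               n_ets = sum(g$ets_overlap), n_elevated = sum(g$elevated),
               n_likely_passenger = sum(g$call == "likely_passenger"),
               n_candidate_driver = sum(g$call == "candidate_driver"),
               n_ambiguous = sum(g$call == "ambiguous"),
               frac_ets = mean(g$ets_overlap),
               frac_elevated = mean(g$elevated),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

#' Compare TSS distances of ETS and non-ETS mutations
#'
#' Two-tailed Mann-Whitney comparison of the TSS distances of mutations
#' overlapping an ETS motif versus those that do not (by default within
#' the protein-coding class).
#'
#' @param catalog annotated mutation data frame with `tss_distance` and
#'   `ets_overlap` columns.
#' @param class mutation class to restrict to; `NULL` for all.
#' @return list: the [mann_whitney()] result plus group medians and sizes.
#' @export
tss_group_compare <- function(catalog, class = "coding") {
  g <- catalog
  if (!is.null(class)) g <- g[g$class == class, , drop = FALSE]
  g <- g[!is.na(g$tss_distance), , drop = FALSE]
  a <- g$tss_distance[g$ets_overlap]
  b <- g$tss_distance[!g$ets_overlap]
  if (!length(a) || !length(b)) stop("both ETS and non-ETS groups must be non-empty")
  mw <- mann_whitney(a, b)
  c(mw, list(median_ets = stats::median(a), median_other = stats::median(b),
             n_ets = length(a), n_other = length(b)))
}
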