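restrict_to_regions <- function(track, regions) {
  keep <- rep(FALSE, nrow(track))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (track$contig == regions$contig[i] &
                    track$pos >= regions$start[i] &
                    track$pos < regions$end[i])
  }
  track[keep, , drop = FALSE]
}

#' Scale a naked-DNA control track to a matched cellular track
#'
#' The naked-DNA library is multiplied by a single global factor so that it
#' carries the same overall number of reads at lesion-forming dipyrimidine
#' sequences as the matched cellular library, computed within the union of
#' the capture regions.
#'
#' @param cellular,naked [lesion_track]s.
#' @param regions capture-region data frame (`contig, start, end`); if
#'   `NULL` the whole track is used.
#' @return list with `scale_factor`, `cellular_total`, `naked_total`
#'   (dipyrimidine read totals within regions) and `track` (the scaled
#'   naked track).
#' @export
scale_naked <- function(cellular, naked, regions = NULL) {
  cw <- if (is.null(regions)) cellular else restrict_to_regions(cellular, regions)
  nw <- if (is.null(regions)) naked else restrict_to_regions(naked, regions)
  if (!nrow(cw) || !nrow(nw)) stop("empty track within capture regions")
  cell_total <- sum(cw$count) / 2   # each read contributes two position counts
  naked_total <- sum(nw$count) / 2
  if (naked_total == 0) stop("naked-DNA track has no dipyrimidine reads in regions")
  s <- cell_total / naked_total
  scaled <- naked
  scaled$count <- naked$count * s
  attr(scaled, "condition") <- paste0(attr(naked, "condition") %||% "naked", "_scaled")
  attr(scaled, "scale_factor") <- s
  list(scale_factor = s, cellular_total = cell_total,
       naked_total = naked_total, track = scaled)
}

#' Motif-anchored average damage profile
#'
#' Mean strand-summed counts per motif-strand offset across binding sites,
#' oriented so the pyrimidine-strand motif reads left-to-right (a
#' minus-strand site's genomic left flank maps to positive offsets).
#'
#' @param track a [lesion_track].
#' @param sites site table (`contig, midpoint, strand`).
#' @param halfwidth profile half-width in offsets.
#' @return data frame `offset, mean_count`.
#' @export
motif_profile <- function(track, sites, halfwidth = 10) {
  if (!nrow(sites)) stop("empty site list")
  offs <- seq(-halfwidth, halfwidth)
  m <- vapply(offs, function(off) {
    mean(track_values(track, sites$contig, off_to_pos(sites, off)))
  }, numeric(1))
  data.frame(offset = offs, mean_count = m)
}

flank_positions <- function(sites, window = c(6, 180)) {
  offs <- c(-rev(seq(window[1], window[2])), seq(window[1], window[2]))
  data.frame(
    contig = rep(sites$contig, each = length(offs)),
    pos = as.vector(t(outer(sites$midpoint, offs, `+`))),
    stringsAsFactors = FALSE
  )
}

clip_to_regions <- function(pts, regions) {
  ok <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(regions))) {
    ok <- ok | (pts$contig == regions$contig[i] &
                pts$pos >= regions$start[i] & pts$pos < regions$end[i])
  }
  pts[ok, , drop = FALSE]
}

#' Capture-efficiency filter for binding sites
#'
#' Sites with fewer than `threshold` cellular lesion counts per base pair
#' of flanking DNA (default window 6-180 bp from the midpoint, both sides,
#' clipped to the capture region) are flagged for exclusion: their local
#' capture/sequencing yield is too low for per-site induction analysis.
#'
#' @param sites site table.
#' @param cellular cellular [lesion_track].
#' @param regions capture regions used for clipping.
#' @param window flank window `c(min, max)` in bp from the midpoint.
#' @param threshold minimum mean lesion count per flanking bp.
#' @return logical vector: `TRUE` = keep.
#' @export
capture_filter <- function(sites, cellular, regions = NULL,
                           window = c(6, 180), threshold = 1) {
  offs <- c(-rev(seq(window[1], window[2])), seq(window[1], window[2]))
  n <- nrow(sites)
  site_i <- rep(seq_len(n), each = length(offs))
  ctg <- sites$contig[site_i]
  p <- rep(sites$midpoint, each = length(offs)) + offs
  ok <- rep(TRUE, length(p))
  if (!is.null(regions)) {
    ri <- match(ctg, regions$contig)
    ok <- !is.na(ri) & p >= regions$start[ri] & p < regions$end[ri]
  }
  v <- numeric(length(p))
  v[ok] <- track_values(cellular, ctg[ok], p[ok])
  num <- rowsum(v * ok, site_i)[, 1]
  den <- rowsum(as.numeric(ok), site_i)[, 1]
  as.vector(den > 0 & num / pmax(den, 1) >= threshold)
}

#' Per-site, per-offset CPD induction matrix
#'
#' The cluster-plot substrate: rows are binding sites passing the
#' capture-efficiency filter, columns motif-strand offsets, values the CPD
#' induction (cellular minus scaled naked counts, strand-summed).  Rows
#' are ordered by increasing within-motif induction, summarized as the
#' summed induction at offsets -4, -3, -1, 0, +1.
#'
#' @param cellular,scaled_naked [lesion_track]s (naked already scaled).
#' @param sites site table.
#' @param regions capture regions (for the filter); `NULL` to skip clipping.
#' @param halfwidth matrix half-width in offsets.
#' @param filter apply the capture-efficiency filter.
#' @return numeric matrix with site ids as row names and attributes
#'   `sites` (the retained, reordered site table) and `order_key`.
#' @export
induction_matrix <- function(cellular, scaled_naked, sites, regions = NULL,
                             halfwidth = 10, filter = TRUE) {
  keep <- if (filter) capture_filter(sites, cellular, regions) else
    rep(TRUE, nrow(sites))
  st <- sites[keep, , drop = FALSE]
  offs <- seq(-halfwidth, halfwidth)
  m <- sapply(offs, function(off) {
    p <- off_to_pos(st, off)
    track_values(cellular, st$contig, p) -
      track_values(scaled_naked, st$contig, p)
  })
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(st))
  colnames(m) <- offs
  key_offs <- intersect(c(-4, -3, -1, 0, 1), offs)
  key <- rowSums(m[, as.character(key_offs), drop = FALSE])
  o <- order(key)
  m <- m[o, , drop = FALSE]
  st <- st[o, , drop = FALSE]
  rownames(m) <- st$site_id %||% seq_len(nrow(st))
  attr(m, "sites") <- st
  attr(m, "order_key") <- key[o]
  m
}

## CPD-forming genomic positions: part of a dipyrimidine on either strand
## (pyrimidine with a pyrimidine neighbour, or purine with a purine
## neighbour -- the two cases are mutually exclusive at any one position).
cpd_forming <- function(chars, pos) {
  clen <- length(chars)
  b <- chars[pos + 1L]
  lft <- ifelse(pos - 1L >= 0L, chars[pmax(pos, 1L)], NA)
  rgt <- ifelse(pos + 1L < clen, chars[pmin(pos + 2L, clen)], NA)
  pyr <- b %in% PYRIMIDINES
  pur <- b %in% PURINES
  neigh_pyr <- (!is.na(lft) & lft %in% PYRIMIDINES) |
               (!is.na(rgt) & rgt %in% PYRIMIDINES)
  neigh_pur <- (!is.na(lft) & lft %in% PURINES) |
               (!is.na(rgt) & rgt %in% PURINES)
  (pyr & neigh_pyr) | (pur & neigh_pur)
}

#' Empirical null of CPD induction in flanking DNA
#'
#' Mean and standard deviation of per-position CPD induction (cellular
#' minus scaled naked) over all CPD-forming positions in DNA flanking the
#' binding sites (default 6-180 bp from each midpoint, both sides, clipped
#' to the contig).  Used to Z-score within-motif induction.
#'
#' @param cellular,scaled_naked [lesion_track]s.
#' @param sites site table.
#' @param genome named character vector of contig sequences.
#' @param window flank window in bp from the midpoint.
#' @return list of class `flank_null`: `mu_flank`, `sigma_flank`,
#'   `n_positions`, `window`.
#' @export
flank_null <- function(cellular, scaled_naked, sites, genome,
                       window = c(6, 180)) {
  genome <- check_genome(genome)
  chars <- genome_chars(genome)
  pts <- flank_positions(sites, window)
  pts <- unique(pts)
  ## clip to contig bounds
  clens <- vapply(chars, length, integer(1))
  pts <- pts[pts$pos >= 0L & pts$pos < clens[pts$contig], , drop = FALSE]
  ## keep CPD-forming positions only
  keep <- logical(nrow(pts))
  for (ctg in unique(pts$contig)) {
    ii <- pts$contig == ctg
    keep[ii] <- cpd_forming(chars[[ctg]], pts$pos[ii])
  }
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 100) stop("flank null needs >= 100 CPD-forming positions")
  d <- track_values(cellular, pts$contig, pts$pos) -
       track_values(scaled_naked, pts$contig, pts$pos)
  structure(list(mu_flank = mean(d), sigma_flank = stats::sd(d),
                 n_positions = nrow(pts), window = window),
            class = "flank_null")
}

#' @export
print.flank_null <- function(x, ...) {
  cat(sprintf("flank_null: mu = %.4g, sigma = %.4g over %d CPD-forming positions (%d-%d bp)\n",
              x$mu_flank, x$sigma_flank, x$n_positions, x$window[1], x$window[2]))
  invisible(x)
}

#' Z-score of CPD induction against the flanking null
#'
#' @param induction numeric induction value(s).
#' @param null a [flank_null()] result.
#' @return numeric Z-score(s).
#' @export
induction_z <- function(induction, null) {
  stopifnot(inherits(null, "flank_null"))
  (induction - null$mu_flank) / null$sigma_flank
}
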