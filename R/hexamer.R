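## All hexamers with a central dipyrimidine (2 nt flank + dinucleotide +
## 2 nt flank, read on the lesion strand).
all_dipyr_hexamers <- local({
  b <- c("A", "C", "G", "T")
  di <- c("TT", "TC", "CT", "CC")
  fl <- as.vector(outer(b, b, paste0))
  as.vector(outer(outer(fl, di, paste0), fl, paste0))
})

## Candidate lesion dinucleotide per read (shared by call_lesions-style
## consumers that need read-level resolution): leftmost genomic position,
## lesion strand, and whether the read is retained as a dipyrimidine hit.
read_candidates <- function(reads, genome) {
  genome <- check_genome(genome)
  reads <- as_read_frame(reads)
  fg <- flat_genome(genome)
  ct <- candidate_table(reads, fg)
  data.frame(contig = fg$names[ct$ci], left = ct$left,
             lesion_strand = ifelse(ct$lesion_plus, "+", "-"),
             on_contig = ct$on_contig, retained = ct$retained,
             stringsAsFactors = FALSE)
}

hexamer_counts <- function(reads, genome) {
  genome <- check_genome(genome)
  reads <- as_read_frame(reads)
  fg <- flat_genome(genome)
  ct <- candidate_table(reads, fg)
  kk <- which(ct$retained & ct$left - 2L >= 0L &
              ct$left + 3L < fg$clens[ct$ci])
  dropped_edge <- sum(ct$retained) - length(kk)
  counts <- setNames(numeric(length(all_dipyr_hexamers)), all_dipyr_hexamers)
  if (length(kk)) {
    g0 <- fg$offset[ct$ci[kk]] + ct$left[kk] + 1L   # 1-based flat index of left
    cols <- lapply(-2:3, function(d) fg$chars[g0 + d])
    plus <- ct$lesion_plus[kk]
    hx <- character(length(kk))
    hx[plus] <- do.call(paste0, lapply(cols, `[`, plus))
    if (any(!plus)) {
      comp_cols <- lapply(rev(cols), function(x) comp_base(x[!plus]))
      hx[!plus] <- do.call(paste0, comp_cols)
    }
    valid <- !grepl("N", hx, fixed = TRUE)
    dropped_edge <- dropped_edge + sum(!valid)
    tab <- table(hx[valid])
    idx <- match(names(tab), names(counts))
    counts[idx[!is.na(idx)]] <- counts[idx[!is.na(idx)]] +
      as.numeric(tab[!is.na(idx)])
  }
  attr(counts, "dropped_edge") <- dropped_edge
  counts
}

#' De novo hexamer screen for binding-associated damage modulation
#'
#' Tallies cellular and naked-DNA reads per hexamer sequence context
#' (2 nt flank + lesion dinucleotide + 2 nt flank on the lesion strand,
#' one count per read), and tests each hexamer's cellular share against
#' the expectation implied by the global cellular:naked scaling with a
#' two-sided binomial test, Benjamini-Hochberg corrected.  A hexamer is
#' flagged when `q < q_threshold` and `|log2 ratio| >= lfc_threshold`.
#'
#' @param cellular_reads,naked_reads BED6-style read data frames (read
#'   level, because overlapping dipyrimidine steps make per-read hexamer
#'   attribution unrecoverable from position-level tracks).
#' @param genome named character vector of contig sequences.
#' @param scale_factor optional cellular:naked scale; defaults to the
#'   ratio of retained read totals of the two libraries.
#' @param q_threshold,lfc_threshold significance and effect-size cutoffs.
#' @return data frame per hexamer: `hexamer, dinuc, cellular, naked,
#'   scaled_naked, log2_ratio, p, q, flag` (+1 enriched, -1 depleted, 0
#'   otherwise), with attribute `totals`.
#' @export
hexamer_screen <- function(cellular_reads, naked_reads, genome,
                           scale_factor = NULL,
                           q_threshold = 0.05, lfc_threshold = 1) {
  genome <- check_genome(genome)
  ch <- hexamer_counts(cellular_reads, genome)
  nh <- hexamer_counts(naked_reads, genome)
  ctot <- sum(ch); ntot <- sum(nh)
  if (ctot == 0 || ntot == 0) {
    warning("no central-dipyrimidine hexamer occurrences in one library")
    return(data.frame(hexamer = character(), dinuc = character(),
                      cellular = numeric(), naked = numeric(),
                      scaled_naked = numeric(), log2_ratio = numeric(),
                      p = numeric(), q = numeric(), flag = integer(),
                      stringsAsFactors = FALSE))
  }
  s <- scale_factor %||% (ctot / ntot)
  p0 <- s / (1 + s)
  p <- vapply(seq_along(ch), function(i) {
    n <- ch[i] + nh[i]
    if (n == 0) return(NA_real_)
    binom.test(round(ch[i]), round(n), p = p0)$p.value
  }, numeric(1))
  lfc <- log2(ch / (s * nh))
  q <- p.adjust(p, method = "BH")
  flag <- integer(length(ch))
  sig <- !is.na(q) & q < q_threshold & is.finite(lfc) & abs(lfc) >= lfc_threshold
  flag[sig] <- ifelse(lfc[sig] > 0, 1L, -1L)
  out <- data.frame(
    hexamer = names(ch), dinuc = substr(names(ch), 3, 4),
    cellular = as.numeric(ch), naked = as.numeric(nh),
    scaled_naked = as.numeric(nh) * s,
    log2_ratio = unname(lfc), p = unname(p), q = unname(q), flag = flag,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q, -abs(out$log2_ratio)), ]
  rownames(out) <- NULL
  attr(out, "totals") <- c(cellular = ctot, naked = ntot)
  attr(out, "scale_factor") <- s
  out
}
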