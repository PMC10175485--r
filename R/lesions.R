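#' Per-base putative-CPD lesion tracks
#'
#' A `lesion_track` is a sparse, strand-resolved map from genomic position
#' (0-based) to putative-CPD read counts for one library, stored as a data
#' frame with columns `contig`, `strand`, `pos`, `count`.  Each retained
#' read contributes exactly one count to each of the two positions of its
#' candidate lesion dinucleotide, so the column sum equals twice the number
#' of retained dipyrimidine reads.
#'
#' @name lesion_track
NULL

new_lesion_track <- function(df, sample = "sample", condition = "unknown",
                             total_input_reads = NA_integer_,
                             total_dipyrimidine_reads = NA_integer_,
                             dropped_nonpyr = NA_integer_,
                             dropped_off_contig = NA_integer_) {
  df <- df[order(df$contig, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    class = c("lesion_track", "data.frame"),
    sample = sample, condition = condition,
    total_input_reads = total_input_reads,
    total_dipyrimidine_reads = total_dipyrimidine_reads,
    dropped_nonpyr = dropped_nonpyr,
    dropped_off_contig = dropped_off_contig
  )
}

#' @export
print.lesion_track <- function(x, ...) {
  cat("lesion_track:", attr(x, "sample"), "(", attr(x, "condition"), ")\n")
  cat("  positions with counts:", nrow(x),
      " total count:", sum(x$count), "\n")
  cat("  retained dipyrimidine reads:", attr(x, "total_dipyrimidine_reads"),
      "of", attr(x, "total_input_reads"), "input reads\n")
  invisible(x)
}

## The read-to-lesion offset convention.  The candidate lesion dinucleotide
## lies on the strand OPPOSITE the read's mapped strand, occupying the two
## genomic positions immediately past the read's 5' end: the 3'-OH created
## on the 5' side of the cleaved lesion is ligated to the second adapter, so
## sequencing starts adjacent to, and reads away from, the lesion.  For a
## plus-strand read with leftmost aligned coordinate p the candidate sits at
## (p-2, p-1) on the minus strand; for a minus-strand read with rightmost
## aligned coordinate q it sits at (q+1, q+2) on the plus strand.  A single
## constant so an alternative convention is a one-line change.
LESION_OFFSET <- 2L

candidate_positions <- function(start, end, strand) {
  plus_read <- strand == "+"
  left <- ifelse(plus_read, start - LESION_OFFSET, end)
  list(left = as.integer(left),
       lesion_strand = ifelse(plus_read, "-", "+"))
}

## Flat-genome index shared by the hot paths: contig sequences are
## concatenated conceptually; a (contig, pos) pair maps to offset + pos.
flat_genome <- function(genome) {
  chars <- genome_chars(genome)
  clens <- vapply(chars, length, integer(1))
  all_chars <- unlist(chars, use.names = FALSE)
  list(names = names(genome), clens = clens,
       offset = c(0L, cumsum(clens))[seq_along(clens)],
       chars = all_chars,
       is_pyr = all_chars %in% PYRIMIDINES,
       is_pur = all_chars %in% PURINES,
       total = sum(clens))
}

## Vectorized candidate-lesion resolution for all reads at once.
## Returns 0-based left position of the candidate dinucleotide, whether
## the lesion strand is plus, the contig index, and retention status.
candidate_table <- function(reads, fg) {
  ci <- match(reads$chrom, fg$names)
  if (anyNA(ci)) {
    stop("contig(s) absent from genome: ",
         paste(unique(reads$chrom[is.na(ci)]), collapse = ", "))
  }
  bad_strand <- !(reads$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("malformed strand value(s): ",
         paste(unique(reads$strand[bad_strand]), collapse = ", "))
  }
  plus_read <- reads$strand == "+"
  left <- integer(nrow(reads))
  left[plus_read] <- reads$start[plus_read] - LESION_OFFSET
  left[!plus_read] <- reads$end[!plus_read]
  lesion_plus <- !plus_read
  on_ctg <- left >= 0L & left + 1L < fg$clens[ci]
  retained <- logical(nrow(reads))
  ii <- which(on_ctg)
  g1 <- fg$offset[ci[ii]] + left[ii] + 1L
  lp <- lesion_plus[ii]
  retained[ii] <- (lp & fg$is_pyr[g1] & fg$is_pyr[g1 + 1L]) |
                  (!lp & fg$is_pur[g1] & fg$is_pur[g1 + 1L])
  list(ci = ci, left = left, lesion_plus = lesion_plus,
       on_contig = on_ctg, retained = retained)
}

#' Call putative CPD lesions from aligned read positions
#'
#' Converts aligned read positions (BED6, 0-based half-open) into a
#' strand-resolved per-base count track, retaining only reads whose
#' candidate lesion dinucleotide is a dipyrimidine (TT/TC/CT/CC read
#' 5'->3' on the lesion strand).  Each retained read adds one count at
#' each of the two dinucleotide positions on the lesion strand.  Reads
#' whose candidate dinucleotide falls off the contig are dropped and
#' tallied separately.
#'
#' @param reads data frame with columns `chrom, start, end, strand`
#'   (BED6-style, 0-based half-open), or a `GRanges`.
#' @param genome named character vector of contig sequences (or
#'   `DNAStringSet`).
#' @param sample,condition metadata stored on the track.
#' @return a [lesion_track].
#' @export
call_lesions <- function(reads, genome, sample = "sample", condition = "unknown") {
  genome <- check_genome(genome)
  reads <- as_read_frame(reads)
  fg <- flat_genome(genome)
  ct <- candidate_table(reads, fg)

  n_off <- sum(!ct$on_contig)
  n_kept <- sum(ct$retained)
  n_nonpyr <- nrow(reads) - n_kept - n_off

  kk <- which(ct$retained)
  g0 <- fg$offset[ct$ci[kk]] + ct$left[kk]          # 0-based flat position
  strand_shift <- ifelse(ct$lesion_plus[kk], 0L, fg$total)
  idx <- c(g0, g0 + 1L) + 1L + rep(strand_shift, 2L)
  cnt <- tabulate(idx, nbins = 2L * fg$total)
  nz <- which(cnt > 0L)
  if (length(nz)) {
    minus <- nz > fg$total
    flat0 <- ifelse(minus, nz - fg$total, nz) - 1L
    ctg_i <- findInterval(flat0, c(fg$offset, fg$total), rightmost.closed = FALSE)
    df <- data.frame(
      contig = fg$names[ctg_i],
      strand = ifelse(minus, "-", "+"),
      pos = flat0 - fg$offset[ctg_i],
      count = as.numeric(cnt[nz]),
      stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(contig = character(), strand = character(),
                     pos = integer(), count = numeric(),
                     stringsAsFactors = FALSE)
  }
  new_lesion_track(df, sample = sample, condition = condition,
                   total_input_reads = nrow(reads),
                   total_dipyrimidine_reads = n_kept,
                   dropped_nonpyr = n_nonpyr,
                   dropped_off_contig = n_off)
}

#' Dinucleotide composition of candidate lesions
#'
#' Classifies every read's candidate lesion dinucleotide (5'->3' on the
#' lesion strand) as TT, TC, CT, CC or other, and returns the fraction of
#' input reads in each class.  Reads whose candidate falls off the contig
#' are counted as "other".
#'
#' @inheritParams call_lesions
#' @return named numeric vector over `TT, TC, CT, CC, other`; sums to 1.
#' @export
dinucleotide_fractions <- function(reads, genome) {
  genome <- check_genome(genome)
  reads <- as_read_frame(reads)
  if (!nrow(reads)) stop("empty read set")
  fg <- flat_genome(genome)
  ct <- candidate_table(reads, fg)
  cls <- rep("other", nrow(reads))
  ii <- which(ct$on_contig)
  g1 <- fg$offset[ct$ci[ii]] + ct$left[ii] + 1L
  b1 <- fg$chars[g1]; b2 <- fg$chars[g1 + 1L]
  ## 5'->3' on the lesion strand: plus-strand lesions read b1 b2; minus-
  ## strand lesions read comp(b2) comp(b1).
  lp <- ct$lesion_plus[ii]
  dinuc <- character(length(ii))
  dinuc[lp] <- paste0(b1[lp], b2[lp])
  dinuc[!lp] <- paste0(comp_base(b2[!lp]), comp_base(b1[!lp]))
  dinuc[!dinuc %in% c("TT", "TC", "CT", "CC")] <- "other"
  cls[ii] <- dinuc
  tab <- table(factor(cls, levels = c("TT", "TC", "CT", "CC", "other")))
  setNames(as.numeric(tab) / nrow(reads), names(tab))
}

## Both-strand-summed counts at given genomic positions.  A genomic
## position can host counts on only one strand (it is a pyrimidine on
## exactly one strand), so this is a plain aggregation.
track_values <- function(track, contig, pos) {
  key <- paste(track$contig, track$pos)
  agg <- rowsum(track$count, key)
  q <- paste(contig, pos)
  v <- agg[match(q, rownames(agg)), 1L]
  v[is.na(v)] <- 0
  unname(v)
}

#' Average lesion density around region centers, by region class
#'
#' Strand-summed counts averaged across the regions of each class, aligned
#' on the region centers (Fig-1e-style damage-density profiles).
#'
#' @param track a [lesion_track].
#' @param regions data frame with columns `contig, start, end, class`
#'   (0-based half-open).
#' @param halfwidth profile half-width in bp.
#' @return data frame with columns `class, offset, mean_count`.
#' @export
region_density_profile <- function(track, regions, halfwidth = 360) {
  stopifnot(all(c("contig", "start", "end", "class") %in% names(regions)))
  offs <- seq(-halfwidth, halfwidth)
  res <- lapply(split(regions, regions$class), function(rg) {
    centers <- floor((rg$start + rg$end) / 2)
    m <- matrix(0, nrow = nrow(rg), ncol = length(offs))
    for (i in seq_len(nrow(rg))) {
      p <- centers[i] + offs
      ok <- p >= rg$start[i] & p < rg$end[i]
      m[i, ok] <- track_values(track, rg$contig[i], p[ok])
    }
    data.frame(class = rg$class[1], offset = offs,
               mean_count = colMeans(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
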