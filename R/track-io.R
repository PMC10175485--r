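track_file <- function(prefix, strand) {
  paste0(prefix, if (strand == "+") ".plus.bedGraph" else ".minus.bedGraph")
}

#' Write a lesion track as a pair of bedGraph files
#'
#' One file per strand (`<prefix>.plus.bedGraph` / `<prefix>.minus.bedGraph`),
#' 0-based half-open single-base intervals, one line per counted position.
#'
#' @param track a [lesion_track].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_track <- function(track, prefix) {
  paths <- c(track_file(prefix, "+"), track_file(prefix, "-"))
  for (k in 1:2) {
    str <- c("+", "-")[k]
    sub <- track[track$strand == str, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      sub$contig, IRanges::IRanges(start = sub$pos + 1L, width = 1L),
      score = sub$count
    )
    rtracklayer::export(gr, paths[k], format = "bedGraph")
  }
  invisible(paths)
}

#' Read a lesion track from a pair of bedGraph files
#'
#' Inverse of [write_track()]; intervals wider than one base are expanded
#' to per-position counts.  Intervals that overlap (would double-count a
#' position) are an error.
#'
#' @param prefix path prefix used by [write_track()].
#' @param sample,condition metadata for the reconstructed track.
#' @return a [lesion_track].
#' @export
read_track <- function(prefix, sample = basename(prefix), condition = "unknown") {
  parts <- lapply(c("+", "-"), function(str) {
    path <- track_file(prefix, str)
    if (!file.exists(path)) stop("missing track file: ", path)
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!length(gr)) {
      return(data.frame(contig = character(), strand = character(),
                        pos = integer(), count = numeric(),
                        stringsAsFactors = FALSE))
    }
    w <- GenomicRanges::width(gr)
    df <- data.frame(
      contig = rep(as.character(GenomicRanges::seqnames(gr)), w),
      strand = str,
      pos = unlist(lapply(seq_along(gr), function(i) {
        seq(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)
      })),
      count = rep(gr$score, w),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(paste(df$contig, df$pos))) {
      stop("overlapping intervals in ", path)
    }
    df
  })
  new_lesion_track(do.call(rbind, parts), sample = sample, condition = condition,
                   total_dipyrimidine_reads = sum(parts[[1]]$count, parts[[2]]$count) / 2)
}
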