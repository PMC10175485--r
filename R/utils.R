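#' @importFrom stats rpois rbinom rnorm runif rlnorm rgamma qnorm pnorm
#'   setNames aggregate p.adjust binom.test wilcox.test cor optim
#' @importFrom utils read.table write.table
#' @importFrom methods is
NULL

PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

#' Derive a child seed from a master seed and a stage tag
#'
#' One global seed fans out to per-stage streams by stable arithmetic
#' derivation, so adding a stage never perturbs the streams of earlier
#' stages. The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param tag character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

comp_base <- function(x) chartr("ACGTacgtN", "TGCAtgcaN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## Split a genome (named character vector) into per-contig character vectors
## of single bases.  Used by the hot paths; computed once per call.
genome_chars <- function(genome) {
  lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

check_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == "")) {
    stop("genome must be a named character vector of contig sequences or a DNAStringSet")
  }
  genome
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a reference genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  genome <- check_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read aligned read positions from a BED6 file
#'
#' Coordinates are 0-based half-open, as in BED.
#'
#' @param path BED file with at least 6 columns.
#' @return data frame with columns `chrom, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write aligned read positions (or regions) to a BED6 file
#'
#' @param bed data frame with columns `chrom, start, end` and optionally
#'   `name, score, strand` (0-based half-open coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  if (!"chrom" %in% names(bed) && "contig" %in% names(bed)) {
    names(bed)[names(bed) == "contig"] <- "chrom"
  }
  strand <- if ("strand" %in% names(bed)) bed$strand else "*"
  gr <- GenomicRanges::GRanges(
    bed$chrom,
    IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = strand
  )
  if ("name" %in% names(bed)) gr$name <- bed$name
  gr$score <- if ("score" %in% names(bed)) bed$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

as_read_frame <- function(reads) {
  if (is(reads, "GRanges")) {
    reads <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(reads)),
      start = GenomicRanges::start(reads) - 1L,
      end = GenomicRanges::end(reads),
      name = ".",
      score = 0,
      strand = as.character(GenomicRanges::strand(reads)),
      stringsAsFactors = FALSE
    )
  }
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(reads))) {
    stop("reads must have columns chrom, start, end, strand (BED6)")
  }
  reads
}

`%||%` <- function(a, b) if (is.null(a)) b else a
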