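## Shared simulated cohorts, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## 40 variant ETS sites, default damage model
small_cohort <- function() {
  cached("small_cohort", function() simulate_cohort(n_sites = 40, seed = 11))
}

## canonical ETS sites with read tables retained (hexamer screen input)
canonical_cohort <- function() {
  cached("canonical_cohort", function() {
    simulate_cohort(n_sites = 40, seed = 3, kind = "ETS_canonical",
                    keep_reads = TRUE)
  })
}

variant_sites <- function(cohort) cohort$sites[cohort$sites$variant, , drop = FALSE]

## independent brute-force lesion caller: enumerates every dipyrimidine of
## the genome by string inspection and matches reads positionally, one read
## at a time.  Deliberately naive; used as the oracle for call_lesions.
brute_force_track <- function(reads, genome) {
  counts <- list()
  bump <- function(ctg, strand, pos) {
    key <- paste(ctg, strand, pos)
    counts[[key]] <<- (counts[[key]] %||% 0) + 1
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in seq_len(nrow(reads))) {
    ctg <- reads$chrom[i]
    seq <- genome[[ctg]]
    if (reads$strand[i] == "+") {
      p <- reads$start[i]
      lo <- p - 2; strand <- "-"
    } else {
      q <- reads$end[i] - 1
      lo <- q + 1; strand <- "+"
    }
    if (lo < 0 || lo + 1 >= nchar(seq)) next
    b1 <- substr(seq, lo + 1, lo + 1)
    b2 <- substr(seq, lo + 2, lo + 2)
    if (strand == "+") {
      dinuc <- c(b1, b2)
    } else {
      dinuc <- c(comp[[b2]], comp[[b1]])
    }
    if (all(dinuc %in% c("C", "T"))) {
      bump(ctg, strand, lo); bump(ctg, strand, lo + 1)
    }
  }
  if (!length(counts)) {
    return(data.frame(contig = character(), strand = character(),
                      pos = integer(), count = numeric()))
  }
  parts <- strsplit(names(counts), " ", fixed = TRUE)
  df <- data.frame(
    contig = vapply(parts, `[`, "", 1),
    strand = vapply(parts, `[`, "", 2),
    pos = as.integer(vapply(parts, `[`, "", 3)),
    count = as.numeric(unlist(counts)),
    stringsAsFactors = FALSE
  )
  df[order(df$contig, df$strand, df$pos), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genome <- function(n_contigs, len, seed) {
  set.seed(seed)
  g <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(g) <- paste0("ctg", seq_len(n_contigs))
  g
}

random_reads <- function(genome, n, seed) {
  set.seed(seed)
  ctg <- sample(names(genome), n, replace = TRUE)
  len <- nchar(genome)[ctg]
  start <- vapply(len, function(L) sample.int(L - 5L, 1L) - 1L, integer(1))
  data.frame(chrom = ctg, start = start,
             end = pmin(start + 5L, len), name = ".", score = 0,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

## mirror a read table onto the reverse-complemented genome
mirror_reads <- function(reads, genome) {
  L <- nchar(genome)[reads$chrom]
  data.frame(chrom = reads$chrom,
             start = L - reads$end,
             end = L - reads$start,
             name = reads$name, score = reads$score,
             strand = ifelse(reads$strand == "+", "-", "+"),
             stringsAsFactors = FALSE)
}

revcomp_genome <- function(genome) {
  rc <- vapply(genome, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1))
  names(rc) <- names(genome)
  rc
}
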