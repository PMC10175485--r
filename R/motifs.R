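ETS_PENTAMERS <- c(TTCCG = 2L, CTTCC = 3L)  # offset of core's first C from match start

find_fixed <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based
}

#' Scan a sequence for ETS core binding motifs
#'
#' Finds the fixed-string pentamers `TTCCG` and `CTTCC` on the given
#' sequence and their reverse complements on the opposite strand.  The
#' site midpoint is the 0-based position of the first C of the TTCC core
#' on the pyrimidine (motif) strand; overlapping matches of both pentamers
#' around one core (`CTTCCG`) merge into one site.  Sites are classified
#' `variant` when the pyrimidine-strand bases at offsets -4/-3 from the
#' midpoint are both pyrimidines.  Sites with an N anywhere in offsets
#' -4..+2 are dropped and tallied in the `n_dropped` attribute.
#'
#' @param seq character scalar sequence over `A,C,G,T,N`.
#' @param contig contig name recorded on the output.
#' @param offset constant added to all reported positions (for scanning a
#'   subsequence of a larger contig).
#' @return data frame `contig, midpoint, strand, pentamer, variant` with
#'   attribute `n_dropped`.
#' @export
scan_ets <- function(seq, contig = "seq", offset = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  clen <- length(chars)

  hits <- list()
  for (pent in names(ETS_PENTAMERS)) {
    at <- find_fixed(seq, pent)
    if (length(at)) {
      hits[[length(hits) + 1L]] <- data.frame(
        midpoint = at + ETS_PENTAMERS[[pent]], strand = "+",
        pentamer = pent, stringsAsFactors = FALSE
      )
    }
  }
  ## reverse complements: a minus-strand TTCCG appears as CGGAA on the plus
  ## strand (midpoint = match start + 2); CTTCC appears as GGAAG
  ## (midpoint = match start + 1).
  rc <- c(CGGAA = 2L, GGAAG = 1L)
  rc_pent <- c(CGGAA = "TTCCG", GGAAG = "CTTCC")
  for (pat in names(rc)) {
    at <- find_fixed(seq, pat)
    if (length(at)) {
      hits[[length(hits) + 1L]] <- data.frame(
        midpoint = at + rc[[pat]], strand = "-",
        pentamer = rc_pent[[pat]], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    out <- data.frame(contig = character(), midpoint = integer(),
                      strand = character(), pentamer = character(),
                      variant = logical(), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  df <- do.call(rbind, hits)
  ## merge the two pentamers around one core
  key <- paste(df$midpoint, df$strand)
  dup <- duplicated(key)
  both <- key %in% key[dup]
  df$pentamer[both] <- "both"
  df <- df[!dup, , drop = FALSE]

  ## offsets -4..+2 on the motif strand, as genomic positions
  rel <- -4:2
  n_dropped <- 0L
  keep <- logical(nrow(df)); variant <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    gp <- if (df$strand[i] == "+") df$midpoint[i] + rel else df$midpoint[i] - rel
    if (any(gp < 0L | gp >= clen)) { n_dropped <- n_dropped + 1L; next }
    bases <- chars[gp + 1L]
    if (df$strand[i] == "-") bases <- comp_base(bases)
    if (any(bases == "N")) { n_dropped <- n_dropped + 1L; next }
    keep[i] <- TRUE
    variant[i] <- all(bases[rel %in% c(-4L, -3L)] %in% PYRIMIDINES)
  }
  out <- data.frame(contig = rep(contig, sum(keep)),
                    midpoint = df$midpoint[keep] + offset,
                    strand = df$strand[keep],
                    pentamer = df$pentamer[keep],
                    variant = variant[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$midpoint, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Scan every contig of a genome for ETS motifs
#'
#' @param genome named character vector of contig sequences.
#' @return combined [scan_ets()] output with a `site_id` column.
#' @export
scan_genome_ets <- function(genome) {
  genome <- check_genome(genome)
  res <- lapply(names(genome), function(ctg) scan_ets(genome[[ctg]], ctg))
  out <- do.call(rbind, res)
  attr(out, "n_dropped") <- sum(vapply(res, attr, integer(1), "n_dropped"))
  if (nrow(out)) out$site_id <- sprintf("ets_%05d", seq_len(nrow(out)))
  out
}

#' Classify an ETS site as canonical or variant
#'
#' Variant sites carry a pyrimidine dinucleotide at offsets -4/-3 from the
#' motif midpoint on the pyrimidine strand; canonical sites do not.  Sites
#' with an N at those offsets are excluded (`NA`) with a warning.
#'
#' @param site one-row site data frame (`contig, midpoint, strand`).
#' @param genome named character vector of contig sequences.
#' @return `"variant"`, `"canonical"`, or `NA`.
#' @export
classify_variant <- function(site, genome) {
  genome <- check_genome(genome)
  chars <- genome_chars(genome)[[site$contig]]
  gp <- if (site$strand == "+") site$midpoint + c(-4L, -3L) else
    site$midpoint - c(-4L, -3L)
  if (any(gp < 0L | gp >= length(chars))) {
    warning("site offsets -4/-3 fall outside the contig; excluded")
    return(NA_character_)
  }
  bases <- chars[gp + 1L]
  if (site$strand == "-") bases <- comp_base(bases)
  if (any(bases == "N")) {
    warning("N at offsets -4/-3; site excluded from classification")
    return(NA_character_)
  }
  if (all(bases %in% PYRIMIDINES)) "variant" else "canonical"
}

ETS_OVERLAP_OFFSETS <- c(-4L, -3L, 0L, 1L)

#' Annotate recurrent mutations with ETS motif overlap
#'
#' A mutation overlaps an ETS site when its position equals the site
#' midpoint plus one of the offsets -4, -3, 0, +1 (strand-aware).  When
#' several sites qualify, the nearest midpoint wins; remaining ties prefer
#' the site whose motif strand matches the strand on which the mutation's
#' reference base is a pyrimidine.  Idempotent.
#'
#' @param catalog mutation data frame (`contig, position`, optionally `ref`).
#' @param sites ETS site table (`contig, midpoint, strand`).
#' @return `catalog` with columns `ets_overlap`, `ets_offset`,
#'   `ets_midpoint` replaced/added.
#' @export
annotate_mutations <- function(catalog, sites) {
  catalog$ets_overlap <- FALSE
  catalog$ets_offset <- NA_integer_
  catalog$ets_midpoint <- NA_integer_
  if (!nrow(sites) || !nrow(catalog)) return(catalog)
  ## expand sites over the qualifying offsets
  exp <- do.call(rbind, lapply(ETS_OVERLAP_OFFSETS, function(off) {
    data.frame(contig = sites$contig,
               pos = off_to_pos(sites, off),
               midpoint = sites$midpoint,
               strand = sites$strand,
               offset = off, stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(catalog))) {
    hit <- exp[exp$contig == catalog$contig[i] & exp$pos == catalog$position[i], ,
               drop = FALSE]
    if (!nrow(hit)) next
    if (nrow(hit) > 1L) {
      d <- abs(catalog$position[i] - hit$midpoint)
      hit <- hit[d == min(d), , drop = FALSE]
      if (nrow(hit) > 1L && "ref" %in% names(catalog)) {
        pref <- if (catalog$ref[i] %in% PYRIMIDINES) "+" else "-"
        pick <- hit$strand == pref
        if (any(pick)) hit <- hit[pick, , drop = FALSE]
      }
      hit <- hit[1L, , drop = FALSE]
    }
    catalog$ets_overlap[i] <- TRUE
    catalog$ets_offset[i] <- hit$offset
    catalog$ets_midpoint[i] <- hit$midpoint
  }
  catalog
}

#' Distance of each mutation to its gene's transcription start site
#'
#' @param catalog mutation data frame with a `gene` column.
#' @param tss data frame `gene, contig, tss_pos` (0-based).
#' @return `catalog` with `tss_distance` (absolute bp; `NA` with
#'   `tss_missing = TRUE` when the gene is absent from the table).
#' @export
tss_distance <- function(catalog, tss) {
  stopifnot(all(c("gene", "tss_pos") %in% names(tss)))
  i <- match(catalog$gene, tss$gene)
  catalog$tss_distance <- abs(catalog$position - tss$tss_pos[i])
  catalog$tss_missing <- is.na(i)
  catalog
}
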