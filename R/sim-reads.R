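## Truncated lognormal capture-efficiency draws: real capture panels have a
## bounded efficiency range (probe design mitigates extremes), and an
## unbounded lognormal occasionally produces regions whose damage counts
## imply physically impossible mutation recurrence.  Truncation at +/- 1.5
## SD on the log scale keeps the spread that identifies the regression
## coefficients while bounding the per-site rate range.
rtlnorm <- function(n, sdlog, z = 1.5) {
  u <- runif(n, pnorm(-z), pnorm(z))
  exp(sdlog * qnorm(u))
}

## Enumerate CPD-formable dinucleotide base steps of one contig, on both
## strands, restricted to steps whose simulated read stays on the contig.
## Returns leftmost genomic position, lesion strand, and the dinucleotide
## class read 5'->3' on the lesion strand.
enumerate_pairs <- function(chars) {
  clen <- length(chars)
  if (clen < 3L) {
    return(data.frame(left = integer(), strand = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  pyr <- chars %in% PYRIMIDINES
  pur <- chars %in% PURINES
  i <- seq_len(clen - 1L)                       # pair (i, i+1), 1-based here
  plus_pair <- pyr[i] & pyr[i + 1L]             # lesion on + strand
  minus_pair <- pur[i] & pur[i + 1L]            # lesion on - strand
  left0 <- i - 1L                               # 0-based leftmost position
  ## a plus-strand lesion at (p, p+1) is reported by a minus-strand read
  ## ending at p, so p >= 1; a minus-strand lesion is reported by a
  ## plus-strand read starting at p+2, so p+2 <= clen-1.
  pl <- which(plus_pair & left0 >= 1L)
  mi <- which(minus_pair & left0 <= clen - 3L)
  data.frame(
    left = c(left0[pl], left0[mi]),
    strand = c(rep("+", length(pl)), rep("-", length(mi))),
    class = c(paste0(chars[pl], chars[pl + 1L]),
              paste0(comp_base(chars[mi + 1L]), comp_base(chars[mi]))),
    stringsAsFactors = FALSE
  )
}

## Map each base step of a contig to its bound-motif induction factor
## (1 when no factor applies).  Factors are keyed by the 5'-most offset of
## the step on the motif's pyrimidine strand and only apply to steps on
## that strand.
pair_factors <- function(pairs, sites, induction) {
  f <- rep(1, nrow(pairs))
  if (!nrow(sites)) return(f)
  for (k in seq_len(nrow(sites))) {
    if (!isTRUE(sites$bound[k])) next
    imap <- induction[[sites$kind[k]]]
    if (!length(imap)) next
    m <- sites$midpoint[k]
    on_strand <- pairs$strand == sites$strand[k]
    key <- if (sites$strand[k] == "+") pairs$left - m else m - pairs$left - 1L
    hit <- on_strand & as.character(key) %in% names(imap)
    if (any(hit)) f[hit] <- f[hit] * imap[as.character(key[hit])]
  }
  f
}

#' Simulate an aligned-read library from a synthetic genome
#'
#' For the `cellular` and `naked` conditions every CPD-formable base step
#' receives a Poisson read count with mean proportional to sequencing
#' depth, the dinucleotide-class base rate, the region's capture
#' efficiency, and (cellular only, at bound planted motifs) the induction
#' factor.  Each simulated lesion is emitted as one read whose mapped 5'
#' end sits immediately past the lesion on the opposite strand, so
#' [call_lesions()] inverts the simulation exactly.  All conditions also
#' receive uniform background (noise) reads; `no_uv` receives only those.
#'
#' Capture efficiency is lognormal per region (seeded from the parameter
#' seed only, hence shared between the matched cellular and naked calls)
#' times a per-library lognormal jitter.
#'
#' @param gen a [make_genome()] result.
#' @param params a [damage_params()].
#' @param condition one of `"cellular"`, `"naked"`, `"no_uv"`.
#' @return BED6-style data frame (`chrom, start, end, name, score, strand`,
#'   0-based half-open) with attributes `condition` and `latent_pairs`
#'   (the per-step latent lesion counts, for round-trip checks).
#' @export
simulate_reads <- function(gen, params, condition = c("cellular", "naked", "no_uv")) {
  stopifnot(inherits(gen, "uv_genome"), inherits(params, "damage_params"))
  condition <- match.arg(condition)
  genome <- gen$genome
  chars <- genome_chars(genome)
  n_regions <- length(genome)

  region_eff <- with_seed(derive_seed(params$seed, "region-efficiency"),
                          rtlnorm(n_regions, params$efficiency_sdlog))
  lib_eff <- with_seed(derive_seed(params$seed, paste0("lib-eff-", condition)),
                       rtlnorm(n_regions, params$library_sdlog))

  chrom <- list(); start <- list(); end <- list(); strand <- list()
  latent <- list()
  rl <- params$read_length

  with_seed(derive_seed(params$seed, paste0("reads-", condition)), {
    for (ri in seq_len(n_regions)) {
      ctg <- names(genome)[ri]
      clen <- length(chars[[ri]])
      if (condition != "no_uv") {
        pairs <- enumerate_pairs(chars[[ri]])
        rate <- unname(params$base_rate[pairs$class])
        fac <- if (condition == "cellular") {
          pair_factors(pairs, gen$sites[gen$sites$contig == ctg, , drop = FALSE],
                       params$induction)
        } else rep(1, nrow(pairs))
        lam <- params$sequencing_depth * rate * fac *
          region_eff[ri] * lib_eff[ri] / sum(rate)
        cnt <- rpois(length(lam), lam)
        nz <- which(cnt > 0L)
        if (length(nz)) {
          lf <- rep.int(pairs$left[nz], cnt[nz])
          st <- rep.int(pairs$strand[nz], cnt[nz])
          plus_lesion <- st == "+"
          ## plus-strand lesion -> minus-strand read ending at the lesion's
          ## left position; minus-strand lesion -> plus-strand read
          ## starting just past it.
          rs <- ifelse(plus_lesion, pmax(0L, lf - rl), lf + 2L)
          re <- ifelse(plus_lesion, lf, pmin(clen, lf + 2L + rl))
          chrom[[length(chrom) + 1L]] <- rep.int(ctg, length(lf))
          start[[length(start) + 1L]] <- as.integer(rs)
          end[[length(end) + 1L]] <- as.integer(re)
          strand[[length(strand) + 1L]] <- ifelse(plus_lesion, "-", "+")
        }
        latent[[length(latent) + 1L]] <-
          data.frame(contig = ctg, left = pairs$left, strand = pairs$strand,
                     class = pairs$class, count = cnt,
                     stringsAsFactors = FALSE)
      }
      ## uniform background reads (noise floor / no-UV library)
      nbg <- rpois(1L, params$background_rate * 2 * clen)
      if (nbg > 0L) {
        bpos <- sample.int(clen, nbg, replace = TRUE) - 1L
        bstr <- sample(c("+", "-"), nbg, replace = TRUE)
        plus_read <- bstr == "+"
        rs <- ifelse(plus_read, bpos, pmax(0L, bpos - rl + 1L))
        re <- ifelse(plus_read, pmin(clen, bpos + rl), bpos + 1L)
        chrom[[length(chrom) + 1L]] <- rep.int(ctg, nbg)
        start[[length(start) + 1L]] <- as.integer(rs)
        end[[length(end) + 1L]] <- as.integer(re)
        strand[[length(strand) + 1L]] <- bstr
      }
    }
  })

  reads <- data.frame(
    chrom = unlist(chrom) %||% character(),
    start = unlist(start) %||% integer(),
    end = unlist(end) %||% integer(),
    name = ".", score = 0,
    strand = unlist(strand) %||% character(),
    stringsAsFactors = FALSE
  )
  attr(reads, "condition") <- condition
  lt <- if (length(latent)) do.call(rbind, latent) else NULL
  attr(reads, "latent_pairs") <- lt
  attr(reads, "region_efficiency") <- setNames(region_eff, names(genome))
  reads
}
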