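## Planted motif contexts, written 5'->3' on the motif's pyrimidine strand,
## spanning offsets -5..+4 around the motif midpoint (string index 6 is
## offset 0).  For ETS motifs the midpoint is the first C of the TTCC core,
## which makes the conventional offsets self-consistent: the TC base step at
## -1/0, CC at 0/+1, and (for variant sites) a dipyrimidine at -4/-3.  The
## variant context reproduces the STK19 D89 promoter-proximal exon context;
## the canonical context carries a purine at -4 so the -4/-3 step cannot
## form a CPD.
MOTIF_CONTEXTS <- c(
  ETS_variant   = "GTCTTCCGGC",
  ETS_canonical = "GACTTCCGAG",
  NFY           = "CGGATTGGCT",
  AP1           = "TTGACTCAGC",
  SRF           = "CCATATATGG"
)
MOTIF_CONTEXT_OFFSET <- -5L  # offset of the first context base from midpoint

## Occupancy-dependent damage multipliers, keyed by the 5'-most offset of a
## dipyrimidine base step on the motif strand.  Applied in the cellular
## library only, at bound sites.  Chosen so that, with the default base
## rates and a 0.65 bound fraction, the aggregate cellular:scaled-naked
## ratio at -4/-3 of variant sites calibrates to ~7 and the cellular
## -4/-3 : -1/0 ratio to ~4 (adjacent base steps share profile positions,
## so the unboosted TT core at -2/-1 contributes to the -1/0 profile; the
## multipliers below account for that).  The x0.3 entries emulate
## binding-dependent protection of the CT step (and the core TT).
DEFAULT_INDUCTION <- list(
  ETS_variant   = c("-4" = 12.5, "-3" = 0.3, "-2" = 0.3, "-1" = 1.5, "0" = 1.5),
  ETS_canonical = c("-3" = 0.3, "-1" = 3, "0" = 3),
  NFY           = c("-1" = 5),
  AP1           = c("-1" = 0.3, "0" = 0.3),
  SRF           = numeric(0)
)

## Relative CPD formation rates per dinucleotide class.  Absolute
## per-dinucleotide formation rates are not well established; these are
## documented generator constants that make TT dominant, matching the
## qualitative ordering of observed dipyrimidine read fractions.
DEFAULT_BASE_RATE <- c(TT = 1.0, TC = 0.5, CT = 0.2, CC = 0.3)

#' Specification of a synthetic capture-region genome
#'
#' @param n_regions number of capture regions (one contig each).
#' @param region_length region length in bp (default 720, the typical
#'   capture-region size).
#' @param planted_motifs data frame with columns `region` (1-based region
#'   index), `offset` (0-based midpoint position within the region),
#'   `kind` (one of `ETS_canonical, ETS_variant, NFY, AP1, SRF`),
#'   `bound` (logical) and optionally `strand` (`+`/`-`; random if absent).
#' @param gc_background background GC fraction.
#' @param region_class optional character vector of region class labels
#'   (recycled); defaults to `"ETS"` for regions with an ETS motif,
#'   `"TFBS"` for other planted motifs and `"coding"` otherwise.
#' @param seed integer seed; fully determines the output.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_regions, region_length = 720, planted_motifs = NULL,
                        gc_background = 0.5, region_class = NULL, seed = 1) {
  stopifnot(n_regions >= 1, region_length >= 41,
            gc_background > 0, gc_background < 1)
  if (is.null(planted_motifs)) {
    planted_motifs <- data.frame(region = integer(), offset = integer(),
                                 kind = character(), bound = logical(),
                                 stringsAsFactors = FALSE)
  }
  pm <- planted_motifs
  stopifnot(all(c("region", "offset", "kind", "bound") %in% names(pm)))
  if (!all(pm$kind %in% names(MOTIF_CONTEXTS))) {
    stop("unknown motif kind(s): ",
         paste(setdiff(pm$kind, names(MOTIF_CONTEXTS)), collapse = ", "))
  }
  if (any(pm$region < 1 | pm$region > n_regions)) stop("motif region index out of range")
  ## the 10 bp context plus strand mirroring needs offsets in [6, len - 7]
  if (any(pm$offset < 6 | pm$offset > region_length - 7)) {
    stop("motif offset places context outside the region")
  }
  for (r in unique(pm$region)) {
    off <- sort(pm$offset[pm$region == r])
    if (length(off) > 1 && any(diff(off) < 10)) {
      stop("overlapping planted motifs in region ", r)
    }
  }
  structure(list(n_regions = as.integer(n_regions),
                 region_length = as.integer(region_length),
                 planted_motifs = pm, gc_background = gc_background,
                 region_class = region_class, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Damage-model parameters for the read and mutation simulators
#'
#' @param sequencing_depth expected aligned reads per capture region at
#'   unit capture efficiency (default 21600, i.e. about 30 reads per bp of
#'   a 720 bp region, a hybridization-capture-scale depth).
#' @param base_rate relative CPD formation rate per dinucleotide class.
#' @param induction named list: motif kind -> named vector of multiplicative
#'   damage factors keyed by the 5'-most motif-strand offset of the
#'   affected base step.  Applied in the cellular library at bound sites
#'   only; the naked library never sees them.
#' @param background_rate expected non-lesion (noise) reads per strand
#'   position; the no-UV library contains only these.
#' @param glm_beta0,glm_beta_cell,glm_beta_naked coefficients of the
#'   log-linear mutation model (mutation count per site ~
#'   Poisson(exp(b0 + b_cell C + b_naked N)) with C, N the cellular/naked
#'   CPD counts summed over the -4/-3 positions).  The slope defaults are
#'   the published regression coefficients; the intercept is a calibration
#'   constant chosen so per-site means stay single-digit at the default
#'   depth.
#' @param background_mut_rate expected background (context-driven)
#'   mutations per bp before trinucleotide weighting.
#' @param efficiency_sdlog log-SD of the per-region capture-efficiency
#'   lognormal (shared between matched libraries).
#' @param library_sdlog log-SD of the per-region, per-library efficiency
#'   jitter (capture is performed per library).
#' @param read_length simulated read length in bp.
#' @param seed integer seed for all read/mutation randomness.
#' @return an object of class `damage_params`.
#' @export
damage_params <- function(sequencing_depth = 21600,
                          base_rate = DEFAULT_BASE_RATE,
                          induction = DEFAULT_INDUCTION,
                          background_rate = 0.25,
                          glm_beta0 = 2.0,
                          glm_beta_cell = 0.001182,
                          glm_beta_naked = -0.01532,
                          background_mut_rate = 0.018,
                          efficiency_sdlog = 0.4,
                          library_sdlog = 0.3,
                          read_length = 30,
                          seed = 1) {
  stopifnot(sequencing_depth >= 0, all(base_rate >= 0), background_rate >= 0,
            background_mut_rate >= 0, efficiency_sdlog >= 0, library_sdlog >= 0)
  stopifnot(all(c("TT", "TC", "CT", "CC") %in% names(base_rate)))
  if (!all(vapply(induction, function(v) all(v >= 0), logical(1)))) {
    stop("induction factors must be >= 0")
  }
  structure(list(sequencing_depth = sequencing_depth, base_rate = base_rate,
                 induction = induction, background_rate = background_rate,
                 glm_beta0 = glm_beta0, glm_beta_cell = glm_beta_cell,
                 glm_beta_naked = glm_beta_naked,
                 background_mut_rate = background_mut_rate,
                 efficiency_sdlog = efficiency_sdlog,
                 library_sdlog = library_sdlog,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "damage_params")
}

#' Generate a synthetic capture-region genome with planted motifs
#'
#' Each region becomes its own contig of random sequence at the requested
#' GC fraction, with motif contexts written over it at the planted
#' midpoints.  Variant ETS plantings carry a pyrimidine dinucleotide at
#' offsets -4/-3 from the motif midpoint on the pyrimidine strand;
#' canonical plantings carry a purine at -4.
#'
#' @param spec a [genome_spec()].
#' @return list of class `uv_genome` with elements `genome` (named
#'   character vector), `regions` (BED-like data frame with a `class`
#'   column) and `sites` (motif truth table: `contig, midpoint, strand,
#'   kind, variant, bound`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    n <- spec$n_regions; len <- spec$region_length
    gc <- spec$gc_background
    contigs <- sprintf("region_%04d", seq_len(n))
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(names(base_prob), len, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
    names(seqs) <- contigs

    pm <- spec$planted_motifs
    if (nrow(pm) && is.null(pm$strand)) {
      pm$strand <- sample(c("+", "-"), nrow(pm), replace = TRUE)
    }
    sites <- NULL
    if (nrow(pm)) {
      for (i in seq_len(nrow(pm))) {
        ctx <- MOTIF_CONTEXTS[[pm$kind[i]]]
        m <- pm$offset[i]
        if (pm$strand[i] == "+") {
          at <- m + MOTIF_CONTEXT_OFFSET          # 0-based start of context
          ins <- ctx
        } else {
          at <- m - (nchar(ctx) - 1L) - MOTIF_CONTEXT_OFFSET  # mirrored
          ins <- revcomp(ctx)
        }
        s <- seqs[[pm$region[i]]]
        substr(s, at + 1L, at + nchar(ctx)) <- ins
        seqs[[pm$region[i]]] <- s
      }
      is_var <- grepl("variant", pm$kind)
      sites <- data.frame(
        contig = contigs[pm$region], midpoint = pm$offset,
        strand = pm$strand, kind = pm$kind,
        variant = is_var, bound = pm$bound,
        site_id = sprintf("site_%04d", seq_len(nrow(pm))),
        stringsAsFactors = FALSE
      )
    } else {
      sites <- data.frame(contig = character(), midpoint = integer(),
                          strand = character(), kind = character(),
                          variant = logical(), bound = logical(),
                          site_id = character(), stringsAsFactors = FALSE)
    }

    cls <- spec$region_class
    if (is.null(cls)) {
      cls <- rep("coding", n)
      if (nrow(pm)) {
        cls[unique(pm$region[grepl("ETS", pm$kind)])] <- "ETS"
        cls[unique(pm$region[!grepl("ETS", pm$kind)])] <- "TFBS"
      }
    } else {
      cls <- rep(cls, length.out = n)
    }
    regions <- data.frame(contig = contigs, start = 0L, end = len,
                          name = contigs, class = cls,
                          stringsAsFactors = FALSE)
    structure(list(genome = seqs, regions = regions, sites = sites,
                   spec = spec),
              class = "uv_genome")
  })
}

#' @export
print.uv_genome <- function(x, ...) {
  cat("uv_genome:", length(x$genome), "regions of",
      x$spec$region_length, "bp;", nrow(x$sites), "planted motif site(s)\n")
  if (nrow(x$sites)) print(table(x$sites$kind, x$sites$bound))
  invisible(x)
}
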