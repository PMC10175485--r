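## Genomic position of a motif-strand offset for each site (mirrored for
## minus-strand sites, so the motif always reads left-to-right in offsets).
off_to_pos <- function(sites, offset) {
  ifelse(sites$strand == "+", sites$midpoint + offset, sites$midpoint - offset)
}

#' Genomic positions of a motif-strand offset
#'
#' Maps an offset from the motif midpoint (on the pyrimidine strand) to
#' genomic coordinates, mirrored for minus-strand sites.
#'
#' @param sites site table (`midpoint, strand`).
#' @param offset integer offset.
#' @return integer vector of 0-based genomic positions.
#' @export
motif_positions <- function(sites, offset) off_to_pos(sites, offset)

#' Per-site CPD counts summed over motif offsets
#'
#' Both-strand-summed track counts at the given motif-strand offsets,
#' summed per site.  The default offsets are the -4/-3 positions used by
#' the mutation regression.
#'
#' @param track a [lesion_track].
#' @param sites motif site table (`contig, midpoint, strand`).
#' @param offsets integer offsets from the motif midpoint.
#' @return numeric vector, one sum per site.
#' @export
site_lesion_sums <- function(track, sites, offsets = c(-4, -3)) {
  if (!nrow(sites)) return(numeric(0))
  tot <- numeric(nrow(sites))
  for (off in offsets) {
    tot <- tot + track_values(track, sites$contig, off_to_pos(sites, off))
  }
  tot
}

UV_ALT <- c(A = "G", C = "T", G = "A", T = "C")
REGION_CLASS_TO_MUT_CLASS <- c(ETS = "promoter", TFBS = "TFBS",
                               coding = "coding", promoter = "promoter",
                               "5UTR" = "5UTR", "3UTR" = "3UTR",
                               driver_candidate = "driver_candidate")

#' Simulate a recurrent-mutation catalog from damage tracks
#'
#' Per site, a mutation count is drawn from
#' `Poisson(exp(b0 + b_cell * C + b_naked * N))` where C and N are the
#' cellular and naked CPD counts summed over the -4/-3 motif positions,
#' and placed at those positions.  Background mutations are additionally
#' scattered across all regions in proportion to a pyrimidine-strand
#' trinucleotide-context weight table, so context-expected mutation
#' frequencies are estimable downstream.
#'
#' @param cellular,naked [lesion_track]s (naked unscaled; the regression
#'   model is expressed in raw naked counts).
#' @param sites site truth table (typically the variant ETS sites).
#' @param params a [damage_params()].
#' @param gen the [make_genome()] result (provides sequence context and
#'   region classes).
#' @param trinuc_weights background context weights (32 pyrimidine-strand
#'   trinucleotides).
#' @return data frame of mutation records: `contig, position, ref, alt,
#'   tumor_count, class, gene, cancer_gene`, with attribute `site_counts`
#'   (per-site `C`, `N` and simulated mutation sum `y`, including zeros).
#' @export
simulate_mutations <- function(cellular, naked, sites, params, gen,
                               trinuc_weights = default_trinuc_weights) {
  stopifnot(inherits(params, "damage_params"), inherits(gen, "uv_genome"))
  chars <- genome_chars(gen$genome)

  C <- site_lesion_sums(cellular, sites)
  N <- site_lesion_sums(naked, sites)
  if (nrow(sites) && any(C == 0 & N == 0)) {
    warning(sum(C == 0 & N == 0),
            " site(s) have no track coverage at -4/-3; counts treated as 0")
  }
  lam <- exp(params$glm_beta0 + params$glm_beta_cell * C + params$glm_beta_naked * N)

  with_seed(derive_seed(params$seed, "mutations"), {
    y <- if (nrow(sites)) rpois(nrow(sites), lam) else integer(0)
    ## split each site's mutations between the -4 and -3 positions
    ## (the C of the TC step is the dominant mutated base)
    at4 <- rbinom(length(y), y, 0.2)
    at3 <- y - at4
    mut_ctg <- c(rep(sites$contig, at4), rep(sites$contig, at3))
    mut_pos <- c(rep(off_to_pos(sites, -4L), at4), rep(off_to_pos(sites, -3L), at3))

    ## context-weighted background mutations; normalized so the expected
    ## total background count = background_mut_rate * n_positions
    ctx_w <- lapply(names(gen$genome), function(ctg) {
      ch <- chars[[ctg]]
      pos <- seq(1L, length(ch) - 2L)
      w <- unname(trinuc_weights[context_at(ch, pos)])
      w[is.na(w)] <- 0
      list(pos = pos, w = w)
    })
    names(ctx_w) <- names(gen$genome)
    mean_w <- mean(unlist(lapply(ctx_w, `[[`, "w")))
    for (ctg in names(gen$genome)) {
      pos <- ctx_w[[ctg]]$pos
      rate <- params$background_mut_rate * ctx_w[[ctg]]$w / mean_w
      cnt <- rpois(length(rate), rate)
      nz <- which(cnt > 0L)
      if (length(nz)) {
        mut_ctg <- c(mut_ctg, rep.int(ctg, sum(cnt[nz])))
        mut_pos <- c(mut_pos, rep.int(pos[nz], cnt[nz]))
      }
    }

    key <- paste(mut_ctg, mut_pos)
    tab <- table(key)
    ctg_out <- sub(" .*$", "", names(tab)) %||% character(0)
    pos_out <- as.integer(sub("^.* ", "", names(tab)) %||% character(0))
    ref <- vapply(seq_along(ctg_out),
                  function(k) chars[[ctg_out[k]]][pos_out[k] + 1L], character(1))
    cls_by_ctg <- setNames(gen$regions$class, gen$regions$contig)
    cls <- unname(REGION_CLASS_TO_MUT_CLASS[cls_by_ctg[ctg_out]])
    cls[is.na(cls)] <- "promoter"
    catalog <- data.frame(
      contig = ctg_out, position = pos_out,
      ref = ref, alt = unname(UV_ALT[ref]),
      tumor_count = as.integer(tab),
      class = cls, gene = ctg_out,
      cancer_gene = rep(FALSE, length(ctg_out)),
      stringsAsFactors = FALSE
    )
    catalog <- catalog[order(catalog$contig, catalog$position), ]
    rownames(catalog) <- NULL
    attr(catalog, "site_counts") <- data.frame(
      site_id = sites$site_id %||% sprintf("site_%04d", seq_len(nrow(sites))),
      contig = sites$contig, C = C, N = N, y = y,
      stringsAsFactors = FALSE
    )
    catalog
  })
}

#' Simulate accessibility densities rank-correlated with damage induction
#'
#' Generates per-site accessibility (DNase-like) densities whose population
#' Spearman correlation with the supplied per-site induction equals
#' `target_rho`, via a Gaussian rank copula on the normal scores of the
#' induction ranks.  Three replicate tracks are emitted (mirroring
#' replicate accessibility datasets); their per-site sum is the copula
#' variable, so summing per-dataset window averages recovers the target
#' correlation.
#'
#' @param induction numeric per-site induction (>= 10 sites).
#' @param target_rho target Spearman correlation, in (0, 1].
#' @param seed integer seed.
#' @param n_replicates number of replicate tracks.
#' @return data frame with one density column per replicate and attribute
#'   `total` (the per-site summed density).
#' @export
simulate_dnase <- function(induction, target_rho = 0.41, seed = 1,
                           n_replicates = 3) {
  if (length(induction) < 10) stop("fewer than 10 sites: correlation meaningless")
  if (!(target_rho > 0 && target_rho <= 1)) stop("target_rho must be in (0, 1]")
  n <- length(induction)
  ## bivariate-normal Pearson rho giving the requested Spearman rho
  rho_p <- 2 * sin(pi * target_rho / 6)
  with_seed(seed, {
    r <- rank(induction, ties.method = "average")
    z1 <- qnorm((r - 0.375) / (n + 0.25))
    z <- rho_p * z1 + sqrt(max(0, 1 - rho_p^2)) * rnorm(n)
    total <- qlnorm_safe(pnorm(z))
    g <- matrix(rgamma(n * n_replicates, shape = 50, rate = 50),
                nrow = n)
    g <- g / rowSums(g)
    d <- total * g
    out <- as.data.frame(d)
    names(out) <- paste0("rep", seq_len(n_replicates))
    attr(out, "total") <- total
    out
  })
}

qlnorm_safe <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  stats::qlnorm(p, meanlog = log(50), sdlog = 0.6)
}

#' Interval tracks from simulated accessibility densities
#'
#' Converts [simulate_dnase()] output into one bedGraph-style interval
#' data frame per replicate, with the density spread uniformly over the
#' +/- `halfwidth` window around each site midpoint.
#'
#' @param dnase [simulate_dnase()] result.
#' @param sites site table (`contig, midpoint`).
#' @param halfwidth window half-width in bp.
#' @return list of data frames `contig, start, end, value`.
#' @export
dnase_sim_tracks <- function(dnase, sites, halfwidth = 50) {
  stopifnot(nrow(dnase) == nrow(sites))
  lapply(names(dnase), function(cn) {
    data.frame(contig = sites$contig,
               start = pmax(0L, sites$midpoint - halfwidth),
               end = sites$midpoint + halfwidth + 1L,
               value = dnase[[cn]],
               stringsAsFactors = FALSE)
  })
}
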