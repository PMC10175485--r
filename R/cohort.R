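#' Simulate a complete matched-library cohort
#'
#' The standard study design for the synthetic analyses: `n_sites` capture
#' regions, each carrying one variant (or canonical) ETS binding site at
#' its center, with a fraction `bound_fraction` occupied; matched cellular
#' and naked-DNA libraries are simulated, lesions called, and the naked
#' track scaled to the cellular one within the capture regions.
#'
#' @param n_sites number of binding sites (one per region).
#' @param seed master seed; genome, reads and downstream draws derive
#'   deterministic child seeds from it.
#' @param region_length capture-region length in bp.
#' @param bound_fraction probability that a planted site is bound.
#' @param kind motif kind to plant.
#' @param params a [damage_params()]; its seed is overridden by a child
#'   seed of `seed`.
#' @param n_background additional motif-free regions (class `coding`).
#' @param keep_reads retain the simulated read tables (memory-heavy).
#' @return list of class `uv_cohort`: `genome`, `params`, `sites`,
#'   `cellular`, `naked`, `scaled_naked`, `scale_info`, and (optionally)
#'   `cellular_reads`, `naked_reads`.
#' @export
simulate_cohort <- function(n_sites = 300, seed = 1, region_length = 720,
                            bound_fraction = 0.65, kind = "ETS_variant",
                            params = NULL, n_background = 0,
                            keep_reads = FALSE) {
  if (is.null(params)) params <- damage_params(seed = derive_seed(seed, "damage"))
  params$seed <- derive_seed(seed, "damage")
  bound <- with_seed(derive_seed(seed, "occupancy"),
                     runif(n_sites) < bound_fraction)
  pm <- data.frame(region = seq_len(n_sites),
                   offset = as.integer(floor(region_length / 2)),
                   kind = kind, bound = bound, stringsAsFactors = FALSE)
  spec <- genome_spec(n_regions = n_sites + n_background,
                      region_length = region_length,
                      planted_motifs = pm, seed = derive_seed(seed, "genome"))
  gen <- make_genome(spec)

  cellular_reads <- simulate_reads(gen, params, "cellular")
  naked_reads <- simulate_reads(gen, params, "naked")
  cellular <- call_lesions(cellular_reads, gen$genome,
                           sample = "synthetic", condition = "cellular")
  naked <- call_lesions(naked_reads, gen$genome,
                        sample = "synthetic", condition = "naked")
  sc <- scale_naked(cellular, naked, gen$regions)
  out <- list(genome = gen, params = params, sites = gen$sites,
              cellular = cellular, naked = naked,
              scaled_naked = sc$track,
              scale_info = sc[c("scale_factor", "cellular_total", "naked_total")],
              seed = seed)
  if (keep_reads) {
    out$cellular_reads <- cellular_reads
    out$naked_reads <- naked_reads
  }
  class(out) <- "uv_cohort"
  out
}

#' @export
print.uv_cohort <- function(x, ...) {
  cat("uv_cohort:", nrow(x$sites), "planted sites (",
      sum(x$sites$bound), "bound ) in", nrow(x$genome$regions), "regions\n")
  cat(sprintf("  cellular reads %d, naked reads %d, scale factor %.4f\n",
              as.integer(x$scale_info$cellular_total),
              as.integer(x$scale_info$naked_total),
              x$scale_info$scale_factor))
  invisible(x)
}

#' Per-site CPD induction summed over the within-motif offsets
#'
#' Convenience accessor: cellular minus scaled-naked counts summed over
#' the given motif offsets, per site.
#'
#' @param cohort a [simulate_cohort()] result (or any list with
#'   `cellular`, `scaled_naked`, `sites`).
#' @param offsets motif-strand offsets to sum over.
#' @return numeric vector, one induction value per site.
#' @export
site_induction <- function(cohort, offsets = c(-4, -3, -1, 0, 1)) {
  site_lesion_sums(cohort$cellular, cohort$sites, offsets) -
    site_lesion_sums(cohort$scaled_naked, cohort$sites, offsets)
}

#' The coefficient-recovery cohort design
#'
#' A leaner variant of [simulate_cohort()] used for the Poisson-regression
#' parameter-recovery experiments: the same damage model and per-site
#' depth, but shorter (240 bp) capture regions, so that many replicate
#' cohorts can be simulated quickly.  The per-region depth is scaled with
#' region length to keep per-base coverage (and hence the -4/-3 count
#' scale that the regression coefficients act on) unchanged.
#'
#' @param seed master seed.
#' @param n_sites number of variant sites.
#' @return a [simulate_cohort()] result.
#' @export
recovery_cohort <- function(seed = 1, n_sites = 300) {
  params <- damage_params(sequencing_depth = 7200, seed = derive_seed(seed, "damage"))
  simulate_cohort(n_sites = n_sites, seed = seed, region_length = 240,
                  params = params)
}
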