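PIPELINE_KEYS <- c("seed", "outdir", "cohort", "damage", "classify", "dnase")
COHORT_KEYS <- c("n_sites", "region_length", "bound_fraction", "kind",
                 "n_background")
DAMAGE_KEYS <- c("sequencing_depth", "background_rate", "glm_beta0",
                 "glm_beta_cell", "glm_beta_naked", "background_mut_rate",
                 "efficiency_sdlog", "library_sdlog", "read_length")
CLASSIFY_KEYS <- c("fold_threshold", "abs_threshold", "window")
DNASE_KEYS <- c("target_rho", "n_replicates")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  }
}

#' Read and validate a pipeline configuration file (YAML)
#'
#' Unknown keys are rejected; missing keys fall back to package defaults.
#' The configuration round-trips losslessly through [yaml::write_yaml()].
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, PIPELINE_KEYS, "top level")
  check_keys(cfg$cohort %||% list(), COHORT_KEYS, "cohort")
  check_keys(cfg$damage %||% list(), DAMAGE_KEYS, "damage")
  check_keys(cfg$classify %||% list(), CLASSIFY_KEYS, "classify")
  check_keys(cfg$dnase %||% list(), DNASE_KEYS, "dnase")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates the configured cohort, calls lesions, scales the naked-DNA
#' control, and emits every stage's outputs (bedGraph tracks and TSV
#' tables, 1-based positions in human-facing reports) plus a
#' machine-readable run manifest with input/output checksums.  Re-running
#' with the same configuration and seed reproduces byte-identical outputs.
#'
#' @param config a [read_pipeline_config()] result, or a path to one.
#' @param outdir output directory (created; overrides `config$outdir`).
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  co_args <- config$cohort %||% list()
  dm_args <- config$damage %||% list()
  params <- do.call(damage_params, c(dm_args, list(seed = derive_seed(seed, "damage"))))
  cohort <- do.call(simulate_cohort,
                    c(co_args, list(seed = seed, params = params, keep_reads = TRUE)))
  gen <- cohort$genome

  ## genome + regions + truth
  write_genome(gen$genome, file.path(outdir, "genome.fa"))
  write_bed(gen$regions, file.path(outdir, "regions.bed"))
  truth <- gen$sites
  truth$midpoint <- truth$midpoint + 1L  # 1-based in reports
  write_tsv(truth, file.path(outdir, "sites.tsv"))

  ## read libraries and lesion tracks
  write_bed(cohort$cellular_reads, file.path(outdir, "cellular.bed"))
  write_bed(cohort$naked_reads, file.path(outdir, "naked.bed"))
  write_track(cohort$cellular, file.path(outdir, "cellular"))
  write_track(cohort$naked, file.path(outdir, "naked"))
  write_track(cohort$scaled_naked, file.path(outdir, "naked_scaled"))

  ## induction outputs
  vsites <- cohort$sites[cohort$sites$variant, , drop = FALSE]
  if (!nrow(vsites)) vsites <- cohort$sites
  prof <- data.frame(
    offset = motif_profile(cohort$cellular, vsites)$offset,
    cellular = motif_profile(cohort$cellular, vsites)$mean_count,
    scaled_naked = motif_profile(cohort$scaled_naked, vsites)$mean_count
  )
  write_tsv(prof, file.path(outdir, "motif_profile.tsv"))
  mat <- induction_matrix(cohort$cellular, cohort$scaled_naked, vsites,
                          gen$regions)
  write_tsv(cbind(site_id = rownames(mat), as.data.frame(mat)),
            file.path(outdir, "induction_matrix.tsv"))
  fn <- flank_null(cohort$cellular, cohort$scaled_naked, vsites, gen$genome)
  write_tsv(data.frame(mu_flank = fn$mu_flank, sigma_flank = fn$sigma_flank,
                       n_positions = fn$n_positions),
            file.path(outdir, "flank_null.tsv"))
  hx <- hexamer_screen(cohort$cellular_reads, cohort$naked_reads, gen$genome,
                       scale_factor = cohort$scale_info$scale_factor)
  write_tsv(hx, file.path(outdir, "hexamer_screen.tsv"))

  ## mutations, annotation, regression, enrichment
  catalog <- simulate_mutations(cohort$cellular, cohort$naked, vsites,
                                params, gen)
  sc <- attr(catalog, "site_counts")
  scanned <- scan_genome_ets(gen$genome)
  catalog <- annotate_mutations(catalog, scanned)
  report <- catalog
  report$position <- report$position + 1L
  write_tsv(report, file.path(outdir, "mutations.tsv"))

  fit <- fit_poisson_glm(sc$y, sc$C, sc$N)
  write_tsv(data.frame(term = names(coef(fit)), estimate = coef(fit),
                       se = fit$se, lower = fit$ci[, 1], upper = fit$ci[, 2],
                       lrt_p = fit$lrt_p, pseudo_r2 = fit$pseudo_r2),
            file.path(outdir, "poisson_fit.tsv"))

  query <- data.frame(contig = rep(vsites$contig, 2),
                      pos = c(off_to_pos(vsites, -4L), off_to_pos(vsites, -3L)))
  enr <- trinuc_enrichment(catalog, gen$genome, query, gen$regions)
  write_tsv(data.frame(observed = enr$observed, expected = enr$expected,
                       fold = enr$fold),
            file.path(outdir, "trinuc_enrichment.tsv"))

  ## accessibility simulation + correlation
  dn_args <- config$dnase %||% list()
  ind <- site_induction(cohort)
  dn <- do.call(simulate_dnase,
                c(list(induction = ind, seed = derive_seed(seed, "dnase")),
                  dn_args))
  dens <- dnase_density(dnase_sim_tracks(dn, vsites), vsites)
  ct <- spearman_ci(dens, ind)
  write_tsv(data.frame(rho = ct$rho, ci_lower = ct$ci[1], ci_upper = ct$ci[2],
                       n = ct$n, p = ct$p),
            file.path(outdir, "dnase_correlation.tsv"))

  ## classification
  cl_args <- config$classify %||% list()
  ccfg <- do.call(classifier_config, cl_args)
  calls <- classify_sites(catalog, cohort$cellular, cohort$scaled_naked,
                          ccfg, gen$regions)
  calls_report <- calls
  calls_report$position <- calls_report$position + 1L
  write_tsv(calls_report, file.path(outdir, "site_calls.tsv"))
  write_tsv(attr(calls, "summary"), file.path(outdir, "class_summary.tsv"))

  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "uvhotspot",
    version = as.character(utils::packageVersion("uvhotspot")),
    seed = seed,
    scale_factor = cohort$scale_info$scale_factor,
    outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
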