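#' Deterministic 12-site driver-candidate evaluation fixture
#'
#' A fully synthetic, deterministic cohort of twelve recurrent
#' driver-candidate mutation sites mirroring the structure of published
#' non-coding driver catalogs: seven sites sit at bound variant ETS
#' motifs with strong cellular damage induction (recurrent-passenger
#' profile), two sit in ETS motifs without damage induction (the
#' known-driver profile of motif-creating promoter mutations), and three
#' carry neither motif nor induction.  Track counts are fixed constants,
#' not samples, so the classification is reproducible to the byte.
#'
#' @return list: `genome` (a [make_genome()] result), `catalog` (annotated
#'   mutation records), `cellular` and `scaled_naked` tracks, `config`.
#' @export
driver_fixture <- function() {
  n <- 12L
  pm <- data.frame(
    region = 1:9, offset = 120L,
    kind = "ETS_variant",
    bound = c(rep(TRUE, 7), FALSE, FALSE),
    strand = rep(c("+", "-", "+"), length.out = 9),
    stringsAsFactors = FALSE
  )
  spec <- genome_spec(n_regions = n, region_length = 240, planted_motifs = pm,
                      region_class = "driver_candidate", seed = 424242)
  gen <- make_genome(spec)
  sites <- scan_genome_ets(gen$genome)

  ## mutation at the -3 position of each planted motif; arbitrary interior
  ## positions for the three motif-free regions
  mut_pos <- c(off_to_pos(gen$sites, -3L), c(97L, 141L, 163L))
  mut_ctg <- c(gen$sites$contig, gen$regions$contig[10:12])
  chars <- genome_chars(gen$genome)
  ref <- vapply(seq_len(n), function(i) chars[[mut_ctg[i]]][mut_pos[i] + 1L],
                character(1))
  catalog <- data.frame(
    contig = mut_ctg, position = mut_pos, ref = ref,
    alt = unname(UV_ALT[ref]),
    tumor_count = c(9L, 7L, 6L, 6L, 5L, 5L, 5L, 12L, 8L, 6L, 5L, 5L),
    class = "driver_candidate",
    gene = mut_ctg, cancer_gene = c(rep(FALSE, 7), TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  catalog <- annotate_mutations(catalog, sites)

  ## fixed per-site counts: passengers show strong induction (>= 2-fold and
  ## >= +50); the remaining sites sit near the naked-DNA expectation
  cell <- c(420, 380, 300, 260, 220, 180, 160, 90, 70, 55, 40, 30)
  nakd <- c(110, 100, 95, 90, 85, 80, 75, 85, 65, 50, 45, 35)
  cellular <- new_lesion_track(
    data.frame(contig = mut_ctg, strand = "+", pos = mut_pos, count = cell,
               stringsAsFactors = FALSE),
    sample = "fixture", condition = "cellular",
    total_input_reads = sum(cell), total_dipyrimidine_reads = sum(cell) / 2
  )
  scaled_naked <- new_lesion_track(
    data.frame(contig = mut_ctg, strand = "+", pos = mut_pos, count = nakd,
               stringsAsFactors = FALSE),
    sample = "fixture", condition = "naked_scaled",
    total_input_reads = sum(nakd), total_dipyrimidine_reads = sum(nakd) / 2
  )
  list(genome = gen, catalog = catalog, cellular = cellular,
       scaled_naked = scaled_naked, config = classifier_config())
}
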