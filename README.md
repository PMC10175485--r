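# uvhotspot

Analysis of targeted UV-damage sequencing (CPD-capture-seq) data: mapping
cyclobutane pyrimidine dimers (CPDs) at single-nucleotide resolution in
captured genomic regions, quantifying damage induction at transcription-factor
binding sites, and asking whether recurrent somatic mutations in skin cancer
are better explained by locally elevated UV damage (recurrent passengers) than
by selection (drivers).

## The problem and the model

ETS-family transcription factors bind a GGAA-core motif (pyrimidine strand
`TTCC`). Binding photosensitizes adjacent dipyrimidines, so UV irradiation of
cells produces localized CPD hotspots at bound sites — strongest at a
dipyrimidine at offsets −4/−3 from the motif midpoint ("variant" ETS sites) —
that are absent in irradiated naked DNA. Because CPDs drive C→T mutagenesis,
these hotspots can make a site recurrently mutated across tumors without any
selective advantage.

The package implements the full computational chain:

1. **Lesion calling.** Aligned reads (BED6) are mapped to a candidate lesion
   dinucleotide on the strand opposite the read, immediately past its 5′ end;
   reads are retained only when both bases are pyrimidines, and each retained
   read contributes one count to both dinucleotide positions.
2. **Scaling and induction.** The naked-DNA control is scaled so both
   libraries carry equal dipyrimidine read totals within the capture regions;
   induction at a position is `cellular − scaled naked`. Per-site induction is
   Z-scored against an empirical null from flanking DNA (6–180 bp from the
   site midpoint): `z = (d − μ_flank) / σ_flank`.
3. **Motif annotation.** Fixed-string scanning for `TTCCG`/`CTTCC` (both
   strands), canonical/variant classification by the −4/−3 dinucleotide, and
   ETS-overlap annotation of recurrent mutations at offsets −4, −3, 0, +1.
4. **Mutation regression.** Per variant site, melanoma mutation counts summed
   at −4/−3 are modelled as
   `y ~ Poisson(exp(β0 + β_cell·C + β_naked·N))`
   with `C`, `N` the cellular / naked CPD sums at the same positions, fitted
   by IRLS with Wald CIs, a likelihood-ratio test against the naked-only null,
   and McFadden pseudo-R². Trinucleotide-context enrichment, a de novo hexamer
   damage screen, accessibility (DNase) correlations, and Mann-Whitney group
   comparisons complete the statistical layer.
5. **Classification.** A mutation site with cellular CPDs at least twofold
   above and at least 50 reads over the scaled naked control is "elevated";
   elevated + ETS overlap ⇒ likely passenger, not elevated ⇒ candidate driver,
   elevated without a motif ⇒ ambiguous.

A first-class synthetic-data generator (`make_genome()`, `simulate_reads()`,
`simulate_mutations()`, `simulate_dnase()`) emulates the statistical structure
of the real libraries — Poisson read counts with dinucleotide-class base
rates, occupancy-dependent induction at planted motifs, matched naked and
no-UV controls, the log-linear mutation model, and rank-correlated
accessibility — so the whole pipeline is testable without external data.

## Worked example

```r
library(uvhotspot)

co <- simulate_cohort(n_sites = 40, seed = 11)   # matched cellular + naked libraries
co
#> uv_cohort: 40 planted sites ( 29 bound ) in 40 regions
#>   cellular reads 1002478, naked reads 960563, scale factor 1.0436

vs <- co$sites[co$sites$variant, ]
prof <- motif_profile(co$cellular, vs)
prof[prof$offset %in% -4:1, ]
#>    offset mean_count
#> 7      -4    644.700
#> 8      -3    657.550
#> 9      -2     77.775
#> 10     -1    157.100
#> 11      0    148.125
#> 12      1     55.950

fn <- flank_null(co$cellular, co$scaled_naked, vs, co$genome$genome)
fn
#> flank_null: mu = -1.755, sigma = 42.59 over 10509 CPD-forming positions (6-180 bp)

m   <- simulate_mutations(co$cellular, co$naked, vs, co$params, co$genome)
sc  <- attr(m, "site_counts")
fit <- fit_poisson_glm(sc$y, sc$C, sc$N)
fit
#> Poisson regression of mutation counts on CPD counts
#>   n = 40 sites; log-likelihood = -76.451; pseudo-R2 (McFadden) = 0.5727
#>   intercept        cell       naked
#>  1.73473000  0.00129933 -0.01469510
#>   LRT vs naked-only null: chi2(1) = 195.870, p = 1.66e-44
```

The profile peaks at offsets −4/−3 (the variant-site hotspot), the flanking
null sits slightly below zero (global scaling pushes flank induction negative
when motifs absorb extra cellular reads), and the regression recovers slopes
close to the generating coefficients (β_cell = 0.001182, β_naked = −0.01532)
with a decisive LRT.

Classification of the bundled deterministic twelve-site driver-candidate
fixture:

```r
fx <- driver_fixture()
calls <- classify_sites(fx$catalog, fx$cellular, fx$scaled_naked,
                        fx$config, fx$genome$regions)
table(calls$call)
#> candidate_driver likely_passenger
#>                5                7
```

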