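---
title: "Methods: UV damage hotspots at transcription-factor binding sites"
author: "uvhotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UV damage hotspots at transcription-factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvhotspot)
```

## Scope

CPD-capture-seq enriches a few thousand ~720 bp genomic regions before
sequencing a CPD-seq library, giving deep per-base coverage of UV-induced
cyclobutane pyrimidine dimers (CPDs) at transcription-factor binding sites and
recurrently mutated loci. This vignette documents the package's models,
conventions, calibration constants and their rationale. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Lesion calling

A CPD blocks the polymerase used in library preparation; cleavage at the
lesion creates a free 3′-OH on its 5′ side which is ligated to the second
sequencing adapter, so sequencing starts adjacent to the lesion and reads
*away* from it on the opposite strand. The package therefore resolves, for a
plus-strand read with leftmost aligned coordinate `p`, a candidate dinucleotide
at positions `(p-2, p-1)` on the minus strand; for a minus-strand read with
rightmost coordinate `q`, positions `(q+1, q+2)` on the plus strand. The
offset is a single documented constant (`LESION_OFFSET`) so an alternative
convention inherited from a different protocol is a one-line change.

A read is retained iff both candidate bases are pyrimidines on the lesion
strand (dinucleotide classes TT/TC/CT/CC read 5′→3′ on that strand); each
retained read adds one count at *both* positions, so track totals are exactly
twice the retained read count. Duplicate reads are kept (no deduplication is
part of the protocol). Coordinates are 0-based half-open internally and in
BED/bedGraph; human-facing TSV reports are 1-based. Tracks are written as one
bedGraph per strand (`.plus.bedGraph` / `.minus.bedGraph`).

Correctness is pinned by a brute-force oracle (an independent scanner that
enumerates every dipyrimidine and matches reads positionally, run on small
random genomes) and by a strand-mirror symmetry property: calling on the
reverse-complemented genome with coordinate-mirrored, strand-flipped reads
yields the mirrored track exactly.

## Scaling, induction and the flanking null

The naked-DNA control (purified genomic DNA irradiated in vitro) captures
sequence-intrinsic photochemistry without protein binding. It is scaled by a
single global factor — cellular over naked dipyrimidine read totals within
the union of capture regions — so that induction, `cellular − scaled naked`,
sums to zero over the capture space by construction. Scaling is library-wide,
not per region, because one matched pair is one experiment; per-region
scaling would erase genuine regional induction.

Significance of within-motif induction is judged against an empirical null
from flanking DNA: all CPD-forming positions 6–180 bp from each site midpoint
(both sides, clipped to the contig), pooled across sites, yield `μ_flank` and
`σ_flank`; `z = (d − μ_flank)/σ_flank`. Because bound motifs absorb extra
cellular reads while scaling equalizes totals, the flank mean is expected to
be slightly negative — at the default calibration, about −1.5 reads per
position. The null pools variant-site flanks by default; any site set can be
supplied.

Per-site induction matrices (the cluster-plot substrate) drop sites whose
mean cellular lesion count per flanking bp is below 1 ("capture efficiency"
filter; read counts rather than distinct lesion positions, because
distinct-position density saturates at 1/bp at high depth) and order rows by
the summed induction at offsets {−4, −3, −1, 0, +1} — the within-motif
positions where binding modulates damage.

## Motif conventions

ETS sites are found by fixed-string search for the pentamers `TTCCG` and
`CTTCC` on both strands. The midpoint is the first C of the `TTCC` core,
which makes the conventional offsets self-consistent: the TC base step at −1/0,
CC at 0/+1, and the variant-defining dipyrimidine at −4/−3 (so the STK19 D89
hotspot falls at −3). When both pentamers flank one core (`CTTCCG`) a single
site is emitted. Sites with an N in offsets −4..+2 are dropped with a tally.
Position-weight-matrix scanning is deliberately out of scope; the motif list
is a configurable set of fixed strings.

A recurrent mutation overlaps an ETS site when its position equals the
midpoint plus one of {−4, −3, 0, +1}, strand-aware; nearest midpoint wins
ties, with a deterministic strand preference (the site on the strand where
the mutation's reference base is a pyrimidine) as the final tie-break.

## The mutation regression

Per variant site, mutation counts summed over the −4/−3 positions are
modelled as `y ~ Poisson(exp(β0 + β_cell·C + β_naked·N))`, with `C` and `N`
the cellular and (raw) naked CPD sums at the same two positions; summing the
covariates over the same positions as the response is the package's reading
of the per-site observation unit. The fitter is iteratively reweighted least
squares written in the package (log link, convergence on relative
log-likelihood change < 1e-10, 100-iteration cap, step-halving, lm-style
aliasing of rank-deficient columns); `stats::glm` serves only as an
independent cross-check in the tests, alongside a grid/simplex maximizer of
the log-likelihood. Inference: Wald 95% CIs from observed information
(profile-likelihood intervals are a documented alternative; Wald matches the
reference coefficient intervals), a 1-df likelihood-ratio test against the
naked-only null, and McFadden's pseudo-R² (`1 − ℓ_model/ℓ_intercept`), the
flavor labelled in the output because "pseudo-R²" alone is ambiguous.

Trinucleotide-context enrichment compares observed mutation counts at query
positions with the context-expected count, contexts collapsed to the
pyrimidine strand (32 classes), rates estimated from capture-region
background. The query positions themselves are excluded from the background
tally by default: on a ~300-region synthetic cohort the hotspot positions are
a non-negligible fraction of their contexts' occurrences, so leaving them in
would let the hotspot inflate its own expectation (a circularity a
genome-scale background does not suffer).

The hexamer screen (2 nt flank + lesion dinucleotide + 2 nt flank on the
lesion strand) counts once per read — which is why it consumes read tables
rather than position tracks: with overlapping dipyrimidine steps, per-read
attribution cannot be recovered from position counts. Each hexamer's cellular
count is tested against the share implied by the global scale factor
(two-sided binomial, Benjamini-Hochberg across hexamers); a context is
flagged at q < 0.05 and |log2 ratio| ≥ 1. The test choice is the package's
own, configurable; the original analysis reported enrichment without naming a
procedure.

Group comparisons (ETS vs non-ETS induction, TSS distances) use the
Mann-Whitney test: exact for combined n ≤ 20 without ties, otherwise the
normal approximation with mid-ranks, tie-corrected variance and continuity
correction. Accessibility densities are per-dataset means within ±50 bp of
the midpoint, summed across the three replicate datasets, correlated with
induction by Spearman's ρ with a Fisher-z CI (`se = 1/sqrt(n-3)`).

## The synthetic-data generator

The generator is first-class, tested code that defines the study conditions
for every recovery experiment. Each capture region is its own contig
(default 720 bp, GC 0.5) carrying at most one planted motif context written
on a random strand; the variant ETS context `GTCTTCCGGC` reproduces the
STK19-type pyrimidine-strand core, the canonical context `GACTTCCGAG` carries
a purine at −4.

Read counts per dipyrimidine step are Poisson with mean

```
depth × base_rate(class) × induction(kind, offset | bound, cellular) × eff_region × eff_library / Σ rates
```

* `base_rate = {TT 1.0, TC 0.5, CT 0.2, CC 0.3}` — absolute per-dinucleotide
  formation rates are not well established; these documented constants make
  TT dominant, matching the observed qualitative ordering of read fractions.
* `sequencing_depth = 21600` reads per 720 bp region (≈30 reads/bp), a
  hybridization-capture-scale depth that puts −4/−3 count sums in the
  hundreds-to-thousands range on which the published regression coefficients
  act.
* Capture efficiency is lognormal per region (sdlog 0.4, shared between the
  matched libraries, as probe quality is a region property) times a
  per-library lognormal jitter (sdlog 0.3, as capture is performed per
  library), both truncated at ±1.5 SD on the log scale: real panels have a
  bounded efficiency range, and an unbounded lognormal occasionally yields
  regions whose damage counts would imply mutation recurrence beyond any
  finite tumor cohort. The jitter supplies the between-site covariate
  variation that makes both regression slopes identifiable.
* Bound fraction 0.65 ("two-thirds or fewer" of sites show induction).
* Induction multipliers, keyed by the 5′-most motif-strand offset of the
  step and applied only at bound sites in the cellular library:
  variant `{−4: ×12.5, −3 (CT): ×0.3, −2 (core TT): ×0.3, −1: ×1.5, 0: ×1.5}`;
  canonical `{−3 (CT): ×0.3, −1: ×3, 0: ×3}`; NF-Y `{−1 (TT): ×5}`; AP-1
  `{−1, 0: ×0.3}`. These are calibration constants chosen from an analytic
  expectation (verified in the tests by Monte Carlo) so that the aggregate
  −4/−3 cellular:scaled-naked ratio over all variant sites is ≈7 and the
  cellular −4/−3 : −1/0 ratio is ≈4. A naive reading — putting the full
  target factors on each step — misses both targets because adjacent steps
  share profile positions: the unboosted core TT at −2/−1 bleeds into the
  −1/0 profile, so the −4 step must carry more (×12.5) and the −1/0 steps
  less (×1.5), with the core TT shielded (×0.3, an occupancy-protection
  reading consistent with the observed CT-step suppression).
* `background_rate = 0.25` uniform noise reads per strand-position in every
  condition; the no-UV library contains only these.
* Mutation model: `y ~ Poisson(exp(β0 + 0.001182·C − 0.01532·N))` with the
  published slopes as defaults. No reference intercept exists;
  β0 = 2.0 is the package's calibration so that per-site means stay
  single-digit *at the default depth* (with counts of order 10³ and the
  fixed slopes, a smaller intercept would push means near zero and destroy
  the information needed for coefficient recovery). Background mutations are
  scattered with C>T-dominant pyrimidine-strand trinucleotide weights
  (TCN 1.0, CCN 0.6, other-C 0.08, dipyrimidine-T 0.15, lone-T 0.03);
  `background_mut_rate = 0.018` per bp is calibrated so the variant-site
  −4/−3 positions come out ≈60-fold enriched over context expectation.
* Accessibility: a Gaussian rank copula on the normal scores of per-site
  induction (Pearson ρ = 2·sin(π·ρs/6) for a Spearman target ρs, default
  0.41) produces a lognormal total density split into three replicate tracks
  whose per-site sum is exactly the copula variable, mirroring the
  three-replicate-dataset design.

Every generator draw is seeded; one master seed fans out to per-stage child
seeds by stable derivation (`derive_seed`), so adding a stage never perturbs
earlier streams and equal seeds give byte-identical outputs.

Read placement inverts the lesion-calling convention exactly, so
`call_lesions(simulate_reads(...))` reproduces the latent step counts — a
round-trip identity asserted in the tests with background noise disabled.

### What the generator does and does not emulate

It reproduces Poisson counting noise, class-dependent formation rates,
occupancy-dependent induction and suppression, capture-efficiency
heterogeneity, matched-control scaling behavior, context-driven background
mutagenesis, and accessibility-induction rank correlation. It does not
emulate read-level sequence content or sequencing error, alignment artifacts,
mappability, probe cross-hybridization beyond the per-region efficiency
scalar, G/C-rich capture dropout (the TERT caveat), chromatin effects on
repair, or inter-tumor heterogeneity of the mutation catalog. Passing
recovery tests therefore demonstrates the correctness and calibration of the
analysis chain under its stated assumptions, not the biological conclusions
on real libraries.

## Problem sizes and numerical choices

The recovery experiments use cohorts of ~300 variant sites on 240 bp regions
with depth scaled to keep per-bp coverage (hence the covariate scale)
unchanged — the shorter flanks leave the −4/−3 statistics untouched while
making 100-replicate recovery runs cheap. The default full cohorts use 324
sites on 720 bp regions (matching the accessibility-analysis site count);
flanking-null and ratio targets are averaged over three such cohorts in the
acceptance script. Ties in ranks use mid-ranks; degenerate regression inputs
(all-zero response, < 3 sites, non-integer counts) are rejected with explicit
errors; all-zero covariate columns are aliased rather than fitted.

## Classification taxonomy

"At least twofold" and "at least 50 reads" are inclusive bounds. Per-site
CPD counts are both-strand sums at the mutation base (window configurable,
default 1 bp, since no window is canonical). Elevated + ETS ⇒
`likely_passenger`; not elevated ⇒ `candidate_driver`; elevated without a
motif ⇒ `ambiguous` — a third state the source implies but never names.
Mutations outside every capture region are reported `uncovered` and excluded
from summary fractions. The bundled twelve-site fixture plants seven
passenger-profile sites (bound variant ETS, strong induction), two
motif-bearing sites without induction (the known-driver profile of
ETS-creating promoter mutations) and three motif-free sites, with fixed
(non-sampled) track counts so its 7/12 split is reproducible to the byte.

## Full-data mode

On real data the same functions apply unchanged: align reads upstream
(alignment is out of scope), then `read_bed()` + `read_genome()` →
`call_lesions()` → `scale_naked()` → `motif_profile()`/`induction_matrix()`/
`flank_null()`, `scan_genome_ets()` + published recurrent-mutation lists →
`annotate_mutations()` → `fit_poisson_glm()`/`trinuc_enrichment()`/
`classify_sites()`. Genome-scale inputs (hg19, GEO CPD-capture-seq libraries,
ICGC mutation catalogs) are beyond desk scale and are not exercised by the
test suite.

## Known limitations

Fixed-string motif scanning misses degenerate ETS cores; the capture filter
assumes one region per contig when clipping; the hexamer screen's
binomial/BH procedure is one reasonable choice among several and is kept
configurable; the read-to-lesion offset is documented as this package's
convention, inherited from the damage-seq protocol family, and is a single
constant to change; and the flanking null inherits any non-ETS binding signal
present in flanks, which inflates `σ_flank` and makes Z-scores conservative.
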