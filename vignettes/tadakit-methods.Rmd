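---
title: "Models and methods behind tadakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tadakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

tadakit analyses Targeted DamID (TaDa) and Dam-only chromatin
accessibility (CaTaDa) data for two cell lineages sharing one genome. Its
unit of resolution is the *GATC fragment*: the interval between successive
DpnI cut sites (GA^TC), because Dam methylation is read out from
DpnI-digested fragments and no feature smaller than a fragment is
observable. Everything downstream — ratio tracks, peaks, differential
loci, interval statistics — lives on this coordinate system.

This vignette explains the models, the defaults and the design decisions;
the README shows a worked example.

# The signal model

Two channels are sequenced per lineage and replicate:

* **Dam-only**: untethered Dam methylates accessible chromatin, so the
  per-fragment read density is proportional to accessibility.
* **Dam-fusion**: Dam tethered to a transcription factor methylates where
  the factor binds, which requires accessible chromatin; density is
  proportional to accessibility x occupancy.

The binding signal for fragment $f$ is the normalized log ratio

$$r_f = \log_2\frac{\mathrm{cpm}^{fus}_f + c}{\mathrm{cpm}^{dam}_f + c} - \hat{f},$$

with pseudo-cpm $c = 0.5$ guaranteeing finiteness on zero-count
fragments, and $\hat f$ a single normalization factor per sample pair.

## Decile-exclusion normalization

Fragments are ranked into ten equal-frequency bins separately on fusion
cpm and Dam cpm. The retained set excludes the fusion top decile (likely
true signal, which would bias the factor upward) and the Dam bottom three
deciles (poorly measured, noise-dominated), and requires a non-zero raw
count in both channels. $\hat f$ is the **median** retained log2 ratio, so
the retained-set median of the track is exactly zero — a robust choice
where the procedure's source description names no statistic. Deciles are
computed on cpm rather than raw counts so the retained set is invariant
to library size; rank ties are broken by fragment id, making the
procedure fully deterministic. One published description of this
normalization calls it "quantile normalised" while the procedural
description is the decile-exclusion rule implemented here; the two are
not the same, and this package implements the procedural rule.

## Read extension

Reads are extended from their 5' end in the strand direction to
`min(300 bp, the first GATC cut at or beyond the read's 3' end)`, never
shortened, clipped at chromosome bounds. The 300-bp cap reflects typical
DamID fragment amplicon sizes; stopping at the first cut keeps a read's
evidence inside the fragments it could actually have come from. A cut
coinciding with the read's end boundary stops extension immediately.
Counting is overlap-based: an extended read increments every fragment it
overlaps by at least 1 bp, and the library size is the number of reads.

# Peak calling

The published analyses used an external narrow-peak caller; numerical
identity with it is a non-goal here. tadakit's caller is a transparent
fragment-resolution Poisson model:

* **TaDa mode** (`call_peaks_ratio`): fragment fusion count vs the
  expectation `max(dam_count x library ratio, genome-wide control rate x
  fragment length, 0.25)`, upper tail only. The genome-wide floor
  prevents fragments where only the control is depleted from being
  called.
* **CaTaDa mode** (`call_peaks_accessibility`): control-free; the
  expectation is the max of the genome-wide rate and local rates in 5-kb
  and 10-kb windows centered on the fragment (a local-lambda background).

P-values are Benjamini-Hochberg corrected genome-wide (not per
chromosome); fragments with `q <= 0.05` are significant; significant
fragments separated by at most one non-significant fragment merge
(fragment-resolution signal makes a bp-based gap arbitrary); merged runs
with fewer than two significant fragments are dropped as
single-fragment noise. Peak summits are the center of the
smallest-p fragment.

# Differential binding

Peaks from all replicates of both lineages are chained by >= 1 bp overlap
into consensus intervals; an interval needs support from >= 2 peaksets.
Extended reads are counted over consensus intervals per sample to form
the binding affinity matrix.

The test is a deliberately simple negative-binomial Wald test rather
than a wrap of the established differential packages — the downstream
claim structure depends on thresholded classification, not a particular
shrinkage estimator:

* size factors by median-of-ratios against the per-peak geometric mean
  (peaks with a zero anywhere are excluded from factor estimation);
* one common dispersion $\phi$ by method-of-moments on normalized
  counts, pooled across peaks and groups, floored at $10^{-6}$
  (variance model $\mu + \phi\mu^2$);
* Wald statistic on $\log_2(\bar\mu_A/\bar\mu_B)$ with delta-method
  variance; when exactly one group mean is zero a half-count
  pseudo-mean keeps the statistic finite, and all-zero rows get p = 1.

Classification uses the inclusive thresholds FDR <= 0.01 and fold
change >= 2 (`|log2FC| >= 1`); `enriched_A` / `enriched_B` /
`not_differential`.

# Interval statistics

* **Overlap** is >= 1 bp, reported in both directions. Adjacency (zero
  shared bases) is not overlap.
* **Random peaksets** preserve, per chromosome, the number and the exact
  length multiset of the reference peaks; each peak is placed uniformly
  and independently (mutual overlap among random peaks permitted — the
  randomization matches independent placement, and forbidding collisions
  would bias long-peak chromosomes).
* **mc_overlap** randomizes the query set A while B stays fixed, n = 100
  iterations by default; **mc_signal_ratio** randomizes both sets,
  n = 1000, and compares mean signal over 4-kb windows (2 kb either side
  of peak centers). Both report the null mean and sd, Z-score, a
  one-sided parametric normal-tail p, and the empirical
  `p = (r + 1)/(n + 1)`. The parametric tail exists because genuinely
  strong enrichments produce p-values far below anything reachable
  empirically with a few hundred draws; the empirical p is the honest,
  assumption-free companion. Because the overlap statistic is an integer
  count, null draws can tie with the observed value, which makes the
  empirical p conservative (super-uniform); a tie-corrected mid-p, which
  stays exactly calibrated under exchangeability, is reported alongside.
  When the null has zero variance the result is flagged degenerate and
  only the empirical p is reported.
* The signal comparison reports both the ratio (headline) and the raw
  difference of grand means; descriptions of this analysis mix the two,
  so both are emitted rather than resolving the ambiguity.
* **closest_fisher** measures the distance from each query peak's center
  to the nearest reference peak edge (0 when the center lies inside
  one), counts centers within 2 kb, and tests the 2x2 table of two query
  sets with a two-sided Fisher exact test computed by exhaustive
  hypergeometric enumeration. This two-query-set form directly tests the
  printed comparison (counts near the reference in set A vs set B); the
  genome-background interval Fisher model of the external tool it
  replaces is a non-goal.

# Metaprofiles and correlation

`reference_point_matrix` bins +/-W around each peak center (defaults
W = 5 kb, b = 50 bp; matrix tools never state their bin size, 50 bp
resolves sub-fragment structure without bloating the matrix). Cells are
length-weighted bin means with uncovered bases as 0; bins extending past
a chromosome end are *absent* (excluded from column means), not
zero-filled, to avoid edge artifacts. Replicate correlation uses read 5'
ends in 1-kb bins so counts conserve library size exactly; bins all-zero
across samples are dropped; raw counts by default with a `log1p` option.

# The synthetic experiment

The generator encodes the causal model the analysis is meant to detect:
open chromatin gates transcription factor binding.

* A random i.i.d. genome (default three 2-Mb chromosomes, GC 0.5) gives
  GATC fragments of ~256 bp expected spacing — the natural resolution of
  the real assay.
* Open domains (150 shared, 120 per lineage, 8 fragments each ~ 2 kb)
  are placed uniformly without overlap, so truth labels are unambiguous
  for recovery scoring. Accessibility is 1 at baseline, x4 inside a
  lineage's open domains.
* Bound loci (100 shared, 100 per lineage, 2 fragments) are placed only
  inside open domains of the matching class; occupancy is 1 at baseline,
  x4 at bound loci. Real effect sizes for these folds are not
  established; 4 is a realistic mid-range choice that leaves the
  inference non-trivial at the default depth, and it is deliberately not
  revisited.
* Reads: expected fragment counts proportional to length x accessibility
  (x occupancy for the fusion channel), scaled to 4e5 reads/sample —
  the published experiments' ~0.2-0.4 reads/bp scaled to the 6-Mb toy
  genome — drawn independently per fragment as negative binomial with
  dispersion 0.1 (variance mu + 0.1 mu^2, a typical replicate-level
  overdispersion; 0 gives Poisson). Read starts are uniform within the
  fragment, strands fair coin flips, 100-bp reads truncated at
  chromosome ends rather than discarded. Library sizes therefore equal
  the target in expectation, not exactly — matching how sequencing depth
  actually varies.

What the generator does **not** emulate: sequencing errors, PCR
duplicates, mappability and GC bias, copy-number structure, chromatin
states between "open" and "closed", partial occupancy, or inter-locus
correlation. Passing tests show the pipeline recovers the truth when its
own model is correct; they do not show robustness to these real-data
complications.

# Determinism and numerics

Every stage seed derives from the global seed as a hash of
`(seed, stage name, labels)`, so adding a stage never perturbs earlier
stages' draws and whole-pipeline output is hash-identical across runs at
one seed. The Fisher p sums hypergeometric probabilities
`<= p_obs x (1 + 1e-7)` (the standard tie tolerance). Emitted signal
values are written with 6 significant digits. q-values of 0 are floored
at 1e-300 before -log10. Bedgraph/BED coordinates are 0-based half-open
externally; Bioconductor 1-based closed internally.

# Problem sizes in the test suite

The suite exercises the full pipeline at the default conditions above
(~2.5 minutes per run) and the statistical calibrations at reduced sizes
chosen for tight oracles: 1,000-fragment tables for normalization
equivalence, 10,000 random reads for extension equivalence, 100
repetitions for Monte Carlo p-value uniformity, 10-20 seeds for
null-calibration checks. These sizes are the package's own choice of the
smallest scales at which the checked properties are statistically
meaningful.

# Known limitations

* The peak caller is fragment-resolution and Poisson; it does not model
  fragment-size distributions or duplicate reads, and produces no
  broad-peak mode.
* The common-dispersion NB test will be anticonservative if dispersion
  varies strongly across loci; with three replicates per group this is
  the price of transparency, and the null-calibration tests bound the
  practical effect under the generator's conditions.
* Randomized peaksets are uniform within chromosomes; no GC-, gap- or
  mappability-aware shuffling.
* Interval statistics assume peaks are small relative to chromosomes;
  a reference peak spanning a whole chromosome degenerates to a forced
  placement.
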