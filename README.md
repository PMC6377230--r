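# tadakit

Lineage-resolved Targeted DamID (TaDa) and chromatin accessibility
(CaTaDa) analysis at GATC-fragment resolution.

## The problem

DamID maps protein-DNA interactions by fusing the *E. coli* Dam
methyltransferase to a protein of interest: everywhere the fusion binds,
nearby GATC sites acquire adenine methylation, which is read out by DpnI
digestion and sequencing. Two channels are profiled per cell type —
Dam-only (untethered Dam methylates open chromatin, giving an
accessibility readout, "CaTaDa") and the Dam-fusion (accessibility x
occupancy, "TaDa"). The natural resolution unit is the **GATC fragment**,
the interval between successive DpnI cut points (GA^TC).

tadakit is for researchers comparing a transcription factor's
genome-wide binding between two related cell lineages (for example two
individually identifiable neural stem cells) and asking whether
lineage-specific binding is *gated* by lineage-specific open chromatin.
It implements the complete analysis graph:

1. **Ratio profiling** — reads are extended to
   `min(300 bp, next GATC cut)`, counted per fragment, and converted to
   the normalized binding signal
   `log2((fusion_cpm + 0.5)/(dam_cpm + 0.5)) − f`, where the
   normalization factor `f` is the median log2 ratio over fragments
   outside the fusion top decile and outside the Dam bottom three
   deciles (decile-exclusion normalization).
2. **Peak calling** — a transparent fragment-level Poisson caller:
   one-sided tests against a Dam-only control (TaDa) or a local-lambda
   background (CaTaDa), BH-corrected at q <= 0.05, significant fragments
   merged across gaps of at most one fragment.
3. **Differential binding** — replicate peaksets are merged into a
   consensus (>= 1 bp overlap chains, support >= 2), extended reads are
   counted into a binding affinity matrix, and a common-dispersion
   negative-binomial Wald test classifies each locus as `enriched_A`,
   `enriched_B` or `not_differential` at FDR <= 0.01 and >= 2-fold.
4. **Interval statistics** — Monte Carlo overlap and signal-ratio tests
   against random peaksets that preserve per-chromosome peak counts and
   lengths (Z-score, parametric tail p, empirical `(r+1)/(n+1)` p and a
   tie-corrected mid-p), plus a closest-peak / Fisher-exact spatial
   enrichment test (centers within 2 kb of a reference set).
5. **Metaprofiles & QC** — reference-point signal matrices around peak
   centers and replicate Pearson correlation on binned coverage.
6. **Synthetic data** — a generator that encodes the
   "open chromatin gates binding" model (lineage-specific open domains,
   bound loci only inside open domains of the matching class,
   negative-binomial replicate noise), so the whole pipeline is testable
   end to end with no sequencing data.

See `vignettes/tadakit-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

The default configuration simulates the standard study conditions: two
lineages on a 6-Mb genome, 150 shared + 120 lineage-specific open
domains, 100 bound loci per class at accessibility and occupancy folds
of 4, three replicates of 4e5 reads per channel.

```r
library(tadakit)
run <- run_pipeline(pipeline_config(seed = 1), outdir = "run_out")
run
#> <pipeline_run> seed 1: 96/98 enriched A/B binding loci, recall 0.960, precision 0.990

run$overlap$A      # A-enriched binding vs A-enriched open chromatin
#> <overlap_result> A: 89/96 (92.7%), B: 88/116 (75.9%)
run$mc_overlap$A
#> <mc_result> observed 0.9271 vs null 0.0625 +/- 0.0213 (n=100): Z=40.59, p_param=0, p_emp=0.0099
run$signal_test    # lineage-A accessibility at A- vs B-enriched loci
#> <mc_result> observed 2.258 vs null 1.005 +/- 0.08007 (n=1000): Z=15.65, p_param=1.74e-55, p_emp=0.000999
run$closest
#> <closest_result> within 2000 bp: A 92/96, B 4/98; Fisher p = 1.53e-44
```

Reading: 96 and 98 loci are called differentially bound between the
lineages (of 100 + 100 simulated, recall 0.96 at precision 0.99); 92.7%
of A-enriched binding loci fall in A-specific open chromatin (Z = 40.6
against randomized peaksets, parametric p underflowing to 0); the
lineage-A accessibility signal is
2.26-fold higher around A-enriched than B-enriched binding loci; and
A-enriched loci are overwhelmingly the ones within 2 kb of A-specific
open chromatin (Fisher p ~ 1e-44). That is the causal structure the
generator encodes, recovered by the analysis.

`run_out/` contains the ratio bedgraphs, narrowPeak files, differential
tables, per-class BEDs, JSON statistics and a manifest with md5 hashes;
runs with the same seed are hash-identical.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/tadakit-cli.R`
(`simulate | profile | callpeaks | overlap-test | signal-test |
closest-test | metaprofile | correlate | run`).

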