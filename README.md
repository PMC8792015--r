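# promnuc

Nucleosome occupancy inference on promoter DNA from three complementary
assays, as a tested R package plus a small analysis workflow:

* **Single-molecule psoralen-crosslink EM.** Psoralen crosslinks
  protein-free duplex DNA; after deproteinization and denaturing
  spreading, nucleosome-protected regions open into single-stranded
  "bubbles". Given traced strand coordinates, the package calibrates
  pixel arc length to base pairs using the known template length
  (461 bp), builds per-base inter-strand distance profiles by
  closest-distance pairing, labels bases single-stranded above an
  empirically calibrated (Otsu) threshold, segments contiguous runs into
  bubbles, and scores a bubble as a nucleosome when it is longer than
  90 bp (bubble fusions count once).
* **Occupancy statistics.** Per-molecule nucleosome counts per condition
  are fit as Poisson (lambda-hat = sample mean) with 10,000-iteration
  bootstrap 95% CIs; conditions are compared with the exact conditional
  Poisson rate test: under equal rates, K_a | (K_a+K_b) ~
  Binomial(K_a+K_b, n_a/(n_a+n_b)).
* **MNase-ChIP occupancy + FP binding.** Mononucleosome-size fragment
  filtering, 1 bp TSS-oriented occupancy matrices and aggregate
  profiles, a >4.7-fold IP/input enrichment surrogate, windowed
  occupancy comparisons, and global single-site (probe-depletion
  quadratic) fits of fluorescence-polarization titrations with shared
  (Kd, free, bound) across replicates.

A synthetic-data generator plants known bubbles, +1 nucleosome dyads,
and binding curves, so every stage is verified against ground truth.
It is for chromatin biochemists and genomics analysts who want these
measurement models as reusable, tested functions rather than one-off
scripts. The methods vignette
(`vignettes/nucleosome-occupancy-methods.Rmd`) documents the models,
defaults, and limitations.

## Worked example

Simulate two reconstitution conditions of the 461 bp promoter template
and run the EM pipeline end to end:

```r
library(promnuc)
cfg <- pipeline_config(
  conditions = list(octamer      = list(lambda_true = 0.6),
                    octamer_muvb = list(lambda_true = 1.3)),
  n_molecules = 150L, n_boot = 10000L, seed = 400L)
report <- run_pipeline(cfg)
print(report)
```

```
<pipeline_report> 2 condition(s), threshold 5.94 px
<poisson_summary> octamer: lambda = 0.633 [0.507, 0.760], n = 150
<poisson_summary> octamer_muvb: lambda = 1.267 [1.107, 1.427], n = 150
```

The calibrated threshold (5.94 px) falls between the generator's closed
(2 px) and open (10 px) strand separations. Each condition reports the
mean nucleosome-sized bubbles per molecule with its bootstrap 95% CI;
the MuvB-containing condition roughly doubles occupancy, and
`report$pairwise_p["octamer", "octamer_muvb"]` (1.9e-08) is the exact
conditional Poisson p-value for that rate difference.

The numbered drivers under `analysis/` run the full workflow on
simulated inputs and write tables under `results/`:

```sh
Rscript analysis/01_simulate_conditions.R   # traces, fragments, titrations
Rscript analysis/02_em_bubble_statistics.R  # bubble calls + Poisson layer
Rscript analysis/03_mnase_tss_profiles.R    # TSS matrices, enrichment, diffs
Rscript analysis/04_fp_binding_fits.R       # global Kd fits
```

For example, `03` recovers the planted +1 nucleosome at +112 bp from the
TSS (planted +110) with 100% precision/recall at the 4.7-fold threshold,
and `04` reports Kd = 258 ± 12 nM for a titration simulated at 250 nM
while flagging the flat titration "no binding detected".

## Layout

```
R/                 implementation (simulators, geometry, bubble caller,
                   statistics, MNase occupancy, binding fits, IO, pipeline)
tests/testthat/    unit, property, and end-to-end acceptance tests
analysis/          numbered workflow drivers (write to results/)
scripts/           acceptance.R
vignettes/         methods vignette
```
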