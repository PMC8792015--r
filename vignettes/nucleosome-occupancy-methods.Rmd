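---
title: "Methods: single-molecule bubble calling, TSS occupancy profiling, and global binding fits"
author: "promnuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule bubble calling, TSS occupancy profiling, and global binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promnuc)
```

# Overview

`promnuc` implements three linked analyses of nucleosome occupancy on
promoters, each verifiable end to end against a synthetic-data generator
with known ground truth:

1. **Psoralen-crosslink EM bubble calling.** Trimethylpsoralen crosslinks
   protein-free duplex DNA; after protein digestion and denaturing
   spreading, formerly nucleosome-protected regions appear as
   single-stranded "bubbles" in electron micrographs. From traced strand
   coordinates the package reconstructs, per molecule, which base pairs
   were protected, and counts nucleosome-sized bubbles.
2. **Occupancy statistics.** Per-molecule bubble counts across
   reconstitution conditions are summarised by Poisson fits with
   bootstrap confidence intervals and compared with an exact conditional
   Poisson rate test.
3. **MNase fragment occupancy and FP binding fits.** TSS-oriented
   occupancy matrices and aggregate profiles at 1 bp resolution with a
   fold-enrichment surrogate, and global single-site fits of
   fluorescence-polarization titrations.

# The EM measurement model

## From traces to base pairs

A molecule is two ordered strand polylines in pixel coordinates, each
traced from an identified molecule end. The analysis needs three steps,
all deliberately simple and deterministic:

* **Orientation** (`orient_strands()`): the two strands may have been
  traced from opposite ends. The orientation minimising the summed
  endpoint-to-endpoint distance decides whether strand B is reversed.
  When the two pairings differ by less than a margin (default 1 px) the
  molecule is flagged ambiguous and excluded; with realistic spread
  molecules, whose end-to-end span is hundreds of pixels, ties occur only
  for pathological (nearly closed) traces. Molecules whose strand arc
  lengths differ by more than 15% are flagged as likely tracing errors;
  the threshold is configurable because no quantitative QC rule exists
  for this preparation.
* **Base calibration** (`assign_base_positions()`): the template length is
  known exactly (461 bp for the promoter fragment this workflow was built
  around), so each strand carries its own scale, total arc length /
  template length. Base $k$ (0-based) sits at arc length
  $(k + 0.5) \times \mathrm{scale}$, linearly interpolated along the
  polyline. The half-base offset treats the first and last base
  symmetrically and matches the 0-based half-open convention used for
  every interval in the package.
* **Pairing** (`pair_and_profile()`): for every base position on a
  reference strand (default: the longer-arc strand, which preserves
  resolution), the inter-strand distance is the Euclidean distance to the
  closest point of the other strand's polyline, measured point-to-segment
  so that uneven tracing density cannot inflate distances. A symmetric
  variant (average of both directions) is available by flag.

## Bubble segmentation and the 90 bp rule

Pooled per-base distances from a dataset are bimodal: crosslinked duplex
regions sit at the closed separation, bubbles at the open separation.
The threshold between them is determined empirically; the default method
is Otsu's two-class split of the pooled histogram because it is
deterministic, standard for bimodal separation, and needs no tuning.
When several splits tie for maximal between-class variance — which
happens exactly when the two modes are separated by an empty gap — the
centre of the tying plateau is returned, so the threshold lands midway
between the modes rather than at the gap's edge. Effectively unimodal
pools, where no split achieves positive between-class variance, are an
error instructing a manual threshold.

A base is labelled single-stranded if its distance **strictly exceeds**
the threshold; maximal runs of single-stranded labels are bubbles; a
bubble is a nucleosome if its length **strictly exceeds** 90 bp. Both
inequalities are strict by construction and unit-tested at the boundary
(a 90 bp bubble is never a nucleosome, a 91 bp bubble always is).
Adjacent nucleosomes can fuse into one long bubble; under the default
policy a fusion still counts as **one** nucleosome, which biases counts
down slightly but predictably (fusions are rare at these occupancies —
a few percent of bubbles). Bubbles longer than 240 bp (about 1.6
nucleosome footprints) are flagged `is_fusion_suspect` for diagnostics,
and a non-default `"divide"` policy (counting
$\max(1, \lfloor \mathrm{length}/147 \rfloor)$) exists for sensitivity
analysis.

Optional morphological cleanup — close label gaps of at most 2 bp, then
drop runs of at most 3 bp — absorbs isolated label flips under noise.
Both parameters default small and can be set to 0 for the literal
run-length behaviour, which the oracle tests use.

## Statistics layer

With $n$ molecules and counts $k_1 \dots k_n$:

* $\hat\lambda$ is the Poisson MLE, i.e. the sample mean; the fitted pmf
  is reported over the observed support.
* The 95% CI is a nonparametric bootstrap of the mean, 10,000 resamples,
  percentile interval. The percentile type matches plain resampling;
  BCa is available by flag.
* Two conditions are compared by conditioning on the total count: under
  equal rates, $K_a \mid (K_a + K_b) \sim
  \mathrm{Binomial}(K_a + K_b,\; n_a/(n_a + n_b))$, which handles unequal
  molecule numbers. The default two-sided p doubles the smaller tail
  (capped at 1); a minimum-likelihood variant (the convention of
  `stats::poisson.test()`, against which it is cross-checked in the test
  suite) is available by flag. The test is exact and mildly conservative;
  simulated type-I error at $\alpha = 0.05$ stays at or below 0.06.

# The trace generator

The generator is first-class, tested code: it defines the study
conditions under which every claim about the pipeline is verified.

* **Counts.** Per-molecule nucleosome numbers are Poisson(`lambda_true`)
  draws, truncated by physical packing: drawn bubble lengths are placed
  with at least `min_gap_bp` (default 5 bp) of duplex between them, and
  a count whose lengths cannot fit after rejection-resampling is
  decremented. The realized planted rate therefore sits slightly below
  `lambda_true` (about 0.04 low at $\lambda = 1.3$ on 461 bp), and the
  ground-truth table records the realized spans, which downstream
  recovery tests score against.
* **Lengths.** Nucleosome bubbles are normal(147, 15) bp truncated at
  $\pm 3$ SD, i.e. 102–192 bp: a bubble left by an octamer footprint
  cannot be much shorter than ~100 bp, and the truncation keeps planted
  "nucleosome-sized" unambiguous under the >90 bp rule. Sub-threshold
  small bubbles (uniform 20–60 bp, rate 0.2 per molecule) exercise the
  rule's lower side.
* **Geometry.** A smooth random backbone (cumulative turning angles,
  SD 0.05 rad/bp before an 11 bp running-mean smoothing) is rendered at
  2 px/bp; strands sit at $\pm\mathrm{sep}/2$ along the backbone normal.
  The separation is the closed value (2 px) outside bubbles and the open
  value (10 px) inside, joined by a cosine shoulder of half-width 2 bp
  centred on the span boundary, so the separation crosses the
  closed/open midpoint exactly at the boundary: strictly above it at
  every interior base, strictly below outside. The smooth shoulder
  avoids a rectangular opening that would make threshold calibration
  trivial. Polyline vertices are kept every 4 bp (a tracing click
  density) and jittered with Gaussian noise (default SD 0.5 px);
  configurations where open − closed < 2 × noise SD are rejected as
  physically unresolvable. Strand B is recorded in reversed order with
  probability 0.5 to exercise orientation recovery. The pixel scale and
  spread geometry of real micrographs are not published for this
  preparation; these defaults are explicit, exposed placeholders.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: micrograph pixels and skeletonization, psoralen
crosslinking chemistry or UV dose dependence, tracing mistakes beyond
coordinate jitter (skipped strand segments, crossovers), and
non-nucleosomal protection. One real physical effect it does share with
the experiment: the single-stranded path through a bubble is longer than
the duplex path per base, so the uniform arc-length calibration shifts
base assignments by a few bp near bubbles. Span boundaries move by that
small distortion, but both edges of a bubble shift coherently, so bubble
*lengths* — and therefore nucleosome counts — are essentially unaffected:
count recovery on noise-free data is exact in 100 of 100 simulated
datasets, and at default noise stays at or above 95% exact agreement.
This is also why count-vs-threshold monotonicity is only guaranteed in
the calibrated regime: far below it, two nearby bubbles merge across
their ramp saddle (a fusion), and raising the threshold can split the
fusion back into two countable nucleosomes.

# MNase occupancy

All intervals are 0-based half-open (BED convention); the TSS "+1" is the
first transcribed base and maps to matrix column 0. Fragments are
filtered to mononucleosome inserts (default 120–180 bp, bracketing the
~150 bp mononucleosome; exact bounds are configurable because published
pipelines rarely state them). Coverage counts whole-fragment overlap per
base (NucTools-style); a midpoint mode exists for dyad-style maps.
TSS matrices reverse minus-strand windows so all rows share a uniform
direction of transcription — mirroring the genome and the strands leaves
matrices bit-identical, which the suite asserts. Aggregate profiles
normalise each gene row to unit mean (zero rows are left out of the
column mean, not averaged in as zeros) before averaging columns.

Peak calling proper is out of scope; the enrichment surrogate preserves
only the thresholding logic: fragments overlapping the ±1 kb TSS window
are counted in IP and control, counts get +1 pseudocounts, are scaled by
library size, and the ratio is flagged above 4.7-fold. The windowed
occupancy comparison (default windows +100..+200 and −200..−100 bp)
takes the difference of across-gene mean normalised occupancy on the
shared gene set and attaches a paired gene-level bootstrap p (10,000
resamples, add-one smoothed two-sided percentile); the underlying
published comparison does not state its test, so the bootstrap is the
package's documented choice, cross-checked against a sign-flip
permutation oracle in the tests.

The fragment generator plants a +1 dyad at TSS + 110 bp in transcription
direction with Gaussian positional fuzziness (default 20 bp), insert
lengths normal(150, 20) clipped at 1, and exact per-gene fragment
totals. Enriched genes (default half) receive positioned IP fragments
with a 20% uniform background; non-enriched genes shed only that
nonspecific background into the IP, and the input sample is 95% diffuse —
an input library samples the whole genome, so its per-promoter positioned
signal is heavily diluted relative to an IP concentrated on its targets.
Without that asymmetry no gene can exceed ~2-fold enrichment by
construction and a 4.7-fold threshold would be meaningless.

# FP binding fits

The single-site bound fraction uses the exact mass-balance (depletion)
solution
$$ f = \frac{R_t + L_t + K_d - \sqrt{(R_t + L_t + K_d)^2 - 4 R_t L_t}}{2 L_t}, $$
evaluated in the rationalised form $2R_t / (s + \sqrt{s^2 - 4R_tL_t})$,
which is numerically stable and passes smoothly to the hyperbolic limit
$R_t/(R_t + K_d)$ as $L_t \to 0$. The depletion form is the default
because the probe is at 20 nM and affinities can be comparable; the
hyperbola costs accuracy there and is kept only as a flag.

The global fit shares $(K_d, \mathrm{fp}_\mathrm{free},
\mathrm{fp}_\mathrm{bound})$ across all replicate points. $K_d$ is
optimised as $\log K_d$ within $[\min R_t / 100,\; \max R_t \times 100]$
for conditioning; for each start on a 25-point log grid the two
polarization endpoints are profiled out by linear regression (the model
is linear in them given $K_d$), and the best starts are polished with
Levenberg–Marquardt. The returned optimum is never worse than any
multistart seed, which the suite asserts. Standard errors come from the
final Jacobian; the $K_d$ SE is delta-transformed from the log scale.
A fit is reported "no binding detected / $K_d$ above the titrated range"
when the fitted amplitude is below 3× the residual SD or the fitted
$K_d$ exceeds 10× the top titrant concentration — mirroring how flat
titrations are reported in practice. A reportable series needs at least
4 distinct concentrations spanning 2 orders of magnitude.

The titration generator draws the mean response from the same quadratic
model (so generator and fitter share only the closed-form physics, not
code paths — the oracle for the model itself is an independent numerical
root finder) with i.i.d. Gaussian well noise in triplicate.

# Numerical and design choices

* Strict ">" at both the distance threshold and the 90 bp rule; boundary
  behaviour unit-tested.
* Otsu plateau-centre tie-break (above); 256 histogram bins.
* Cleanup defaults g = 2 bp, d = 3 bp; 0/0 gives literal run-length
  behaviour.
* Orientation ambiguity margin 1 px; arc-length mismatch QC at 15%.
* Bootstrap percentile intervals, add-one smoothing only for the paired
  window-difference p (where a raw 0 would otherwise be reported).
* Tail-doubling two-sided exact p by default, min-likelihood by flag.
* One RNG stream per simulated dataset, seed recorded in the output
  metadata; pipeline reports carry a config hash, the seed, and the
  package version, and fixed seeds reproduce bit-identical reports.

Problem sizes used by the test and acceptance runs — 100 noise-free and
25 noisy 150-molecule datasets for count recovery, 500 bootstrap-coverage
datasets, 2,000 equal-rate pairs for type-I error, 1,000 random fragment
sets for coverage conservation, 200 noisy titrations for Kd recovery —
are the package's own verification design: large enough that the checked
rates are stable to a percent or two, small enough to run routinely.

# Known limitations

* The EM pipeline assumes 2D spread molecules and two complete strand
  traces; partial traces and crossing strands are not modelled or
  recovered.
* Base calibration inherits the uniform-scale assumption; single-stranded
  regions are physically longer per base, shifting assignments a few bp
  near bubbles (counts are robust; exact bubble *positions* are biased
  accordingly).
* The enrichment surrogate is not a peak caller; it reproduces a
  fold-threshold contract on fixed TSS windows only.
* The windowed occupancy comparison tests a difference of means under
  gene resampling; it does not model fragment-level noise within genes.
* The binding model is single-site; cooperative or multi-site titrations
  will show structured residuals rather than a refusal to fit.
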