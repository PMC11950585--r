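---
title: "Monitoring imaging streams for OOD inputs and data drift with SPC charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring imaging streams for OOD inputs and data drift with SPC charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcdrift)
library(dplyr)
```

## The monitoring problem

A deployed imaging model was trained on some in-distribution (ID) population —
say axial CT slices, or adult chest radiographs. Once in production, the input
stream can drift: wrong acquisition planes, different modalities, demographic
shifts. The model keeps producing outputs either way, so the failure is
silent. `spcdrift` monitors the *inputs*: every image is embedded in a feature
space, scored by a geometric out-of-distribution (OOD) metric against a
reference profile fitted on ID data, and the scores are tracked with
statistical process control (SPC) charts — a three-sigma chart for flagging
individual images, and a CUSUM chart over daily mean scores for detecting
small sustained drift.

The pipeline is deliberately model-agnostic: any feature extractor can stand
in front of it, and the charts only ever see scalar metric values.

## Reference profile and OOD metrics

`fit_reference()` computes, from an ID embedding matrix:

* the mean feature vector $\boldsymbol\mu$ (the reference point),
* the sample covariance $S$ plus a small ridge (below),
* the mean $\mu$ and standard deviation $\sigma$ of the chosen metric over
  the reference images themselves.

Two metrics are supported. Cosine similarity,
$\mathrm{CS}(\mathbf a,\mathbf b)=\mathbf a\cdot\mathbf b/(\lVert\mathbf
a\rVert\,\lVert\mathbf b\rVert)\in[-1,1]$, is non-parametric and
scale-free; drift shows up as a *drop* in similarity to $\boldsymbol\mu$.
Mahalanobis distance,
$D_M(\mathbf x)=\sqrt{(\mathbf x-\boldsymbol\mu)^\top S^{-1}(\mathbf
x-\boldsymbol\mu)}$, accounts for feature variances and covariances; drift
shows up as *growth*. Both are computed post hoc in representation space, so
nothing about the upstream model needs to change.

Numerical choices:

* The covariance ridge defaults to $10^{-6}\,\mathrm{tr}(S)/p$. It guarantees
  a usable Cholesky factor when $n < p$ or features are collinear while
  perturbing the informative eigenvalues by a relative $10^{-6}$. Distances
  are always computed through the stored factor, never an explicit inverse.
* A reference set whose images all score identically ($\sigma = 0$) has no
  usable control limits; `fit_reference()` refuses it loudly rather than
  emitting infinite-sensitivity charts.
* Zero-magnitude embeddings make cosine similarity undefined. They indicate
  an extractor fault, so scoring raises an error naming the offending image
  instead of silently returning 0.
* The reference $\mu/\sigma$ are computed on the fitting split itself. If a
  held-out ID split is preferred, fit the profile on one split and read
  $\mu/\sigma$ from a profile fitted on the other; both are plain function
  calls.

## The charts

**Per-image three-sigma chart.** An image is flagged when its metric falls
strictly outside $[\mu - 3\sigma,\ \mu + 3\sigma]$. Values exactly on a limit
are in control — the chart flags *exceedance*. Under Gaussian in-control
scores the false-positive rate is $2\Phi(-3)\approx 0.27\%$, which the test
suite checks by simulation. The multiplier is a parameter; a two-of-three
run rule at the $2\sigma$ limits (`run_rule_two_of_three()`) is available for
applications that need more sensitivity to moderate shifts.

**Daily CUSUM.** Each day's batch is collapsed to its mean metric $x_i$ and
tracked by the tabular CUSUM
$$S_i^+ = \max(0,\ S_{i-1}^+ + x_i - \mu_0 - k), \qquad
  S_i^- = \min(0,\ S_{i-1}^- + x_i - \mu_0 + k),$$
with $\mu_0$ the in-control mean. The high side alarms when $S_i^+ > h$;
since $S^-$ is kept non-positive, the low side alarms when $|S_i^-| > h$
(the low-side signal crossing $-h$). Defaults are the classical
$k = \sigma/2$ and $h = 4\sigma$. The state is *not* reset after an alarm: a
sustained shift keeps signalling, which is itself evidence that the first
alarm was real, and all alarm days are reported.

**Which $\sigma$ for $k$ and $h$?** This is the one genuinely open design
choice, because $k$ and $h$ chart a *daily mean* while the profile's
$\sigma$ is *per-image*. `monitor_stream()` defaults to the raw per-image
$\sigma$ (`cusum_scale = "per-image"`). The alternative,
`"daily-mean"`, rescales by $\sqrt{d}$ for a batch of $d$ images. We made
per-image the default for two reasons. First, calibration: with
$k = 0.5\,\sigma_{\text{chart}}$ and $h = 4\,\sigma_{\text{chart}}$ on a
correctly scaled statistic, the standardized in-control run length is only a
couple of hundred steps, so over a two-month horizon a false alarm is more
likely than not — a chart nobody would deploy at those defaults. Expressed
in per-image $\sigma$, the same defaults give an allowance of $5$
daily-mean standard deviations (at $d = 100$): noise alone essentially never
accumulates, and the chart responds only when contamination moves the daily
mean by a percent-scale fraction of the ID–OOD separation. Second, that is
the operating regime in which the whole design — quiet first month at 0–1%
contamination, alarm within days at 3–5% — is reproducible; the scaled
convention remains available for deliberately hypersensitive monitoring.

For cosine similarity drift manifests on the low side and for Mahalanobis on
the high side, but both charts are run two-sided and the report annotates
the alarm side rather than assuming a direction.

The daily three-sigma chart reuses the per-image limits by default. Daily
averaging smooths percent-level contamination far inside those limits, so
this chart is expectedly insensitive — which is exactly the behaviour worth
demonstrating next to CUSUM. Passing `tighten_daily_limits = TRUE` rescales
its $\sigma$ by $\sqrt{d}$ for a properly calibrated daily Shewhart chart.

## The drift simulator

`drift_scenario()` + `generate_stream()` emulate a monitored facility:
$N$ days, $d$ images per day, each image's feature vector drawn from a
diagonal-Gaussian ID cluster or from one of the OOD clusters. Phases tile
the horizon; each day draws its OOD fraction uniformly from the active
phase's interval. The bundled `ct_drift_scenario()` preset runs 60 days at
100 images/day with a 0–1% OOD rate for the first month and 3–5% (2–4% for
`cxr_drift_scenario()`) from day 31 — the second month models the drifted
regime, with the shift starting the day after the midpoint.

Generator decisions, fixed once at design time:

* **Counts.** The daily OOD count is `round(rate * batch)` with R's
  round-half-to-even, unbiased over uniformly drawn rates. A per-image
  Bernoulli option (`rate_model = "per-image"`) exists for streams where
  day-level counts should themselves be noisy.
* **Cluster geometry.** Feature dimension 8; ID cluster
  $\mathcal N(\mathbf m, I)$ with $\mathbf m = (3.5,\dots,3.5)$; the OOD
  cluster flips the sign of half the coordinates, making its mean orthogonal
  to $\mathbf m$ at equal norm. In cosine terms this yields an ID score of
  about $0.966 \pm 0.019$ and OOD scores near 0 — a separation of roughly
  $50$ per-image standard deviations. That scale was chosen (by a one-off
  design calculation, not by iterating on tests) so that the preset
  reproduces the qualitative regime of interest: a single OOD image per day
  (the 0–1% phase) moves the daily mean by just under the CUSUM allowance,
  while 3–5% contamination exceeds it several-fold and alarms about two
  days after the shift.
* **Multiple OOD subtypes** are mixed uniformly per image, there being no
  principled proportion to prefer.
* **Seeding** is hierarchical: the scenario seed spawns one substream per
  day, so day $k$'s data is bit-identical across scenarios that differ only
  in other days' parameters. Streams serialize byte-identically from the
  same seed.

What the simulator does *not* model: anatomy, scanner physics, correlated
slices from the same patient, non-Gaussian embedding geometry, or gradual
(rather than stepwise) drift. Tests passing on these streams demonstrate the
statistical machinery, not performance on clinical data.

## Desk-scale feature extractors

For end-to-end exercises the package bundles a toy image task and four
extractors (`feature_extractor()`):

* `stats_baseline`: mean, population SD, skewness, excess kurtosis, plus
  eight gray-level co-occurrence summaries (contrast, dissimilarity,
  homogeneity, energy, entropy, correlation, maximum probability, cluster
  shade) at 8 gray levels over right/down neighbours, symmetrized. Constant
  images define skewness, kurtosis and correlation as 0 to keep control
  limits finite.
* `autoencoder`: dense encoder–decoder trained by minibatch SGD on
  reconstruction error; the embedding is the bottleneck activation.
* `supervised_bce`: dense binary classifier; embedding from the penultimate
  layer by default, or the logits via `embedding_layer = "logits"`.
* `contrastive`: dense encoder trained with a pairwise margin loss — squared
  distance for same-label pairs, squared hinge on `margin` minus distance
  for different-label pairs.

These are compact single-hidden-layer networks sized so the full training
loop runs in seconds on one CPU; the monitoring framework never sees
anything but their output vectors, so swapping in a production CNN changes
no downstream code.

The toy images are 28×28 grayscale: discs with jittered centre, radius and
contrast (ID) versus oriented stripe gratings (OOD). Both classes share the
same foreground-area and intensity distributions, so first-order intensity
statistics overlap by construction and the separation lives in shape and
texture. That is what makes the comparison informative: the statistics
baseline separates the classes only partially, supervised and contrastive
embeddings separate them almost completely, and a strongly compressed
autoencoder — we use a 2-unit bottleneck, matching the roughly
two-dimensional (radius × contrast) variation of the ID family — yields the
characteristic low-sensitivity/high-specificity profile of reconstruction-
oriented features: its compressed representation places OOD images at ID-like
distances, so the three-sigma chart flags few of them, in either direction.

In the end-to-end toy monitoring exercise the pre-shift month is kept purely
in-distribution. With such separable embeddings even sub-1% contamination is
(correctly) detectable, so a contaminated "in-control" phase would make the
notion of a false alarm meaningless at desk scale; pure ID pre-shift keeps
"quiet before the shift, alarm within days after it" a well-posed check.

## Evaluation protocol

`confusion_stats()` reports sensitivity (flagged fraction of true OOD),
specificity (unflagged fraction of true ID) and accuracy, refusing
populations with a missing class. `bootstrap_ci()` repeats the computation
on `n_bootstrap = 100` subsets of `subset_size = 500` drawn uniformly *with*
replacement and reports percentile (2.5/97.5) intervals; replicates that
miss a class are redrawn (counted, at most 10 attempts each). Oversized
subset requests are clipped with a warning. `scenario_sweep()` re-runs whole
seeded scenarios over a grid of CUSUM settings with paired replicate seeds,
so monotone effects of `k` (fewer false alarms, longer delays) hold pathwise
rather than merely on average.

## Problem sizes used by the test suite

The suite exercises the framework at the preset's full stream size
(60 × 100): 200 replicates for delay and false-alarm statistics, 100 per
setting for rate- and allowance-monotonicity sweeps, $10^6$ draws for
three-sigma calibration, $10^4$ for profile recovery, and 300 training /
600 test toy images for the extractor comparison. These sizes keep every
statistical check comfortably reproducible under fixed seeds.

## Known limitations

* Simulated streams are i.i.d. within day and stepwise-drifted; real drift
  is often gradual and autocorrelated.
* The charts monitor one metric at a time; a deployment worried about both
  orientation drift *and* covariance inflation should run cosine and
  Mahalanobis monitors side by side.
* An alarm localizes *when* the input distribution changed, not *why*; root
  cause analysis is out of scope.
* The bundled encoders are CPU-scale conveniences, not competitive feature
  extractors for real radiology data.
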