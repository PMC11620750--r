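---
title: "Methods: word-level naturalistic fMRI analysis in conceptflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: word-level naturalistic fMRI analysis in conceptflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

conceptflux implements a word-level analysis chain for naturalistic
(movie-watching) fMRI aimed at one scientific question: do concrete and
abstract words modulate distinct brain systems, and does that modulation
shift with the visual context in which a word is heard? The chain has five
statistical stages — amplitude-modulated deconvolution, group mixed-effects
inference, multi-threshold cluster correction, peaks-and-valleys reverse
correlation, and contextual-situatedness scoring — plus a synthetic-data
generator that plants known ground truth in every input so each stage can be
validated end to end without any imaging data. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices,
and what the validation does and does not establish.

## Amplitude-modulated deconvolution

Words in a film arrive continuously, so the BOLD response to each word is
estimated by deconvolution rather than by assuming a canonical hemodynamic
response. For every regressor set $s$ (concrete words, abstract words,
remaining words, and optionally all no-speech timepoints) the model estimates
an impulse-response function (IRF) on a 20-s window after word onset,
sampled at 21 knots ($t = 0, 1, \dots, 20$ s at TR = 1 s):

$$
y(t) = \sum_s \sum_{e \in s} \Big[ \alpha_s
      + \textstyle\sum_m \beta_{s,m} (x_{e,m} - \bar{x}_{s,m}) \Big]
      \, h_s(t - t_e) + \text{drift}(t) + \varepsilon(t),
$$

where each $h_s$ is expanded in an interpolating basis. Two bases are
provided: `tent` (piecewise linear) and `csplin` (cardinal natural cubic
splines, the default — smoother interpolation between the 1-s knots). Both
are *cardinal*: evaluated at the knots they form the identity, so a
coefficient is the IRF value at its knot.

Per-event amplitudes are modulated by one covariate of interest — the word's
concreteness rating (0–5) — and five nuisance covariates: luminance,
loudness, duration, log word frequency, and speaking rate (phonemes/s).
Modulators are centered within their regressor set; without centering the
onset and modulator columns would be confounded. A consequence used by the
tests: adding a constant to all of a set's modulator values leaves the
modulator coefficients unchanged.

Decisions worth knowing:

* **20 contrast timepoints from 21 knots.** Contrasts and per-timepoint
  tests are reported at $t = 1, \dots, 20$ s; the $t = 0$ knot (pre-response)
  is estimated but not tested. The per-side area under the curve is the
  plain sum of the evaluated IRF over the 20 contrast timepoints.
* **Estimation is OLS** with per-run Legendre drift polynomials (order 2 by
  default). Residual autocorrelation is deliberately handled at the *group*
  stage, not by single-subject prewhitening, mirroring the division of
  labor of the analysis this package implements. Single-subject t
  statistics are therefore exactly calibrated under exchangeable noise and
  mildly anticonservative under AR(1) noise — a documented limitation, and
  why the type-I validation simulates white noise.
* **Collinearity guard.** The design's condition number is checked against
  `1e8`; rank-deficient designs abort with the dependent columns named. A
  caution: with strictly regular word onsets on the TR grid, the
  partition-of-unity of onset columns plus a no-speech set is exactly
  collinear with the intercept; continuous (jittered) onsets, as in real
  speech, avoid this.

## Group inference

Per-subject interest-modulator IRF values (20 per class) enter a voxelwise
linear mixed-effects model (REML, via nlme) with a random intercept per
participant, covariates for age (centered), gender and movie, and an
optional AR(1) structure for within-subject residuals over the time factor.
Because per-timepoint concrete-vs-abstract contrasts require the
contrast-by-time cell means to be estimable, the fixed effects are
`contrast * time + age + gender + movie` (and
`word_type * context * time + ...` for the context analysis); constant
covariates and single-level factors are dropped automatically, so the
degenerate one-timepoint, covariate-free design reduces *exactly* (to about
1e-8 relative accuracy, enforced by test) to the paired t-test. The context
analysis reports four general linear tests collapsed over time by averaging
the per-timepoint contrast rows — no timing prediction is imposed — plus a
word-type-by-context interaction (double difference). Voxels where the mixed
model fails to converge fall back first to a stock-tolerance refit, then to
the no-random-effect fit, and are counted (`fallback_count`), so
mass-univariate analyses proceed.

REML with AR(1) is a package decision; the estimator behind the original
analysis tool is not documented, so equivalence is validated against
*reductions* (paired t, balanced OLS estimates) and planted-effect recovery
rather than against another mixed-model implementation.

## Multi-threshold cluster correction

Smoothness is estimated from residual maps as an isotropic spatial ACF at
integer voxel lags (averaged over axes and volumes). Two summary scales are
reported: `fwhm`, the half-width of the ACF itself — the resolution of the
field, 1 voxel for white noise — and `kernel_fwhm`, the FWHM of the Gaussian
kernel that, applied to white noise (with voxel-box sampling accounted for,
ACF variance $= 2\sigma_k^2 + 1/6$), reproduces that ACF. The null simulator
consumes `kernel_fwhm`: white noise is smoothed circularly in the Fourier
domain with a unit-sum-of-squares kernel, giving exactly unit-variance
fields, so estimation and simulation invert each other (validated: a
2-voxel-FWHM generator setting is recovered within 15%).

`simulate_thresholds` finds, for each of nine voxelwise two-sided p values
(0.05 … 0.0001), the smallest cluster extent $k$ whose noise-only exceedance
probability is at most the corrected $\alpha = 0.01$, using 26-connectivity
with positive and negative voxels clustered separately. `multithreshold_merge`
then keeps any voxel belonging, at some threshold, to a cluster of that
threshold's size, retains original z values, and drops final components
under 20 voxels.

A property users should know: each of the nine thresholds individually
controls family-wise error at 0.01, but their *union* is looser, because a
null map can produce either a large-weak or a small-tall cluster — the nine
exceedance events are only partially dependent. On 24³ unit-variance fields
at kernel FWHM 2 the merged map's empirical family-wise rate is about
0.025–0.04 (the acceptance script recomputes this as `cluster_fwe_rate`).
Tightening it would require calibrating each threshold below 0.01, which
would depart from the per-threshold definition this procedure is built on;
the merged map should therefore be read as corrected at a mildly
anticonservative 0.01 (roughly 0.03 family-wise).

## Peaks-and-valleys reverse correlation

For each surviving cluster the in-cluster mean BOLD series is reduced to
peaks and valleys by the discrete difference $\Delta x[i] = x[i+1] - x[i]$:
a peak is a $+\to-$ sign change, a valley the reverse, runs of zero
difference (plateaus) count once at their floor-midpoint, and endpoints are
excluded (all verified against a brute-force enumeration of every short 0/1
series). Words are attached to an extremum at time $t$ if their onset falls
in the one-TR window $[t - L - \tfrac{1}{2}, t - L + \tfrac{1}{2})$ for
hemodynamic lags $L \in \{4, 5, 6\}$ s; onsets (not offsets or spans) are
used. Each attached word is binarized against each of the 13 experiential
dimensions (Auditory … Valence, Arousal): 1 iff its rating is at least one
corpus SD above the corpus mean — inclusive at the boundary, high tail only.
Peak and valley arrays are compared with a tie-corrected Kruskal-Wallis
statistic,

$$
H = \frac{\frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \bar R)^2}
         {1 - \sum_t (t^3 - t) / (N^3 - N)},
$$

with p from $\chi^2_1$; when every pooled value ties, $H = 0$, $p = 1$. A
dimension is *associated* with a cluster when $p < 0.05$ (uncorrected — the
analysis is exploratory) and peaks carry more high-rated words than valleys.
Agreement between lags is the cosine of their 13-long binary association
vectors; extremum types with fewer than 5 attached words are flagged low-n
and not tested.

## Contextual situatedness

Each concrete/abstract word is scored against the objects visible just
before it is spoken: object labels with detection confidence ≥ 0.9
(inclusive) are kept; labels detected at least 3 population-SDs more often
than the mean label count are removed everywhere (on real movies this
removes ubiquitous generics like "person"); the context vector is the
unweighted mean embedding of every remaining label *appearance* (repetition
counts) in the 2-s pre-onset window; and the situatedness score $c$ is the
cosine between the word's embedding and that context vector. Words with
$c > 0.6$ are situated, $c < 0.4$ displaced, the closed middle band is
excluded; the four word-type-by-context cells are then subsampled (seeded,
without replacement) to the smallest cell. Multi-token labels missing from
the embedding vocabulary fall back to the mean of their constituent tokens;
out-of-vocabulary words and zero-label windows are excluded and counted,
never imputed. Cosines can be negative with real embeddings; negative
scores classify as displaced and their count is reported.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline targets:
TR 1 s, 600-s runs, 80 words per class, concreteness-rating means 3.22
(concrete) vs 1.83 (abstract) with within-class SD 0.5, shared log-frequency
distribution (mean 3.61), luminance means 0.72 vs 0.65 and loudness 0.69 vs
0.77 (SD 0.12), and label streams at the 0.16-s prediction-frame cadence
(a "2-s (60 video frames) context window" therefore holds 12 prediction
frames). Words are spaced at least 2.25 s apart so each word's 2-s context
window precedes it cleanly. The true IRF is a difference of gammas with
configurable peak latency (default 5 s) — deliberately *outside* both
estimation bases, so recovery tests are not circular. Noise is AR(1)
(coefficient 0.3 by default, typical at TR 1 s). The noise scale is set by
an *effect* signal-to-noise ratio: SNR is the SD of the interest-modulated
signal component over the noise SD (default 1). Calibrating noise to the
component being recovered keeps benchmark difficulty invariant to the
(large, separately estimated) onset response; an explicit `noise_sd`
overrides it.

Planted ground truth covers every downstream stage: per-voxel modulation
weights (IRF recovery), situated words whose context labels are embedding
neighbours (cosine to the word vector near 1) versus displaced words with
unrelated background labels (cosine near 0), norms pushed ≥ 1 corpus SD
above the mean on designated dimensions, and a peaks-and-valleys generator
that plants high-rated words one hemodynamic delay before detected peaks
with ±0.5-s onset jitter.

What the generator does *not* emulate: real movie statistics (dialogue
bursts, correlated luminance/loudness dynamics), motion artifacts,
multi-echo/multiband acquisition physics, spatially varying smoothness, or
embedding anisotropy. Passing validation therefore demonstrates estimator
correctness under the stated model, not robustness to everything real data
can do.

## Validation scale and numerics

The test suite and `scripts/acceptance.R` rerun every property from scratch
at these sizes (chosen as the smallest that make the Monte-Carlo bounds
meaningful): IRF recovery over 60–100 seeded 600-s runs; per-timepoint
type-I calibration over 100–200 null runs (white noise, see above); cluster
thresholds from 3000–5000 null fields on a 24³ grid with 300–500 fresh maps
for the achieved family-wise rate; peaks-and-valleys recovery over 60–100
runs; situatedness over 200 words. Mixed-model fits use strict nlme
tolerances (`msTol 1e-14`, `tolerance 1e-12`, nlminb) so degenerate-design
reductions hold to ~1e-8; every stochastic stage derives its sub-seed from
one master seed, and identical configurations are bit-reproducible.

## Known limitations

* Single-subject OLS t statistics are anticonservative under autocorrelated
  noise; inference is meant to be drawn at the group stage.
* The merged multi-threshold map is mildly anticonservative (above).
* The peaks-and-valleys test assumes word attachment by onset and a 1-TR
  window; published variants of the method are not explicit about either.
* Printed group-level H statistics in the literature this method family
  comes from imply a three-group structure that cannot be reconstructed
  from their text; nothing in this package attempts to reproduce them.
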