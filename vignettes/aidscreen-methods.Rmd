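---
title: "Models and methods behind aidscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aidscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidscreen)
```

This vignette explains the statistical models the package implements, the
choices made where the procedures left genuine freedom, what the
synthetic-data generators do and do not emulate, and the known limitations.

# Competition fitness

## Model

Two strains are co-cultured and sampled by flow cytometry once per interval
$\Delta t$ (default 24 h). Growth is modeled as effective exponential at
rate $\ln 2 / T$ per hour: the daily dilution of the co-culture multiplies
both populations equally and cancels from every count ratio, so a single
effective doubling time per strain suffices and saturation kinetics need
not be modeled. If the reference strain doubles every $T$ hours and its
competitor every $T(1+\delta)$ hours, the expected log count ratio gains

$$\alpha = \Delta t \cdot \ln 2 \left(\frac{1}{T} -
  \frac{1}{T(1+\delta)}\right)
  = \frac{\Delta t \ln 2}{T}\cdot\frac{\delta}{1+\delta}$$

per interval. `alpha_from_doubling_diff()` implements this map and its
inverse. At $T = 4.5$ h and $\Delta t = 24$ h, $\delta = 0.05$ gives
$\alpha = 0.1760$ and $\delta = 0.20$ gives $\alpha = 0.6161$; the
conventional decision thresholds 0.175 and 0.611 correspond to
$T \approx 4.53$ h, inside the $\pm 0.1$ h uncertainty of the measured
doubling time, so the printed constants are kept as configurable defaults
(`bias_thresholds()`) rather than recomputed.

## Estimation

`estimate_alpha()` fits the zero-intercept regression
$\hat\alpha = \sum_t t\,y_t / \sum_t t^2$ over days $t > 0$, with
$y_t = \ln[(n_1/n_2)(t)/(n_1/n_2)(0)]$. Forcing the intercept through the
origin uses the day-0 measurement as the normalization point rather than a
free parameter. The standard error comes from the residuals with $n-1$
degrees of freedom. Numerical edge cases:

* a zero count at any time point adds 0.5 to **both** classes at that point
  and flags the fit `pseudocount_used` — the well stays analyzable but
  marked;
* fewer than two usable post-baseline points flags `insufficient` and
  returns `NA`;
* double-positive events are counted separately (`n_double`) and excluded
  from both marker ratios, since they cannot be attributed to either
  strain.

Gating thresholds derive from a non-fluorescent control, by default its
per-channel maximum (`gate_config("control_max")`); a quantile rule
(`"control_quantile"`, e.g. 0.9999) is available when the control contains
outliers. The small marker-pair fitness baseline observable between two
untagged marker strains is reported by the generator (`marker_offset`) but
not subtracted by the estimator, the measured effect being small against
the decision thresholds.

Triple co-cultures (`fit_triple()`) reuse the same estimator on three
ratios; the slopes satisfy
$\alpha(A,B) = \alpha(A,\mathrm{wt}) - \alpha(B,\mathrm{wt})$ exactly in
the noiseless limit, which the tests verify by construction.

# Colony fluorescence and degradation classification

## Dual-gain consolidation

The plate reader records each colony at two detector gains so dim and
bright colonies both land in a usable range. The two channels are modeled
as affine transforms of the true intensity with hard saturation of the
high-gain channel. `consolidate_gains()` fits
`high ~ gain_factor * low + offset` by least squares on colonies
unsaturated in both channels (at least 3 required) and outputs the
high-gain reading where valid, otherwise the calibrated low-gain reading.
Preferring the high-gain channel keeps the better signal-to-noise for dim
colonies; the calibration extends the same scale beyond the ceiling.

## Group normalization and classification

Every ORF occupies one 4×4 group holding 6 OsTIR1⁺ replicates, 3 OsTIR1⁻
replicates, 3 non-fluorescent background colonies and 4 bright reference
colonies. Dividing all 16 colonies by the group's reference mean cancels
smooth spatial and plate effects at the scale of the group; the group's
background mean (on the reference-normalized scale) then provides both
corrections used downstream: division (mNG/bkg) and subtraction (mNG−bkg).

Classification (`classify_degradation()`, defaults in
`degradation_thresholds()`): a strain whose OsTIR1⁻ level is at most 1.2×
background is *not detected*; otherwise the degradation fold
$\rho = (\mathrm{mNG{-}bkg})^+ / (\mathrm{mNG{-}bkg})^-$ (clipped at 0, and
undefined — routed to not-detected — when the OsTIR1⁻ background-corrected
level is non-positive) decides: $\rho < 0.5$ with a significant
unequal-variance t-test means *degraded* (if the OsTIR1⁺ level is itself at
or below 1.2× background) or *partially degraded* (if not); anything else
detected is *not affected*. Two choices the rule set leaves open are
resolved as: the t-test is Welch's (two-sided, unequal variance), and the
significance gate uses the BH-adjusted p-value, with all strains analyzed
together forming one family. The rules partition — every strain gets
exactly one label — and raising the fold threshold can only move strains
toward the depleted classes, both properties covered by tests.

## Detection-limit calibration

`calibrate_detection_limit()` regresses log normalized fluorescence on log
absolute abundance over calibration strains and inverts the fit at a
fluorescence threshold, by default mNG/bkg = 1.2 — the same boundary that
defines detectability in the classifier. The confidence interval is a
parametric bootstrap (default 2,000 draws): responses are resampled from
the fitted line plus Gaussian residual noise, the regression is refit in
closed form and the limit recomputed per draw. An exact calibration line
yields a zero-width interval.

# Colony-size screens and CGI scoring

## Normalization chain

Per plate: (1) `trim_border()` removes the 4-deep frame of dummy colonies
whose growth advantage at the plate edge would otherwise distort
everything downstream; (2) `spatial_correct()` divides by a local-median
surface (7×7 window, clipped at plate edges) rescaled to plate median 1 —
the median makes the surface robust to isolated sick or jackpot colonies
while tracking smooth gradients; (3) `robust_plate_normalize()` divides by
the median of the colonies lying between the 40th and 80th percentiles.
The restricted band exists because screening plates carry many impaired
strains: a plain median would sit inside the sick tail, whereas the
40–80 band straddles the healthy mode. The same restricted median
re-normalizes each condition. The 2D median filter is a small hand-written
loop (base R has no two-dimensional running median); at 24×40 working
grids its cost is negligible.

One subtlety matters for interaction scoring. The median of the 40–80 band
is, by construction, close to the 60th percentile of the colony-size
distribution, so on a healthy plate the normalizer sits slightly *above*
the healthy mode and typical strains land slightly *below* 1. The CGI
score is nonlinear in that anchor: a common scale $k \ne 1$ turns the
perfect multiplicative null into a spurious mean score
$k^{-1}(1-k^{-1}) \ne 0$. The pipeline therefore median-centers each
condition at the strain level — per-ORF means are divided by the median
ORF of the condition — which pins the typical, unaffected strain at
exactly $W = 1$ before scores are formed. Simulated null screens confirm
the centered scores are unbiased, while omitting the centering leaves a
systematic offset of about $+0.01$ at 5% measurement noise.

## OsTir1 correction

Expressing the degron machinery itself costs fitness. `estimate_tir1_effect()`
computes $\tau$ as the mean (a median estimator is available) of per-ORF
OsTIR1⁺/OsTIR1⁻ normalized size ratios over non-essential ORFs, and
`correct_tir1()` divides OsTIR1⁺ sizes by $\tau$ under the multiplicative
model, in which the machinery cost and the target-depletion effect are
independent. Impaired-fitness calls then require a corrected size ratio
below 0.8 **and** BH-adjusted Welch significance below 0.05.

## CGI score and test

With $W_I$, $W_{GA}$, $W_{IG}$ the normalized median-centered sizes under
the inducer, the genotoxic agent, and both,

$$S = W_{IG} - W_I \cdot W_{GA},$$

zero under independent (multiplicative) fitness effects. Significance
compares the double-perturbation replicates against a distribution of
single-perturbation products (`cgi_test()`). Two constructions are
offered: all $n \times m$ pairwise products (default) or index-paired
products after a seeded within-condition shuffle. The default is the
all-pairs construction: with the 2×2 layout's four replicates, a
four-point product sample estimates its own spread so noisily that
genuine interactions of size $\varepsilon = -0.4$ intermittently fail the
BH threshold, while the sixteen-product sample stabilizes the test without
inflating false calls on simulated null screens (the products reuse
replicates and are therefore correlated, which costs the nominal
independence of the sample but empirically keeps the null clean at these
effect and noise scales). Hit calls require all three of
$W_{IG} \le 0.9$, $S \le -0.2$ and adjusted $p < 0.05$; only negative
interactions are called.

# Synthetic data generators

The generators produce data with known ground truth so every stage of the
pipeline is verifiable without external measurements.

* `simulate_competition()` — multinomial daily sampling (10,000 events by
  default) of exponentially growing subpopulations; per-event intensities
  are lognormal per channel with a shared autofluorescence distribution
  for negative channels, matching the non-fluorescent control
  (`simulate_control_events()`). All events are singlets: scatter-based
  gating is considered upstream and not simulated.
* `make_layout()` — 32×48 plates, a 4-deep dummy border, 4×4 fluorescence
  groups (60 ORFs/plate) or 2×2 fitness groups (240 ORFs/plate). Within
  the 4×4 group the three strain types are interleaved across rows and
  columns (references in the last column): a clustered arrangement makes
  the local-median spatial surface systematically genotype-dependent and
  biases the $\tau$ estimate by about half a percent, which the
  interleaved pattern removes. The printed design fixes the group
  composition, not the within-group arrangement.
* `simulate_fluor_array()` — colony intensity = background + abundance ×
  degradation fold, colony size carries the $\tau$ effect for OsTIR1⁺
  positions; both are multiplied by a smooth spatial field (linear
  gradient or Gaussian bumps, strictly positive, mean 1) and lognormal
  noise; two affine detector channels with hard high-gain saturation.
  Not-detected strains carry at most 5% of background signal — they model
  unexpressed or untagged proteins, not proteins hovering at the
  detection boundary.
* `simulate_screen()` — expected size $w_i \cdot w_{ga} \cdot
  (1+\varepsilon)$ relative to control before field and noise; a
  configurable fraction of strains (default 15%) has impaired
  single-condition fitness. Planted interactors are placed on strains
  with healthy single-condition fitness: an interaction on a strain with
  $w_i w_{ga} < 0.5$ is arithmetically below the $|S| \ge 0.2$ call
  threshold, and genuine resistance factors grow normally in the absence
  of the agent.

Determinism: each generator takes a `seed` and consumes the R RNG stream
in a fixed order (plates, then positions; days, then events), so identical
seeds give identical output. Replicate sub-streams per well or plate were
not needed for any property the pipeline relies on.

What the generators deliberately do **not** emulate: saturation and lag
kinetics of batch growth (an effective doubling time stands in), doublet
and debris events, spillover between fluorescence channels, the coupling
of colony fluorescence to colony size (a known caveat of colony assays:
fluorescence scales with biomass, so sick strains read artificially dim),
pinning failures, and non-smooth plate artifacts (row/column striping).
Passing recovery tests on these simulations therefore demonstrates the
correctness of the estimators under the stated noise model, not robustness
to every artifact of real arrays.

# Problem sizes and test design

The test suite and the acceptance script run at sizes chosen to estimate
each quantity with comfortable margin while staying quick on a laptop:
200 replicate wells for slope recovery (SE of the mean
$\approx 7\times10^{-4}$ per day), 540 ORFs (9 plates) for $\tau$ recovery
(SE $\approx 0.002$), 480 ORFs for degradation-state recovery, 200 ORFs
with 10 planted interactors for screen power, and a 100-repetition
coverage simulation for the detection-limit bootstrap. Oracle tests
compare the closed-form estimators against independent brute-force
computations: iterated grid refinement for the zero-intercept slope,
sorted-sublist selection for the restricted median, exhaustive step-up for
BH, and full hypergeometric enumeration for Fisher's exact test.

# Known limitations

* The restricted-median normalizer is only an approximation to the healthy
  mode when the impaired fraction is far from the 40–80 design point; the
  strain-level median centering absorbs the residual scale but assumes
  fewer than half the strains are affected in any one condition.
* The CGI score's nonlinearity means constitutively sick strains
  (impaired in *all* conditions, including control) acquire positive
  scores $W - W^2 > 0$ under the null; the pipeline calls only negative
  interactions, so this inflates no hit lists, but the score distribution
  of sick strains should not be over-interpreted.
* Degradation classification near the 1.2× background boundary is a
  hard-threshold decision on a noisy ratio; strains whose true level sits
  at the boundary will flip categories between replicate experiments.
* The detection-limit bootstrap propagates regression uncertainty only; it
  assumes the calibration abundances themselves are exact.
* FCS parsing is out of scope: event tables arrive as CSV, converted
  upstream by the user's cytometry software.
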