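---
title: "Cross-interference calibration of a sweetness/saltiness sensor pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-interference calibration of a sweetness/saltiness sensor pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etongue)
```

## The measurement and the model

A potentiometric taste sensor cycle produces three membrane potentials:
`Vr` in the reference solution (0.3 mM tartaric acid + 30 mM KCl),
`Vs` in the sample, and `Vr'` back in the reference solution after a
gentle rinse. The *relative value* `Vs − Vr` captures both
electrostatic and hydrophobic interactions with the membrane; the *CPA
value* `Vr' − Vr` is the adsorbed remainder. For high-potency
sweeteners the relative value runs several times larger than the CPA
value, which is why this package quantifies from relative values.

Sensor response follows the Weber–Fechner law: approximately
logarithmic in stimulus intensity. For a mixture of acesulfame K
(`x`, mM) and NaCl (`y`, mM) measured by a sweetness sensor (response
`F`, mV) and a saltiness sensor (response `G`, mV), the forward model is

$$F = a\,\ln(p x + h y), \qquad G = b\,\ln(q x + i y)$$

with slopes `a`, `b` (mV) and nonnegative sensitivities `p`, `h`, `q`,
`i` (1/mM). Both sensors see both analytes — that is the
cross-interference. The logarithm is natural: the inverse model below
must cancel it with `exp(F/a)`, and a base-10 reading would break that
cancellation.

Writing `u = e^{F/a}`, `v = e^{G/b}` turns the forward model into the
linear system `u = p x + h y`, `v = q x + i y`, inverted exactly by the
2×2 matrix inverse:

$$x = j u + k v,\quad y = m u + n v; \qquad
  j = \tfrac{i}{D},\; k = \tfrac{-h}{D},\; m = \tfrac{-q}{D},\;
  n = \tfrac{p}{D},\; D = p i - h q.$$

`derive_inversion_constants()` implements this closed form; a test
suite verifies it against an independent Cramer's-rule oracle on random
nonsingular draws. All four linear constants are used in the *additive*
convention above — any signs live in the constants themselves.

Real sensor pairs deviate from the pure log-linear picture. The
deviations are modelled by exponential corrections in the
between-sensor difference, which vanish identically when the sensors
agree:

$$\hat x = j e^{F/a} + k e^{G/b} + c\,(e^{(F-G)/e} - 1), \qquad
  \hat y = m e^{F/a} + n e^{G/b} + d\,(e^{(F-G)/f} - 1)$$

with amplitudes `c`, `d` (mM) and decay constants `e`, `f` (mV). The
package ships a packaged parameter file with the constants published
for a laboratory calibration of this sensor pair
(`reference_inversion_params()`); evaluated at the blank point
`F = G = 0` they return `x̂ = 0.01` mM and `ŷ = −1.10` mM — small
residual intercepts the laboratory fit absorbed, a useful worked
example and plausibility anchor.

```{r blank}
predict_concentrations(0, 0, reference_inversion_params())
```

## Units, parameters, defaults

Everything is in mV (potentials, slopes, decay constants) and mM
(concentrations, linear and interaction amplitudes); exponent arguments
are dimensionless mV/mV ratios. Parameters that matter:

* `noise_sd` (simulator, default 1 mV): additive Gaussian measurement
  noise per relative value. The real instrument's replicate scatter is
  not published; 1 mV is a conservative fraction of the 50–80 mV
  signals and is configurable.
* `n_replicates` (default 1; recovery experiments use 4): replicate
  measurements are fitted as individual rows, never pre-averaged.
* Fit initialization: slopes start at −50 mV (the instrument's response
  scale); sensitivities at a linearized regression estimate
  (`exp(F/a₀) − offset` regressed on the concentrations, clamped
  nonnegative); interaction amplitudes at 0 with decays at −20 and
  −50 mV. Trust-region least squares (`minpack.lm::nls.lm`), iteration
  cap 1000, cost tolerance 1e−10. Identical inputs give bit-identical
  fits.

## The zero-concentration blank

The bare forward model is undefined at `x = y = 0`, yet the canonical
calibration design contains the blank. The simulator and default fits
therefore use a *unit-offset* variant, `F = a\ln(1 + p x + h y)`, which
pins `F(0,0) = 0` exactly while remaining log-linear at higher
concentrations. The bare form is retained (`offset_mode = "bare"`)
because it is exactly invertible: the round-trip
forward-then-derived-inverse identity and the Cramer's-rule oracle are
tested in bare mode. The published constants themselves leave a
near-zero blank prediction (0.01 mM), consistent with a fit that
absorbed the baseline implicitly.

## Fitting strategies

`fit_inversion()` offers two routes:

* **two_stage** (default): fit the forward model per sensor, derive
  `(j, k, m, n)` analytically, then fit `(c, e)` on the acesulfame K
  residuals and `(d, f)` on the NaCl residuals. Exact on data generated
  by a bare forward model; on unit-offset data it carries a small
  offset bias the interaction terms cannot represent.
* **direct**: jointly refit all ten constants to the
  `(F, G) → (x, y)` map, initialized from the two-stage solution. NaCl
  residuals are divided by the design's maximum NaCl level (50 mM in
  the canonical design) so that 1 mM of acesulfame K error and 50 mM of
  NaCl error weigh equally; otherwise NaCl dominates the cost. This is
  the strategy of choice for designs that include the blank.

Numerical guards: exponent arguments are clipped at ±50 before
exponentiation (with a warning — values that large indicate a broken
fit, not a measurement); the decay constants are kept at magnitude
≥ 0.1 mV to avoid overflow. Because a box constraint cannot exclude an
interval around zero, the decays are constrained to the negative side
(≤ −0.1 mV), matching their initialization and the negative-going
responses of this sensor family. If the linear-stage residuals are
flat (spread < 1e−6 mM), the interaction amplitude is fixed at 0 and
the decay at its initial value rather than left to wander.

Identifiability requires at least 10 distinct design points (ten
constants), two distinct levels of each analyte, and — for the forward
fit — variation in any analyte whose sensitivity is not fixed by the
caller.

## What the simulator does and does not emulate

`simulate_panel()` draws each relative value from the forward model
plus independent Gaussian noise, optionally synthesizing raw potentials
(`Vr` near 0 mV, `Vs = Vr +` relative value, CPA at 20% of the relative
value — the relative value of this sensor family runs several times
above its CPA value). The default scenario
(`default_forward_params()`) uses the published slopes
`a = −50.75` mV, `b = −47.6` mV and back-solves the sensitivities so
the noise-free responses hit `F(1 mM, 0) = −80` mV,
`F(0, 50 mM) = −45` mV, `G(1 mM, 0) = −10` mV,
`G(0, 50 mM) = −50` mV — the qualitative selectivity picture of the
real sensor pair (sweetness channel responds strongly to both analytes,
saltiness channel mainly to NaCl). These anchors are scenario defaults
chosen to look like the real system, not measured constants.

Not emulated: drift, hysteresis, membrane aging, temperature effects,
non-Gaussian or correlated noise, and responses to bitter, sour or
astringent substances (near zero for these sensors). Passing tests on
simulated panels therefore demonstrate that the *estimation machinery*
is correct and noise-robust under the stated noise model — they cannot
certify accuracy on real beverages, where matrix effects and drift
enter.

```{r calibration}
design <- make_design(c(0, 0.25, 0.5, 1), c(0, 10, 30, 50))
cfg <- simulation_config(design, noise_sd = 1, seed = 1)
tab <- as_calibration_table(simulate_panel(cfg))
fit <- fit_inversion(tab, strategy = "direct")
fit
```

## Problem sizes and open choices

The package's own experiments use the 16-point factorial design, 20
simulation seeds for median statistics, 4 replicates for
parameter-recovery runs, and 100–1000 random draws for the algebraic
property checks — sizes at which every result here recomputes in
seconds. Choices that were genuinely open and how they were settled:

* Whether replicate rotations are averaged before fitting is not
  specified by the source calibration; replicates enter as rows.
* R² is the pooled coefficient of determination of estimated vs actual
  concentration, `1 − Σ(x̂−x)²/Σ(x−x̄)²`, over all calibration rows —
  the predicted-versus-actual framing; no per-series splitting.
* The direct fit is initialized from the two-stage solution. A
  multi-start over the decay-constant signs was explored and reached
  equal cost, so the single deterministic start is kept.
* Negative concentration estimates are reported and flagged
  (`evaluate_predictions()`), never clipped: the published constants
  themselves leave a −1.10 mM NaCl blank intercept, and clipping would
  mask such fit diagnostics.

## Limitations

The model is strictly two-analyte; a third tastant that either sensor
responds to will be folded into the two estimates. The interaction
terms are a low-order empirical correction in `F − G`, not a mechanistic
adsorption model. With 16 points and ten constants the direct fit is
barely overdetermined; replicated designs are recommended when noise is
appreciable.
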