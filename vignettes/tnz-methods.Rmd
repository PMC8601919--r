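---
title: "Estimating the thermoneutral zone and evaporative cooling efficiency from flow-through respirometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the thermoneutral zone and evaporative cooling efficiency from flow-through respirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnztools)
```

## The problem

Small birds defend a constant body temperature over a band of ambient
temperatures — the thermoneutral zone (TNZ) — within which resting
metabolic rate is minimal and flat. Below the lower critical temperature
($T_{lc}$) metabolism rises to offset heat loss; above the upper critical
temperature ($T_{uc}$) it rises again while evaporative water loss (EWL)
accelerates. The position of these breakpoints, the basal metabolic rate
(BMR) on the plateau, and the efficiency with which evaporation sheds
metabolic heat (EHL/MHP) are the standard currency of avian heat-tolerance
physiology, and are often related to the relative surface areas of the
unfeathered appendages (bill and legs), which act as "thermal windows".

`tnztools` implements the full chain from raw flow-through respirometry
traces to these quantities, together with the information-theoretic
model-selection layer used to relate them to appendage morphometrics, and
a synthetic-data generator that reproduces the statistical structure of a
stepped-temperature metabolic trial on a ~16 g tit. Everything downstream
of the generator is exactly the code a user would run on real traces; the
generator exists so the whole pipeline can be validated by parameter
recovery.

## The model

Steady-state oxygen consumption as a function of ambient temperature
$T_a$ is modeled as a continuous piecewise-linear ("broken-stick") curve

$$\mathrm{VO_2}(T_a) = \beta_0 + \beta_1 T_a + \delta_1 (T_a - \psi_1)_+ +
\delta_2 (T_a - \psi_2)_+,$$

with $\psi_1 = T_{lc}$ and $\psi_2 = T_{uc}$. EWL uses the one-breakpoint
version (flat, then rising at the inflection). For fixed breakpoints the
model is linear, so the profile residual sum of squares can be minimized
exhaustively over a breakpoint grid; `fit_piecewise()` scans a 0.05 °C
grid inside user-supplied bounds and then polishes each breakpoint by
bounded one-dimensional minimization. With only eight test temperatures
per bird, the exhaustive profile search is the point: iterative
linearization (`iterative_refit()`, provided for large-n series) is fast
but has no global guarantee at n = 8. Grid ties are broken toward the
midpoint of the bounds.

A fit is flagged non-converged when a segment contains fewer than two
observations or a gap coefficient is numerically zero (flat data);
non-converged birds are excluded from, and counted in, the population
summary (mean ± SE over individuals). TNZ breadth is defined as
$T_{uc} - T_{lc}$ exactly, and BMR as the mean *observed* VO₂ at test
temperatures inside the fitted zone — the fitted plateau value is used
only (and flagged) when no observation falls inside.

Breakpoint standard errors use the segmented-regression delta method:
refit with the gap covariate $-\mathbf{1}(x > \psi_j)$ and take
$\mathrm{SE}(\psi_j) = \mathrm{SE}(\gamma_j)/|\delta_j|$.

## Trace reduction

Raw traces are reduced in four steps:

1. **Drift correction.** Anchor points (midpoint time, central-80%
   trimmed mean) are taken from every baseline segment; a Catmull-Rom
   spline through the anchors (one-sided endpoint tangents) is subtracted
   and the nominal incurrent value added back. A single baseline
   degrades gracefully to a constant offset. The trimmed mean guards
   against multiplexer switching artifacts at segment edges.
2. **Equilibration discard.** The chamber behaves as a single
   well-mixed compartment with time constant $\tau$ = volume/flow
   (234 s at 1000 ml min⁻¹). Because the bird occupies the chamber
   continuously while the multiplexer merely selects which chamber is
   sampled, the washout clock runs on elapsed trial time; samples before
   $5\tau$ are discarded (residual transient $e^{-5} \approx 0.7\%$).
3. **Gas equations.** The dry-air, CO₂-unscrubbed form
   $\mathrm{VO_2} = FR(F_iO_2 - F_eO_2)/(1 - F_iO_2(1 - RQ))$ with
   RQ = 0.70, and
   $\mathrm{EWL} = FR(F_eH_2O - F_iH_2O)/(1 - F_eH_2O) \times 0.803
   \ \mathrm{mg\,ml^{-1}} \times 60$, where the water-vapor fractions are
   pressures divided by barometric pressure. The alternative denominator
   convention (excurrent rather than incurrent O₂ fraction) differs by
   under 0.1% at these depletions.
4. **Lowest stable 2-min window.** Among all contiguous 120-s windows
   whose internal SD is at most 5% of the window mean, the one with the
   lowest mean is selected (ties to the earliest); EWL is averaged over
   the same window. "Stable" is not standardized in the respirometry
   literature; the 5% rule is this package's operational definition and
   is configurable.

## Energetics

Metabolic heat production converts VO₂ at 20 kJ l⁻¹ O₂ (so 1 ml O₂ min⁻¹
is exactly 1/3 W). Evaporative heat loss multiplies EWL by the latent
heat of vaporization at chamber temperature, using the linear
approximation $\lambda(T) = 2501 - 2.361\,T$ J g⁻¹ (within 0.2% of
tabulated values over 0–50 °C). Cooling efficiency is the ratio EHL/MHP,
evaluated at the test temperatures above $T_{uc}$ (35, 37, 40 °C).

## Morphometrics

The bill is an elliptical cone: area $= \pi\,BL\,(BW + BD)/4$. Each
tarsus is an elliptical cylinder with perimeter
$\pi\sqrt{2[(TW/2)^2 + (TD/2)^2] - \tfrac12[(TW - TD)/2]^2}$ (the
standard elliptic approximation, exact for circles, written consistently
in semi-axes; the alternative reading of the ambiguous printed form
changes areas by <2% at tit-like dimensions), times tarsus length, times
two legs. Whole-body area uses the Meeh allometry $10\,M_b^{0.667}$ cm².
Relative size indices are within-sex OLS residuals of log area on log
wing length (natural logs; wing length is the conventional structural
size proxy in small passerines, and stratifying by sex removes the size
dimorphism). Mass-independent rates are pooled-sex residuals of log rate
on log body mass; pooling is a documented, switchable choice — the
stratification matters for the dimorphic morphometrics, not for the
mass correction.

## Model selection

For each physiological response the candidate set contains every
marginality-respecting subset of {sex, bill index, tarsi index,
bill × sex, tarsi × sex} (13 models; EHL/MHP responses add body mass,
26). Models are Gaussian identity-link GLMs fitted by OLS; the
log-likelihood is the Gaussian ML form, and the parameter count includes
the residual variance (so the null model has k = 2). Ranking uses
AICc $= -2\ell + 2k + 2k(k+1)/(n-k-1)$; Akaike weights are computed over
the *full* candidate set, and the ΔAICc < 2 cut is applied only for
reporting and averaging — printed per-response weight columns therefore
do not renormalize to 1 over the displayed rows. Averaging is
conditional ("natural"): each coefficient is averaged over only the
top-set models containing it, with renormalized weights and the
Burnham–Anderson unconditional standard error
$\sqrt{\sum_m w_m[\mathrm{SE}_m^2 + (\beta_m - \bar\beta)^2]}$. When a
single model holds ≥0.9 of the weight it is reported unaveraged. The
relative importance weight of a term is the summed weight of all
candidate models containing it. Collinearity is checked with
main-effects VIFs ($1/(1-R^2_j)$, sex coded 0/1 with female reference).

## The synthetic-data generator

The generator draws, per bird, sex-specific morphometrics and latent
physiological truths, then noisy steady-state profiles, and (optionally)
full analyzer traces by inverting the gas equations with first-order
washout, linear drift and white analyzer noise. Defaults encode the
study conditions the package targets:

* n = 24 birds, half male; test temperatures 10, 15, 20, 25, 30, 35,
  37, 40 °C.
* Truth means $T_{lc}$ = 17.7 °C, $T_{uc}$ = 34.5 °C, EWL inflection
  31.85 °C, BMR 0.96 ml O₂ min⁻¹. Between-individual SDs (1.5, 0.7,
  0.8 °C, 0.12 ml min⁻¹) are this package's choices: published ± values
  are standard errors of population means that fold in estimation error,
  so they bound rather than identify the individual-level spread;
  individual $T_{lc}, T_{uc}$ pairs are redrawn until
  $T_{lc} < T_{uc} - 5$ so the plateau stays identifiable.
* Slopes: −0.11 ml min⁻¹ °C⁻¹ below $T_{lc}$ (a doubling of BMR by
  ~10 °C), +0.04 above $T_{uc}$; EWL baseline 100 mg h⁻¹ rising at
  47.65 mg h⁻¹ °C⁻¹ above the inflection. The EWL slope is calibrated so
  that the noise-free population mean EHL/MHP at 40 °C equals 0.83, the
  reference maximum cooling efficiency for this kind of passerine.
* Rate noise is multiplicative lognormal with CV 5% (positive,
  right-skewed, a free parameter — within-individual variability of
  steady-state rates is rarely published); analyzer noise is additive
  Gaussian.
* Sexual dimorphism: males larger in mass, wing and bill dimensions;
  tarsus distributions identical. Morphometric means/SDs are
  literature-plausible values for a ~16 g tit; all tests depend only on
  the relative structure, never on these absolutes.
* A male-only effect scales EWL at 40 °C by
  $\exp(b \cdot \text{tarsi index})$ with $b$ = 4 by default. With the
  realized index SD (~0.05) and the full between-individual ratio noise
  (CV ~14%), this puts the tarsi × sex interaction model at $R^2 \approx
  0.5$ — the effect scale at which the detection experiments are run.
* One master seed; every bird draws from its own substream (a fixed
  offset schedule), so enlarging a population never perturbs the birds
  already generated.

What the generator does *not* emulate: behavioral noise (panting, wing
drooping, activity bursts), body-temperature dynamics, analyzer
cross-channel artifacts, or any correlation between morphometrics and
the latent physiological truths other than the male tarsi effect.
Passing recovery tests therefore demonstrates the estimators are correct
and well-calibrated under the stated noise model, not that real traces
are this clean.

## Numerical choices and problem sizes

Grid searches use a 0.05 °C step with bounds [12, 28] °C and [28, 38] °C
for the two VO₂ breakpoints and [28, 38] °C for the EWL inflection,
reflecting the protocol's temperature coverage; polishing is accepted
only when it does not increase the RSS. Recovery experiments in the test
suite and the acceptance script use 20 replicate populations of 24 birds
(fits for 480 birds per quantity), which puts Monte-Carlo error on
population means well inside the ±1 °C recovery tolerance. Detection
experiments use 50 replicates per condition. The trace round-trip checks
use single traces per flow rate; with zero noise the reduction recovers
the generator's steady states to ≲0.3%, dominated by the residual
washout transient.

## Known limitations

* Per-individual fits with 8 points yield noisy breakpoint estimates
  (individual SEs of ~1 °C); the package aggregates per-individual fits
  to a population mean ± SE rather than fitting a simultaneous
  population-level (GEE-type) breakpoint model.
* The upper breakpoint is estimated from only three supra-thermoneutral
  temperatures; in noisy data its population mean recovers with a mild
  downward bias (a few tenths of a degree), visible in the recovery
  experiments and well inside their tolerance.
* Fits are flagged, not repaired, when a breakpoint wanders into a
  one-point segment; expect a handful of exclusions per 24-bird
  population at 5% noise (the summary reports the count).
* The stability threshold and the equilibration discard are conventions;
  both are exposed as arguments.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(generator = generator_config(seed = 1))
res <- run_pipeline(cfg)
res$population_estimates
res$model_tables$ratio40
plot_vo2_curve(res)
```
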