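---
title: "Scoring migration and death in wound-healing assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring migration and death in wound-healing assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundscore)
```

## The measurement model

A scratch assay monitors relative wound density (RWD) — the fraction of
the original wound area repopulated by cells — every ~2 h for ~3 days,
together with an integrated caspase-3/7 signal reporting cumulative
apoptosis. Proliferation is assumed normalized away by mitomycin-C
pre-treatment (an annotation, not a computation, in this package), so a
drug can delay closure through exactly two phenotypes: inhibiting
migration, or killing cells. The package's job is to apportion the
observed delay between the two at every dose.

Internally RWD is a fraction in [0, 1]; the percent scale exists only in
the I/O layer (`read_timeseries()` divides by 100, values in (100, 105]%
are treated as instrument overshoot and clamped, larger values are
rejected). Replicate wells are averaged pointwise before any scoring, so
all downstream quantities describe per-condition mean curves. Time grids
must match exactly within a control-normalization stratum; the package
never resamples, because a grid mismatch in one instrument export is a
fault worth surfacing, not smoothing over.

## Closure and death changes

For each condition *xi* of a (cell line, density, MMC) stratum, over an
analysis window $[0, T]$:

$$WC_{xi} = \frac{AUC(RWD)_{ctrl} - AUC(RWD)_{xi}}{AUC(RWD)_{ctrl}},
\qquad WC_{ind} = 1 - WC_{xi},$$

$$DC_{xi} = \frac{AUC(D)_{xi} - AUC(D)_{ctrl}}{AUC(D)_{max}}.$$

Integration is trapezoidal on the native sampling grid (exact for
piecewise-linear traces; the window end is linearly interpolated when it
falls between samples). $AUC(D)_{max}$ is the stratum-wide maximum
including the control — the normalizer's scope was a genuinely open
choice, and the stratum-wide maximum keeps $DC \le 1$ by construction and
uses only data that share a control. Negative $DC$ (less death signal
than vehicle) is clamped to 0, since the decomposition asks how much
death *contributes to* a delay; the raw value is kept in `dc_raw`.
Negative $WC$ (closure faster than vehicle) is retained in the metrics
but scores (0, 0) downstream with a `closure_enhancement` flag — the
tangent decomposition is only meaningful for delays.

## Analysis-window criteria

Three endpoint rules are implemented (`analysis_config()`):

* **A** — the fixed experiment endpoint, default 72 h. Simple, but fast
  strata spend most of the window saturated at RWD = 1.
* **B** — the earliest time at which the *control's* closure rate has
  declined to ≤ 0.02 RWD-fraction per hour; the same window is applied to
  every condition of the stratum. The slope is a central difference
  smoothed by a 3-point moving average (both config-exposed), and the
  search starts only after the control RWD exceeds half the closure
  target (default 0.25): an unsmoothed or unguarded rule would fire on
  sampling noise or on the initial lag plateau, where the slope is also
  near zero. The threshold's unit (fraction/h rather than %/h) is a
  package choice, config-exposed.
* **C** — the per-condition time to reach 50% closure, falling back to
  the last observed time when never reached. Because windows then differ
  between conditions, AUCs are divided by the window length
  (time-averaged) before the $WC$/$DC$ formulas, so a slow condition is
  compared on mean closure rather than penalized for a longer window.

## The death–closure landscape and the tangent rule

Each dose contributes a point $(DC, WC)$; the vehicle control pins the
origin. Death change is drawn on the horizontal axis and closure change
on the vertical: a compound that delays closure without any death traces
a **vertical** line, and one whose delay is pure killing bends the curve
toward the **horizontal**. The dose-parameterized relationship is fitted
with the first-order rate form

$$WC = WC_{max}\,(1 - e^{-k \cdot DC}),$$

by bounded Levenberg–Marquardt least squares ($WC_{max} \in (0, 1.5]$,
$k \in (0, 10^4]$; started at $WC_{max}^0 = \max WC$ and $k^0$ from the
initial secant slope, floored at $10^{-3}$). $r^2$ is computed on the
$WC$ residuals; if $r^2 < 0.6$, if the points have no usable spread in
$DC$ (variance below $10^{-12}$ — the vertical, death-free case), or if
the optimizer fails, a straight line through the origin
$DC = s \cdot WC$ is fitted instead and accepted without a second
quality gate.

The tangent angle $\theta$ at a dose point is measured **from the
vertical axis**, $\theta = \arctan(dDC/dWC)$ along the fit. This
orientation is the only one under which the two limiting phenotypes come
out right: vertical landscape $\Rightarrow \theta = 0 \Rightarrow$ pure
migration; horizontal $\Rightarrow \theta = \pi/2 \Rightarrow$ pure
death. The scores are then

$$Death_{xi} = WC_{xi}\cdot\frac{\theta_{xi}}{\pi/2},\qquad
Migration_{xi} = WC_{xi} - Death_{xi},$$

so conservation $Migration + Death = \max(WC, 0)$ holds identically.
Under the first-order model the point is projected onto the curve through
its observed $WC$ — $dc_{fit} = -\log(1 - WC/WC_{max})/k$, giving the
closed form $\theta = \arctan\!\big(1/(k\,(WC_{max} - WC))\big)$ — rather
than evaluated at the noisy observed $DC$; a point at or beyond
$WC_{max}$ has no tangent and is clamped to $\pi/2$ with a warning. This
makes $\theta$ nondecreasing in $WC$, so along a saturating landscape the
death share grows with dose — the migrastatic-to-cytotoxic switch the
decomposition is designed to expose. A negative fitted linear slope
clamps $\theta$ to 0: a drug cannot carry a negative death share.

## Lumped scores, bias and classification

A dose series is summarized by the trapezoidal AUC of each score against
$\log_2$(concentration), divided by the $\log_2$ range — a mean over the
log-dose axis, chosen because the standard design is a two-fold serial
dilution and because normalizing by axis length keeps scores comparable
across drugs with different dose ranges. A constant score $c$ lumps to
$c$ on any grid.

Phenotypic bias places each dose in the (migration, death) plane and
measures deviation from the no-bias diagonal two ways: the signed
perpendicular distance $\sin(\pi/4)(Death - Migration)$ (the magnitude
measure) and the angular deviation $\arctan2(Death, Migration) - \pi/4$
(the radial measure, defined as 0 at the origin). Classification uses
two floors, both config-exposed and both 0.05 by default (5% of the score
scale; the underlying decision rule has no published thresholds):
total lumped activity below `activity_floor` is *inactive*; otherwise the
sign of the lumped bias beyond `bias_floor` separates *migrastatic* from
*cytotoxic*, with *balanced* in between. Cell lines can be grouped by
their per-drug lumped-bias fingerprints with agglomerative hierarchical
clustering (Euclidean distance, average linkage, rows pre-sorted by label
for determinism); metric and linkage are recorded in the output
attributes since they are a package choice.

Robustness across seeding densities is tested per density pair by the
two-sample Kolmogorov–Smirnov statistic on per-dose bias values, with the
exact small-sample p-value whenever $n_a n_b \le 10^4$ (always, for
8-dose series) and the asymptotic formula beyond. The per-dose bias
values are used directly as the KS samples; no cumulative-over-dose
transform is applied, as the accumulation was never specified and the
per-dose values are the primitive measurements.

## The synthetic-assay generator

`simulate_well()` draws from a deliberately small mechanistic model. The
closure front advances at speed
$v = v_0 (\rho/\rho_{ref})^{\gamma} (1 - E_{mig} H_{mig}(d))$ and cells
die at rate $\delta = \delta_0 + \delta_{max} H_{death}(d)$, with Hill
dose responses $H(d) = d^h/(EC_{50}^h + d^h)$. Only surviving cells
migrate, so

$$RWD(t) = 1 - \exp\!\Big(-v\,\frac{1 - e^{-\delta t}}{\delta}\Big)
\;\xrightarrow{\delta \to 0}\; 1 - e^{-v t},$$

computed via `expm1` so the small-$\delta$ limit is stable to well below
$10^{-9}$. Death therefore both slows closure and caps its plateau at
$1 - e^{-v/\delta}$ — reproducing the assay's central confound, a
cytotoxic drug masquerading as a migration inhibitor in the raw RWD
trace. The caspase reporter integrates death,
$caspase(t) = baseline + gain\,(1 - e^{-\delta t})$. Noise is
multiplicative lognormal per sample (additive Gaussian would produce
negative caspase values), and each well's stream is seeded by hashing the
master seed with the full condition, so any subset of wells is
reproducible independently of generation order and the session RNG is
left untouched.

Defaults describe an intermediate-motility bile-duct cancer line under
MMC: $v_0 = 0.1$/h (half-closure ≈ 7 h at the 30,000 cells/well
reference; real cell lines range from a few hours to more than a day), $\gamma = 0.5$ (higher
seeding closes faster, sublinearly), $\delta_0 = 0.002$/h baseline death,
motility inhibition with $E_{mig} = 0.9$, $EC_{50} = 0.5\,\mu M$, Hill
1.5, and death induction with $\delta_{max} = 0.15$/h (saturating death
half-life ≈ 4.6 h — a potent apoptosis inducer whose caspase signal
saturates within the first day), $EC_{50} = 2.5\,\mu M$, Hill 2, so the
default mixed compound is migrastatic at low dose and cytotoxic at high
dose. Observation noise is 2% relative. Scenarios zero the appropriate
branch: `pure_migrastatic` ($\delta_{max} = 0$), `pure_cytotoxic`
($E_{mig} = 0$), `null` (both), `mixed` (both active, with
$EC_{50,death} > EC_{50,mig}$).

What the generator does **not** emulate: spatial structure of the wound
(no front roughness, no edge effects), proliferation escaping MMC,
drug-response heterogeneity between wells beyond observation noise,
non-saturating or biphasic dose responses, and caspase-independent death
modes. Passing tests on simulated screens therefore demonstrate that the
scoring machinery recovers known ground truth under the model's
assumptions — not that those assumptions hold for any particular cell
line or instrument.

## Numerical conventions and problem sizes

Degenerate inputs are defined, not crashed on: an all-zero death series
yields death scores identically 0; an all-zero closure series yields all
scores 0; a zero control closure AUC is an explicit error (there is
nothing to normalize by); a zero stratum-wide death maximum sets all
$DC = 0$ with a warning. CSV outputs are written with 9 significant
digits so regression comparisons are platform-stable; the dataset
writer, by contrast, writes full precision (times and caspase round-trip
bit-exactly; RWD, which crosses the percent conversion, to the last
ulp). Test and example screens use one cell line, 8 doses, 1–3 densities
and 2 replicates (27–54 wells, 37 time points each), sizes at which the
full simulate–score–compare pipeline runs in seconds while exercising
every code path; nothing in the implementation is specific to these
sizes.

## Limitations

The tangent rule distributes a *relative* delay; it cannot see effects
the AUC window misses (e.g. transient early inhibition that recovers
before the window ends). Scores from different strata share no common
normalizer beyond their own controls, so cross-cell-line comparisons
should use the lumped, control-normalized quantities only. The linear
fallback carries no quality gate, by design — when the saturating model
fails, the line is the declared interpretation, not a competing fit. And
with 8 bias values per sample the exact KS test's granularity is coarse
(distances are multiples of 1/8); significant density artifacts are
detectable, but small ones are not resolvable at that sample size.
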