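---
title: "Simulating maize root system architecture under strigolactone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating maize root system architecture under strigolactone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizersa)
```

## The model

`maizersa` simulates whole maize root systems (RSAs) in three dimensions as
collections of straight stochastic strands. A plant carries exactly one
primary axis, plus seminal, crown and brace axes whose numbers are drawn from
literature-derived count distributions. Each axis owns a fixed direction,
drawn once from axial angles A ~ U[180°, 360°] and B ~ U[0°, 180°], giving the
unit vector (cos A cos B, cos B sin A, −sin B); because B stays in [0°, 180°]
the vertical component is never positive and strands never grow upward.

Elongation follows the negative-exponential law

> G(t) = k (1 − e^(−r t / k)),

with maximal length k = 22.67 cm for all four axis classes and initial rate
r = 2 cm/day. A strand's cumulative length is the elongation function

> EF(t) = G(t) · LD · SL_effect,

where LD is a per-strand normalized length multiplier drawn from the class's
trait distribution (gamma(5, 0.22) for primary and seminal, normal(0.98, 0.11)
for crown, normal(1, 0.38) for brace) and SL_effect is the strigolactone
multiplier described below, both fixed at strand initiation. The time axis
[0, tf] (tf = 35 days by default, the midpoint of the 30–40 day range over
which a maize RSA develops) is divided into n equal iterations, and point i
of the polyline sits at arc distance EF(t_i) from the origin. The increments
EF(t_i) − EF(t_{i−1}) telescope, so the completed strand length is exactly
EF(tf) = k · LD · SL_effect at any grid resolution — a property the test
suite exploits by running large ensembles on a coarse grid (n = 20) without
changing any length statistic. The alternative reading of the stepping rule
(adding a full EF term per iteration) diverges past k and would contradict
k's meaning as a maximal root length, which is why we use increments.

Origins follow the whorl rules. Ground level is z = 0; one whorl distance
wd is drawn per plant (normal(2.0, 0.3) cm truncated at 0.1 cm — the source
literature fits this spacing but does not reprint its parameters, so the
default is a configurable, field-plausible choice). The primary root starts
at the origin; seminal roots start at a uniform depth in [−wd, 0] (the
minimal reading of "at or below ground"); brace roots start on one of the 2
above-ground whorls {wd, 2wd}; crown roots on one of the 6 below-ground
whorls {0, −wd, …, −5wd}, with uniform whorl choice.

## Lateral branching

Branching is quantified as lateral roots per cm of parent axis. For each
axis a density B is drawn from the class's branching distribution
(e.g. normal(6.65, 0.63) per cm for the primary); the maximum possible
branch count is m = round(B × length), and m candidate points are placed at
equal arc spacing along the strand (an explicit determinism choice — the
source procedure does not state a placement rule). The branching scale MedL
is the median of 1000 draws from the same density distribution times the
parent length; drawing from the fitted distribution (rather than resampling
raw data, which is not available) is the only bootstrap consistent with the
shipped parameterization.

At each candidate point the lateral root function draws P ~ U[0, m] and
branches iff P < SBT, where SBT = MedL · SL_effect uses the branching
dose-response curve. The realized branch probability is therefore
min(SBT/m, 1), and realized density is approximately min(MedL, B) per cm —
slightly below the mean density because draws above the median are clamped.
This is why the realized wild-type-normalized branching ratio at 5 µM is
≈ 0.76 rather than the raw multiplier 0.73: the threshold mechanism, not a
calibration error. Tests compare against a Monte-Carlo evaluation of the
min() closed form.

A realized lateral draws a radial angle R ~ U[0°, 180°], a fair-coin sign
(one per lateral), a growth threshold LRGT ~ U[0.4, 0.9] (one per lateral)
and a normalized lateral length LLD. Its direction is the unit vector of the
angles (A ± R, B ± R); point q sits at distance G_lat(t_q) · LLD from the
branch point, where t_q = q·tf/n is the lateral's age and

> G_lat(t) = k_lat (1 − e^(−r_lat(t) t / k_lat)),  r_lat(t) = 6.4 e^(−0.8 t).

After each point a uniform draw against LRGT decides whether growth
continues, capped at n iterations, so the number of points beyond the first
is geometric with mean LRGT/(1 − LRGT). Two modelling notes: k_lat is not
fixed by the source data (the table cell is blank); the default of 2.0 cm
keeps laterals an order of magnitude shorter than axes and is configurable.
And because r_lat decays with the same t that enters G_lat, the composite is
not globally monotone — it peaks near t = 1.25 days and would place later
points closer to the branch point again. Laterals rarely live that long
(median one iteration ≈ 0.18 days), so in practice geometry is monotone; we
implement the composite exactly as defined rather than freezing r_lat at
emergence. Higher-order laterals (laterals of laterals) are not modelled.

## Strigolactone dose response

The effect of strigolactone (assayed via its synthetic analog GR24) on each
trait is a dimensionless multiplier normalized to wild type, anchored at
experimentally determined concentrations: a taproot-length curve (primary
and seminal axes, anchors at 0, 1.25, 2.5, 5, 10 µM), a nodal-length curve
(crown and brace, anchors at 0, 0.01, 0.1, 1, 10 µM) and a single branching
curve shared by all classes. Between consecutive anchors the multiplier is
interpolated linearly — the local slope is the experimental ΔRT/ΔSL, so each
anchor is reproduced exactly — and beyond the anchored range the nearest
anchor value is held constant, since unbounded linear extrapolation would
eventually drive lengths negative. The 0.25 µM-resolution dose sweep
therefore evaluates interpolated multipliers between anchors; step-holding
was the alternative and would produce staircase dose-response curves with
the same anchor values. SL is constant within one simulated plant; the
concentration may come from an external biosynthesis model via the scalar
`sl` argument or the config file.

## Randomness and reproducibility

All draws flow through named hierarchical streams: a stream is (seed, path),
e.g. seed 42 with path `rsa_17/crown_axis_3`, hashed to an independent
Mersenne-Twister state. Identical (seed, path) replay identical sequences,
and adding an axis or plant never perturbs the draws of existing ones, so
ensembles are order-independent and individual plants can be regenerated in
isolation from their recorded seed. Ensembles at different SL concentrations
reuse the same stream layout, which makes dose-response curves paired
comparisons: per-strand LD draws cancel exactly in normalized length ratios.

Truncation of normal trait draws is by rejection (draws below the bound are
redrawn), applied before integer rounding for count traits and with a 10⁻⁶
lower bound for length multipliers. The rejection bias matters only for the
brace length distribution normal(1, 0.38), whose truncated mean is ≈ 1.0048
— the dominant term in the ~0.5% distribution-fidelity deviation reported by
the acceptance script, and well inside the 1% band the simulator is
validated against.

## Ensemble phenotyping

Within one plant, a class trait is the median across that plant's axes of
the class (axis length in cm; realized lateral density per cm). Across an
ensemble, the reported statistic is the median of per-plant values with a
percentile-bootstrap confidence interval of the median (99%, 2000 resamples
by default; the interval construction is our choice — the source analysis
names the interval but not its estimator). `dose_response_sweep()` runs one
ensemble per concentration on the default grid 0.25–10 µM in 0.25 µM steps
(40 levels) plus a wild-type reference at 0 µM, and normalizes every trait
to wild type, which passes through 1 at SL = 0 by construction.

Problem sizes are choices, not physics: the shipped defaults (100 plants per
ensemble; 20,000 axes per class for distribution-fidelity checks; 1000
plants for whorl-structure enumeration) give standard errors a few times
smaller than the effects being checked, and the test suite scales grids and
ensembles down (n = 20 time steps, 20–60 plants) where the property under
test is invariant to the reduction.

## What the generator does and does not emulate

Synthetic ensembles reproduce the statistical properties the trait registry
encodes: length and count distributions per class, whorl-structured origins,
density-driven branching, and the tabulated hormone responses. They do not
emulate soil mechanics, nutrient or water fields, tropisms, root diameter,
inter-root competition, curvature of real strands (axes are straight unless
per-step angular jitter is enabled via `jitter_sd`), or any hormone other
than strigolactone. Passing tests therefore demonstrate internal consistency
with the configured distributions and dose-response tables — not field
validity of any particular simulated plant.

## Worked example

```{r example, eval = FALSE}
prof <- default_maize_profile()
rsa <- build_rsa(prof, sl = 0, seed = 7)
rsa
rsa_summary(rsa)

# dose response at three informative concentrations
tab <- dose_response_sweep(prof, sl_grid = c(1.25, 5, 10), n_rsa = 50,
                           seed = 7)
subset(tab, root_class == "primary" & trait == "axis_length")

write_rsml(rsa, "maize_rsa.rsml")
```

The same operations are available from the shell through the
`inst/scripts/maizersa` entry point (`demo`, `generate`, `sweep`,
`validate-config`).
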