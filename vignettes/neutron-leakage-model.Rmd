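---
title: "Modeling leakage-neutron equivalent dose in passively scattered proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling leakage-neutron equivalent dose in passively scattered proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrondose)
```

## The problem

Passively scattered proton therapy shapes the beam with scatterers, range
modulators and collimators. Protons stopped in the final collimator produce
neutrons that leak into the treatment room and expose the patient far outside
the treatment field. This stray neutron dose is not computed by treatment
planning systems, yet it drives estimates of second-cancer risk. Monte Carlo
transport can predict it accurately but takes hours; survey-meter
measurements are sparse. `neutrondose` implements a fast analytical model of
the *neutron equivalent dose per therapeutic absorbed dose*, H/D (Sv/Gy), at
any point in a water phantom or in air, together with the constrained fitting
machinery used to train it and a synthetic-data generator that emulates the
detector layouts used in model development.

## The model

H/D at a point p is a product of an isocenter calibration, a power-law
distance falloff, and a sum over four neutron energy regimes — intranuclear
cascade (direct), evaporation, epithermal (1/E) and thermal — each with its
own in-phantom attenuation and lateral Gaussian spread:

$$
(H/D)_p \;=\; (H/D)_{E,\mathrm{iso}} \left(\frac{d}{d_\mathrm{iso}}\right)^{-q}
\sum_{i=1}^{4} C_i(E)\,
e^{-\alpha_i\,(d' - d'_\mathrm{iso})}\,
\exp\!\left[-\frac{(x^2+y^2)\,d_\mathrm{iso}^2}{2\sigma_i^2 z^2}\right]
$$

where `d` is the distance from the effective neutron source (taken at the
treatment-head exit) to the point, `d'` the in-phantom path along that ray,
`d_iso` and `d'_iso` their isocenter counterparts, `q` the falloff exponent,
`alpha_i` (cm^-1) the water attenuation coefficient of regime `i`, and
`sigma_i` (cm) its lateral Gaussian width parameter.

Two supporting parameterizations make the model continuous in proton beam
energy from 100 to 250 MeV:

* the isocenter term follows a power law,
  $(H/D)_{E,\mathrm{iso}} = \alpha_E E^{p_E} (H/D)_{\mathrm{ref,iso}}$, with
  the reference value at 100 MeV obtained as the quotient of the
  closed-collimator neutron yield and the open-collimator absorbed-dose
  yield (`hd_ref_iso_from_yields()`);
* the regime fractions $C_i(E)$ are smooth functions of energy — linear for
  the cascade regime, a bounded cumulative normal for evaporation, a
  constant for epithermal, a quadratic for thermal — constrained to sum to
  unity at every energy.

The single-energy in-air variant for ocular beamlines replaces the power law
with a measured isocenter H/D, the $C_i(E)$ curves with scalar fractions,
and pins every attenuation coefficient at zero (there is no phantom).

### Coordinate and geometry conventions

Coordinates are Cartesian and source-centered: +z along the beam axis, so
`z` is the axial distance from the effective source to the point's
transverse plane and the lateral Gaussian width grows linearly with `z`
(at `z = d_iso` the lateral kernel has width `sigma_i`). This is the only
reading under which the lateral exponent is dimensionless and consistent
with a diverging source. The phantom entrance plane sits at
`d_iso - iso_depth`; in-phantom path lengths are measured along the ray, via
`d' = (d/z) * max(0, z - (d_iso - iso_depth))`, a form chosen so that at the
isocenter the attenuation argument cancels exactly in floating point.

`d_iso` is not a published quantity. The general-purpose configuration uses
230 cm (a typical gantry source–axis distance) with the isocenter at 22 cm
depth; the ocular configuration uses 100 cm. Both are configuration values,
stated in the shipped JSON files, and every result in this package that
involves geometry is conditional on them.

## Shipped configurations and their parameters

```{r presets}
beamline_preset("general_purpose_100_250")
beamline_preset("ocular_75MeV")
```

The general-purpose set: calibration `alpha_E = 8.0e-9`, `p_E = 4.1`,
`(H/D)_ref,iso = 1.2e-4` Sv/Gy at 100 MeV; apportionment coefficients
`a1 = -4.8e-4` MeV^-1, `b1 = 0.6`, `a2 = 0.12`, `b2 = 130` MeV, `c2 = 5`
MeV, `d2 = -1.3e-11`, `a3 = 0.4`, `a4 = 1.2e-7` MeV^-2, `b4 = -6.6e-5`
MeV^-1, `c4 = 1.1e-2`; attenuation `alpha = (1.3e-2, 1.3e-2, 3.2e-2,
3.3e-1)` cm^-1; widths `sigma = (14, 77, 3900, 3900)` cm; `q = 1.13`. The
very large widths of the epithermal and thermal regimes correspond to an
essentially isotropic distribution, while the cascade regime is strongly
forward peaked. The ocular set: scalar fractions `(0.011, 0.78, 0.10,
0.096)`, widths `(9.4, 1000, 4200, 4200)` cm, measured isocenter H/D
`5.2e-5` Sv/Gy at 75 MeV, `q = 1.5` — the sharper falloff is expected for a
narrower beamline that better resembles a point source.

## Numerical choices

* **Sum-to-unity.** Published coefficients are rounded, so the raw fractions
  do not total exactly 1. Evaluation renormalizes by the raw sum
  (`renormalize = TRUE`, the default, and always forced during fitting);
  after division, the thermal fraction is replaced by the exact double
  complement of the other three so the accumulated sum is exactly 1 and H/D
  at the isocenter equals the calibration value bit-identically. Raw
  coefficients remain available with `renormalize = FALSE`.
* **Negative fractions.** The published evaporation lower bound `d2` is a
  numerically negligible negative number, so the raw evaporation fraction
  dips below zero at low energy; it is clipped at zero with a warning. A
  negative fraction in any other regime is an error naming the regime.
* **Energy range.** The energy-dependent parameterization is supported on
  [100, 250] MeV; evaluation outside warns but proceeds (the in-air variant
  shows the functional form extends downward).
* **Printed-parameter self-consistency.** The published calibration is not
  exactly self-consistent at the reference energy
  (`alpha_E * 100^4.1` is about 1.27, not 1, presumably from rounding of the
  printed values); shipped values are used as printed, and
  `self_consistent_calibration()` derives `alpha_E = ref_energy^(-p_E)` when
  exactness at the reference point is wanted.

## Fitting

Training minimizes the **mean squared local relative residual**,
`mean(((model - observed)/observed)^2)`: the literature describes the
objective only as minimizing local relative differences, and the squared
form is smooth and scale-free; a mean-absolute alternative is available via
`fit_config(objective = "mean_absolute")`. Because the relative objective is
invariant under a common rescaling, `hd_ref_iso` (which enters only as a
product with `alpha_E`) is always held fixed, as is the measured isocenter
value in the ocular variant.

The optimizer is box-constrained L-BFGS-B, with multi-start initialization:
each start perturbs the supplied parameter set by a uniform ±20% factor
(seed default 1905), and the best converged start is polished by a bounded
number of restarts. Three implementation details matter for reliable
convergence:

* parameters with strictly positive bounds (scales, widths, exponents) are
  optimized on the log scale, which decorrelates `alpha_E` and `p_E`;
* numeric gradients use a central-difference step of 1e-6 on the scaled
  parameters (the default 1e-3 step leaves visible residual error in the
  21-parameter closed loop);
* the sum-to-unity constraint is enforced by renormalization *inside* the
  model — identically at every energy, which an explicit equality constraint
  at discrete energies cannot achieve — and raw fractions that go negative
  during a line search are clipped with a quadratic penalty (weight 1e4) so
  the objective stays continuous across the feasibility boundary.

Non-convergence within the iteration budget (relative objective change
below 1e-10 or 500 iterations per start) is flagged on the result, not
raised. Underdetermined problems (no more records than free parameters)
are errors.

## The synthetic-data generator

No Monte Carlo or measured H/D datasets are deposited with the source
literature, so the package generates model-based surrogates for both
development layouts:

* `mdacc_grid()` — 100 point detectors in the water phantom: 20 per
  longitudinal line at 0, 10, 40 and 80 cm off-axis plus 20 on a lateral
  line at the 22 cm isocenter depth. The published description fixes the
  line offsets and the lateral-line depth but not the depth spacing; the
  default 20 evenly spaced depths from 2 to 40 cm are this package's choice,
  and configurable.
* `ocular_positions()` — 10 in-air points along rays at 0°, 45° and 90° to
  the beam axis. The measurement distances are not tabulated in the source
  literature; the defaults (25–100 cm from isocenter) are round numbers and
  explicitly not published values.

`generate_dataset()` evaluates the model at these points and multiplies by
noise factors — Gaussian `1 + rel_sd * Z` (non-positive draws rejected) or a
unit-mean log-normal whose relative sd matches the nominal value at first
order. Noiseless generation is bit-reproducible; seeded generation is
reproducible across runs.

Because the surrogate is generated *from the model itself*, closed-loop
tests demonstrate parameter identifiability and optimizer correctness — they
do not validate the model against independent physics. The published
validation errors against Monte Carlo (10% average, 60% maximum local
relative error) and against measurements (16% average, 24% maximum) are
properties of datasets this package cannot reconstruct, and are therefore
not reproduction targets; the package reproduces the *report structure*
(per-energy and overall mean/max local relative error) on synthetic data.

## Problem sizes and observed behavior

The test suite and the acceptance script run at desk scale: the 800-record
grid dataset (100 points × 8 energies), the 10- and 30-point ocular ray
sets, 20-replicate noise studies, and multi-start counts of 2–5. At these
sizes each single-parameter fit takes well under a second and the
21-parameter closed loop about a minute on one CPU. In the noiseless closed
loop, every single-parameter recovery (falloff exponent, power-law exponent,
cascade width, cascade attenuation) returns the generating value to within
0.1%, and the all-free refit reproduces the generating dataset to a mean
local relative error below 0.5%.

One identifiability limit is worth stating plainly: with the isocenter
22 cm deep in the phantom at `d_iso = 230` cm, the detector grid spans
source distances of only about 0.90–1.12 times `d_iso`, so the falloff
exponent is estimated through a lever arm `|log(d/d_iso)|` of at most about
0.11. Under 5% relative noise a single-replicate estimate of `q` then has a
standard error near 3%, and individual replicates can deviate by 10% or
more even though the optimizer finds the exact minimizer of each replicate's
objective. Recovery under noise is therefore assessed on the mean over the
20 seeded replicates, which is accurate to well under 5%.

## Limitations

* Pristine (unmodulated) Bragg peaks only: no spread-out-Bragg-peak /
  range-modulation support, no field-size dependence beyond the closed
  final collimator.
* The four-regime split apportions equivalent dose; the model produces no
  neutron energy spectrum and no instrument response (the 1 cm spherical
  detectors and survey meters behind the original datasets are treated as
  points).
* Water phantom and in-air geometries only — no patient anatomy, no
  treatment-planning integration, no second-cancer risk modeling.
* `d_iso`, the effective source position and the ocular measurement
  distances are configuration values; results that depend on absolute
  geometry inherit that choice.
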