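# neutrondose

Out-of-field neutron dosimetry for passively scattered proton therapy.

Protons stopped in the treatment head — above all in a closed or nearly
closed final collimator — produce leakage neutrons that deliver dose far
outside the treatment field. Treatment planning systems ignore this
exposure, but it matters for second-cancer risk estimation. `neutrondose`
implements a fast analytical model of the **neutron equivalent dose per
therapeutic absorbed dose**, H/D (Sv/Gy), for researchers and medical
physicists who need out-of-field neutron estimates in seconds rather than
Monte Carlo hours: model evaluation at arbitrary points, constrained
training on H/D datasets, synthetic-data generation, validation reports,
plotting, and a command-line interface.

## The model

H/D at a point p in a water phantom (or in air) is

```
(H/D)_p = (H/D)_{E,iso} * (d/d_iso)^(-q)
          * sum_{i=1..4} C_i(E) * exp(-alpha_i (d' - d'_iso))
                        * exp(-(x^2+y^2) d_iso^2 / (2 sigma_i^2 z^2))
```

a product of the isocenter H/D at the beam energy, a power-law falloff with
source distance, and contributions from four neutron energy regimes —
intranuclear cascade, evaporation, epithermal (1/E) and thermal — each with
exponential attenuation along the in-phantom path `d'` and a lateral
Gaussian of width `sigma_i` that scales with axial distance `z`. The
isocenter term follows a power law in proton energy,
`(H/D)_{E,iso} = alpha_E * E^p_E * (H/D)_{ref,iso}`, and the regime
fractions `C_i(E)` are smooth functions of energy constrained to sum to
unity, which makes the model continuous from 100 to 250 MeV. A single-energy
in-air variant (scalar fractions, zero attenuation, measured isocenter
value) covers ocular beamlines; both variants ship as validated JSON
presets: `general_purpose_100_250` (q = 1.13) and `ocular_75MeV` (q = 1.5).

Training minimizes the mean squared local relative residual
`((model - observed)/observed)^2` with box-constrained L-BFGS-B from
multiple perturbed starts, with the sum-to-unity constraint enforced by
renormalization inside the model. See the methods vignette
(`vignettes/neutron-leakage-model.Rmd`) for conventions, numerical choices
and limitations.

## Worked example

Evaluate the general-purpose beamline at three points in the isocenter
plane of the phantom (230 cm from the source, 22 cm deep) for a 200 MeV
beam, then simulate a noisy survey on the 100-detector grid and refit the
distance-falloff exponent:

```r
library(neutrondose)

cfg <- beamline_preset("general_purpose_100_250")
pts <- tibble::tibble(x_cm = c(0, 10, 40), y_cm = 0, z_cm = 230)
evaluate_hd(pts, cfg, energy = 200)
#> # A tibble: 3 × 5
#>    x_cm energy_MeV hd_Sv_per_Gy hd_direct_Sv_per_Gy hd_epithermal_Sv_per_Gy
#>   <dbl>      <dbl>        <dbl>               <dbl>                   <dbl>
#> 1     0        200      0.00261           0.00128                  0.00102
#> 2    10        200      0.00231           0.000991                 0.00101
#> 3    40        200      0.00128           0.0000212                0.000989

ds  <- generate_dataset(mdacc_grid(), cfg, noise = noise_model(0.05, seed = 1))
fit <- fit_general(ds, cfg, free = "q")
fit
#> <hd_fit> general_purpose_100_250
#>   800 records, 1 free parameter(s): q
#>   objective (mean_squared relative residual): 0.002708; converged: TRUE
#>   local relative error: mean 4.13%, max 17.8%
#>   estimates: q = 1.1637
```

On the beam axis a 200 MeV beam delivers about 2.6 mSv of neutron dose per
treatment gray; at 40 cm off-axis the forward-peaked cascade component has
almost vanished and the near-isotropic epithermal regime dominates. The
refitted falloff exponent (1.16 under 5% noise, generating value 1.13)
illustrates the estimator dispersion discussed in the vignette. Broom-style
`tidy()`/`glance()` summarize fits, `autoplot()` draws observed-vs-modeled
H/D, and `validate_report()` tabulates mean and maximum local relative
error per energy:

```r
validate_report(fit$config, ds)
#> # A tibble: 9 × 4
#>   energy     n mean_pct max_pct
#>   <chr>  <int>    <dbl>   <dbl>
#> 1 All      800     4.13    17.8
#> 2 250      100     4.63    14.7
#> 3 225      100     4.48    17.0
#> 4 200      100     3.94    14.5
#> # ℹ 5 more rows
```

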