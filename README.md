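# dyefront

Dye-front tracking and pseudo diffusion coefficients for dissolved CO₂
in hydrogels.

## What it does

A hydrogel column doped with an alkaline bromothymol blue solution is
gassed with CO₂ from above. The dissolving gas acidifies the gel from
the top down, flipping the indicator from blue to yellow, and the sharp
colour front that migrates downward is an optical proxy for the
penetration depth of dissolved CO₂. From time-lapse vial images,
`dyefront`:

* detects the blue/yellow interface per frame — homography
  rectification, ROI crop, HSV saturation, Otsu binarization, smoothed
  row profile, sub-pixel 0.5-crossing;
* converts the track to interface velocities `Vi = |x0 − xt| / t` and
  pseudo diffusion coefficients `D_pseudo = (x0 − xt)² / (2 t)` using
  the pre-gassing frame as the reference `x0`, and fits the
  square-root-of-time law `d² = 2 D t`;
* aggregates replicate vials as mean ± sd and compares hydrogels by
  fold ratio;
* models the underlying chemistry — carbonate speciation by bisection
  on the charge balance, Henderson–Hasselbalch indicator protonation —
  and provides 1-D diffusion generators (erfc closed form and explicit
  finite differences);
* renders seeded, ground-truthed synthetic vial images (logistic colour
  transition, yellow backlight filter, illumination gradient, sensor
  noise, dropping meniscus) so the full pipeline is testable end to end
  without the original, confidential imagery.

The methods vignette (`vignettes/indicator-front-analysis.Rmd`) records
the model, the parameter rationale and the known accuracy limits.

## Worked example

Simulate three replicate vials of an agarose-like gel
(`D = 11.55e-9 m²/s`, one frame every 5 min for an hour), track the
front and fit the kinetics:

```r
library(dyefront)

series <- render_multivial(rep(11.55e-9, 3), config = render_config(seed = 42L))
tracks <- track_series(series)
tracks[[1]]
#> Interface track, vial 1: 13 frames, x0 = 24.50 px
#>  time_s position_mm         flag
#>       0          NA no_interface
#>     300       2.630           ok
#>     600       3.727           ok
#>     900       4.568           ok
#>    1200       4.919      clamped
#>    1500          NA no_interface
#>    ...
```

The pre-gassing frame has no interface, so `x0` falls back to the gel
surface; by 20 minutes the front nears the 5.3 mm gel floor (flagged
`clamped`, excluded from fitting), and soon after the gel is fully
yellow — matching the published observation that the agarose gel has
almost completely turned after an hour.

```r
fit <- fit_front(tracks[[1]])
summary(fit)
#> Front kinetics fit (vial 1): 3/12 usable points
#>   mean per-time D_pseudo: 1.16e-08 m^2/s
#>   fitted D (d^2 = 2 D t): 1.16e-08 m^2/s
#>   per-time D_pseudo range: 1.15e-08 .. 1.16e-08 m^2/s
#>   residual sd of displacement: 4.37e-06 m
#>  time_s displacement_m velocity_m_s d_pseudo_m2_s
#>     300    0.002629589 8.765295e-06  1.152456e-08
#>     600    0.003726927 6.211545e-06  1.157499e-08
#>     900    0.004568117 5.075686e-06  1.159316e-08
coef(fit)
#>     fitted_D       mean_D
#> 1.158307e-08 1.156424e-08

summarize_replicates(lapply(tracks, fit_front), "agarose-like")
#> agarose-like: D_pseudo = 1.15e-08 +/- 1.98e-11 m^2/s (mean +/- sd, n = 3)
```

`fit_front()` returns a classed `"front_fit"` object with the usual
modelling methods (`print`, `summary`, `coef`, `predict`, `plot`,
`residuals`, `simulate`).

The same chain is scriptable: `run_simulate()` / `run_detect()` /
`run_analyze()` (or `run_end2end()`) move PNG frames, track CSVs and
result CSVs through disk, configured by YAML (`load_run_config()`), and
`inst/cli/ida.R` wraps them for the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ida.R", package = "dyefront"))')" \
  end2end --out workdir --label agarose
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "dyefront", load_package = "installed")'
```

The suite covers each module against independent oracles (closed-form
chemistry, brute-force Otsu, erfc solutions, exact √t tracks) plus
end-to-end recovery. One check fails by design: the strict
half-pixel-everywhere localization sweep on noise-free frames exceeds
its bound by ~0.1 px at a handful of depths, a structural quantization
floor of threshold-then-interpolate localization at this resolution
(documented in the vignette); it is reported honestly rather than
loosened.
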