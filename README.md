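# darcyflow

Recovery of convective transport properties — flow speed and Darcy
permeability — of perfused porous tissue from 4D dynamic contrast-enhanced
CT, with an extended Tofts compartmental model as the control and a
synthetic perfusion phantom for validation. It is aimed at quantitative
imaging researchers who want perfusion parameters with direct meaning in
the governing equations of convective transport (units of speed, pressure
gradient, permeability) rather than compartmental rate constants.

## The method

Perfused tissue is treated as a saturated porous mixture
(φ_tissue + φ_nano + φ_blood = 1, s_nano + s_blood = 1). Transport of
contrast along characteristics normal to the imaging-visible vessels obeys
a first-order hyperbolic equation whose solution is a delayed copy of the
arterial input:

    s_nano(x, t) = s_AIF(t − d(x) / a(x))

so the flow speed is measurable as distance over bolus transit time,

    a(x) = d(x) / (BAT(x) − BAT_inlet)

with d(x) an exact Euclidean distance map to the vessel mask and arrival
times (BAT) from the peak-gradient method. SLIC superpixels provide a
piecewise-constant basis a(x) = Σ_i α_i ψ_i(x); each α_i is refit to the
region's raw enhancement curves with per-voxel amplitudes profiled out.
Combining Darcy's law with Poiseuille flow in the feeding vessel (radius
R, flow rate Q), viscosity cancels and

    κ = a · π R⁴ / (8 Q)          [m²]

Blood-volume and mass-conservation flow-rate estimators, a
Frangi-type vesselness segmenter, a skeleton-based mean-radius estimator,
and the extended Tofts forward model/fit complete the toolbox.

## Worked example

```r
library(darcyflow)
ph  <- build_phantom(phantom_config(seed = 1))   # 60^3, 30 frames, 8 speed blocks
run <- darcy_run(ph$series, ph$labels, n_pre = 3)
print(run)
```

```
Convective transport fit
  stages: baseline -> enhancement -> aif -> bat -> distance -> speed ->
          superpixels -> speed_fit -> permeability -> tofts -> correlations
  27 superpixel regions; inlet BAT 12 s; vessel radius 1.41 mm
  mean tissue permeability: 1.23e-09 m^2
  correlations (region level):
    speed_vs_alpha   r =  0.970  (n = 27)
    speed_vs_ktrans  r = -0.139  (n = 27)
    speed_vs_ve      r =  0.257  (n = 27)
    speed_vs_fpv     r =  0.876  (n = 27)
```

The phantom's true speeds span 0.5–4 mm/s in eight blocks. `run$regions`
holds the per-superpixel table — e.g. region 2 (a pure 0.5 mm/s block)
averages 0.507 mm/s pixelwise and refits to 0.500 mm/s, with
κ = 2.66e-10 m² at the estimated 1.41 mm vessel radius and 177 ml/min
hepatic flow. `speed_vs_alpha` is the consistency of the superpixel basis
with the pixelwise measurement (the key internal validation);
`speed_vs_fpv` is the positive association between flow speed and the
Tofts fractional plasma volume. `plot(run)` draws the region-level speed
consistency scatter; `coef(run)` returns the fitted α_i.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/darcyflow.R phantom --out phantom_dir --seed 1
Rscript inst/cli/darcyflow.R run --config cfg.json
```

## Layout

* `R/` — containers and NIfTI I/O, phantom generator, vessel geometry,
  arrival mapping, convective transport estimators, Tofts control,
  pipeline.
* `src/` — compiled exact Euclidean distance transform, connected
  components, symmetric 3×3 eigenvalues.
* `vignettes/convective-transport.Rmd` — the model, its assumptions, and
  every numerical choice.
* `tests/testthat/` — oracle-backed unit and property tests plus the
  end-to-end validation suite.
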