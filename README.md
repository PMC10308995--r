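# optopore

Analysis tools for gold-nanoparticle mediated photoporation of mammalian
cells. When a nanosecond laser pulse fires on membrane-bound nanoparticles,
transient pores open in the cell membrane; extracellular macromolecules
(e.g. FITC-dextran) diffuse in until the membrane reseals. Two quantities
control the achievable **loading efficiency**: the **membrane resealing
time** — measurable as the recovery of a voltage-sensitive dye's
fluorescence to 90 % of its resting level — and the tracer's molecular
weight, which sets its diffusion speed through the Stokes–Einstein
relation *D = k<sub>B</sub>T / (6πηR)* with *R ∝ M<sup>1/3</sup>*.

The package is aimed at labs doing optoporation / intracellular-delivery
work who want a tested, reproducible implementation of the measurement and
modelling chain:

* **Trace processing** — linear photobleaching correction fitted on the
  pre-laser background frames, k-sigma perforation calls, and the 90 %
  recovery rule with sub-frame interpolation (`bleach_correct()`,
  `classify_perforated()`, `resealing_time()`, `analyze_traces()`).
* **Brownian-motion Monte Carlo** — point tracers random-walk between a
  unit spherical cell and a reflecting outer boundary and are absorbed
  through spherical-cap pores while the pores are open; the per-step
  displacement scales as *M<sup>−1/3</sup>* (`simulate_loading()`,
  `calibrate_step()`, `loading_vs_time()`, `loading_vs_mw()`; Rcpp
  kernel).
* **Exponential calibration fits** — `y = a·e^(±x/b) + c` by multi-start
  Levenberg–Marquardt, with R² as the coefficient of determination
  (`fit_exp_growth()`, `fit_exp_decay()`, `concordance()`).
* **Synthetic data with ground truth** — traces, 16-bit TIFF image stacks
  and experiment tables whose true resealing times are known exactly
  (`make_trace()`, `make_stack()`, `make_experiment()`), plus an
  end-to-end pipeline (`run_pipeline()`) and a thin CLI
  (`inst/cli/optopore`).

## Worked example

```r
library(optopore)

# a synthetic perforated cell: 1000 AU resting level, linear bleaching,
# dip to 60 % of rest, true resealing time 41.59 s
spec <- trace_spec(resting_intensity = 1000, bleach_slope = -0.5,
                   dip_fraction = 0.6, true_resealing_time = 41.59)
tr <- make_trace(spec, cell_id = "demo")$trace
analyze_trace(tr)
#>   cell_id perforated dip_depth resealing_time_s resting_intensity bleach_slope
#> 1    demo       TRUE       0.4         41.59403              1000         -0.5

# predicted loading of a 10 kDa tracer during an 88.7 s pore opening
cell <- cell_model()                       # unit cell, one 0.2 rad pore
mol  <- molecule_spec(10, M_ref = 10, s_ref = 1.95)
sim  <- sim_params(n_particles = 1000, n_replicates = 4, seed = 1)
res  <- simulate_loading(cell, mol, sim, open_time = 88.7)
sprintf("loading = %.3f (sem %.4f)", res$loading_efficiency, res$sem_over_replicates)
#> "loading = 0.216 (sem 0.0064)"

# refit the fluence -> resealing-time calibration from noiseless samples
x <- c(0.064, 0.32, 0.64, 0.96, 1.28, 1.6)   # J/cm^2
fit_exp_growth(x, 106.3 * exp(x / 2.7) - 80.6)
#> Exponential growth fit: y = 106.3 * exp(x / 2.7) + -80.6
#>   n = 6, R^2 = 1, converged = TRUE
```

The analysed trace recovers the constructed 41.59 s resealing time to a
few milliseconds (sub-frame interpolation of the 90 % crossing); the
Monte Carlo run predicts ~22 % loading at the experimental optimum; and
the fitter recovers the generating calibration parameters exactly.

## Vignette

`vignettes/optopore-methods.Rmd` documents the models and their
assumptions: the 90 %-recovery convention and its confirmation window,
the bleaching-correction model, the Monte Carlo geometry, step model,
time-step rule and free-flight acceleration, the multi-start exponential
fitting (including why the growth family's rate grid covers both signs),
what the synthetic generator does and does not emulate, and the package's
numerical tolerances and known limitations.
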