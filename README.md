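# uterowave

Forward electromagnetic modelling of uterine contractions during pregnancy.

Predicting the onset of term and pre-term labor from abdominal-surface
recordings — electromyography (EMG) and magnetomyography (MMG) — requires a
forward model connecting myometrial electrophysiology to the fields a
sensor array measures. `uterowave` implements such a multiscale model in R:

* **Cell**: a modified FitzHugh–Nagumo ionic model with a plateau-type
  action potential,
  `J_ion = -(1/ε₁)[k (v_m − v₁)(v₂ − v_m)(v_m − v₃) − w]`,
  `∂w/∂t = ε₂(β v_m − γ w + δ)`, parameterised for term-pregnancy human
  myometrium (resting −56 mV, plateau near −20 mV for tens of seconds,
  after-hyperpolarisation).
* **Tissue**: the anisotropic monodomain reaction–diffusion equation
  `∇·( ς/(ς+1) G_e′ ∇v_m ) = a_m c_m ∂v_m/∂t + a_m (J_ion − J_stim)`
  on 1-D cables, 2-D annuli or 3-D spherical myometrial shells, with
  conductivity tensors `G′ = (σ_l − σ_t) a₃a₃ᵀ + σ_t I` built from designed
  fiber-direction fields `a₃(r)`, and σ values estimated from myocyte
  packing via Archie's law and a cubical-grid model.
* **Organ**: a four-compartment spherical volume conductor (fetus,
  amniotic cavity, myometrium, offset abdomen) solved quasi-statically for
  the surface potential `∇·(G∇φ) = ∇·J_s` with `J_s = −G_i′∇v_m`, and the
  abdominal magnetic field computed by Biot–Savart quadrature over the
  total current density, projected on the sensor normals (the MMG signal).

Meshing (structured, deterministic, interface-conforming), FEM assembly,
IMEX/BDF time integration, pacemaker stimuli, sensor arrays, waveform and
contracting-volume metrics, VTK/CSV/YAML/JSON I/O and a config-driven
pipeline (`run_pipeline()`) are all included. See the methods vignette
(`vignettes/uterowave-methods.Rmd`) for the model derivations, parameter
meanings, numerical choices and known limitations.

## Worked example

Derive the myometrial conductivities from the myocyte table, inspect the
excitability structure, and run a 20 cm monodomain cable:

```r
library(uterowave)

cond <- conductivity_model()     # Archie + grid chain, anisotropy 0.8
cond
#> Volume-conductor conductivities (S/m)
#>   compartments: G_A = 0.2, G_U = 1.74, G_F = 0.2
#>   extracellular medium sigma_e~ = 1.697
#>   myometrium: sigma_el = 0.6764, sigma_et = 0.2154, varsigma = 0.8
#>   intracellular: sigma_il = 0.5411, sigma_it = 0.1723

p <- ionic_params()
nullcline_fixed_points(p)        # frozen-recovery cubic roots (V)
#> [1] -0.06000000 -0.04850781 -0.01649219

sim <- simulate_cable(p, cond$sigma_el, cond$varsigma, dt = 0.01, t_end = 90)
waveform_metrics(sim$trace, resting = p$v_mr)
#> waveform_metrics: peak -17.0 mV, plateau mean -20.4 mV, duration 28.4 s (resting -56.0 mV)
round(100 * sim$speed, 3)        # measured front speed, cm/s
#> [1] 0.815
```

The cable probe records the plateau-type action potential the model was
designed for: an upstroke from −56 mV to about −17 mV (the upper root of
the ionic cubic at resting recovery), a sagging plateau around −20 mV,
repolarisation after about half a minute, and a hyperpolarising undershoot
that makes the tissue refractory for roughly two minutes
(`refractory_period(p)`). The front travels at ~0.8 cm/s with the derived
conductivities and anisotropy ratio 0.8.

A full 3-D run — fundal pacemaker on the spherical myometrium, surface
potentials, MMG at an abdominal sensor array, contracting-volume curve —
is one call:

```r
cfg <- run_config(mesh = list(resolution = 0.012, dimension = 3),
                  solver = list(dt = 0.02, t_end = 130, output_stride = 100),
                  out_dir = "run1")
res <- run_pipeline(cfg)
```

which writes the mesh (VTK), sensor layout, probe traces,
contracting-fraction and MMG time series (CSV) and a JSON manifest into
`run1/`. A thin command-line wrapper with `calibrate`, `simulate`,
`run-all` and `metrics` subcommands is installed at
`inst/cli/uterowave.R`.

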