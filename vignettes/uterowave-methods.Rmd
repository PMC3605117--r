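---
title: "Modelling uterine contractions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling uterine contractions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`uterowave` implements a multiscale forward electromagnetic model of the
pregnant uterus: a cellular ionic model generates a plateau-type action
potential, a tissue-level monodomain reaction–diffusion equation propagates
it over the myometrium, and quasi-static volume-conductor physics maps the
resulting current sources to the surface electric potential (EMG) and
magnetic field (MMG) a sensor array would record over the abdomen.

## Cellular scale: a modified FitzHugh–Nagumo model

Pregnant human myometrium near term predominantly shows *plateau-type*
transmembrane potentials: a depolarisation from about −56 mV sustained near
−20 mV for tens of seconds, terminated by an abrupt repolarisation and an
after-hyperpolarisation. A two-variable FitzHugh–Nagumo variant captures
this:

$$J_{ion} = -\frac{1}{\varepsilon_1}\Big[k\,(v_m-v_1)(v_2-v_m)(v_m-v_3) - w\Big],
\qquad
\frac{\partial w}{\partial t} = \varepsilon_2(\beta v_m - \gamma w + \delta).$$

The defaults of `ionic_params()` are the published term-pregnancy set:
$\varepsilon_1 = 200\ \Omega\,\mathrm{m}^2$ (edge sharpness; a resistivity,
so smaller values mean a more permeable membrane and steeper edges),
$\varepsilon_2 = 0.09\ \mathrm{s^{-1}}$ (duration; smaller is longer),
$k = 10^4\ \mathrm{V^{-2}}$, $(v_1, v_2, v_3) = (-20, -40, -65)$ mV,
$\delta = 52$ mV, $\gamma = 0.1$, $\beta = 1$,
$c_m = 0.01\ \mathrm{F/m^2}$, $v_{mr} = -56$ mV, and the surface-to-volume
ratio $a_m = 4/d_{cell} + 2/l_{cell} = 5.7587\times 10^5\ \mathrm{m^{-1}}$
of a closed 7 µm × 450 µm cylindrical myocyte.

**Unit convention.** $J_{ion}$ and the pacemaker stimulus
$J_{stim} = \varepsilon_1^{-1}\sum_i \nu_i h_i(r,t)$ are membrane current
densities *per unit membrane area* (A/m²), consistent with
$\varepsilon_1$'s units; the volume current density entering the tissue
equations is $a_m J$. All integrators in the package therefore solve
$c_m\,\partial_t v_m = -J_{ion} + J_{stim}$ at a point, and
$a_m c_m\,\partial_t v_m = \nabla\!\cdot(\sigma\nabla v_m) +
a_m(-J_{ion}+J_{stim})$ in tissue. This is the only reading under which the
published parameter tables produce the published physiology — the package's
test suite verifies a plateau peak near −16 mV (the upper root of the
cubic at resting recovery), a duration of tens of seconds and an
after-hyperpolarisation to about −68 mV. Dropping the $a_m$ factor slows
the dynamics by three orders of magnitude and produces no plateau at all.

## Tissue scale: conductivities and the monodomain equation

The bidomain description assigns the intra- and extracellular spaces
conductivity tensor fields $G_i'(r)$, $G_e'(r)$. Because no measured values
exist for human myometrium, the package *designs* them:

1. **Archie's law** (`archie_extracellular()`): the extracellular medium
   conductivity is $\tilde\sigma_e = \sigma_M/(1-p)^m$ from the bulk value
   $\sigma_M = 0.5$ S/m, myocyte volume fraction $p = 0.6$ and cementation
   factor $m = 4/3$ (long cylinders).
2. **Grid model** (`grid_conductivities()`): cylinders on a cubical grid
   occlude a fraction of the cross-section, giving
   $\sigma_{el} = \tilde\sigma_e(1-\pi d_{cell}^2/(4 d_T^2)) \approx 0.68$
   S/m along the fiber and
   $\sigma_{et} = \tilde\sigma_e(1-d_{cell}l_{cell}/(d_T l_T)) \approx 0.22$
   S/m across it.
3. **Equal anisotropy** $G_i' = \varsigma G_e'$, which decouples the
   bidomain system into the monodomain equation
   $$\nabla\cdot\Big(\tfrac{\varsigma}{\varsigma+1}G_e'\nabla v_m\Big)
     = a_m c_m\,\partial_t v_m + a_m(J_{ion} - J_{stim})$$
   and the elliptic recovery of the interstitial potential.

**Calibrating $\varsigma$.** Substituting a traveling wave
$v_m(\xi\cdot r - ct)$ with the recovery variable frozen at its resting
value turns the monodomain equation into the classical bistable front
problem, whose exact speed is $c = \sqrt{KD/2}\,(v_1^*-2v_2^*+v_3^*)$ with
$K = k/(\varepsilon_1 c_m)$,
$D = \tfrac{\varsigma}{1+\varsigma}\sigma_{el}/(a_m c_m)$, and
$v_1^*<v_2^*<v_3^*$ the roots of the frozen-recovery cubic
(`nullcline_fixed_points()`; for the default set:
−60.0, −48.5, −16.5 mV). Inverting for the ratio,
$$\varsigma = g\!\left(\frac{2c^2\varepsilon_1 a_m c_m^2}
  {\sigma_{el}\,k\,(v_1^*-2v_2^*+v_3^*)^2}\right),\qquad g(x) = \frac{x}{1-x},$$
valid only while the argument is below one, i.e. while $\varepsilon_1$ lies
inside an admissible interval (`eps1_upper_bound()`). The derivation fixes
an ambiguity in the printed formula: the denominator carries
$a_m c_m^2$, not $(a_m c_m)^2$. A direct speed-matching oracle
(`calibrate_varsigma_numeric()`, bisection on a simulated 1-D cable) checks
the closed form; the two routes agree to a few percent in the
frozen-recovery regime (small $\varepsilon_2$), which the test suite
verifies.

**An honest discrepancy.** With the published tables and the literature
propagation speed $c = 1.15$ cm/s, the closed form is *infeasible*: the
admissible interval for $\varepsilon_1$ ends at ≈188 Ω m², below the
table's 200, so no nonnegative ratio reaches that speed and
`anisotropy_ratio()` raises a calibration error — the published value
$\varsigma = 0.8$ cannot be reproduced from its stated inputs. Conversely,
taking $\varsigma = 0.8$ as given, the model's plane-wave speed is
$\approx 0.74$ cm/s analytically and $\approx 0.82$ cm/s measured on a
converged cable — consistent with the original simulation snapshots, in
which the excitation wave is still traversing the 16 cm sphere some 55 s
after onset. The package therefore treats $\varsigma = 0.8$ as the
reference value for simulations and reports the speed it actually
produces, rather than tuning either to the printed 1.15 cm/s.

## Fiber architecture

The myometrium is a union of closed layers (level sets of an implicit
$f(r)$). At each point, a local frame is erected from the layer normal
$\hat n = \nabla f/\|\nabla f\|$ and the tangent $\hat k$ of the *curve of
symmetry* (the fundus-to-cervix axis) at its nearest perpendicular foot:
$\hat t_1 = \beta\hat k + \gamma\hat n$ (meridional) and
$\hat t_2 = \hat t_1\times\hat n$ (circumferential), with
$\beta = 1/\sqrt{1-\langle\hat k,\hat n\rangle^2}$. The sign branch is fixed
so that $\hat t_1$ points from the fundus towards the cervix. The fiber
direction is $a_3 = \hat t_1\cos\alpha + \hat t_2\sin\alpha$; at the poles,
where the frame degenerates, $a_3 = 0$ and the tensor assembler falls back
to isotropy $\sigma_t I$. For spherical layers the construction reduces to
a closed form (`spherical_fiber_direction()`), re-derived here from the
axis-aligned matrix route because the printed component formula contains a
typographical artifact; the package cross-validates all three construction
routes against each other. The default orientation angle is
$\alpha = 45^\circ$, mixing circumferential and oblique fibers.

Tensors follow as
$G'(r) = (\sigma_l-\sigma_t)\,a_3 a_3^T + \sigma_t I$
(`assemble_tensor_field()`), cylindrically symmetric with eigenvalues
$(\sigma_t,\sigma_t,\sigma_l)$.

## Organ scale: volume conductor and fields

The geometry is four concentric-to-offset spheres: fetus F (12 cm),
amniotic cavity U, myometrial shell M (15–16 cm, 1 cm wall), and the
abdomen A (21 cm, shifted −3 cm along x so the uterus sits ventrally).
Compartment conductivities: $G_A = G_F = 0.2$ S/m, $G_U = 1.74$ S/m
(amniotic fluid). The vernix caseosa switch $\lambda$ either insulates the
fetal surface ($\lambda = 0$, the term-pregnancy default) or includes the
fetal compartment conductively.

Given $v_m$, the potential solves
$\nabla\cdot(G\nabla\phi) = \nabla\cdot J_s$ with
$J_s = -G_i'\nabla v_m$, potential continuity at interfaces (imposed by a
single conforming discretisation with piecewise tensors), no flux through
the abdominal surface, and a zero-mean gauge over the abdominal-surface
nodes — the natural gauge for differential surface-EMG measurements.

The magnetic field is computed by Biot–Savart quadrature over the total
current $J = -G_i'\nabla v_m - G_M'\nabla\phi_e$ (myometrium) and
$-G\nabla\phi$ (passive compartments), with element-midpoint quadrature
refined to a four-point rule near sensors. Under quasi-statics this is
equivalent to solving the magnetostatic boundary problem with an auxiliary
air volume, but needs no mesh of free space. The MMG signal is the
projection of $B$ on the outward abdominal normals.

# Numerical choices

* **Meshes** are structured and fully deterministic: uniform cables in 1-D,
  polar grids in 2-D, and radially layered subdivided-icosahedron
  tetrahedral meshes in 3-D whose layers coincide with the compartment
  interfaces (so labels and interface tags are exact). The abdominal
  band's outer surface follows the off-centre sphere through a
  direction-dependent radial map, keeping all four interfaces conforming
  in one mesh. The wall always receives at least two element layers.
* **Time stepping** is IMEX — implicit (backward-Euler) diffusion via a
  cached sparse Cholesky factorisation, explicit reaction — with automatic
  step halving on divergence; the 0-D integrator is BDF2 with damped
  Newton (default $dt = 1$ ms; the tissue default is 10 ms). The reaction
  explicit-stability limit for the default parameters is ~40 ms, so 10 ms
  is comfortably stable, and halving it moves the measured front speed by
  under 2% (verified in the tests).
* **Singular sources.** Point current dipoles (used only for validation
  against closed-form sphere solutions) are discretised either directly on
  the P1 basis or, for homogeneous conductors, by the subtraction method —
  the analytic free-space dipole potential plus a smooth FEM correction
  driven by surface loads — which restores fast convergence near the
  singularity. Return-current magnetic validation uses smooth compact
  current blobs instead of point dipoles, because the Biot–Savart integral
  of a point dipole's return current is log-divergent at the source; a
  *radial* blob in a spherically symmetric conductor is magnetically
  silent in the normal component by the same triple-product argument as
  the classical radial-dipole result.
* **Front-speed measurement** fits upstroke arrival times (crossings of
  $v_2 = -40$ mV) against distance over the central half of the cable,
  excluding boundary effects, and reports the fit's $R^2$.
* **Waveform metrics.** The action-potential duration is the time between
  the upward and downward crossings of the resting level (the
  hyperpolarisation onset). The plateau level is the median of the
  post-peak samples above rest — robust to a brief post-upstroke spike —
  and the plateau window runs from the first post-peak sample to the
  downward crossing of a 5 mV band below that level. This is a documented
  operational choice: the source literature never defines the averaging
  window, and because the simulated plateau sags continuously from the
  peak to the repolarisation knee, any window convention shifts the mean
  by a few mV. (On an idealised spike-then-flat trace the definition
  recovers the flat level exactly, which is the anchor the package's
  tests use.)
* **"Contracting" threshold.** The contracting-volume fraction counts
  element volume with $v_m \ge -40$ mV (the excitation threshold $v_2$):
  cells depolarised past threshold are in the force-generating plateau.
  The threshold is a configurable argument.
* **Refractory protocol.** Two identical pulses, bisection (1 s
  tolerance) on the inter-stimulus interval for a second response peaking
  within 5 mV of the first. The default pulse is the pacemaker amplitude
  (2 V) at 1.1× the threshold duration: near-threshold stimulation probes
  the intrinsic recovery limit, and the measured interval is insensitive
  to the exact factor (1.02–1.2× give the same interval to within 1 s).
  Under this protocol the default parameter set recovers full-amplitude
  re-excitability roughly two minutes after a stimulus, well before the
  membrane potential itself has returned to the resting level
  (`recovery_time()`, which takes several minutes depending on the
  tolerance); the published "one contraction every 240 s" corresponds to
  the latter, stricter, full-recovery reading. Both quantities are
  computed, not asserted.

# What the synthetic setting does and does not show

The built-in geometry and meshes emulate the published numerical study: a
spherical uterus, a single fundal pacemaker patch (2 V, 100 ms, the
spherical band $0.15 \le \|r\| \le 0.16$, $z \ge 0.15$), homogeneous
anisotropic myometrium, passive homogeneous compartments, and a spherical
abdominal sensor surface. Passing tests demonstrate internal correctness
(convergence to analytic sphere/cable solutions, conservation and
symmetry properties, determinism) and reproduction of the cellular-scale
physiology. They do *not* demonstrate fidelity to real anatomy: pear-shaped
or MRI-derived uterine shapes, DTMRI fiber maps, skin/fat layering,
electrode/SQUID characteristics and biological variability are all outside
the model class, so quantitative agreement with clinical EMG/MMG recordings
should not be inferred from green tests here.

Problem sizes used by the test-suite study: 1-D cables of 200 elements
(1 mm), a myometrial shell of ≈29k tetrahedra (12 mm edge target), a full
U+M+A conductor of ≈130k tetrahedra for the forward sweep, and
homogeneous balls of 16–36k tetrahedra for the analytic-oracle
comparisons. These sizes keep every simulation deterministic and
desk-scale while remaining fine enough that the wavefront (≈1.3 cm wide)
propagates without numerical block; coarser shells (≥18 mm edges) visibly
block propagation, which is why the shell fixtures use 12 mm.

# Known limitations

* The equal-anisotropy monodomain reduction cannot represent unequal
  anisotropy ratios; the full bidomain time integration is out of scope.
* Element-midpoint Biot–Savart quadrature is first-order; fields very
  close to the source volume (closer than about two element sizes) rely
  on the four-point refinement and should not be trusted below the few
  percent level.
* The ionic model has no explicit calcium dynamics; burst/spike-train
  electrograms are outside its repertoire.
* The spherical closed-form fiber field is singular at the poles; the
  isotropic fallback there is a modelling convention, not anatomy.
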