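---
title: "Methods: reduced-order coronary stenosis UQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order coronary stenosis UQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and limitations behind
`corouq`, in the spirit of a methods section: everything a user needs to
judge what the computed sensitivity indices do and do not mean.

## The physical model and its assumptions

The object of study is a single idealized coronary conduit with an eccentric
stenosis, described by five geometric parameters (segment lengths `Li`,
`Lm`, `Lo`, reference diameter `D`, severity `s0`) plus a fixed eccentricity
(35%). The diameter narrows as a quarter-sine over the converging ramp,
stays at `D (1 - s0)` across the throat, and recovers as a quarter-cosine;
the centerline offsets by up to `e0 = eps0 * s0 * D / 2`. Continuity at the
four junctions and the exact throat diameter are enforced by construction
and verified in the test suite to floating precision.

Blood is incompressible and Newtonian (density 1050 kg/m³, kinematic
viscosity 3.5e-6 m²/s). Flow through the conduit is modelled as a transient
quasi-one-dimensional series network rather than by 3D CFD:

* a distributed viscous term, `R_v = ∫ 128 μ / (π d(z)^4) dz` over the whole
  conduit (straight segments, ramps and throat), the exact Poiseuille limit
  for slowly varying lumen;
* a single empirical expansion loss `K Q |Q|` with
  `K = Kt (ρ/2) (1/A_throat − 1/A_ref)²`, a Borda–Carnot form for the
  post-throat jet separation; `Kt = 1.52`, a classic empirical value for
  smooth axisymmetric constrictions, exposed as an argument;
* a lumped microcirculation resistance `R_eff` at the outlet with venous
  pressure `Pv = 0`: the calibration of `R_eff` at baseline absorbs any
  constant venous offset, so its value is not separately identifiable here.

Hyperemia is modelled by quartering the microvascular resistance
(`hyperemia_factor = 0.25`). The inlet is a two-harmonic periodic pressure
waveform rescaled so its discrete mean is exactly the prescribed mean aortic
pressure; the true aortic shape is patient-specific and unavailable in
closed form, and because the network is quasi-steady and FFR/AWSS are
cycle-averaged ratios, only the mean (and weakly the pulse amplitude through
the quadratic loss) matters. Each 1.0 s cycle is discretized in 120 steps.

At every timestep the scalar balance
`Pa(t) − R_v Q − K Q|Q| − R_eff Q − Pv = 0`
is solved for `Q(t)` by bracketed root finding to 1e-10 ml/s. With zero
outlet compliance the steps decouple and the first cycle is already
periodic; the solver still verifies the cycle-to-cycle mean-flow criterion
(< 1e-8 ml/s). An implicit-Euler compliance branch exists (`C > 0` places a
capacitor at the conduit/microcirculation junction and marches cycles to
periodicity) but is off by default: no capacitance value is part of the
study definition, and the cycle-averaged outputs are insensitive to it.

Outputs:

* `FFR = mean(Pd) / mean(Pa)` under hyperemia, with `Pd` evaluated 20 mm
  downstream of the stenosis (ratio of cycle means — the clinical
  convention; the alternative mean-of-ratios differs and is deliberately not
  used);
* `AWSS_prox`: the Poiseuille closure `τ = 32 μ Q / (π d³)` averaged
  uniformly over the converging segment `[z0, z1]` and over the cycle, at
  baseline. The converging ramp is taken as "proximal" because that is where
  high-shear plaque burden localizes; the upstream straight conduit would
  give a `d = D` constant profile instead.

## Uncertain inputs and the sampling design

The seven uncertain inputs are independent uniforms; "5% uncertainty" is
interpreted as a symmetric relative half-width, `bounds = mean (1 ± u)`
(so `Pa ~ U[81, 99]` mmHg, `s0 ~ U[0.475, 0.525]`). No dispersion measure
other than these percentages is available, making the half-width convention
the natural reading; it is applied uniformly, including to `s0`.

Designs are Latin hypercubes: per input an independent random permutation of
the `Ns` equal-probability strata, with points at stratum midpoints by
default. Midpoint placement is deterministic given the permutations, keeps
column means exactly at the input means, and conditions the collocation
matrix well; a jittered variant is available. One integer seed drives all
columns, and identical seeds reproduce designs (and every downstream
artifact) byte for byte.

Microvascular calibration is performed once, at the input means, to a
baseline mean flow of 1 ml/s, and the calibrated `R_micro_base` is held
fixed across samples; the sampled normalized resistance `R` multiplies it.
This keeps `R` an independent uncertain input rather than re-absorbing
geometric uncertainty into the outlet at every sample.

## Polynomial chaos and Sobol indices

The surrogate basis is the total-degree tensorized family of *orthonormal*
Legendre polynomials on the per-input standardized interval, with
`Np = (n + p)! / (n! p!)` terms. Orthonormality (validated against a Gauss
quadrature Gram matrix to 1e-8) makes the moment formulas exact —
mean = constant coefficient, variance = sum of squared remaining
coefficients — and turns the Sobol conditional-variance definitions into an
exact partition of squared coefficients: terms involving only input `i`
give `Si`, terms involving `i` at all give `SiT`. Whether the basis is
normalized or merely orthogonal does not change `Si`/`SiT`; the orthonormal
convention is chosen because it makes the algebra transparent.

Coefficients are estimated by least squares at `Ns = ceiling(nps * Np)`
design points via QR decomposition; the design matrix condition number is
computed by SVD and fitting aborts beyond 1e10 (rank deficiency is reported
rather than silently regularized). An in-span response is recovered to
1e-8, and square systems (`nps = 1`) agree with oversampled ones for
in-span models.

An independent Monte Carlo pick-freeze oracle (Saltelli main-effect and
Jansen total-effect estimators with reported standard errors) implements
the literal conditional-variance definitions; the test suite requires the
coefficient partition and the oracle to agree within three standard errors
on every benchmark. Density estimates use Freedman–Diaconis histograms plus
a Gaussian kernel on 1e5 seeded surrogate resamples; the 95% prediction
interval uses linear-interpolation empirical quantiles.

## Synthetic benchmarks: what they do and do not show

The benchmark problems (`linear_additive`, `product`, `ishigami`,
`quadratic_mixed`) emulate exactly the statistical structure the study
assumes — independent uniform inputs mapped through a smooth deterministic
response — with closed-form moments and indices. They exercise the
production sampling/fit/analysis path end to end and pin down its
correctness to 0.01 in the indices (to 1e-8 for in-span responses).

They do not validate the hemodynamic model itself: passing benchmarks shows
the UQ machinery is right, not that a quasi-1D network reproduces 3D
coronary flow. The solver's own checks are physical instead: Poiseuille
closed forms, Ohmic limits, pressure-budget closure, monotonicity of FFR in
severity and length, and the 3–4x hyperemic flow ratio.

## Study sizes and runtime

The headline studies use `(p = 3, nps = 2)`, i.e. 240 transient solves of
120 timesteps each, which the reduced solver completes in seconds; the
convergence grid over `p = 1..4`, `nps = 1, 2` totals 1,482 solves. These
sizes follow the standard oversampling recommendation (`nps = 2`) and the
observation, reproducible with `run_convergence()`, that `(3, 2)` is where
the mean, density shape and index ranking stabilize.

## Known limitations

* The reduced-order solver is separable: `AWSS_prox` is (nearly) a product
  `Q * ⟨d^-3⟩` of factors each driven by single inputs. Its main indices
  make the reference diameter `D` the dominant AWSS input (exponent −3) and
  give Pa and R comparable shares, and its interaction gaps `SiT − Si` are
  at the percent level. Full 3D simulations of the same configuration
  report a different structure for proximal WSS — severity first, aortic
  pressure second, and substantial interaction terms — driven by flow
  separation and jet dynamics a 1D closure cannot represent. The FFR side
  is robust to this reduction (near-additive in both settings); the WSS
  side should be read as a demonstration of the pipeline, not as a
  validated WSS sensitivity ranking.
* Single conduit only: no side branches, no collateral flow, no wall
  elasticity, no non-Newtonian rheology.
* The eccentricity does not enter the 1D solver (it cannot distinguish
  offset from concentric narrowing at equal area); it matters only for the
  exported 3D surfaces.
* Inlet/outlet conduit lengths (10 mm / 25 mm) are modelling choices that
  keep the measurement plane inside the domain; they add only straight-tube
  Poiseuille resistance.
* Uniform input distributions with the half-width convention are an
  interpretation; other dispersion conventions would rescale the input
  variances and hence the indices.
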