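---
title: "Estimating myocardial elasticity from echocardiography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating myocardial elasticity from echocardiography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvelast)
```

## The forward model and its assumptions

`lvelast` idealizes the left ventricle as a thick-walled ellipsoidal
pressure vessel made of linear-elastic, isotropic, homogeneous material
that recovers its reference shape when unloaded. Internal pressure $P$
acts on the endocardial surface; the epicardial surface is
traction-free. Only the equatorial latitude plane is considered — the
plane that splits the ellipsoid into equal halves — which corresponds to
shape ratio $\kappa = 1$ in the general shell solution. These are strong
assumptions: real myocardium is anisotropic (fiber-oriented), undergoes
large deformations, and carries bending and shear that the symmetric
configuration ignores. The package's claims are therefore about this
model class, not about unrestricted cardiac mechanics.

The general-$\kappa$ stress field is controlled by three coefficients,

$$n = \frac{4\kappa\nu(1-\kappa) + (1-\nu)(4+5\kappa^2)}{\kappa^2(1-\nu)},
\qquad C_0 = \frac{\kappa+\nu}{1+\kappa},
\qquad C_1 = \frac{\nu(1-\kappa)}{1+\kappa\nu},$$

which collapse at $\kappa = 1$ to $n = 9$, $C_0 = (1+\nu)/2$, $C_1 = 0$
for every Poisson ratio. The printed general stress expressions are
typographically ambiguous in their source notation (stacked exponents of
the form $(n\pm3)/2$); this package adopts the reading under which each
stress is $K$ times a bracket, with
$K = P R_0^{(n+3)/2} r^{(n-3)/2} / ((R_0+T)^n - R_0^n)$, because that
reading (a) satisfies the pressure boundary conditions
$\sigma_{rr}(R_0) = -P$, $\sigma_{rr}(R_0+T) = 0$ for *every* $\kappa$,
and (b) reduces exactly to the unambiguous closed $\kappa=1$ form. The
test suite enforces both properties to $10^{-10}$ and $10^{-12}$
relative, respectively; the $\kappa=1$ form is normative wherever the
two could disagree.

At $\kappa = 1$ and midwall radius $R = (2R_0+T)/2$:

$$A = \frac{P R_0^6 R^3}{(R_0+T)^9 - R_0^9}, \quad
B = \frac{5R^9 + 4(R_0+T)^9}{R^9}, \quad
\sigma_{rr} = A\frac{R^9 - (R_0+T)^9}{R^9}, \quad
\sigma_{\theta\theta} = \frac{2AB}{3+\nu}, \quad
\sigma_{\phi\phi} = \frac{(1+\nu)AB}{3+\nu},$$

so $\sigma_{\theta\theta} + \sigma_{\phi\phi} = AB$ identically — the
reason $A$ and $B$ are carried on every stress triplet. $R$ is stored as
an explicit field (`R_mid`) rather than recomputed, so sensitivity
analyses can move the evaluation point.

Units: all lengths in cm (they cancel in $A$ and $B$ except through
ratios), all pressures, stresses and moduli in Pa. Ninth powers of
cm-scale radii stay comfortably inside double precision, so no log-space
rearrangement is needed; each power is computed once per evaluation.

## The inverse problem

Hooke's law maps stresses to strains,
$\varepsilon_{rr} = [\sigma_{rr} - \nu(\sigma_{\theta\theta}+\sigma_{\phi\phi})]/E$
and cyclic permutations. Substituting the shell stresses gives three
equations in the two unknowns $(E, \nu)$. Each equation rearranges into
a residual function that equals $\nu$ at consistency:

$$f_1 = \frac{\sigma_{rr} - \varepsilon_{rr}E}{AB},\qquad
f_2 = \frac{2AB/(3+\nu) - E\varepsilon_{\theta\theta}}
           {\sigma_{rr} + \frac{1+\nu}{3+\nu}AB},\qquad
f_3 = \frac{\frac{1+\nu}{3+\nu}AB - E\varepsilon_{\phi\phi}}
           {\sigma_{rr} + \frac{2}{3+\nu}AB},$$

and the estimator minimizes $J = \tfrac12\sum_i(\nu - f_i)^2$. An
important subtlety: the identity $f_1 = f_2 = f_3 = \nu$ holds only when
the stress triplet is evaluated at the *same* $\nu$ as the strains —
$\sigma_{\theta\theta}$ and $\sigma_{\phi\phi}$ split $AB$ by a
$\nu$-dependent factor. The residuals only ever consume $\sigma_{rr}$
and the product $AB$, both $\nu$-independent, which is what makes $J$ a
well-defined function of $(E,\nu)$ for fixed geometry and pressure.
`forward_strains()` packages the consistent chain and is the canonical
generator for recovery experiments.

The stationarity system $\partial J/\partial E = \partial J/\partial\nu
= 0$ could be solved by root finding; minimizing $J$ directly with
analytic gradients plus multi-start is more robust (no spurious
convergence to saddle configurations of the root system, and cheap
global coverage of a 2-D box). The gradients are re-derived from the
sum-of-squares form rather than taken from any printed display, and are
cross-validated against central finite differences at $10^3$ random
points in the test suite (agreement $\sim 4\times10^{-9}$ away from the
residual poles; within about $10^{-2}\,|AB|$ of a vanishing denominator
the finite-difference oracle itself loses validity, so gradient checks
exclude that neighborhood).

Numerical choices, all exposed in `estimator_config()`:

* **Search box**: $E \in (0, 5\times10^4]$ Pa, $\nu \in (-0.999, 1.5)$.
  The $\nu$ window deliberately exceeds the isotropic-material range
  $(-1, 0.5]$ because clinically recovered ratios reach above 0.7; it is
  a search region, not a physical claim.
* **Multi-start**: 8 log-spaced $E$ starts $\times$ 6 equispaced $\nu$
  starts, each jittered reproducibly from the seed ($J$ is cheap and the
  landscape low-dimensional, so dense coverage is the simple robust
  choice). The cost has more than one stationary point in general; all
  distinct ones are recorded and the feasible minimum wins, ties broken
  toward smaller $E$.
* **Local search**: L-BFGS-B with the analytic gradient, followed by a
  damped Newton polish of the 2×2 stationarity system (Hessian by
  central differences of the analytic gradient). $J$ is exactly
  quadratic in $E$ at fixed $\nu$, so the polish converges in a few
  steps and delivers machine-precision round trips
  ($\sim 10^{-16}$ relative, asserted at $10^{-6}$ with
  $J < 10^{-12}$ over 100 seeded draws).
* **Singularities**: points where a residual denominator vanishes get a
  large finite penalty ($10^{12}$) so box-constrained searches step away
  instead of aborting; the strict `residual_functions()` interface
  errors there, naming the offending term.
* **Determinism**: the start jitter runs under a private RNG state
  seeded from the config and restored afterwards; identical seeds give
  bit-identical estimates.
* **Scale covariance**: all stresses are linear in $P$, so scaling $P$
  by $c$ at fixed strains scales the recovered $E$ by $c$ exactly — a
  tested invariant that also explains why pressure-estimate bias maps
  one-to-one into stiffness bias.

## Sign conventions

Echo machines report radial strain positive and GCS/GLS negative
(reference state end-diastole). The forward model under internal
pressure produces the opposite signs at midwall: radial compression
($\varepsilon_{rr}<0$) and in-plane stretch. The source literature never
reconciles the two. `lvelast` supports both: `sign_convention = "echo"`
takes measurements as reported (the apparent historical practice), and
`"model"` flips all three signs into the forward model's own convention,
under which forward-generated strains are exactly recoverable. Recovery
and round-trip guarantees are stated for the model convention only; the
cylinder's exact solve in particular yields a negative (rejected)
modulus if fed echo-signed strains, which is itself a useful reminder
that the convention matters.

## Pressure and geometry from measurements

$R_0 = \mathrm{LVIDd}/2$, $T = \mathrm{LVPWd}$ (the posterior wall; the
septal thickness IVSd is carried for reporting but never feeds $T$), and
$P = (1.9 + 1.24\,e/e')/0.0075$ Pa — an affine filling-pressure
surrogate with slope $1.24/0.0075 \approx 165.3$ Pa per unit ratio and
intercept $1.9/0.0075 \approx 253.3$ Pa, which places typical clinical
ratios (7–12) in the 1.4–2.2 kPa range. Strain percents are divided by
100 exactly once, at parse time.

## The cylinder comparison model

The field's prior model treats the ventricle as an axisymmetric
thick-walled cylinder in plane strain ($\varepsilon_{zz} = 0$). Its
governing equations are not printed in the source literature; this
package adopts the standard Lamé solution with internal pressure only
and labels it a reconstruction in its documentation and CLI output.
With $x = (1-\nu^2)/E$ and $y = \nu(1+\nu)/E$ the constitutive map is
linear, two equations solve $(x, y)$ exactly, and
$\nu = y/(x+y)$, $E = (1-\nu^2)/x$. Geometry parity with the ellipsoid:
$a = \mathrm{LVIDd}/2$, $b = a + \mathrm{LVPWd}$, midwall evaluation
$(a+b)/2$ (the prior model's own evaluation point is unknown; midwall
mirrors the ellipsoid choice).

A known, deliberate consequence of this reconstruction: at the same
geometry and pressure the Lamé midwall hoop stress is roughly twice the
ellipsoid shell's, so on strains generated by the ellipsoid forward map
the cylinder reads systematically stiffer (about 2.2–2.4×), and its
stiffness-age slope inherits that factor. The two models' slopes agree
in sign on every tested synthetic cohort, but their ratio sits near
2.3–2.9 rather than inside the nominal [0.5, 2.0] similarity band; the
corresponding acceptance check is left failing rather than loosened,
because the band describes a comparison between two models fitted to
the *same real data* by a cylinder formulation (with interior and
exterior pressure) that is out of scope to reproduce.

## The synthetic cohort generator

`cohort_config()` defines the simulated study conditions; its defaults
are fixed anchors, chosen once from published group summaries of a
mixed normotensive/hypertensive adult echo cohort, not tuned knobs:

* 96 subjects, ages uniform on 40–82 years (populating both sides of
  the 65-year elderly cut), hypertension prevalence 0.51;
* latent stiffness $E = 1000 + 96\cdot\mathrm{age} +
  500\cdot\mathrm{htn} + \mathcal N(0, 1500^2)$ Pa, giving stratum means
  near 6100 Pa (younger) and 8100 Pa (elderly) with realistic spread;
* latent ratio $\nu = 0.545 + 0.001\cdot\mathrm{age} +
  0.12\cdot\mathrm{htn} + \mathcal N(0, 0.05^2)$, giving roughly 0.60
  normotensive vs 0.72 hypertensive;
* geometry from truncated normals around LVIDd 4.9 cm, LVPWd 0.88 cm,
  IVSd 0.85 cm, with small age/hypertension shifts encoding inward
  (hypertensive) vs outward (normotensive) remodeling of the internal
  dimension and septal thickening;
* e/e′ affine in age and hypertension (≈7.2 normotensive at 50 years,
  ≈11.3 hypertensive at 71), truncated to [2, 25];
* strains from the forward map at the latent truth, plus additive
  Gaussian measurement noise of SD 0.01 strain fraction by default.

Draws the linear model cannot represent (a strain magnitude reaching 1,
as happens for very soft walls under high pressure) are re-sampled with
a bounded retry budget. Gaussian noise everywhere is itself a modeling
choice — only means and SDs are published. The generator emits the echo
sign convention (`LVIDs = LVIDd(1+\varepsilon_{rr})`, negative GLS/GCS
percents) at full floating-point precision, so noiseless cohorts are
exactly recoverable *from the emitted table*, which is the module's core
acceptance surface.

What the generator does **not** emulate: the real joint distribution of
geometry, pressure and strain (conditional-independence assumptions
throughout), medication effects, comorbidities, longitudinal
trajectories, and — most importantly — any departure of real myocardium
from the isotropic linear-elastic model. Passing recovery tests
therefore demonstrate the estimator inverts its own forward model
correctly and preserves configured group structure; they say nothing
about anisotropy, hyperelasticity, or speckle-tracking measurement
physics.

## Reporting layer

`group_compare()` uses the Welch t test by default — the source
literature says only "Student's t test", and unequal variances are the
safer default — with the pooled-variance variant behind a flag; four
crossed strata go through one-way ANOVA. No multiple-testing correction
is applied (matching the practice being emulated), and the output
records that. `age_trend()` reports Pearson r, $R^2$, slope and p-value
per stratum; partial correlations are deliberately unsupported because
the conditioning covariates were never specified in the source
practice.

## Forward pressure–thickness exploration

`forward_thickness_curve()` reconstructs the forward analysis pattern:
for fixed $(E, \nu, R_0)$ and each pressure on a grid, it solves by
bracketed bisection (with secant polish) for the wall thickness at
which the midwall circumferential strain magnitude equals a target
(default 0.18, the order of observed global circumferential strain).
The strain magnitude is strictly decreasing in thickness, so the root
is unique; solutions reproduce the target to $10^{-8}$ and the solver
errors clearly when no thickness in $(0, 10R_0]$ can reach the target.
The published exploration's exact procedure is not recoverable, so the
output is flagged `reconstruction` in both the return attribute and the
CLI CSV.

## Problem sizes and runtime choices

The shipped suite exercises: $10^4$ random geometries for boundary
conditions, $2\times10^3$ for the reduction identity, $10^3$
finite-difference gradient points, $10^2$ forward–inverse round trips,
a $400\times400$ grid-search optimality oracle, $2\times10^2$ exact
cylinder recoveries, and 20 seeded default-size (96-subject) synthetic
cohorts for the direction checks — sizes chosen to give stable
Monte-Carlo verdicts on a single CPU in a few minutes. Null-calibration
of the t test runs at 300 simulations against a 3-sigma binomial band.

## Known limitations

* Isotropic linear elasticity at a single latitude plane; no fibers,
  no large-strain kinematics, no bending or shear.
* Pressure enters only through the e/e′ surrogate; its biases propagate
  multiplicatively into $E$ (exact scale covariance).
* The echo/model sign discrepancy is supported but not resolved;
  estimates from echo-signed strains are not guaranteed recoverable.
* The cylinder comparison is a reconstruction; it reproduces the prior
  model's *form*, not its published numerics.
* Three residual equations over two unknowns means real (inconsistent)
  data end at a strictly positive $J$; `J_final` should be reported
  alongside the moduli as a model-adequacy signal.
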