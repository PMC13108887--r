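---
title: "Phase-field vesicle membranes with area-difference elasticity: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field vesicle membranes with area-difference elasticity: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclepf)
```

## The model

A vesicle membrane is represented by a smooth phase field $\varphi$ on a
periodic cube $\Omega = [0, L)^3$: $\varphi \approx +1$ in the enclosed
fluid, $\approx -1$ outside, with a $\tanh$ transition layer of width
$\sim \varepsilon$ whose zero level set is the membrane $\Gamma$. The
package minimizes, by gradient flow, the penalized energy

$$E(\varphi) = W(\varphi) + G(\varphi)
  + M_1\,(V(\varphi)-\alpha)^2 + M_2\,(A(\varphi)-\beta)^2 .$$

**Bending energy.** $W = \frac{\kappa\varepsilon}{2}\int_\Omega
\big(\Delta\varphi - \tfrac{1}{\varepsilon^2}(\varphi^2-1)(\varphi +
C\varepsilon)\big)^2\,dx$ is the standard diffuse-interface relaxation of
the Helfrich energy $\tfrac{\kappa}{2}\oint (2H - 2c_0)^2\,dA$ (up to a
constant factor), with $C = 2c_0$ twice the spontaneous curvature. On a
planar equilibrium profile $\varphi = \tanh(d/\sqrt{2}\varepsilon)$ the
integrand vanishes identically; for a sphere $W \to
\kappa\,\tfrac{16\sqrt{2}\pi}{3}$ independent of radius, a closed form the
test suite uses to pin the normalization.

**Volume and area.** $V = \int (\varphi+1)/2\,dx$ tends to the enclosed
volume; the Modica–Mortola-type functional
$B = \int \tfrac{\varepsilon}{2}|\nabla\varphi|^2 +
\tfrac{1}{4\varepsilon}(\varphi^2-1)^2\,dx$ carries
$\tfrac{2\sqrt 2}{3}$ per unit interface area (the 1D profile integral
$\int(1-\varphi^2)^2 dx = \tfrac{4\sqrt 2}{3}\varepsilon$), so
$A = \tfrac{3\sqrt 2}{4} B$ measures membrane area. Both are enforced
softly through quadratic penalties with coefficients $M_1, M_2$.

**Area-difference elasticity.** The two leaflets of a bilayer with neutral
surfaces separated by $D$ differ in area by $\Delta A = D \oint 2H\,dA$.
Using the phase-field representation of the mean curvature and the profile
integral above, the package evaluates this entirely in the bulk,

$$\Delta A(\varphi) = -\frac{3D}{4}\int_\Omega
  (1-\varphi^2)\Delta\varphi +
  \frac{1}{\varepsilon^2}\varphi(1-\varphi^2)^2 \, dx ,$$

with the orientation convention (interior $\{\varphi > 0\}$) under which a
sphere of radius $R$ gives $+8\pi D R$. The ADE energy penalizes deviation
from the relaxed (preferred) difference $\Delta A_0$:

$$G(\varphi) = \frac{\bar\kappa\pi}{2 A_0 D^2}\,
  (\Delta A(\varphi) - \Delta A_0)^2 ,$$

a global (non-local) quadratic: its variational derivative couples every
point to the integral $\Delta A$, which is the source of the stiffness the
implicit schemes address. $A_0$ is fixed to the area target $\beta$, which
is itself measured from the initial shape — the membrane area is treated
as conserved material.

Because $\Delta A$ is one global integral over all of $\Omega$, the same
ADE penalty continues to act, as the sum over sheets, after fission or
fusion events — this is what lets a single energy drive topological
transitions while conserving the parent vesicle's material properties.

**Reduced parameters.** Runs are specified by the dimensionless reduced
volume $v = \alpha/(\tfrac{4\pi}{3}R_s^3)$ and reduced area difference
$\Delta a_0 = \Delta A_0/(8\pi D R_s)$, with $R_s = \sqrt{\beta/4\pi}$ the
radius of the area-equivalent sphere; both equal 1 for a sphere.
`derive_constraint_targets()` converts a prescribed $(v, \Delta a_0)$ plus
the measured area of the initial field into $(\alpha, \beta, \Delta A_0)$.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `eps` | interface width (domain length units) | per experiment (0.02–0.04) | needs $\varepsilon/h \gtrsim 1.3$ to resolve the layer |
| `kappa` | bending modulus | 1 | sets the energy scale |
| `kbar` | ADE modulus | 1.4 | relative strength of the leaflet-area constraint |
| `C` | twice the spontaneous curvature | 0 | 0 isolates the ADE effect |
| `D` | leaflet separation | $\tfrac{2}{3}\varepsilon$ | bilayer-geometry coupling; overridable |
| `M1`, `M2` | volume/area penalty coefficients | $10^5$, $10^4$ | soft constraints: steady states satisfy the targets to a few percent |
| `dt` | time step | per experiment ($10^{-7}$–$10^{-6}$) | semi-implicit scheme tolerates these values at $64^3$ |

The defaults (cubic box $L = 1$, $N = 64$, and the table above) are the
conditions of the simulated experiments; the preset registry (`preset()`)
overrides them per morphology, e.g. the nested configuration uses
$L = 2$, $N = 100$, $\varepsilon = 0.03$, $\bar\kappa = 4$,
$M_1 = M_2 = 10^4$.

## Discretization and time stepping

All spatial operators are Fourier-spectral on the uniform periodic grid
$x_i = ih$, $h = L/N$: the Laplacian is multiplication by $-|k|^2$ in
transform space, $\int |\nabla\varphi|^2$ is evaluated by Parseval, and
quadrature is the rectangle rule (spectrally accurate for smooth periodic
integrands). Nonlinear terms are formed by collocation (pointwise
products) without dealiasing; the fields of interest are strongly
band-limited by the $\tanh$ layer, and the optional resolution rule
$\varepsilon/h \gtrsim 1.3$ keeps aliasing below the truncation error. The
even-$N$ Nyquist mode is retained: its Laplacian/biharmonic symbols are
real and even, so no special treatment is needed. All transforms use the
real part of the inverse FFT; realness is exact by construction since
every symbol is real.

Three steppers integrate $\varphi_t = -\delta E/\delta\varphi$:

* **Forward Euler** — explicit; stable only for $\Delta t \lesssim
  (\kappa\varepsilon |k|_{\max}^4)^{-1}$, provided for reference and
  small-step descent tests.
* **Semi-implicit (default)** — the stiff linear part of the bending
  force, $\kappa(\varepsilon\Delta^2 + \tfrac{2}{\varepsilon}\Delta)
  \varphi^{n+1}$, is implicit (a diagonal solve in Fourier space); the
  remaining nonlinearity, the ADE force and the penalties are explicit at
  $\varphi^n$. First-order in time; the Fourier symbol
  $1/\Delta t + \kappa(\varepsilon|k|^4 - \tfrac{2}{\varepsilon}|k|^2)$
  is checked for positivity at every mode and a violation (too-large
  $\Delta t$) is refused with the offending mode named.
* **Fully implicit symmetrized** — both endpoint states enter through
  two-argument forms $f(\varphi,\eta)$, $g(\varphi,\eta)$,
  $h(\varphi,\eta)$ constructed so that the *exact difference identities*

  $$W(\varphi)-W(\eta) = \int (\varphi-\eta)\,\kappa g(\varphi,\eta)\,dx,
  \qquad G(\varphi)-G(\eta) = \int (\varphi-\eta)\,h(\varphi,\eta)\,dx,$$

  and their volume/area counterparts hold identically (not just to leading
  order). Multiplying the scheme by $\varphi^{n+1}-\varphi^n$ and summing
  the identities yields the discrete energy law
  $E(\varphi^{n+1}) - E(\varphi^n) + \tfrac{1}{\Delta t}\int
  (\varphi^{n+1}-\varphi^n)^2 dx = 0$ — unconditional energy dissipation.
  The symmetric ADE bracket requires care: the naive symmetrization of the
  single-argument derivative misses two terms that are products of
  swap-antisymmetric factors (hence symmetric, and vanishing at equal
  arguments). The package derives and uses the exact form

  $$-\tfrac{1}{2}(\varphi+\eta)\Delta(\varphi+\eta)
    - \tfrac{1}{2}\Delta(\varphi^2+\eta^2)
    + \tfrac{1}{\varepsilon^2}\,
      \frac{\varphi(1-\varphi^2)^2 - \eta(1-\eta^2)^2}{\varphi-\eta},$$

  with the last factor expanded as the symmetric polynomial
  $1 - 2(\varphi^2{+}\varphi\eta{+}\eta^2) + \varphi^4 + \varphi^3\eta +
  \varphi^2\eta^2 + \varphi\eta^3 + \eta^4$. `verify_identities()` checks
  all four identities to machine precision on random smooth fields, and
  `verify_energy_law()` checks the per-step law itself. The nonlinear
  system is solved by Picard (fixed-point) iteration preconditioned by the
  semi-implicit linear operator — simple and robust at the small
  $\Delta t$ these simulations use (tolerance $10^{-10}$ in max norm, cap
  200 iterations; non-contraction is reported as a too-large time step).
  Newton iteration would converge faster per step but is unnecessary here.

The semi-implicit scheme is the production integrator: it is not provably
energy-stable, but the dissipation is verified numerically — the
energy-stability test tracks per-step energy differences over the
discocyte and torus runs and bounds any increase by $10^{-10}|E|$.

**Steady-state detection.** Runs stop when the max-norm rate
$\|\varphi^{n+1}-\varphi^n\|_\infty/\Delta t$ stays below `steady_rate_tol`
(default $10^{-3}$ in $\varphi$-units per unit time) for `steady_window`
(default 100) consecutive steps. A rate-based criterion is
$\Delta t$-independent, unlike thresholds on per-step increments. Both
knobs are configurable; energy plateaus can be confirmed from the logged
series. Time steps are fixed (no adaptivity); each experiment has a known
workable value.

**Divergence guard.** $\max|\varphi| > 2.5$ or any non-finite value aborts
a step: $\varphi$ physically lives near $[-1, 1]$, and excursions beyond
~2 only occur when a scheme has destabilized.

## Initial shapes and presets

Initial conditions are analytic $\tanh$ profiles of implicit surfaces:
ellipsoids $\tanh\!\big((r_0 - \sqrt{\textstyle\sum_i (x_i-c_i)^2/d_i})/
\sqrt{2}\varepsilon\big)$ and unions of two spheres
$\tanh(\max(r_1-d_1,\, r_2-d_2)/\sqrt{2}\varepsilon)$ (the deliberately
asymmetric seed used for pear shapes, where symmetric seeds get trapped in
metastable symmetric states). The preset registry carries each
experiment's full parameter set. Two presets (`chain` and
`budding_series_b`) are parameterized identically yet target different
morphologies (distinct basins of the same energy landscape); the registry
ships both and the ambiguity is documented rather than resolved. The `pear` preset
requires explicit $(v, \Delta a_0)$ — the pear region is narrow and best
explored by parameter continuation (`sweep_targets(continuation = TRUE)`
seeds each run with the nearest completed neighbor's final state). An
optional seeded band-limited perturbation (`add_perturbation()`) is
available for symmetry breaking but is off by default: the presets break
symmetry through the initial geometry instead.

A small bias worth knowing about: for a $\tanh$ sphere of radius $R$ the
volume functional carries an intrinsic $O(\varepsilon^2)$ excess,
$V = \tfrac{4\pi}{3}R^3 + \tfrac{2\pi^3}{3} R\,\varepsilon^2 + \dots$
(about $+1.6\%$ at $\varepsilon = 0.02$, $R = 0.35$), which is a property
of the diffuse functional itself, not of the discretization. Area and
area-difference converge faster in practice. Consequently measured reduced
volumes sit slightly above their sharp-interface values at finite
$\varepsilon$, and constraint targets derived *from* the diffuse
functionals are self-consistent.

## Shape diagnostics

* **Reduced parameters** are recomputed from the current field (volume,
  area, area difference), so they track the dynamics, not the targets.
  Because the penalties are soft, steady states satisfy
  $|v - v_{\text{target}}| \lesssim 0.05$.
* **Component counts** label the voxel sets $\{\varphi > 0\}$ /
  $\{\varphi < 0\}$ by flood fill (vectorized min-label propagation),
  honoring the periodic wrap; default 6-connectivity never merges diagonal
  touches. Membrane sheets are counted as interior + exterior components
  − 1 (a sphere-within-shell state has one interior shell region and two
  exterior regions: two sheets).
* **Arm counting** has no canonical definition; the package defines an arm
  as a direction-localized protrusion: with $r_{\text{lo}}$ the smallest
  directional extent of the interior (over a coarse 26-direction fan) and
  $r_{\text{hi}}$ the largest centroid distance, components of the
  interior beyond $r_c = r_{\text{lo}} + \texttt{core\_fraction}\,
  (r_{\text{hi}} - r_{\text{lo}})$ are counted if they exceed a few voxels
  and their mean resultant direction length is $\ge 0.5$. The thresholds
  make a sphere report 0 (its tips are indistinguishable from its waist),
  keep an oblate discocyte's equatorial rim from registering (its
  directions cancel), and are insensitive to whole-cell translations. A
  simpler rule — cut at a fixed fraction of the maximal extent — fails
  exactly those degenerate cases.
* **Reflection asymmetry** measures up-down symmetry breaking (pear
  shapes): the interior's principal axis is snapped to the nearest grid
  axis and the field is reflected about the centroid plane by exact index
  reversal (both candidate planes bracketing the centroid are tried and
  the smaller score kept), scoring
  $\|\varphi - \varphi_{\text{refl}}\|_1 / \|\varphi + 1\|_1 \in [0,1]$.
  Index reflection avoids interpolation error entirely; the cost is that
  shapes whose principal axis is far from every grid axis are scored
  against the nearest-axis mirror, which overestimates their asymmetry —
  acceptable for the axis-aligned seeds used here.

## Verification suites and problem sizes

The package verifies itself at sizes chosen to keep the full suite at a
few minutes:

* `verify_gradients()` ($32^3$, 5 random smooth pairs): Richardson-
  extrapolated directional derivatives vs the analytic variational
  derivatives of $W, G, T_1, T_2$, to $10^{-6}$ relative. This single
  check certifies every reconstructed constant ($\tfrac{3\sqrt 2}{4}$,
  $\tfrac{3\sqrt 2}{2}$, the ADE prefactor and its sign).
* `verify_sphere()` ($64^3$, $\varepsilon = 0.02$): $V, A, \Delta A, v,
  \Delta a$ against the closed sphere forms.
* `verify_identities()` ($48^3$): the four exact difference identities.
* `verify_energy_law()` ($32^3$, 20 steps): the discrete energy law of the
  fully implicit scheme, residual $\le 10^{-8}|E|$.
* `verify_cauchy()` ($64^3$, horizon $T = 2\times10^{-6}$, ladder
  $\Delta t = 2\times10^{-7} \dots 1.25\times10^{-8}$): successive
  $L^2$ Cauchy differences of the semi-implicit solution at $T$; orders
  $\log_2(e_{\Delta t}/e_{\Delta t/2})$ approach 1. The configuration —
  discocyte physics on a fixed fine grid, a short horizon, and the halving
  ladder — isolates the temporal error; the grid is fine enough that the
  spectral spatial error is negligible against the $O(\Delta t)$ terms.
* Morphology fixtures (disjoint balls, ball-with-capsule-arms, nested
  shells) are generated analytically in the test helpers; they exercise
  the counting metrics at full fidelity without long simulations.

What these fixtures do **not** show: the analytic shapes have exact tanh
profiles and clean geometry, whereas simulated steady states carry
anisotropic layer perturbations, near-touching necks and grid-scale
features. The full-scale morphology claims (fission at
$\Delta a_0 = 1.8$, six arms, nesting) require running the presets to
steady state — hours of desk time — and are therefore exercised by the
fixtures in routine testing, with the presets provided for the long runs.

## Known limitations

* The composition kinks of min/max-built profiles (slabs, sphere unions)
  produce spectral ringing; residual-based checks near such kinks are
  limited to ~$10^{-3}$ rather than machine precision.
* Penalty (not Lagrange/projection) constraint enforcement: volume and
  area drift of a few percent from their targets is expected, scaled by
  $1/M_1, 1/M_2$.
* Collocation without dealiasing assumes resolved interfaces; with
  $\varepsilon/h < 1$ the schemes remain stable but the functionals lose
  accuracy.
* No hydrodynamics, no Gaussian-curvature (topology-sensing) energy term,
  no multi-component membranes; the gradient flow is non-conserved
  Allen–Cahn relaxation, so the dynamics is a path to equilibrium, not a
  physical trajectory.
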