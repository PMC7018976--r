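---
title: "Bead formation on heterogeneous membrane nanotubes: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead formation on heterogeneous membrane nanotubes: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobead)
```

Membrane nanotubes are thin lipid tethers, tens of micrometres long and a
few tens of nanometres in radius, that can connect cells. They are usually
cylindrical, but locally they may swell into bead-like dilations. This
package models those beads as equilibrium shapes of an elastic membrane
whose composition is locally heterogeneous: a phase-separated protein
domain that induces spontaneous curvature, stiffens the membrane, or both.

# The model

## Energy

The membrane is a thin, areally incompressible elastic surface with energy
per unit area

$$W = \kappa(u)\,[H - C(\sigma)]^2 + \kappa_G(u)\,K
      \;-\; \alpha\,\sigma^2 \;+\; \beta\,(\nabla\sigma)^2
      \;\Big[+\; k_BT\,\sigma(\log(\sigma/\sigma_s) - 1)\Big],$$

where $H$ and $K$ are the mean and Gaussian curvatures, $\sigma(u)$ is the
surface density of a cone-shaped protein, and the induced spontaneous
curvature is linear in the density, $C = \mu\varphi\sigma$, with
$\varphi < 0$ so that proteins bend the membrane outward. The $-\alpha
\sigma^2$ term is the attraction between neighbouring proteins, the
$\beta(\nabla\sigma)^2$ term penalizes sharp composition gradients, and
the bracketed entropic term is retained behind a flag
(`include_entropy`) but off by default: for bending rigidities of
20–40 $k_BT$ and dilute densities it is below 1% of the bending energy
(the test suite checks this on a solved bead).

Mechanical equilibrium under a local area constraint (Lagrange multiplier
field $\lambda$, interpreted as the membrane tension) gives two balance
laws: the normal balance ("shape equation")

$$\Delta[\kappa(H - C)] - (\kappa_G)_{;\xi\eta}\tilde b^{\xi\eta}
  - 2\kappa H (H-C)^2 + 2\kappa(H-C)(2H^2 - K)
  + 2H\alpha\sigma^2 - 2H\beta(\nabla\sigma)^2 = p + 2\lambda H,$$

and the tangential balance

$$\nabla\lambda = 2[\kappa\mu\varphi(H - C) + \alpha\sigma]\,\nabla\sigma
  - \beta\,\nabla\sigma\,\partial(\nabla\sigma)
  - (H-C)^2\,\nabla\kappa - K\,\nabla\kappa_G.$$

The aggregation source in the tangential balance must carry
$\alpha\sigma\,\nabla\sigma$ (not $\alpha\,\nabla\sigma$) on dimensional
grounds; it is the explicit derivative of $-\alpha\sigma^2$. One useful
exact property follows: adding a constant to $\alpha$ shifts
$\lambda$ by $\alpha\sigma^2$ pointwise and changes no shape — the
aggregation strength is a gauge term for prescribed $\sigma$. This is why
equilibrium shapes are insensitive to $\alpha$.

## Material (area) parameterization

Because the bilayer is locally area-incompressible, a protein domain is a
fixed patch of membrane *material*. The solver therefore parameterizes the
surface by the material coordinate $u \in [0, L_c]$, the length the tube
would have in its undeformed reference state; the membrane area
$2\pi R_c L_c$ is conserved, and the deformed arclength follows from the
area map

$$\frac{ds}{du} = \frac{R_c}{r(u)}.$$

All heterogeneity fields are material fields $\sigma(u)$, $\kappa(u)$,
$\kappa_G(u)$, and the stated domain length (e.g. $L_{protein} = 8\,\mu m$)
is material length, i.e. membrane area $2\pi R_c L_{protein}$. This
reading has a direct physical consequence: a protein patch of material
length $L_p$ can balloon into at most a sphere of radius
$\sqrt{R_c L_p / 2} \approx 374$ nm for $L_p = 8\,\mu m$ — precisely the
few-hundred-nanometre scale of the observed beads. (Parameterizing by
deformed arclength instead would let a bead recruit membrane without
bound, losing the fixed-area cap that sets this scale; that variant was
implemented during development and rejected.)

## First-order system

With tangent angle $\psi$ ($r' = \cos\psi$, $z' = \sin\psi$ in arclength,
$2H = \psi' + \sin\psi/r$, $K = \psi'\sin\psi/r$) and the auxiliary moment
flux $\ell = r\,d[\kappa(H-C)]/ds$, the two balances reduce to six
first-order ODEs in $u$ for $(r, z, \psi, H, \ell, \lambda)$; every
arclength derivative carries the transport factor $R_c/r$, while the
material fields differentiate directly (their derivatives are analytic
tanh expressions, never finite differences). The Gaussian-modulus term
reduces on a surface of revolution to
$(\kappa_G)_{;\xi\eta}\tilde b^{\xi\eta} = \frac{1}{r}\frac{d}{ds}
[\kappa_G'\sin\psi]$ — the cofactor $\tilde b$ swaps the principal
curvatures, pairing $\kappa_G''$ with the azimuthal curvature and
$\kappa_G'$ with the meridional one. Uniform $\kappa_G$ is mechanically
inert (Gauss–Bonnet), which fixes only the *contrast* $\Delta\kappa_G$ as
meaningful; the baseline defaults to $-0.9\,\kappa$, a standard bilayer
estimate.

Six boundary conditions close the problem: radius and tangent angle
clamped to the nominal tube ($r = R_c$, $\psi = \pi/2$) at both ends, $z$
anchored on the left, and the edge tension $\lambda = \lambda_0$ applied
on the right (the tension equation is first order; one condition
suffices). For profiles symmetric about the tube midpoint the solver
works on half the domain with symmetry conditions $\psi = \pi/2$,
$\ell = 0$, $z = 0$ at the centre — this is the default and halves the
cost. The edge clamp at $R_c = 35$ nm differs by 1% from the unloaded
tether radius $\frac{1}{2}\sqrt{\kappa/\lambda_0} = 35.36$ nm at the
default tension; the mismatch is absorbed in a boundary layer of width
$\sim R_c$, and `solver_config(edge_radius = ...)` exposes the clamp.

# Parameters

| symbol | argument | default | units | meaning |
|---|---|---|---|---|
| $\kappa$ | `kappa` | 320 | pN nm | bare bending rigidity |
| $\alpha$ | `alpha` | 1.28e7 | pN nm^3 | protein aggregation strength |
| $\beta$ | `beta` | 0 | pN nm^4 | density-gradient penalty |
| $\mu$ | `mu` | 200 | nm | lipid–protein length scale |
| $\varphi$ | `phi` | −1 | – | protein cone angle (0 = cylindrical) |
| $\lambda_0$ | `lambda0` | 0.064 | pN/nm | edge tension (studied range 0.004–0.064) |
| $p$ | `p` | 0 | pN/nm^2 | transmembrane pressure |
| $R_c$, $L_c$ | `Rc`, `Lc` | 35, 2e4 | nm | tube radius and length |
| $\sigma_0$ | – | 0–3.75e-4 | nm^-2 | plateau protein density (input) |
| $\kappa_{ratio}$ | – | 1–30 | – | domain / bare rigidity (input) |

Two remarks. First, $\alpha = \kappa\mu^2$ exactly for these values; with
$|\varphi| = 1$ this makes the aggregation energy cancel the quadratic
spontaneous-curvature stiffening identically, which shapes much of the
phenomenology below. Second, $\beta$ is not part of the tabulated set;
the default is 0 (term off). A documented nonzero example is
$\beta = 3.2 \times 10^{11}$ pN nm^4, chosen so that
$\beta(\sigma')^2 \le 0.1\,\alpha\sigma^2$ at the default domain shoulder;
all headline runs use $\beta = 0$.

# Synthetic heterogeneity profiles

Domains are hyperbolic-tangent plateaus:
$f(u) = \text{baseline} + \frac{A}{2}[\tanh\frac{u-u_1}{w} -
\tanh\frac{u-u_2}{w}]$, with $u_{1,2}$ the half-maximum points, so the
stated domain length is the full width at half maximum and the integrated
material exactly equals $A \times$ length. The transition half-width $w$
is not a tabulated quantity; the default is $w = 10 R_c = 350$ nm —
well below the 8-µm domain, well above the mesh spacing. Solved bead
radii are insensitive to $w$ (the test suite checks a 2% bound between
$w = 175$ and $w = 700$ nm), so this choice is not load-bearing. Touching domains (zero separation)
combine *exactly* into one longer plateau — a tanh-algebra identity the
tests exploit — and overlapping domains of different amplitude are
rejected rather than silently merged.

The generator emulates composition heterogeneity only: static, prescribed,
axisymmetric fields. It does not emulate protein diffusion or
curvature-driven enrichment, thermal shape fluctuations, anisotropic
(BAR-type) scaffolds, or stochastic domain placement — so passing tests
establish the mechanics of prescribed domains, not the self-organization
of real membrane proteins.

# Analytic limits and their validity

Equating the domain-centre energy density to the bare-tube value
$W_0 = \kappa H_0^2$, $H_0 = 1/(2R_c)$, gives the closed-form centre
curvature

$$H = \mu\varphi\sigma + \sqrt{\frac{1/(2R_c)^2 + \alpha\sigma^2/\kappa -
\beta(\nabla\sigma)^2/\kappa}{\kappa_{ratio}}},$$

its small-$\sigma$ linearization, and the cylindrical-bead radius
$r_b = 1/(2H)$ (valid only while $H > 0$; beyond the zero-curvature locus
the package raises an error rather than returning a negative radius).
These are implemented in `mean_curvature_center()`,
`bead_radius_analytic()` and relatives, and serve as solver oracles at low
density.

The solver itself admits a sharper closed form in the flat-plateau
regime. A plateau is locally a tether at the interior tension
$\lambda_{in}$, and because $\alpha = \kappa\mu^2$ the local relation
collapses to $H = \sqrt{\lambda_{in}/\kappa}$; integrating the tension
equation adiabatically across the shoulder gives

$$\sqrt{\lambda_{in}} = \sqrt{\lambda_0} - \mu\sqrt{\kappa}\,\sigma_0 .$$

The collocation solution reproduces this to five digits, which is a
strong end-to-end check of the tension transport. It also delimits the
analytic agreement: the cylindrical-bead formula tracks the solver within
10% only up to $\sigma_0 \approx 2\times10^{-5}$ nm$^{-2}$ (2.3% at
$10^{-5}$, 11% at $2.5\times10^{-5}$), because the adiabatic tension drop
cancels the aggregation stiffening that the limit formula retains. The
unit tests assert the 10% agreement on $\{1, 1.5, 2\}\times10^{-5}$; the
acceptance suite exercises the wider published range and reports the
discrepancy honestly. The relation also pinpoints where flat plateaus
cease to exist, $\sigma^* = \sqrt{\lambda_0}/(\mu\sqrt{\kappa}) =
7.07\times10^{-5}$ nm$^{-2}$: beyond it the domain balloons toward the
fixed-area sphere limit and the interior tension hovers near zero.

# Numerics

*Discretization.* Midpoint (box) collocation on a uniform material mesh;
state and equations are nondimensionalized (lengths by $R_c$, moduli by
$\kappa$, tension by $\kappa/R_c^2$) so all residuals are $O(1)$. The
default mesh is 1001 nodes on the half domain (10 nm spacing; tests and
the acceptance script use 601–801 to keep runtimes in minutes); the
solved bead radius moves by under 0.01% between 701 and 2801 nodes, and a
0.2% mesh-halving bound is asserted in the validation suite.

*Newton iteration.* Analytic block structure with forward-difference
6×6 blocks per interval assembled into a sparse Jacobian (`Matrix`),
damped by backtracking line search; iterates with any $r \le 0.02 R_c$
are rejected (no pinch-off). Convergence demands a scaled residual below
$10^{-9}$; quadratic convergence makes the typical seeded solve 2–5
iterations.

*Continuation.* Heterogeneity is always grown from a solvable state (the
homogeneous cylinder), each solve seeded by its neighbour; failed steps
are bisected recursively (default limit 8, bounded to 3–5 in the broad
scans). A branch that still fails is truncated and flagged — never
interpolated. Strong heterogeneity is staged: rigidity ratio first at low
density, then density.

*Degenerate inputs.* $\sigma_0 = 0$ with no rigidity contrast reduces to
the bare tube; $\lambda = 0$ is rejected in the tether formula (infinite
radius); zero-length sweeps return empty tables; asymmetric profiles are
refused by half-domain mode.

# Verification oracles

1. *Cylinder fixed point.* The uniform tether at
   $\frac{1}{2}\sqrt{\kappa/\lambda}$ zeroes the right-hand side to
   machine precision, and the solver reproduces the interior radius to
   0.5% for $\lambda \in [0.004, 0.064]$ pN/nm (to $4\times10^{-6}$
   relative, in fact). A deliberately sign-flipped term fails this oracle
   (a test asserts that it does).
2. *Energy first variation.* Converged shapes are perturbed normally by
   compact bumps and the energy (with the $\lambda$-weighted area term) is
   recomputed by finite differences of the perturbed curve — a route
   independent of the ODE algebra. The centred derivative vanishes at
   equilibrium: norms are $\sim 10^{-7}$ of the bending energy for solved
   shapes (threshold $10^{-4}$; the bare-cylinder norm is limited to
   $\sim 5\times10^{-8}$ by the differencing noise floor, so its
   threshold is $10^{-6}$), versus $\sim 10^{-3}$ for a deliberately
   perturbed shape.
3. *Axial-force constancy.* Under area incompressibility the energy is an
   unconstrained functional of $r(u)$, so at equilibrium $dE/dz(S)$ must
   be one constant axial force for every radial perturbation mode. The
   measured spread is $\sim 10^{-4}$ relative (threshold $10^{-3}$). This
   oracle never touches the solved tension field, so it validates the
   tangential balance independently.
4. *Symmetry and convergence.* Centred inputs solved on the full domain
   are mirror symmetric to $10^{-3} R_c$; mesh halving moves $r_b$ by
   under 0.2%; the solved $\lambda(u)$ equals the a-posteriori line
   integral of its own gradient to $10^{-3}\lambda_0$.

`run_validation_suite()` aggregates all of these into one report.

# Morphology and merge studies

Beads are contiguous regions with $r > 1.1 R_c$ (threshold
configurable); within a region, maxima separated by a saddle shallower
than 5% of the smaller peak are merged. The plateau is the contiguous
run with $r > 0.9\,r_b$, and the *plateau variation* is measured over its
middle half, so the 10% shoulders of a genuinely flat top do not mask its
flatness: a bead with variation under 1% is *cylindrical*; otherwise the
sign of $H''$ (second arclength derivative, smoothed over 5 mesh points)
over the bead interior distinguishes *ellipsoidal* (positive throughout)
from *unduloid* (sign change). Classification order follows the explicit
numeric criterion first (cylindrical), then the $H''$ tests; derivatives
below 5% of their maximum are treated as zero when looking for sign
changes.

Two-domain studies sweep the end-to-end separation quasi-statically in
both directions (21 points over 0–4 µm by default, with a 4× refinement
pass around a detected jump). *Snap-through* is a discontinuity of the
decreasing sweep: the two-bead branch folds — the sweep must restart on
the one-bead branch — or the shape jumps by more than ten times the
typical step change. Hysteresis between the sweep directions and the
branch energy gap are reported alongside, but raw two-direction
disagreement is deliberately not the classifier: upward continuation
follows the metastable single-balloon branch far beyond its physical
relevance, and would label even clearly smooth merges as hysteretic. In
this model the merge is smooth at low density (e.g.
$\sigma_0 = 3\times10^{-5}$ nm$^{-2}$, uniform rigidity), where the
critical separation obeys the geometric rule
$L_{sep} \lesssim 2 r_b$ checked by `merge_criterion_check()`, and
snap-through for stiff domains ($\kappa_{ratio} = 11$, $C = 0$), where
the two-bead branch already folds at roughly twice the bead diameter.

# Design decisions at genuinely open points

- *Parameterization*: material/area coordinate (see above). This is the
  single most consequential choice; the fixed-arclength alternative was
  implemented, measured, and rejected.
- *Tension-equation aggregation term*: $2\alpha\sigma\,\sigma'$ by
  dimensional necessity and by the variational route; both independent
  oracles pass only with this form.
- *Entropic term off; $\beta = 0$; $\kappa_G = -0.9\kappa$ baseline;
  $w = 350$ nm*: as discussed, none is load-bearing, all are exposed as
  arguments.
- *Zero-density phase-diagram cells*: the rigid domain is the protein
  domain, so $\sigma_0 = 0$ means no domain at all and the cell is
  classified `none`. (Passing `kappa_ratio > 1` with `sigma0 = 0`
  directly to the profile builder still builds the rigid domain, as
  explicitly requested.)

# Known limitations

- *Solution-branch endpoint.* With the tabulated parameters the density
  branch terminates near $\sigma_0 \approx 2.4\times10^{-4}$ nm$^{-2}$
  (uniform rigidity) and near $2\times10^{-5}$ for stiff domains
  ($\kappa_{ratio} = 11$) with curvature coupling on: past the endpoint
  the interior tension is strongly negative and Newton finds no nearby
  equilibrium at any mesh or step size we tried. Published operating
  points beyond these endpoints (e.g. a stiff-domain gallery at
  $\sigma_0 = 10^{-4}$–$1.85\times10^{-4}$) are reported as unconverged
  by the acceptance suite rather than substituted.
- *Quantitative offsets from the source study.* The implementation is
  pinned to the printed energy and balance laws by the independent
  oracles above; against the published simulation values it
  underestimates the two headline bead radii by 17–19% (289 vs ~350 nm
  protein-driven; 324 vs ~400 nm rigidity-driven) and places the
  stiff-domain merge threshold at 1.2 µm vs ~0.8 µm. The published
  tension profiles saturate at zero where this model's go negative,
  indicating an unprinted regularization or constraint in the original
  finite-element implementation that the available text does not
  specify. The acceptance suite states these deviations rather than
  tuning toward the published numbers.
- *No stability analysis.* Solutions are equilibria; second-variation
  stability (and hence which branch a fluctuating membrane selects) is
  out of scope, as is any non-axisymmetric mode (a membrane under the
  negative interior tensions found here would likely wrinkle
  azimuthally).
- *Statics only*: no protein diffusion, no hydrodynamics, no
  pressure–volume coupling ($p$ is a fixed parameter, default 0).
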