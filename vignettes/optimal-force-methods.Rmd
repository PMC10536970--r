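---
title: "Optimal mechanical forces on an electronic energy gap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal mechanical forces on an electronic energy gap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgmf)
```

## The problem

A mechanical force applied to a molecule relaxes its structure on the
electronic state the force acts on (here always the initial state, "0"):
at the new equilibrium the internal and external forces cancel, so the
relaxed geometry $q$ satisfies $\nabla E_0(q) = F_{\mathrm{ext}}$. Because
the geometry moves, the energy gap to a second state,
$\Delta E(q) = E_1(q) - E_0(q)$, shifts with it — this is how stretching a
mechanophore tunes its excitation or emission energy. Among all forces of
a given magnitude there is (generically) one that shifts the gap most in
each direction. This package computes those optimal forces and the
structures they select, as a function of force magnitude, in two ways:

1. **Closed form on quadratic surfaces.** If both states are exact
   second-order expansions around the state-0 minimum, maximizing
   $\Delta\Delta E(q)$ subject to $\|F_{\mathrm{ext}}\|^2 =
   q^\top H_0^2 q = C$ by a Lagrange multiplier $\lambda$ gives a shifted
   linear system in $\lambda$; scanning $\lambda$ (`lambda_scan()`) or
   inverting the $\lambda\!\to\!\|F\|$ map by a secular equation
   (`quadratic_optimum_at_force()`) traces the whole family.
2. **Iteratively on arbitrary surfaces** (`run_ramp()`). A
   predictor/corrector continuation grows each branch in fixed increments
   of the force magnitude, using only local second-order expansions plus
   exact gradient verification, so anharmonicity is handled exactly up to
   the convergence thresholds.

The optimality certificate in both routes is the *parallelism condition*:
at a constrained optimum the gap gradient $\nabla\Delta E$ is parallel
(or antiparallel) to the constraint normal $\nabla\|F_{\mathrm{ext}}\|^2
= 2 H_0 \nabla E_0$, so the cosine $\alpha$ of their angle satisfies
$|\cos\alpha| = 1$. Every quantity the package reports is checked against
this condition with *exact* gradients, never only against the local
model.

## Sign convention of the optimality system

Two sign bookkeepings of the multiplier/curvature appear for the linear
system $(2\lambda H_0^2 \mp (H_1 - H_0))\,\Delta q = g_1$, and they are
not equivalent in more than one dimension. `optimal_structure()` solves
the form with $+H_1 - H_0$ first, then evaluates the parallelism cosine
at the solution; if the condition fails (the generic multi-dimensional
situation) it solves the variant obtained from direct stationarity of
$\nabla\Delta E = \lambda\,\nabla\|F\|^2$, keeps whichever validates, and
records the convention in the solution's metadata. The parallelism check
is convention-independent ground truth, so the choice can never silently
corrupt a result. In one dimension both forms validate (any two nonzero
scalars are parallel) and the first form is kept.

`nosym_eigenvalues()` reports the multipliers at which the
non-totally-symmetric block system becomes singular, i.e. the eigenvalues
of $\tfrac12 H_0^{-2}(H_0 - H_1)$ restricted to the block, solved as a
symmetric generalized eigenproblem. At such a multiplier the block admits
infinitely many optimal distortions along the matching eigenvectors;
`symmetry_split_solve()` reports those directions instead of fabricating
a particular solution.

## The iterative engine

Each branch starts at an optimized point of state 0 (usually the
minimum) and repeats:

* **Predictor.** Displace along the previous displacement (first point:
  along $\pm\nabla\Delta E$), scaled so the *model* force magnitude grows
  by exactly the configured `force_step`. The scale is the positive root
  of a scalar quadratic, solved in closed form with safeguards.
* **Corrector.** On the local model, decompose $\nabla\Delta E$ into
  components parallel and perpendicular to $\nabla\|F\|^2$ and drive the
  perpendicular part to zero while staying on the constant-force level
  set. The implementation is two-phase:
  * a global phase stepping along $\nabla\Delta E^\perp$ (toward larger
    gap on the increasing branch, smaller on the decreasing branch) with
    the step scaled by the inverse curvature of the Lagrangian along that
    direction, an Armijo backtracking acceptance on the model gap, and
    the adaptive proportionality constant: halved when a trial is
    rejected or the perpendicular norm grows, doubled (capped at its
    initial value) after three consecutive decreases;
  * once $|\cos\alpha| \ge 0.99$, a tangent-space Newton polish (a
    bordered KKT solve) accepted only when it reduces
    $\|\nabla\Delta E^\perp\|$, which converges quadratically to machine
    precision.
  A plain first-order corrector stopped at $|\cos\alpha| = 0.999$ leaves
  gap errors around $10^{-3}$ Hartree-scale on our fixtures; the polish
  phase is what lets validation runs certify agreement with the closed
  form at $10^{-6}$ and below.
* **Retraction.** After each corrector move the displacement is pulled
  back onto the constant-force level set of the model: first by a
  one-dimensional quadratic solve along the constraint normal, and — when
  that line does not intersect the level set, as can happen right after a
  re-expansion — by an exact rescale along $H_0^{-1}\nabla E_0$, which
  reaches any magnitude.
* **Verification.** The converged candidate is re-evaluated with exact
  gradients (and Hessians per `hessian_policy`) and the parallelism
  condition is checked there. On failure, or when the achieved force
  deviates from the scheduled one by more than `force_budget` (default
  the 5% rule), the expansion is refreshed at the candidate and the
  corrector resumes — this is what makes the converged points exact on
  anharmonic surfaces rather than model-optimal only.
* **Continuation.** On persistent non-convergence the force increment is
  halved (twice at most) before the branch is truncated with a recorded
  termination reason.

Points are emitted only when verified and within budget, so the ramp
invariants — exact-gradient certificate, 5% force control, strictly
increasing magnitudes — hold by construction.

### Hessian policy

`"exact-every-point"` re-evaluates both Hessians at each accepted point.
`"bfgs"` starts from exact Hessians at the ramp origin and applies the
rank-two secant update per state from consecutive gradient differences,
falling back to an exact evaluation whenever the curvature condition
$\Delta q^\top y > 0$ fails (the skip is logged). Both states are treated
symmetrically. On quadratic surfaces the update is a fixed point of the
true Hessian, so the two policies coincide there; on general surfaces the
BFGS policy trades Hessian cost for a slightly weaker certificate, since
$\nabla\|F\|^2 = 2H_0\nabla E_0$ uses the updated $H_0$.

### Choice of the first direction and branch identity

The first increment is seeded with $\pm\nabla\Delta E$; afterwards each
point continues along the previous displacement. If the gap gradient
vanishes at the start (a symmetry-degenerate situation), the engine seeds
with the extreme eigenvector of the local multiplier pencil instead. The
corrector is a local method: the first increment selects the continuation
branch, and the engine deliberately performs no global search over
disconnected families. With the default small `force_step` the first
landing lies in the basin of the global constrained optimum (the gap is
dominated by its linear term on a small level set, which has a single
maximum/minimum pair); our quadratic validation shows the continuation
then tracks the globally optimal family over the whole 2 nN range on all
seeded fixtures. Note one labeling subtlety: `run_ramp()` names branches
by their continuation direction, while `lambda_scan()` partitions by the
sign of the gap variation; on surfaces where the maximizing family's gap
variation changes sign at large force the two labelings can differ.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `force_step` | 0.05 | nN | increment of the applied force magnitude between optimized points; the control parameter. Tens to hundreds of pN keeps the local model valid between points. |
| `force_max` | 2 | nN | ramp ceiling; the range over which rigid molecules are typically scanned. |
| `cos_tolerance` | 0.999 | — | convergence threshold on the parallelism cosine. The practical band is 0.99–0.999; validation runs in this package use $1 - 10^{-10}$ so oracle comparisons measure the algorithm, not its stopping rule. |
| `force_budget` | 0.05 | relative | permitted deviation of achieved from scheduled magnitude (the 5% rule); violations trigger recalibration from the updated expansion. |
| `corrector_constant` | 1.0 | — | initial proportionality constant of the corrector displacement. |
| `corrector_max_iter` | 200 | — | corrector iteration cap per attempt. |
| `hessian_policy` | exact-every-point | — | see above. |

Internally everything is Hartree/Bohr atomic units; files store Å and nN
and all conversion goes through one CODATA-derived constants table
(`unit_convert()`, `unit_table()`), never hard-coded factors.

## What the synthetic fixtures emulate

`make_quadratic_pair()` builds random two-state quadratic pairs by
spectral synthesis: a Haar-random orthogonal eigenbasis with eigenvalues
drawn uniformly from a prescribed range, so conditioning is controlled.
The defaults mimic molecular scales — state-0 force constants in
0.2–1.5 Hartree/Bohr², a state-1 gradient of norm 0.1 Hartree/Bohr, and a
vertical gap of 0.223 Hartree (≈140 kcal/mol, a typical bright
excitation). `make_model2d_pair()` is a two-dimensional anharmonic pair
with one soft (0.05 Hartree/Bohr²) and one stiff (1.0) direction, quartic
hardening and a cubic soft–stiff coupling on the ground state: the regime
where a single second-order prediction from the minimum degrades quickly
with force along the soft mode. `make_morse_pair()` adds realistic
softening-at-extension. Identical seeds give bit-identical fixtures, and
the generator restores the caller's RNG state.

What these fixtures do *not* model: real electronic structure (surfaces
here are cheap closed forms, not TD-DFT), conical intersections or state
crossings, coordinate redundancy/mass weighting, and the "isometric"
constraint variants of pulling experiments. Passing tests therefore
demonstrate the correctness of the optimization machinery on controlled
surfaces, not the chemistry of any particular molecule; applying the
engine to a real system requires a backend adapter
(`backend_surface()`) supplying gradients (and optionally Hessians) from
a quantum-chemistry code.

## Numerical choices

* **Singularity handling.** A multiplier is "at" the pencil spectrum when
  the solve's smallest singular value is below $10^{-8}$ times the
  largest; such solutions are flagged, and `lambda_scan()` drops them
  with a message rather than extrapolating through the pole.
* **Degenerate certificate.** At zero force (the unforced minimum)
  $\nabla\|F\|^2 = 0$ and the parallelism cosine is undefined; the start
  point is recorded with $\cos\alpha = 1$ by convention and a vanishing
  gap variation.
* **Brute-force oracle.** For ≤2 degrees of freedom,
  `brute_force_optimum()` parameterizes the force level set radially
  from the minimum (dense fan of directions, exact radial root per
  direction) and polishes the best direction with a golden-section
  refinement, giving oracle accuracy far below the tolerances it is used
  to check. It deliberately does not scale beyond 2 dof; the closed-form
  solver plays the oracle in higher dimension.
* **Secular equation.** `quadratic_optimum_at_force()` works in the
  eigenbasis of $H_0^{-1}(H_1 - H_0)H_0^{-1}$, brackets the outer-interval
  root of the force equation monotonically, and handles the hard case
  (no gap-gradient component along the extreme eigenvector) by filling
  the force budget along that eigenvector, as in trust-region practice.
* **Finite differences.** The backend Hessian fallback uses central
  differences with a 10⁻³ Bohr step, symmetrized; exact on quadratics,
  second-order convergent elsewhere.

## Validation summary

The test suite ties every claim to an independent oracle: hand-derived
scalar cases; brute-force dense search on 1D/2D pairs; the closed-form
solver against the iterative engine on twenty seeded quadratic pairs of
4–30 degrees of freedom ramped to 2 nN (pointwise agreement at 10⁻⁶
Hartree or better); the parallelism certificate and the 5% force budget
re-derived from exact gradients at every emitted point; the small-force
slope against $\|H_0^{-1}g_1\|$; BFGS-policy ramps against exact-Hessian
ramps; and, on the soft-mode fixture, the engine against dense search at
matched force magnitudes together with its strict advantage over the
single second-order prediction evaluated on the true surfaces. Problem
sizes were chosen so the full suite and the acceptance script each run in
well under a minute of compute on one core while still covering the
dimension range of interest. `scripts/acceptance.R` recomputes all of
these quantities from scratch against the installed package.

## Known limitations

* The engine follows continuation branches; it will not discover a
  disconnected family that becomes optimal only at large force.
* Coordinates are plain Cartesians. Mode mixing between soft and stiff
  directions is handled exactly on the model surfaces, but no
  mass-weighting or internal-coordinate transformation is offered.
* The symmetry split relies on a user-supplied symmetry-adapted basis;
  point groups are not detected.
* Force-pair decomposition quantifies (via its residual) but cannot
  overcome the fact that a prescribed optimal force may be poorly
  representable by few experimentally realizable pairs; how many pairs
  suffice is system dependent, and no truncation default is asserted.
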