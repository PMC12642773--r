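---
title: "Decomposing viability regions: models, manifolds, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing viability regions: models, manifolds, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viadeco)
```

## The model

`viadeco` analyses autonomous ODE cell models $\dot x = f(x)$ together with a
*viability region* $V$: the set of states in which the modelled cell counts as
alive. $V$ is the intersection of constraints, each either a bound on one
essential variable (a box facet) or a smooth scalar condition $g(x) \le 0$.
Death is deterministic and instantaneous: a trajectory dies at its first
transversal crossing of $\partial V$.

Two conventions matter and are fixed package-wide:

- **Closed region.** Boundary states are members of $V$ — the boundary is the
  last living set, and death occurs at the first *crossing*, not on contact.
  The reference treatment leaves this open for continuous systems; we adopt
  the closed convention because it makes tangency points (which never cross)
  well-defined members and matches the discrete case, where a configuration
  on the boundary is still the individual and only its *transition* is
  terminal.
- **Undecided is a first-class outcome.** A state whose trajectory neither
  exits $V$ nor converges to a viable attractor within the horizon is
  labelled `undecided`, never silently asymptotic. Slow transients therefore
  cannot masquerade as survival; they can only cost horizon budget.

A state in $V$ is *asymptotically viable* if its forward trajectory stays in
$V$ and converges to an attractor inside $V$, and *transiently viable* if it
exits in finite time. `classify_state()` decides this by event-detecting
integration and is deliberately the dumbest possible oracle: every geometric
claim the package makes is ultimately validated against it.

## The organizing manifolds

On a smooth stretch of facet, the normal flow $f(x)\cdot n(x)$ (outward unit
normal $n$) can only change sign — from immediately fatal to inward — through
a zero: a **tangency point**. If the forward fate of a tangency is
asymptotically viable, it is a *mortality point* and its backward-time
trajectory is a **mortality manifold**: states on one side can still reach
the attractor, states on the other die first. If the forward fate is
transient the tangency organizes nothing; it is retained but flagged
non-organizing, and `mortality_manifold()` refuses it with a
`not_a_mortality_point` error.

Where two facets meet with strictly positive outward flow through both, the
corner is **joint-fatal**: a trajectory through it violates both constraints
simultaneously. Its backward trajectory is an **ordering manifold**; on
either side, one or the other constraint is violated first. Strictness is
deliberate — a zero normal component makes the corner a degenerate
(measure-zero) case, which is reported in a separate `marginal` list rather
than seeded.

In a multicellular system, death events delete the dying cells' variables and
the survivors continue under their own registered dynamics. Any structure
that organizes the reduced space — here, an unstable equilibrium separating a
survivor's viable and terminal attractors — has a pre-image on the dying
cell's death facet (under the default projection collapse rule, simply the
facet slice whose surviving coordinates equal the target). Integrating that
**collapse point** backward in the pre-death space yields a **collapse
manifold** separating pre-death states by post-death fate. We implement
unstable-equilibrium targets; arbitrary separatrix points can be supplied as
registered states, but no continuation along whole separatrices is attempted.

**Verification, not faith.** `verify_separation()` is the package's defining
test: it samples the polyline arc-length-uniformly (seeded), places probe
pairs at $\pm b$ along local normals, classifies both probes by brute-force
simulation, and reports the fraction of pairs whose outcomes are distinct and
match the manifold's declared sides. Probes outside $V$ or within $b$ of
$\partial V$ are skipped (their classification is dominated by the boundary,
not the manifold). A correct manifold scores 1.0; a straight chord through
the same region scores well below it and returns counterexamples.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `rtol` / `atol` | `1e-8` / `1e-10` | relative / state | backward integration amplifies drift; manifolds inherit integrator error |
| classification `horizon` | 50 | time | long enough for fixture transients; undecided beyond it |
| `conv_tol` | `1e-2` | state distance | attractor-convergence radius; crossing it ends classification early |
| `tie_tol` | `1e-9` | time | constraint crossings within this window form one joint death |
| `backward_horizon` | 100 | time | manifold growth cap when the region is bounded |
| scan resolution | 200 | points/facet | tangency bracketing density; doubling it finds nothing new on fixtures |
| probe `band` | `1e-2` | state distance | about 1% of fixture region diameters; probes nearer the boundary are skipped |
| equilibrium merge radius | `1e-6` | state distance | multistart duplicates collapse |
| finite-difference step | `1e-6 max(1, ‖x‖)` | state | scale-aware Jacobian fallback |

Backward integration is implemented by negating the right-hand side rather
than passing negative time spans, so one integrator contract covers both
directions. Manifold seeds sit exactly on $\partial V$, where the event root
function is zero at $t=0$; the integration start is therefore nudged
$10^{-9}$ along the inward normal (and $10^{-7}$ for tangency forward-fate
classification, where the flow is additionally tangent). The recorded
polyline still begins at the exact seed.

Two-cell fixture regions are bounded below only, so backward trajectories
from the corner never exit them; ordering and collapse manifolds there use a
finite `backward_horizon` (6 time units in the tests and the acceptance
script), which already carries the manifolds far outside the state range any
probe classification visits. This is a property of the fixture geometry, not
a tolerance.

## The fixture systems

The package's reference schematics come with no equations, so the fixtures
module supplies concrete, closed-form-verifiable instantiations; they are the
study conditions for every test.

- **Scenario A** — $\dot x = -(x - c)$, $c = (0.5, 0.5)$, box $[0,1]^2$. All
  boundary flow inward; every interior state asymptotically viable.
- **Scenario B** — same field with $c = (1.5, 0.5)$: the attractor is outside
  $V$, every state dies through the $x_1$ upper facet; from the center at
  exactly $t = \ln 2$ (closed form of the linear flow).
- **Scenario C** — spiral $\lambda = -0.1$, $\omega = 1$ about the origin in
  $[-1,1] \times [-1, 0.5]$. The normal flow on the upper facet is
  $\omega x_1 + \lambda x_2$, giving one tangency at $x_1 = 0.05$ — the mixed
  regime with a mortality manifold.
- **Two-cell fixture** — blue and purple, one essential variable each with
  lower bounds $b_{\min} = 0.1$, $p_{\min} = 0.05$. Joint dynamics
  $\dot x = A(x - c)$ with $A = \begin{pmatrix}-1 & -0.2\\ -0.2 & -1\end{pmatrix}$,
  $c = (-0.1, -0.1)$: a stable node below both thresholds, so both variables
  are driven down, coupled, and which cell dies first depends on the initial
  condition. Reduced one-cell dynamics are the bistable cubic
  $\dot v = -v(v - a)(v - 1)$, $a = 0.4$: viable attractor at 1, terminal
  attractor at 0 below the bound, unstable point $a$ — so the collapse point
  on purple's facet is $(a, p_{\min}) = (0.4, 0.05)$. The coupling strength
  and node location are this package's choice (the schematics fix none);
  they were picked once for closed-form verifiability — a linear field whose
  corner flow components, $(-0.23, -0.19)$, are checkable by hand.
- **Glider fixtures** — the standard glider (one chirality, heading
  down-right), block, blinker, and a glider-meets-block scene.

What the fixtures emulate: the qualitative geometry of the reference
regimes — inward boundaries, external attractors, tangencies, joint-fatal
corners, bistable survivors. What they do not emulate: high-dimensional state
spaces, non-box constraint geometry beyond a smoke-tested disc, stiff or
oscillatory biochemical kinetics, stochastic death hazards. Passing tests
demonstrate the decomposition machinery is correct on systems where ground
truth is analytic; they do not certify accuracy on an arbitrary user model,
where integrator tolerances and the finite classification horizon do real
work.

## The intrinsic case: the glider

The Game-of-Life engine uses the standard birth-on-3 / survive-on-2-or-3
synchronous update on a bounded window with quiescent exterior, auto-growing
by 8 cells per side (capped at 512) when live cells approach the edge. The
glider's identity is an exact phase-pattern match up to translation within
one chirality/heading set, *including* an all-off one-cell membrane — the
off-cell layer is part of the individual. Re-identification across rotations
or reflections is off by default: the glider is a single individual, and
treating its mirror image as "the same" is a modelling choice we do not make
for it.

A configuration is classified by simulation with identity checks at period-4
boundaries (default horizon 64 steps, 16 checks): `interior` if the identity
holds at every check, `boundary` if it is lost and never regained (the first
failing step is recorded), `nonmember` if no glider is present at $t = 0$.
Identity lost and later regained counts as interior with a `recovered` flag —
only a *terminal* transition puts a state on the boundary. One consequence,
adopted deliberately: a glider with an on-cell deleted is a nonmember, not a
boundary state, because the individual is already absent at $t = 0$; boundary
states are intact gliders whose next transitions destroy them.

How much environment belongs to a "glider-environment configuration" is not
fixed anywhere; the perturbation window is therefore a parameter, reported
with every partition. The default window is a 3×3 rectangle ahead of the
glider's heading and flush with its membrane — the nearest region where
single flipped cells interact with the glider's update before they decay
(an isolated live cell two or more cells away simply vanishes in one step,
making remote single-flip perturbations trivially interior).

## Numerical choices and degenerate inputs

- Integration uses `deSolve::lsodar` (adaptive, with built-in root finding);
  constraint crossings are solver-refined roots of the signed constraint
  values, not interpolated afterwards.
- `first_violation()` on stored trajectories brackets sign changes on the
  dense output and refines by `uniroot` on linear interpolants — accurate to
  the output spacing squared, sufficient for its `1e-4` contract.
- Equilibrium search is damped Newton from a seeded Halton multistart.
  Multistart search is documented as incomplete: the returned list contains
  only genuine roots but may miss some. Classification ties at zero real part
  are labelled `center` and flagged degenerate.
- A backward trajectory that converges to an interior equilibrium
  ($\|f\| < 10^{-12}$) stops and flags the manifold
  (`converged_to_interior_equilibrium`); one that exits immediately yields a
  zero-length manifold flagged `degenerate`.
- Simultaneity of deaths is decided in time (`tie_tol`), not space: every
  constraint whose crossing falls within `tie_tol` of the first joins the
  dying subset. At $t = 0$, cells already outside their regions die in an
  immediate event rather than raising an error, keeping batch sweeps total.
- Triple-constraint corners are detected but never seeded (measure-zero).
- Grid classification skips lattice points within $10^{-9}$ of the boundary
  to avoid event-at-start ambiguity.

## Problem sizes

The test suite and acceptance script run 20×20 classification grids
(400 event-detecting integrations per regime), 100 probe pairs per manifold
(each probe one full classification or hybrid simulation), a 50-trajectory
hybrid batch for the dimension-bookkeeping check, 50 random 32×32 grids for
20 steps in the cellular-automaton cross-validation, and 64-step horizons
for the 10-configuration single-flip partition. These sizes were chosen so
the full suite exercises every code path at fixture scale; all of them are
parameters, and nothing in the machinery is specific to these values.

## Known limitations

- Exact manifolds are 2-D only. Backward trajectories are the codimension-1
  separating objects only in the plane; in higher dimensions the package
  offers probe classification against brute-force simulation, not manifold
  globalization. Continuation methods for $(n-1)$-manifolds are out of scope.
- Where a backward trajectory should terminate is underdetermined in general;
  we halt at region exit, interior-equilibrium convergence, or the horizon,
  and record which.
- No stochastic dynamics, time-varying constraints, probabilistic death
  functions, birth/division events, or manifold bifurcation tracking.
- Post-death dynamics must be registered per alive subset; the package does
  not derive them from the full field, because in general they are not its
  restriction.
- The multistart equilibrium finder can miss roots; supply `attractors`
  explicitly when they are known.
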