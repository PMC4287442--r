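---
title: "Multi-scale polymerization modelling with polymersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale polymerization modelling with polymersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymersim)
```

## The model

Polymerization spans time scales from nanoseconds (a monomer diffusing
near the growing tip) to seconds (the emergence of the whole
macromolecule). `polymersim` treats the two ends of that range with the
model class that fits each best, and couples them:

* the **grammar level** is a parametric, open L-system
  `L = <A, omega, P>` whose string *is* the polymer: Structure symbols
  are placed monomers, Binding symbols are the rigid transforms between
  them, End symbols close branches, and Communication symbols
  `C(O, Type, t, r)` stand for processes in flight. A production rule
  `id: predecessor : condition -> successors : probability` fires only
  if its predecessor pattern matches (literal parameters equal, pattern
  variables bound), its condition holds under the bindings, and an
  independent uniform draw falls below its probability. All symbols of
  a generation are rewritten in parallel; the grammar is context-free.
* the **particle level** is an agent population. Each agent carries a
  position, an orientation quaternion, a drift velocity and a type.
  Per step each coordinate receives the Brownian increment
  `sqrt(2 D dt) * xi` with `xi ~ N(0,1)` (the Einstein relation, which
  makes the mean squared displacement `6 D t` testable), plus an
  attraction drift toward active binding sites. Orientations undergo
  rotational diffusion: a random-axis rotation with angle
  `N(0, sqrt(2 D_rot dt))`.
* the **steering level** is a set of piecewise-linear density schedules
  `d_a(t)`. Every step, each type's population is reconciled to
  `round(d_a(t) * V)` by uniform-random spawns or removals. This is
  what an experimenter turns to starve or flood the reaction.

The **communication system** connects the levels. After interpretation,
every unresolved Communication symbol yields a query
`Q(pos, ori, type, time, result)` anchored at the current interpreter
pose. The time-scale probability `P(dt)` is exactly 0 below a switching
threshold and rises monotonically toward 1; it gates resolution:

* `P = 0` (monomer-motion scale): the agent system resolves queries.
  An agent of the requested type that reaches the anchor within the
  positional and angular tolerances is consumed — removed from the
  population — and its type is written into the query result. At the
  next step the L-system sees the result and the growth rule extends
  the structure. This one-to-one exchange (one agent removed, one
  Structure symbol added) is the conservation contract across the
  bridge, and the suite asserts it over seeded runs.
* `P > 0` (process scale): the agent system is bypassed and the query
  resolves with probability `clamp(P(dt) * d_type(t) * a_type, 0, 1)`.
  Written as a formula,
  `P(dt) d_type(t) a_type + (1 - P(dt)) AS(t)`, the blend mixes a
  probability-like scalar with an event outcome; we realize it as a two-channel
  stochastic choice — the density channel fires with the clamped
  product, otherwise the agent outcome is adopted with weight
  `1 - P` — which preserves both limiting cases (`P = 0` reproduces the
  agent outcome exactly; large `P` gives density-driven Bernoulli
  growth) while keeping results inside the outcome alphabet.

One driver step therefore runs: (1) age processes by `dt`, write back
query results, derive, interpret; (2) reconcile densities; (3) resolve
queries through whichever channel `P(dt)` selects; advance the clock.
When the monomer scale is active but no query is live, the population
is *fast-forwarded* — positions redrawn uniformly in the box,
orientations uniformly on SO(3) — reflecting that between binding
events monomer motion has no frame-to-frame correlation.

## Geometry

The interpreter is a quaternion turtle. Reading left to right it places
each Structure symbol at its current pose and advances across each
Binding symbol by

```
pos' = pos + rotate(ori, Bin_pos)        ori' = ori (x) Bin_ori
```

with the Hamilton product, right-multiplication (local-frame
composition) and
renormalization after every composition. A binding with
`branch_start = TRUE` pushes the pose on a stack; the matching End
symbol pops it. An End symbol at zero depth is a plain chain
terminator — the grammar of an unbranched polymer ends its axis with
the same symbol that closes branches. Only the pose is restored at a
pop; interpreter-local annotations are not.

Branches place their closing End symbol *together with* the branch
(`b m g C(...) E`), so the string is well-formed at every generation
and monomers added later to the main chain are never captured inside an
open branch frame. Aging rules consequently *erase* stale process
symbols rather than emitting a second End.

Model units are arbitrary: one monomer diameter is about 1 length unit
(no physical nm calibration is attempted), times are in seconds.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `dt` | 0.01 | s | step length; also the time-scale selector |
| `domain` | 20×20×20 | model units | reflective simulation box |
| `t_max` | 5 | s | process lifetime limit; aging conditions `t > t_max` terminate processes the environment never completed |
| `D`, `D_rot` | 1, 1 | units²/s, rad²/s | translational / rotational diffusivity per type |
| `time_scale$threshold` | 0.1 | s | below it `P(dt)` is exactly 0 |
| `time_scale$midpoint`, `steepness` | 1, 5 | s, 1/s | logistic ramp of `P`, rescaled to be continuous (= 0) at the threshold |
| `attraction$radius` | 5 | units | capture radius around a binding site |
| `attraction$speed` | 5 | units/s | approach speed; covers the radius in ~100 default steps |
| `tol_pos` | 0.25 | units | positional binding tolerance (a quarter diameter) |
| `tol_ang` | 180 (driver), 30 (`try_bind`) | degrees | angular binding tolerance, see below |
| `a_type` | `1/density` | — | affinity; saturates the density channel at nominal density |
| `p_branch` | 0.05 | — | PARP branch probability; gives the characteristic 20–25 monomers per branch (`1/p`) |
| `sigma` | 0.1 | probability | bandwidth of the branching-uncertainty kernel |

Two of these deserve justification:

* **Angular tolerance.** `try_bind()` offers the full contract — type,
  position *and* orientation within `tol_ang` — with a 30° default.
  The driver, however, runs with `tol_ang = 180`: the placed monomer's
  orientation is dictated by the binding-site geometry at docking (the
  interpreter pose), not by the orientation the agent happened to
  arrive with, so orientation gating is a kinetic refinement rather
  than a structural one. With gating at 30° and free rotational
  diffusion, the expected wait for an orientation hit is thousands of
  steps per bind; illustrative runs would starve.
* **Affinity.** The dimensional semantics of `a_type` (and whether
  `d_type(t)` means density at the site or globally) are open; we use
  the global density and choose `a_type = 1/d_nominal` so that at the
  nominal density the process-scale channel saturates
  (`clamp(p·d·a) = p`): growth at the large time scale is then limited
  by `P(dt)` alone, and starving the density below nominal throttles
  it proportionally.

## The packaged scenarios

The scenarios are the package's study conditions, not adjustable
fixtures. Their scripts encode textbook descriptions of the four systems; every
probability, density and binding geometry without an established
literature value is a documented default chosen once to reproduce the
characteristic morphology:

* **cellulose** — growth rule plus expiry rule; binding `g` advances one
  unit along the chain axis and rotates 180° about it, the stated
  geometry of the beta-1,4 linkage. The measured inter-monomer
  rotation is therefore exactly 180°.
* **parp** — the branch decision is an independent Bernoulli draw per
  growth event: the branching rule (probability `p_branch`) precedes
  the growth rule (probability 1), so under first-wins resolution the
  branch rate among growth events is exactly `p_branch` and
  monomers-per-branch follows the geometric law with mean `1/p_branch`
  (the default 0.05 matches the 20–25 monomers per branch
  characteristic of poly-ADP-ribose).
* **microtubule** — one growth event attaches a whole dimer
  (`a v b h`). The lateral binding `h` is the constant screw transform
  `offset = (R(cos θ − 1), R sin θ, rise − 1)`, `rotation = θ` about
  the local axis, with `θ = 2π/13`, `R = 1/(2 sin(θ/2))` (13 dimer
  widths around the circumference) and `rise = 2/13` (one dimer height
  per turn). Repeating it winds the tube directly — no sheet folding is
  modelled — and the longitudinal columns are the 13 protofilaments.
* **showcase** — helical main branch (`p1`–`p3` grow and sprout side
  branches), side-branch growth (`p4`–`p6`), and a terminal star
  (`p7`–`p10`): when the main growth process ages out it is replaced by
  five branch-start bindings at azimuths `360°/5` apart, each carrying
  a linear branch whose subunits alternate cube/cylinder with period
  two (the star growth process swaps its requested type each
  rewrite). Star branch count defaults to 5.

What the scenarios emulate is the *logic* of assembly — stochastic
arrival, conditional growth, branching, steering. What they do not
emulate: atomistic monomer shapes (placeholder primitives replace
PDB-derived meshes), inter-agent collisions and crowding, hydrodynamics,
enzyme catalysis, rigid-body relaxation of the grown structure, and
context-sensitive rules. Tests passing on these scenarios show the
machinery is faithful to its model, not that the model is a quantitative
account of any real polymer system.

## Branching uncertainty

Every derivation records, for each growth event in which a
branch-decision rule competed, the uniform draw `u` and the threshold
`theta` in force. `annotate_uncertainty()` gives monomers that started
a branch the peak-normalized Gaussian kernel value
`exp(-(u - theta)^2 / (2 sigma^2))` — a draw exactly at the decision
boundary is maximally uncertain (1.0), a draw `5 sigma` away is below
`1e-4` — while monomers from plain growth events carry the branching
probability itself. The two annotations are the white-to-red and
white-to-blue channels of an uncertainty visualization.

## Numerical choices

* Quaternions are stored scalar-first, renormalized after every
  composition; unit-norm checks use a 1e-6 entry tolerance and the
  angular metric `2 acos(|<a, b>|)` is double-cover safe.
* Fractional density targets use `round()` (half-to-even), not a
  Poisson draw: reconciliation is then deterministic given the
  schedule, which makes the steering tests exact.
* Rule selection draws one uniform per matching rule; ties (several
  rules firing) resolve to the first in script order. This preserves
  the per-rule "happens at all" probability reading and is
  reproducible under a seed.
* Protofilament counting fits the tube axis by minimizing the variance
  of radial distances (Nelder–Mead seeded from the principal components
  and the coordinate axes — raw PCA alone tilts on short helices
  because azimuthal phase correlates with height), then single-links
  the azimuth angles with a 10° gap threshold, below the 27.7°
  inter-column spacing. Structures with maximal radial extent under a
  quarter diameter count as one column.
* Degenerate inputs: an empty successor list erases the symbol; an End
  at zero branch depth is a terminator; a zero-density type with
  infinite affinity resolves to zero growth (starvation wins); an empty
  agent population fast-forwards to itself.
* Walls are reflective (positions are folded back into the box), which
  keeps `d·V` interpretable as an in-box count.

## Reproducibility and problem sizes

A run is a pure function of (scenario, config, seed): logs, final
strings and exports are byte-identical across repeats. The shipped
tests exercise the documented study conditions at desk scale — 100-mer
cellulose chains, 44-dimer microtubules (3+ turns), 50-replicate PARP
ensembles pooling over 2000 growth events, 10⁴-agent diffusion checks —
sizes at which the statistical oracles (Einstein relation, binomial and
geometric laws, uniformity tests) have enough power at 3σ while a full
suite run stays in the minutes range.

## Known limitations

Only positional attraction is modelled during approach (no alignment
torque); whether the original system biases orientation is unstated.
The grammar is context-free, so neighbourhood-dependent sub-processes
cannot be expressed. One derivation is applied per step regardless of
`dt`, so very large steps under-count generations rather than batching
them. Third parties (enzymes) and reaction energetics are out of scope.
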