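# polymersim

A headless, scriptable simulator of polymer growth for molecular
illustration and in-silico experimentation. It fuses three models that
operate at different time scales:

1. **A parametric, open L-system** describes the large-scale growth
   grammar of the polymer. The alphabet is split into *Structure*
   symbols (monomers), *Binding* symbols (the rigid transform between
   two monomers, possibly opening a branch), *End* symbols (closing a
   branch) and *Communication* symbols `C(O, Type, t, r)` — an
   in-progress process `O` (grow, branch, ...) that requests an agent of
   type `Type`, has been pending for `t` seconds and awaits a result
   `r`. Production rules are `id: predecessor : condition -> successors
   : probability`; all symbols are rewritten in parallel each step.
2. **An agent-based system** moves individual monomers as Brownian
   particles (`Δx = sqrt(2 D Δt) ξ` per axis), biases them toward
   active binding sites, and binds them on arrival — the rule that
   consumed the monomer then extends the structure.
3. **A system of densities** steers the experiment: per-type target
   schedules `d_a(t)` are enforced every step by spawning/removing
   agents so that the population matches `round(d_a(t) · V)`.

The communication system bridges the scales. Each unresolved
communication symbol becomes a query `Q(pos, ori, type, time, result)`
anchored at the growing tip. A probability function `P(Δt)` — exactly 0
below a switching threshold, rising monotonically to 1 — decides which
channel resolves the query: below threshold the agent system does
(diffusion + binding), above it growth is drawn from the density channel
with probability `clamp(P(Δt) · d_type(t) · a_type, 0, 1)`.

A quaternion turtle interprets derived strings into placed 3-D geometry
(`pos' = pos + rotate(ori, Bin_pos)`, `ori' = ori ⊗ Bin_ori`), which can
be exported as CSV or Wavefront OBJ.

Four scenario bundles are packaged (see `inst/extdata/scenarios/`):

| scenario | structure |
|---|---|
| `cellulose` | unbranched D-glucose chain, each monomer flipped 180° |
| `parp` | branched poly-ADP-ribose; branch decision with probability `p_branch` |
| `microtubule` | 13-protofilament tube of alternating α/β tubulin dimers |
| `showcase` | helical main branch, side branches, terminal 5-branch star of alternating cube/cylinder subunits |

The packaged rule scripts encode textbook descriptions of these
polymers; probabilities, densities and binding geometries without an
established literature value are documented scenario defaults. Monomer geometry is placeholder
geometry (sphere/cube/cylinder), with one monomer diameter ≈ 1 model
unit.

## Worked example

Grow cellulose at the monomer time scale (Δt below the switching
threshold, so every monomer is diffused, attracted and bound
individually):

```r
library(polymersim)
sc <- build_cellulose()
res <- run(sc, config = list(dt = 0.01, steps = 400, seed = 2))
res
#> <simrun 'cellulose': 400 steps, t = 4 s, 3 monomers placed, 100 agents>
str(measure_structure(res$placements))
#> List of 5
#>  $ n_monomers       : int 3
#>  $ n_branches       : int 0
#>  $ main_chain_length: int 3
#>  $ branch_sizes     : int(0)
#>  $ n_columns        : int 1
```

In 4 simulated seconds three D-glucose agents found the growing tip and
were bound — each bind removed one agent, set the query result, and the
growth rule `p1` rewrote the communication symbol into `m g C(grow,
Dglucose, 0, EMPTY)`: one new monomer, one binding, one fresh process.
The density layer kept the free population at 100 agents
(`0.0125 × 20³`) throughout.

The same machinery at the process time scale (Δt = 5 s, density channel
saturated) assembles a microtubule deterministically:

```r
big <- run("microtubule", config = list(dt = 5, steps = 45, seed = 1))
big
#> <simrun 'microtubule': 45 steps, t = 225 s, 88 monomers placed, 100 agents>
measure_structure(big$placements)$n_columns
#> [1] 13
export_structure(big$placements, "microtubule.obj", "obj")
```

44 tubulin dimers (88 monomers) wind a helix of 13 dimers per turn whose
longitudinal columns are the 13 protofilaments.

There is also a thin command-line front end:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/polymersim.R", package="polymersim"))')" \
  run --scenario cellulose --steps 400 --dt 0.01 --seed 2 --out out/
```

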