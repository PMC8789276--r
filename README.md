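# divlab

Invasion analysis of reproductive division of labour in structured and
unstructured clonal groups.

## The problem

Why do some clonal groups of cells split into sterile **helpers** and
fertile **reproductives**? The classical answer requires an *accelerating*
return from individual specialisation. But in topologically constrained
groups — filaments, branching growths — division of labour can be favoured
even with diminishing returns. `divlab` is for theoreticians who want to
dissect *why*: it computes, for an explicit group topology and
viability–fecundity tradeoff, whether a division-of-labour mutant can invade
a uniformly cooperating resident, and through which of three distinct
routes.

## The model

A group of `n > 2` cells sits on a connected undirected graph. A cell
investing `z ∈ [0, 1]` in cooperation produces `H(z)` of a public good and
has fecundity `F(z)` (with `F' < 0`, `H' > 0`). It keeps a fraction `1 − λ`
of the good and shares the rest equally among its `d` direct neighbours, so
its viability (good absorbed) is

    V_i = (1 − λ) H(z_i) + λ Σ_{j ~ i} H(z_j) / d_j,

and group fitness is `W = Σ_i F(z_i) V_i`. The parametric family is
`F(z) = 1 − z`, `H(z) = z^α` (exponent `α > 1`: accelerating returns;
`α < 1`: diminishing). Because sharing conserves the good, the uniform
resident has `W = n F(z) H(z)` on every topology, with ES level
`z* = α / (1 + α)`.

A mutant assigns helpers `z_h` and reproductives `z_r < z_h` on an
*equitable* partition (every cell of a class has the same neighbour-class
counts), giving the two-variable fitness
`W(z_h, z_r) = n_h F(z_h) V_h + n_r F(z_r) V_r`. A second-order expansion at
`(z*, z*)` classifies invasion:

1. **Accelerating returns** — a positive diagonal of the 2×2 Hessian
   (`W^{z_h z_h} > 0` or `W^{z_r z_r} > 0`);
2. **Between-individual differences** — a nonzero gradient (`W^{z_h} ≠ 0`),
   which arises exactly when neighbour counts differ between cells;
3. **Reciprocal specialisation** — non-positive diagonals but
   `det < 0`: a saddle where simultaneous opposite shifts by the two
   classes pay synergistically.

For degree-regular groups the saddle condition has a spectral form
`λ μ > d`, where `μ` is the largest Laplacian eigenvalue — how easily the
group is bi-partitioned into cross-helping classes (maximal, `μ = 2d`, for
bipartite graphs such as the alternating filament). With uncoordinated
(random, per-cell Bernoulli) role assignment the expected mutant fitness
collapses to `n[(1 − λ) E[FH] + λ E[F] E[H]]` — no graph term survives, and
only accelerating returns (`α > 1`) can pay.

## Worked example

A six-cell periodic filament with alternating roles, linear returns
(`α = 1`), sharing λ = 0.6:

```r
library(divlab)
g     <- filament_graph(6)
cs    <- classify_partition(g, alternating_roles(g))
model <- power_tradeoff(1)

solve_uniform_ess(g, 0.6, model)
#> uniform_ess: z* = 0.5 (W* = 1.5)

classify_invasion(cs, 0.6, model)
#> invasion_report: z* = 0.5, INVADABLE (reciprocal_specialisation)
#>   gradient: (0, 0)
#>   hessian:  [-2.4, -3.6; -3.6, -2.4]  det = -7.2
#>   scenarios: reciprocal_specialisation
#>   benefit:  0.2 at (z_h, z_r) = (1, 0)

bipartition_measure(g)
#> spectral_summary: d = 2, mu = 4, invasion threshold lambda > 0.5
```

Reading: at the uniform ES level `z* = 1/2` each class feels no directional
selection (gradient zero) and unilateral shifts are disfavoured (negative
diagonals), but the cross term `−6λ = −3.6` dominates, so the Hessian is a
saddle — reciprocal specialisation invades. The best division of labour is
full specialisation `(z_h, z_r) = (1, 0)`, worth a 20% group-fitness gain
over uniform cooperation. The spectral summary confirms the filament's
threshold: `λ μ > d` ⟺ `λ > 1/2`, so λ = 0.6 is just inside the invadable
region. Removing coordination kills all of this:
`critical_alpha_random(g, lambda = 1)` returns `1.0` (to bisection
tolerance) — without positional information, division of labour needs
`α > 1` no matter the topology.

Phase diagrams over λ × α (the machine-readable analogue of the invadability
panels) come from `sweep_phase()` / `export_phase()`, or from the thin CLI in
`inst/scripts/dol.R`:

```sh
Rscript inst/scripts/dol.R sweep --structure filament --mode coordinated \
    --n 12 --lambda-grid 0.02:1:50 --alpha-grid 0.04:2:50 --out phase.csv
Rscript inst/scripts/dol.R classify --structure well-mixed --n 10 --lambda 0.95 --alpha 1
```

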