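---
title: "Invasion analysis of reproductive division of labour on group graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion analysis of reproductive division of labour on group graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divlab)
```

## The model

`divlab` asks when a clonal group of cells that all cooperate at the same
level can be invaded by a mutant strain that divides labour: `n_h` helpers
investing `z_h` in cooperation and `n_r = n - n_h` reproductives investing
`z_r < z_h`. Individual fitness is fecundity times viability. Fecundity
`F(z)` is a decreasing function of own cooperation; viability is the total
public good a cell absorbs. A cell producing `H(z)` of good keeps the
fraction `1 - lambda` and shares the fraction `lambda` (the *shareability*)
equally among its direct neighbours on the group graph:

$$V_i = (1-\lambda)H(z_i) + \lambda \sum_{j \sim i} H(z_j)/d_j,
\qquad W = \sum_i F(z_i)\,V_i .$$

Viability selection acts just before reproduction, so there is no feedback
from a cell's viability onto its capacity to produce the good. Two
structural identities do a lot of work and are enforced as tests:

* **conservation** — sharing redistributes but never creates or destroys
  good, $\sum_i V_i = \sum_i H(z_i)$ for every graph, every profile and
  every $\lambda \in [0,1]$;
* **uniform collapse** — hence a uniform profile has
  $W(z,\dots,z) = n F(z) H(z)$ regardless of topology and shareability, so
  the uniform evolutionarily stable level $z^*$ (the root of
  $\mathrm{d}[F H]/\mathrm{d}z$) is structure-free. For the parametric
  family $F = 1-z$, $H = z^\alpha$ it is $z^* = \alpha/(1+\alpha)$.

## Tunable parameters

| parameter | meaning | range | default / notes |
|---|---|---|---|
| `lambda` | shared fraction of the good (dimensionless) | `[0, 1]` | no default; `0` kept only for degenerate checks, `1` is an "others-only" good |
| `alpha`  | return exponent of `H(z) = z^alpha` | `> 0`, sweeps use `(0, 2]` | `1` = linear; `> 1` accelerating, `< 1` diminishing |
| `z` | cooperation level (dimensionless investment) | `[0, 1]` | `z = 1` admissible with `F(1) = 0` exact, so full specialisation is evaluable |
| `n`, `n_node` | group sizes | `n > 2` | sweep defaults: filament `n = 12`, branching `n_node = 4`, well-mixed `n = 10` |

General `F` and `H` can be supplied as functions; missing derivative
accessors fall back to central finite differences with step `1e-5`.

## Three routes to invasion

A second-order expansion of the two-class fitness
$W(z_h, z_r) = n_h F(z_h) V_h + n_r F(z_r) V_r$ at $(z^*, z^*)$ gives a
gradient and a symmetric 2x2 Hessian, assembled analytically by
`analytic_derivatives()` (the class viabilities are separable in
$H(z_h), H(z_r)$, so their cross-partials vanish). `classify_invasion()`
flags, with tolerance `1e-9`:

1. *accelerating returns* — some diagonal entry positive: a unilateral
   second-order gain for one class;
2. *between-individual differences* — nonzero gradient: a first-order gain,
   which for this sharing rule arises exactly when
   $\sum_{j\sim k} 1/d_j \ne 1$ for some cell, i.e. when neighbour counts
   vary (the branching structure's degree-2 edge cells vs degree-3 node
   cells);
3. *reciprocal specialisation* — non-positive diagonals but negative
   determinant: a saddle, the route open to degree-regular structured
   groups such as the alternating filament.

Flags are reported independently (they are terms of one expansion, not
exclusive regimes); the `scenario` field reports the first triggered one in
the order above. All inequalities are strict: a threshold case counts as
*not* invadable, since invasion needs a strictly positive fitness
difference. For partitions with no equitable two-class summary the
classification falls back to the full $n \times n$ per-cell Hessian, taking
roles from the sign pattern of its leading eigenvector.

One consequence worth stating because it is easy to get wrong: with no
sharing ($\lambda = 0$) the group fitness is separable,
$W = \sum_i F(z_i)H(z_i)$, and for the power family $(FH)''(z^*) < 0$ for
*every* $\alpha > 0$ — so uniform cooperation is stable at $\lambda = 0$
even under strongly accelerating returns. The accelerating-returns diagonal
on the filament is positive exactly when $(\alpha-1)/\alpha > 2(1-\lambda)$:
accelerating returns open the door only in combination with sharing. The
test suite asserts this corrected property.

## The spectral condition

For a $d$-regular graph with the linear model, the full per-cell Hessian at
the uniform point is $-2(1-\lambda)I - (2\lambda/d)A$. Its leading
eigenvalue is $2(\lambda\mu/d - 1)$ where $\mu = d - a_{\min}(A)$ is the
largest Laplacian eigenvalue, so instability is exactly
$\lambda\mu > d$. We adopt this as the definition of the
bi-partitionability measure $\mu$, because it is forced by consistency: it
reproduces the filament threshold $\lambda > 1/2$ ($\mu = 2d$ for bipartite
graphs) and the well-mixed threshold $\lambda > (n-1)/n$ ($\mu = n$,
$d = n-1$ for $K_n$), and it is derivable exactly from the $n$-variable
Hessian, an equivalence kept as a standing test against a brute-force
eigenvalue oracle on C5, C6, C12, the cube, the Petersen graph and complete
graphs. `sparse_condition()` evaluates the inequality on the
leading-eigenvalue scale with a `1e-10` strictness guard so that the
spectral and brute-force verdicts agree even at exact thresholds. Whether a
per-edge or otherwise normalised variant of $\mu$ might be preferred
elsewhere does not matter here: the two printed thresholds pin the
convention.

## Random (uncoordinated) specialisation

If the mutant cannot target roles by position, each cell becomes a helper
independently with probability `p` (a fixed-count variant, enumerating
assignments with exactly `n_h` helpers, is available for sensitivity).
Independence of a cell's fecundity from its neighbours' identities plus
conservation ($\sum_i \sum_{j\sim i} 1/d_j = n$) give the closed form

$$\mathbb{E}[W] = n\left[(1-\lambda)\,\mathbb{E}[FH] +
\lambda\,\mathbb{E}[F]\mathbb{E}[H]\right],$$

with expectations over the two-point role distribution. No graph quantity
survives: randomising roles erases every topological benefit. The closed
form is verified exactly against enumeration over all $2^n$ assignments
(`n <= 12` in tests) and against seeded Monte Carlo within three standard
errors.

`critical_alpha_random()` bisects the smallest $\alpha$ at which any
$(p, z_h, z_r)$ on a search grid ($p \in \{0.1,\dots,0.9\}$, 101 points per
$z$ axis, margin `1e-9`) beats the uniform-ES fitness. Two facts shape how
we report it:

* for $\alpha \le 1$ no strategy beats uniform cooperation at any
  shareability (for linear $H$,
  $\mathbb{E}[F]\mathbb{E}[H] = (1-m)m \le 1/4$ with $m = \mathbb{E}[z]$,
  and Jensen bounds the sub-linear case);
* at full sharing ($\lambda = 1$) the strategy $(p, z_h, z_r) =
  (1/2, 1, 0)$ has $\mathbb{E}[F]\mathbb{E}[H] = 1/4$ *independent of
  $\alpha$*, while the uniform-ES fitness
  $n\,\alpha^\alpha/(1+\alpha)^{1+\alpha}$ strictly decreases in $\alpha$ —
  so the critical exponent at $\lambda = 1$ is exactly 1.

For $\lambda < 1$ the per-shareability threshold lies strictly above 1
(about 1.12 at $\lambda = 0.9$; the privately kept fraction
$(1-\lambda)\mathbb{E}[FH]$ penalises spread strategies at first order while
the Jensen gain is only of order $\alpha - 1$). The boundary of the whole
invadable region over $(\lambda, \alpha)$ is therefore $\alpha = 1$,
attained at $\lambda = 1$, and that is the quantity the acceptance script
reports — evaluated independently on the filament, branching and well-mixed
structures, whose agreement is itself a check of the topology-independence
result.

## Numerical choices

* **ES solver** — bracketed sign-change search on `[1e-9, 1 - 1e-9]` (1001
  probe points) plus `uniroot` to tolerance `1e-10`; a probe landing
  exactly on the root (as at `z = 1/2` for `alpha = 1`) is returned
  directly; no sign change reports the better boundary with
  `boundary_flag` instead of an error; multiple sign changes warn and take
  the smallest root (none arise in the power family).
* **Benefit optimisation** — `optimal_specialisation()` maximises
  `W(z_h, z_r)` over the admissible square restricted to `z_h >= z_r`
  (without loss of generality) on a 201-point-per-axis grid, polished by
  box-constrained BFGS; the benefit `W_max / W(z*, z*) - 1` is floored at
  0. Whether a shading should use the global-optimum benefit or a
  fixed-mutation-size benefit is a genuinely open presentation choice; the
  global optimum is implemented and labelled as such.
* **Thresholds** — all scenario inequalities are strict with tolerance
  `1e-9`; phase diagrams therefore colour threshold points as
  non-invadable.
* **Branching realisation** — any graph whose cells alternate between two
  and three neighbours is the subdivision of a cubic multigraph on the node
  cells; we use a deterministic scaffold (three parallel links for
  `n_node = 2`, giving the minimal instance $K_{2,3}$; otherwise a
  circulant cycle plus antipodal matching) so construction is reproducible
  without randomness. Any other realisation with the same degree pattern
  has the identical equitable summary, so results do not depend on this
  choice.
* **Filament default** — periodic. An open chain's end cells have one
  neighbour, which injects between-individual differences and muddies the
  filament's role as the clean test of reciprocal specialisation; the open
  chain remains available via `periodic = FALSE`.
* **Two-step invasion** — a slightly deleterious single-trait mutant
  drifting to fixation and then destabilising the second trait requires the
  same saddle condition as the joint mutation; only the algebraic condition
  is implemented, not the drift dynamics.

## What the synthetic structures do and do not emulate

All inputs are synthetic: canonical graphs (cycle, subdivided cubic,
complete) or user edge lists, with the power tradeoff family. These capture
the *topological* content of the theory — degree heterogeneity,
bi-partitionability, sparsity — under clonality, exact equitable
partitions, deterministic payoffs and infinitesimal mutant analysis. They
do not emulate: demographic noise or finite-population drift, growth and
rearrangement of group topology over a life cycle, viability feedback on
production, micro-environmental heterogeneity, or partially coordinated
(noisy-cue) role allocation. Passing tests therefore validate the
mathematical claims about this model class, not predictions for any
particular organism.

## Problem sizes

Tests and the acceptance script run on small instances chosen to make every
check exact or cheaply exhaustive: filaments up to `n = 12`, branching
structures up to `n_node = 6`, complete graphs up to `n = 14` (the
brute-force Hessian oracle's cap), enumeration of role assignments up to
`2^12`, Monte Carlo at `1e5` replicates, and sweep grids up to 50 x 50.
Because the quantities checked (thresholds, closed forms, spectra) are
size-free or have known size dependence (`(n-1)/n` for the well-mixed
threshold), larger instances add cost, not information.

## Known limitations

* The equitable two-class reduction covers the structures of interest; for
  arbitrary graphs with non-equitable role partitions the fallback is the
  full per-cell Hessian, whose leading eigenvector proposes roles but whose
  scenario attribution is coarser (first-order vs curvature-driven only).
* `sparse_condition()` applies only to degree-regular graphs by design;
  non-regular graphs are routed to between-individual differences.
* The random-specialisation search certifies invasion by grid witness; a
  grid can only under-report the invadable region, which makes the
  "no invasion for `alpha <= 1`" results conservative in the right
  direction.
* Only two roles are modelled; castes beyond helper/reproductive, and any
  evolutionary dynamics beyond the local stability analysis (fixation
  probabilities, adaptive-dynamics trajectories), are out of scope.
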