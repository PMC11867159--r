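# neutraldiv

Neutral models of phylogenetic tree shape and the biodiversity measures
built on them, for people who study how much evolutionary history and how
many biological features an extinction event is expected to erase:
mathematical phylogeneticists, conservation researchers working with
phylogenetic diversity (PD) and evolutionary distinctiveness, and anyone
who needs exact reference values for the Yule–Harding distribution.

## What it implements

**Neutral tree models.** The Yule–Harding (YH) distribution on binary tree
shapes, `p(τ) = 2^(n−1−s(τ)) / Π_v n_τ(v)` (with `s(τ)` the number of
symmetry vertices and `n_τ(v)` the descendant-leaf count minus one), and
the induced distribution `p(τ)·2^(s(τ))/n!` on labelled trees — in exact
rational arithmetic; the uniform (PDA) model; discrete samplers for both;
exhaustive enumerators of shapes (Wedderburn–Etherington counts) and
labelled trees (`(2n−3)!!`); exact leaf-depth laws driven by unsigned
Stirling numbers of the first kind, `P(D_n = k) = 2^k c(n−1,k)/n!` for
reduced trees and `P(D_n′ = k) = c(n,k+1)/n!` for evolutionary trees, with
their common mean `Σ_{i=2}^n 1/i` and the Poisson(`ln n + γ − 1`) limit.

**Birth–death simulation.** Constant-rate (and neutrally time-varying)
birth–death realizations with complete, reduced and reduced-evolutionary
views, exact pruning bookkeeping, and the edge-length laws of Yule trees:
uniformly sampled pendant and interior edges are Exponential(2λ), the
total length `S_n` is Gamma(n−1, λ), the longest pendant edge approaches
`t/2` on reduced trees and `(1 − μ/λ)t/2` on complete trees, and the
rescaled shortest interior edge has limiting survival `1/(1+2x)`.

**Diversity under extinction.** Rooted PD with greedy (provably optimal)
subset maximization; the fair-proportion and equal-splits indices and the
Shapley value; the expected PD loss under (generalized) field-of-bullets
extinction `Σ_e ℓ_e Π_{x∈C(e)} ε_x / Σ_e ℓ_e`; the EDGE2-style indices
`ψ` and `ψ′ = ψ·ε_x`; the identity FP = E[ψ(ε)] under a uniform prior on
ε; and the closed-form limiting survival curve `φ_PD(s) = s ln(1/s)/(1−s)`
(Yule) with its birth–death generalization.

**Feature diversity.** FD from feature assignments; PD-as-FD and the
nestedness criterion deciding when FD is representable as PD (with tree
reconstruction); a stochastic gain/loss simulator (gain rate `r`, loss
rate `ν`); an exact expected-FD recursion; expected-feature edge lengths
`ℓ′`; the inequality comparing expected FD loss with its PD proxy; and the
quadrature-based curve `φ_FD(s)` with its `ν = 0` reduction to `φ_PD`,
`r`-independence, and monotone decrease in `ν`.

## A worked example

```r
library(neutraldiv)

tr <- harding_tree()            # the classic five-leaf example
shape_of(tr)
#> tree shape: n = 5, s = 3, encoding (((*,*),(*,*)),*)
format(yh_shape_probability(tr))
#> [1] "1/6"
format(yh_tree_probability(tr))
#> [1] "1/90"
```

One in six neutral five-leaf trees has this shape; with labels attached,
each of the 15 labelled trees of this shape occurs with probability 1/90.

```r
bd <- reduce_tree(simulate_bd(lambda = 1, n_leaves = 8,
                              condition = "fixed_n", seed = 42))
round(pd_index(bd, "fp"), 3)
#>    t1    t2    t3    t4    t5    t6    t7    t8
#> 0.869 0.510 0.534 0.534 0.432 0.270 0.247 0.247
max_pd_subset(bd, 3)
#> $leaves: "t1" "t2" "t3"   $value: 2.277113
expected_pd_loss(bd, 0.5)
#> [1] 0.3954  (39.5% of the tree's PD expected lost at eps = 0.5)

phi_pd(0.5)                 # large-tree limit of the surviving PD share
#> [1] 0.6931472             #   = ln 2: half the species keep 69% of PD
phi_fd(0.5, lambda = 1, mu = 0, nu = 0.5)
#> [1] 0.6471749             # feature loss (nu > 0) pulls the share down
```

The fair-proportion column sums to the total PD of the tree; the
comparison of the last two numbers is the package's core message —
measuring diversity by features that can be lost (`ν > 0`) always predicts
a larger proportional loss than PD does.

A thin command-line interface over the same functions ships in
`inst/cli/neutraldiv` (subcommands `yh-prob`, `depth-dist`, `simulate-bd`,
`pd`, `index`, `pd-loss`, `phi-pd`, `fd`, `simulate-features`, `prop5`,
`phi-fd`, `three-layer`).

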