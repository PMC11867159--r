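---
title: "Neutral tree models and the expected loss of phylogenetic and feature diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral tree models and the expected loss of phylogenetic and feature diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutraldiv)
```

## The models

This package implements the probability theory of neutral phylogenies and
the biodiversity measures built on them. Three layers recur throughout:

1. **A tree layer.** A constant-rate birth--death process starts from a
   single lineage at time 0; each extant lineage splits at rate $\lambda$
   and dies at rate $\mu$, with the lineage involved in an event chosen
   uniformly. The *complete* tree keeps all lineages; the *reduced*
   (reconstructed) tree drops lineages extinct before the sampling time and
   suppresses the resulting degree-one vertices; the *evolutionary* views
   additionally record, at every split, which daughter is the designated
   new species. Under any neutral model -- the rates may even depend on
   time or the current species count, as long as the per-lineage choice
   stays uniform -- the shape of the reduced tree with $n$ leaves follows
   the Yule--Harding (YH) distribution
   $p(\tau) = 2^{\,n-1-s(\tau)}/\prod_{v} n_\tau(v)$, which the package
   evaluates in exact rational arithmetic.

2. **A feature layer.** Discrete features arise along edges at rate $r$
   per unit time (each arises exactly once) and are lost independently at
   rate $\nu$ per feature per lineage; a loss removes the feature from the
   entire subtree below it while copies on sibling branches persist. The
   feature diversity FD of a species subset is the total weight of features
   present in at least one member.

3. **An extinction layer.** The field-of-bullets (FOB) model kills each
   extant species independently with probability $\epsilon = 1 - s$; the
   generalized model (gFOB) gives each species its own $\epsilon_x$.

On top of these sit phylogenetic diversity (PD), its indices (fair
proportion / evolutionary distinctiveness, equal splits, the Shapley
value), the per-species expectation indices $\psi$ and $\psi' = \psi
\epsilon_x$, and the limiting proportions $\varphi_{PD}(s)$ and
$\varphi_{FD}(s)$ of diversity that survive a FOB event on a large
birth--death tree.

## Parameters and their meaning

| parameter | unit | default | role |
|---|---|---|---|
| $\lambda$ | events / lineage / time | 1 | speciation rate; sets the time scale |
| $\mu$ | events / lineage / time | 0 | extinction rate; $\lambda > \mu$ wherever limits are taken |
| $r$ | features / lineage / time | -- | feature gain rate ($\varphi_{FD}$ does not depend on it) |
| $\nu$ | losses / feature / time | 0 | feature loss rate; $\nu = 0$ collapses FD onto PD |
| $s$ | probability | -- | FOB per-species survival; $\epsilon = 1-s$ |
| $t$ | time | -- | tree age; asymptotic statements need $\lambda t$ large |
| $F_0$ | count | 0 | features present at the top of the stem edge |

Trees are `ape` `phylo` objects. A stem edge (the lineage from the origin
to the root split) is stored as `root.edge`; it is excluded from PD, edge
statistics and depth queries by default, matching the convention of the
quantities implemented, and included where the construction demands it
(feature gains on the stem, the expected-feature lengths
$\ell'$).

## Exact arithmetic

Worked-example probabilities (1/6, 1/90, the depth laws 1/3, 1/2, 1/6) are
required bit-exactly, so small-$n$ probabilities are computed in a minimal
exact rational type on IEEE doubles. Every operation verifies that the
integers involved stay below $2^{53}$ and stops rather than rounding; in
practice this covers $n \le 12$ everywhere the interface promises
exactness (and further in most places; addition works over the lcm of the
denominators to delay overflow). Unsigned Stirling numbers of the first
kind $c(n,k)$ -- which drive the leaf-depth laws
$P(D_n = k) = 2^k c(n-1,k)/n!$ (reduced) and $P(D_n' = k) = c(n,k+1)/n!$
(evolutionary) -- are computed exactly for $n \le 500$ with an internal
base-$10^7$ digit-matrix big integer (the recurrence needs only addition
and multiplication by a small scalar), and in log space beyond.

## Evolutionary depth semantics

The evolutionary depth of a leaf counts only "new species" edges on its
root path. Two rules fix the semantics on reduced trees: extinct lineages
are ignored, and a lineage is not treated as a new species if it branched
off a lineage with no surviving descendants. Concretely, each edge of the
reduced tree represents a chain of lineage segments; the edge is a
new-species edge exactly when the *first* segment of that chain was the
designated offspring at the (visible) split above it. The designation at
each split is uniform between the two daughters. In the discrete YH
attachment sampler the attached leaf is the designated offspring and the
initial two-leaf split designates uniformly; both routes reproduce the
exact three-leaf law $(1/3, 1/2, 1/6)$, which the tests check by
exhaustive history enumeration and by birth--death simulation with
$\mu > 0$.

## Conditioning semantics

`simulate_bd()` supports three conditionings, matching the statements the
results are proved under: `none` (run to age $t$, possibly extinct),
`survival` (rejection sampling on $N_t > 0$; unbiased for conditional
laws), and `fixed_n` (run until the leaf count would first change from $n$
to $n+1$ and sample just before that split -- the convention under which a
uniformly sampled pendant or interior edge of a Yule tree is exactly
Exponential$(2\lambda)$ and the total length $S_n$ is
Gamma$(n-1, \lambda)$). For the pure Yule case the simulator uses a
vectorized fast path (pre-generated waiting times and lineage choices);
time-varying neutral rates are simulated by thinning against the supplied
caps, preserving per-lineage uniformity by construction.

## The survival curves $\varphi_{PD}$ and $\varphi_{FD}$

$\varphi_{PD}(s)$ has closed forms: $s\ln(1/s)/(1-s)$ for Yule trees and,
with $\rho = \mu/\lambda > 0$,
$\frac{\rho s}{\rho + s - 1}\cdot\frac{\ln(s/(1-\rho))}{\ln(1/(1-\rho))}$,
with the removable singularity at $\rho = 1 - s$ filled by
$(1-s)/\ln(1/s)$; the branch is selected within $10^{-12}$ of the
singular manifold and one-sided limits agree to $10^{-9}$ (tested).

For $\varphi_{FD}$ the package derives the integrand from the
feature-survival integral: the number of species carrying a feature born
at time $t_0$ is a birth--death process with rates $(\lambda, \mu+\nu)$
sampled at probability $s$, whose survival probability $R^s_\tau$ has the
classical closed form. Writing $g_s(\tau) = R^s_\tau(\lambda, \mu+\nu)/s$,
$$\varphi_{FD}(s) = \frac{s\,I(s)}{I(1)}, \qquad
  I(s) = \int_0^\infty e^{-(\lambda-\mu)\tau} g_s(\tau)\, d\tau.$$
This normalization is the one that reduces exactly to $\varphi_{PD}$ at
$\nu = 0$ (checked to $10^{-9}$ across an $s$-grid, for $\mu = 0$ and
$\mu > 0$). The integrand is a ratio of exponentials whose antiderivative
is not an elementary exponential sum, so $I(s)$ is evaluated by adaptive
quadrature after the substitution $u = e^{-(\lambda-\mu)\tau}$, which
maps the improper integral onto $(0, 1]$ with a bounded integrand; an
independent direct quadrature over $(0, \infty)$ is kept as a cross-check
oracle in the tests (agreement to $10^{-8}$ across a parameter sweep that
brackets the $\rho = 1$ branch).

## The expected-FD recursion and the PD proxy

For a fixed tree, the expected FD of a subset $Y$ is computed exactly by
an absence-probability recursion: $q_v$ is the probability that a feature
present at vertex $v$ reaches no leaf of $Y$, with $q_{\text{leaf}}$
either the $Y$-membership indicator or $1 - s$ under FOB marginalization,
and $q_v = \prod_c \left(e^{-\nu \ell_c} q_c + 1 - e^{-\nu
\ell_c}\right)$ over child edges. Each edge contributes
$r(1 - e^{-\nu\ell_e})/\nu \cdot (1 - q_{\text{bottom}(e)})$ (with a
series branch below $\nu\ell < 10^{-8}$ to keep the $\nu \to 0$ limit
$r\ell_e$ numerically continuous). Setting $Y = X$ per edge yields the
expected-feature lengths $\ell'_e$, which sum to $E[FD(X)]$ by
construction.

The bound comparing expected FD loss with PD loss computed on $\ell'$ is
implemented with the stem edge included as an edge whose clade is all of
$X$. One consequence is worth recording: with a *positive* stem length and
$\nu > 0$ the bound is strict even on star trees (the stem term
$1 - \prod_x(1 - s\,e^{-\nu\ell_x})$ differs from its PD counterpart
$(1-\prod_x(1-e^{-\nu \ell_x}))(1 - (1-s)^n)$ already for two leaves);
equality on star trees is exact when the stem is absent or has zero
length, and the tests assert exactly that dichotomy. Equality at
$s \in \{0, 1\}$ holds always.

## What the generators emulate -- and what they do not

The synthetic data used everywhere are draws from the models themselves:
discrete YH and uniform (PDA) topologies, constant-rate birth--death trees
(ultrametric, in time units), Poisson feature gain with exponential loss,
and independent extinction at the present. They deliberately do not
emulate features of real data -- rate variation across clades, imbalance
beyond the YH law, correlated extinction risks, fossil sampling,
reticulation, or measurement error in branch lengths. A passing suite
therefore certifies the mathematics of the neutral models, not the fit of
those models to any empirical phylogeny.

## Numerical and testing choices

* Distributional tests run at $\alpha = 0.001$ with fixed seeds;
  Monte-Carlo point checks use $3\sigma$ bands derived from the ensemble
  itself.
* Problem sizes were chosen to keep the whole suite a few minutes on one
  CPU while leaving comfortable statistical power: 20\,000 trees for the
  $\chi^2$ shape tests, 8\,000 replicates for the edge-length KS tests,
  150 replicates of the three-layer process at $\lambda t = 9$ for the
  $\varphi_{FD}$ convergence check (the per-replicate ratio concentrates,
  so the standard error is well below the 0.02 acceptance band), 1\,000
  random instances for the FD/PD-proxy inequality sweep.
* Ties in greedy PD maximization break towards the lexicographically
  smallest leaf label, so outputs are deterministic.
* Replicates whose tree degenerates to a single surviving lineage carry no
  PD (or FD) ratio; the empirical-ratio functions drop them and report the
  dropped fraction as an attribute rather than silently imputing a value.
* All stochastic entry points accept an explicit integer seed.

## Known limitations

* Exact rationals overflow deliberately (with an error) rather than fall
  back silently; probability computations beyond the exact regime return
  plain doubles computed in log space.
* The classification of the (finitely many) tree shapes on which expected
  FD is exactly representable as PD is not implemented; the package
  reports the inequality and its gap instead.
* Unrooted trees, phylogenetic networks, multiple origins of a feature,
  and extinction cascades are out of scope; multifurcations parse and work
  for PD/FD arithmetic but all shape-probability machinery assumes binary
  trees.
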