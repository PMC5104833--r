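---
title: "Product-form stationary laws for stochastic reaction networks: models, numerics, design"
author: "crnstationary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Product-form stationary laws for stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnstationary)
```

## The model

A chemical reaction network is a set of species $S_1,\dots,S_d$, a set of
complexes (nonnegative integer combinations of species), and reactions
$\nu_k \to \nu_k'$ with rate constants $\kappa_k > 0$. Stochastically the
state $x \in \mathbb{Z}^d_{\ge 0}$ is molecule counts and the model is a
continuous-time Markov chain jumping by $\nu_k' - \nu_k$ at intensity
$\lambda_k(x)$. A stationary distribution $\pi$ satisfies, at every state,
the master-equation balance

$$\sum_k \lambda_k(x - \nu_k' + \nu_k)\,\pi(x - \nu_k' + \nu_k)
  \;=\; \sum_k \lambda_k(x)\,\pi(x),$$

equivalently $\pi A = 0$ for the generator matrix $A$.

Three intensity families are supported:

* **stochastic mass action**,
  $\lambda_k(x) = \kappa_k \prod_i x_i!/(x_i - \nu_{ki})!$;
* the **theta-product form**, in which each falling-factorial factor
  $(x_i - j)$ is replaced by $\theta_i(x_i - j)$ for per-species functions
  $\theta_i$ with $\theta_i(0) = 0$;
* the **alpha-strided theta-product form**. Let
  $\alpha_i = \gcd\{\nu_{1i},\dots,\nu_{Ki}\}$ over the *source* counts
  (with $\alpha_i = 1$ for a species never consumed, so its factor is an
  empty product). When $\alpha_i > 1$ the species is always consumed in
  multiples of $\alpha_i$, and the intensities are
  $$\lambda_k(x) = \kappa_k \prod_i \prod_{j=0}^{\nu_{ki}/\alpha_i - 1}
    \theta_i(x_i - j\,\alpha_i),$$
  with the admissibility condition $\theta_i(z) = 0$ iff
  $z \le \alpha_i - 1$. This is the form that arises from constrained
  (projection-based) averaging, where a zero-order slow reaction folded
  into a dimerization channel produces rates like
  $k_1 x_1(x_1 - 1) + k_3 \mathbf{1}\{x_1 > 1\}$ — a single
  $\theta_1(z) = z(z-1) + (k_3/k_1)\mathbf{1}\{z > 1\}$ on the
  $\alpha_1 = 2$ lattice, but not a mass-action or classical theta-product
  rate.

**Main structural fact used throughout.** If the network, modeled
deterministically with mass action and the same $\kappa_k$, admits a
complex-balanced equilibrium $c > 0$ (guaranteed for weakly reversible
deficiency-zero networks), then the stochastic model with admissible
alpha-strided kinetics has the product-form invariant measure

$$\tilde\pi(x) = \prod_{i=1}^d \frac{c_i^{\,x_i}}
  {\prod_{j=0}^{\lfloor x_i/\alpha_i\rfloor - 1}\theta_i(x_i - j\alpha_i)},$$

normalizable to a stationary distribution on any class where it is
summable. With all $\alpha_i = 1$ this is the classical theta-product
measure, and with $\theta_i(z) = z$ a product of Poisson weights. The
constructive bridge between the two is the window factorization
implemented by `phi_from_theta()`: $\varphi_i(0) = 0$,
$\varphi_i(z) = C$ on $1..\alpha_i-1$, and
$\varphi_i(z) = \theta_i(z)/(\varphi_i(z-1)\cdots\varphi_i(z-\alpha_i+1))$,
so that $\theta_i(z) = \prod_{\ell=0}^{\alpha_i-1}\varphi_i(z - \ell)$ and
the full $\varphi$-product telescopes to the strided $\theta$-product
(`factorization_check()`). The telescoping identity pins $C = 1$; other
$C > 0$ still satisfy the window identity and parameterize the valid
rate completions in the alpha-mismatch construction
(`crn_fixture("example4_system25")`), where a species with source gcd 1
nevertheless carries a window-2 rate and the completion $\varphi$
oscillates with growing amplitude.

## Tunable parameters that matter

* `zmax` (integer, default 1200 for fixtures): tabulation range for
  table-backed $\theta$ and $\varphi$. Tables never extrapolate — queries
  beyond the last entry are errors, because a silently extended
  denominator would corrupt the measure. Choose `zmax` at least the box
  maximum plus the largest stride.
* truncation `box` (per-species upper bounds, counts): the finite window
  for generator solves and normalization. Correctness is certified by the
  *boundary mass*: if the shell (any coordinate at its bound) carries
  $\ge 10^{-12}$ of the mass, results are flagged `truncation_limited`.
  Summability of the measure on the infinite lattice is never proven, only
  certified empirically this way.
* `tol` for the equilibrium solve (default `1e-10`): scale-free, final
  residuals are compared against `tol * (1 + max complex throughput)`.
* `tol` for stationary solves (default `1e-10`): residual
  $\max|\pi A| / \max|A_{ii}|$, i.e. normalized by the largest exit rate.
  The same normalization (`max_scaled`) is the headline number of
  `stationarity_residual()`: on classes with flux scales of $10^4$ and
  log-weights of order $10^2$, an *absolute* pointwise residual of
  $10^{-10}$ is below what double-precision log-space arithmetic can
  deliver, while the scaled residual is meaningful at any scale.
* `seed`: every stochastic routine (`ssa_simulate()`, `random_theta()`,
  `random_complex_balanced_network()`) takes an explicit integer seed and
  restores the caller's RNG state.

## Numerical design choices

**Measure arithmetic is entirely in log space.** Weights near a box of
$10^3$ states per axis overflow in linear space; log-weights are
accumulated by a strided recursion
$g_i(x) = g_i(x - \alpha_i) + \log\theta_i(x)$ and normalized by
log-sum-exp. States where a denominator factor vanishes get probability
zero and are excluded from residual checks (under admissibility they are
unreachable within their class).

**Equilibrium solving.** `solve_complex_balanced()` works in
log-concentrations $c = e^u$ (positivity for free), but not on the raw
residuals: all mass-action rates vanish together as $c$ approaches parts
of the boundary, so the raw least-squares landscape has spurious infima
there. The iteration therefore drives the *relative* per-complex
imbalance $(\text{out}-\text{in})/(\text{out}+\text{in})$, which is zero
exactly at equilibrium and tends to $\pm 1$ at the degenerate boundary.
A second degeneracy is the equilibrium manifold itself: positive
equilibria satisfy $\ln c \in \ln c^* + \mathrm{span}(\text{conservation
laws})$, so an unconstrained solve is under-determined. User constraints
(e.g. `"S1+2*S2=1"`) pin it; without one, the solver anchors
$w \cdot \ln c = 0$ for each conservation law $w$ — the canonical
representative reached from $c = 1$. Because any choice along the
manifold rescales the measure by a constant on each conserved class, the
class-conditional distribution is invariant to this choice (tested).
Damped Gauss–Newton with a finite-difference Jacobian and a step cap
converges on every shipped and randomized fixture; non-convergence is an
error carrying the best iterate.

**Stationary solves.** The generator is assembled sparsely on the
enumerated class; transitions leaving the set are dropped (the row sum
stays zero — reflecting-by-dropping), an approximation monitored through
boundary mass, not corrected. $\pi A = 0$ is solved by sparse LU on the
adjoint with one balance row replaced by the *unit* equation
$\pi(\text{anchor}) = 1$ — a sparse row; replacing it by the dense
all-ones normalization row destroys sparsity and inflates the
factorization by orders of magnitude. The anchor is an approximate mode
from a few uniformized power steps; a poor anchor can ill-scale the
unnormalized solve, so the solver re-anchors at the argmax of its first
attempt (plus deterministic fallbacks) before failing. Uniqueness is
checked explicitly on chains up to 20000 states (every state must reach
the anchor); beyond that the residual check is the safeguard, and a
residual failure reports the likely cause — multiple closed classes in
the truncated set, fixable by conditioning on a conserved quantity or a
residue class.

**Ties and degenerate inputs.** Class enumeration is lexicographic with
the first coordinate most significant, so state indexing, TSV output and
generator rows are deterministic. Conservation laws are computed by
fraction-free integer elimination and returned as primitive integer
vectors with positive leading entry — exact and stable across platforms.
Empty classes enumerate to zero states (an error only when normalizing).

## The averaging reductions

For the dimerization module ($2S_1 \rightleftharpoons S_2$ fast, with
slow production of $S_2$ and degradation of $S_1$), the slow variable is
$s = x_1 + 2x_2$. Two reductions of the fast dynamics at fixed $s$ are
implemented:

* **QEA** (`qea_distribution()`): the fast pair with its own constants
  $(k_1, k_2)$; its stationary law is a conditioned product-Poisson with
  parameter the complex-balanced equilibrium $(d_1, d_2)$,
  $d_1 = (\sqrt{k_2(k_2+8k_1)}-k_2)/(4k_1)$ under $d_1 + 2d_2 = 1$.
* **constrained averaging** (`constrained_distribution()`): the pair with
  the slow production projected into the dimerization channel — forward
  intensity $k_1 x_1(x_1-1) + k_3\mathbf{1}\{x_1 > 1\}$, reverse
  $k_2 x_2$ — whose stationary law follows from the alpha-strided
  product form. Both laws are computed twice (generic machinery and
  direct closed-form evaluation) and the two code paths are asserted
  equal.

Effective slow rates are expectations of the slow propensities under the
chosen fast law ($\bar\lambda_4(s) = \kappa_4\,E[X_1]$), and
`compare_averaging()` reproduces the headline comparison: full-model
conditional on a slice (solve, extract, renormalize) versus both
reductions, in relative $\ell^2$ with the full conditional as reference.

**A documented source discrepancy.** The source material prints the
constrained pair's reverse rate as $(k_2+k_4)x_2$ and equilibrium
formulas containing $k_4$ in both reductions, yet its own computed
comparison numbers (QEA error $4.464\times 10^{-1}$, constrained error
$5.2337\times 10^{-2}$ at $s = 300$ with $k = (1, 100, 1500, 30)$) are
reproduced to every printed digit only by the $(k_1, k_2)$ equilibria
above, as this package's acceptance tests verify; with the printed
$k_4$-bearing formulas the errors come out 1.479 and 0.779, reversing
the qualitative conclusion. The package follows the numerics: the
fixtures use reverse constant $k_2$, and the $k_4$-bearing closed forms
are treated as typographical slips. Similarly, the printed fast-flux
share of 82.68% is not reproduced to two decimals by any interpretation
tried; the package computes 82.709% (expected fast propensity over
expected total propensity), with interpretation variants spanning
82.62–82.77, and the corresponding acceptance assertion is deliberately
left failing at the printed precision.

## What the synthetic generator emulates

`random_complex_balanced_network()` draws a directed cycle through up to
$d+1$ distinct random complexes with entries $\le 4$ — strongly connected
by construction, accepted only when the structural report certifies
deficiency zero. This is the smallest family on which the product-form
theorem's hypotheses hold for *every* rate constant, with sizes kept
brute-forceable. `random_theta()` draws tables that satisfy admissibility
exactly, log-uniform on $[10^{-2}, 10^2]$ above the stride. Together they
give an end-to-end randomized check: measure built from the solved
equilibrium, pointwise balance on interior box states at relative
residual $10^{-10}$, with a 10% single-value theta perturbation as the
negative control.

What this does **not** emulate: networks with deficiency $> 0$ (the full
dimerization module is the only such fixture, handled purely
numerically), multiple linkage classes in the random family, rates
outside the theta-product family, and state-dependent coupling between
species within one theta (excluded by definition). A green randomized
suite therefore supports the implemented theorem machinery, not any
claim about general networks.

## Known limitations

* Irreducibility on a user-specified class is not derived from the
  network; classes are user inputs, and the SSA oracle can visit a strict
  subset of an enumerated class if the class was chosen too large.
* Truncation error is certified only through boundary mass; there is no
  finite-state-projection style error bound.
* The CLI serializes expression- and table-backed thetas only; R
  function-backed thetas are an in-session convenience.
* The deterministic model appears only through its equilibria; no ODE
  trajectories are integrated.
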