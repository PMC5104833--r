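# crnstationary

Stationary analysis of stochastically modeled chemical reaction networks,
for modelers who need exact stationary distributions of fast subsystems —
typically inside a multiscale averaging loop where a numerical
stationary solve per outer step would be the bottleneck.

## The science in brief

A reaction network with species $S_1,\dots,S_d$ and reactions
$\nu_k \to \nu_k'$ (rate constants $\kappa_k$) is modeled as a
continuous-time Markov chain on counts $x \in \mathbb{Z}^d_{\ge 0}$ with
intensities $\lambda_k(x)$. For **complex-balanced** networks (in
particular weakly reversible networks of **deficiency zero**) with
intensities of the per-species theta-product form on an
$\alpha$-strided lattice,

$$\lambda_k(x) = \kappa_k \prod_{i=1}^{d}\ \prod_{j=0}^{\nu_{ki}/\alpha_i - 1} \theta_i(x_i - j\,\alpha_i),
\qquad \alpha_i = \gcd_k \nu_{ki},\qquad \theta_i(z)=0 \iff z \le \alpha_i - 1,$$

the stationary distribution is known in closed product form,

$$\pi(x) \;\propto\; \prod_{i=1}^{d} \frac{c_i^{\,x_i}}{\prod_{j=0}^{\lfloor x_i/\alpha_i\rfloor-1} \theta_i(x_i - j\alpha_i)},$$

where $c$ is a complex-balanced equilibrium of the associated
*deterministic mass-action* system. Rates of this form (e.g.
$k_1x_1(x_1-1) + k_3\mathbf{1}\{x_1>1\}$) arise from constrained
stochastic averaging, where they are neither mass action nor classical
theta products. The package implements:

* structural calculus: complexes, linkage classes, weak reversibility,
  deficiency $\delta = n - \ell - s$, exact integer conservation laws,
  the $\alpha$-partition (`crn_structure()`, `alpha_partition()`);
* kinetics: mass action, theta products, admissibility validation, and
  the constructive window factorization
  $\theta(z) = \varphi(z)\cdots\varphi(z-\alpha+1)$
  (`theta_fn()`, `validate_assumption1()`, `phi_from_theta()`);
* complex-balanced equilibria by damped Gauss–Newton in log
  concentrations (`solve_complex_balanced()`);
* product-form measures, normalization on state classes (conserved
  slices, parity classes), moments (`product_form_measure()`,
  `normalize_measure()`, `expectation()`);
* numerical ground truth: sparse truncated-generator stationary solves,
  pointwise stationarity residuals, Gillespie simulation
  (`build_generator()`, `solve_stationary()`, `ssa_simulate()`);
* multiscale reductions: quasi-equilibrium vs constrained averaging with
  effective slow rates and relative-$\ell^2$ comparisons
  (`qea_distribution()`, `constrained_distribution()`,
  `compare_averaging()`, `fast_reaction_proportion()`).

Worked example systems (the dimerization module and friends) ship as
code-built fixtures: `fixture_names()`, `crn_fixture()`.

## Worked example

The constrained-averaging subsystem of the dimerization module:
`2S1 <-> S2` with forward intensity $x_1(x_1-1) + 1500\cdot\mathbf{1}\{x_1>1\}$
($\theta_1$ on the $\alpha_1 = 2$ lattice) and reverse $100\,x_2$.

```r
library(crnstationary)

fx <- crn_fixture("constrained_system18")   # k1=1, k2=100, k3=1500, k4=30
crn_structure(fx$net)
#> CRN structure: n = 2 complexes, l = 1 linkage classes, rank s = 1
#>   deficiency  = 0
#>   weakly reversible: TRUE
#>   conservation laws: 1

eq <- solve_complex_balanced(fx$net, constraint = "S1+2*S2=1")
eq
#> Complex-balanced equilibrium:
#>          S1          S2
#> 0.980762110 0.009618943
#>   max |complex-balance residual| = 4.440892e-16

## stationary law on the conserved class x1 + 2 x2 = 50
meas <- product_form_measure(eq$c, fx$kin, fx$net, ap = fx$ap)
cls  <- state_class(c("S1", "S2"), box = c(50L, 25L),
                    invariants = list("S1+2*S2=50"))
dist <- normalize_measure(meas, cls)
dist
#> Distribution over 26 states in 2 coordinates
#>   boundary mass: 0
#>   P(16,17) = 0.122219
#>   P(14,18) = 0.118145
#>   P(18,16) = 0.115046

## against the exact truncated-generator solve of the same chain
exact <- solve_stationary(build_generator(fx$net, fx$kin, cls, ap = fx$ap))
distribution_distance(dist, exact, "total_variation")
#> [1] 4.647493e-15
expectation(dist, "S2")
#> [1] 17.39487
```

The closed form and the numerical solve agree to machine precision: with
50 monomers' worth of mass, on average ~17.4 dimers are bound, and e.g.
`effective_rates(fx$params, 50, "constrained")` turns such expectations
into the averaged slow-model rates.

A command-line front end covers the same workflows
(`analyze`, `equilibrium`, `stationary`, `solve-exact`, `simulate`,
`compare-averaging`, `fixtures`); see `?crn_cli` and `inst/cli/`.

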