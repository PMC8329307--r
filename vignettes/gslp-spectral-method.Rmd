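---
title: "Spectral optimization of Caputo fractional systems with generalized shifted Legendre bases"
author: "gslpode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral optimization of Caputo fractional systems with generalized shifted Legendre bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslpode)
```

## The problem

`gslpode` solves initial-value problems for systems of nonlinear Caputo
fractional ordinary differential equations,

$$ D^{\eta_i}\, y_i(t) = f_i\big(t, y_1(t), \ldots, y_d(t)\big), \qquad
   y_i(0) = y_{i,0}, \qquad 0 < \eta_i \le 1, $$

where $D^{\eta}$ is the Caputo derivative,
$D^{\eta} f(t) = \frac{1}{\Gamma(1-\eta)} \int_0^t (t-\xi)^{-\eta}
f'(\xi)\, d\xi$ for $\eta < 1$ and the ordinary derivative at $\eta = 1$.
The convolution kernel gives the derivative memory: the value at $t$
depends on the entire history of $f$ on $[0, t]$, which is what makes
fractional models attractive for biological populations with hereditary
effects — and what makes them awkward for step-by-step integrators.

The bundled showcase is a five-compartment breast cancer competition
model: cancer stem cells $C$, tumor cells $T$, healthy cells $H$, immune
cells $I$ and excess estrogen $E$, with logistic growth, immune kill
terms, Michaelis–Menten-type estrogen interactions, and a constant
estrogen infusion. Every rate constant $r$ appears as $r^{\eta_i}$ in
equation $i$, so each term carries units of day$^{-\eta_i}$ and the
system reduces exactly to its classical counterpart at $\eta_i = 1$
(`fbccm_rhs_classical()` / `fbccm_rhs_fractional()`). All twenty-seven
baseline constants live in `fbccm_parameters()`.

## The basis and the operational matrix

Shifted Legendre polynomials $L_j$ on $[0,1]$ have the exact monomial
representation $L_j(t) = \sum_k p_{jk} t^k$ with integer coefficients
(`slp_coefficient_matrix()`). The *generalized* shifted Legendre family
replaces each monomial $t^j$ by $t^{j+\alpha_j}$, where the exponent
shifts $\alpha_j$ ("control parameters") are free reals subject only to
$j + \alpha_j > 0$. This is a Müntz-type family: by the Müntz–Szász
density condition such shifted-power spans remain dense in $C[0,1]$, and
— crucially for fractional problems — they can represent functions whose
expansion near $t = 0$ proceeds in powers of $t^{\eta}$ rather than $t$.
The solution of a fractional relaxation problem behaves like
$y_0 + c\, t^{\eta} + \ldots$, which no fixed polynomial basis of small
degree captures well.

The Caputo derivative acts diagonally on the generalized monomial vector
$\Psi(t) = (1, t^{1+\alpha_1}, \ldots, t^{m+\alpha_m})^T$:

$$ D^{\eta}\, t^{j+\alpha_j} =
   \frac{\Gamma(j+1+\alpha_j)}{\Gamma(j+1-\eta+\alpha_j)}\,
   t^{\,j+\alpha_j-\eta}, $$

so differentiation of an entire expansion is one diagonal matrix
(`caputo_operational_matrix()`) plus a shared $t^{-\eta}$ factor. We
combine the exponents analytically before evaluating
(`caputo_psi()`), so $t \to 0$ never touches $0^{-\eta}$: an exponent
$j + \alpha_j - \eta > 0$ gives 0, an exponent equal to 0 gives the
Gamma ratio itself. The Gamma ratios are evaluated via `lgamma`
differences; the integer coefficient matrices via
`choose(i+j, i-j) * choose(2j, j)`, which is exact in double precision
for every size used here.

The analytic monomial rule and a desingularized adaptive quadrature of
the defining convolution integral (`caputo_monomial()`,
`caputo_quadrature()`, substitution $u = (t-\xi)^{1-\eta}$) serve as
mutually independent oracles; the test suite holds them to $10^{-6}$
relative agreement across orders 0.1–0.9 and powers 0.5–3.

## Residual minimization with initial-condition constraints

Each state is expanded as $y_l(t) = c_l^T Q\, \Psi_l(t)$ with its own
basis size $m_l$ and shift vector. Substituting the expansions and the
operational matrix into the system defines residual functions
$R_i(t)$ (`gslp_residuals_at()`), which we nondimensionalize by fixed
state scales — for the cancer model the three carrying capacities, the
immune threshold and the estrogen threshold, so all five residuals are
commensurate. The objective is the integrated squared residual

$$ M = \int_0^k \sum_i R_i^2(t)\, dt, $$

discretized by Gauss–Legendre quadrature with nodes strictly inside
$(0, k)$ (`quadrature_rule()`), and minimized subject to the five
initial-condition constraints $\Theta_i = 0$ (`gslp_constraints()`).
The constrained problem has the Lagrangian $J = M + \lambda \cdot \Theta$
(`gslp_lagrangian()`) and the usual stationarity system
(`gslp_stationarity()`, all partials computed analytically, including
the digamma terms from differentiating the Gamma ratios with respect to
the shifts).

### How the optimizer actually works

Because $\Psi(0) = (1, 0, \ldots, 0)^T$, each constraint is *linear* in
the coefficients with weights $(\pm 1)$, and we eliminate it exactly by
solving for the zeroth coefficient. The remaining free coefficients
(scaled by the state scales for conditioning) and the exponent shifts are
optimized by bound-constrained Levenberg–Marquardt on the
$\sqrt{w_k}\,R_i(t_k)$ stack with a dense analytic Jacobian — the same
stationary points as the Lagrangian system, but far more robust than
root-finding on the raw optimality conditions. Lagrange multipliers are
recovered afterwards from $\lambda_l = -\partial M / \partial c_{l,0}$,
and the reported `stationarity_norm` diagnostic closes the loop.

The landscape in the exponent shifts is genuinely multimodal. Four
devices keep the solver out of poor basins, all deterministic given the
seed:

* **Deterministic starts**: all shifts zero (classical polynomials);
  fractional power-series shifts $\alpha_j = j(\eta-1)$ (exponents
  $j\eta$); integer-shifted exponents $\alpha_j = \eta - 1$ (exponents
  $j - 1 + \eta$); plus seeded random draws.
* **Warm starts** by least-squares projection of a coarse
  predictor-corrector trajectory onto the basis, when that integration
  is stable.
* **Continuation in basis size**: optimize at basis sizes truncated to
  $1, 2, \ldots$, re-embedding each optimum into the next larger space.
  This is what makes the strongly fractional configurations (orders
  0.1–0.3) tractable; direct multistart reliably stalls three or more
  orders of magnitude higher.
* **Two-stage effort**: every start is screened cheaply at 64 nodes;
  only the best few are polished at the full node count, with
  Levenberg–Marquardt restarted from its own endpoint until the
  objective stops improving by 0.1%.

The quadrature is verified a posteriori by node doubling until the
objective is stable to `quad_rtol` (default $10^{-3}$ relative), capped
at `max_nquad`; the integrand contains $t^{-2\eta}$-type terms near the
origin, so the reported objective uses the finest verified rule.

### Numerical choices and degenerate inputs

* Shift bounds: $j + \alpha_j \ge 10^{-6}$ (validity of the basis) and
  $\alpha_j \le 5$ (keeps exponents in a numerically sane range).
* Factorial-formula matrices exact in integer arithmetic; Gamma ratios
  by `lgamma` differences; all powers of $t$ with combined exponents.
* Residuals are undefined at $t = 0$ (the operational matrix carries
  $t^{-\eta}$); all quadrature nodes and residual evaluations are
  interior.
* Ties between multistart optima resolve to the smallest objective by
  construction (strict `<` comparisons keep the earlier, deterministic
  start on exact ties).

## The verification oracle

`pece_solve()` implements the fractional Adams–Bashforth–Moulton
predictor-corrector on a uniform grid, with one convolution history per
component so every equation keeps its own order. It shares nothing with
the spectral code path — no basis, no operational matrix, no optimizer —
which makes agreement between the two methods meaningful evidence. Its
empirical convergence order $O(h^{1+\eta})$ is asserted in the tests.
Being explicit, it can be unstable for strongly fractional stiff
problems (orders near 0.1 on this model); it then fails loudly and the
solver simply proceeds without that warm start. `classical_solve()`
(adaptive LSODA) covers the $\eta_i = 1$ limit, and
`manufactured_system()` builds single-equation problems with known exact
solutions $t^p$ for exact-error measurement.

## Default study conditions

The bundled example configurations (`run_example()`) use the published
baseline parameters, the reference initial state
$(7.371 \times 10^5,\ 7.6167 \times 10^6,\ 2.5 \times 10^7,\ 0,\ 0)$,
basis sizes between 2 and 8 per compartment, and two order families per
example (strongly fractional and near-unit). The integration horizon
defaults to $k = 1$ day — the natural interval of the shifted Legendre
basis; longer horizons are configurable but were not the conditions the
solver's defaults are calibrated for. Default solver effort (6 starts,
128 nodes polished, continuation on) was chosen so a full
five-configuration sweep runs in minutes on one core; the basis sizes
are those of the bundled examples, so tests and the acceptance sweep use
problem sizes between 25 and 62 unknowns.

## What the checks do and do not show

The test suite establishes: exact basis algebra; $10^{-6}$ agreement of
three independent Caputo implementations; recovery of representable
manufactured solutions to $10^{-8}$; agreement of the spectral solution
with adaptive classical integration at unit orders to better than 1%;
agreement with the independent fractional predictor-corrector at
near-unit orders to 5%; and non-increase of the optimal objective under
basis enlargement (an empirical stand-in for the density argument above).

Two caveats deserve emphasis. First, the residual objective is a
*backward* error; converting it to a forward trajectory error depends on
the conditioning of the model and is only probed indirectly through the
dual-method comparisons. Second, reported optimal objectives depend on
the state scaling and the horizon entering $M$; they are comparable
across configurations of this package but not directly against values
computed under other (often unstated) normalizations, and double
precision bounds how deep the optimizer can push the smallest objectives
— regimes below roughly $10^{-13}$ in $M$ would require extended-precision
arithmetic that this implementation deliberately does not carry.

On the solve horizon of one day the fitted cancer-model trajectories
show growing stem-cell populations, declining healthy tissue and rising
estrogen — the directions the vector field points at this initial state
(tumor and immune counts are near-balanced and their endpoint signs vary
with the configuration). Statements about long-run remission dynamics
concern far longer horizons and are outside what these fits show.

## Known limitations

* Orders are restricted to $(0, 1]$; no Riemann–Liouville or
  distributed-order variants.
* The exponent-shift optimization is local-plus-multistart; no global
  optimality certificate is possible or claimed.
* The PECE oracle is fixed-step and explicit; it is a verification tool,
  not a production integrator for stiff strongly fractional problems.
* Double precision throughout.

## A worked example

```{r example, eval = FALSE}
sys <- fbccm_system(orders = c(0.98, 0.99, 0.97, 0.98, 0.99))
fit <- gslp_solve(sys, m = c(2, 3, 3, 3, 4), seed = 1)
summary(fit)
head(predict(fit, times = seq(0, 1, 0.25)))
```
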