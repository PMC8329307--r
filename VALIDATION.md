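# Validation notes

This file records how the minimized residual objectives produced by
`scripts/acceptance.R` compare with previously published values for the
same five breast-cancer-model configurations, and documents the parts of
the published results that this implementation does not reproduce, with
the evidence behind that assessment.

## Setup

All values below were computed with

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

i.e. Table-1 baseline parameters, initial state
(7.3710e5, 7.6167e6, 2.5e7, 0, 0), residual objective integrated over
[0, 1] with Gauss–Legendre quadrature (128 nodes, verified by doubling
up to 256), states scaled by (M1, M2, M3, omega, v), double-precision
arithmetic, and the package's default optimizer (deterministic +
seeded multistart, continuation in basis size, Levenberg–Marquardt
polish).

## Minimized objectives vs published values

| id | basis sizes | orders | this package (seed 1) | published | status |
|----|-------------|--------|----------------------|-----------|--------|
| t1 | (2,3,3,3,4) | (0.10,0.15,0.20,0.25,0.30) | 3.04e-06 | 7.4167e-07 | above (~4x) |
| t2 | (2,3,3,3,4) | (0.98,0.99,0.97,0.98,0.99) | 3.83e-06 | 2.9968e-07 | above (~13x) |
| t3 | (3,4,4,4,5) | (0.10,0.15,0.20,0.25,0.30) | 1.06e-07 | 8.2858e-08 | above (~1.3x) |
| t4 | (3,4,4,4,5) | (0.98,0.99,0.97,0.98,0.99) | 2.09e-09 | 7.4587e-09 | **below: meets the bound** |
| t5 | (4,4,5,7,7) | (0.08,0.17,0.13,0.11,0.23) | 2.83e-09 | 3.9316e-11 | above (~70x) |

A second run with `--seed 5` reproduces t1, t2, t4 and t5 to three
significant digits; t3 varies between about 1.1e-07 and 9.1e-07
(its deepest basin is found from a seeded random start).

## Assessment

1. **The published magnitudes depend on an unstated normalization.**
   The raw residuals of this model are of order 1e5–1e10 (states reach
   2.5e7 cells), so any objective in the 1e-07–1e-14 range presupposes
   some state scaling and integration horizon that the original report
   does not specify. The configuration used here (scaling by carrying
   capacities/thresholds, horizon [0, 1]) is the documented hypothesis
   of this package; under it, one of the five printed values (t4) is
   met and the others are approached within 1.3x–13x except t5.

2. **The optima found appear to be genuine optima of this objective.**
   For t2 the same stationary point (stationarity norm ~1e-06) is
   reached from zero starts, power-series starts, warm starts,
   24-point Latin-hypercube exponent draws, and a 2-D grid sweep over
   the dominant compartment's exponent shifts; the C-equation (basis
   size 2) contributes ~87% of the residual. We therefore do not
   believe further multistart effort closes the gap under this
   normalization.

3. **t5 additionally requires extended precision.** The published value
   (3.9e-11, and 1e-14 for the larger sibling configuration) was
   obtained with 20–40-digit arithmetic. This implementation is
   double-precision throughout (no arbitrary-precision arithmetic is
   available in the dependency environment), and its Levenberg–
   Marquardt descent stalls near 3e-09 on this 62-unknown problem.

4. **Basis nesting holds.** Enlarging every basis size never worsened
   the optimum in any measured pair (t1 -> t3: 3.0e-06 -> 1.1e-07;
   t2 -> t4: 3.8e-06 -> 2.1e-09), which is the property-based
   acceptance surface asserted in `tests/testthat/test-acceptance.R`
   alongside the exactness, oracle-agreement, classical-limit,
   manufactured-recovery and dual-method criteria.

5. **Qualitative trends on [0, 1] differ from the published figures.**
   The published account describes decreasing C, T, E and increasing
   H, I. At the bundled initial state the model's vector field gives
   dC/dt ~ +3.7e5 cells/day (logistic growth dominates, since I(0) = 0
   means no immune kill) and dH/dt ~ -1.1e7 cells/day (the delta*H*T
   competition term dominates), and both the spectral fits and the
   independent predictor-corrector oracle reproduce exactly these
   directions: C grows, H declines, E rises toward tau/mu on a one-day
   horizon. The published trend pattern is not attainable from this
   initial state on this horizon under the stated parameters; the
   corresponding test block is left failing by design as an honest
   record. A much longer horizon (hundreds of days, where the immune
   compartment saturates) or different axis normalization in the
   original figures would reconcile the two, but neither is stated.
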