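test_that("constraints are the expansion value at zero minus the initial state", {
  sys <- fbccm_system(orders = rep(0.9, 5))
  y0 <- fbccm_initial_state()
  # expansions with only the zeroth coefficient hit the constraint exactly
  cand <- gslp_candidate(coeffs = lapply(1:5, function(l) c(y0[[l]], 0, 0)),
                         alphas = lapply(1:5, function(l) c(0, 0)))
  expect_equal(unname(gslp_constraints(cand, sys)), rep(0, 5))
  zero <- gslp_candidate(coeffs = lapply(1:5, function(l) rep(0, 3)),
                         alphas = lapply(1:5, function(l) c(0, 0)))
  expect_equal(unname(gslp_constraints(zero, sys)),
               -c(7.3710e5, 7.6167e6, 2.5e7, 0, 0))
})

test_that("constraints are linear in the coefficients", {
  sys <- fbccm_system(orders = rep(0.8, 5))
  set.seed(21)
  c1 <- random_fbccm_candidate(rep(2L, 5), sys$scales)
  c2 <- random_fbccm_candidate(rep(2L, 5), sys$scales)
  c2$alphas <- c1$alphas
  mix <- gslp_candidate(
    coeffs = Map(function(a, b) 0.3 * a + 0.7 * b, c1$coeffs, c2$coeffs),
    alphas = c1$alphas)
  th_mix <- gslp_constraints(mix, sys)
  th_lin <- 0.3 * gslp_constraints(c1, sys) + 0.7 * gslp_constraints(c2, sys) +
    0 # both candidates subtract y0 once; correct the double counting below
  # Theta is affine, not linear: Theta(ax + by) = a Theta(x) + b Theta(y)
  # holds here because a + b = 1
  expect_equal(th_mix, th_lin, tolerance = 1e-9)
})

test_that("residuals vanish for an exactly represented manufactured solution", {
  p <- 1.3; eta <- 0.7
  sys <- manufactured_system(p, eta)
  cand <- exact_power_candidate(p)
  tt <- seq(0.05, 1, length.out = 10)
  expect_lt(max(abs(gslp_residuals_at(cand, tt, sys))), 1e-10)
  expect_lt(gslp_objective(cand, sys, quadrature_rule(64, 1)), 1e-18)
})

test_that("a constant candidate leaves minus the scaled right-hand side", {
  sys <- fbccm_system(orders = rep(1, 5))
  y0 <- fbccm_initial_state()
  cand <- gslp_candidate(coeffs = lapply(1:5, function(l) c(y0[[l]], 0)),
                         alphas = lapply(1:5, function(l) 0))
  r <- gslp_residuals_at(cand, 0.4, sys)
  ref <- -fbccm_rhs_classical(unname(y0), fbccm_parameters()) / sys$scales
  expect_equal(unname(drop(r)), ref)
})

test_that("every coefficient influences some residual", {
  sys <- fbccm_system(orders = c(0.5, 0.6, 0.7, 0.8, 0.9))
  set.seed(22)
  cand <- random_fbccm_candidate(rep(2L, 5), sys$scales)
  tt <- c(0.2, 0.5, 0.9)
  r0 <- gslp_residuals_at(cand, tt, sys)
  for (l in 1:5) {
    for (j in 1:3) {
      pert <- cand
      pert$coeffs[[l]][j] <- pert$coeffs[[l]][j] * 1.01 + sys$scales[l] * 1e-3
      expect_gt(max(abs(gslp_residuals_at(pert, tt, sys) - r0)), 0)
    }
  }
})

test_that("objective is a quadrature of the squared residuals", {
  # positive shifts keep every residual exponent above the order, so the
  # integrand is smooth and the two rules must agree closely
  sys <- fbccm_system(orders = rep(0.5, 5))
  set.seed(23)
  # states stay near half their scale so no Michaelis denominator gets
  # close to zero anywhere on the horizon
  cand <- gslp_candidate(
    coeffs = lapply(1:5, function(l)
      c(0.5, rnorm(2, 0, 0.05)) * sys$scales[l]),
    alphas = lapply(1:5, function(l) c(0.3, 0.3)))
  quad <- quadrature_rule(128, 1)
  M <- gslp_objective(cand, sys, quad)
  expect_gte(M, 0)
  # brute-force trapezoid reference on a fine grid
  tg <- seq(1e-8, 1, length.out = 100001)
  integ <- colSums(gslp_residuals_at(cand, tg, sys)^2)
  Mref <- sum((integ[-1] + integ[-length(integ)]) / 2 * diff(tg))
  expect_equal(M, Mref, tolerance = 1e-5)
})

test_that("objective is quadratic under residual scaling", {
  # zero forcing and zero initial state: residual is linear in the coeffs
  sys <- fractional_system(rhs = function(t, y) 0,
                           jac = function(t, y) matrix(0, 1, 1),
                           orders = 0.6, y0 = 0, state_names = "y")
  cand1 <- gslp_candidate(coeffs = list(c(0.3, -0.2, 0.4)),
                          alphas = list(c(0.1, -0.2)))
  cand2 <- gslp_candidate(coeffs = list(2 * c(0.3, -0.2, 0.4)),
                          alphas = list(c(0.1, -0.2)))
  quad <- quadrature_rule(32, 1)
  expect_equal(gslp_objective(cand2, sys, quad),
               4 * gslp_objective(cand1, sys, quad), tolerance = 1e-12)
})

test_that("Lagrangian reduces to the objective when it should", {
  sys <- fbccm_system(orders = rep(0.9, 5))
  set.seed(24)
  cand <- random_fbccm_candidate(rep(2L, 5), sys$scales)
  quad <- quadrature_rule(32, 1)
  M <- gslp_objective(cand, sys, quad)
  expect_equal(gslp_lagrangian(cand, rep(0, 5), sys, quad), M)
  # feasible candidate: constraints vanish, any multipliers give J = M
  y0 <- fbccm_initial_state()
  feas <- gslp_candidate(coeffs = lapply(1:5, function(l) c(y0[[l]], 0, 0)),
                         alphas = cand$alphas)
  Mf <- gslp_objective(feas, sys, quad)
  expect_equal(gslp_lagrangian(feas, rnorm(5), sys, quad), Mf)
  # linear in the multipliers
  l1 <- rnorm(5); l2 <- rnorm(5)
  expect_equal(gslp_lagrangian(cand, l1 + l2, sys, quad) - M,
               (gslp_lagrangian(cand, l1, sys, quad) - M) +
                 (gslp_lagrangian(cand, l2, sys, quad) - M),
               tolerance = 1e-8)
})

test_that("stationarity system matches finite differences of the Lagrangian", {
  sys <- fbccm_system(orders = c(0.5, 0.6, 0.7, 0.8, 0.9))
  quad <- quadrature_rule(24, 1)
  set.seed(25)
  for (rep in 1:3) {
    cand <- random_fbccm_candidate(rep(2L, 5), sys$scales, alpha_range = 0.25)
    lam <- rnorm(5, 0, 1e-3)
    g <- gslp_stationarity(cand, lam, sys, quad)
    # multiplier block reproduces the constraints identically
    expect_equal(unname(g[grepl("^theta_", names(g))]),
                 unname(gslp_constraints(cand, sys)))
    pk <- c(unlist(cand$coeffs), unlist(cand$alphas), lam)
    obj <- function(x) {
      cc <- split(x[1:15], rep(1:5, each = 3))
      aa <- split(x[16:25], rep(1:5, each = 2))
      gslp_lagrangian(gslp_candidate(cc, aa), x[26:30], sys, quad)
    }
    gfd <- vapply(seq_along(pk), function(i) {
      h <- 1e-6 * max(abs(pk[i]), 1e-2)
      xp <- pk; xm <- pk
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (obj(xp) - obj(xm)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
  }
})

test_that("the solver recovers a representable manufactured solution", {
  sys <- manufactured_system(p = 1.3, eta = 0.7)
  fit <- gslp_solve(sys, m = 1, alphas = list(0.3), multistart = 2,
                    seed = 1, warm_start = FALSE)
  tt <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(predict(fit, tt)$y - tt^1.3)), 1e-8)
  expect_lt(fit$objective, 1e-16)
  expect_lt(max(abs(fit$constraints)), 1e-10)
})

test_that("enlarging the basis does not worsen the optimum", {
  sys <- manufactured_system(p = 2.6, eta = 0.9)
  f1 <- gslp_solve(sys, m = 1, multistart = 3, seed = 1, warm_start = FALSE,
                   nquad = 48, max_nquad = 48)
  f2 <- gslp_solve(sys, m = 2, multistart = 3, seed = 1, warm_start = FALSE,
                   nquad = 48, max_nquad = 48)
  expect_lte(f2$objective, f1$objective * (1 + 1e-6) + 1e-18)
})

test_that("fitted solutions satisfy constraints and expose diagnostics", {
  sys <- manufactured_system(p = 1.5, eta = 0.5)
  fit <- gslp_solve(sys, m = 2, multistart = 2, seed = 3, warm_start = FALSE,
                    nquad = 32, max_nquad = 64)
  expect_s3_class(fit, "gslp_fit")
  expect_lt(max(abs(fit$constraints)), 1e-8)
  expect_true(is.finite(fit$stationarity_norm))
  expect_true(fit$objective >= 0)
  expect_output(print(fit), "objective")
  expect_output(print(summary(fit)), "Exponent shifts")
  expect_named(coef(fit), "y")
  expect_equal(deviance(fit), fit$objective)
})

test_that("prediction reproduces initial conditions and rejects bad grids", {
  sys <- manufactured_system(p = 1.5, eta = 0.5)
  fit <- gslp_solve(sys, m = 2, multistart = 1, seed = 1, warm_start = FALSE,
                    nquad = 32, max_nquad = 32)
  tr <- predict(fit, times = c(0, 0.5, 1))
  expect_equal(nrow(tr), 3)
  expect_lt(abs(tr$y[1] - 0), 1e-9)
  expect_error(predict(fit, times = c(0.5, 2)), "horizon")
  r <- residuals(fit)
  expect_equal(dim(r), c(1L, length(fit$quad$nodes)))
})
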