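test_that("SLP coefficient matrix matches the closed form on small sizes", {
  expect_identical(slp_coefficient_matrix(0), matrix(1, 1, 1))
  P1 <- slp_coefficient_matrix(1)
  expect_identical(P1[1, ], c(1, 0))
  expect_identical(P1[2, ], c(-1, 2))          # L_1(t) = 2t - 1
  P2 <- slp_coefficient_matrix(2)
  expect_identical(P2[3, ], c(1, -6, 6))       # L_2(t) = 6t^2 - 6t + 1
  expect_error(slp_coefficient_matrix(-1), "non-negative")
})

test_that("factorial-formula matrix equals the recurrence-built matrix exactly", {
  for (n in c(3L, 7L, 10L, 12L)) {
    expect_identical(slp_coefficient_matrix(n), slp_matrix_by_recurrence(n))
  }
})

test_that("SLP endpoint identities hold exactly up to degree 12", {
  for (j in 0:12) {
    expect_identical(eval_slp(j, 0), (-1)^j)
    expect_identical(eval_slp(j, 1), 1)
  }
  expect_equal(eval_slp(2, 0.5), -0.5)
  expect_error(eval_slp(3, 1.2), "\\[0, 1\\]")
})

test_that("analytic form agrees with the three-term recurrence on a grid", {
  tgrid <- seq(0, 1, by = 0.1)
  for (j in 2:15) {
    P <- slp_matrix_by_recurrence(j)
    ref <- drop(outer(tgrid, 0:j, "^") %*% P[j + 1L, ])
    expect_equal(eval_slp(j, tgrid), ref, tolerance = 1e-9)
  }
})

test_that("GSLP coefficient matrix follows the factorial rule with unit first row", {
  Q1 <- gslp_q_matrix(1)
  expect_identical(Q1, matrix(c(1, -1, 0, 2), 2, 2))
  Q2 <- gslp_q_matrix(2)
  expect_identical(Q2[3, ], c(1, -6, 6))
  expect_identical(Q2[1, ], c(1, 0, 0))
  expect_identical(Q2[2, 3], 0)                # k < j zero rule
  expect_error(gslp_q_matrix(0), ">= 1")
})

test_that("generalized monomial vector handles shifts, t = 0 and t = 1", {
  b <- gslp_basis(2)
  expect_equal(gslp_psi(b, 0.5), c(1, 0.5, 0.25))
  ba <- gslp_basis(3, alphas = c(0.37, -0.81, 0.2))
  expect_equal(gslp_psi(ba, 1), rep(1, 4))
  expect_equal(gslp_psi(ba, 0), c(1, 0, 0, 0))
  bh <- gslp_basis(1, alphas = 0.5)
  expect_equal(gslp_psi(bh, 0.25), c(1, 0.125))   # 0.25^1.5
  expect_error(gslp_basis(2, alphas = c(-1, 0)), "> 0")
})

test_that("GSLP expansion evaluation is consistent with the SLP and linear", {
  b <- gslp_basis(4)
  expect_equal(eval_gslp_expansion(c(1, 0, 0, 0, 0), b, c(0.1, 0.7)), c(1, 1))
  expect_equal(eval_gslp_expansion(c(0, 0, 1, 0, 0), b, 0.5), eval_slp(2, 0.5))
  expect_equal(eval_gslp_expansion(c(3.5, 0, 0, 0, 0), b, 0.42), 3.5)
  set.seed(11)
  cf <- rnorm(5)
  tg <- seq(0, 1, length.out = 21)
  ref <- Reduce(`+`, lapply(0:4, function(j) cf[j + 1] * eval_slp(j, tg)))
  expect_equal(eval_gslp_expansion(cf, b, tg), ref, tolerance = 1e-12)
  expect_error(eval_gslp_expansion(1:3, b, 0.5), "length")
})

test_that("operational matrix diagonal matches the Gamma-ratio rule", {
  op <- caputo_operational_matrix(gslp_basis(2), eta = 1)
  expect_equal(op$diag, c(0, 1, 2))
  op2 <- caputo_operational_matrix(gslp_basis(1), eta = 0.5)
  expect_equal(op2$diag[2], gamma(2) / gamma(1.5))
  expect_identical(op2$diag[1], 0)
  expect_error(caputo_operational_matrix(gslp_basis(1), 1.2), "\\(0, 1\\]")
})

test_that("operational matrix reproduces the Caputo derivative of each basis power", {
  alphas <- c(-0.4, 0.3, 0.15)
  b <- gslp_basis(3, alphas = alphas)
  for (eta in c(0.1, 0.5, 0.9)) {
    op <- caputo_operational_matrix(b, eta)
    for (tt in c(0.25, 0.5, 1)) {
      dvec <- caputo_psi(op, tt)
      for (j in 1:3) {
        p <- j + alphas[j]
        ref <- caputo_quadrature(function(x) x^p, eta, tt,
                                 fprime = function(x) p * x^(p - 1))
        expect_equal(dvec[j + 1L], ref, tolerance = 1e-6)
      }
      expect_identical(dvec[1L], 0)   # derivative of the constant
    }
  }
})

test_that("classical limit of the operational matrix is the ordinary derivative", {
  b <- gslp_basis(3)
  op <- caputo_operational_matrix(b, eta = 1)
  tt <- c(0.3, 0.8)
  dv <- caputo_psi(op, tt)
  expect_equal(dv[2, ], c(1, 1))            # d/dt t
  expect_equal(dv[3, ], 2 * tt)             # d/dt t^2
  expect_equal(dv[4, ], 3 * tt^2)
})
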