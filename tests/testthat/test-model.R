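test_that("baseline parameters carry the published values", {
  p <- fbccm_parameters()
  expect_equal(p$s, 1.3e4)
  expect_equal(p$tau, 2000)
  expect_equal(p$a1, 1.135e6)          # half the stem-cell capacity
  expect_equal(p$a2, p$M2 / 2)
  expect_equal(p$a3, p$M3 / 2)
  expect_equal(fbccm_parameters(tau = 0)$tau, 0)
  expect_error(fbccm_parameters(bogus = 1), "unknown parameter")
})

test_that("reference initial state matches the bundled example", {
  y0 <- fbccm_initial_state()
  expect_equal(unname(y0["C"]), 7.3710e5)
  expect_equal(unname(y0["H"]), 2.5000e7)
  expect_equal(unname(y0[c("I", "E")]), c(0, 0))
})

test_that("right-hand sides reproduce hand-computed values", {
  p <- fbccm_parameters()
  expect_equal(fbccm_rhs_classical(rep(0, 5), p), c(0, 0, 0, 1.3e4, 2000))
  expect_equal(fbccm_rhs_fractional(rep(0, 5), p, rep(1, 5)),
               c(0, 0, 0, 1.3e4, 2000))
  # logistic mid-point of the healthy compartment
  v <- fbccm_rhs_classical(c(0, 0, p$M3 / 2, 0, 0), p)
  expect_equal(v[3], 0.70 * (p$M3 / 2) * 0.5)
  # logistic term vanishes at carrying capacity
  v2 <- fbccm_rhs_fractional(c(0, 0, p$M3, 0, 0), p, c(1, 1, 1, 1, 1))
  expect_equal(v2[3], 0)
})

test_that("unit orders reduce the fractional model to the classical one", {
  p <- fbccm_parameters()
  set.seed(4)
  for (i in 1:100) {
    st <- c(runif(3, 0, 1) * c(p$M1, p$M2, p$M3), runif(1, 0, 1e5),
            runif(1, 0, 2000))
    expect_equal(fbccm_rhs_fractional(st, p, rep(1, 5)),
                 fbccm_rhs_classical(st, p))
  }
})

test_that("zero-tumor states are invariant for the C and T equations", {
  p <- fbccm_parameters()
  set.seed(5)
  for (i in 1:20) {
    st <- c(0, 0, runif(1, 0, p$M3), runif(1, 0, 1e5), runif(1, 0, 2000))
    v <- fbccm_rhs_fractional(st, p, runif(5, 0.1, 1))
    expect_identical(v[1:2], c(0, 0))
  }
})

test_that("the immune kill switch changes only the tumor equation", {
  p <- fbccm_parameters()
  st <- c(1e5, 2e6, 1e7, 5e4, 300)
  ords <- c(0.9, 0.8, 0.7, 0.95, 0.85)
  vC <- fbccm_rhs_fractional(st, p, ords, immune_kill_target = "C")
  vT <- fbccm_rhs_fractional(st, p, ords, immune_kill_target = "T")
  expect_equal(vC[-2], vT[-2])
  expect_equal(vT[2] - vC[2],
               p$gamma2^ords[2] * st[4] * (st[1] - st[2]))
})

test_that("analytic state Jacobian matches central finite differences", {
  p <- fbccm_parameters()
  ords <- c(0.9, 0.8, 0.7, 0.95, 0.85)
  set.seed(6)
  for (i in 1:5) {
    st <- c(runif(3, 0.05, 0.9) * c(p$M1, p$M2, p$M3), runif(1, 0, 1e5),
            runif(1, 0, 1500))
    J <- gslpode:::fbccm_jacobian(st, p, ords)
    Jfd <- matrix(0, 5, 5)
    for (l in 1:5) {
      h <- 1e-5 * max(abs(st[l]), 1)
      sp <- st; sm <- st
      sp[l] <- sp[l] + h; sm[l] <- sm[l] - h
      Jfd[, l] <- (fbccm_rhs_fractional(sp, p, ords) -
                     fbccm_rhs_fractional(sm, p, ords)) / (2 * h)
    }
    # normalized by the dominant entry: the right-hand sides reach 1e9
    # while some partials are 1e-7, far below central-difference noise
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("parameters and initial conditions survive a JSON round trip", {
  path <- tempfile(fileext = ".json")
  y0 <- fbccm_initial_state()
  y0["I"] <- 123
  write_fbccm_json(path, fbccm_parameters(mu = 0.5), y0)
  back <- read_fbccm_json(path)
  expect_equal(back$params$mu, 0.5)
  expect_equal(back$params$M2, 2.27e7)
  expect_equal(unname(back$y0["I"]), 123)
  unlink(path)
})

test_that("the system container validates its inputs", {
  expect_error(fractional_system(function(t, y) y, orders = c(0.5, 0.5),
                                 y0 = 1), "match")
  expect_error(fractional_system(function(t, y) y, orders = 1.5, y0 = 1),
               "\\(0, 1\\]")
  sys <- fbccm_system(orders = rep(0.9, 5))
  expect_s3_class(sys, "frac_system")
  expect_equal(sys$scales, c(2.27e6, 2.27e7, 2.5e7, 3e5, 400))
})
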