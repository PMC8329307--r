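#' Fractional Adams--Bashforth--Moulton (PECE) integrator
#'
#' Predictor-corrector time stepping for systems of Caputo fractional
#' ODEs on a uniform grid, with one convolution history per component so
#' that every equation may carry its own order. The predictor uses the
#' fractional rectangle weights
#' \eqn{b_{j,n+1} = (h^\eta/\eta)\,[(n+1-j)^\eta - (n-j)^\eta]} and the
#' corrector the fractional trapezoid weights; at \eqn{\eta = 1} the
#' scheme reduces to a classical second-order Adams method. Entirely
#' independent of the spectral machinery, it serves as the
#' cross-validation oracle for [gslp_solve()].
#'
#' @param system a [fractional_system()].
#' @param tmax end of the integration interval (days).
#' @param n_steps number of uniform steps (step size \code{tmax/n_steps}).
#' @param corrector_iters number of corrector sweeps per step.
#' @return trajectory table: data frame with column \code{t} followed by
#'   one column per state.
#' @examples
#' sys <- manufactured_system(p = 1, eta = 0.5)
#' tail(pece_solve(sys, tmax = 1, n_steps = 200), 1)  # y(1) close to 1
#' @export
pece_solve <- function(system, tmax = 1, n_steps = 400L,
                       corrector_iters = 1L) {
  stopifnot(inherits(system, "frac_system"))
  if (tmax <= 0 || n_steps < 1) stop("need tmax > 0 and n_steps >= 1")
  d <- system$dim
  h <- tmax / n_steps
  tgrid <- h * (0:n_steps)
  eta <- system$orders
  # k^eta and k^(eta+1) tables, one row per component
  kp <- outer(eta, 0:(n_steps + 1L), function(e, k) k^e)
  kp1 <- outer(eta + 1, 0:(n_steps + 1L), function(e, k) k^e)
  Y <- matrix(0, d, n_steps + 1L)
  Fv <- matrix(0, d, n_steps + 1L)
  Y[, 1L] <- system$y0
  Fv[, 1L] <- system$rhs(0, system$y0)
  if (any(!is.finite(Fv[, 1L]))) stop("instability at step 0")
  c_pred <- h^eta / eta / gamma(eta)
  c_corr <- h^eta / gamma(eta + 2)
  for (n in 0:(n_steps - 1L)) {
    j <- 0:n
    # predictor
    yp <- numeric(d)
    for (i in seq_len(d)) {
      b <- kp[i, n + 2L - j] - kp[i, n + 1L - j]   # (n+1-j)^eta - (n-j)^eta
      yp[i] <- system$y0[i] + c_pred[i] * sum(b * Fv[i, j + 1L])
    }
    if (any(!is.finite(yp))) stop("instability at step ", n + 1L)
    tn1 <- tgrid[n + 2L]
    fp <- system$rhs(tn1, yp)
    # corrector
    ynew <- yp
    for (it in seq_len(corrector_iters)) {
      for (i in seq_len(d)) {
        a0 <- kp1[i, n + 1L] - (n - eta[i]) * kp[i, n + 2L]
        aj <- if (n >= 1L) {
          jj <- 1:n
          kp1[i, n - jj + 3L] + kp1[i, n - jj + 1L] - 2 * kp1[i, n - jj + 2L]
        } else numeric(0)
        hist <- a0 * Fv[i, 1L] +
          (if (n >= 1L) sum(aj * Fv[i, 2:(n + 1L)]) else 0)
        ynew[i] <- system$y0[i] + c_corr[i] * (fp[i] + hist)
      }
      fp <- system$rhs(tn1, ynew)
    }
    if (any(!is.finite(ynew)))
      stop("instability at step ", n + 1L)
    Y[, n + 2L] <- ynew
    Fv[, n + 2L] <- fp
  }
  out <- data.frame(t = tgrid, t(Y))
  names(out) <- c("t", system$state_names)
  out
}

#' Manufactured single-equation test system
#'
#' Builds the one-dimensional system
#' \eqn{D^\eta y = \Gamma(p+1)/\Gamma(p+1-\eta)\, t^{p-\eta}},
#' \eqn{y(0) = 0}, whose exact solution is \eqn{y(t) = t^p}. The forcing
#' is the analytic Caputo derivative of the target, so any solver that
#' reproduces \eqn{t^p} exactly drives the residual to zero.
#'
#' @param p power of the exact solution (\eqn{> 0}).
#' @param eta Caputo order in \eqn{(0, 1]}.
#' @return a [fractional_system()] with an \code{exact} element.
#' @export
manufactured_system <- function(p, eta) {
  if (length(p) != 1L || is.na(p) || p <= 0) stop("'p' must be > 0")
  cp <- exp(lgamma(p + 1) - lgamma(p + 1 - eta))
  fractional_system(
    rhs = function(t, y) cp * t^(p - eta),
    jac = function(t, y) matrix(0, 1, 1),
    orders = eta, y0 = 0, state_names = "y",
    exact = function(t) t^p
  )
}

#' Compare two trajectory tables
#'
#' Interpolates \code{b} onto the time grid of \code{a} (linear) and
#' reports, per shared state column, the maximum absolute error, the
#' maximum error relative to the sup-norm of \code{a}'s component, and
#' the root-mean-square error.
#'
#' @param a,b data frames with a \code{t} column followed by state
#'   columns.
#' @return data frame with columns \code{component}, \code{max_abs},
#'   \code{max_rel}, \code{rms}.
#' @export
compare_trajectories <- function(a, b) {
  if (!("t" %in% names(a)) || !("t" %in% names(b)))
    stop("both tables need a 't' column")
  if (min(b$t) > max(a$t) || max(b$t) < min(a$t))
    stop("time ranges do not overlap")
  keep <- a$t >= min(b$t) & a$t <= max(b$t)
  if (!any(keep)) stop("no common time points")
  comps <- intersect(setdiff(names(a), "t"), setdiff(names(b), "t"))
  if (!length(comps)) stop("no shared state columns")
  out <- data.frame(component = comps, max_abs = NA_real_,
                    max_rel = NA_real_, rms = NA_real_)
  for (k in seq_along(comps)) {
    av <- a[[comps[k]]][keep]
    bv <- stats::approx(b$t, b[[comps[k]]], xout = a$t[keep])$y
    err <- abs(av - bv)
    out$max_abs[k] <- max(err)
    out$max_rel[k] <- max(err) / max(max(abs(av)), .Machine$double.xmin)
    out$rms[k] <- sqrt(mean(err^2))
  }
  out
}

#' Classical (integer-order) reference integration
#'
#' Adaptive integration of the system's right-hand sides with
#' \code{deSolve::ode} (LSODA). Intended for systems whose orders are all
#' 1, where the fractional model reduces to the classical one; the
#' fractional orders are ignored.
#'
#' @param system a [fractional_system()].
#' @param times output time grid.
#' @param ... passed to \code{deSolve::ode}.
#' @return trajectory table (data frame \code{t} + states).
#' @export
classical_solve <- function(system, times = seq(0, 1, length.out = 101L),
                            ...) {
  stopifnot(inherits(system, "frac_system"))
  sol <- deSolve::ode(
    y = system$y0, times = times,
    func = function(t, y, parms) list(system$rhs(t, y)),
    parms = NULL, rtol = 1e-9, atol = 1e-6, ...)
  out <- as.data.frame(sol)
  names(out) <- c("t", system$state_names)
  out
}
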