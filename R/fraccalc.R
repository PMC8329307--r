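#' Caputo derivative of a power function (analytic rule)
#'
#' For \eqn{p > 0} the Caputo derivative of order \eqn{\eta \in (0, 1]} of
#' \eqn{t^p} is \eqn{\Gamma(p+1)/\Gamma(p+1-\eta)\, t^{p-\eta}}; the
#' derivative of a constant (\eqn{p = 0}) vanishes. The rule holds for
#' arbitrary real \eqn{p > 0}, not only integers, and is validated in the
#' test suite against direct quadrature of the defining convolution
#' integral.
#'
#' @param p power (\eqn{\ge 0}).
#' @param eta Caputo order in \eqn{(0, 1]}.
#' @param t abscissa or vector of abscissae (\eqn{> 0}).
#' @return numeric vector of derivative values.
#' @examples
#' caputo_monomial(1, 0.5, 1)  # Gamma(2)/Gamma(1.5) = 1.128379...
#' @export
caputo_monomial <- function(p, eta, t) {
  if (length(p) != 1L || is.na(p) || p < 0) stop("'p' must be a single value >= 0")
  if (length(eta) != 1L || is.na(eta) || eta <= 0 || eta > 1)
    stop("'eta' must be in (0, 1]")
  if (any(t <= 0)) stop("'t' must be > 0")
  if (p == 0) return(rep(0, length(t)))
  exp(lgamma(p + 1) - lgamma(p + 1 - eta)) * t^(p - eta)
}

#' Caputo derivative by direct quadrature of the convolution integral
#'
#' Approximates
#' \deqn{\frac{1}{\Gamma(1-\eta)} \int_0^t (t-\xi)^{-\eta} f'(\xi)\, d\xi}
#' after removing the weakly singular kernel at \eqn{\xi = t} with the
#' substitution \eqn{u = (t-\xi)^{1-\eta}}, which turns the integral into
#' \deqn{\frac{1}{(1-\eta)\,\Gamma(1-\eta)} \int_0^{t^{1-\eta}}
#'       f'\!\left(t - u^{1/(1-\eta)}\right) du,}
#' evaluated with adaptive quadrature. Any remaining algebraic singularity
#' of \eqn{f'} at \eqn{\xi = 0} sits at the (upper) endpoint, where the
#' adaptive rule remains accurate. Serves as the independent oracle for the
#' analytic monomial rule and the operational matrix.
#'
#' @param f scalar function of one variable with integrable first
#'   derivative on \eqn{[0, t]}.
#' @param eta Caputo order in \eqn{(0, 1]}.
#' @param t abscissa (\eqn{> 0}).
#' @param fprime optional derivative of \code{f}; when \code{NULL} a
#'   five-point central finite difference is used.
#' @param rel_tol relative tolerance passed to the adaptive quadrature.
#' @param subdivisions maximum number of adaptive subintervals
#'   (\eqn{\ge 8}).
#' @return scalar derivative estimate.
#' @examples
#' caputo_quadrature(function(t) t, 0.5, 1, fprime = function(t) rep(1, length(t)))
#' @export
caputo_quadrature <- function(f, eta, t, fprime = NULL,
                              rel_tol = 1e-10, subdivisions = 500L) {
  if (length(t) != 1L || is.na(t) || t <= 0) stop("'t' must be a single value > 0")
  if (length(eta) != 1L || is.na(eta) || eta <= 0 || eta > 1)
    stop("'eta' must be in (0, 1]")
  if (subdivisions < 8L) stop("'subdivisions' must be >= 8")
  if (is.null(fprime)) {
    h0 <- 1e-5 * max(t, 1)
    fprime <- function(x) {
      h <- pmin(h0, x / 2)          # keep the stencil inside [0, t]
      (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
    }
  }
  if (eta == 1) return(fprime(t))
  om <- 1 - eta
  integrand <- function(u) fprime(pmax(t - u^(1 / om), 0))
  val <- stats::integrate(integrand, 0, t^om, rel.tol = rel_tol,
                          subdivisions = subdivisions)$value
  val / (om * gamma(om))
}
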