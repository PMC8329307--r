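#' Shifted Legendre coefficient matrix
#'
#' Lower-triangular matrix \eqn{P} mapping the monomial vector
#' \eqn{(1, t, \ldots, t^n)} to the shifted Legendre polynomials on
#' \eqn{[0, 1]}: row \eqn{j} holds the monomial coefficients of
#' \eqn{L_j(t)}, i.e. \eqn{p_{ij} = (-1)^{i+j} (i+j)! / ((i-j)! (j!)^2)}
#' for \eqn{i \ge j} and 0 otherwise.
#'
#' Entries are assembled as \code{choose(i + j, i - j) * choose(2j, j)},
#' which is an exact integer computation in double precision for every
#' basis size used here (all intermediate values stay far below 2^53).
#'
#' @param n maximum polynomial degree (integer, \eqn{\ge 0}).
#' @return numeric \eqn{(n+1) \times (n+1)} lower-triangular matrix.
#' @examples
#' slp_coefficient_matrix(2)  # row 3 is (1, -6, 6): 6 t^2 - 6 t + 1
#' @export
slp_coefficient_matrix <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer")
  P <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) {
    j <- 0:i
    P[i + 1L, j + 1L] <- (-1)^(i + j) * choose(i + j, i - j) * choose(2 * j, j)
  }
  P
}

#' Evaluate a shifted Legendre polynomial
#'
#' Analytic-form evaluation of \eqn{L_j(t)} on \eqn{[0, 1]} via its exact
#' monomial coefficients. Satisfies \eqn{L_j(0) = (-1)^j}, \eqn{L_j(1) = 1}.
#'
#' @param j degree (integer, \eqn{\ge 0}).
#' @param t abscissa or vector of abscissae in \eqn{[0, 1]}.
#' @return numeric vector of values, same length as \code{t}.
#' @examples
#' eval_slp(2, 0.5)  # -0.5
#' @export
eval_slp <- function(j, t) {
  if (length(j) != 1L || is.na(j) || j < 0 || j != floor(j))
    stop("'j' must be a single non-negative integer")
  if (any(t < 0 | t > 1)) stop("'t' must lie in [0, 1]")
  cf <- slp_coefficient_matrix(j)[j + 1L, ]
  drop(outer(t, 0:j, "^") %*% cf)
}

#' Generalized shifted Legendre coefficient matrix
#'
#' The \eqn{(m+1) \times (m+1)} lower-triangular coefficient matrix
#' \eqn{Q} acting on the generalized monomial vector
#' \eqn{\Psi(t) = (1, t^{1+\alpha_1}, \ldots, t^{m+\alpha_m})}. Its first
#' row is \eqn{(1, 0, \ldots, 0)} and rows \eqn{k \ge 1} follow the same
#' factorial rule as the shifted Legendre coefficients, so the matrix
#' numerically coincides with [slp_coefficient_matrix()] of the same size;
#' the generalization lives entirely in the exponent shifts carried by
#' \eqn{\Psi}.
#'
#' @param m basis size (integer, \eqn{\ge 1}).
#' @return numeric \eqn{(m+1) \times (m+1)} lower-triangular matrix.
#' @export
gslp_q_matrix <- function(m) {
  if (length(m) != 1L || is.na(m) || m < 1 || m != floor(m))
    stop("'m' must be a single integer >= 1")
  slp_coefficient_matrix(m)
}

#' Construct a generalized shifted Legendre basis
#'
#' A basis of size \code{m} replaces each monomial \eqn{t^j} (for
#' \eqn{j = 1, \ldots, m}) with \eqn{t^{j+\alpha_j}}; the exponent shifts
#' \eqn{\alpha_j} ("control parameters") are free real numbers subject to
#' \eqn{j + \alpha_j > 0}. With all shifts zero the basis reduces to the
#' classical shifted Legendre polynomials.
#'
#' @param m basis size (integer, \eqn{\ge 1}).
#' @param alphas numeric vector of length \code{m} of exponent shifts;
#'   defaults to all zero.
#' @return object of class \code{gslp_basis}: a list with elements
#'   \code{m}, \code{alphas}, and the coefficient matrix \code{Q}.
#' @examples
#' b <- gslp_basis(2, alphas = c(-0.5, 0.25))
#' gslp_psi(b, 0.5)
#' @export
gslp_basis <- function(m, alphas = rep(0, m)) {
  if (length(m) != 1L || is.na(m) || m < 1 || m != floor(m))
    stop("'m' must be a single integer >= 1")
  alphas <- as.numeric(alphas)
  if (length(alphas) != m) stop("'alphas' must have length m")
  if (any(!is.finite(alphas)) || any(seq_len(m) + alphas <= 0))
    stop("invalid basis: need j + alphas[j] > 0 for all j")
  structure(list(m = m, alphas = alphas, Q = gslp_q_matrix(m)),
            class = "gslp_basis")
}

#' @export
print.gslp_basis <- function(x, ...) {
  cat("Generalized shifted Legendre basis, size m =", x$m, "\n")
  cat("  exponents:", paste0(format(seq_len(x$m) + x$alphas, digits = 4),
                             collapse = ", "), "\n")
  invisible(x)
}

# exponents of the generalized monomial vector, including the leading 1
psi_exponents <- function(basis) c(0, seq_len(basis$m) + basis$alphas)

#' Generalized monomial vector
#'
#' Evaluates \eqn{\Psi(t) = (1, t^{1+\alpha_1}, \ldots, t^{m+\alpha_m})^T}
#' for a [gslp_basis()]. At \eqn{t = 0} all shifted powers vanish (the
#' validity condition \eqn{j + \alpha_j > 0} guarantees this), so
#' \eqn{\Psi(0) = (1, 0, \ldots, 0)^T}.
#'
#' @param basis a [gslp_basis()].
#' @param t abscissa (single non-negative number).
#' @return numeric vector of length \code{m + 1}.
#' @export
gslp_psi <- function(basis, t) {
  stopifnot(inherits(basis, "gslp_basis"))
  if (length(t) != 1L || is.na(t) || t < 0) stop("'t' must be a single value >= 0")
  ex <- psi_exponents(basis)
  if (t == 0) c(1, rep(0, basis$m)) else t^ex
}

# matrix of Psi columns over a vector of abscissae: (m+1) x length(tvec)
psi_matrix <- function(basis, tvec) {
  ex <- psi_exponents(basis)
  out <- outer(ex, tvec, function(e, t) t^e)
  out[1L, ] <- 1
  if (any(tvec == 0)) out[-1L, tvec == 0] <- 0
  out
}

#' Evaluate a GSLP expansion
#'
#' Computes \eqn{c^T Q \Psi(t)} for a coefficient vector \eqn{c} of length
#' \code{m + 1}.
#'
#' @param coeffs numeric coefficient vector, length \code{m + 1}.
#' @param basis a [gslp_basis()].
#' @param t abscissa or vector of abscissae (\eqn{\ge 0}).
#' @return numeric vector of expansion values.
#' @export
eval_gslp_expansion <- function(coeffs, basis, t) {
  stopifnot(inherits(basis, "gslp_basis"))
  if (length(coeffs) != basis$m + 1L)
    stop("'coeffs' must have length m + 1 = ", basis$m + 1L)
  if (any(t < 0)) stop("'t' must be >= 0")
  drop(crossprod(coeffs, basis$Q %*% psi_matrix(basis, t)))
}

#' Caputo operational matrix of a GSLP basis
#'
#' The Caputo derivative of order \eqn{\eta \in (0, 1]} acts diagonally on
#' the generalized monomial vector:
#' \eqn{D^\eta t^{j+\alpha_j} =
#'   \Gamma(j+1+\alpha_j)/\Gamma(j+1-\eta+\alpha_j)\, t^{j+\alpha_j-\eta}},
#' and annihilates the constant. The operational matrix is stored as the
#' diagonal of Gamma ratios together with the shared \eqn{t^{-\eta}}
#' factor; [caputo_psi()] applies it with the exponents combined
#' analytically so that \eqn{t = 0} never requires \eqn{0^{-\eta}}.
#'
#' @param basis a [gslp_basis()].
#' @param eta Caputo order in \eqn{(0, 1]}.
#' @return object of class \code{caputo_opmat}: list with \code{diag}
#'   (length \code{m + 1}, first entry 0), \code{eta}, and the basis.
#' @examples
#' caputo_operational_matrix(gslp_basis(2), eta = 1)$diag  # 0 1 2
#' @export
caputo_operational_matrix <- function(basis, eta) {
  stopifnot(inherits(basis, "gslp_basis"))
  if (length(eta) != 1L || is.na(eta) || eta <= 0 || eta > 1)
    stop("'eta' must be a single order in (0, 1]")
  j <- seq_len(basis$m)
  g <- exp(lgamma(j + 1 + basis$alphas) - lgamma(j + 1 - eta + basis$alphas))
  structure(list(diag = c(0, g), eta = eta, basis = basis),
            class = "caputo_opmat")
}

#' @export
print.caputo_opmat <- function(x, ...) {
  cat("Caputo operational matrix, order eta =", x$eta,
      "(diagonal Gamma ratios, shared t^-eta factor)\n")
  print(x$diag)
  invisible(x)
}

#' Caputo derivative of the generalized monomial vector
#'
#' Applies the operational matrix to \eqn{\Psi(t)} with exponents combined
#' analytically: entry \eqn{j} equals
#' \eqn{g_j\, t^{j+\alpha_j-\eta}} where \eqn{g_j} is the Gamma-ratio
#' diagonal, entry 0 is identically 0. Exponents equal to zero yield the
#' constant \eqn{g_j} even at \eqn{t = 0}.
#'
#' @param op a [caputo_operational_matrix()].
#' @param t abscissa or vector of abscissae (\eqn{> 0}, or 0 when all
#'   combined exponents are \eqn{\ge 0}).
#' @return numeric matrix \eqn{(m+1) \times} \code{length(t)} of
#'   elementwise Caputo derivatives of \eqn{\Psi}.
#' @export
caputo_psi <- function(op, t) {
  stopifnot(inherits(op, "caputo_opmat"))
  ex <- psi_exponents(op$basis) - op$eta
  ex[1L] <- 0                      # multiplied by diag 0 anyway
  if (any(t < 0)) stop("'t' must be >= 0")
  if (any(t == 0) && any(ex[-1L] < 0))
    stop("t = 0 with a negative combined exponent")
  pw <- outer(ex, t, function(e, tt) ifelse(tt == 0 & e == 0, 1, tt^e))
  out <- op$diag * pw
  out[1L, ] <- 0
  out
}
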