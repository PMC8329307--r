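#' Baseline parameters of the breast cancer competition model
#'
#' Returns the published baseline rate, capacity and threshold constants of
#' the five-compartment breast cancer competition model (cancer stem cells
#' C, tumor cells T, healthy cells H, immune cells I, excess estrogen E).
#' Time is measured in days; capacities and thresholds in cells, estrogen
#' in pg/mL. The half-saturation counts default to half the corresponding
#' carrying capacity.
#'
#' @param ... named overrides of individual constants (e.g. \code{tau = 0}).
#' @return named list of class \code{fbccm_params} with elements
#'   \code{k1, k2, q, M1, M2, M3, gamma1, gamma2, gamma3, p1, p2, p3,
#'   a1, a2, a3, n1, n2, delta, s, rho, omega, u, v, tau, mu, d1, d2, d3}.
#' @examples
#' fbccm_parameters()$s     # 13000
#' fbccm_parameters(tau = 0)$tau
#' @export
fbccm_parameters <- function(...) {
  p <- list(
    k1 = 0.75, k2 = 0.514, q = 0.70,
    M1 = 2.27e6, M2 = 2.27e7, M3 = 2.5e7,
    gamma1 = 3e-7, gamma2 = 3e-6, gamma3 = 1e-7,
    p1 = 600, p2 = 0, p3 = 100,
    a1 = 2.27e6 / 2, a2 = 2.27e7 / 2, a3 = 2.5e7 / 2,
    n1 = 0.01, n2 = 0.29,
    delta = 6e-8, s = 1.3e4, rho = 0.20, omega = 3e5,
    u = 0.20, v = 400, tau = 2000, mu = 0.97,
    d1 = 0.01, d2 = 0.01, d3 = 0.01
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  structure(p, class = "fbccm_params")
}

#' Reference initial state of the breast cancer competition model
#'
#' The initial cell counts and estrogen level used by the bundled worked
#' examples: an established tumor (C and T at about a third of capacity),
#' healthy tissue at carrying capacity, and no immune activation or excess
#' estrogen yet.
#'
#' @return named numeric vector \code{(C, T, H, I, E)}.
#' @export
fbccm_initial_state <- function() {
  c(C = 7.3710e5, T = 7.6167e6, H = 2.5000e7, I = 0, E = 0)
}

# powers of every rate constant by its equation's fractional order; with
# all orders 1 this is the identity and the classical system is recovered
fbccm_powered <- function(params, orders) {
  e <- orders
  list(
    K1 = params$k1^e[1], G1 = params$gamma1^e[1], P1 = params$p1^e[1],
    K2 = params$k2^e[2], N1 = params$n1^e[2], G2 = params$gamma2^e[2],
    P2 = params$p2^e[2],
    Qd = params$q^e[3], DEL = params$delta^e[3], P3 = params$p3^e[3],
    S = params$s^e[4], RHO = params$rho^e[4], G3 = params$gamma3^e[4],
    N2 = params$n2^e[4], U = params$u^e[4],
    TAU = params$tau^e[5], MU = params$mu^e[5],
    D1 = params$d1^e[5], D2 = params$d2^e[5], D3 = params$d3^e[5]
  )
}

#' Right-hand sides of the fractional breast cancer competition model
#'
#' Evaluates the five Caputo-derivative right-hand sides with every rate
#' constant raised to the power of its equation's fractional order (the
#' dimension-correction that gives each term units of day^-eta_i). With all
#' orders equal to 1 this reduces exactly to [fbccm_rhs_classical()].
#'
#' The immune kill term in the tumor equation is \eqn{\gamma_2 I C} as
#' published; set \code{immune_kill_target = "T"} for the \eqn{\gamma_2 I T}
#' variant (a plausible intended form).
#'
#' @param state numeric 5-vector \code{(C, T, H, I, E)}.
#' @param params a [fbccm_parameters()] list.
#' @param orders numeric 5-vector of Caputo orders in \eqn{(0, 1]}.
#' @param immune_kill_target which population the immune kill term in the
#'   tumor equation multiplies: \code{"C"} (as published, default) or
#'   \code{"T"}.
#' @return numeric 5-vector of Caputo-derivative values.
#' @export
fbccm_rhs_fractional <- function(state, params, orders,
                                 immune_kill_target = c("C", "T")) {
  immune_kill_target <- match.arg(immune_kill_target)
  if (length(orders) != 5L || any(orders <= 0) || any(orders > 1))
    stop("'orders' must be five values in (0, 1]")
  C <- state[[1]]; Tc <- state[[2]]; H <- state[[3]]
  I <- state[[4]]; E <- state[[5]]
  w <- fbccm_powered(params, orders)
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3
  if (a1 + C == 0 || a2 + Tc == 0 || a3 + H == 0 ||
      params$omega + Tc == 0 || params$v + E == 0)
    stop("state hits a zero denominator")
  X <- if (immune_kill_target == "C") C else Tc
  c(
    w$K1 * C * (1 - C / params$M1) - w$G1 * I * C +
      w$P1 * C * E / (a1 + C),
    w$K2 * C * (C / params$M1) * (1 - Tc / params$M2) - w$N1 * Tc -
      w$G2 * I * X + w$P2 * Tc * E / (a2 + Tc),
    w$Qd * H * (1 - H / params$M3) - w$DEL * H * Tc -
      w$P3 * H * E / (a3 + H),
    w$S + w$RHO * I * Tc / (params$omega + Tc) - w$G3 * I * Tc -
      w$N2 * I - w$U * I * E / (params$v + E),
    w$TAU - (w$MU + w$D1 * C / (a1 + C) + w$D2 * Tc / (a2 + Tc) +
               w$D3 * H / (a3 + H)) * E
  )
}

#' Right-hand sides of the classical (integer-order) model
#'
#' @inheritParams fbccm_rhs_fractional
#' @return numeric 5-vector of time derivatives (units day^-1).
#' @export
fbccm_rhs_classical <- function(state, params,
                                immune_kill_target = c("C", "T")) {
  fbccm_rhs_fractional(state, params, orders = rep(1, 5),
                       immune_kill_target = match.arg(immune_kill_target))
}

# analytic state Jacobian of fbccm_rhs_fractional; used by the spectral
# solver's residual Jacobian
fbccm_jacobian <- function(state, params, orders,
                           immune_kill_target = "C") {
  C <- state[[1]]; Tc <- state[[2]]; H <- state[[3]]
  I <- state[[4]]; E <- state[[5]]
  w <- fbccm_powered(params, orders)
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3
  om <- params$omega; v <- params$v
  J <- matrix(0, 5, 5)
  J[1, 1] <- w$K1 * (1 - 2 * C / params$M1) - w$G1 * I +
    w$P1 * E * a1 / (a1 + C)^2
  J[1, 4] <- -w$G1 * C
  J[1, 5] <- w$P1 * C / (a1 + C)
  J[2, 1] <- 2 * w$K2 * C / params$M1 * (1 - Tc / params$M2) -
    (if (immune_kill_target == "C") w$G2 * I else 0)
  J[2, 2] <- -w$K2 * C^2 / (params$M1 * params$M2) - w$N1 +
    w$P2 * E * a2 / (a2 + Tc)^2 -
    (if (immune_kill_target == "T") w$G2 * I else 0)
  J[2, 4] <- -w$G2 * (if (immune_kill_target == "C") C else Tc)
  J[2, 5] <- w$P2 * Tc / (a2 + Tc)
  J[3, 2] <- -w$DEL * H
  J[3, 3] <- w$Qd * (1 - 2 * H / params$M3) - w$DEL * Tc -
    w$P3 * E * a3 / (a3 + H)^2
  J[3, 5] <- -w$P3 * H / (a3 + H)
  J[4, 2] <- w$RHO * I * om / (om + Tc)^2 - w$G3 * I
  J[4, 4] <- w$RHO * Tc / (om + Tc) - w$G3 * Tc - w$N2 -
    w$U * E / (v + E)
  J[4, 5] <- -w$U * I * v / (v + E)^2
  J[5, 1] <- -w$D1 * a1 / (a1 + C)^2 * E
  J[5, 2] <- -w$D2 * a2 / (a2 + Tc)^2 * E
  J[5, 3] <- -w$D3 * a3 / (a3 + H)^2 * E
  J[5, 5] <- -(w$MU + w$D1 * C / (a1 + C) + w$D2 * Tc / (a2 + Tc) +
                 w$D3 * H / (a3 + H))
  J
}

#' Define a generic Caputo fractional system
#'
#' Container for a system of Caputo fractional ODEs
#' \eqn{D^{\eta_i} y_i(t) = f_i(t, y)} with initial state \eqn{y(0)}. This
#' is the input type of [gslp_solve()] and [pece_solve()]; the bundled
#' breast cancer model is built by [fbccm_system()].
#'
#' @param rhs function \code{(t, y) -> d-vector} of right-hand sides.
#' @param orders numeric vector of Caputo orders in \eqn{(0, 1]}, one per
#'   equation.
#' @param y0 numeric initial state; its length sets the dimension.
#' @param jac optional function \code{(t, y) -> d x d matrix} of partial
#'   derivatives of \code{rhs} with respect to the state; when absent a
#'   central finite difference is used where a Jacobian is required.
#' @param scales positive state scales used to nondimensionalize the
#'   residuals (default all 1).
#' @param state_names optional character names for the components.
#' @param exact optional function \code{(t) -> d-vector} giving a known
#'   exact solution (used by manufactured test systems).
#' @return object of class \code{frac_system}.
#' @export
fractional_system <- function(rhs, orders, y0, jac = NULL,
                              scales = rep(1, length(y0)),
                              state_names = names(y0), exact = NULL) {
  d <- length(y0)
  if (length(orders) != d) stop("'orders' must match length(y0)")
  if (any(orders <= 0) || any(orders > 1)) stop("orders must lie in (0, 1]")
  if (length(scales) != d || any(scales <= 0)) stop("invalid 'scales'")
  if (is.null(state_names)) state_names <- paste0("y", seq_len(d))
  structure(list(dim = d, rhs = rhs, jac = jac, y0 = unname(as.numeric(y0)),
                 orders = as.numeric(orders), scales = as.numeric(scales),
                 state_names = state_names, exact = exact),
            class = "frac_system")
}

#' @export
print.frac_system <- function(x, ...) {
  cat("Caputo fractional system, dimension", x$dim, "\n")
  cat("  orders:", paste(format(x$orders), collapse = ", "), "\n")
  cat("  y(0):  ", paste(format(x$y0), collapse = ", "), "\n")
  invisible(x)
}

#' The fractional breast cancer competition model as a solvable system
#'
#' Wires [fbccm_rhs_fractional()], its analytic Jacobian, the baseline
#' parameters and the reference initial state into a [fractional_system()].
#' The default state scales (carrying capacities for the three cell
#' populations, the immune threshold for I and the estrogen threshold for
#' E) bring all residuals to comparable dimensionless magnitude.
#'
#' @param orders numeric 5-vector of Caputo orders in \eqn{(0, 1]}.
#' @param params a [fbccm_parameters()] list.
#' @param y0 initial state, default [fbccm_initial_state()].
#' @param scaling logical; apply the default state scales (default TRUE) or
#'   leave all scales at 1.
#' @param immune_kill_target see [fbccm_rhs_fractional()].
#' @return a [fractional_system()].
#' @examples
#' sys <- fbccm_system(orders = rep(1, 5))
#' sys$rhs(0, fbccm_initial_state())
#' @export
fbccm_system <- function(orders = rep(1, 5), params = fbccm_parameters(),
                         y0 = fbccm_initial_state(), scaling = TRUE,
                         immune_kill_target = c("C", "T")) {
  immune_kill_target <- match.arg(immune_kill_target)
  scales <- if (scaling) {
    c(params$M1, params$M2, params$M3, params$omega, params$v)
  } else rep(1, 5)
  # specialize the right-hand sides once: the order-powered rates are
  # constants of the system, not of the state
  w <- fbccm_powered(params, orders)
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3
  M1 <- params$M1; M2 <- params$M2; M3 <- params$M3
  om <- params$omega; v <- params$v
  kill_C <- immune_kill_target == "C"
  rhs <- function(t, y) {
    C <- y[1]; Tc <- y[2]; H <- y[3]; I <- y[4]; E <- y[5]
    X <- if (kill_C) C else Tc
    c(w$K1 * C * (1 - C / M1) - w$G1 * I * C + w$P1 * C * E / (a1 + C),
      w$K2 * C * (C / M1) * (1 - Tc / M2) - w$N1 * Tc - w$G2 * I * X +
        w$P2 * Tc * E / (a2 + Tc),
      w$Qd * H * (1 - H / M3) - w$DEL * H * Tc - w$P3 * H * E / (a3 + H),
      w$S + w$RHO * I * Tc / (om + Tc) - w$G3 * I * Tc - w$N2 * I -
        w$U * I * E / (v + E),
      w$TAU - (w$MU + w$D1 * C / (a1 + C) + w$D2 * Tc / (a2 + Tc) +
                 w$D3 * H / (a3 + H)) * E)
  }
  jac <- function(t, y) {
    C <- y[1]; Tc <- y[2]; H <- y[3]; I <- y[4]; E <- y[5]
    J <- matrix(0, 5, 5)
    J[1, 1] <- w$K1 * (1 - 2 * C / M1) - w$G1 * I + w$P1 * E * a1 / (a1 + C)^2
    J[1, 4] <- -w$G1 * C
    J[1, 5] <- w$P1 * C / (a1 + C)
    J[2, 1] <- 2 * w$K2 * C / M1 * (1 - Tc / M2) - (if (kill_C) w$G2 * I else 0)
    J[2, 2] <- -w$K2 * C^2 / (M1 * M2) - w$N1 + w$P2 * E * a2 / (a2 + Tc)^2 -
      (if (kill_C) 0 else w$G2 * I)
    J[2, 4] <- -w$G2 * (if (kill_C) C else Tc)
    J[2, 5] <- w$P2 * Tc / (a2 + Tc)
    J[3, 2] <- -w$DEL * H
    J[3, 3] <- w$Qd * (1 - 2 * H / M3) - w$DEL * Tc - w$P3 * E * a3 / (a3 + H)^2
    J[3, 5] <- -w$P3 * H / (a3 + H)
    J[4, 2] <- w$RHO * I * om / (om + Tc)^2 - w$G3 * I
    J[4, 4] <- w$RHO * Tc / (om + Tc) - w$G3 * Tc - w$N2 - w$U * E / (v + E)
    J[4, 5] <- -w$U * I * v / (v + E)^2
    J[5, 1] <- -w$D1 * a1 / (a1 + C)^2 * E
    J[5, 2] <- -w$D2 * a2 / (a2 + Tc)^2 * E
    J[5, 3] <- -w$D3 * a3 / (a3 + H)^2 * E
    J[5, 5] <- -(w$MU + w$D1 * C / (a1 + C) + w$D2 * Tc / (a2 + Tc) +
                   w$D3 * H / (a3 + H))
    J
  }
  fractional_system(
    rhs = rhs, jac = jac,
    orders = orders, y0 = y0, scales = scales,
    state_names = c("C", "T", "H", "I", "E")
  )
}

#' Read or write model parameters and initial conditions as JSON
#'
#' Keys are named exactly as the model symbols (\code{k1}, \code{M1},
#' \code{gamma1}, ..., \code{d3}); the initial state uses
#' \code{C0, T0, H0, I0, E0}.
#'
#' @param path file path.
#' @param params a [fbccm_parameters()] list.
#' @param y0 optional named initial state vector.
#' @return \code{read_fbccm_json()} returns a list with elements
#'   \code{params} and \code{y0}; \code{write_fbccm_json()} returns
#'   \code{path} invisibly.
#' @export
write_fbccm_json <- function(path, params = fbccm_parameters(),
                             y0 = fbccm_initial_state()) {
  obj <- c(unclass(params),
           list(C0 = y0[[1]], T0 = y0[[2]], H0 = y0[[3]],
                I0 = y0[[4]], E0 = y0[[5]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fbccm_json
#' @export
read_fbccm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ic <- c("C0", "T0", "H0", "I0", "E0")
  y0 <- fbccm_initial_state()
  have <- intersect(ic, names(obj))
  y0[match(have, ic)] <- unlist(obj[have])
  pars <- do.call(fbccm_parameters, obj[setdiff(names(obj), ic)])
  list(params = pars, y0 = y0)
}
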