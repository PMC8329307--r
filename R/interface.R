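# printed example configurations bundled with the package
example_configs <- function() {
  list(
    "1" = list(
      m = list(c(2L, 3L, 3L, 3L, 4L), c(3L, 4L, 4L, 4L, 5L)),
      orders = list(small = c(0.10, 0.15, 0.20, 0.25, 0.30),
                    near_unit = c(0.98, 0.99, 0.97, 0.98, 0.99))),
    "2" = list(
      m = list(c(4L, 4L, 5L, 7L, 7L), c(6L, 6L, 6L, 8L, 8L)),
      orders = list(small = c(0.08, 0.17, 0.13, 0.11, 0.23),
                    near_unit = c(0.96, 0.98, 0.99, 0.96, 0.95)))
  )
}

#' Run a bundled breast-cancer example configuration
#'
#' Solves the fractional breast cancer competition model with one of the
#' bundled (basis sizes, orders) configurations: two example families,
#' each with two nested basis-size cases and two order sets (strongly
#' fractional and near-unit).
#'
#' @param example example family, \code{1} or \code{2}.
#' @param case basis-size case within the family, \code{1} or \code{2}.
#' @param orders_set \code{"small"} (strongly fractional orders) or
#'   \code{"near_unit"}.
#' @param out_dir optional directory; when given, the trajectory is
#'   written as \code{trajectory.csv} (header \code{t,C,T,H,I,E}) and the
#'   solution record as \code{solution.json}.
#' @param ... further arguments to [gslp_solve()] (e.g. \code{seed},
#'   \code{multistart}).
#' @return the [gslp_solve()] fit, with the evaluated trajectory attached
#'   as attribute \code{"trajectory"} and endpoint trend flags as
#'   attribute \code{"trends"}.
#' @export
run_example <- function(example = 1, case = 1,
                        orders_set = c("small", "near_unit"),
                        out_dir = NULL, ...) {
  orders_set <- match.arg(orders_set)
  cfgs <- example_configs()
  key <- as.character(example)
  if (!key %in% names(cfgs) || !case %in% c(1, 2))
    stop("unknown example/case combination")
  cfg <- cfgs[[key]]
  sys <- fbccm_system(orders = cfg$orders[[orders_set]])
  fit <- gslp_solve(sys, m = cfg$m[[case]], ...)
  tr <- predict(fit, times = seq(0, fit$horizon, length.out = 201L))
  attr(fit, "trajectory") <- tr
  attr(fit, "trends") <- trend_flags(tr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tr, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    write_solution_json(fit, file.path(out_dir, "solution.json"))
  }
  fit
}

#' Endpoint trend flags of a trajectory
#'
#' Sign checks on the difference between the last and first row of every
#' state column: \code{-1} decreasing, \code{+1} increasing, \code{0}
#' flat (relative change below \code{tol}).
#'
#' @param trajectory data frame \code{t} + state columns.
#' @param tol relative flatness threshold.
#' @return named integer vector of trend flags.
#' @export
trend_flags <- function(trajectory, tol = 1e-9) {
  comps <- setdiff(names(trajectory), "t")
  flags <- vapply(comps, function(cn) {
    v <- trajectory[[cn]]
    dv <- v[length(v)] - v[1L]
    scale <- max(abs(v), .Machine$double.xmin)
    if (abs(dv) <= tol * scale) 0L else as.integer(sign(dv))
  }, 0L)
  flags
}

#' Serialize a fitted spectral solution as JSON
#'
#' Writes the coefficients, exponent shifts, Lagrange multipliers,
#' objective and run metadata of a [gslp_solve()] fit.
#'
#' @param fit a \code{gslp_fit}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_solution_json <- function(fit, path) {
  obj <- list(
    states = fit$system$state_names,
    orders = fit$system$orders,
    basis_sizes = fit$m,
    horizon = fit$horizon,
    objective = fit$objective,
    constraints = as.numeric(fit$constraints),
    multipliers = as.numeric(fit$multipliers),
    coefficients = fit$candidate$coeffs,
    alphas = fit$candidate$alphas,
    stationarity_norm = fit$stationarity_norm,
    quad_nodes = length(fit$quad$nodes),
    seed = fit$diagnostics$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a solve described by a JSON configuration file
#'
#' The configuration may contain: \code{orders} (5 numbers),
#' \code{basis_sizes} (5 integers), \code{horizon}, \code{nquad},
#' \code{multistart}, \code{seed}, \code{scaling} (logical),
#' \code{immune_kill_target}, \code{params} (named overrides of the model
#' constants), \code{y0} (5 numbers), and \code{out_dir}. Missing fields
#' fall back to the package defaults.
#'
#' @param config path to a JSON file, or an equivalent named list.
#' @return the [gslp_solve()] fit (with trajectory attached, as in
#'   [run_example()]).
#' @export
run_config <- function(config) {
  cf <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  orders <- cf$orders %||% rep(1, 5)
  params <- if (!is.null(cf$params)) do.call(fbccm_parameters, as.list(cf$params))
            else fbccm_parameters()
  y0 <- if (!is.null(cf$y0)) stats::setNames(as.numeric(cf$y0),
                                             c("C", "T", "H", "I", "E"))
        else fbccm_initial_state()
  sys <- fbccm_system(orders = orders, params = params, y0 = y0,
                      scaling = cf$scaling %||% TRUE,
                      immune_kill_target = cf$immune_kill_target %||% "C")
  fit <- gslp_solve(sys,
                    m = cf$basis_sizes %||% rep(3L, 5L),
                    horizon = cf$horizon %||% 1,
                    nquad = cf$nquad %||% 64L,
                    multistart = cf$multistart %||% 5L,
                    seed = cf$seed %||% 1L)
  tr <- predict(fit, times = seq(0, fit$horizon, length.out = 201L))
  attr(fit, "trajectory") <- tr
  attr(fit, "trends") <- trend_flags(tr)
  if (!is.null(cf$out_dir)) {
    dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tr, file.path(cf$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    write_solution_json(fit, file.path(cf$out_dir, "solution.json"))
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write reference fixtures for debugging and external checks
#'
#' Writes, under \code{dir}: the shifted Legendre coefficient matrices
#' for sizes 1..6 and the operational-matrix diagonals at the bundled
#' example orders (CSV), a set of seeded random candidates (JSON), and a
#' checksum manifest. Deterministic given the seed.
#'
#' @param dir output directory.
#' @param seed integer seed for the random candidates.
#' @return path of the manifest file, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  files <- character(0)
  for (m in 1:6) {
    f <- file.path(dir, sprintf("q_matrix_m%d.csv", m))
    utils::write.table(gslp_q_matrix(m), f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  cfgs <- example_configs()
  for (ex in names(cfgs)) {
    for (set in names(cfgs[[ex]]$orders)) {
      ords <- cfgs[[ex]]$orders[[set]]
      diags <- lapply(seq_along(ords), function(i) {
        op <- caputo_operational_matrix(gslp_basis(4), ords[i])
        op$diag
      })
      f <- file.path(dir, sprintf("opmat_example%s_%s.csv", ex, set))
      utils::write.table(do.call(rbind, diags), f, sep = ",",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, f)
    }
  }
  cand <- lapply(1:3, function(i) {
    m <- sample(1:4, 5, replace = TRUE)
    list(coeffs = lapply(m, function(mm) round(stats::rnorm(mm + 1), 6)),
         alphas = lapply(m, function(mm)
           round(stats::runif(mm, -0.5, 0.5), 6)))
  })
  f <- file.path(dir, "random_candidates.json")
  jsonlite::write_json(cand, f, digits = NA)
  files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
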