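# shared utilities for the test suite

# shifted Legendre coefficient rows built from the three-term recurrence
# (j+1) L_{j+1} = (2j+1)(2t-1) L_j - j L_{j-1}; all intermediates are
# exactly representable, so this is an independent oracle for the
# factorial-formula matrix
slp_matrix_by_recurrence <- function(n) {
  P <- matrix(0, n + 1L, n + 1L)
  P[1L, 1L] <- 1
  if (n >= 1L) P[2L, 1:2] <- c(-1, 2)
  if (n >= 2L) {
    for (j in 1:(n - 1L)) {
      Lj <- P[j + 1L, ]
      Ljm1 <- P[j, ]
      shifted <- c(0, Lj[-(n + 1L)])          # t * L_j
      P[j + 2L, ] <- ((2 * j + 1) * (2 * shifted - Lj) - j * Ljm1) / (j + 1)
    }
  }
  P
}

# random but well-scaled candidate for the breast-cancer system
random_fbccm_candidate <- function(m, scales, alpha_range = 0.3) {
  gslp_candidate(
    coeffs = lapply(seq_along(m), function(l)
      stats::rnorm(m[l] + 1L, 0, 1) * scales[l]),
    alphas = lapply(m, function(mm)
      stats::runif(mm, -alpha_range, alpha_range)))
}

# candidate whose single expansion is exactly t^p for a basis of size 1
# with shift p - 1: c^T Q Psi = (c0 - c1) + 2 c1 t^p
exact_power_candidate <- function(p) {
  gslp_candidate(coeffs = list(c(0.5, 0.5)), alphas = list(p - 1))
}
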