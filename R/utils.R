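# Internal helpers shared across modules.

# Fold an angle (degrees) into [0, 180). The lobe axis is a line, not a
# vector, so theta and theta + 180 are the same orientation.
fold_angle_deg <- function(theta_deg) {
  theta_deg %% 180
}

assert_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Chebyshev polynomial design matrix T_0..T_degree evaluated at t.
# Uses the three-term recurrence so evaluation extrapolates polynomially
# for |t| slightly beyond 1 (out-of-range calls are flagged by callers).
cheb_design <- function(t, degree) {
  n <- length(t)
  B <- matrix(0, n, degree + 1L)
  B[, 1L] <- 1
  if (degree >= 1L) B[, 2L] <- t
  if (degree >= 2L) {
    for (k in 3L:(degree + 1L)) {
      B[, k] <- 2 * t * B[, k - 1L] - B[, k - 2L]
    }
  }
  B
}

# Least-squares Chebyshev fit of y against x, with x rescaled to [-1, 1]
# over `xlim`. Returns coefficients plus the scaling needed to evaluate.
cheb_fit <- function(x, y, degree, xlim = range(x)) {
  t <- 2 * (x - xlim[1]) / (xlim[2] - xlim[1]) - 1
  B <- cheb_design(t, degree)
  coef <- qr.coef(qr(B), y)
  coef[is.na(coef)] <- 0
  list(coef = as.numeric(coef), degree = degree, xlim = as.numeric(xlim))
}

cheb_eval <- function(fit, x) {
  t <- 2 * (x - fit$xlim[1]) / (fit$xlim[2] - fit$xlim[1]) - 1
  drop(cheb_design(t, fit$degree) %*% fit$coef)
}

# Deterministic greedy one-to-one selection: `ord` gives the processing
# order over candidate pairs (i, j); a pair is accepted iff neither index
# has been used before. Returns logical acceptance vector.
greedy_accept <- function(i, j, ord, n_i, n_j) {
  used_i <- logical(n_i)
  used_j <- logical(n_j)
  acc <- logical(length(ord))
  for (k in ord) {
    if (!used_i[i[k]] && !used_j[j[k]]) {
      acc[k] <- TRUE
      used_i[i[k]] <- TRUE
      used_j[j[k]] <- TRUE
    }
  }
  acc
}
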