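# Shared fixtures and independent oracles for the test suite.

# A tiny hand-built cohort: 2 families x 2 children, 2-3 waves each.
make_mini_cohort <- function() {
  tibble::tibble(
    family_id = rep(c("F1", "F1", "F2", "F2"), times = c(3, 3, 2, 2)),
    child_id = rep(c("F1_1", "F1_2", "F2_1", "F2_2"), times = c(3, 3, 2, 2)),
    twin_index = rep(c(1L, 2L, 1L, 2L), times = c(3, 3, 2, 2)),
    zygosity = rep(c("MZ", "MZ", "DZ", "DZ"), times = c(3, 3, 2, 2)),
    sex = rep(c("female", "female", "male", "male"), times = c(3, 3, 2, 2)),
    wave = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 1L, 2L),
    age = c(7.1, 9.2, 11.5, 7.1, 9.2, 11.5, 8.0, 10.1, 8.0, 10.1),
    measure = "ct",
    value = c(3.0, 2.9, 2.8, 3.1, 3.0, 2.9, 2.7, 2.6, 2.8, 2.75)
  )
}

# Pair set built directly from matrices.
make_pair_set <- function(mz, dz, measure = "m", parameter = "intercept") {
  twinace:::new_pair_set(mz, dz, measure, parameter)
}

# Independent dense oracle for the ACE deviance: per pair, builds the full
# 2x2 covariance matrix and evaluates the bivariate normal -2 log density
# with solve() and determinant() — no shared code with ace_nll().
dense_ace_deviance <- function(mu, a, c, e, pairs) {
  total <- 0
  for (g in list(list(m = pairs$mz, rho_a = 1), list(m = pairs$dz, rho_a = 0.5))) {
    if (!nrow(g$m)) next
    sigma <- matrix(c(a + c + e, g$rho_a * a + c,
                      g$rho_a * a + c, a + c + e), 2, 2)
    if (det(sigma) <= 1e-300) return(1e10)
    si <- tryCatch(solve(sigma), error = function(e) NULL)
    if (is.null(si)) return(1e10)
    ld <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
    for (i in seq_len(nrow(g$m))) {
      d <- as.numeric(g$m[i, ]) - mu
      total <- total + 2 * log(2 * pi) + ld + drop(t(d) %*% si %*% d)
    }
  }
  total
}

# Vectorized profiled deviance at standardized component fractions
# (a2, c2), with the mean and total variance profiled analytically
# (weighted mean and mean quadratic form, derived independently of the
# package internals). Expects already-standardized pair matrices.
make_dev_at <- function(mz, dz) {
  n_m <- nrow(mz); n_d <- nrow(dz); n <- n_m + n_d
  s1_m <- sum(mz); s2_m <- sum(mz^2); s12_m <- sum(mz[, 1] * mz[, 2])
  s1_d <- sum(dz); s2_d <- sum(dz^2); s12_d <- sum(dz[, 1] * dz[, 2])
  function(a2, c2) {
    r_m <- pmin(a2 + c2, 1 - 1e-7)
    r_d <- pmin(0.5 * a2 + c2, 1 - 1e-7)
    w_m <- 1 / (1 + r_m); w_d <- 1 / (1 + r_d)
    mu <- (w_m * s1_m + w_d * s1_d) / (2 * (n_m * w_m + n_d * w_d))
    q_m <- (s2_m - 2 * mu * s1_m + 2 * n_m * mu^2 -
              2 * r_m * (s12_m - mu * s1_m + n_m * mu^2)) / (1 - r_m^2)
    q_d <- (s2_d - 2 * mu * s1_d + 2 * n_d * mu^2 -
              2 * r_d * (s12_d - mu * s1_d + n_d * mu^2)) / (1 - r_d^2)
    s2hat <- (q_m + q_d) / (2 * n)
    ifelse(s2hat > 0,
           2 * n * log(2 * pi) + 2 * n * log(s2hat) +
             n_m * log(1 - r_m^2) + n_d * log(1 - r_d^2) + 2 * n,
           Inf)
  }
}

# Brute-force grid-search oracle for the ML deviance minimum: scans the
# standardized (a2, c2) simplex on an n_grid x n_grid grid with two local
# refinements.
grid_search_deviance <- function(mz, dz, n_grid = 200, refine = 2) {
  dev_at <- make_dev_at(mz, dz)

  scan <- function(a_lo, a_hi, c_lo, c_hi, k) {
    a_seq <- seq(a_lo, a_hi, length.out = k)
    c_seq <- seq(c_lo, c_hi, length.out = k)
    g <- expand.grid(a2 = a_seq, c2 = c_seq)
    g <- g[g$a2 + g$c2 <= 1 + 1e-12 & g$a2 >= 0 & g$c2 >= 0, ]
    dev <- dev_at(g$a2, g$c2)
    i <- which.min(dev)
    list(a2 = g$a2[i], c2 = g$c2[i], dev = dev[i],
         step_a = if (length(a_seq) > 1) diff(a_seq)[1] else a_hi - a_lo,
         step_c = if (length(c_seq) > 1) diff(c_seq)[1] else c_hi - c_lo)
  }

  best <- scan(0, 1, 0, 1, n_grid)
  for (r in seq_len(refine)) {
    best <- scan(max(0, best$a2 - 2 * best$step_a),
                 min(1, best$a2 + 2 * best$step_a),
                 max(0, best$c2 - 2 * best$step_c),
                 min(1, best$c2 + 2 * best$step_c), 41)
  }
  best
}

# Standardize pair matrices the way fit_ace does (pooled z-score).
standardize_pairs <- function(pairs) {
  v <- c(pairs$mz, pairs$dz)
  ctr <- mean(v); s <- stats::sd(v)
  list(mz = (pairs$mz - ctr) / s, dz = (pairs$dz - ctr) / s)
}
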