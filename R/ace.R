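# Maximum-likelihood ACE variance-component modeling for twin pairs.
#
# Model: a twin pair's phenotypes are bivariate normal with a common mean
# mu and common variance a + c + e, where the additive-genetic variance a
# covaries fully within MZ pairs and at rate 0.5 within DZ pairs, the
# shared-environment variance c covaries fully in both, and the unique
# environment / measurement-error variance e is uncorrelated across twins:
#
#   cov_MZ = a + c,   cov_DZ = 0.5 a + c,   var = a + c + e.
#
# Because the likelihood depends on the data only through per-zygosity
# sufficient statistics (n, sum x, sum x^2, sum x1 x2), and the mean and
# the total variance have closed-form profile maximizers given the implied
# within-pair correlations, fitting reduces to a 2-D search over the
# standardized simplex: t = a2 (the heritability fraction) and
# u = c / (c + e) (the shared-environment share of the remainder).

pair_suffstats <- function(m) {
  list(n = nrow(m), s1 = sum(m), s2 = sum(m^2),
       s12 = sum(m[, 1] * m[, 2]))
}

DEV_BIG <- 1e10
RHO_CAP <- 1 - 1e-7

# Deviance (-2 log L) profiled over mu and total variance, given the
# implied within-pair correlations for the two zygosity groups.
profiled_deviance <- function(r_mz, r_dz, ss_mz, ss_dz, details = FALSE) {
  r_mz <- min(max(r_mz, -RHO_CAP), RHO_CAP)
  r_dz <- min(max(r_dz, -RHO_CAP), RHO_CAP)
  w_m <- 1 / (1 + r_mz)
  w_d <- 1 / (1 + r_dz)
  n_m <- ss_mz$n; n_d <- ss_dz$n
  n_tot <- n_m + n_d
  mu <- (w_m * ss_mz$s1 + w_d * ss_dz$s1) / (2 * (n_m * w_m + n_d * w_d))
  quad <- function(ss, r) {
    a <- ss$s2 - 2 * mu * ss$s1 + 2 * ss$n * mu^2
    b <- ss$s12 - mu * ss$s1 + ss$n * mu^2
    (a - 2 * r * b) / (1 - r^2)
  }
  q <- (if (n_m) quad(ss_mz, r_mz) else 0) + (if (n_d) quad(ss_dz, r_dz) else 0)
  sigma2 <- q / (2 * n_tot)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    return(if (details) list(dev = DEV_BIG, mu = mu, sigma2 = NA_real_) else DEV_BIG)
  }
  dev <- 2 * n_tot * log(2 * pi) + 2 * n_tot * log(sigma2) +
    n_m * log(1 - r_mz^2) + n_d * log(1 - r_dz^2) + 2 * n_tot
  if (details) list(dev = dev, mu = mu, sigma2 = sigma2) else dev
}

rho_from_fractions <- function(a2, c2) {
  list(mz = a2 + c2, dz = 0.5 * a2 + c2)
}

#' ACE model deviance for twin-pair data
#'
#' Evaluates -2 log likelihood of the ACE model at raw (unstandardized)
#' variance components: each pair contributes a bivariate-normal density
#' with mean `(mu, mu)`, variance `a + c + e`, and within-pair covariance
#' `a + c` (MZ) or `0.5 a + c` (DZ). A proposal whose implied covariance is
#' not positive definite returns a large finite deviance rather than an
#' error, so the function is safe inside optimizers.
#'
#' @param mu phenotype mean.
#' @param a,c,e non-negative variance components (phenotype units squared).
#' @param pairs a `pair_set` (see [build_pairs()]), or any list with `mz`
#'   and `dz` n x 2 matrices.
#' @return the deviance (a scalar; `1e10` for non-PD proposals).
#' @export
ace_nll <- function(mu, a, c, e, pairs) {
  if (min(a, c, e) < 0) return(DEV_BIG)
  v <- a + c + e
  covs <- c(mz = a + c, dz = 0.5 * a + c)
  total <- 0
  for (g in c("mz", "dz")) {
    m <- pairs[[g]]
    if (!nrow(m)) next
    det <- v^2 - covs[[g]]^2
    if (!(v > 0) || det <= 0) return(DEV_BIG)
    d1 <- m[, 1] - mu
    d2 <- m[, 2] - mu
    q <- (v * sum(d1^2 + d2^2) - 2 * covs[[g]] * sum(d1 * d2)) / det
    total <- total + nrow(m) * (2 * log(2 * pi) + log(det)) + q
  }
  total
}

#' Fit the ACE model to a twin-pair set by maximum likelihood
#'
#' Phenotypes are z-scored on the pooled pair sample (the standardized
#' variance fractions are invariant to this affine rescaling; it merely
#' stabilizes the optimizer and makes deviances comparable). The search
#' runs over the standardized simplex with closed-form profiling of the
#' mean and the total variance, from multiple starts that always include
#' the Falconer moment initializer `a2 = 2(r_mz - r_dz)`,
#' `c2 = 2 r_dz - r_mz` (clipped to the simplex), followed by a
#' Nelder-Mead polish of the best start.
#'
#' @param pairs a `pair_set`.
#' @param standardize z-score the phenotype before fitting (default TRUE).
#' @param min_pairs minimum per-zygosity pair count below which the fit is
#'   flagged `low_n` (default 10).
#' @return an object of class `ace_fit` with standardized components `a2`,
#'   `c2`, `e2` (summing to 1), `mu` and `sigma2` on the fitting scale,
#'   `minus2ll`, `converged`, `low_n`, and per-component `boundary` flags.
#' @export
fit_ace <- function(pairs, standardize = TRUE, min_pairs = 10) {
  if (!nrow(pairs$mz) && !nrow(pairs$dz))
    stopf("pair set is empty for both zygosities")
  low_n <- nrow(pairs$mz) < min_pairs || nrow(pairs$dz) < min_pairs

  scale_center <- 0; scale_sd <- 1
  mz <- pairs$mz; dz <- pairs$dz
  if (standardize) {
    all_vals <- c(mz, dz)
    scale_center <- mean(all_vals)
    scale_sd <- stats::sd(all_vals)
    if (!is.finite(scale_sd) || scale_sd == 0) scale_sd <- 1
    mz <- (mz - scale_center) / scale_sd
    dz <- (dz - scale_center) / scale_sd
  }
  ss_mz <- pair_suffstats(mz)
  ss_dz <- pair_suffstats(dz)

  obj <- function(par) {
    t <- min(max(par[1], 0), 1)
    u <- min(max(par[2], 0), 1)
    rho <- rho_from_fractions(t, u * (1 - t))
    profiled_deviance(rho$mz, rho$dz, ss_mz, ss_dz)
  }

  starts <- ace_starts(mz, dz)
  best <- NULL
  ok <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1, 1),
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) ok <- TRUE
  }
  if (is.null(best)) stopf("ACE optimizer failed from every start")
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  t <- min(max(best$par[1], 0), 1)
  u <- min(max(best$par[2], 0), 1)
  a2 <- t; c2 <- u * (1 - t); e2 <- (1 - u) * (1 - t)
  rho <- rho_from_fractions(a2, c2)
  det <- profiled_deviance(rho$mz, rho$dz, ss_mz, ss_dz, details = TRUE)

  structure(
    list(
      a2 = a2, c2 = c2, e2 = e2,
      mu = det$mu, sigma2 = det$sigma2,
      minus2ll = det$dev,
      converged = ok && is.finite(det$dev),
      low_n = low_n,
      boundary = c(a2 = a2 < 1e-4, c2 = c2 < 1e-4, e2 = e2 < 1e-4),
      n_mz = nrow(pairs$mz), n_dz = nrow(pairs$dz),
      measure = pairs$measure, parameter = pairs$parameter,
      scale = list(center = scale_center, sd = scale_sd)
    ),
    class = "ace_fit"
  )
}

ace_starts <- function(mz, dz) {
  starts <- list(c(0.33, 0.4), c(0.05, 0.05), c(0.8, 0.2), c(0.1, 0.8))
  r_mz <- if (nrow(mz) >= 3) suppressWarnings(stats::cor(mz[, 1], mz[, 2])) else NA
  r_dz <- if (nrow(dz) >= 3) suppressWarnings(stats::cor(dz[, 1], dz[, 2])) else NA
  if (is.finite(r_mz) && is.finite(r_dz)) {
    a20 <- min(max(2 * (r_mz - r_dz), 0), 1)          # Falconer initializer
    c20 <- min(max(2 * r_dz - r_mz, 0), 1 - a20)
    u0 <- if (a20 < 1) c20 / (1 - a20) else 0.5
    starts <- c(list(c(a20, u0)), starts)
  }
  starts
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE fit (%s / %s): a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$measure %||% "?", x$parameter %||% "?", x$a2, x$c2, x$e2))
  cat(sprintf("  n_mz = %d, n_dz = %d, -2logL = %.3f%s%s\n",
              x$n_mz, x$n_dz, x$minus2ll,
              if (!x$converged) ", NOT converged" else "",
              if (x$low_n) ", low n" else ""))
  invisible(x)
}

# Implied correlations when profiling one standardized component at value t,
# with u splitting the remaining mass between the other two components.
component_rhos <- function(component, t, u) {
  switch(component,
    a2 = rho_from_fractions(t, u * (1 - t)),
    c2 = rho_from_fractions(u * (1 - t), t),
    e2 = rho_from_fractions(u * (1 - t), (1 - u) * (1 - t)),
    stopf("unknown component '%s'", component)
  )
}

#' Profile-likelihood confidence interval for a standardized ACE component
#'
#' The interval is the set of component values whose profile deviance
#' (minimized over the mean, the total variance, and the split of the
#' remaining variance between the other two components) lies within the
#' chi-squared(1) cutoff of the fitted minimum (3.841 at the default 95%
#' level). A bound is reported as the boundary marker (`NA` with the
#' corresponding flag) when the point estimate itself sits on the 0 or 1
#' boundary; a bound of exactly 0 or 1 with the flag set means the profile
#' stays under the cutoff all the way to that boundary.
#'
#' @param fit an [fit_ace()] result.
#' @param pairs the `pair_set` the fit was computed from.
#' @param component `"a2"`, `"c2"`, or `"e2"`.
#' @param level confidence level (default 0.95).
#' @return a list with `lower`, `upper`, `boundary_lower`,
#'   `boundary_upper`, `component`, `level`.
#' @export
ace_profile_ci <- function(fit, pairs, component = c("a2", "c2", "e2"),
                           level = 0.95) {
  component <- match.arg(component)
  if (!fit$converged)
    stopf("cannot profile a non-converged fit")
  mz <- (pairs$mz - fit$scale$center) / fit$scale$sd
  dz <- (pairs$dz - fit$scale$center) / fit$scale$sd
  ss_mz <- pair_suffstats(mz)
  ss_dz <- pair_suffstats(dz)

  prof <- function(t) {
    f <- function(u) {
      rho <- component_rhos(component, t, u)
      profiled_deviance(rho$mz, rho$dz, ss_mz, ss_dz)
    }
    opt <- stats::optimize(f, c(0, 1), tol = 1e-7)
    min(opt$objective, f(0), f(1))
  }

  cutoff <- stats::qchisq(level, df = 1)
  t_hat <- fit[[component]]
  dev_min <- min(fit$minus2ll, prof(t_hat))
  target <- dev_min + cutoff
  g <- function(t) prof(t) - target

  if (max(abs(c(prof(0), prof(0.5), prof(1)) - dev_min)) < 1e-8) {
    warnf("flat profile for %s: interval is [0, 1]", component)
    return(list(lower = 0, upper = 1, boundary_lower = TRUE,
                boundary_upper = TRUE, component = component, level = level))
  }

  eps <- 1e-6
  boundary_lower <- FALSE
  if (t_hat <= eps) {
    lower <- NA_real_; boundary_lower <- TRUE
  } else if (g(0) <= 0) {
    lower <- 0; boundary_lower <- TRUE
  } else {
    lower <- stats::uniroot(g, c(0, t_hat), tol = 1e-6)$root
  }
  boundary_upper <- FALSE
  if (t_hat >= 1 - eps) {
    upper <- NA_real_; boundary_upper <- TRUE
  } else if (g(1) <= 0) {
    upper <- 1; boundary_upper <- TRUE
  } else {
    upper <- stats::uniroot(g, c(t_hat, 1), tol = 1e-6)$root
  }

  list(lower = lower, upper = upper,
       boundary_lower = boundary_lower, boundary_upper = boundary_upper,
       component = component, level = level)
}

#' Batch twin correlations and ACE fits across measures and parameters
#'
#' For each measure x parameter, assembles complete pairs, computes the
#' MZ/DZ correlations and their Fisher comparison, fits the ACE model, and
#' (optionally) profiles the 95% confidence interval of each component.
#' Per-key failures are caught and reported as flagged rows; the batch
#' always completes.
#'
#' @param growth a [fit_subject_lines()] table.
#' @param meta pedigree metadata (see [build_pairs()]).
#' @param measures measures to fit; `NULL` for all in `growth`.
#' @param parameters growth parameters to fit.
#' @param ci compute profile-likelihood CIs (default TRUE).
#' @param level CI level.
#' @param quiet suppress per-key logging.
#' @return a tibble, one row per measure x parameter, with correlation
#'   columns, `a2`/`c2`/`e2`, CI bounds (`*_lo` is `NA` at the 0 boundary,
#'   mirroring the reference table's printed boundary marker), and flags.
#' @export
fit_ace_all <- function(growth, meta, measures = NULL,
                        parameters = c("intercept", "slope"),
                        ci = TRUE, level = 0.95, quiet = TRUE) {
  measures <- measures %||% unique(growth$measure)
  grid <- expand.grid(measure = measures, parameter = parameters,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$measure[i]; p <- grid$parameter[i]
    tryCatch({
      pairs <- build_pairs(growth, meta, m, p, quiet = quiet)
      corr <- correlate_pairs(pairs)
      fit <- fit_ace(pairs)
      row <- dplyr::bind_cols(
        corr,
        tibble::tibble(a2 = fit$a2, c2 = fit$c2, e2 = fit$e2,
                       minus2ll = fit$minus2ll,
                       converged = fit$converged, low_n = fit$low_n,
                       error = NA_character_)
      )
      if (ci && fit$converged) {
        for (comp in c("a2", "c2", "e2")) {
          ci_k <- ace_profile_ci(fit, pairs, comp, level = level)
          row[[paste0(comp, "_lo")]] <- ci_k$lower
          row[[paste0(comp, "_hi")]] <- ci_k$upper
        }
      }
      row
    }, error = function(e) {
      tibble::tibble(measure = m, parameter = p,
                     r_mz = NA_real_, p_mz = NA_real_, n_mz = NA_integer_,
                     r_dz = NA_real_, p_dz = NA_real_, n_dz = NA_integer_,
                     z_diff = NA_real_, p_diff = NA_real_,
                     a2 = NA_real_, c2 = NA_real_, e2 = NA_real_,
                     minus2ll = NA_real_, converged = FALSE, low_n = NA,
                     error = conditionMessage(e))
    })
  })
  dplyr::bind_rows(rows)
}
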