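# Maximum-likelihood ACE fitting, likelihood oracles, profile CIs.

test_that("the deviance reduces to independent univariate normals when a = c = 0", {
  withr::with_seed(7, {
    mz <- matrix(stats::rnorm(4), 2, 2)
    dz <- matrix(stats::rnorm(4), 2, 2)
  })
  pairs <- make_pair_set(mz, dz)
  got <- ace_nll(mu = 0, a = 0, c = 0, e = 1, pairs)
  expect_equal(got, -2 * sum(stats::dnorm(c(mz, dz), log = TRUE)),
               tolerance = 1e-10)
})

test_that("the deviance matches a dense bivariate-normal oracle", {
  withr::with_seed(11, {
    for (rep in 1:6) {
      pairs <- make_pair_set(matrix(stats::rnorm(10), 5, 2),
                             matrix(stats::rnorm(10), 5, 2))
      mu <- stats::rnorm(1)
      a <- stats::runif(1, 0.05, 1)
      c <- stats::runif(1, 0.05, 1)
      e <- stats::runif(1, 0.05, 1)
      expect_equal(ace_nll(mu, a, c, e, pairs),
                   dense_ace_deviance(mu, a, c, e, pairs),
                   tolerance = 1e-10)
    }
  })
})

test_that("duplicating every pair exactly doubles the deviance", {
  ps <- simulate_twin_pairs(8, 8, 0.4, 0.3, 0.3, seed = 3)
  doubled <- make_pair_set(rbind(ps$mz, ps$mz), rbind(ps$dz, ps$dz))
  d1 <- ace_nll(0.1, 0.3, 0.2, 0.5, ps)
  d2 <- ace_nll(0.1, 0.3, 0.2, 0.5, doubled)
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("non-PD proposals are optimizer-safe, not errors", {
  ps <- simulate_twin_pairs(5, 5, 0.4, 0.3, 0.3, seed = 4)
  expect_true(is.finite(ace_nll(0, 1, 1, 0, ps)) || ace_nll(0, 1, 1, 0, ps) >= 1e9)
  expect_gte(ace_nll(0, 0, 0, 0, ps), 1e9)
  expect_gte(ace_nll(0, -1, 0.5, 0.5, ps), 1e9)
})

test_that("the noiseless perfect-heritability construction drives a2 to 1", {
  withr::with_seed(5, {
    g1 <- stats::rnorm(60)
    g2 <- stats::rnorm(60)
    mz <- cbind(g1, g1)                           # r_MZ = 1 exactly
    dz_1 <- stats::rnorm(60)
    dz <- cbind(dz_1, 0.5 * dz_1 + sqrt(0.75) * g2)
  })
  fit <- fit_ace(make_pair_set(mz, dz))
  expect_gt(fit$a2, 0.95)
  expect_lt(fit$e2, 0.05)
})

test_that("equal MZ and DZ correlations put the variance on C (moment limit)", {
  # construct near-exact r_mz = r_dz = 0.4 via a shared factor
  withr::with_seed(6, {
    n <- 4000
    make <- function(n) {
      s <- stats::rnorm(n)
      cbind(sqrt(0.4) * s + sqrt(0.6) * stats::rnorm(n),
            sqrt(0.4) * s + sqrt(0.6) * stats::rnorm(n))
    }
    fit <- fit_ace(make_pair_set(make(n), make(n)))
  })
  expect_lt(fit$a2, 0.05)
  expect_equal(fit$c2, 0.4, tolerance = 0.05)
  expect_equal(fit$e2, 0.6, tolerance = 0.05)
})

test_that("fit recovers generator truth within simulation error", {
  # per-replicate estimates at n = 1000/1000 carry Monte-Carlo error of a
  # few percentage points; the mean over 20 replicates pins them down
  ests <- vapply(1:40, function(i) {
    ps <- simulate_twin_pairs(1000, 1000, 0.4, 0.3, 0.3, seed = 1900 + i)
    fit <- fit_ace(ps)
    expect_true(fit$converged)
    c(fit$a2, fit$c2, fit$e2)
  }, numeric(3))
  expect_lt(max(abs(rowMeans(ests) - c(0.4, 0.3, 0.3))), 0.04)
})

test_that("standardization identity holds on every fit", {
  for (i in 1:5) {
    a2 <- c(0.1, 0.3, 0.5, 0.0, 0.7)[i]
    ps <- simulate_twin_pairs(40, 40, a2, 0.2, 0.8 - a2, seed = 500 + i)
    fit <- fit_ace(ps)
    expect_equal(fit$a2 + fit$c2 + fit$e2, 1, tolerance = 1e-6)
    expect_true(all(c(fit$a2, fit$c2, fit$e2) >= 0))
    # reported deviance equals the raw-parameter likelihood at the optimum
    sp <- standardize_pairs(ps)
    dev <- ace_nll(fit$mu, fit$sigma2 * fit$a2, fit$sigma2 * fit$c2,
                   fit$sigma2 * fit$e2, list(mz = sp$mz, dz = sp$dz))
    expect_equal(dev, fit$minus2ll, tolerance = 1e-6)
  }
})

test_that("the fitted deviance matches the simplex grid-search oracle", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n_mz <- sample(15:30, 1)
      n_dz <- sample(15:30, 1)
      a2 <- stats::runif(1, 0, 0.7)
      c2 <- stats::runif(1, 0, 0.9 - a2)
      ps <- simulate_twin_pairs(n_mz, n_dz, a2, c2, 1 - a2 - c2)
      fit <- fit_ace(ps)
      sp <- standardize_pairs(ps)
      oracle <- grid_search_deviance(sp$mz, sp$dz)
      expect_lt(abs(fit$minus2ll - oracle$dev), 1e-4)
    }
  })
})

test_that("profile CIs bracket the estimate and mark boundaries", {
  ps <- simulate_twin_pairs(250, 250, 0.4, 0.2, 0.4, seed = 29)
  fit <- fit_ace(ps)
  ci <- ace_profile_ci(fit, ps, "a2")
  expect_true(is.finite(ci$lower) || ci$boundary_lower)
  if (is.finite(ci$lower)) expect_lte(ci$lower, fit$a2)
  expect_gte(ci$upper, fit$a2)

  # E includes measurement error: its lower bound is strictly positive
  ci_e <- ace_profile_ci(fit, ps, "e2")
  expect_true(is.finite(ci_e$lower))
  expect_gt(ci_e$lower, 0)

  # a component estimated at zero gets the boundary marker
  ps0 <- simulate_twin_pairs(200, 200, 0.6, 0, 0.4, seed = 31)
  fit0 <- fit_ace(ps0)
  if (fit0$c2 < 1e-4) {
    ci0 <- ace_profile_ci(fit0, ps0, "c2")
    expect_true(ci0$boundary_lower)
    expect_true(is.na(ci0$lower))
    expect_gt(ci0$upper, 0)
  }
})

test_that("profile CI endpoints agree with a dense deviance grid", {
  ps <- simulate_twin_pairs(25, 25, 0.5, 0.2, 0.3, seed = 37)
  fit <- fit_ace(ps)
  ci <- ace_profile_ci(fit, ps, "a2")
  # brute force: profile deviance on a fine (a2, c2) simplex grid, then
  # take per-a2 minima over c2 and read the chi-squared(1) crossing off
  # the grid
  sp <- standardize_pairs(ps)
  dev_at <- make_dev_at(sp$mz, sp$dz)
  step <- 0.002
  grid <- expand.grid(a2 = seq(0, 1, by = step), c2 = seq(0, 1, by = step))
  grid <- grid[grid$a2 + grid$c2 <= 1, ]
  grid$dev <- dev_at(grid$a2, grid$c2)
  prof <- tapply(grid$dev, grid$a2, min)
  t_grid <- as.numeric(names(prof))
  target <- min(prof) + stats::qchisq(0.95, 1)
  inside <- t_grid[prof <= target]
  expect_equal(ci$lower, min(inside), tolerance = 0.01)
  expect_equal(ci$upper, max(inside), tolerance = 0.01)
})

test_that("batch fitting is keyed, isolated, and deterministic", {
  truths <- lapply(1:4, function(i)
    generator_truth(n_families = 80, measure = paste0("m", i)))
  sim <- generate_cohort_set(truths, seed = 901)
  cohort <- sim$cohort
  growth <- fit_subject_lines(cohort, group_slope = -0.02)
  meta <- dplyr::distinct(cohort[, c("child_id", "family_id", "zygosity")])
  res <- fit_ace_all(growth, meta, ci = FALSE)
  expect_equal(nrow(res), 8)   # 4 measures x intercept/slope
  expect_true(all(is.na(res$error)))

  res2 <- fit_ace_all(growth, meta, ci = FALSE)
  expect_equal(res, res2)

  # identical seeds and truths give identical estimates across two runs
  t_same <- generator_truth(n_families = 80, measure = "x", seed = 1234)
  r_twice <- lapply(1:2, function(k) {
    s <- generate_cohort(t_same)
    g <- fit_subject_lines(s$cohort, group_slope = -0.02)
    mt <- dplyr::distinct(s$cohort[, c("child_id", "family_id", "zygosity")])
    fit_ace_all(g, mt, ci = FALSE)
  })
  expect_equal(r_twice[[1]], r_twice[[2]])

  # a failing key is isolated: measure z observed for one family only
  tiny <- cohort[cohort$measure == "m1" & cohort$family_id == "F0001", ]
  tiny$measure <- "z"
  g_bad <- fit_subject_lines(dplyr::bind_rows(cohort, tiny),
                             group_slope = -0.02)
  r_bad <- fit_ace_all(g_bad, meta, ci = FALSE)
  expect_equal(nrow(r_bad), 10)
  expect_true(all(is.na(r_bad$error[r_bad$measure != "z"])))
  expect_true(all(!r_bad$converged[r_bad$measure == "z"]))
})

test_that("a 22-measure batch mimicking the region set completes converged", {
  a2s <- rep(c(0.2, 0.35, 0.5, 0.6, 0.25, 0.45, 0.3, 0.55, 0.4, 0.15, 0.35), 2)
  truths <- lapply(seq_along(a2s), function(i) {
    generator_truth(n_families = 300, measure = sprintf("roi%02d", i),
                    a2_i = a2s[i], c2_i = 0.2, e2_i = 0.8 - a2s[i])
  })
  sim <- generate_cohort_set(truths, seed = 7001)
  growth <- fit_subject_lines(sim$cohort, group_slope = -0.02)
  meta <- dplyr::distinct(sim$cohort[, c("child_id", "family_id", "zygosity")])
  res <- fit_ace_all(growth, meta, parameters = "intercept", ci = FALSE)
  expect_equal(nrow(res), 22)
  expect_true(all(res$converged))
  expect_true(all(abs(res$a2 + res$c2 + res$e2 - 1) < 1e-6))
  # recovery within simulation error: at ~150 pairs per zygosity the
  # sampling SD of a heritability estimate is itself close to 0.15
  truth_by_m <- vapply(truths, `[[`, numeric(1), "a2_i")
  names(truth_by_m) <- vapply(truths, `[[`, character(1), "measure")
  expect_lt(mean(abs(res$a2 - truth_by_m[res$measure])), 0.2)
})
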