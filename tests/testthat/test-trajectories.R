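# Group-level age model and per-subject growth-parameter extraction.

test_that("two-point subject lines are the exact closed-form line", {
  cohort <- tibble::tibble(
    family_id = "F1", child_id = c("F1_1", "F1_1"), twin_index = 1L,
    zygosity = "MZ", sex = "female", wave = 1:2,
    age = c(7.02, 9.02), measure = "ct", value = c(2.0, 2.2)
  )
  g <- fit_subject_lines(cohort, reference_age = 7.02)
  expect_equal(g$slope, 0.1, tolerance = 1e-12)
  expect_equal(g$intercept, 2.0, tolerance = 1e-12)
  expect_equal(g$n_timepoints, 2L)
})

test_that("exactly collinear points are recovered exactly", {
  ages <- c(7.5, 9.0, 12.0)
  cohort <- tibble::tibble(
    family_id = "F1", child_id = "F1_1", twin_index = 1L, zygosity = "MZ",
    sex = "male", wave = 1:3, age = ages, measure = "ct",
    value = 3.4 - 0.031 * (ages - 7.02)
  )
  g <- fit_subject_lines(cohort, reference_age = 7.02)
  expect_equal(g$slope, -0.031, tolerance = 1e-12)
  expect_equal(g$intercept, 3.4, tolerance = 1e-12)
  # identical to lm() on the same child
  fit <- stats::lm(value ~ I(age - 7.02), data = cohort)
  expect_equal(g$intercept, unname(stats::coef(fit)[1]), tolerance = 1e-10)
  expect_equal(g$slope, unname(stats::coef(fit)[2]), tolerance = 1e-10)
})

test_that("single-timepoint children get no slope; intercept strategies differ", {
  truth <- generator_truth(n_families = 60, seed = 31,
                           wave_completion_probs = c(0.4, 0.3, 0.3))
  cohort <- generate_cohort(truth)$cohort
  g_adj <- fit_subject_lines(cohort, group_slope = truth$mu_slope)
  g_raw <- fit_subject_lines(cohort, single_strategy = "raw")
  singles <- g_adj$n_timepoints == 1
  expect_gt(sum(singles), 0)
  expect_true(all(is.na(g_adj$slope[singles])))
  expect_true(all(!is.na(g_adj$slope[!singles & !g_adj$degenerate_ages])))
  expect_true(all(g_adj$single_timepoint_adjusted[singles]))
  expect_false(any(g_raw$single_timepoint_adjusted))
  # adjusted = raw - group_slope * (age - ref) for the singles
  ref <- min(cohort$age)
  ages1 <- dplyr::summarise(dplyr::group_by(cohort, .data$child_id),
                            age1 = .data$age[1], .groups = "drop")
  ages1 <- ages1[match(g_adj$child_id[singles], ages1$child_id), ]
  delta <- g_raw$intercept[singles] - g_adj$intercept[singles]
  expect_equal(delta, truth$mu_slope * (ages1$age1 - ref), tolerance = 1e-12)
})

test_that("duplicate-age observations flag an undefined slope", {
  cohort <- tibble::tibble(
    family_id = "F1", child_id = "F1_1", twin_index = 1L, zygosity = "MZ",
    sex = "female", wave = 1:2, age = c(8, 8), measure = "ct",
    value = c(2.0, 2.2)
  )
  g <- fit_subject_lines(cohort, reference_age = 7.02)
  expect_true(is.na(g$slope))
  expect_true(g$degenerate_ages)
})

test_that("shifting the reference age is an exact intercept identity", {
  truth <- generator_truth(n_families = 50, seed = 8)
  cohort <- generate_cohort(truth)$cohort
  delta <- 1.7
  g1 <- fit_subject_lines(cohort, reference_age = 7.02,
                          group_slope = truth$mu_slope)
  g2 <- fit_subject_lines(cohort, reference_age = 7.02 + delta,
                          group_slope = truth$mu_slope)
  expect_equal(g1$slope, g2$slope, tolerance = 1e-12)
  multi <- g1$n_timepoints >= 2
  expect_equal(g2$intercept[multi], g1$intercept[multi] + g1$slope[multi] * delta,
               tolerance = 1e-12)
})

test_that("the group mixed model recovers a noiseless age slope", {
  truth <- generator_truth(n_families = 40, seed = 13, mu_slope = 0.5,
                           total_sd_intercept = 0, total_sd_slope = 0,
                           residual_sd = 0,
                           wave_completion_probs = c(0, 0.3, 0.7))
  cohort <- generate_cohort(truth)$cohort
  fit <- fit_group_lmm(cohort, "phenotype", reference_age = 7.02)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "age_c"], 0.5, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "(Intercept)"], truth$mu_intercept,
               tolerance = 1e-6)
})

test_that("group model errors on absent measures and tiny designs", {
  cohort <- make_mini_cohort()
  expect_error(fit_group_lmm(cohort, "nope"), "absent")
  one_fam <- cohort[cohort$family_id == "F1", ]
  expect_error(fit_group_lmm(one_fam, "ct"), "2 families")
})

test_that("estimated slopes track latent slopes better as noise shrinks", {
  cors <- vapply(c(0.08, 0.02, 0), function(noise) {
    truth <- generator_truth(n_families = 120, seed = 17, residual_sd = noise,
                             wave_completion_probs = c(0, 0.3, 0.7))
    sim <- generate_cohort(truth)
    g <- fit_subject_lines(sim$cohort, group_slope = truth$mu_slope)
    merged <- dplyr::inner_join(g, sim$latent, by = "child_id")
    merged <- merged[!is.na(merged$slope.x), ]
    stats::cor(merged$slope.x, merged$slope.y)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_equal(cors[3], 1, tolerance = 1e-9)
})

test_that("the group age-slope Wald interval has near-nominal coverage", {
  n_rep <- 100
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    truth <- generator_truth(n_families = 60, seed = 4000 + i,
                             mu_slope = 0.01, residual_sd = 0.05)
    cohort <- generate_cohort(truth)$cohort
    fit <- fit_group_lmm(cohort, "phenotype", reference_age = 7.02)
    co <- fit$coefficients
    est <- co$estimate[co$term == "age_c"]
    se <- co$se[co$term == "age_c"]
    covered[i] <- abs(est - 0.01) <= 1.96 * se
  }
  expect_gte(sum(covered), 88)
})

test_that("age-effect summaries star truly developing measures only", {
  # strong true slope, tiny noise: always starred at the strictest level
  truth <- generator_truth(n_families = 60, seed = 23, mu_slope = 0.05,
                           residual_sd = 0.01)
  cohort <- generate_cohort(truth)$cohort
  tab <- summarize_age_effects(cohort)
  expect_equal(tab$slope_sig, "***")

  # null slope: no star in most replicate cohorts at alpha = .05
  hits <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    truth0 <- generator_truth(n_families = 50, seed = 6000 + i, mu_slope = 0,
                              total_sd_slope = 0, residual_sd = 0.05)
    cohort0 <- generate_cohort(truth0)$cohort
    tab0 <- summarize_age_effects(cohort0)
    hits <- hits + (tab0$slope_p < 0.05)
  }
  expect_lte(hits, 8)  # ~5% type-I rate among 60 null replicates

  # stars follow the supplied thresholds (e.g. from the Sidak module):
  # a threshold below the measured p removes every star, one above keeps all
  p_obs <- tab$slope_p
  tab_tight <- summarize_age_effects(cohort, thresholds = rep(p_obs / 2, 3))
  expect_equal(tab_tight$slope_sig, "")
  tab_loose <- summarize_age_effects(cohort, thresholds = rep(1, 3))
  expect_equal(tab_loose$slope_sig, "***")
})
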