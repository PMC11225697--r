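# Group-level age trends and per-subject growth parameters.
#
# The group model is a linear mixed-effects model of the phenotype on age
# (centered at the reference age), sex, their interaction, and zygosity,
# with a random intercept per family and a random intercept + age slope per
# child. Per-subject growth parameters are ordinary least-squares lines per
# child: the intercept is the fitted value at the reference age, the slope
# the regression coefficient per year. Children seen once contribute an
# intercept only.

#' Fit the group linear mixed-effects age model for one measure
#'
#' `value ~ age_c * sex + zygosity + (1 | family_id) + (1 + age_c | child_id)`
#' fitted by REML, with `age_c = age - reference_age` so the fixed intercept
#' is the expected phenotype at the reference age. Sex is coded
#' female = 0 / male = 1 and zygosity DZ = 0 / MZ = 1. Inference on the
#' fixed effects uses Wald z statistics (a documented simplification of
#' small-sample denominator-degree-of-freedom corrections). A singular
#' random-effects fit is automatically refitted without the random slope
#' and flagged; non-convergence is flagged, never thrown.
#'
#' @param cohort a validated cohort tibble.
#' @param measure measure label to model.
#' @param reference_age age at which intercepts are estimated; defaults to
#'   the minimum age observed for the measure.
#' @return an object of class `twinace_lmm`: a list with `coefficients`
#'   (tibble of term/estimate/se/z/p), `reference_age`, `singular`,
#'   `converged`, `random_slope_dropped`, and the fitted `model`.
#' @export
fit_group_lmm <- function(cohort, measure, reference_age = NULL) {
  dat <- cohort[cohort$measure == measure, , drop = FALSE]
  if (!nrow(dat)) stopf("measure '%s' is absent from the cohort", measure)
  if (dplyr::n_distinct(dat$family_id) < 2)
    stopf("need at least 2 families to fit the group model")
  if (dplyr::n_distinct(dat$wave) < 2)
    stopf("need observations at >= 2 waves for measure '%s'", measure)

  reference_age <- reference_age %||% min(dat$age)
  dat$age_c <- dat$age - reference_age
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  dat$zygosity <- factor(dat$zygosity, levels = c("DZ", "MZ"))

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_formula <- function(f) {
    withCallingHandlers(
      tryCatch(lme4::lmer(f, data = dat, REML = TRUE, control = ctrl),
               error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    )
  }

  full <- value ~ age_c * sex + zygosity + (1 | family_id) + (1 + age_c | child_id)
  reduced <- value ~ age_c * sex + zygosity + (1 | family_id) + (1 | child_id)

  model <- fit_formula(full)
  random_slope_dropped <- FALSE
  if (inherits(model, "error") || lme4::isSingular(model, tol = 1e-5)) {
    refit <- fit_formula(reduced)
    if (!inherits(refit, "error")) {
      model <- refit
      random_slope_dropped <- TRUE
    }
  }
  if (inherits(model, "error"))
    stopf("mixed model could not be fitted for '%s': %s", measure,
          conditionMessage(model))

  converged <- length(model@optinfo$conv$lme4$messages %||% character()) == 0
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- est / se
  coefficients <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z)))
  )

  structure(
    list(
      measure = measure,
      reference_age = reference_age,
      coefficients = coefficients,
      singular = lme4::isSingular(model, tol = 1e-5),
      converged = converged,
      random_slope_dropped = random_slope_dropped,
      n_children = dplyr::n_distinct(dat$child_id),
      model = model
    ),
    class = "twinace_lmm"
  )
}

#' @export
print.twinace_lmm <- function(x, ...) {
  cat(sprintf("Group age model for '%s' (intercept at age %.2f)\n",
              x$measure, x$reference_age))
  print(as.data.frame(x$coefficients), digits = 4)
  if (x$random_slope_dropped) cat("note: random slope dropped (singular fit)\n")
  if (!x$converged) cat("note: optimizer reported convergence issues\n")
  invisible(x)
}

#' Extract per-subject growth parameters
#'
#' Fits an ordinary least-squares line of `value` on `age - reference_age`
#' per child: `intercept` is the fitted phenotype at the reference age and
#' `slope` the change per year. Children with a single timepoint get no
#' slope; their intercept is, by default, the observed value minus the
#' group fixed-effect age slope times `(age - reference_age)` (strategy
#' `"adjusted"`, which removes the mean age trend without inventing
#' subject-level slope information), or the raw observed value (strategy
#' `"raw"`). Children whose observations all share one age have an
#' undefined slope and are flagged.
#'
#' @param cohort a validated cohort tibble.
#' @param measure measure to extract; `NULL` for all measures.
#' @param reference_age reference age; defaults to the minimum age per
#'   measure.
#' @param group_slope group-level age slope (units/year) used by the
#'   `"adjusted"` single-timepoint strategy; when `NULL` it is estimated
#'   with [fit_group_lmm()].
#' @param single_strategy `"adjusted"` or `"raw"` (see above).
#' @return a tibble of `GrowthParams`: `child_id`, `measure`, `intercept`,
#'   `slope`, `n_timepoints`, `single_timepoint_adjusted`, `degenerate_ages`.
#' @export
fit_subject_lines <- function(cohort, measure = NULL, reference_age = NULL,
                              group_slope = NULL,
                              single_strategy = c("adjusted", "raw")) {
  single_strategy <- match.arg(single_strategy)
  measures <- measure %||% unique(cohort$measure)

  out <- lapply(measures, function(m) {
    dat <- cohort[cohort$measure == m, , drop = FALSE]
    if (!nrow(dat)) stopf("measure '%s' is absent from the cohort", m)
    ref <- reference_age %||% min(dat$age)

    gs <- group_slope
    if (is.null(gs) && single_strategy == "adjusted" &&
        any(table(dat$child_id) == 1)) {
      lmm <- fit_group_lmm(dat, m, reference_age = ref)
      gs <- lmm$coefficients$estimate[lmm$coefficients$term == "age_c"]
    }

    per <- dplyr::summarise(
      dplyr::group_by(dat, .data$child_id),
      n_timepoints = dplyr::n(),
      age_bar = mean(.data$age),
      value_bar = mean(.data$value),
      sxx = sum((.data$age - mean(.data$age))^2),
      sxy = sum((.data$age - mean(.data$age)) * (.data$value - mean(.data$value))),
      age1 = .data$age[1],
      value1 = .data$value[1],
      .groups = "drop"
    )

    multi <- per$n_timepoints >= 2
    degenerate <- multi & per$sxx <= 0      # repeated identical ages
    slope <- rep(NA_real_, nrow(per))
    slope[multi & !degenerate] <- per$sxy[multi & !degenerate] /
      per$sxx[multi & !degenerate]

    intercept <- rep(NA_real_, nrow(per))
    ok <- multi & !degenerate
    intercept[ok] <- per$value_bar[ok] - slope[ok] * (per$age_bar[ok] - ref)
    single <- !multi
    if (any(single)) {
      if (single_strategy == "adjusted") {
        intercept[single] <- per$value1[single] -
          gs * (per$age1[single] - ref)
      } else {
        intercept[single] <- per$value1[single]
      }
    }
    intercept[degenerate] <- per$value_bar[degenerate]

    tibble::tibble(
      child_id = per$child_id,
      measure = m,
      intercept = intercept,
      slope = slope,
      n_timepoints = per$n_timepoints,
      single_timepoint_adjusted = single & single_strategy == "adjusted",
      degenerate_ages = degenerate
    )
  })
  dplyr::bind_rows(out)
}

#' Summarize group-level age effects across measures
#'
#' Fits [fit_group_lmm()] per measure and reports the fixed intercept (the
#' expected phenotype at the reference age) and the age slope with their
#' standard errors, Wald p-values, and significance stars at the supplied
#' thresholds (the first threshold may come from [sidak_threshold()]).
#'
#' @param cohort a validated cohort tibble.
#' @param measures measures to summarize; `NULL` for all.
#' @param thresholds decreasing significance thresholds for the 1/2/3-star
#'   labels.
#' @param reference_age passed to [fit_group_lmm()].
#' @return a tibble, one row per measure.
#' @export
summarize_age_effects <- function(cohort, measures = NULL,
                                  thresholds = c(0.05, 0.01, 0.001),
                                  reference_age = NULL) {
  measures <- measures %||% unique(cohort$measure)
  thresholds <- sort(thresholds, decreasing = TRUE)
  stars <- function(p) {
    vapply(p, function(pi) {
      paste(rep("*", sum(pi < thresholds)), collapse = "")
    }, character(1))
  }
  rows <- lapply(measures, function(m) {
    fit <- fit_group_lmm(cohort, m, reference_age = reference_age)
    co <- fit$coefficients
    pick <- function(term, col) co[[col]][co$term == term]
    tibble::tibble(
      measure = m,
      intercept = pick("(Intercept)", "estimate"),
      intercept_se = pick("(Intercept)", "se"),
      intercept_p = pick("(Intercept)", "p"),
      intercept_sig = stars(pick("(Intercept)", "p")),
      slope = pick("age_c", "estimate"),
      slope_se = pick("age_c", "se"),
      slope_p = pick("age_c", "p"),
      slope_sig = stars(pick("age_c", "p")),
      converged = fit$converged,
      singular = fit$singular
    )
  })
  dplyr::bind_rows(rows)
}
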