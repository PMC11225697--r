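# Component-reporting rules, multiple-testing thresholds for correlated
# phenotypes, and aggregation of reported variance components.

#' Decide which ACE components are reported for one measure x parameter
#'
#' Applies the three-step reporting convention used with twin correlation
#' tables:
#' \enumerate{
#'   \item report higher genetic input (A) when the MZ correlation is
#'     significantly higher than the DZ correlation (Fisher comparison
#'     significant and `r_mz > r_dz`);
#'   \item report additional shared environment (A + C pattern) when both
#'     correlations are significant but not significantly different;
#'   \item additionally report any component whose confidence interval
#'     excludes zero.
#' }
#' A row where neither within-pair correlation reaches `alpha` is not
#' reported at all. The decision records which steps fired (`rule_trace`).
#'
#' @param corr a one-row data frame or list with `r_mz`, `p_mz`, `r_dz`,
#'   `p_dz`, `p_diff` (e.g. from [correlate_pairs()]).
#' @param fit a one-row data frame or list with `a2`, `c2`, `e2` and CI
#'   bounds `a2_lo`, `c2_lo`, `e2_lo` (`NA` = boundary marker); `NULL` when
#'   no fit is available, in which case the decision is deferred.
#' @param alpha significance level for the correlation tests.
#' @return a list (`report_decision`): `reported`, `components` (character
#'   subset of A/C/E), `rule_trace`, `deferred`.
#' @export
classify_components <- function(corr, fit, alpha = 0.05) {
  if (is.null(fit)) {
    return(structure(list(reported = NA, components = character(),
                          rule_trace = character(), deferred = TRUE),
                     class = "report_decision"))
  }
  comps <- character()
  trace <- character()
  sig_mz <- isTRUE(corr$p_mz < alpha)
  sig_dz <- isTRUE(corr$p_dz < alpha)
  sig_diff <- isTRUE(corr$p_diff < alpha)

  if (sig_mz || sig_dz) {
    if (sig_diff && isTRUE(corr$r_mz > corr$r_dz)) {
      comps <- union(comps, "A")
      trace <- c(trace, "step1_A_dominant")
    }
    if (sig_mz && sig_dz && !sig_diff) {
      comps <- union(comps, c("A", "C"))
      trace <- c(trace, "step2_A_plus_C")
    }
    ci_excludes_zero <- function(lo) is.finite(lo) && lo > 0
    step3 <- c(A = ci_excludes_zero(fit$a2_lo),
               C = ci_excludes_zero(fit$c2_lo),
               E = ci_excludes_zero(fit$e2_lo))
    if (any(step3)) {
      comps <- union(comps, names(step3)[step3])
      trace <- c(trace, "step3_ci_excludes_zero")
    }
  } else {
    trace <- c(trace, "no_significant_correlation")
  }

  comps <- intersect(c("A", "C", "E"), comps)   # canonical order
  structure(list(reported = length(comps) > 0, components = comps,
                 rule_trace = trace, deferred = FALSE),
            class = "report_decision")
}

#' @export
print.report_decision <- function(x, ...) {
  if (isTRUE(x$deferred)) {
    cat("report decision deferred (no fit available)\n")
  } else if (x$reported) {
    cat("reported components:", paste(x$components, collapse = ", "),
        sprintf("(rules: %s)\n", paste(x$rule_trace, collapse = " -> ")))
  } else {
    cat("not reported\n")
  }
  invisible(x)
}

#' Sidak-type significance threshold for correlated tests
#'
#' `1 - (1 - alpha)^(1 / m_eff)` with an effective number of tests
#' `m_eff = k^(1 - r_bar)`: plain Sidak at `r_bar = 0`, approaching the
#' nominal `alpha` as the tested variables become perfectly correlated.
#' Another effective-test formula can be plugged in via `m_eff_fn`.
#'
#' @param alpha nominal significance level.
#' @param k number of tests (>= 1).
#' @param r_bar mean pairwise correlation among the tested variables, in
#'   `[0, 1]`.
#' @param m_eff_fn optional function `(k, r_bar) -> m_eff` overriding the
#'   default.
#' @return the adjusted threshold.
#' @export
sidak_threshold <- function(alpha = 0.05, k, r_bar = 0, m_eff_fn = NULL) {
  if (k < 1 || k != round(k)) stopf("k must be a positive integer")
  if (r_bar < 0 || r_bar > 1) stopf("r_bar must lie in [0, 1]")
  m_eff_fn <- m_eff_fn %||% function(k, r_bar) k^(1 - r_bar)
  m_eff <- max(1, m_eff_fn(k, r_bar))
  1 - (1 - alpha)^(1 / m_eff)
}

#' Mean pairwise correlation among phenotypes
#'
#' Mean of the upper off-diagonal triangle of the Pearson correlation
#' matrix across subjects; the input to the correlated-variables Sidak
#' threshold. Constant columns are excluded with a warning.
#'
#' @param x a numeric matrix or data frame, one column per phenotype and
#'   one row per subject, or a long [fit_subject_lines()] table together
#'   with `measures` and `parameter` to pivot.
#' @param measures,parameter optional: when `x` is a long growth table,
#'   the measures (columns of the pivot) and the growth parameter to use.
#' @return the mean pairwise correlation (scalar).
#' @export
mean_pairwise_correlation <- function(x, measures = NULL, parameter = "intercept") {
  if (is.data.frame(x) && all(c("child_id", "measure") %in% names(x))) {
    measures <- measures %||% unique(x$measure)
    x <- x[x$measure %in% measures, c("child_id", "measure", parameter)]
    x <- tidyr::pivot_wider(x, names_from = "measure",
                            values_from = dplyr::all_of(parameter))
    x <- as.matrix(x[, -1, drop = FALSE])
  } else {
    x <- as.matrix(x)
  }
  if (ncol(x) < 2) stopf("need at least 2 phenotype columns")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | !is.finite(sds))) {
    warnf("excluding %d constant column(s)", sum(sds == 0 | !is.finite(sds)))
    x <- x[, sds > 0 & is.finite(sds), drop = FALSE]
    if (ncol(x) < 2) stopf("fewer than 2 non-constant columns remain")
  }
  cm <- stats::cor(x, use = "pairwise.complete.obs")
  mean(cm[upper.tri(cm)])
}

#' Mean reported A/C/E percentages by grouping scheme
#'
#' Averages the standardized variance components over the rows flagged
#' `reported`, within groups defined by `scheme`, separately for each
#' growth parameter, and expresses them as whole percents (ties rounded
#' up). Groups present in the row set but without any reported row are
#' kept with `NA` percents (the explicit absent marker); they are never
#' reported as zero.
#'
#' @param rows a data frame with columns `network`, `roi`, `hemisphere`,
#'   `dimension`, `parameter`, `a2`, `c2`, `e2`, `reported` — e.g. the
#'   bundled [load_reference_estimates()] table or a labelled
#'   [fit_ace_all()] result.
#' @param scheme one of `"network"`, `"roi"`, `"dimension"`,
#'   `"network_dimension"`, `"hemisphere"`.
#' @return a tibble with `scheme`, `group`, `parameter`, `n_reported`,
#'   `a_pct`, `c_pct`, `e_pct`.
#' @export
aggregate_means <- function(rows, scheme = c("network", "roi", "dimension",
                                             "network_dimension", "hemisphere")) {
  scheme <- match.arg(scheme)
  rows <- tibble::as_tibble(rows)
  rows$group <- switch(scheme,
    network = rows$network,
    roi = rows$roi,
    dimension = rows$dimension,
    network_dimension = paste0(rows$network, ":", rows$dimension),
    hemisphere = rows$hemisphere
  )
  groups <- unique(rows$group)
  if (scheme == "network_dimension") {
    groups <- as.vector(outer(unique(rows$network), unique(rows$dimension),
                              paste, sep = ":"))
  }
  grid <- tidyr::expand_grid(group = groups,
                             parameter = unique(rows$parameter))

  rep_rows <- rows[rows$reported, , drop = FALSE]
  means <- dplyr::summarise(
    dplyr::group_by(rep_rows, .data$group, .data$parameter),
    n_reported = dplyr::n(),
    a_pct = round_half_up(mean(.data$a2 * 100)),
    c_pct = round_half_up(mean(.data$c2 * 100)),
    e_pct = round_half_up(mean(.data$e2 * 100)),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, means, by = c("group", "parameter"))
  out$n_reported[is.na(out$n_reported)] <- 0L
  dplyr::bind_cols(tibble::tibble(scheme = scheme), out)
}

#' Render the pipeline's summary tables to files
#'
#' Writes deterministic CSVs (stable row and column order, literal `NA`
#' for boundary/absent markers): an age-effects table, a correlations +
#' ACE-estimates table, and one mean-percentages table per grouping
#' scheme. Rerunning on identical inputs yields byte-identical files.
#'
#' @param age_effects a [summarize_age_effects()] table, or `NULL`.
#' @param estimates a labelled [fit_ace_all()] table, or `NULL`.
#' @param aggregates a list of [aggregate_means()] tables, or `NULL`.
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
render_tables <- function(age_effects = NULL, estimates = NULL,
                          aggregates = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  write_one <- function(tab, name) {
    path <- file.path(dir, name)
    tab <- dplyr::arrange(tab, dplyr::across(dplyr::any_of(
      c("scheme", "group", "measure", "parameter"))))
    readr::write_csv(tab, path, na = "NA", progress = FALSE)
    written[[name]] <<- path
  }
  if (!is.null(age_effects)) write_one(age_effects, "age_effects.csv")
  if (!is.null(estimates)) write_one(estimates, "ace_estimates.csv")
  if (!is.null(aggregates)) {
    agg <- dplyr::bind_rows(aggregates)
    write_one(agg, "mean_percentages.csv")
  }
  invisible(unlist(written))
}
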