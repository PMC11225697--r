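# End-to-end orchestration: generator -> growth parameters -> twin
# correlations -> ACE fits -> reporting, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' A small three-measure synthetic run (one measure per network, one per
#' morphological dimension) suitable for smoke tests and as a template:
#' copy, edit, and pass to [run_pipeline()] (or serialize to YAML for the
#' command-line wrapper).
#'
#' @return a nested list understood by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 20260920,
    n_families = 150,
    alpha = 0.05,
    single_strategy = "adjusted",
    fixture_only = FALSE,
    measures = list(
      list(name = "ct_demo", roi = "demo_ct", hemisphere = "right",
           dimension = "CT", network = "sensorimotor",
           truth = list(mu_intercept = 3.0, mu_slope = -0.02,
                        total_sd_intercept = 0.15, total_sd_slope = 0.02,
                        residual_sd = 0.05)),
      list(name = "sa_demo", roi = "demo_sa", hemisphere = "right",
           dimension = "SA", network = "social",
           truth = list(mu_intercept = 4000, mu_slope = 15,
                        total_sd_intercept = 350, total_sd_slope = 8,
                        residual_sd = 60,
                        a2_i = 0.45, c2_i = 0.15, e2_i = 0.40)),
      list(name = "vo_demo", roi = "demo_vo", hemisphere = "right",
           dimension = "VO", network = "affective",
           truth = list(mu_intercept = 4300, mu_slope = -14,
                        total_sd_intercept = 400, total_sd_slope = 10,
                        residual_sd = 80,
                        a2_i = 0.30, c2_i = 0.20, e2_i = 0.50))
    )
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  config$alpha <- config$alpha %||% 0.05
  config$seed <- config$seed %||% 1L
  config$single_strategy <- config$single_strategy %||% "adjusted"
  config$fixture_only <- isTRUE(config$fixture_only)
  if (!config$fixture_only) {
    n <- config$n_families
    if (is.null(n) || !is.numeric(n) || n < 1 || n != round(n))
      stopf("config error: n_families must be a positive integer")
    if (is.null(config$measures) || !length(config$measures))
      stopf("config error: at least one measure must be configured")
    for (m in config$measures) {
      if (is.null(m$name)) stopf("config error: every measure needs a name")
    }
  }
  if (config$alpha <= 0 || config$alpha >= 1)
    stopf("config error: alpha must lie in (0, 1)")
  config
}

#' Run the full twin-heritability pipeline
#'
#' Executes the stages in order — simulate each configured measure's
#' cohort (per-measure sub-seeds derived from the global seed, so results
#' do not depend on stage order), extract per-subject growth parameters,
#' fit twin correlations and ACE models, apply the reporting rules, and
#' aggregate — and writes all tables plus a JSON manifest with the config
#' snapshot, the seed, per-stage counts, and an MD5 digest of every output
#' file. With `fixture_only: true` the simulation stages are skipped and
#' the bundled reference-estimate table is aggregated instead.
#'
#' Per-measure model failures are recorded in the results (and counted in
#' the manifest); they do not abort the remaining measures.
#'
#' @param config a config list (see [default_config()]) or a YAML path.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage_log <- function(stage) {
    message(sprintf("[twinace] %s (t = %.1fs)", stage,
                    proc.time()[["elapsed"]] - t0))
  }

  if (config$fixture_only) {
    stage_log("aggregating bundled reference estimates")
    ref <- load_reference_estimates()
    aggregates <- lapply(
      c("network", "roi", "dimension", "network_dimension", "hemisphere"),
      function(s) aggregate_means(ref, s)
    )
    files <- render_tables(aggregates = aggregates, dir = out_dir)
    manifest <- build_manifest(config, files,
                               counts = list(reference_rows = nrow(ref)))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stage_log("done")
    return(invisible(manifest))
  }

  measures <- config$measures
  stage_log(sprintf("simulating %d measure(s), %d families",
                    length(measures), config$n_families))
  truths <- lapply(seq_along(measures), function(i) {
    mcfg <- measures[[i]]
    args <- c(
      list(n_families = config$n_families, measure = mcfg$name,
           seed = config$seed),
      mcfg$truth %||% list()
    )
    do.call(generator_truth, args)
  })
  sim <- generate_cohort_set(truths, config$seed)
  cohort <- sim$cohort
  validate_cohort(cohort)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)

  stage_log("extracting per-subject growth parameters")
  growth <- fit_subject_lines(cohort,
                              single_strategy = config$single_strategy)
  growth_path <- file.path(out_dir, "growth_params.csv")
  readr::write_csv(growth, growth_path, na = "NA", progress = FALSE)

  stage_log("summarizing group age effects")
  age_effects <- summarize_age_effects(cohort)

  stage_log("fitting twin correlations and ACE models")
  meta <- dplyr::distinct(cohort[, c("child_id", "family_id", "zygosity")])
  estimates <- fit_ace_all(growth, meta)

  stage_log("applying reporting rules and aggregating")
  labels <- dplyr::bind_rows(lapply(measures, function(m) {
    tibble::tibble(measure = m$name, roi = m$roi %||% m$name,
                   hemisphere = m$hemisphere %||% "right",
                   dimension = m$dimension %||% "CT",
                   network = m$network %||% "unlabelled")
  }))
  estimates <- dplyr::left_join(estimates, labels, by = "measure")
  decisions <- lapply(seq_len(nrow(estimates)), function(i) {
    row <- estimates[i, ]
    if (!isTRUE(row$converged)) return(classify_components(row, NULL))
    classify_components(row, row, alpha = config$alpha)
  })
  estimates$reported <- vapply(decisions, function(d) isTRUE(d$reported), logical(1))
  estimates$components <- vapply(decisions, function(d)
    paste(d$components, collapse = ","), character(1))

  aggregates <- lapply(
    c("network", "roi", "dimension", "network_dimension", "hemisphere"),
    function(s) aggregate_means(estimates, s)
  )
  files <- render_tables(age_effects = age_effects, estimates = estimates,
                         aggregates = aggregates, dir = out_dir)
  files <- c(files, cohort = cohort_path, growth = growth_path)

  counts <- list(
    n_families = config$n_families,
    n_measures = length(measures),
    n_children = dplyr::n_distinct(cohort$child_id),
    n_rows = nrow(cohort),
    n_fits = nrow(estimates),
    n_converged = sum(estimates$converged, na.rm = TRUE),
    n_failed = sum(!is.na(estimates$error)),
    n_reported = sum(estimates$reported)
  )
  manifest <- build_manifest(config, files, counts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_log("done")
  invisible(manifest)
}

build_manifest <- function(config, files, counts) {
  digests <- as.list(tools::md5sum(unname(unlist(files))))
  names(digests) <- basename(names(digests))
  list(
    tool = "twinace",
    version = as.character(utils::packageVersion("twinace")),
    seed = config$seed,
    config = config,
    counts = counts,
    files = digests
  )
}
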