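# Synthetic twin-cohort generator.
#
# Latent per-subject growth parameters (an intercept at the reference age and
# a linear slope per year) are drawn with a classical ACE covariance
# structure: the additive-genetic part A correlates 1 within monozygotic
# pairs and 0.5 within dizygotic pairs, the shared-environment part C is
# identical within a pair, and the unique-environment part E is independent.
# Observed values add a fixed sex effect and i.i.d. within-subject
# measurement noise at each wave.

#' Describe the generating truth of a synthetic twin cohort
#'
#' Collects and validates every knob of the simulator. Defaults emulate a
#' longitudinal twin cohort measured at up to three biennial MRI waves
#' between ages 7 and 14: wave age means 7.97/10.01/12.28 years (SDs
#' .67/.68/.74), ~53% monozygotic pairs, subjects completing 1/2/3 waves
#' with probabilities 118/206/161 out of 485, and intercepts referenced to
#' the minimum age 7.02 years. Phenotype-scale defaults are on a
#' cortical-thickness-like scale (mm).
#'
#' @param n_families number of twin pairs (families).
#' @param p_mz probability that a family is monozygotic.
#' @param measure phenotype label written into the cohort table.
#' @param mu_intercept,mu_slope population mean of the latent intercept
#'   (phenotype units at `reference_age`) and slope (units/year).
#' @param a2_i,c2_i,e2_i standardized variance components of the latent
#'   intercept; must be non-negative and sum to 1.
#' @param a2_s,c2_s,e2_s standardized variance components of the latent slope.
#' @param total_sd_intercept,total_sd_slope total SD of the latent intercept
#'   and slope (phenotype units; units/year).
#' @param sex_effect additive shift for males (phenotype units).
#' @param residual_sd SD of within-subject measurement noise per wave.
#' @param wave_age_means,wave_age_sds per-wave age means and SDs (years);
#'   means must be strictly increasing.
#' @param wave_completion_probs probabilities of completing exactly 1, 2, or
#'   3 waves; dropout is monotone (a subject with k waves has waves 1..k)
#'   and independent of the phenotype.
#' @param reference_age age (years) at which intercepts are defined.
#' @param seed integer seed; every draw of [generate_cohort()] is a pure
#'   function of the truth including this seed.
#' @return an object of class `generator_truth` (a validated list).
#' @seealso [generate_cohort()], [sample_wave_ages()], [simulate_twin_pairs()]
#' @export
generator_truth <- function(n_families = 240,
                            p_mz = 0.53,
                            measure = "phenotype",
                            mu_intercept = 3.0,
                            mu_slope = -0.02,
                            a2_i = 0.35, c2_i = 0.15, e2_i = 0.50,
                            a2_s = 0.20, c2_s = 0.10, e2_s = 0.70,
                            total_sd_intercept = 0.15,
                            total_sd_slope = 0.02,
                            sex_effect = 0,
                            residual_sd = 0.05,
                            wave_age_means = c(7.97, 10.01, 12.28),
                            wave_age_sds = c(0.67, 0.68, 0.74),
                            wave_completion_probs = c(118, 206, 161) / 485,
                            reference_age = 7.02,
                            seed = 1L) {
  truth <- structure(
    list(
      n_families = n_families, p_mz = p_mz, measure = measure,
      mu_intercept = mu_intercept, mu_slope = mu_slope,
      a2_i = a2_i, c2_i = c2_i, e2_i = e2_i,
      a2_s = a2_s, c2_s = c2_s, e2_s = e2_s,
      total_sd_intercept = total_sd_intercept,
      total_sd_slope = total_sd_slope,
      sex_effect = sex_effect, residual_sd = residual_sd,
      wave_age_means = wave_age_means, wave_age_sds = wave_age_sds,
      wave_completion_probs = wave_completion_probs,
      reference_age = reference_age, seed = as.integer(seed)
    ),
    class = "generator_truth"
  )
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  with(truth, {
    if (!is.numeric(n_families) || n_families < 1 || n_families != round(n_families))
      stopf("n_families must be a positive integer (got %s)", format(n_families))
    if (p_mz < 0 || p_mz > 1) stopf("p_mz must lie in [0, 1] (got %g)", p_mz)
    for (set in list(c(a2_i, c2_i, e2_i), c(a2_s, c2_s, e2_s))) {
      if (any(set < 0))
        stopf("variance components must be non-negative (got %s)",
              paste(format(set), collapse = ", "))
      if (abs(sum(set) - 1) > 1e-8)
        stopf("variance components must sum to 1 (got %s summing to %g)",
              paste(format(set), collapse = ", "), sum(set))
    }
    if (total_sd_intercept < 0 || total_sd_slope < 0 || residual_sd < 0)
      stopf("standard deviations must be non-negative")
    if (length(wave_age_means) != length(wave_age_sds))
      stopf("wave_age_means and wave_age_sds must have equal length")
    if (any(!is.finite(wave_age_means)) || any(!is.finite(wave_age_sds)) ||
        any(wave_age_sds < 0))
      stopf("wave age parameters must be finite with non-negative SDs")
    if (any(diff(wave_age_means) <= 0))
      stopf("wave_age_means must be strictly increasing")
    if (length(wave_completion_probs) != length(wave_age_means) ||
        any(wave_completion_probs < 0) ||
        abs(sum(wave_completion_probs) - 1) > 1e-8)
      stopf("wave_completion_probs must be non-negative and sum to 1")
  })
  invisible(truth)
}

# Draw one latent ACE variable for a set of twin pairs. Returns an n x 2
# matrix of zero-mean values with variance total_sd^2, cross-twin
# correlation a2 + c2 within MZ pairs and 0.5*a2 + c2 within DZ pairs.
draw_ace_latent <- function(zygosity, a2, c2, e2, total_sd) {
  n <- length(zygosity)
  mz <- zygosity == "MZ"
  a <- matrix(0, n, 2)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  a[mz, 1] <- z1[mz]
  a[mz, 2] <- z1[mz]                       # A shared completely in MZ pairs
  a[!mz, 1] <- z1[!mz]
  a[!mz, 2] <- 0.5 * z1[!mz] + sqrt(0.75) * z2[!mz]  # corr 0.5 in DZ pairs
  cc <- stats::rnorm(n)
  e <- matrix(stats::rnorm(2 * n), n, 2)
  total_sd * (sqrt(a2) * a + sqrt(c2) * cbind(cc, cc) + sqrt(e2) * e)
}

#' Simulate twin-pair phenotypes with a known ACE structure
#'
#' Draws complete pairs directly (no waves, no measurement noise): the
#' building block used by [generate_cohort()] for the latent growth
#' parameters, and a convenient primitive for calibration studies where
#' exact per-zygosity pair counts are wanted.
#'
#' @param n_mz,n_dz number of monozygotic / dizygotic pairs.
#' @param a2,c2,e2 standardized variance components (sum to 1).
#' @param mu phenotype mean.
#' @param total_sd total phenotype SD.
#' @param seed optional integer seed (draws from the current RNG state when
#'   `NULL`).
#' @return a `pair_set` (see [build_pairs()]) with `measure = "simulated"`.
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, a2, c2, e2,
                                mu = 0, total_sd = 1, seed = NULL) {
  if (any(c(a2, c2, e2) < 0) || abs(a2 + c2 + e2 - 1) > 1e-8)
    stopf("variance components must be non-negative and sum to 1")
  draw <- function() {
    zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
    vals <- mu + draw_ace_latent(zyg, a2, c2, e2, total_sd)
    new_pair_set(
      mz = vals[zyg == "MZ", , drop = FALSE],
      dz = vals[zyg == "DZ", , drop = FALSE],
      measure = "simulated", parameter = "latent"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Sample per-wave assessment ages
#'
#' Draws age triples for `n` sampling units from a longitudinal design
#' model: a baseline (enrollment) age at wave 1 plus per-wave revisit gaps.
#' Ages within a unit are therefore strongly correlated across waves, as
#' in a biennial follow-up design — the wave-to-wave gap varies by only a
#' fraction of a year, while the cross-sectional age spread comes mostly
#' from enrollment age. Gap SDs are derived so that the per-wave marginal
#' means and SDs converge to the configured values (`sd_gap_k^2 =
#' sd_k^2 - sd_{k-1}^2` when the configured SDs increase across waves, as
#' biennial designs imply; otherwise a small floor of 5% of the mean gap
#' is used). Draws are rejected and redrawn until every wave age lies
#' within 3 SD of its configured mean and ages strictly increase.
#'
#' @param truth a [generator_truth()].
#' @param n number of units (families, in [generate_cohort()]).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return an `n` x `n_waves` matrix of ages in years.
#' @export
sample_wave_ages <- function(truth, n, seed = NULL) {
  validate_truth(truth)
  if (n < 1 || n != round(n)) stopf("n must be a positive integer")
  mu <- truth$wave_age_means
  sd <- truth$wave_age_sds
  k <- length(mu)
  gap_mu <- diff(mu)
  gap_sd <- if (k > 1) {
    sqrt(pmax(sd[-1]^2 - sd[-k]^2, (0.05 * gap_mu)^2 * (sd[-1] > 0)))
  } else numeric()
  draw <- function() {
    ages <- matrix(0, n, k)
    todo <- rep(TRUE, n)
    while (any(todo)) {
      m <- sum(todo)
      cand <- matrix(0, m, k)
      cand[, 1] <- mu[1] + sd[1] * stats::rnorm(m)
      for (j in seq_len(k - 1)) {
        cand[, j + 1] <- cand[, j] + gap_mu[j] + gap_sd[j] * stats::rnorm(m)
      }
      dev_ok <- abs(sweep(cand, 2, mu)) <= rep(3 * sd, each = m) + 1e-12
      inc_ok <- if (k > 1) {
        cand[, -1, drop = FALSE] - cand[, -k, drop = FALSE] > 0
      } else TRUE
      ok <- rowSums(dev_ok) == k & rowSums(cbind(inc_ok)) == k - 1
      idx <- which(todo)[ok]
      ages[idx, ] <- cand[ok, , drop = FALSE]
      todo[idx] <- FALSE
    }
    ages
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Draw the shared pedigree/design of a cohort: zygosity, sex, wave ages
# (shared by both twins of a family, as for twins scanned at the same
# visit), and the monotone MCAR wave-completion pattern. Pure function of
# the RNG state.
draw_pedigree <- function(truth) {
  n <- as.integer(truth$n_families)
  fam <- sprintf("F%04d", seq_len(n))
  zyg <- ifelse(stats::runif(n) < truth$p_mz, "MZ", "DZ")
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  ages <- sample_wave_ages(truth, n)
  k <- ncol(ages)
  n_waves <- matrix(
    sample.int(k, 2 * n, replace = TRUE, prob = truth$wave_completion_probs),
    n, 2
  )
  list(n = n, fam = fam, zyg = zyg, sex = sex, ages = ages, n_waves = n_waves)
}

# Draw one measure's latent growth parameters and observed rows on a given
# pedigree. Pure function of the RNG state.
assemble_measure <- function(truth, ped) {
  intercepts <- truth$mu_intercept +
    draw_ace_latent(ped$zyg, truth$a2_i, truth$c2_i, truth$e2_i,
                    truth$total_sd_intercept)
  slopes <- truth$mu_slope +
    draw_ace_latent(ped$zyg, truth$a2_s, truth$c2_s, truth$e2_s,
                    truth$total_sd_slope)

  per_child <- function(tw) {
    m <- ped$n_waves[, tw]
    idx <- rep(seq_len(ped$n), m)
    wave <- sequence(m)
    age <- ped$ages[cbind(idx, wave)]
    value <- intercepts[cbind(idx, tw)] +
      slopes[cbind(idx, tw)] * (age - truth$reference_age) +
      truth$sex_effect * (ped$sex[idx] == "male") +
      stats::rnorm(length(idx), sd = truth$residual_sd)
    tibble::tibble(
      family_id = ped$fam[idx],
      child_id = paste0(ped$fam[idx], "_", tw),
      twin_index = tw,
      zygosity = ped$zyg[idx],
      sex = ped$sex[idx],
      wave = wave,
      age = age,
      measure = truth$measure,
      value = value
    )
  }
  cohort <- dplyr::arrange(
    dplyr::bind_rows(per_child(1L), per_child(2L)),
    .data$family_id, .data$twin_index, .data$wave
  )
  latent <- tibble::tibble(
    family_id = rep(ped$fam, 2),
    child_id = c(paste0(ped$fam, "_1"), paste0(ped$fam, "_2")),
    twin_index = rep(1:2, each = ped$n),
    zygosity = rep(ped$zyg, 2),
    sex = rep(ped$sex, 2),
    measure = truth$measure,
    intercept = c(intercepts[, 1], intercepts[, 2]),
    slope = c(slopes[, 1], slopes[, 2]),
    n_waves = c(ped$n_waves[, 1], ped$n_waves[, 2])
  )
  latent <- dplyr::arrange(latent, .data$family_id, .data$twin_index)
  list(cohort = cohort, latent = latent)
}

#' Generate a synthetic twin cohort
#'
#' Draws latent intercepts and slopes with the configured ACE structure,
#' assigns zygosity, sex (per family, P(male) = 0.5), wave ages (shared by
#' both twins of a family, as for twins scanned at the same visit), and a
#' monotone missing-completely-at-random wave-completion pattern, then emits
#' the observed long-format table
#' `value = intercept + slope * (age - reference_age) + sex_effect * male + noise`.
#'
#' @param truth a [generator_truth()]; its `seed` makes the draw
#'   deterministic (identical truth implies byte-identical output).
#' @return a list with
#'   \describe{
#'     \item{cohort}{tibble with columns `family_id`, `child_id`,
#'       `twin_index`, `zygosity`, `sex`, `wave`, `age`, `measure`, `value`.}
#'     \item{latent}{tibble of the true per-child `intercept`, `slope`, and
#'       `n_waves`, for parameter-recovery studies.}
#'     \item{truth}{the input truth.}
#'   }
#' @seealso [generate_cohort_set()] for several measures on one shared
#'   pedigree.
#' @export
generate_cohort <- function(truth) {
  validate_truth(truth)
  withr::with_seed(truth$seed, {
    ped <- draw_pedigree(truth)
    out <- assemble_measure(truth, ped)
    list(cohort = out$cohort, latent = out$latent, truth = truth)
  })
}

#' Generate several measures on one shared twin pedigree
#'
#' Real longitudinal cohorts measure many phenotypes on the same children:
#' zygosity, sex, assessment ages, and the wave-completion pattern are
#' common across measures, while each measure has its own latent growth
#' parameters and noise. This draws the pedigree once (from `seed`) and
#' then each measure's latents from an independent, order-stable
#' sub-stream, so adding a measure never perturbs the others.
#'
#' @param truths a list of [generator_truth()] objects with identical
#'   design fields (`n_families`, `p_mz`, wave setup, `reference_age`) and
#'   distinct `measure` labels.
#' @param seed integer master seed.
#' @return as [generate_cohort()], with row-bound `cohort` and `latent`
#'   tables across measures and `truths` in place of `truth`.
#' @export
generate_cohort_set <- function(truths, seed) {
  stopifnot(length(truths) >= 1)
  lapply(truths, validate_truth)
  design_of <- function(t) t[c("n_families", "p_mz", "wave_age_means",
                               "wave_age_sds", "wave_completion_probs",
                               "reference_age")]
  base <- design_of(truths[[1]])
  for (t in truths[-1]) {
    if (!isTRUE(all.equal(design_of(t), base)))
      stopf("all truths in a cohort set must share the same design fields")
  }
  labels <- vapply(truths, `[[`, character(1), "measure")
  if (anyDuplicated(labels))
    stopf("measure labels must be distinct within a cohort set")

  ped <- withr::with_seed(as.integer(seed), draw_pedigree(truths[[1]]))
  parts <- lapply(seq_along(truths), function(i) {
    withr::with_seed(substream_seed(seed, i),
                     assemble_measure(truths[[i]], ped))
  })
  list(
    cohort = dplyr::bind_rows(lapply(parts, `[[`, "cohort")),
    latent = dplyr::bind_rows(lapply(parts, `[[`, "latent")),
    truths = truths
  )
}
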