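# Twin-pair assembly and zygosity-specific correlations.

new_pair_set <- function(mz, dz, measure, parameter,
                         ordering = "child_id") {
  mz <- as.matrix(mz); dz <- as.matrix(dz)
  if ((nrow(mz) && ncol(mz) != 2) || (nrow(dz) && ncol(dz) != 2))
    stopf("pair matrices must have two columns")
  structure(
    list(measure = measure, parameter = parameter,
         mz = mz, dz = dz,
         n_mz = nrow(mz), n_dz = nrow(dz),
         ordering = ordering),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %s / %s — %d MZ and %d DZ complete pairs (ordered by %s)\n",
              x$measure, x$parameter, x$n_mz, x$n_dz, x$ordering))
  invisible(x)
}

#' Assemble complete twin pairs for one measure and growth parameter
#'
#' Joins per-subject growth parameters to the pedigree metadata and keeps
#' only families where both twins have a non-missing value. Within each
#' pair, twin 1 / twin 2 are assigned deterministically by ascending
#' `child_id` so that repeated runs are reproducible.
#'
#' @param growth a [fit_subject_lines()] table (or any table with
#'   `child_id`, `measure`, and the parameter columns).
#' @param meta pedigree metadata with `child_id`, `family_id`, `zygosity`
#'   (one row per child; extra rows, e.g. a cohort table, are collapsed).
#' @param measure measure label.
#' @param parameter `"intercept"` or `"slope"`.
#' @param quiet suppress the exclusion log.
#' @return a `pair_set`.
#' @export
build_pairs <- function(growth, meta, measure, parameter = c("intercept", "slope"),
                        quiet = FALSE) {
  parameter <- match.arg(parameter)
  meta <- dplyr::distinct(
    tibble::as_tibble(meta)[, c("child_id", "family_id", "zygosity")]
  )
  g <- growth[growth$measure == measure, c("child_id", parameter)]
  names(g)[2] <- "value"
  d <- dplyr::inner_join(g, meta, by = "child_id")
  d <- d[!is.na(d$value), , drop = FALSE]
  d <- dplyr::arrange(d, .data$family_id, .data$child_id)

  fam <- dplyr::summarise(
    dplyr::group_by(d, .data$family_id),
    n = dplyr::n(),
    v1 = .data$value[1],
    v2 = .data$value[min(2, dplyr::n())],
    zygosity = .data$zygosity[1],
    .groups = "drop"
  )
  complete <- fam[fam$n == 2, , drop = FALSE]
  dropped <- sum(fam$n != 2) + (dplyr::n_distinct(meta$family_id) - nrow(fam))
  if (!quiet && dropped > 0)
    message(sprintf("build_pairs(%s, %s): %d incomplete famil%s excluded",
                    measure, parameter, dropped, if (dropped == 1) "y" else "ies"))

  mz <- as.matrix(complete[complete$zygosity == "MZ", c("v1", "v2")])
  dz <- as.matrix(complete[complete$zygosity == "DZ", c("v1", "v2")])
  dimnames(mz) <- dimnames(dz) <- NULL
  new_pair_set(mz, dz, measure, parameter)
}

#' Pearson correlation of twin-pair values
#'
#' Product-moment correlation between the twin-1 and twin-2 columns, with a
#' two-sided p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param x an n x 2 matrix of pairs, or the twin-1 vector.
#' @param y the twin-2 vector when `x` is a vector.
#' @return a list with `r`, `p`, `n`, and `defined` (FALSE when either
#'   column has zero variance, in which case `r` is `NA`).
#' @export
pair_correlation <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    x <- m[, 1]; y <- m[, 2]
  }
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n, defined = TRUE)
}

#' Fisher r-to-z test of the difference between two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, compared to a
#' standard normal; antisymmetric in the two groups. Used here to compare
#' the MZ and DZ within-pair correlations.
#'
#' @param r1,r2 correlations, strictly inside (-1, 1).
#' @param n1,n2 pair counts (>= 4).
#' @return a list with `z` and the two-sided `p`.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stopf("need n >= 4 in both groups")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stopf("|r| = 1 has an infinite Fisher transform")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Zygosity-specific correlations and their comparison for a pair set
#'
#' @param pairs a `pair_set`.
#' @return a one-row tibble with `r_mz`, `p_mz`, `n_mz`, `r_dz`, `p_dz`,
#'   `n_dz`, `z_diff`, `p_diff` (the Fisher comparison is `NA` when either
#'   correlation is undefined or at |r| = 1).
#' @export
correlate_pairs <- function(pairs) {
  stopifnot(inherits(pairs, "pair_set"))
  cm <- pair_correlation(pairs$mz)
  cd <- pair_correlation(pairs$dz)
  zd <- if (cm$defined && cd$defined &&
            abs(cm$r) < 1 && abs(cd$r) < 1 &&
            cm$n >= 4 && cd$n >= 4) {
    fisher_z_diff(cm$r, cm$n, cd$r, cd$n)
  } else list(z = NA_real_, p = NA_real_)
  tibble::tibble(
    measure = pairs$measure, parameter = pairs$parameter,
    r_mz = cm$r, p_mz = cm$p, n_mz = cm$n,
    r_dz = cd$r, p_dz = cd$p, n_dz = cd$n,
    z_diff = zd$z, p_diff = zd$p
  )
}
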