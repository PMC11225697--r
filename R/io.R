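# Reading, writing, and validating the tidy phenotype format, plus loaders
# for the bundled reference-estimate tables.

cohort_columns <- c("family_id", "child_id", "twin_index", "zygosity",
                    "sex", "wave", "age", "measure", "value")

#' Validate a long-format twin cohort table
#'
#' Checks the pedigree and layout invariants: exactly two children per
#' family, zygosity and sex constant within a family, known zygosity codes,
#' no duplicate (child, wave, measure) rows, and ages strictly increasing
#' across waves within a child.
#'
#' @param cohort a data frame with the tidy cohort columns.
#' @return the cohort, invisibly, or an error naming the offending rows.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))

  bad_zyg <- which(!cohort$zygosity %in% c("MZ", "DZ"))
  if (length(bad_zyg))
    stopf("unknown zygosity code '%s' in row %d",
          cohort$zygosity[bad_zyg[1]], bad_zyg[1])

  dup <- duplicated(cohort[c("child_id", "wave", "measure")])
  if (any(dup)) {
    i <- which(dup)[1]
    stopf("duplicate (child_id, wave, measure) row: (%s, %s, %s)",
          cohort$child_id[i], cohort$wave[i], cohort$measure[i])
  }

  fam <- dplyr::summarise(
    dplyr::group_by(cohort, .data$family_id),
    n_children = dplyr::n_distinct(.data$child_id),
    n_zyg = dplyr::n_distinct(.data$zygosity),
    n_sex = dplyr::n_distinct(.data$sex),
    .groups = "drop"
  )
  bad <- fam$family_id[fam$n_children != 2]
  if (length(bad))
    stopf("family '%s' has %d children; twin families must have exactly 2",
          bad[1], fam$n_children[fam$family_id == bad[1]][1])
  bad <- fam$family_id[fam$n_zyg != 1 | fam$n_sex != 1]
  if (length(bad))
    stopf("family '%s' has inconsistent zygosity or sex across rows", bad[1])

  ord <- dplyr::arrange(cohort, .data$child_id, .data$measure, .data$wave)
  by_child <- dplyr::summarise(
    dplyr::group_by(ord, .data$child_id, .data$measure),
    ok = all(diff(.data$age) > 0) || dplyr::n() == 1,
    .groups = "drop"
  )
  if (any(!by_child$ok))
    stopf("ages are not strictly increasing across waves for child '%s'",
          by_child$child_id[!by_child$ok][1])

  invisible(cohort)
}

#' Read a tidy long-format cohort file
#'
#' Accepts comma- or tab-separated files (auto-detected from the extension
#' or the first line when `delim = NULL`) with a case-insensitive header
#' carrying the nine tidy columns. Zygosity codes other than "MZ"/"DZ"
#' (e.g. registry codes 1/2) can be mapped via `zygosity_map`.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` to auto-detect.
#' @param zygosity_map named character vector mapping input codes to
#'   `"MZ"`/`"DZ"`, e.g. `c("1" = "MZ", "2" = "DZ")`.
#' @param quiet suppress the per-wave child counts log.
#' @return a validated cohort tibble.
#' @export
read_cohort <- function(path, delim = NULL,
                        zygosity_map = c(MZ = "MZ", DZ = "DZ"),
                        quiet = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- delim %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols))
    stopf("header is missing column(s): %s", paste(missing_cols, collapse = ", "))
  cohort <- tibble::as_tibble(raw[cohort_columns])

  zin <- as.character(cohort$zygosity)
  known <- zin %in% names(zygosity_map)
  if (any(!known)) {
    i <- which(!known)[1]
    stopf("unknown zygosity code '%s' in row %d of %s", zin[i], i, path)
  }
  cohort$zygosity <- unname(zygosity_map[zin])
  cohort$twin_index <- as.integer(cohort$twin_index)
  cohort$wave <- as.integer(cohort$wave)

  validate_cohort(cohort)
  if (!quiet) {
    counts <- table(cohort$wave[!duplicated(paste(cohort$child_id, cohort$wave))])
    message("read_cohort: children per wave: ",
            paste(sprintf("wave %s = %d", names(counts), counts), collapse = ", "))
  }
  cohort
}

#' Write a cohort table to CSV/TSV
#'
#' @param cohort a cohort tibble.
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @param delim field delimiter; `NULL` to derive from the extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(cohort[cohort_columns], path, delim = delim)
  invisible(path)
}

detect_delim <- function(path) {
  if (grepl("\\.tsv$", path)) return("\t")
  if (grepl("\\.csv$", path)) return(",")
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Convert a wide per-subject region table to tidy cohort rows
#'
#' FreeSurfer-style stats exports are wide: one row per subject and scan,
#' one column per region. This melts the region columns into tidy cohort
#' rows for one morphological measure, joining subject metadata either from
#' columns present in the file or from a supplied `metadata` table keyed by
#' `child_id` (and `wave`, when present in both).
#'
#' @param path wide table (CSV/TSV); must contain a `child_id` column.
#' @param measure_prefix string prepended to each region column name to form
#'   the tidy `measure` label (e.g. `"ct_"`).
#' @param metadata optional data frame with the pedigree columns
#'   (`family_id`, `twin_index`, `zygosity`, `sex`, and `wave`/`age` if not
#'   in the wide file).
#' @param delim field delimiter; `NULL` to auto-detect.
#' @return a validated cohort tibble covering the melted regions.
#' @export
read_freesurfer_wide_table <- function(path, measure_prefix = "",
                                       metadata = NULL, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- delim %||% detect_delim(path)
  wide <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  names(wide) <- tolower(names(wide))
  if (!"child_id" %in% names(wide))
    stopf("wide table must contain a child_id column")

  meta_cols <- intersect(cohort_columns, names(wide))
  region_cols <- setdiff(names(wide), cohort_columns)
  if (!length(region_cols)) stopf("no region columns found in %s", path)
  for (rc in region_cols) {
    v <- wide[[rc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stopf("region column '%s' contains non-numeric entries", rc)
      wide[[rc]] <- vn
    }
  }

  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(region_cols),
                              names_to = "measure", values_to = "value")
  long$measure <- paste0(measure_prefix, long$measure)

  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    names(metadata) <- tolower(names(metadata))
    keys <- intersect(c("child_id", "wave"), intersect(names(long), names(metadata)))
    add <- setdiff(intersect(cohort_columns, names(metadata)), names(long))
    long <- dplyr::left_join(long, metadata[unique(c(keys, add))], by = keys)
  }
  missing_cols <- setdiff(cohort_columns, names(long))
  if (length(missing_cols))
    stopf("missing metadata column(s) after join: %s",
          paste(missing_cols, collapse = ", "))
  validate_cohort(tibble::as_tibble(long[cohort_columns]))
}

#' Load the bundled reference twin-correlation and ACE-estimate table
#'
#' Returns the package's transcription of a published reference table from a
#' longitudinal twin study of brain structure: for each of 11 brain regions
#' (7 cortical, measured as cortical thickness and surface area; 4
#' subcortical, measured as volume), both hemispheres, and both growth
#' parameters (intercept at age 7.02 and slope), the printed within-pair
#' Pearson correlations for MZ and DZ twins, the z statistic comparing
#' them, printed p-value labels, standardized ACE estimates, and their 95%
#' confidence bounds. Lower/upper bounds printed as "NA" at the 0/1
#' boundary are encoded as missing values (the boundary marker). The
#' `reported` flag and `components` column transcribe which rows (and which
#' of A/C/E) the source's results text singles out under its three
#' reporting rules; `text_table_conflict` marks rows where the printed
#' significance stars and the results text disagree (the text is encoded).
#'
#' @return a tibble with 72 rows.
#' @export
load_reference_estimates <- function() {
  path <- system.file("extdata", "reference_ace_estimates.csv",
                      package = "twinace", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$reported <- as.logical(out$reported)
  out$text_table_conflict <- as.logical(out$text_table_conflict)
  out
}

#' Load the bundled reference mean-percentage table
#'
#' The published companion summary of [load_reference_estimates()]: mean
#' reported A/C/E percentages by network, region, morphological dimension,
#' dimension within network, and hemisphere, for intercepts and slopes, as
#' printed (including the handful of cells that are arithmetically
#' inconsistent with the reported rows; see the package vignette).
#'
#' @return a tibble with columns `scheme`, `group`, `parameter`,
#'   `a_pct`, `c_pct`, `e_pct` (integer percents, `NA` = printed absent
#'   marker).
#' @export
load_reference_aggregates <- function() {
  path <- system.file("extdata", "reference_mean_percentages.csv",
                      package = "twinace", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
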