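#' Read a peak table from CSV
#'
#' Reads the canonical wide-format peak-table CSV (one numeric column per
#' sample) together with its companion samples CSV mapping sample id to
#' group. A long-format reader is provided as a convenience via
#' `format = "long"`.
#'
#' The fixed CSV dialect is UTF-8, comma-separated, `.` decimal, first row
#' header. Wide columns: `id, name, cas, formula, class, rt_min,
#' match_score`, then one column per sample. Long columns: the same metadata
#' plus `sample` and `area`. Empty area cells become area 0 with
#' `detected = FALSE`.
#'
#' @param path Path to the peak-table CSV.
#' @param samples Path to the samples CSV (`sample_id, group` columns), or a
#'   named character vector mapping sample id to group.
#' @param format `"wide"` (default) or `"long"`.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, samples, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Peak table file not found: %s", path),
          class = "aromascreen_io_error")
  }
  groups <- if (is.character(samples) && !is.null(names(samples))) {
    samples
  } else {
    if (!file.exists(samples)) {
      abort(sprintf("Samples file not found: %s", samples),
            class = "aromascreen_io_error")
    }
    smp <- read_csv_plain(samples)
    check_columns(smp, c("sample_id", "group"), samples)
    setNames(as.character(smp$group), as.character(smp$sample_id))
  }

  raw <- read_csv_plain(path)
  meta_cols <- c("id", "name", "cas", "formula", "class", "rt_min",
                 "match_score")
  if (format == "wide") {
    check_columns(raw, c("id", "name", "class", "rt_min"), path)
    sample_cols <- setdiff(names(raw), meta_cols)
    missing_samples <- setdiff(names(groups), sample_cols)
    if (length(missing_samples) > 0) {
      abort(sprintf("Sample column(s) absent from %s: %s", path,
                    paste(missing_samples, collapse = ", ")),
            class = "aromascreen_format_error")
    }
    areas <- parse_area_block(raw, names(groups), path)
  } else {
    check_columns(raw, c("id", "name", "class", "rt_min", "sample", "area"),
                  path)
    raw <- tidyr::pivot_wider(raw, names_from = "sample",
                              values_from = "area")
    areas <- parse_area_block(raw, names(groups), path)
  }
  detected <- !is.na(areas)
  areas[is.na(areas)] <- 0

  cmp <- raw[, intersect(meta_cols, names(raw)), drop = FALSE]
  peak_table(compounds = cmp, areas = areas, groups = groups,
             detected = detected)
}

#' Write a peak table to CSV
#'
#' Writes the wide-format peak-table CSV and companion samples CSV.
#' Undetected cells are written as empty fields so that
#' `read_peak_table()` round-trips areas bit-identically and restores the
#' detection flags.
#'
#' @param x A [peak_table()].
#' @param path Output path for the peak-table CSV.
#' @param samples_path Output path for the samples CSV.
#' @return `x`, invisibly.
#' @export
write_peak_table <- function(x, path, samples_path) {
  areas <- as.data.frame(x$areas)
  for (j in seq_along(areas)) areas[[j]][!x$detected[, j]] <- NA_real_
  out <- cbind(as.data.frame(x$compounds), areas)
  readr::write_csv(out, path, na = "")
  readr::write_csv(tibble(sample_id = x$samples,
                          group = unname(x$groups)), samples_path)
  invisible(x)
}

#' Read an n-alkane ladder from CSV
#'
#' Expects columns `carbon_number, rt_min`; rows in any order. The ladder is
#' validated (strictly increasing in both columns) and sorted.
#'
#' @param path CSV path.
#' @return An [alkane_ladder()].
#' @export
read_alkane_ladder <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Alkane ladder file not found: %s", path),
          class = "aromascreen_io_error")
  }
  x <- read_csv_plain(path)
  check_columns(x, c("carbon_number", "rt_min"), path)
  alkane_ladder(as.integer(x$carbon_number), as.numeric(x$rt_min))
}

#' Read an odor-threshold table from CSV
#'
#' Expects columns `name, threshold_mg_per_kg, descriptors`, the latter a
#' semicolon-separated list of aroma terms. Empty threshold cells are kept
#' as `NA` (compound scored as threshold-unknown); non-positive thresholds
#' are rejected.
#'
#' @param path CSV path.
#' @return A [threshold_table()].
#' @export
read_threshold_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Threshold table file not found: %s", path),
          class = "aromascreen_io_error")
  }
  x <- read_csv_plain(path)
  check_columns(x, c("name", "threshold_mg_per_kg"), path)
  desc <- if ("descriptors" %in% names(x)) {
    replace(x$descriptors, is.na(x$descriptors), "")
  } else {
    rep("", nrow(x))
  }
  threshold_table(x$name, as.numeric(x$threshold_mg_per_kg), desc)
}

# ---- internal IO helpers ----------------------------------------------------

# fixed dialect: UTF-8, comma, "." decimal, header row; "#" lines are run
# metadata written by the pipeline and skipped on read
read_csv_plain <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  comment = "#", progress = FALSE,
                  locale = readr::locale(encoding = "UTF-8"))
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "aromascreen_format_error")
  }
  invisible(df)
}

# parse sample columns read as character into a numeric matrix, reporting
# the exact cell on failure; empty cells -> NA (undetected)
parse_area_block <- function(df, sample_ids, path) {
  areas <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
                  dimnames = list(NULL, sample_ids))
  for (s in sample_ids) {
    raw <- df[[s]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric peak area in %s: row %d, column '%s' (value '%s')",
        path, bad[1], s, raw[bad[1]]
      ), class = "aromascreen_parse_error")
    }
    val[blank] <- NA_real_
    areas[, s] <- val
  }
  areas
}

# write a data frame as CSV with a run-metadata comment header
write_stage_csv <- function(df, path, run_hash = NULL) {
  if (!is.null(run_hash)) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    writeLines(sprintf("# aromascreen run %s", run_hash), con)
    close(con)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(df)
}
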