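#' Construct a GC-MS peak table
#'
#' The central container of the pipeline: integrated peak areas for a set of
#' identified volatile compounds across replicate samples, together with
#' compound metadata and a group label per sample. Missing peaks (a compound
#' not detected in a sample) are stored as area 0 with a parallel
#' `detected = FALSE` flag, so that the area matrix stays complete for
#' multivariate work while detection counts use the flag, never the value.
#'
#' @param compounds A data frame with one row per compound and columns
#'   `id` (unique short label), `name`, `cas`, `formula`,
#'   `class` (one of [compound_classes()]), `rt_min` (retention time,
#'   minutes, > 0) and `match_score` (library-match score in \[0, 100\],
#'   `NA` allowed). Missing `cas`/`formula` may be empty strings.
#' @param areas Numeric matrix, `n_compounds x n_samples`, raw peak areas in
#'   instrument units, all `>= 0`. `NA` cells are converted to 0 with
#'   `detected = FALSE`.
#' @param groups Named character vector mapping sample id to group label.
#'   Names give the sample order; must match `ncol(areas)`.
#' @param detected Optional logical matrix of the same shape as `areas`;
#'   defaults to `areas > 0`. `detected = FALSE` forces the area to 0.
#'
#' @return An object of class `peak_table`: a list with elements `compounds`
#'   (tibble), `samples`, `groups`, `areas` and `detected` (matrices with
#'   compound ids as rownames and sample ids as colnames).
#' @export
#' @examples
#' pt <- peak_table(
#'   compounds = data.frame(
#'     id = c("a", "b"), name = c("hexanal", "octanal"), cas = "", formula = "",
#'     class = "aldehyde", rt_min = c(5.4, 11.1), match_score = c(91, 88)
#'   ),
#'   areas = matrix(c(10, 20, 30, 40), nrow = 2),
#'   groups = c(S1 = "young", S2 = "mature")
#' )
#' pt
peak_table <- function(compounds, areas, groups, detected = NULL) {
  compounds <- as_tibble(as.data.frame(compounds, stringsAsFactors = FALSE))
  required <- c("id", "name", "class", "rt_min")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`compounds` is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "aromascreen_format_error")
  }
  for (opt in c("cas", "formula")) {
    if (!opt %in% names(compounds)) compounds[[opt]] <- ""
  }
  if (!"match_score" %in% names(compounds)) compounds$match_score <- NA_real_
  compounds$id <- as.character(compounds$id)
  compounds$match_score <- as.numeric(compounds$match_score)
  compounds$rt_min <- as.numeric(compounds$rt_min)
  compounds <- compounds[, c("id", "name", "cas", "formula", "class",
                             "rt_min", "match_score")]

  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (nrow(areas) != nrow(compounds)) {
    abort("`areas` must have one row per compound.",
          class = "aromascreen_validation_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named character vector (sample id -> group).",
          class = "aromascreen_validation_error")
  }
  samples <- names(groups)
  if (ncol(areas) != length(samples)) {
    abort("`areas` must have one column per sample named in `groups`.",
          class = "aromascreen_validation_error")
  }
  groups <- setNames(as.character(groups), samples)

  if (any(!is.na(areas) & areas < 0)) {
    abort("Peak areas must be >= 0.", class = "aromascreen_validation_error")
  }
  if (is.null(detected)) {
    detected <- !is.na(areas) & areas > 0
  } else {
    detected <- as.matrix(detected)
  }
  areas[is.na(areas)] <- 0
  areas[!detected] <- 0

  dimnames(areas) <- list(compounds$id, samples)
  dimnames(detected) <- list(compounds$id, samples)

  x <- structure(
    list(compounds = compounds, samples = samples, groups = groups,
         areas = areas, detected = detected),
    class = "peak_table"
  )
  validate_peak_table(x)
}

#' Validate a peak table
#'
#' Checks the structural invariants of a [peak_table()]: unique compound ids,
#' a valid class vocabulary, positive retention times, match scores within
#' \[0, 100\], non-negative areas, `detected = FALSE` implying area 0, and a
#' group label for every sample. Called by the constructor and by the
#' synthetic-data generator; exported so that externally assembled objects
#' can be checked.
#'
#' @param x A `peak_table`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_peak_table <- function(x) {
  cmp <- x$compounds
  if (anyDuplicated(cmp$id)) {
    abort(sprintf("Duplicate compound id(s): %s",
                  paste(unique(cmp$id[duplicated(cmp$id)]), collapse = ", ")),
          class = "aromascreen_validation_error")
  }
  bad_class <- setdiff(unique(cmp$class), COMPOUND_CLASSES)
  if (length(bad_class) > 0) {
    abort(sprintf("Unknown compound class(es): %s (allowed: %s)",
                  paste(bad_class, collapse = ", "),
                  paste(COMPOUND_CLASSES, collapse = ", ")),
          class = "aromascreen_validation_error")
  }
  if (any(!is.na(cmp$rt_min) & cmp$rt_min <= 0)) {
    abort("All retention times must be > 0.",
          class = "aromascreen_validation_error")
  }
  ms <- cmp$match_score
  if (any(!is.na(ms) & (ms < 0 | ms > 100))) {
    abort("match_score must lie in [0, 100].",
          class = "aromascreen_validation_error")
  }
  if (any(x$areas < 0)) {
    abort("Peak areas must be >= 0.", class = "aromascreen_validation_error")
  }
  if (any(x$areas[!x$detected] != 0)) {
    abort("Cells flagged detected = FALSE must have area 0.",
          class = "aromascreen_validation_error")
  }
  if (length(x$groups) != length(x$samples) ||
      !identical(names(x$groups), x$samples)) {
    abort("Every sample must carry a group label.",
          class = "aromascreen_validation_error")
  }
  invisible(x)
}

#' @export
print.peak_table <- function(x, ...) {
  gl <- table(x$groups)
  cat(sprintf("<peak_table> %d compounds x %d samples\n",
              nrow(x$areas), ncol(x$areas)))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(gl), gl), collapse = ", "),
      "\n")
  cat(sprintf("  detected cells: %d / %d\n", sum(x$detected),
              length(x$detected)))
  invisible(x)
}

#' Number of compounds / samples in a peak table
#' @param x A `peak_table`.
#' @return An integer.
#' @export
n_compounds <- function(x) nrow(x$areas)

#' @rdname n_compounds
#' @export
n_samples <- function(x) ncol(x$areas)

#' Group labels of a peak table
#' @param x A `peak_table`.
#' @return Character vector of distinct group labels, in order of appearance.
#' @export
group_levels <- function(x) unique(unname(x$groups))

#' Sample ids belonging to one group
#' @param x A `peak_table`.
#' @param group A group label present in `x$groups`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  if (!group %in% x$groups) {
    abort(sprintf("Unknown group '%s' (groups: %s)", group,
                  paste(group_levels(x), collapse = ", ")),
          class = "aromascreen_key_error")
  }
  x$samples[x$groups == group]
}

#' Subset a peak table by compound
#'
#' `x[i]` keeps compounds selected by `i` (indices, logical mask over
#' compounds, or compound ids), preserving order of selection; samples and
#' groups are untouched.
#'
#' @param x A `peak_table`.
#' @param i Compound selector.
#' @param ... Ignored.
#' @return A `peak_table`.
#' @export
`[.peak_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$compounds$id)
  peak_table(
    compounds = x$compounds[i, , drop = FALSE],
    areas = x$areas[i, , drop = FALSE],
    groups = x$groups,
    detected = x$detected[i, , drop = FALSE]
  )
}

# internal: assert the two-group design required by the differential steps
require_two_groups <- function(x) {
  gl <- group_levels(x)
  if (length(gl) != 2) {
    abort(sprintf(
      "Differential analysis requires exactly 2 groups; found %d (%s).",
      length(gl), paste(gl, collapse = ", ")
    ), class = "aromascreen_validation_error")
  }
  gl
}
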