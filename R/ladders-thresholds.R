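#' Construct an n-alkane ladder
#'
#' A monotone map from alkane carbon number to observed retention time, used
#' to place compounds on the Kovats retention-index scale (alkane with n
#' carbons defines index 100 n).
#'
#' @param carbon_number Integer vector of carbon numbers (>= 5), strictly
#'   increasing.
#' @param rt_min Retention times in minutes, strictly increasing with carbon
#'   number.
#' @return A tibble of class `alkane_ladder` with columns `carbon_number`
#'   and `rt_min`, sorted by carbon number.
#' @export
#' @examples
#' alkane_ladder(7:10, c(3.0, 5.1, 7.9, 10.8))
alkane_ladder <- function(carbon_number, rt_min) {
  carbon_number <- as.integer(carbon_number)
  rt_min <- as.numeric(rt_min)
  if (length(carbon_number) != length(rt_min) || length(carbon_number) < 2) {
    abort("An alkane ladder needs at least 2 (carbon_number, rt_min) pairs.",
          class = "aromascreen_validation_error")
  }
  ord <- order(carbon_number)
  carbon_number <- carbon_number[ord]
  rt_min <- rt_min[ord]
  if (any(carbon_number < 5)) {
    abort("Carbon numbers below C5 are not supported.",
          class = "aromascreen_validation_error")
  }
  if (any(diff(carbon_number) <= 0)) {
    abort("Carbon numbers must be strictly increasing.",
          class = "aromascreen_validation_error")
  }
  if (any(diff(rt_min) <= 0)) {
    abort("Retention times must increase strictly with carbon number.",
          class = "aromascreen_validation_error")
  }
  structure(tibble(carbon_number = carbon_number, rt_min = rt_min),
            class = c("alkane_ladder", class(tibble())))
}

#' Construct an odor-threshold table
#'
#' Per-compound odor thresholds (mg/kg) and free-text aroma descriptors.
#' Thresholds drive rOAV computation; descriptors drive aroma-type
#' profiling. A compound may lack a threshold (`NA`), in which case it is
#' excluded from rOAV scoring with a note.
#'
#' @param name Compound names (matched against the peak table `name`
#'   column).
#' @param threshold_mg_per_kg Positive odor thresholds in mg/kg; `NA`
#'   allowed.
#' @param descriptors List of character vectors (one per compound), or a
#'   character vector of semicolon-separated terms.
#' @return A tibble of class `threshold_table` with columns `name`,
#'   `threshold_mg_per_kg`, `descriptors` (list column).
#' @export
#' @examples
#' threshold_table("Hexanal", 0.005, "green;grass;fruity")
threshold_table <- function(name, threshold_mg_per_kg, descriptors = NULL) {
  name <- as.character(name)
  threshold_mg_per_kg <- as.numeric(threshold_mg_per_kg)
  if (any(!is.na(threshold_mg_per_kg) & threshold_mg_per_kg <= 0)) {
    abort("Odor thresholds must be > 0 (mg/kg).",
          class = "aromascreen_validation_error")
  }
  if (is.null(descriptors)) descriptors <- rep("", length(name))
  if (is.character(descriptors)) {
    descriptors <- lapply(strsplit(descriptors, ";", fixed = TRUE),
                          function(d) trimws(d[nzchar(trimws(d))]))
  }
  stopifnot(length(descriptors) == length(name))
  structure(
    tibble(name = name, threshold_mg_per_kg = threshold_mg_per_kg,
           descriptors = descriptors),
    class = c("threshold_table", class(tibble()))
  )
}
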