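#' Select the reference compound for rOAV normalisation
#'
#' The reference is the compound with the highest odor activity (content
#' divided by odor threshold) among compounds with positive content and a
#' known threshold; its rOAV is fixed at 100 and all other compounds are
#' expressed relative to it. Ties break by compound order.
#'
#' @param contents Named numeric vector of group-mean relative contents
#'   (names = compound names, percent).
#' @param thresholds A [threshold_table()] or named numeric vector of
#'   thresholds (mg/kg).
#' @return The reference compound's name.
#' @export
select_reference <- function(contents, thresholds) {
  thr <- as_threshold_vector(thresholds)
  common <- names(contents)[names(contents) %in% names(thr)]
  common <- common[contents[common] > 0 & !is.na(thr[common])]
  if (length(common) == 0) {
    abort("No compound has both positive content and a known threshold.",
          class = "aromascreen_validation_error")
  }
  activity <- contents[common] / thr[common]
  common[which.max(activity)]  # which.max keeps the first (input-order) tie
}

#' Relative odor activity values (rOAV)
#'
#' Scores each compound's contribution to the overall aroma relative to the
#' most odor-active compound of the group:
#' \deqn{rOAV_i = 100 \cdot (C_i / C_{ref}) \cdot (T_{ref} / T_i)}
#' where C is relative content and T the odor threshold (mg/kg). The
#' reference compound scores exactly 100, every other compound at most 100;
#' the ratio form makes the score invariant to any common rescaling of the
#' contents. The reference's threshold plays the role of the normalising
#' threshold: this is the only reading under which the most odor-active
#' compound scores 100 by construction. Compounds without a known
#' threshold are excluded, with a note listing them.
#'
#' Categories follow the conventional aroma-activity bands: `critical`
#' (rOAV >= 1, drives the aroma), `modifying` (0.1 < rOAV < 1),
#' `negligible` (rOAV <= 0.1).
#'
#' @param contents Named numeric vector of group-mean relative contents.
#' @param thresholds A [threshold_table()] or named numeric vector.
#' @param reference Reference compound name; default auto-selects via
#'   [select_reference()].
#' @param group Optional group label carried into the result.
#' @param quiet Suppress the excluded-compound note.
#' @return A `roav_table` tibble: `name, content_pct, threshold, roav,
#'   category`, with attributes `reference`, `group` and `excluded` (names
#'   of compounds lacking thresholds).
#' @export
compute_roav <- function(contents, thresholds, reference = NULL,
                         group = NULL, quiet = FALSE) {
  thr <- as_threshold_vector(thresholds)
  if (any(!is.na(thr) & thr <= 0)) {
    abort("Odor thresholds must be > 0.",
          class = "aromascreen_validation_error")
  }
  if (is.null(reference)) reference <- select_reference(contents, thresholds)
  if (!reference %in% names(contents) || !reference %in% names(thr) ||
      is.na(thr[reference]) || contents[reference] <= 0) {
    abort(sprintf(
      "Reference '%s' must have positive content and a known threshold.",
      reference
    ), class = "aromascreen_validation_error")
  }
  scored <- names(contents)[names(contents) %in% names(thr)]
  scored <- scored[!is.na(thr[scored])]
  excluded <- setdiff(names(contents), scored)
  if (length(excluded) > 0 && !quiet) {
    inform(sprintf("%d compound(s) without odor thresholds excluded from rOAV: %s",
                   length(excluded), paste(excluded, collapse = ", ")))
  }
  roav <- 100 * (contents[scored] / contents[[reference]]) *
    (thr[[reference]] / thr[scored])
  out <- tibble(
    name = scored,
    content_pct = unname(contents[scored]),
    threshold = unname(thr[scored]),
    roav = unname(roav),
    category = classify_roav(unname(roav))
  )
  attr(out, "reference") <- reference
  attr(out, "group") <- group
  attr(out, "excluded") <- excluded
  class(out) <- c("roav_table", class(out))
  out
}

#' Classify an rOAV into aroma-activity categories
#'
#' `critical` for rOAV >= 1 (the 1 boundary is inclusive), `modifying`
#' for 0.1 < rOAV < 1, `negligible` for rOAV <= 0.1.
#'
#' @param roav Non-negative numeric vector.
#' @return Character vector of categories.
#' @export
classify_roav <- function(roav) {
  if (any(roav < 0)) {
    abort("rOAV must be >= 0.", class = "aromascreen_validation_error")
  }
  ifelse(roav >= 1, "critical",
         ifelse(roav > 0.1, "modifying", "negligible"))
}

#' Aroma-type profile from rOAVs and odor descriptors
#'
#' Aggregates aroma activity by descriptor term: each critical or modifying
#' compound's rOAV is added to every aroma term in its descriptor list, and
#' terms are ranked by total. Negligible compounds are excluded, so the
#' profile reflects the aroma types a panellist would plausibly perceive.
#'
#' @param roav_table A `roav_table` from [compute_roav()].
#' @param thresholds A [threshold_table()] carrying the descriptor lists
#'   (or a named list of character vectors).
#' @return An `aroma_profile` tibble: `term, score, rank`, descending
#'   score; attribute `group` carried over.
#' @export
aroma_profile <- function(roav_table, thresholds) {
  desc <- if (inherits(thresholds, "threshold_table")) {
    setNames(thresholds$descriptors, thresholds$name)
  } else {
    thresholds
  }
  active <- roav_table[roav_table$category %in% c("critical", "modifying"), ]
  scores <- list()
  for (i in seq_len(nrow(active))) {
    terms <- desc[[active$name[i]]]
    for (term in terms) {
      scores[[term]] <- (scores[[term]] %||% 0) + active$roav[i]
    }
  }
  out <- tibble(term = names(scores),
                score = as.numeric(unlist(scores %||% list())))
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  out$rank <- seq_len(nrow(out))
  attr(out, "group") <- attr(roav_table, "group")
  class(out) <- c("aroma_profile", class(out))
  out
}

as_threshold_vector <- function(thresholds) {
  if (inherits(thresholds, "threshold_table")) {
    setNames(thresholds$threshold_mg_per_kg, thresholds$name)
  } else {
    thresholds
  }
}
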