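#' Relative content: peak areas as percentages of the per-sample total
#'
#' Converts raw areas to relative contents, the standard semi-quantification
#' for headspace GC-MS: each compound's area divided by the total peak area
#' of its sample, times 100. Per-group means and standard deviations (n - 1)
#' are computed over the per-sample percentages, matching the usual
#' "mean +/- SD" presentation; this is a mean of percentages, not a
#' percentage of mean areas.
#'
#' @param x A [peak_table()].
#' @return A `relative_content` object: list with `compounds`, `percent`
#'   (matrix, compounds x samples, summing to 100 per sample), `groups`,
#'   and `summary` (tibble `id, name, class`, then `mean_<group>` and
#'   `sd_<group>` per group).
#' @export
relative_content <- function(x) {
  totals <- colSums(x$areas)
  zero <- which(totals <= 0)
  if (length(zero) > 0) {
    abort(sprintf("Sample '%s' has zero total peak area; cannot normalise.",
                  x$samples[zero[1]]),
          class = "aromascreen_validation_error")
  }
  percent <- sweep(x$areas, 2, totals, "/") * 100
  new_relative_content(percent, x$compounds, x$groups)
}

#' Construct a relative-content table from pre-normalised percentages
#'
#' Low-level constructor for data already expressed as relative contents
#' (e.g. published tables that print percentages rather than raw areas).
#' Per-sample sums are checked against 100 within `tol` (relative): exact
#' pipelines use the default tight tolerance, while tables rebuilt from
#' rounded published values need a looser one.
#'
#' @param percent Matrix, compounds x samples, percentages.
#' @param compounds Compound metadata as in [peak_table()].
#' @param groups Named character vector, sample id -> group label.
#' @param tol Allowed relative deviation of each per-sample sum from 100.
#' @return A `relative_content` object.
#' @export
relative_content_table <- function(percent, compounds, groups, tol = 1e-9) {
  percent <- as.matrix(percent)
  dev <- abs(colSums(percent) / 100 - 1)
  if (any(dev > tol)) {
    abort(sprintf(
      "Per-sample percentages must sum to 100 (max relative deviation %.3g > tol %.3g).",
      max(dev), tol
    ), class = "aromascreen_validation_error")
  }
  compounds <- as_tibble(as.data.frame(compounds, stringsAsFactors = FALSE))
  new_relative_content(percent, compounds, groups)
}

new_relative_content <- function(percent, compounds, groups) {
  dimnames(percent) <- list(compounds$id, names(groups))
  summary <- compounds[, c("id", "name", "class")]
  for (g in unique(unname(groups))) {
    cols <- names(groups)[groups == g]
    block <- percent[, cols, drop = FALSE]
    summary[[paste0("mean_", g)]] <- unname(rowMeans(block))
    summary[[paste0("sd_", g)]] <- if (length(cols) > 1) {
      unname(apply(block, 1, sd))
    } else {
      NA_real_
    }
  }
  structure(list(compounds = compounds, percent = percent, groups = groups,
                 summary = summary),
            class = "relative_content")
}

#' @export
print.relative_content <- function(x, ...) {
  cat(sprintf("<relative_content> %d compounds x %d samples (%% of total area)\n",
              nrow(x$percent), ncol(x$percent)))
  print(head(x$summary, 10))
  invisible(x)
}

#' Group-mean relative contents as a named vector
#'
#' @param rc A `relative_content` object.
#' @param group Group label.
#' @return Named numeric vector (names = compound names) of group-mean
#'   percentages.
#' @export
content_means <- function(rc, group) {
  col <- paste0("mean_", group)
  if (!col %in% names(rc$summary)) {
    abort(sprintf("Unknown group '%s'.", group),
          class = "aromascreen_key_error")
  }
  setNames(rc$summary[[col]], rc$summary$name)
}

#' Count compounds detected in a group
#'
#' A compound counts as detected in a group when its detection flag is TRUE
#' in at least one sample of that group; the flag, not the stored area, is
#' authoritative.
#'
#' @param x A [peak_table()].
#' @param group Group label (or omit for detection in any sample).
#' @return Integer count.
#' @export
count_detected <- function(x, group = NULL) {
  cols <- if (is.null(group)) x$samples else group_samples(x, group)
  sum(rowSums(x$detected[, cols, drop = FALSE]) > 0)
}

#' Total relative content per chemical class
#'
#' Sums group-mean relative contents over the compounds of each chemical
#' class. Classes with no compounds score 0, so that the vector always
#' covers the full vocabulary and class totals conserve the overall sum of
#' group means.
#'
#' @param rc A `relative_content` object.
#' @param group Group label.
#' @return Named numeric vector over [compound_classes()], in percent.
#' @export
class_totals <- function(rc, group) {
  means <- rc$summary[[paste0("mean_", group)]]
  if (is.null(means)) {
    abort(sprintf("Unknown group '%s'.", group),
          class = "aromascreen_key_error")
  }
  totals <- tapply(means, factor(rc$summary$class, levels = COMPOUND_CLASSES),
                   sum, default = 0)
  setNames(as.numeric(totals), COMPOUND_CLASSES)
}
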