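#' Kovats retention index by linear interpolation on an alkane ladder
#'
#' Places a retention time on the dimensionless retention-index scale in
#' which the n-alkane with n carbons scores exactly 100 n. Between two
#' bracketing ladder alkanes eluting at `rt_n` and `rt_n1`,
#'
#' \deqn{RI = 100 \left[ n + (n' - n)\,\frac{rt - rt_n}{rt_{n'} - rt_n} \right]}
#'
#' where n' is the next ladder carbon number (n + 1 for a contiguous
#' ladder). A query equal to a ladder retention time returns 100 n exactly.
#' Queries outside the ladder span are errors: the index is defined only
#' between bracketing alkanes and no extrapolation is attempted.
#'
#' @param rt_min Numeric vector of retention times, minutes.
#' @param ladder An [alkane_ladder()].
#' @return A tibble with columns `rt_min`, `ri`, `bracket_low`,
#'   `bracket_high` (the bracketing carbon numbers).
#' @export
#' @examples
#' lad <- alkane_ladder(10:12, c(10, 13, 17.06))
#' retention_index(c(10, 11.5, 17.06), lad)
retention_index <- function(rt_min, ladder) {
  rt_min <- as.numeric(rt_min)
  lrt <- ladder$rt_min
  lcn <- ladder$carbon_number
  span <- range(lrt)
  out_of_span <- !is.na(rt_min) & (rt_min < span[1] | rt_min > span[2])
  if (any(out_of_span)) {
    abort(sprintf(
      "Retention time %.4g min is outside the ladder span [%.4g, %.4g]; no extrapolation.",
      rt_min[which(out_of_span)[1]], span[1], span[2]
    ), class = "aromascreen_range_error")
  }
  idx <- findInterval(rt_min, lrt, all.inside = TRUE)
  lo <- lcn[idx]
  hi <- lcn[idx + 1]
  frac <- (rt_min - lrt[idx]) / (lrt[idx + 1] - lrt[idx])
  ri <- 100 * (lo + frac * (hi - lo))
  # exact self-index for ladder nodes (guards against FP drift in `frac`)
  node <- match(rt_min, lrt)
  hit <- !is.na(node)
  ri[hit] <- 100 * lcn[node[hit]]
  lo[hit] <- lcn[node[hit]]
  hi[hit] <- lcn[pmin(node[hit] + 1, length(lcn))]
  tibble(rt_min = rt_min, ri = ri, bracket_low = lo, bracket_high = hi)
}

#' Assign retention indices to every compound of a peak table
#'
#' @param x A [peak_table()].
#' @param ladder An [alkane_ladder()].
#' @return A tibble `id, name, rt_min, ri, bracket_low, bracket_high`,
#'   in peak-table compound order.
#' @export
assign_retention_indices <- function(x, ladder) {
  ri <- retention_index(x$compounds$rt_min, ladder)
  dplyr::bind_cols(x$compounds[, c("id", "name")], ri)
}

#' Filter a peak table by library match score
#'
#' Retains compounds whose spectral-library match score strictly exceeds
#' `min_score` (default 80, the conventional cut-off for accepting a library
#' identification). Compounds with a missing score are retained with a
#' warning, so that literature-derived tables without scores can flow
#' through the pipeline; `strict = TRUE` turns a missing score into an
#' error instead.
#'
#' @param x A [peak_table()].
#' @param min_score Retention cut-off; strict inequality (a score equal to
#'   `min_score` is dropped).
#' @param strict Error on missing scores instead of retaining them.
#' @return A [peak_table()] containing the retained compounds, input order
#'   preserved. The filter is idempotent.
#' @export
filter_by_match_score <- function(x, min_score = 80, strict = FALSE) {
  score <- x$compounds$match_score
  if (anyNA(score)) {
    if (strict) {
      abort("match_score missing for some compounds (strict mode).",
            class = "aromascreen_validation_error")
    }
    warn(sprintf(
      "match_score missing for %d compound(s); retaining them.",
      sum(is.na(score))
    ))
  }
  keep <- is.na(score) | score > min_score
  x[which(keep)]
}
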