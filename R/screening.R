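#' Screen key compounds by VIP and p-value
#'
#' Applies the classical double criterion for key differential volatiles:
#' a compound passes when its VIP score strictly exceeds `vip_min` (default
#' 1) AND its t-test p-value is strictly below `p_max` (default 0.05).
#' Boundary values (VIP exactly 1, p exactly 0.05) are excluded.
#'
#' @param stats A data frame with columns `vip` and `p` plus any identifier
#'   columns (`id`, `name`, ...), or two named numeric vectors via `vip`
#'   and `p` arguments.
#' @param vip Named numeric VIP vector (alternative to `stats`).
#' @param p Named numeric p-value vector, same names as `vip`.
#' @param vip_min,p_max Screen cut-offs.
#' @return A `screen_result` tibble: identifier columns, `vip`, `p`,
#'   `passed`, sorted by descending VIP within the passing set first. The
#'   attribute `n_passed` gives the count.
#' @export
#' @examples
#' screen_key_compounds(data.frame(id = c("a", "b"), vip = c(1.2, 0.9),
#'                                 p = c(0.01, 0.2)))
screen_key_compounds <- function(stats = NULL, vip = NULL, p = NULL,
                                 vip_min = 1, p_max = 0.05) {
  if (is.null(stats)) {
    if (is.null(vip) || is.null(p)) {
      abort("Provide either `stats` or both `vip` and `p`.",
            class = "aromascreen_argument_error")
    }
    if (!identical(sort(names(vip)), sort(names(p)))) {
      abort("`vip` and `p` must be defined for the same compound set.",
            class = "aromascreen_key_error")
    }
    ids <- names(vip)
    stats <- tibble(id = ids, vip = unname(vip), p = unname(p[ids]))
  }
  stats <- as_tibble(stats)
  check_columns(stats, c("vip", "p"), "screen input")
  stats$passed <- stats$vip > vip_min & stats$p < p_max
  out <- dplyr::arrange(stats, dplyr::desc(.data$passed),
                        dplyr::desc(.data$vip))
  attr(out, "n_passed") <- sum(out$passed)
  class(out) <- c("screen_result", class(out))
  out
}

#' Passing subset of a screen result
#' @param x A `screen_result` from [screen_key_compounds()].
#' @return Tibble of passing compounds, descending VIP.
#' @export
key_compounds <- function(x) {
  out <- x[x$passed, , drop = FALSE]
  class(out) <- setdiff(class(out), "screen_result")
  out
}
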