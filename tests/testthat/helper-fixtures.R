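# small in-code fixtures shared across test files

tiny_compounds <- function(n = 3, class = "ester") {
  data.frame(
    id = paste0("c", seq_len(n)),
    name = paste0("compound-", seq_len(n)),
    cas = "", formula = "",
    class = rep_len(class, n),
    rt_min = seq(5, by = 2, length.out = n),
    match_score = rep(90, n)
  )
}

tiny_peak_table <- function(areas, groups = NULL, ...) {
  areas <- as.matrix(areas)
  if (is.null(groups)) {
    half <- ncol(areas) / 2
    groups <- setNames(rep(c("A", "B"), each = half),
                       paste0("S", seq_len(ncol(areas))))
  }
  peak_table(tiny_compounds(nrow(areas), ...), areas, groups)
}

random_peak_table <- function(n_compounds = 8, n_per_group = 3, seed = 1) {
  withr::with_seed(seed, {
    areas <- matrix(exp(rnorm(n_compounds * 2 * n_per_group, 10, 1)),
                    nrow = n_compounds)
    tiny_peak_table(areas,
                    groups = setNames(rep(c("A", "B"), each = n_per_group),
                                      paste0("S", seq_len(2 * n_per_group))))
  })
}
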