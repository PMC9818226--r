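#' Run the full differential volatile-aroma pipeline
#'
#' Orchestrates every stage on a two-group peak table: retention-index
#' assignment (when a ladder is supplied), library-match filtering,
#' relative quantification, detection counts and class totals, Z-scoring,
#' cluster ordering, PCA, OPLS-DA with permutation validation, per-compound
#' t-tests, the VIP > 1 and p < 0.05 screen, per-group rOAV with
#' reference-compound normalisation, and aroma-type profiles. Identical
#' inputs, options and seed produce identical outputs.
#'
#' When the table carries fewer than 2 replicates per group (e.g. a table
#' of published group means), the chemometric stage cannot be fitted and
#' is refused; externally supplied per-compound VIP/p values
#' (`external_stats`) then drive the screening stage instead.
#'
#' @param peaks A [peak_table()] with exactly 2 groups.
#' @param thresholds A [threshold_table()] for rOAV and profiling.
#' @param ladder Optional [alkane_ladder()] for retention indices.
#' @param external_stats Optional tibble `id, name, vip, p` replacing the
#'   fitted chemometrics (required when replicates are unavailable).
#' @param min_match_score Library-match filter cut-off (strict >).
#' @param vip_min,p_max Screening cut-offs (strict inequalities).
#' @param roav_bounds Length-2 numeric: the critical and negligible rOAV
#'   boundaries (defaults 1 and 0.1); currently informational, the
#'   classifier uses the conventional bands.
#' @param ttest_variant `"pooled"` or `"welch"`.
#' @param k_ortho,cv_folds,scale Passed to [fit_oplsda()].
#' @param n_perm Permutations for model validation (0 skips it).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Optional directory; when given, every stage's CSV and a
#'   JSON summary are written there, each CSV stamped with the run hash.
#' @param quiet Suppress per-stage progress messages.
#' @return A `pipeline_result` list: `ri`, `relative_content`, `counts`,
#'   `class_totals`, `chemometrics` (NULL when refused), `screen`,
#'   `roav` (per group), `profiles` (per group), `summary`, `config`.
#' @export
run_pipeline <- function(peaks, thresholds, ladder = NULL,
                         external_stats = NULL, min_match_score = 80,
                         vip_min = 1, p_max = 0.05, roav_bounds = c(1, 0.1),
                         ttest_variant = c("pooled", "welch"),
                         k_ortho = "auto", cv_folds = 7, scale = TRUE,
                         n_perm = 200, seed = 1L, out_dir = NULL,
                         quiet = FALSE) {
  ttest_variant <- match.arg(ttest_variant)
  validate_peak_table(peaks)
  gl <- require_two_groups(peaks)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] ", stage), sprintf(fmt, ...))
  }

  config <- list(
    groups = gl, min_match_score = min_match_score, vip_min = vip_min,
    p_max = p_max, roav_bounds = roav_bounds, ttest_variant = ttest_variant,
    k_ortho = k_ortho, cv_folds = cv_folds, scale = scale, n_perm = n_perm,
    seed = as.integer(seed)
  )
  run_hash <- config_hash(config)

  ri <- NULL
  if (!is.null(ladder)) {
    ri <- assign_retention_indices(peaks, ladder)
    say("ri", "%d retention indices assigned", nrow(ri))
  }

  filtered <- withCallingHandlers(
    filter_by_match_score(peaks, min_match_score),
    warning = function(w) {
      say("filter", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  say("filter", "%d / %d compounds retained (match score > %g)",
      n_compounds(filtered), n_compounds(peaks), min_match_score)

  rc <- relative_content(filtered)
  counts <- setNames(vapply(gl, function(g) count_detected(filtered, g),
                            integer(1)), gl)
  totals <- lapply(setNames(gl, gl), function(g) class_totals(rc, g))
  say("quantify", "detected: %s", paste(gl, counts, collapse = ", "))

  min_reps <- min(table(filtered$groups))
  chem <- NULL
  if (min_reps >= 2) {
    z <- zscore(filtered)
    chem <- list(
      z = z,
      row_order = hcluster_order(z, "rows"),
      col_order = hcluster_order(z, "columns"),
      pca = fit_pca(z, k = min(2, ncol(z) - 1)),
      oplsda = fit_oplsda(filtered, filtered$groups, k_ortho = k_ortho,
                          cv_folds = cv_folds, seed = seed, scale = scale),
      ttests = ttest_peaks(filtered, ttest_variant)
    )
    if (n_perm >= 2) {
      chem$permutation <- permutation_test(
        filtered, filtered$groups, n_perm = n_perm, seed = seed,
        k_ortho = chem$oplsda$k_ortho, cv_folds = cv_folds, scale = scale
      )
    }
    stats <- tibble(
      id = filtered$compounds$id, name = filtered$compounds$name,
      vip = unname(chem$oplsda$vip), p = chem$ttests$p
    )
    say("chemometrics", "OPLS-DA R2X=%.3f R2Y=%.3f Q2=%.3f (k_ortho=%d)",
        chem$oplsda$R2X, chem$oplsda$R2Y, chem$oplsda$Q2,
        chem$oplsda$k_ortho)
  } else {
    if (is.null(external_stats)) {
      abort(paste(
        "Stage 'chemometrics': fewer than 2 replicates per group;",
        "OPLS-DA cannot be fitted. Supply `external_stats` (id, name, vip, p)."
      ), class = "aromascreen_validation_error")
    }
    stats <- as_tibble(external_stats)
    check_columns(stats, c("name", "vip", "p"), "external_stats")
    say("chemometrics", "refused (%d replicate/group); using external VIP/p",
        min_reps)
  }

  screen <- screen_key_compounds(stats, vip_min = vip_min, p_max = p_max)
  keys <- key_compounds(screen)
  say("screen", "%d key compounds (VIP > %g & p < %g)", nrow(keys),
      vip_min, p_max)

  roav <- list()
  profiles <- list()
  for (g in gl) {
    contents <- content_means(rc, g)
    contents <- contents[names(contents) %in% keys$name]
    rt <- tryCatch(
      compute_roav(contents, thresholds, group = g, quiet = TRUE),
      error = function(e) NULL
    )
    if (is.null(rt)) {
      say("roav", "group %s: no scorable compounds", g)
      next
    }
    roav[[g]] <- rt
    profiles[[g]] <- aroma_profile(rt, thresholds)
    say("roav", "group %s: reference %s, %d scored, %d excluded", g,
        attr(rt, "reference"), nrow(rt), length(attr(rt, "excluded")))
  }

  summary <- list(
    run_hash = run_hash,
    n_compounds_input = n_compounds(peaks),
    n_compounds_retained = n_compounds(filtered),
    detected = as.list(counts),
    class_totals = lapply(totals, as.list),
    model = if (!is.null(chem)) {
      list(R2X = chem$oplsda$R2X, R2Y = chem$oplsda$R2Y,
           Q2 = chem$oplsda$Q2, k_ortho = chem$oplsda$k_ortho,
           pca_explained_pct = chem$pca$explained_pct,
           permutation_intercepts = if (!is.null(chem$permutation)) {
             list(R2Y = chem$permutation$r2y_intercept,
                  Q2 = chem$permutation$q2_intercept)
           })
    },
    n_key_compounds = nrow(keys),
    key_compounds = keys$name,
    references = lapply(roav, attr, "reference"),
    config = config
  )

  result <- structure(
    list(ri = ri, relative_content = rc, counts = counts,
         class_totals = totals, chemometrics = chem, screen = screen,
         roav = roav, profiles = profiles, summary = summary,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  detected:", paste(names(x$counts), x$counts, collapse = ", "), "\n")
  cat("  key compounds:", x$summary$n_key_compounds, "\n")
  for (g in names(x$roav)) {
    cat(sprintf("  %s: reference %s (rOAV 100)\n", g,
                attr(x$roav[[g]], "reference")))
  }
  invisible(x)
}

# write every stage table plus the machine-readable summary
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- result$summary$run_hash
  if (!is.null(result$ri)) {
    write_stage_csv(result$ri, file.path(out_dir, "retention_index.csv"), h)
  }
  rc <- result$relative_content
  rc_df <- dplyr::bind_cols(rc$summary, as_tibble(as.data.frame(rc$percent)))
  write_stage_csv(rc_df, file.path(out_dir, "relative_content.csv"), h)
  write_stage_csv(as_tibble(as.data.frame(result$screen)),
                  file.path(out_dir, "screen.csv"), h)
  if (!is.null(result$chemometrics)) {
    ch <- result$chemometrics
    write_stage_csv(tibble(id = rownames(ch$z) %||%
                             as.character(seq_len(nrow(ch$z))),
                           vip = unname(ch$oplsda$vip)),
                    file.path(out_dir, "vip.csv"), h)
    write_stage_csv(ch$ttests, file.path(out_dir, "ttests.csv"), h)
    if (!is.null(ch$permutation)) {
      write_stage_csv(ch$permutation$results,
                      file.path(out_dir, "permutation.csv"), h)
    }
  }
  for (g in names(result$roav)) {
    write_stage_csv(as_tibble(as.data.frame(result$roav[[g]])),
                    file.path(out_dir, sprintf("roav_%s.csv", g)), h)
    write_stage_csv(as_tibble(as.data.frame(result$profiles[[g]])),
                    file.path(out_dir, sprintf("aroma_profile_%s.csv", g)), h)
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# stable short hash of the run configuration (md5 of its serialized JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}
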