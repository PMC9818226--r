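#' Configuration for the synthetic volatile-compound generator
#'
#' Defines the statistical structure the differential pipeline assumes: a
#' two-group replicated design with log-normally distributed peak areas, a
#' subset of truly differential compounds carrying a fold change in the
#' second group, and a subset of compounds fully (or partially) dropped out
#' in the first group, emulating maturity-specific volatiles. Defaults
#' mirror a typical fruit-volatile study: 42 compounds, 2 groups x 3
#' biological replicates, log-scale SD 0.3 (a coefficient of variation of
#' ~30%, in line with tight replicate SDs in headspace GC-MS), 10
#' differential compounds at log2 fold change 2, and 6 compounds absent
#' from group 1.
#'
#' @param n_compounds Number of compounds.
#' @param n_replicates Replicates per group.
#' @param groups Two group labels.
#' @param mu_log Range (length-2) from which each compound's log-mean
#'   abundance is drawn uniformly (natural log of instrument units).
#' @param sigma_log Log-scale SD of replicate noise (> 0).
#' @param n_differential Number of compounds given a fold change in group 2.
#' @param log2_fc Log2 fold-change magnitude applied to differential
#'   compounds in group 2.
#' @param n_dropout Number of compounds subject to dropout in group 1.
#' @param dropout_prob Per-sample probability that a dropout-subset
#'   compound is missing in group 1 (1 = always absent there).
#' @param ladder_carbons Carbon-number range of the alkane ladder.
#' @param rt_span Retention-time span (minutes) covered by the ladder.
#' @param threshold_range Log-uniform range (mg/kg) for odor thresholds.
#' @param descriptor_vocab Aroma-term vocabulary to draw descriptors from.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_compounds = 42, n_replicates = 3,
                       groups = c("G1", "G2"),
                       mu_log = c(log(1e5), log(1e7)), sigma_log = 0.3,
                       n_differential = 10, log2_fc = 2,
                       n_dropout = 6, dropout_prob = 1,
                       ladder_carbons = c(7, 27), rt_span = c(3, 45),
                       threshold_range = c(1e-4, 10),
                       descriptor_vocab = c("floral", "fruity", "green",
                                            "sweet", "woody", "citrus",
                                            "herbal", "honey", "rose",
                                            "cedar"),
                       seed = 1L) {
  cfg <- list(
    n_compounds = as.integer(n_compounds),
    n_replicates = as.integer(n_replicates),
    groups = as.character(groups),
    mu_log = as.numeric(mu_log), sigma_log = as.numeric(sigma_log),
    n_differential = as.integer(n_differential),
    log2_fc = as.numeric(log2_fc),
    n_dropout = as.integer(n_dropout),
    dropout_prob = as.numeric(dropout_prob),
    ladder_carbons = as.integer(ladder_carbons),
    rt_span = as.numeric(rt_span),
    threshold_range = as.numeric(threshold_range),
    descriptor_vocab = as.character(descriptor_vocab),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_compounds < 1 || n_replicates < 1) {
      abort("n_compounds and n_replicates must be positive.",
            class = "aromascreen_validation_error")
    }
    if (length(groups) != 2 || anyDuplicated(groups)) {
      abort("Exactly 2 distinct group labels are required.",
            class = "aromascreen_validation_error")
    }
    if (sigma_log <= 0) {
      abort("sigma_log must be > 0.", class = "aromascreen_validation_error")
    }
    if (n_differential > n_compounds || n_dropout > n_compounds) {
      abort("Differential/dropout subsets cannot exceed n_compounds.",
            class = "aromascreen_validation_error")
    }
    if (dropout_prob < 0 || dropout_prob > 1) {
      abort("dropout_prob must lie in [0, 1].",
            class = "aromascreen_validation_error")
    }
    if (any(threshold_range <= 0) || diff(threshold_range) < 0) {
      abort("threshold_range must be positive and increasing.",
            class = "aromascreen_validation_error")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic volatile-compound experiment
#'
#' Draws a complete, validated experiment from a [sim_config()]: a
#' [peak_table()] with log-normal areas, fold changes injected into the
#' differential subset (group 2) and dropouts into the dropout subset
#' (group 1); an [alkane_ladder()] spanning the configured retention
#' window; a [threshold_table()] with log-uniform thresholds and random
#' descriptors; and a ground-truth record naming the injected compounds.
#' Identical seeds give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list `peak_table`, `ladder`, `thresholds`, `truth` (list with
#'   `differential`, `dropout`, `log2_fc`, `seed`).
#' @export
#' @examples
#' sim <- simulate_volatile_experiment(sim_config(seed = 7))
#' sim$truth$differential
simulate_volatile_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, {
    nc <- config$n_compounds
    nr <- config$n_replicates
    samples <- paste0(rep(config$groups, each = nr), "_", seq_len(nr))
    groups <- setNames(rep(config$groups, each = nr), samples)

    ids <- paste0("V", seq_len(nc))
    carbons <- seq(config$ladder_carbons[1], config$ladder_carbons[2])
    ladder_rt <- sort(runif(length(carbons), config$rt_span[1],
                            config$rt_span[2]))
    ladder <- alkane_ladder(carbons, ladder_rt)
    # compound RTs within the ladder's observed span so every compound is
    # indexable without extrapolation
    rt <- sort(runif(nc, min(ladder_rt), max(ladder_rt)))

    compounds <- tibble(
      id = ids,
      name = paste0("compound-", seq_len(nc)),
      cas = "", formula = "",
      class = sample(COMPOUND_CLASSES, nc, replace = TRUE),
      rt_min = rt,
      match_score = round(runif(nc, 81, 99), 1)
    )

    mu <- runif(nc, config$mu_log[1], config$mu_log[2])
    areas <- matrix(
      exp(rnorm(nc * length(samples), mean = mu, sd = config$sigma_log)),
      nrow = nc
    )
    diff_idx <- if (config$n_differential > 0) {
      sort(sample(nc, config$n_differential))
    } else {
      integer(0)
    }
    g2_cols <- which(groups == config$groups[2])
    areas[diff_idx, g2_cols] <- areas[diff_idx, g2_cols] * 2^config$log2_fc

    drop_pool <- setdiff(seq_len(nc), diff_idx)
    drop_idx <- if (config$n_dropout > 0) {
      sort(sample(drop_pool, min(config$n_dropout, length(drop_pool))))
    } else {
      integer(0)
    }
    detected <- matrix(TRUE, nc, length(samples))
    g1_cols <- which(groups == config$groups[1])
    for (i in drop_idx) {
      miss <- runif(length(g1_cols)) < config$dropout_prob
      detected[i, g1_cols[miss]] <- FALSE
    }
    areas[!detected] <- 0

    thresholds <- threshold_table(
      name = compounds$name,
      threshold_mg_per_kg = exp(runif(nc, log(config$threshold_range[1]),
                                      log(config$threshold_range[2]))),
      descriptors = vapply(seq_len(nc), function(i) {
        paste(sample(config$descriptor_vocab,
                     sample(1:3, 1)), collapse = ";")
      }, character(1))
    )

    list(
      peak_table = peak_table(compounds, areas, groups, detected),
      ladder = ladder,
      thresholds = thresholds,
      truth = list(differential = ids[diff_idx], dropout = ids[drop_idx],
                   log2_fc = config$log2_fc, seed = config$seed)
    )
  })
}

#' Write a simulated experiment to the canonical CSV files
#'
#' Emits the three canonical inputs (`peaks.csv` + `samples.csv`,
#' `ladder.csv`, `thresholds.csv`) plus a `truth.json` sidecar recording
#' the injected effects and the seed.
#'
#' @param sim Result of [simulate_volatile_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_table(sim$peak_table, file.path(dir, "peaks.csv"),
                   file.path(dir, "samples.csv"))
  readr::write_csv(as.data.frame(sim$ladder), file.path(dir, "ladder.csv"))
  thr <- tibble(
    name = sim$thresholds$name,
    threshold_mg_per_kg = sim$thresholds$threshold_mg_per_kg,
    descriptors = vapply(sim$thresholds$descriptors, paste,
                         character(1), collapse = ";")
  )
  readr::write_csv(thr, file.path(dir, "thresholds.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
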