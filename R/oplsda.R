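#' Orthogonal partial least squares discriminant analysis (OPLS-DA)
#'
#' Fits a two-class OPLS-DA model: class labels are dummy-coded and
#' centred, `k_ortho` components of predictor variation orthogonal to the
#' class contrast are iteratively removed (orthogonal signal correction),
#' and a single predictive PLS component is fitted on the filtered matrix.
#' This is the standard supervised screen for two-group metabolite panels:
#' the predictive component carries the between-group contrast, the
#' orthogonal components absorb structured within-group variation, and the
#' per-variable VIP scores rank compounds by contribution to the
#' separation.
#'
#' Model statistics follow the usual conventions: `R2X` is the cumulative
#' fraction of (preprocessed) X variance captured by all extracted
#' components, `R2Y` the fraction of class-label variance explained by the
#' fitted predictive component, and `Q2 = 1 - PRESS/SS` from stratified
#' k-fold cross-validation in which the whole extraction (orthogonal
#' filtering included) is refitted on every training split. With fewer
#' samples than `cv_folds` the scheme reduces to leave-one-out, the
#' de-facto behaviour for typical 3 + 3 replicate designs.
#'
#' @param x Samples x variables numeric matrix, or a [peak_table()] (rows
#'   become variables).
#' @param y Class labels: factor/character/logical with exactly 2 levels,
#'   each with >= 2 samples.
#' @param k_ortho Number of orthogonal components, or `"auto"`: components
#'   are added while cross-validated Q2 improves by more than 0.01, capped
#'   at `min(n_samples - 3, 5)`.
#' @param cv_folds Cross-validation folds (default 7, reduced to
#'   leave-one-out when `n_samples < cv_folds`).
#' @param seed Integer seed fixing the stratified fold assignment.
#' @param scale Unit-variance scale each variable (default TRUE, matching a
#'   z-score pipeline); centring is always applied.
#' @param vip_flavor `"total"` (VIP over predictive + orthogonal
#'   components, weighted by explained label variance) or `"predictive"`.
#' @return An `oplsda` object: list with predictive
#'   scores/loadings/weights (`scores_pred`, `loadings_pred`,
#'   `weights_pred`, regression coefficient `q`), orthogonal counterparts
#'   (`scores_ortho`, ...), `fitted`, `R2X`, `R2Y`, `Q2`, `vip`,
#'   `k_ortho`, `cv_config`, `y_levels`, `y_num`.
#' @export
fit_oplsda <- function(x, y, k_ortho = "auto", cv_folds = 7, seed = 1L,
                       scale = TRUE, vip_flavor = c("total", "predictive")) {
  vip_flavor <- match.arg(vip_flavor)
  if (inherits(x, "peak_table")) x <- t(x$areas)
  X0 <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) {
    abort(sprintf("OPLS-DA requires exactly 2 classes; got %d.", nlevels(y)),
          class = "aromascreen_validation_error")
  }
  if (any(table(y) < 2)) {
    abort("Each class needs at least 2 samples.",
          class = "aromascreen_validation_error")
  }
  n <- nrow(X0)
  if (length(y) != n) {
    abort("length(y) must equal nrow(x).",
          class = "aromascreen_validation_error")
  }

  prep <- opls_preprocess(X0, scale)
  yn <- as.numeric(y == levels(y)[2])
  yc <- yn - mean(yn)

  folds <- make_stratified_folds(y, cv_folds, seed)
  n_folds <- length(unique(folds))

  cap <- max(0, min(n - 3, 5))
  if (identical(k_ortho, "auto")) {
    q2 <- oplsda_cv_q2(X0, yn, y, 0, folds, scale)
    k_sel <- 0
    while (k_sel < cap) {
      q2_next <- oplsda_cv_q2(X0, yn, y, k_sel + 1, folds, scale)
      if (is.na(q2_next) || q2_next - q2 <= 0.01) break
      q2 <- q2_next
      k_sel <- k_sel + 1
    }
    k_ortho <- k_sel
    Q2 <- q2
  } else {
    k_ortho <- as.integer(k_ortho)
    Q2 <- oplsda_cv_q2(X0, yn, y, k_ortho, folds, scale)
  }

  core <- opls_core(prep$X, yc, k_ortho)
  R2X <- core$ssx_explained / sum(prep$X^2)
  R2Y <- 1 - sum((yc - core$yhat)^2) / sum(yc^2)

  model <- structure(
    list(
      scores_pred = core$t_pred, loadings_pred = core$p_pred,
      weights_pred = core$w_pred, q = core$q,
      scores_ortho = core$t_ortho, loadings_ortho = core$p_ortho,
      weights_ortho = core$w_ortho,
      fitted = core$yhat + mean(yn),
      R2X = R2X, R2Y = R2Y, Q2 = Q2,
      k_ortho = k_ortho,
      cv_config = list(folds = n_folds, requested_folds = cv_folds,
                       seed = seed, scheme = if (n_folds == n) "loo"
                       else "stratified k-fold"),
      y_levels = levels(y), y_num = yn,
      scale = scale, preprocess = prep[c("center", "scale_vec")],
      var_names = colnames(X0) %||% paste0("V", seq_len(ncol(X0)))
    ),
    class = "oplsda"
  )
  model$vip <- compute_vip(model, vip_flavor)
  if (!is.na(model$Q2) && model$Q2 > model$R2Y) {
    warn(sprintf("Q2 (%.3f) exceeds R2Y (%.3f); inspect the fit.",
                 model$Q2, model$R2Y))
  }
  model
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "<oplsda> 1 predictive + %d orthogonal component(s)\n  R2X = %.3f, R2Y = %.3f, Q2 = %.3f (%s, %d folds, seed %d)\n",
    x$k_ortho, x$R2X, x$R2Y, x$Q2, x$cv_config$scheme, x$cv_config$folds,
    x$cv_config$seed
  ))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' VIP summarises each variable's contribution to a PLS-type model:
#' \deqn{VIP_j = \sqrt{ p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a }}
#' with p the number of variables, `w_a` the component weight vectors and
#' `SSY_a` the label variance explained by component a. The mean of squared
#' VIP over variables is 1 by construction, so VIP > 1 flags variables
#' contributing more than average. The `"total"` flavor sums over the
#' predictive and orthogonal components jointly (orthogonal components
#' explain essentially no label variance, so in practice it coincides with
#' the predictive flavor up to the weight they carry); `"predictive"` uses
#' the predictive component alone.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param flavor `"total"` or `"predictive"`.
#' @return Named numeric vector of VIP scores, one per variable.
#' @export
compute_vip <- function(model, flavor = c("total", "predictive")) {
  flavor <- match.arg(flavor)
  yc <- model$y_num - mean(model$y_num)
  comp_w <- list(model$weights_pred)
  comp_t <- list(model$scores_pred)
  if (flavor == "total" && model$k_ortho > 0) {
    for (a in seq_len(model$k_ortho)) {
      comp_w <- c(comp_w, list(model$weights_ortho[, a]))
      comp_t <- c(comp_t, list(model$scores_ortho[, a]))
    }
  }
  p <- length(model$weights_pred)
  num <- rep(0, p)
  den <- 0
  for (a in seq_along(comp_w)) {
    t_a <- as.numeric(comp_t[[a]])
    w_a <- as.numeric(comp_w[[a]])
    b <- sum(yc * t_a) / sum(t_a^2)
    ssy <- b^2 * sum(t_a^2)
    num <- num + ssy * (w_a / sqrt(sum(w_a^2)))^2
    den <- den + ssy
  }
  setNames(sqrt(p * num / den), model$var_names)
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model under `n_perm` random permutations of the class labels
#' with identical hyperparameters, recording for each the absolute Pearson
#' correlation between permuted and original dummy-coded labels together
#' with the refitted R2Y and Q2. A sound model's permuted Q2 values fall
#' toward or below zero as the label correlation drops; the intercepts of
#' the least-squares lines of R2Y and Q2 versus label correlation summarise
#' the validation plot. The unpermuted model is included as the reference
#' point (correlation 1).
#'
#' @param x,y,k_ortho,cv_folds,scale As in [fit_oplsda()].
#' @param n_perm Number of permutations (>= 2; classical default 200).
#' @param seed Integer seed for the permutations and fold assignments.
#' @return An `oplsda_permutation` object: list with `results` (tibble
#'   `correlation, R2Y, Q2, reference`), `r2y_intercept`, `q2_intercept`,
#'   `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 200, seed = 1L, k_ortho = "auto",
                             cv_folds = 7, scale = TRUE) {
  if (n_perm < 2) {
    abort("n_perm must be >= 2.", class = "aromascreen_argument_error")
  }
  if (inherits(x, "peak_table")) x <- t(x$areas)
  y <- as.factor(y)
  yn <- as.numeric(y == levels(y)[2])

  ref <- fit_oplsda(x, y, k_ortho = k_ortho, cv_folds = cv_folds,
                    seed = seed, scale = scale)
  k_fixed <- ref$k_ortho  # identical hyperparameters for every refit

  perms <- withr::with_seed(seed, {
    replicate(n_perm, sample(seq_along(yn)), simplify = FALSE)
  })
  rows <- lapply(perms, function(idx) {
    yp <- y[idx]
    fit <- fit_oplsda(x, yp, k_ortho = k_fixed, cv_folds = cv_folds,
                      seed = seed, scale = scale)
    tibble(
      correlation = abs(cor(as.numeric(yp == levels(y)[2]), yn)),
      R2Y = fit$R2Y, Q2 = fit$Q2, reference = FALSE
    )
  })
  results <- dplyr::bind_rows(
    tibble(correlation = 1, R2Y = ref$R2Y, Q2 = ref$Q2, reference = TRUE),
    dplyr::bind_rows(rows)
  )
  structure(
    list(
      results = results,
      r2y_intercept = unname(coef(lm(R2Y ~ correlation, data = results))[1]),
      q2_intercept = unname(coef(lm(Q2 ~ correlation, data = results))[1]),
      n_perm = n_perm, model = ref
    ),
    class = "oplsda_permutation"
  )
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf(
    "<oplsda_permutation> %d permutations\n  intercepts at zero label-correlation: R2Y = %.3f, Q2 = %.3f\n",
    x$n_perm, x$r2y_intercept, x$q2_intercept
  ))
  invisible(x)
}

# ---- internal OPLS machinery -----------------------------------------------

opls_preprocess <- function(X, scale, center = NULL, scale_vec = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (is.null(scale_vec)) {
    scale_vec <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
    scale_vec[scale_vec == 0] <- 1
  }
  list(X = sweep(Xc, 2, scale_vec, "/"), center = center,
       scale_vec = scale_vec)
}

# one predictive PLS component after k_ortho rounds of orthogonal signal
# correction (Trygg & Wold style O-PLS for a single response)
opls_core <- function(X, yc, k_ortho) {
  p <- ncol(X)
  n <- nrow(X)
  w_ortho <- matrix(0, p, 0)
  p_ortho <- matrix(0, p, 0)
  t_ortho <- matrix(0, n, 0)
  ssx_explained <- 0
  Xf <- X
  for (a in seq_len(k_ortho)) {
    w <- crossprod(Xf, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_p <- Xf %*% w
    pl <- crossprod(Xf, t_p) / sum(t_p^2)
    wo <- pl - as.numeric(crossprod(w, pl)) * w
    won <- sqrt(sum(wo^2))
    if (won < 1e-12) break  # no orthogonal variation left
    wo <- wo / won
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    w_ortho <- cbind(w_ortho, as.numeric(wo))
    p_ortho <- cbind(p_ortho, as.numeric(po))
    t_ortho <- cbind(t_ortho, as.numeric(to))
    ssx_explained <- ssx_explained + sum(to^2) * sum(po^2)
  }
  w <- crossprod(Xf, yc)
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) {
    abort("Predictor matrix carries no variation along the class contrast.",
          class = "aromascreen_validation_error")
  }
  w <- as.numeric(w / wn)
  t_pred <- as.numeric(Xf %*% w)
  p_pred <- as.numeric(crossprod(Xf, t_pred) / sum(t_pred^2))
  q <- sum(yc * t_pred) / sum(t_pred^2)
  list(
    w_pred = w, t_pred = t_pred, p_pred = p_pred, q = q,
    yhat = t_pred * q,
    w_ortho = w_ortho, p_ortho = p_ortho, t_ortho = t_ortho,
    n_ortho = ncol(w_ortho),
    ssx_explained = ssx_explained + sum(t_pred^2) * sum(p_pred^2)
  )
}

# stratified fold ids; reduces to LOO when n < requested folds
make_stratified_folds <- function(y, cv_folds, seed) {
  n <- length(y)
  if (n < cv_folds) return(seq_len(n))
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
  })
  # every training split must retain both classes
  for (f in unique(folds)) {
    if (nlevels(droplevels(y[folds != f])) < 2) {
      abort("A cross-validation split loses an entire class; reduce folds.",
            class = "aromascreen_validation_error")
    }
  }
  folds
}

# cross-validated Q2 = 1 - PRESS/SS for a fixed k_ortho
oplsda_cv_q2 <- function(X0, yn, y, k_ortho, folds, scale) {
  press <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    te <- !tr
    prep <- opls_preprocess(X0[tr, , drop = FALSE], scale)
    yc_tr <- yn[tr] - mean(yn[tr])
    core <- opls_core(prep$X, yc_tr, k_ortho)
    Xte <- opls_preprocess(X0[te, , drop = FALSE], scale,
                           center = prep$center,
                           scale_vec = prep$scale_vec)$X
    if (core$n_ortho > 0) {
      for (a in seq_len(core$n_ortho)) {
        to <- Xte %*% core$w_ortho[, a]
        Xte <- Xte - to %*% t(core$p_ortho[, a])
      }
    }
    yhat <- as.numeric(Xte %*% core$w_pred) * core$q + mean(yn[tr])
    press <- press + sum((yn[te] - yhat)^2)
  }
  1 - press / sum((yn - mean(yn))^2)
}
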