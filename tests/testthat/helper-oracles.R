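# Independent oracles used to cross-check the package's computations.
# Each is written from first principles and shares no code with R/.

# piecewise-linear interpolation of retention index on the 100*carbon scale
oracle_ri <- function(rt, carbons, ladder_rt) {
  stats::approx(x = ladder_rt, y = 100 * carbons, xout = rt)$y
}

# naive O(n^3) average-linkage (UPGMA) agglomeration on Euclidean distances;
# returns merge heights and the partition (list of index sets) after each
# merge; ties broken by the lexicographically smallest index pair
oracle_upgma <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d - 1e-12) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for set comparison
canon_partition <- function(sets) {
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","),
                 character(1), USE.NAMES = FALSE)
  sort(unname(keys))
}

# textbook NIPALS iteration for a single-response, one-component PLS1 fit
oracle_nipals_pls1 <- function(X, y, tol = 1e-12, max_iter = 500) {
  u <- y
  w <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    w_new <- crossprod(X, u)
    w_new <- w_new / sqrt(sum(w_new^2))
    t_sc <- X %*% w_new
    q <- sum(y * t_sc) / sum(t_sc^2)
    u <- y * q
    if (sqrt(sum((w_new - w)^2)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  t_sc <- as.numeric(X %*% w)
  list(w = as.numeric(w), t = t_sc, q = sum(y * t_sc) / sum(t_sc^2))
}

# two-sided p-value of a t statistic via numeric integration of the t density
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# direct VIP formula evaluation from a fitted model's stored components
oracle_vip <- function(model) {
  yc <- model$y_num - mean(model$y_num)
  W <- cbind(model$weights_pred,
             if (model$k_ortho > 0) model$weights_ortho)
  Tm <- cbind(model$scores_pred,
              if (model$k_ortho > 0) model$scores_ortho)
  p <- nrow(W)
  ssy <- apply(Tm, 2, function(t_a) {
    b <- sum(yc * t_a) / sum(t_a^2)
    b^2 * sum(t_a^2)
  })
  sqrt(p * as.numeric((W^2 / rep(colSums(W^2), each = p)) %*% ssy) / sum(ssy))
}
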