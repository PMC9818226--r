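test_that("well-separated clusters fit with near-perfect R2Y and Q2", {
  withr::with_seed(1, {
    X <- rbind(matrix(rnorm(10 * 5), 10), matrix(rnorm(10 * 5, mean = 10), 10))
  })
  y <- rep(c("A", "B"), each = 10)
  m <- fit_oplsda(X, y, seed = 1)
  expect_gt(m$R2Y, 0.95)
  expect_gt(m$Q2, 0.9)
  expect_true(m$R2X >= 0 && m$R2X <= 1)
})

test_that("with no orthogonal components the predictive fit equals a NIPALS PLS1 oracle", {
  withr::with_seed(3, {
    X <- matrix(rnorm(8 * 6), nrow = 8)
    y <- rep(c(0, 1), each = 4)
  })
  m <- fit_oplsda(X, factor(y), k_ortho = 0, seed = 1, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  orc <- oracle_nipals_pls1(Xc, yc)
  s <- sign(sum(m$weights_pred * orc$w))
  expect_equal(s * m$weights_pred, orc$w, tolerance = 1e-9)
  expect_equal(s * m$scores_pred, orc$t, tolerance = 1e-9)
  expect_equal(s * m$q, orc$q, tolerance = 1e-9)
  # oracle weights are proportional to X'y
  expect_equal(orc$w, as.numeric(crossprod(Xc, yc)) /
                 sqrt(sum(crossprod(Xc, yc)^2)), tolerance = 1e-9)
})

test_that("VIP mean-square is 1 and matches direct formula recomputation", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      sim <- simulate_volatile_experiment(sim_config(seed = rep + 40,
                                                     n_compounds = 15,
                                                     n_dropout = 0))
      pt <- sim$peak_table
      m <- fit_oplsda(pt, pt$groups, seed = rep)
      expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
      expect_equal(unname(m$vip), oracle_vip(m), tolerance = 1e-9)
      expect_true(all(m$vip >= 0))
    }
  })
})

test_that("two variables with symmetric equal contributions both score VIP 1", {
  withr::with_seed(2, {
    t0 <- rnorm(12)
  })
  X <- cbind(t0, t0)  # identical weights and contribution by construction
  y <- factor(t0 > median(t0))
  m <- fit_oplsda(X, y, k_ortho = 0, seed = 1, scale = FALSE)
  expect_equal(unname(m$vip), c(1, 1), tolerance = 1e-9)
})

test_that("randomly permuted labels give non-positive Q2 on average", {
  withr::with_seed(17, {
    X <- matrix(rnorm(6 * 20), nrow = 6)
  })
  y <- factor(rep(c("A", "B"), each = 3))
  q2 <- vapply(1:25, function(i) {
    yp <- withr::with_seed(1000 + i, sample(y))
    if (nlevels(droplevels(yp)) < 2) return(NA_real_)
    fit_oplsda(X, yp, k_ortho = 0, seed = i)$Q2
  }, numeric(1))
  expect_lte(mean(q2, na.rm = TRUE), 0)
})

test_that("permutation validation records n_perm triples with the reference at correlation 1", {
  sim <- simulate_volatile_experiment(sim_config(seed = 5, n_compounds = 20,
                                                 n_dropout = 0))
  pt <- sim$peak_table
  perm <- permutation_test(pt, pt$groups, n_perm = 15, seed = 2)
  expect_equal(nrow(perm$results), 16)
  expect_equal(perm$results$correlation[perm$results$reference], 1)
  # strongly separated data: original Q2 beats every permuted Q2 except
  # label permutations equivalent to the original assignment
  permuted <- perm$results[!perm$results$reference, ]
  expect_true(all(permuted$Q2[permuted$correlation < 1] <
                    perm$model$Q2))
  # overfitting ordering of the intercepts on pure noise
  noise <- withr::with_seed(4, matrix(rnorm(6 * 15), nrow = 6))
  pn <- permutation_test(noise, rep(c("A", "B"), each = 3), n_perm = 15,
                         seed = 3, k_ortho = 0)
  expect_lt(pn$q2_intercept, pn$r2y_intercept)
  expect_error(permutation_test(noise, rep(c("A", "B"), each = 3),
                                n_perm = 1),
               class = "aromascreen_argument_error")
})

test_that("predictive scores are stable against adding orthogonal components on unstructured data", {
  withr::with_seed(23, {
    X <- matrix(rnorm(10 * 8), nrow = 10)
  })
  y <- factor(rep(c("A", "B"), each = 5))
  m0 <- fit_oplsda(X, y, k_ortho = 0, seed = 1)
  m1 <- fit_oplsda(X, y, k_ortho = 1, seed = 1)
  ab <- abs(cor(m0$scores_pred, m1$scores_pred))
  expect_gt(ab, 0.9)
})

test_that("degenerate designs are refused", {
  X <- matrix(rnorm(12), nrow = 4)
  expect_error(fit_oplsda(X, c("A", "A", "B", "C")),
               class = "aromascreen_validation_error")
  expect_error(fit_oplsda(X, c("A", "A", "A", "B")),
               class = "aromascreen_validation_error")
})

test_that("top-VIP ranks and the VIP > 1 band recover injected differential compounds", {
  hits_top <- numeric(0)
  hits_band <- numeric(0)
  for (s in 1:10) {
    sim <- simulate_volatile_experiment(sim_config(seed = s, n_dropout = 0))
    pt <- sim$peak_table
    m <- fit_oplsda(pt, pt$groups, seed = s)
    inj <- pt$compounds$id %in% sim$truth$differential
    d <- sum(inj)
    hits_top <- c(hits_top, mean((rank(-unname(m$vip)) <= d)[inj]))
    hits_band <- c(hits_band, mean((unname(m$vip) > 1)[inj]))
  }
  expect_gte(mean(hits_top), 0.75)
  expect_gte(mean(hits_band), 0.95)
})
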