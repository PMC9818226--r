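test_that("z-scoring standardises rows and zeroes constant rows", {
  z <- zscore(matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  expect_equal(unname(z[2, ]), c(0, 0, 0))
  expect_true(attr(z, "constant")[2])

  withr::with_seed(12, {
    m <- matrix(rnorm(60, sd = 4), nrow = 6)
    z <- zscore(m)
    expect_equal(unname(rowMeans(z)), rep(0, 6), tolerance = 1e-12)
    expect_equal(unname(apply(z, 1, sd)), rep(1, 6), tolerance = 1e-12)
    # idempotence on non-constant rows
    expect_equal(unname(zscore(z)), unname(z), tolerance = 1e-12)
  })
})

test_that("z-scoring a single sample is refused", {
  expect_error(zscore(matrix(1:3, ncol = 1)),
               class = "aromascreen_validation_error")
})

test_that("cluster ordering places identical rows adjacent and handles 1-item axes", {
  m <- rbind(c(0, 0, 0), c(0, 0, 0), c(50, 50, 50))
  ord <- hcluster_order(m, "rows")
  expect_equal(sort(abs(diff(match(1:2, ord)))), 1)  # the twin pair adjacent
  expect_equal(hcluster_order(matrix(1:3, nrow = 1), "rows"), 1L)
})

test_that("average-linkage merge sequence equals a naive O(n^3) agglomeration oracle", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      m <- matrix(rnorm(6 * 4), nrow = 6)
      hc <- hclust(dist(m), method = "average")
      orc <- oracle_upgma(m)
      expect_equal(sort(hc$height), sort(orc$heights), tolerance = 1e-10)
      for (step in seq_along(orc$partitions)) {
        k <- 6 - step
        if (k < 1) break
        got <- split(seq_len(6), stats::cutree(hc, k = k))
        expect_identical(canon_partition(got),
                         canon_partition(orc$partitions[[step]]))
      }
    }
  })
})

test_that("PCA explains 100% on collinear data and matches closed-form eigenvalues", {
  line <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), ncol = 2)  # y = 2x
  mod <- fit_pca(line, k = 1, samples_in_rows = TRUE)
  expect_equal(mod$explained_pct[1], 100)

  # 2 x 2 covariance with known eigenvalues: points (+-1, 0), (0, +-c)
  cc <- 0.5
  pts <- rbind(c(1, 0), c(-1, 0), c(0, cc), c(0, -cc))
  mod2 <- fit_pca(pts, k = 2, samples_in_rows = TRUE)
  ev <- c(2, 2 * cc^2)  # column sums of squares (centred), eigenvalues ratio
  expect_equal(mod2$explained_pct, 100 * ev / sum(ev), tolerance = 1e-12)
})

test_that("full-rank PCA reconstructs the centred matrix and ignores sample order", {
  withr::with_seed(14, {
    X <- matrix(rnorm(5 * 7), nrow = 5)
    k <- 4  # n_samples - 1
    mod <- fit_pca(X, k = k, samples_in_rows = TRUE)
    rec <- mod$scores %*% t(mod$loadings)
    expect_equal(rec, sweep(X, 2, colMeans(X)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(abs(crossprod(mod$loadings) - diag(k)) < 1e-9))

    perm <- sample(5)
    mod_p <- fit_pca(X[perm, ], k = 2, samples_in_rows = TRUE)
    expect_equal(mod_p$explained_pct,
                 fit_pca(X, k = 2, samples_in_rows = TRUE)$explained_pct,
                 tolerance = 1e-9)
  })
  expect_error(fit_pca(matrix(rnorm(12), 3), k = 5, samples_in_rows = TRUE),
               class = "aromascreen_argument_error")
})

test_that("pooled t-test matches a numeric t-CDF oracle and t.test", {
  got <- ttest_groups(c(1, 2, 3), c(4, 5, 6))
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, oracle_t_pvalue(got$t, 4), tolerance = 1e-8)

  # swapping groups negates t, preserves p
  rev <- ttest_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)

  welch <- ttest_groups(c(1, 2, 3), c(4, 5, 9), variant = "welch")
  refw <- t.test(c(1, 2, 3), c(4, 5, 9))
  expect_equal(welch$p, refw$p.value)
})

test_that("degenerate t-test inputs follow the stated conventions", {
  same <- ttest_groups(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(lim <- ttest_groups(c(1, 1), c(2, 2)), "Zero variance")
  expect_equal(lim$p, 0)
  ident <- ttest_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("per-compound t-tests contrast the two groups in compound order", {
  pt <- random_peak_table(n_compounds = 4, seed = 6)
  tt <- ttest_peaks(pt)
  expect_equal(tt$id, pt$compounds$id)
  i <- 3
  ref <- t.test(pt$areas[i, 1:3], pt$areas[i, 4:6], var.equal = TRUE)
  expect_equal(tt$p[i], ref$p.value)
  expect_equal(tt$p_adj, p.adjust(tt$p, "BH"))
})
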