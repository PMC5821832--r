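test_that("center_gram matches the explicit-loop oracle and is idempotent", {
  set.seed(20)
  X <- matrix(rnorm(15), 5, 3)
  K <- gram_matrix(X, kernel_spec("anova", 0.3))$values
  Kc <- center_gram(K)
  expect_equal(Kc, oracle_center(K), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(Kc))), 1e-10)
  expect_lt(max(abs(colSums(Kc))), 1e-10)
  expect_equal(center_gram(Kc), Kc, tolerance = 1e-10)
  # constant matrix is pure mean structure
  expect_equal(center_gram(matrix(7, 4, 4)), matrix(0, 4, 4))
  expect_error(center_gram(matrix(rnorm(12), 3, 4)), "square")
})

test_that("linear-kernel KPCA reproduces classical PCA scores up to sign", {
  set.seed(21)
  for (trial in 1:10) {
    X <- matrix(rnorm(20 * 10), 20, 10)
    m <- kpca_fit(scale(X, scale = FALSE), kernel_spec("linear"), 4)
    px <- prcomp(X)$x
    for (j in 1:4) {
      err <- min(max(abs(m$scores[, j] - px[, j])),
                 max(abs(m$scores[, j] + px[, j])))
      expect_lt(err, 1e-8)
    }
  }
})

test_that("kpca_fit satisfies its spectral contracts", {
  set.seed(22)
  X <- matrix(rnorm(40), 10, 4)
  m <- kpca_fit(X, kernel_spec("anova", 0.5), 5)
  # eigenvalues sorted descending and positive
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(m$eigenvalues > 0))
  # dual normalization: lambda * alpha'alpha = 1
  expect_equal(m$eigenvalues * colSums(m$alpha^2), rep(1, 5),
               tolerance = 1e-8)
  # score columns mutually orthogonal
  cp <- crossprod(m$scores)
  off <- cp - diag(diag(cp))
  expect_lt(max(abs(off)), 1e-8 * max(diag(cp)))
  # contribution rates normalized over positive spectrum
  expect_equal(sum(m$all_positive_eigenvalues) * m$contribution_rates,
               m$eigenvalues, tolerance = 1e-10)
  # independent oracle: scalar kernel -> loop centering -> eigen
  Ko <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    Ko[i, j] <- oracle_anova(X[i, ], X[j, ], 0.5, 1)
  }
  eo <- eigen(oracle_center(Ko), symmetric = TRUE)
  so <- eo$vectors[, 1:5] %*% diag(sqrt(eo$values[1:5]))
  for (j in 1:5) {
    err <- min(max(abs(m$scores[, j] - so[, j])),
               max(abs(m$scores[, j] + so[, j])))
    expect_lt(err, 1e-8)
  }
})

test_that("duplicated samples receive identical scores", {
  set.seed(23)
  X <- matrix(rnorm(24), 6, 4)
  Xd <- rbind(X, X)
  m <- kpca_fit(Xd, kernel_spec("anova", 0.4), 3)
  expect_equal(m$scores[1:6, ], m$scores[7:12, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("kpca_fit errors when asking beyond the positive spectrum", {
  X <- matrix(rnorm(12), 6, 2)
  # linear kernel rank <= 2 after centering
  expect_error(kpca_fit(scale(X, scale = FALSE), kernel_spec("linear"), 5),
               "positive eigenvalues")
})

test_that("contribution_rates follow eigenvalue shares", {
  set.seed(24)
  X <- matrix(rnorm(30), 10, 3)
  m <- kpca_fit(X, kernel_spec("gaussian", 0.5), 2)
  lam <- m$all_positive_eigenvalues
  expect_equal(contribution_rates(m), lam[1:2] / sum(lam),
               tolerance = 1e-12)
  expect_equal(sum(lam / sum(lam)), 1, tolerance = 1e-10)
})

test_that("quadrant labeling implements the sign rule and tie convention", {
  sc <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1), c(0, -2), c(0, 0))
  rownames(sc) <- paste0("s", 1:6)
  lab <- quadrant_labels(sc)
  expect_equal(unname(lab$class), c(1L, 2L, 3L, 4L, 4L, 1L))
  # custom mapping permutes classes
  lab2 <- quadrant_labels(sc, mapping = c(4L, 3L, 2L, 1L))
  expect_equal(unname(lab2$class), c(4L, 3L, 2L, 1L, 1L, 4L))
  expect_error(quadrant_labels(sc, mapping = c(1L, 1L, 2L, 3L)),
               "permutation")
  set.seed(25)
  rnd <- matrix(rnorm(60), 30, 2)
  expect_equal(sum(table(quadrant_labels(rnd)$class)), 30)
})

test_that("deterministic sign convention: refitting gives identical scores", {
  set.seed(26)
  X <- matrix(rnorm(48), 12, 4)
  m1 <- kpca_fit(X, kernel_spec("anova", 0.3), 3)
  m2 <- kpca_fit(X, kernel_spec("anova", 0.3), 3)
  expect_identical(m1$scores, m2$scores)
  for (j in 1:3) {
    expect_gt(m1$alpha[which.max(abs(m1$alpha[, j])), j], 0)
  }
})

test_that("scan_sigma reports the grid and a usable best sigma", {
  set.seed(27)
  X <- matrix(rnorm(80), 20, 4)
  one <- scan_sigma(X, sigma_grid = 0.2)
  expect_equal(nrow(one), 1)
  m <- kpca_fit(X, kernel_spec("anova", 0.2), 2)
  expect_equal(one$pc1_rate, m$contribution_rates[1], tolerance = 1e-12)
  grid <- c(0.05, 0.15, 0.3)
  sc <- scan_sigma(X, sigma_grid = grid)
  expect_equal(sc$sigma, grid)
  expect_true(all(sc$pc1_rate > 0 & sc$pc1_rate <= 1))
  expect_true(attr(sc, "best_sigma") %in% grid)
  expect_error(scan_sigma(X, sigma_grid = numeric(0)), "positive")
})

test_that("dispersion-maximizing sigma keeps quadrant occupancy at least as
           balanced as the grid extremes on 4-cluster data", {
  st <- generate_study(n = 120, p = 30, n_informative = 6, n_planted = 4,
                       seed = 5)
  X <- autoscale(st$features)
  grid <- seq(0.05, 0.30, by = 0.05)
  sc <- scan_sigma(X, sigma_grid = grid)
  balance <- function(sg) {
    m <- kpca_fit(X, kernel_spec("anova", sg), 2)
    counts <- tabulate(quadrant_labels(m)$class, 4)
    min(counts) / max(counts)
  }
  best <- balance(attr(sc, "best_sigma"))
  extremes <- c(balance(grid[1]), balance(grid[length(grid)]))
  expect_gte(best, min(extremes) - 1e-12)
})

test_that("rand_index agrees with pair counting on small cases", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # hand count: partitions {a}{bc} vs {ab}{c} on 3 elements agree only on
  # the (a,c) pair -> 1/3
  expect_equal(rand_index(c(1, 2, 2), c(1, 1, 2)), 1 / 3)
})
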