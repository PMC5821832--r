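sep_study <- function(seed, n = 80, p = 20) {
  generate_study(n = n, p = p, n_informative = 4, n_planted = 4,
                 nonlinearity = "none", noise_sd = 0.1, seed = seed)
}

test_that("a perfect separator variable is split at every root, OOB 1.0", {
  set.seed(30)
  n <- 60
  y <- rep(1:4, each = 15)
  X <- cbind(sep = y + 0, matrix(rnorm(n * 9), n, 9))
  fit <- fit_forest(X, y, forest_config(ntree = 30, mtry = 10, seed = 1))
  roots <- vapply(fit$trees, function(t) t$var[1], integer(1))
  expect_true(all(roots == 0L))  # 0-based index of the separator column
  expect_equal(fit$oob_accuracy, 1.0)
  expect_equal(as.integer(as.character(predict(fit))), y)
})

test_that("same seed gives identical forests; different seed differs", {
  st <- sep_study(31)
  f1 <- fit_forest(st$features, st$class, forest_config(ntree = 15, seed = 9))
  f2 <- fit_forest(st$features, st$class, forest_config(ntree = 15, seed = 9))
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$oob, f2$oob)
  f3 <- fit_forest(st$features, st$class, forest_config(ntree = 15, seed = 10))
  expect_false(identical(f1$trees, f3$trees))
})

test_that("in-bag and out-of-bag partition the samples, drawn without
           replacement", {
  st <- sep_study(32, n = 50)
  cfg <- forest_config(ntree = 10, sample_fraction = 0.632, seed = 3)
  fit <- fit_forest(st$features, st$class, cfg)
  n <- 50
  for (t in seq_along(fit$trees)) {
    oob <- fit$oob[[t]] + 1L
    expect_equal(length(oob) + round(0.632 * n), n)
    expect_false(anyDuplicated(oob) > 0)
  }
})

test_that("permuted labels give chance-level OOB accuracy", {
  st <- generate_study(n = 200, p = 30, n_informative = 5, n_planted = 5,
                       seed = 33)
  set.seed(34)
  yperm <- sample(st$class)
  fit <- fit_forest(st$features, yperm, forest_config(ntree = 60, seed = 7))
  band <- 3 * sqrt(0.25 * 0.75 / 200)
  expect_lt(abs(fit$oob_accuracy - 0.25), band)
})

test_that("class with fewer than 2 samples is rejected", {
  X <- matrix(rnorm(60), 12, 5)
  y <- c(rep(1, 11), 2)
  expect_error(fit_forest(X, y, forest_config(ntree = 5)), "< 2 samples")
})

test_that("constant variables get importance exactly 0", {
  st <- sep_study(35, n = 60)
  X <- st$features$values
  X[, 7] <- 3.14
  const_name <- colnames(X)[7]
  fit <- fit_forest(X, st$class, forest_config(ntree = 20, seed = 2))
  imp <- conditional_importance(fit)
  expect_identical(imp$importance[imp$variable == const_name], 0)
})

test_that("a label-copy variable dominates the importance ranking", {
  set.seed(36)
  n <- 100
  y <- rep(1:4, each = 25)
  X <- cbind(matrix(rnorm(n * 14), n, 14), copy = y + rnorm(n, 0, 0.01))
  fit <- fit_forest(X, y, forest_config(ntree = 40, seed = 4))
  imp <- conditional_importance(fit)
  expect_equal(imp$variable[1], "copy")
  expect_gt(imp$importance[1], 2 * imp$importance[2])
})

test_that("conditional importance of a correlated decoy is below its
           unconditional importance (debiasing)", {
  deltas <- vapply(1:5, function(s) {
    st <- generate_study(n = 150, p = 40, n_informative = 5, n_planted = 5,
                         seed = 40 + s)
    fit <- fit_forest(st$features, st$class,
                      forest_config(ntree = 50, seed = s))
    ci <- conditional_importance(fit, conditional = TRUE)
    ui <- conditional_importance(fit, conditional = FALSE)
    dec <- st$decoys$decoy
    mean(ui$importance[match(dec, ui$variable)]) -
      mean(ci$importance[match(dec, ci$variable)])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("label-independent variables have importance centered at 0", {
  set.seed(37)
  n <- 120
  y <- rep(1:4, each = 30)
  vals <- vapply(1:10, function(s) {
    X <- cbind(sig = y + rnorm(n, 0, 0.3), matrix(rnorm(n * 10), n, 10))
    fit <- fit_forest(X, y, forest_config(ntree = 30, seed = s))
    imp <- conditional_importance(fit)
    mean(imp$importance[imp$variable != "sig"])
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), max(2 * se, 0.005))
})

test_that("rank_report slices, truncates with warning, breaks ties by name", {
  imp <- data.frame(variable = c("b", "a", "c"),
                    modality = "nmr",
                    importance = c(0.5, 0.5, 0.1),
                    rank = 1:3)
  class(imp) <- c("importance_table", "data.frame")
  expect_equal(nrow(rank_report(imp, 2)), 2)
  expect_warning(full <- rank_report(imp, 10), "truncating")
  expect_equal(nrow(full), 3)
  # tie order is established by conditional_importance's sort; check there
  st <- sep_study(38, n = 40)
  fit <- fit_forest(st$features, st$class, forest_config(ntree = 10, seed = 1))
  imp2 <- conditional_importance(fit)
  ties <- imp2[imp2$importance == 0, "variable"]
  expect_equal(ties, sort(ties))
  top1 <- rank_report(imp2, 1)
  expect_equal(top1$variable, imp2$variable[which.max(imp2$importance)])
})

test_that("LOOCV: confusion accounting, fold class-dropout, row-order
           invariance", {
  st <- sep_study(39, n = 30, p = 8)
  cv <- loocv(st$features, st$class, forest_config(ntree = 15, seed = 6))
  expect_equal(unname(rowSums(cv$confusion)), cv$per_class)
  expect_equal(sum(diag(cv$confusion)) / sum(cv$confusion), cv$accuracy)
  # permute rows: identical report
  perm <- sample(seq_len(30))
  cv2 <- loocv(st$features[perm, ], st$class[perm],
               forest_config(ntree = 15, seed = 6))
  expect_identical(cv$confusion, cv2$confusion)
  expect_equal(cv$accuracy, cv2$accuracy)
})

test_that("LOOCV proceeds when a fold loses a class", {
  set.seed(41)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- c(2, rep(c(1, 3), 12))  # class 2 is a singleton
  X[y == 1, 1] <- X[y == 1, 1] + 4
  X[y == 3, 2] <- X[y == 3, 2] + 4
  msgs <- capture_messages(
    cv <- loocv(feature_matrix(X), y, forest_config(ntree = 10, seed = 2)))
  expect_true(any(grepl("absent from training", msgs)))
  expect_equal(sum(cv$confusion), 25)
})
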