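#' Forest configuration
#'
#' Settings for the conditional permutation importance forest. Trees are
#' CART-style (Gini splits) grown on subsamples drawn \emph{without}
#' replacement (fraction 0.632), the sampling scheme recommended for
#' unbiased permutation importance; \code{mtry} candidate variables are
#' drawn at each node. The study preset for wide spectral tables
#' (\code{ntree = 80}, \code{mtry = 900}) is available via
#' \code{forest_config_spectral()}.
#'
#' @param ntree number of trees (default 80)
#' @param mtry candidate variables per split; default
#'   \code{ceiling(sqrt(p))}, capped at p
#' @param sample_fraction subsample fraction drawn without replacement
#' @param min_split minimum node size eligible for splitting
#' @param seed master seed; per-tree and per-fold seeds are derived from it
#'   by a counter scheme, so results do not depend on execution order
#' @param cor_threshold |Pearson r| above which a variable joins another's
#'   conditioning set for conditional importance
#' @return a list of class \code{forest_config}
#' @export
forest_config <- function(ntree = 80L, mtry = NULL, sample_fraction = 0.632,
                          min_split = 5L, seed = 1L, cor_threshold = 0.2) {
  stopifnot(ntree >= 1, sample_fraction > 0, sample_fraction <= 1,
            min_split >= 2, cor_threshold >= 0)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 sample_fraction = sample_fraction,
                 min_split = as.integer(min_split), seed = as.integer(seed),
                 cor_threshold = cor_threshold),
            class = "forest_config")
}

#' @rdname forest_config
#' @param ... overrides passed to \code{forest_config}
#' @export
forest_config_spectral <- function(...) {
  cfg <- forest_config(ntree = 80L, mtry = 900L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# derive a deterministic sub-seed from the master seed and a counter
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 69621 + counter * 97) %% 2147483629) + 1L
}

as_class_vector <- function(labels) {
  if (inherits(labels, "quadrant_labeling")) labels <- labels$class
  factor(labels)
}

#' Fit a subsample forest on pseudo-class labels
#'
#' Grows \code{ntree} CART-style trees, each on a random subsample drawn
#' without replacement, recording in-bag and out-of-bag (OOB) index sets.
#' Fully reproducible: the same seed yields an identical forest regardless
#' of prior RNG state.
#'
#' @param X numeric matrix or \code{\link{feature_matrix}}
#' @param labels a \code{\link{quadrant_labels}} result, factor, or vector
#'   with >= 2 classes, each represented by >= 2 samples
#' @param config a \code{\link{forest_config}}
#' @return an object of class \code{forest_model} holding the trees, OOB
#'   sets, level mapping, training data and OOB accuracy
#' @export
fit_forest <- function(X, labels, config = forest_config()) {
  fm_mod <- if (inherits(X, "feature_matrix")) X$modality else NULL
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as_class_vector(labels)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("labels length != number of samples")
  if (n < 10) stop("need n >= 10 samples")
  if (nlevels(y) < 2) stop("need >= 2 classes")
  small <- table(y) < 2
  if (any(small)) {
    stop("class(es) with < 2 samples: ",
         paste(names(which(small)), collapse = ", "))
  }
  y0 <- as.integer(y) - 1L
  mtry <- if (is.null(config$mtry)) ceiling(sqrt(p)) else config$mtry
  mtry <- as.integer(min(mtry, p))
  n_sub <- max(2L, round(config$sample_fraction * n))
  trees <- vector("list", config$ntree)
  oob <- vector("list", config$ntree)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  for (t in seq_len(config$ntree)) {
    set.seed(derive_seed(config$seed, t))
    inbag <- sort(sample.int(n, n_sub))
    trees[[t]] <- cpp_grow_tree(X, y0, nlevels(y), inbag - 1L, mtry,
                                config$min_split)
    oob[[t]] <- setdiff(seq_len(n), inbag) - 1L
  }
  model <- structure(
    list(trees = trees, oob = oob, levels = levels(y), X = X, y = y,
         modality = fm_mod, mtry = mtry, config = config),
    class = "forest_model"
  )
  model$oob_accuracy <- oob_accuracy(model)
  model
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, mtry %d, %d classes, OOB accuracy %.3f\n",
              length(x$trees), x$mtry, length(x$levels), x$oob_accuracy))
  invisible(x)
}

#' Predict classes with a fitted forest
#'
#' Majority vote over trees; ties go to the lowest class.
#'
#' @param object a \code{\link{fit_forest}} model
#' @param newdata matrix or \code{\link{feature_matrix}} with the training
#'   columns; defaults to the training data
#' @param ... ignored
#' @return factor of predicted classes
#' @export
predict.forest_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  votes <- cpp_forest_votes(object$trees, as.matrix(newdata),
                            length(object$levels))
  pred <- apply(votes, 1, which.max)  # tie -> lowest class index
  factor(object$levels[pred], levels = object$levels)
}

# OOB accuracy: each sample predicted by majority vote of the trees that
# did not train on it
oob_accuracy <- function(model) {
  n <- nrow(model$X)
  k <- length(model$levels)
  votes <- matrix(0L, n, k)
  for (t in seq_along(model$trees)) {
    o <- model$oob[[t]]
    if (!length(o)) next
    pr <- cpp_predict_tree(model$trees[[t]], model$X, o)
    for (i in seq_along(o)) {
      votes[o[i] + 1L, pr[i] + 1L] <- votes[o[i] + 1L, pr[i] + 1L] + 1L
    }
  }
  has_vote <- rowSums(votes) > 0
  pred <- apply(votes, 1, which.max)
  mean(pred[has_vote] == as.integer(model$y)[has_vote])
}

#' Permutation variable importance (conditional or unconditional)
#'
#' For each variable and tree, the variable's out-of-bag values are permuted
#' and the drop in that tree's OOB accuracy is recorded; importance is the
#' mean drop over trees. In the conditional variant the permutation is
#' performed within strata defined by the tree's own split points of the
#' variables correlated with the target (|Pearson r| above
#' \code{config$cor_threshold}), which removes the inflation that plain
#' permutation importance awards to variables merely correlated with truly
#' informative ones. Variables a tree never splits on contribute exactly 0
#' for that tree, so constant or never-used variables get importance 0.
#'
#' @param model a \code{\link{fit_forest}} result
#' @param conditional permute within correlation strata (default) or
#'   globally
#' @return an \code{importance_table}: data.frame(variable, modality,
#'   importance, rank) sorted by decreasing importance, ties broken by
#'   variable name
#' @export
conditional_importance <- function(model, conditional = TRUE) {
  stopifnot(inherits(model, "forest_model"))
  X <- model$X
  p <- ncol(X)
  if (conditional) {
    r <- suppressWarnings(stats::cor(X))
    r[!is.finite(r)] <- 0
    cond <- lapply(seq_len(p), function(j) {
      which(abs(r[, j]) > model$config$cor_threshold &
              seq_len(p) != j) - 1L
    })
  } else {
    cond <- rep(list(integer(0)), p)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(derive_seed(model$config$seed, if (conditional) 7919L else 7920L))
  imp <- cpp_importance(model$trees, model$oob, X,
                        as.integer(model$y) - 1L, length(model$levels),
                        cond, conditional)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("V", seq_len(p))
  modality <- if (is.null(model$modality)) rep(NA_character_, p) else
    model$modality
  ord <- order(-imp, nms)
  out <- data.frame(variable = nms[ord], modality = modality[ord],
                    importance = imp[ord], rank = seq_len(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top slice of an importance table
#'
#' @param importance an \code{importance_table}
#' @param top number of leading variables to keep (truncated to p with a
#'   warning if larger)
#' @return the first \code{top} rows
#' @export
rank_report <- function(importance, top = 100L) {
  stopifnot(inherits(importance, "data.frame"), top >= 1)
  if (top > nrow(importance)) {
    warning("top = ", top, " exceeds ", nrow(importance),
            " variables; truncating")
    top <- nrow(importance)
  }
  utils::head(importance, top)
}

#' Leave-one-out cross-validation of the forest classifier
#'
#' Each sample is predicted by a forest trained on the remaining n - 1
#' samples (majority vote, ties to the lowest class). Per-fold seeds derive
#' from the master seed and the held-out sample's rank among sorted sample
#' ids, so the report is invariant to row order. A fold whose training set
#' lacks a class proceeds with the remaining classes and is logged.
#'
#' @param X matrix or \code{\link{feature_matrix}}
#' @param labels class labels as in \code{\link{fit_forest}}
#' @param config a \code{\link{forest_config}}
#' @return an object of class \code{cv_report}: overall \code{accuracy},
#'   k x k \code{confusion} matrix (rows = true), \code{per_class} counts
#' @export
loocv <- function(X, labels, config = forest_config()) {
  ids <- if (inherits(X, "feature_matrix")) X$sample_ids else
    paste0("S", seq_len(nrow(as.matrix(X))))
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as_class_vector(labels)
  n <- nrow(X)
  k <- nlevels(y)
  if (n < k + 1) stop("need n >= number of classes + 1")
  # canonical sample order: makes the report invariant to input row order
  o <- order(ids)
  X <- X[o, , drop = FALSE]
  y <- y[o]
  ids <- ids[o]
  pred <- character(n)
  for (i in seq_len(n)) {
    fold_seed <- derive_seed(config$seed, 100000L + match(ids[i], sort(ids)))
    cfg <- config
    cfg$seed <- fold_seed
    keep <- setdiff(seq_len(n), i)
    ytr <- y[keep]
    # classes reduced below 2 training samples cannot be stratified; the
    # fold proceeds without them
    usable <- names(which(table(ytr) >= 2))
    if (length(usable) < nlevels(y)) {
      message("fold ", ids[i], ": class ",
              paste(setdiff(levels(y), usable), collapse = ","),
              " absent from training")
      keep <- keep[as.character(ytr) %in% usable]
      ytr <- y[keep]
    }
    fit <- fit_forest(X[keep, , drop = FALSE], droplevels(ytr), cfg)
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE]))
  }
  pred <- factor(pred, levels = levels(y))
  confusion <- table(true = y, predicted = pred)
  structure(
    list(accuracy = mean(pred == y),
         confusion = unclass(confusion),
         per_class = as.integer(table(y)),
         levels = levels(y)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: accuracy %.1f%% over %d samples\n",
              100 * x$accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}
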