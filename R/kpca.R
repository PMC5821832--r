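#' Double-center a Gram matrix
#'
#' Kernel PCA requires the implicit feature map to be mean-centered in
#' feature space; on the Gram matrix this is the double-centering
#' \deqn{\tilde K = K - 1_n K - K 1_n + 1_n K 1_n} with \eqn{1_n} the
#' n x n matrix of 1/n. Every row and column of the result sums to zero,
#' and the operation is idempotent.
#'
#' @param K a \code{\link{gram_matrix}} or a symmetric numeric matrix
#' @return the centered matrix (plain numeric matrix)
#' @export
center_gram <- function(K) {
  if (inherits(K, "gram_matrix")) K <- K$values
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("K must be symmetric")
  }
  rm_ <- colMeans(K)            # row of column means (= row means, symmetric)
  g <- mean(K)
  Kc <- K - outer(rep(1, nrow(K)), rm_) - outer(rm_, rep(1, nrow(K))) + g
  (Kc + t(Kc)) / 2
}

#' Fit kernel PCA
#'
#' Eigendecomposes the centered Gram matrix. Dual coefficients
#' \eqn{\alpha_i} are normalized so that \eqn{\lambda_i \alpha_i^\top
#' \alpha_i = 1} (unit-norm feature-space principal axes); component scores
#' are \eqn{\tilde K \alpha_i}, i.e. the i-th score column has squared norm
#' \eqn{\lambda_i}. With the linear kernel on mean-centered data this
#' reproduces classical PCA scores exactly (up to per-column sign). The sign
#' of each component is fixed deterministically by making its
#' largest-magnitude dual coefficient positive.
#'
#' @param X numeric n x p matrix or \code{\link{feature_matrix}}
#' @param spec a \code{\link{kernel_spec}}
#' @param n_components number of components to retain (<= usable positive
#'   eigenvalues; the pipeline uses 2 for quadrant labeling)
#' @return an object of class \code{kpca_model}: eigenvalues (descending),
#'   dual coefficients \code{alpha}, \code{scores}, \code{contribution_rates}
#'   over all positive eigenvalues, the kernel spec and sample ids.
#' @export
kpca_fit <- function(X, spec, n_components = 2L) {
  sample_ids <- if (inherits(X, "feature_matrix")) X$sample_ids else
    paste0("S", seq_len(nrow(as.matrix(X))))
  G <- gram_matrix(X, spec)
  Kc <- center_gram(G)
  eig <- eigen(Kc, symmetric = TRUE)
  lambda <- eig$values
  tol <- max(abs(lambda)) * 1e-10
  n_pos <- sum(lambda > tol)
  if (n_components > n_pos) {
    stop(sprintf("requested %d components but only %d positive eigenvalues",
                 n_components, n_pos))
  }
  idx <- seq_len(n_components)
  alpha <- eig$vectors[, idx, drop = FALSE]
  # sign convention: largest-|alpha| entry positive per component
  for (j in idx) {
    k <- which.max(abs(alpha[, j]))
    if (alpha[k, j] < 0) alpha[, j] <- -alpha[, j]
  }
  alpha <- sweep(alpha, 2, sqrt(lambda[idx]), "/")
  scores <- Kc %*% alpha
  colnames(scores) <- paste0("PC", idx)
  rownames(scores) <- sample_ids
  pos <- lambda[lambda > tol]
  structure(
    list(eigenvalues = lambda[idx], all_positive_eigenvalues = pos,
         alpha = alpha, scores = scores,
         contribution_rates = lambda[idx] / sum(pos),
         kernel = spec, sample_ids = sample_ids),
    class = "kpca_model"
  )
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("kpca_model: %d samples, %d components (%s kernel)\n",
              length(x$sample_ids), length(x$eigenvalues), x$kernel$family))
  cat("contribution rates:",
      paste(sprintf("%.3f", x$contribution_rates), collapse = ", "), "\n")
  invisible(x)
}

#' Contribution rates of a fitted model
#'
#' The fraction of total positive eigenvalue mass carried by each retained
#' component -- the kernel-space analogue of variance explained.
#'
#' @param model a \code{\link{kpca_fit}} result
#' @return numeric vector of per-component fractions
#' @export
contribution_rates <- function(model) {
  stopifnot(inherits(model, "kpca_model"))
  model$contribution_rates
}

#' Scan the kernel bandwidth
#'
#' Fits one KPCA per sigma over a grid (default 0.05 to 0.30, the range a
#' metabolic profiling study would explore for autoscaled data) and reports
#' the PC1 contribution rate together with a score-plot dispersion score:
#' the mean pairwise distance of the min-max-normalized 2-D scores. Samples
#' concentrated at particular positions of the plot (the linear-PCA
#' pathology this method exists to avoid) yield a low score; embeddings
#' that spread samples across the plot score high. Well-dispersed score
#' plots avoid biased quadrant grouping, so the suggested sigma (attribute
#' \code{"best_sigma"}) maximizes dispersion. A failed fit is recorded as
#' NA and the scan continues.
#'
#' @param X matrix or \code{\link{feature_matrix}}
#' @param sigma_grid positive bandwidth grid
#' @param degree ANOVA degree d
#' @param n_components components per fit (>= 2 for the dispersion score)
#' @param family kernel family
#' @return data.frame(sigma, pc1_rate, dispersion) with attribute
#'   \code{"best_sigma"}
#' @export
scan_sigma <- function(X, sigma_grid = seq(0.05, 0.30, by = 0.025),
                       degree = 1L, n_components = 2L, family = "anova") {
  if (!length(sigma_grid) || any(sigma_grid <= 0)) {
    stop("sigma_grid must be non-empty and positive")
  }
  rows <- lapply(sigma_grid, function(s) {
    fit <- tryCatch(
      kpca_fit(X, kernel_spec(family, sigma = s, degree = degree),
               n_components = n_components),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(data.frame(sigma = s, pc1_rate = NA_real_,
                        dispersion = NA_real_))
    }
    data.frame(sigma = s, pc1_rate = fit$contribution_rates[1],
               dispersion = score_dispersion(fit$scores[, 1:2, drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  ok <- which(!is.na(out$dispersion))
  attr(out, "best_sigma") <- if (length(ok)) {
    out$sigma[ok[which.max(out$dispersion[ok])]]
  } else {
    NA_real_
  }
  out
}

# mean pairwise distance after min-max normalization of each axis
score_dispersion <- function(scores2d) {
  Z <- apply(scores2d, 2, function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else v * 0
  })
  mean(stats::dist(Z))
}

#' Quadrant pseudo-labeling from KPCA scores
#'
#' Assigns each sample one of four classes from the signs of its first two
#' component scores. A score of exactly zero counts as positive (a
#' measure-zero tie that must be broken deterministically). The default
#' mapping follows score-plot quadrant order counter-clockwise from the
#' upper right: (+,+) -> 1, (-,+) -> 2, (-,-) -> 3, (+,-) -> 4; any
#' permutation can be supplied, and all downstream stages are
#' mapping-agnostic.
#'
#' @param model a \code{\link{kpca_fit}} result with >= 2 components, or a
#'   numeric score matrix with >= 2 columns
#' @param mapping integer vector of length 4 giving the class for the sign
#'   patterns (+,+), (-,+), (-,-), (+,-) in that order
#' @return an object of class \code{quadrant_labeling}: list with
#'   \code{class} (integer per sample, named by sample id) and
#'   \code{mapping}
#' @export
quadrant_labels <- function(model, mapping = c(1L, 2L, 3L, 4L)) {
  scores <- if (inherits(model, "kpca_model")) model$scores else
    as.matrix(model)
  if (ncol(scores) < 2) stop("need >= 2 components for quadrant labeling")
  if (length(mapping) != 4 || !setequal(mapping, 1:4)) {
    stop("mapping must be a permutation of 1:4")
  }
  pos1 <- scores[, 1] >= 0
  pos2 <- scores[, 2] >= 0
  quadrant <- ifelse(pos1 & pos2, 1L,
              ifelse(!pos1 & pos2, 2L,
              ifelse(!pos1 & !pos2, 3L, 4L)))
  cls <- as.integer(mapping[quadrant])
  names(cls) <- rownames(scores)
  structure(list(class = cls, mapping = as.integer(mapping)),
            class = "quadrant_labeling")
}

#' @export
print.quadrant_labeling <- function(x, ...) {
  tab <- table(factor(x$class, levels = sort(unique(x$mapping))))
  cat("quadrant_labeling:",
      paste(sprintf("class %s: n=%d", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rand index between two labelings
#'
#' Fraction of sample pairs on which two partitions agree (both together or
#' both apart); invariant to label permutation. Used to compare quadrant
#' pseudo-classes against ground truth.
#'
#' @param a,b class vectors of equal length
#' @return Rand index in [0, 1]
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}
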