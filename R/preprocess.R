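#' Construct a spectral block
#'
#' A raw spectral table (e.g. 1D 1H NMR) before peak picking: one intensity
#' row per sample over a common, strictly monotone axis (ppm for NMR).
#'
#' @param intensities numeric sample x point matrix, finite, typically
#'   non-negative.
#' @param axis numeric per-point coordinate, strictly monotone.
#' @param sample_ids,subject_ids identifiers as in
#'   \code{\link{feature_matrix}}.
#' @return an object of class \code{spectral_block}
#' @export
spectral_block <- function(intensities, axis = NULL, sample_ids = NULL,
                           subject_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  m <- ncol(intensities)
  if (is.null(axis)) axis <- seq_len(m)
  if (length(axis) != m) stop("axis length != number of points")
  d <- diff(axis)
  if (m > 1 && !(all(d > 0) || all(d < 0))) stop("axis must be strictly monotone")
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids) || any(is.na(sample_ids)) ||
      any(sample_ids == "")) {
    stop("sample_ids must be unique and non-missing")
  }
  if (is.null(subject_ids)) subject_ids <- sample_ids
  structure(
    list(intensities = intensities, axis = as.numeric(axis),
         sample_ids = sample_ids, subject_ids = as.character(subject_ids)),
    class = "spectral_block"
  )
}

#' @export
print.spectral_block <- function(x, ...) {
  cat(sprintf("spectral_block: %d samples x %d points (axis %g..%g)\n",
              nrow(x$intensities), ncol(x$intensities),
              x$axis[1], x$axis[length(x$axis)]))
  invisible(x)
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample multiplicative dilution (the dominant nuisance in urine
#' NMR, where water intake scales whole spectra). Each sample is divided by
#' the median of its point-wise quotients against a reference spectrum. The
#' default reference is the point-wise median spectrum of the total-area
#' normalized samples (the standard Dieterle variant); any per-point vector
#' can be supplied instead.
#'
#' PQN output is invariant to rescaling any individual sample by c > 0, and
#' re-applying PQN yields per-sample factors of 1 (idempotence up to a global
#' scalar).
#'
#' @param block a \code{\link{spectral_block}} with non-negative intensities.
#' @param reference optional per-point reference spectrum; must be the same
#'   length as the axis.
#' @return a \code{spectral_block} with normalized intensities and an
#'   attribute \code{"pqn_factors"} holding the per-sample dilution factors.
#' @export
pqn_normalize <- function(block, reference = NULL) {
  stopifnot(inherits(block, "spectral_block"))
  X <- block$intensities
  if (any(X < 0)) stop("PQN requires non-negative intensities")
  totals <- rowSums(X)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("all-zero sample(s): ", paste(block$sample_ids[zero], collapse = ", "))
  }
  if (is.null(reference)) {
    if (nrow(X) < 2) stop("need >= 2 samples to build a PQN reference")
    area_norm <- X / totals
    reference <- apply(area_norm, 2, stats::median)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) stop("reference length != number of points")
  usable <- which(reference > 0)
  if (!length(usable)) stop("reference has no positive points")
  factors <- vapply(seq_len(nrow(X)), function(i) {
    q <- X[i, usable] / reference[usable]
    stats::median(q)
  }, numeric(1))
  if (any(factors <= 0)) {
    bad <- block$sample_ids[factors <= 0]
    stop("non-positive PQN factor for sample(s): ", paste(bad, collapse = ", "))
  }
  out <- spectral_block(X / factors, axis = block$axis,
                        sample_ids = block$sample_ids,
                        subject_ids = block$subject_ids)
  attr(out, "pqn_factors") <- factors
  out
}

#' Pick peaks from the mean spectrum
#'
#' Convenience utility: the canonical pipeline entry point is a pre-picked
#' table, but a simple picker is provided for raw spectra. Variables are
#' local maxima of the mean spectrum exceeding \code{min_height} and
#' separated by at least \code{min_separation} points; when two maxima fall
#' closer than that, the higher apex wins. Each sample's value at a picked
#' variable is its own intensity at the picked coordinate.
#'
#' @param block a \code{\link{spectral_block}}
#' @param min_height minimum mean-spectrum intensity for a peak
#' @param min_separation minimum index distance between picked peaks (>= 1)
#' @param modality modality tag for the resulting variables
#' @return a \code{\link{feature_matrix}} with one column per picked peak,
#'   named by the axis coordinate.
#' @export
peak_pick <- function(block, min_height, min_separation = 1L,
                      modality = "nmr") {
  stopifnot(inherits(block, "spectral_block"))
  if (min_separation < 1) stop("min_separation must be >= 1")
  m <- ncol(block$intensities)
  mu <- colMeans(block$intensities)
  is_max <- vapply(seq_len(m), function(i) {
    left <- if (i > 1) mu[i - 1] else -Inf
    right <- if (i < m) mu[i + 1] else -Inf
    mu[i] > left && mu[i] >= right && mu[i] > min_height
  }, logical(1))
  cand <- which(is_max)
  # greedy: keep highest apex first, suppress neighbors within min_separation
  cand <- cand[order(mu[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  if (!length(kept)) {
    warning("no peaks found above min_height = ", min_height)
    vals <- matrix(numeric(0), nrow = nrow(block$intensities), ncol = 0)
    return(feature_matrix(vals, sample_ids = block$sample_ids,
                          subject_ids = block$subject_ids,
                          modality = character(0),
                          variable_names = character(0)))
  }
  vals <- block$intensities[, kept, drop = FALSE]
  feature_matrix(vals, sample_ids = block$sample_ids,
                 subject_ids = block$subject_ids,
                 modality = modality,
                 variable_names = format(block$axis[kept], trim = TRUE))
}

#' Auto scaling (unit-variance scaling)
#'
#' Centers every variable to mean 0 and scales to sample standard deviation
#' 1, putting NMR intensities and element concentrations on a common scale
#' before they are merged and kernelized. Zero-variance columns carry no
#' information and are dropped with a warning rather than raising an error,
#' since merged omics tables routinely contain them.
#'
#' @param matrix a \code{\link{feature_matrix}} with >= 2 samples
#' @return a \code{feature_matrix} with scaled columns
#' @export
autoscale <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  X <- matrix$values
  if (nrow(X) < 2) stop("autoscale needs >= 2 samples")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  feature_matrix(X, sample_ids = matrix$sample_ids,
                 subject_ids = matrix$subject_ids,
                 modality = matrix$modality[keep])
}

#' Merge feature blocks column-wise
#'
#' Concatenates feature matrices (e.g. picked NMR peaks and ICP-OES
#' elements) aligned on sample ids. Row order follows the first block;
#' blocks listing the same samples in a different order give an identical
#' result. Variable name collisions across blocks are resolved by prefixing
#' with the modality.
#'
#' @param blocks list of \code{\link{feature_matrix}} objects sharing the
#'   same sample ids (order-insensitive)
#' @return a merged \code{feature_matrix}
#' @export
merge_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  for (b in blocks) stopifnot(inherits(b, "feature_matrix"))
  blocks <- Filter(function(b) ncol(b$values) > 0 || length(blocks) == 1,
                   blocks)
  ref <- blocks[[1]]
  ids <- ref$sample_ids
  for (b in blocks[-1]) {
    missing_in_b <- setdiff(ids, b$sample_ids)
    extra_in_b <- setdiff(b$sample_ids, ids)
    if (length(missing_in_b) || length(extra_in_b)) {
      stop("sample_id mismatch; missing: [",
           paste(missing_in_b, collapse = ", "), "] extra: [",
           paste(extra_in_b, collapse = ", "), "]")
    }
  }
  aligned <- lapply(blocks, function(b) b[ids, ])
  vals <- do.call(cbind, lapply(aligned, function(b) b$values))
  modality <- unlist(lapply(aligned, function(b) b$modality))
  nms <- unlist(lapply(aligned, function(b) colnames(b$values)))
  dup <- duplicated(nms) | duplicated(nms, fromLast = TRUE)
  if (any(dup)) {
    nms[dup] <- paste0(modality_prefix[modality[dup]], ":", nms[dup])
  }
  if (anyDuplicated(nms)) {
    nms <- make.unique(nms, sep = "_")
  }
  feature_matrix(vals, sample_ids = ids, subject_ids = ref$subject_ids,
                 modality = unname(modality), variable_names = nms)
}
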