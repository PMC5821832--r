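#' Kruskal-Wallis rank test with tie correction
#'
#' Omnibus rank test validating that an important variable actually differs
#' across the four pseudo-classes. With N observations in k groups,
#' mid-ranks \eqn{R_j} summed per group and tie multiplicities t,
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3(N+1)}
#'            {1 - \sum (t^3 - t) / (N^3 - N)}}
#' and the p-value comes from the chi-squared distribution with k - 1
#' degrees of freedom. When all values are identical the tie correction
#' degenerates; H is defined as 0 with p = 1. Significance tiers: * p <
#' 0.05, ** p < 0.01, *** p < 0.001.
#'
#' @param values numeric vector
#' @param groups group membership (>= 2 groups, each non-empty)
#' @param variable optional variable name carried into the result
#' @return an object of class \code{group_test}: list with
#'   \code{variable}, \code{statistic} (H), \code{df}, \code{p_value},
#'   \code{tier}
#' @export
kruskal_wallis <- function(values, groups, variable = NA_character_) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  if (anyNA(values)) stop("missing values")
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H0 <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H0 / corr
    H <- max(H, 0)
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  tier <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  structure(list(variable = variable, statistic = H, df = k - 1L,
                 p_value = p, tier = tier),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g %s\n",
              x$statistic, x$df, x$p_value, x$tier))
  invisible(x)
}

#' Kruskal-Wallis tests over a set of variables
#'
#' Runs \code{\link{kruskal_wallis}} per variable against the pseudo-class
#' labels. Raw p-value tiers are reported by default; pass
#' \code{adjust = "BH"} for Benjamini-Hochberg adjusted p-values (tiers
#' then follow the adjusted values).
#'
#' @param matrix a \code{\link{feature_matrix}}
#' @param labels class labels (\code{\link{quadrant_labels}} result or
#'   vector)
#' @param variables variables to test (default all)
#' @param adjust \code{"none"} (default) or \code{"BH"}
#' @return data.frame(variable, H, df, p_value, tier) ordered as requested
#' @export
kruskal_wallis_table <- function(matrix, labels, variables = NULL,
                                 adjust = c("none", "BH")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  adjust <- match.arg(adjust)
  y <- as_class_vector(labels)
  if (is.null(variables)) variables <- colnames(matrix$values)
  missing_vars <- setdiff(variables, colnames(matrix$values))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  }
  res <- lapply(variables, function(v) {
    gt <- kruskal_wallis(matrix$values[, v], y, variable = v)
    data.frame(variable = v, H = gt$statistic, df = gt$df,
               p_value = gt$p_value, tier = gt$tier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$tier <- ifelse(out$p_adjusted < 0.001, "***",
                ifelse(out$p_adjusted < 0.01, "**",
                ifelse(out$p_adjusted < 0.05, "*", "ns")))
  }
  rownames(out) <- NULL
  out
}

#' Per-group quartile summaries (box-plot numbers)
#'
#' For each requested variable and class: min, Q1, median, Q3, max and n.
#' Quartiles use linear interpolation of the empirical CDF (R quantile
#' type 7), the convention stated once and used everywhere since box-plot
#' definitions differ between tools.
#'
#' @inheritParams kruskal_wallis_table
#' @return data.frame(variable, class, min, q1, median, q3, max, n)
#' @export
group_summaries <- function(matrix, labels, variables = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  y <- as_class_vector(labels)
  if (is.null(variables)) variables <- colnames(matrix$values)
  missing_vars <- setdiff(variables, colnames(matrix$values))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  }
  rows <- list()
  for (v in variables) {
    for (cl in levels(y)) {
      x <- matrix$values[y == cl, v]
      q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                           names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, class = cl, min = q[1], q1 = q[2], median = q[3],
        q3 = q[4], max = q[5], n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
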