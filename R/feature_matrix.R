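#' Construct a feature matrix
#'
#' The central container of the package: a numeric sample x variable table
#' carrying sample identifiers, optional subject identifiers, and a modality
#' tag per variable. Modalities distinguish the heterogeneous blocks that a
#' metabolic profiling study merges: \code{"nmr"} (spectral peak intensities),
#' \code{"element"} (e.g. ICP-OES element concentrations) and
#' \code{"nutrient"} (dietary record variables used only by the association
#' mining stage).
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames or \code{S1..Sn}.
#' @param subject_ids character vector mapping each sample to a subject
#'   (volunteer); defaults to the sample ids (one subject per sample).
#' @param modality character vector, one of \code{"nmr"}, \code{"element"},
#'   \code{"nutrient"} per variable, or a single value recycled.
#' @param variable_names optional column names; defaults to existing colnames
#'   or \code{V1..Vp}.
#' @return an object of class \code{feature_matrix}: a list with elements
#'   \code{values}, \code{sample_ids}, \code{subject_ids}, \code{modality}.
#' @export
feature_matrix <- function(values, sample_ids = NULL, subject_ids = NULL,
                           modality = "nmr", variable_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length != number of rows")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (any(is.na(sample_ids)) || any(sample_ids == "")) {
    stop("missing sample_ids")
  }
  if (is.null(subject_ids)) subject_ids <- sample_ids
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop("subject_ids length != number of rows")
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
    if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))
  }
  variable_names <- as.character(variable_names)
  if (length(variable_names) != p) {
    stop("variable_names length != number of columns")
  }
  if (length(modality) == 1L) modality <- rep(modality, p)
  if (length(modality) != p) stop("modality length != number of columns")
  bad <- setdiff(unique(modality), c("nmr", "element", "nutrient"))
  if (length(bad)) {
    stop("unknown modality: ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("feature matrix contains missing or non-finite values")
  }
  dimnames(values) <- list(sample_ids, variable_names)
  structure(
    list(values = values, sample_ids = sample_ids,
         subject_ids = subject_ids, modality = modality),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$modality)
  cat("modalities:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Variable names of a feature matrix
#' @param x a \code{feature_matrix}
#' @return character vector of variable names
#' @export
variable_names <- function(x) colnames(x$values)

#' Subset a feature matrix
#'
#' @param x a \code{feature_matrix}
#' @param i sample index (ids, logical or integer)
#' @param j variable index (names, logical or integer)
#' @param ... ignored
#' @return a \code{feature_matrix}
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$sample_ids)
  ii <- seq_len(nrow(x$values))[i]
  if (is.character(j)) j <- match(j, colnames(x$values))
  jj <- seq_len(ncol(x$values))[j]
  feature_matrix(x$values[ii, jj, drop = FALSE],
                 sample_ids = x$sample_ids[ii],
                 subject_ids = x$subject_ids[ii],
                 modality = x$modality[jj])
}

modality_prefix <- c(nmr = "nmr", element = "elem", nutrient = "nutr")

#' Write a feature matrix to TSV
#'
#' Layout: first column \code{sample_id}, second column \code{subject_id},
#' then one column per variable. Modality is carried in the header by a
#' prefix convention: \code{nmr:}, \code{elem:}, \code{nutr:}.
#'
#' @param x a \code{feature_matrix}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_feature_matrix <- function(x, path) {
  hdr <- paste0(modality_prefix[x$modality], ":", colnames(x$values))
  df <- data.frame(sample_id = x$sample_ids, subject_id = x$subject_ids,
                   x$values, check.names = FALSE)
  colnames(df) <- c("sample_id", "subject_id", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' Inverse of \code{\link{write_feature_matrix}}. Columns without a modality
#' prefix are assigned \code{default_modality}. Missing values are rejected:
#' the pipeline assumes complete tables.
#'
#' @param path file path
#' @param default_modality modality for unprefixed columns
#' @return a \code{feature_matrix}
#' @export
read_feature_matrix <- function(path, default_modality = "nmr") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = list(sample_id = "character"))
  if (!"sample_id" %in% colnames(df)) {
    stop("no sample_id column in ", path)
  }
  sample_ids <- as.character(df$sample_id)
  subject_ids <- if ("subject_id" %in% colnames(df)) {
    as.character(df$subject_id)
  } else {
    sample_ids
  }
  keep <- setdiff(colnames(df), c("sample_id", "subject_id"))
  vals <- as.matrix(df[, keep, drop = FALSE])
  if (anyNA(vals)) stop("missing values in ", path, "; imputation is not supported")
  prefix_of <- sub("^(nmr|elem|nutr):.*$", "\\1", keep)
  has_prefix <- grepl("^(nmr|elem|nutr):", keep)
  rev_map <- c(nmr = "nmr", elem = "element", nutr = "nutrient")
  modality <- ifelse(has_prefix, rev_map[prefix_of], default_modality)
  names_clean <- ifelse(has_prefix, sub("^(nmr|elem|nutr):", "", keep), keep)
  feature_matrix(vals, sample_ids = sample_ids, subject_ids = subject_ids,
                 modality = unname(modality), variable_names = names_clean)
}
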