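#' Pipeline configuration
#'
#' Everything the end-to-end run needs, validated before any stage
#' executes. Defaults mirror the study protocol: ANOVA kernel (degree 1)
#' with a bandwidth scan over 0.05-0.30 unless a fixed sigma is given
#' (the study preset is sigma = 0.135), two components for quadrant
#' labeling, an 80-tree forest, and association-rule cutoffs
#' support 0.0625 / confidence 0.25 / lift 1.2.
#'
#' @param kernel a \code{\link{kernel_spec}}; its sigma is used as-is when
#'   \code{scan_sigma = FALSE}
#' @param scan_sigma scan the bandwidth grid and use the
#'   dispersion-maximizing sigma
#' @param sigma_grid grid for the scan
#' @param n_components components retained (2 drives the quadrants)
#' @param mapping quadrant-to-class mapping, see
#'   \code{\link{quadrant_labels}}
#' @param labels_file optional TSV (sample_id, class) overriding the
#'   quadrant labels with a hand-made grouping
#' @param forest a \code{\link{forest_config}}
#' @param run_loocv whether to run the (costly) leave-one-out validation
#' @param top_n variables carried into the rank report, Kruskal-Wallis
#'   table and association mining
#' @param min_support,min_confidence,min_lift association-rule cutoffs
#' @param max_len maximum itemset size
#' @param discretize_scheme see \code{\link{discretize}}
#' @param autoscale autoscale the merged matrix before KPCA
#' @return a validated list of class \code{pipeline_config}
#' @export
pipeline_config <- function(kernel = kernel_spec("anova", sigma = 0.135,
                                                 degree = 1L),
                            scan_sigma = TRUE,
                            sigma_grid = seq(0.05, 0.30, by = 0.025),
                            n_components = 2L, mapping = c(1L, 2L, 3L, 4L),
                            labels_file = NULL,
                            forest = forest_config(), run_loocv = TRUE,
                            top_n = 100L, min_support = 0.0625,
                            min_confidence = 0.25, min_lift = 1.2,
                            max_len = 3L, discretize_scheme = "median",
                            autoscale = TRUE) {
  stopifnot(inherits(kernel, "kernel_spec"),
            inherits(forest, "forest_config"))
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  if (min_confidence <= 0 || min_confidence > 1) {
    stop("min_confidence must be in (0, 1]")
  }
  if (min_lift <= 0) stop("min_lift must be positive")
  if (n_components < 2) stop("need >= 2 components for quadrant labeling")
  if (top_n < 1) stop("top_n must be >= 1")
  structure(
    list(kernel = kernel, scan_sigma = scan_sigma, sigma_grid = sigma_grid,
         n_components = as.integer(n_components),
         mapping = as.integer(mapping), labels_file = labels_file,
         forest = forest, run_loocv = run_loocv, top_n = as.integer(top_n),
         min_support = min_support, min_confidence = min_confidence,
         min_lift = min_lift, max_len = as.integer(max_len),
         discretize_scheme = discretize_scheme, autoscale = autoscale),
    class = "pipeline_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stage order follows the study protocol: (optional) auto scaling ->
#' KPCA (with bandwidth scan) -> quadrant pseudo-labels -> forest variable
#' importance (+ LOOCV validation) -> Kruskal-Wallis tests on the top
#' variables -> association mining of top variables plus nutrients ->
#' Cytoscape network export. Every intermediate is written as a plain-text
#' artifact in \code{out_dir} together with a log and the resolved config,
#' and a rerun with the same config and seed reproduces all files. A stage
#' failure aborts with the stage name; artifacts already written persist.
#'
#' @param features a \code{\link{feature_matrix}} (NMR/element variables)
#'   or a TSV path readable by \code{\link{read_feature_matrix}}
#' @param nutrients optional nutrient \code{feature_matrix} or TSV path
#'   (required for the association stage)
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir run directory (created if absent)
#' @return invisibly, a list with all in-memory results (\code{scores},
#'   \code{labels}, \code{importance}, \code{cv}, \code{kw},
#'   \code{rules}, \code{sigma}, paths of written artifacts)
#' @export
run_pipeline <- function(features, nutrients = NULL,
                         config = pipeline_config(), out_dir = "run") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(features)) features <- read_feature_matrix(features)
  if (is.character(nutrients)) {
    nutrients <- read_feature_matrix(nutrients,
                                     default_modality = "nutrient")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage %s: done", name)
    res
  }
  cfg_snapshot <- config
  cfg_snapshot$kernel <- unclass(config$kernel)
  cfg_snapshot$forest <- unclass(config$forest)
  jsonlite::write_json(unclass(cfg_snapshot),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  logf("pipeline start: n=%d p=%d seed=%d", nrow(features$values),
       ncol(features$values), config$forest$seed)

  X <- stage("preprocess", {
    if (config$autoscale) autoscale(features) else features
  })
  write_feature_matrix(X, file.path(out_dir, "matrix.tsv"))

  kernel <- config$kernel
  if (config$scan_sigma && kernel$family != "linear") {
    scan <- stage("sigma_scan", {
      scan_sigma(X, sigma_grid = config$sigma_grid,
                 degree = kernel$degree, family = kernel$family,
                 n_components = config$n_components)
    })
    write_tsv(scan, file.path(out_dir, "sigma_scan.tsv"))
    best <- attr(scan, "best_sigma")
    if (is.na(best)) stop("pipeline stage 'sigma_scan' failed: no usable sigma")
    logf("sigma scan: selected sigma = %g", best)
    kernel <- kernel_spec(kernel$family, sigma = best,
                          degree = kernel$degree)
  }

  model <- stage("kpca", kpca_fit(X, kernel, config$n_components))
  labels <- stage("labels", {
    if (!is.null(config$labels_file)) {
      df <- utils::read.delim(config$labels_file,
                              colClasses = c(sample_id = "character"))
      cls <- df$class[match(X$sample_ids, df$sample_id)]
      if (anyNA(cls)) stop("labels file missing sample(s)")
      structure(list(class = stats::setNames(as.integer(cls),
                                             X$sample_ids),
                     mapping = config$mapping),
                class = "quadrant_labeling")
    } else {
      quadrant_labels(model, mapping = config$mapping)
    }
  })
  scores_df <- data.frame(sample_id = X$sample_ids,
                          PC1 = model$scores[, 1], PC2 = model$scores[, 2],
                          class = labels$class)
  write_tsv(scores_df, file.path(out_dir, "scores.tsv"))

  forest <- stage("forest", fit_forest(X, labels, config$forest))
  importance <- stage("importance", conditional_importance(forest))
  top <- rank_report(importance, min(config$top_n, nrow(importance)))
  write_tsv(importance, file.path(out_dir, "importance.tsv"))

  cv <- NULL
  if (config$run_loocv) {
    cv <- stage("loocv", loocv(X, labels, config$forest))
    cv_df <- as.data.frame(cv$confusion)
    write_tsv(cv_df, file.path(out_dir, "confusion.tsv"))
    writeLines(sprintf("accuracy\t%.10g", cv$accuracy),
               file.path(out_dir, "cv_accuracy.tsv"))
    logf("loocv accuracy: %.4f", cv$accuracy)
  }

  kw <- stage("kruskal_wallis", {
    kruskal_wallis_table(X, labels, variables = top$variable)
  })
  write_tsv(kw, file.path(out_dir, "kw.tsv"))

  rules <- NULL
  if (!is.null(nutrients)) {
    rules <- stage("mba", {
      mba_input <- merge_blocks(list(X[, top$variable], nutrients))
      tx <- discretize(mba_input, scheme = config$discretize_scheme)
      mine_rules(tx, min_support = config$min_support,
                 min_confidence = config$min_confidence,
                 min_lift = config$min_lift, max_len = config$max_len)
    })
    write_rules(rules, file.path(out_dir, "rules.tsv"))
    if (nrow(rules)) {
      stage("network", export_network(rules,
                                      file.path(out_dir, "network")))
    } else {
      logf("no rules passed the cutoffs; network export skipped")
    }
  }
  logf("pipeline done")
  invisible(list(matrix = X, kernel = kernel, model = model,
                 labels = labels, importance = importance, top = top,
                 cv = cv, kw = kw, rules = rules, out_dir = out_dir))
}
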