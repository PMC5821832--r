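#' Discretize a feature table into transactions
#'
#' Market basket analysis needs categorical items, so continuous metabolite,
#' element and nutrient levels are binned per variable. The default median
#' split emits \code{"<name>=high"} for samples strictly above the
#' variable's median, \code{"<name>=low"} strictly below, and nothing at the
#' median; a k-quantile scheme (\code{scheme = 3} for tertiles, giving items
#' \code{"<name>=q1"} .. \code{"<name>=qk"}) is available. Constant
#' variables emit no items.
#'
#' @param matrix a \code{\link{feature_matrix}}
#' @param scheme \code{"median"} or an integer k >= 2 for k-quantile bins
#' @return an object of class \code{transaction_set}: list with
#'   \code{items} (one character vector per sample), \code{universe},
#'   \code{sample_ids}
#' @export
discretize <- function(matrix, scheme = "median") {
  stopifnot(inherits(matrix, "feature_matrix"))
  X <- matrix$values
  n <- nrow(X)
  if (n < 1) stop("need >= 1 sample")
  items <- replicate(n, character(0), simplify = FALSE)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    nm <- colnames(X)[j]
    if (length(unique(v)) == 1) {
      message("constant variable emits no items: ", nm)
      next
    }
    lab <- if (identical(scheme, "median")) {
      md <- stats::median(v)
      ifelse(v > md, "high", ifelse(v < md, "low", NA_character_))
    } else {
      k <- as.integer(scheme)
      if (is.na(k) || k < 2) stop("scheme must be 'median' or an integer >= 2")
      br <- stats::quantile(v, probs = seq(0, 1, length.out = k + 1))
      br <- unique(br)
      if (length(br) < 3) {
        message("degenerate quantile bins, no items for: ", nm)
        next
      }
      as.character(cut(v, breaks = br, labels = paste0("q", seq_len(length(br) - 1)),
                       include.lowest = TRUE))
    }
    for (i in which(!is.na(lab))) {
      items[[i]] <- c(items[[i]], paste0(nm, "=", lab[i]))
    }
  }
  items <- lapply(items, unique)
  structure(
    list(items = items, universe = sort(unique(unlist(items))),
         sample_ids = matrix$sample_ids),
    class = "transaction_set"
  )
}

#' Build a transaction set from item lists
#'
#' @param items list of character vectors (one transaction per sample)
#' @param sample_ids optional identifiers
#' @return a \code{transaction_set}
#' @export
transaction_set <- function(items, sample_ids = NULL) {
  items <- lapply(items, function(x) unique(as.character(x)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(items))
  structure(
    list(items = items, universe = sort(unique(unlist(items))),
         sample_ids = as.character(sample_ids)),
    class = "transaction_set"
  )
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("transaction_set: %d transactions over %d items\n",
              length(x$items), length(x$universe)))
  invisible(x)
}

#' Write/read transactions in basket text format (one line per sample,
#' tab-separated items)
#' @param x a \code{transaction_set}
#' @param path file path
#' @return \code{path} (write) or a \code{transaction_set} (read)
#' @export
write_transactions <- function(x, path) {
  writeLines(vapply(x$items, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  lines <- readLines(path)
  transaction_set(lapply(strsplit(lines, "\t", fixed = TRUE),
                         function(v) v[v != ""]))
}

itemset_key <- function(items) paste(sort(items), collapse = "\x1f")

#' Mine frequent itemsets (Apriori)
#'
#' Level-wise candidate generation with the downward-closure prune: a
#' (k+1)-itemset is only counted if all its k-subsets are frequent.
#' Supports are exact counts / n.
#'
#' @param transactions a \code{\link{transaction_set}}
#' @param min_support minimum support in (0, 1]
#' @param max_len maximum itemset size (default 3, bounding combinatorics)
#' @return an object of class \code{frequent_itemsets}: list with
#'   \code{items} (list of sorted character vectors), \code{support},
#'   \code{n_transactions}
#' @export
apriori <- function(transactions, min_support, max_len = 3L) {
  stopifnot(inherits(transactions, "transaction_set"))
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  n <- length(transactions$items)
  if (n == 0) stop("empty transaction set")
  universe <- transactions$universe
  # incidence matrix: n x |universe|
  inc <- matrix(FALSE, n, length(universe),
                dimnames = list(NULL, universe))
  for (i in seq_len(n)) inc[i, transactions$items[[i]]] <- TRUE
  supp1 <- colMeans(inc)
  frequent_items <- universe[supp1 >= min_support]
  out_items <- as.list(frequent_items)
  out_supp <- supp1[supp1 >= min_support]
  level <- lapply(frequent_items, identity)
  level_mask <- lapply(frequent_items, function(it) inc[, it])
  k <- 1L
  freq_keys <- new.env(parent = emptyenv())
  for (it in frequent_items) assign(itemset_key(it), TRUE, envir = freq_keys)
  while (length(level) >= 2 && k < max_len) {
    # join step: combine sets sharing their first k-1 items
    keys <- vapply(level, function(s) paste(s[-length(s)], collapse = "\x1f"),
                   "")
    next_level <- list()
    next_mask <- list()
    groups <- split(seq_along(level), keys)
    for (g in groups) {
      if (length(g) < 2) next
      lasts <- vapply(level[g], function(s) s[length(s)], "")
      o <- order(lasts)
      g <- g[o]
      for (a in seq_len(length(g) - 1)) {
        for (b in seq((a + 1), length(g))) {
          cand <- c(level[[g[a]]], level[[g[b]]][k])
          # downward-closure prune over all k-subsets
          ok <- all(vapply(seq_len(k + 1), function(drop_i) {
            exists(itemset_key(cand[-drop_i]), envir = freq_keys)
          }, logical(1)))
          if (!ok) next
          mask <- level_mask[[g[a]]] & inc[, cand[k + 1]]
          s <- sum(mask) / n
          if (s >= min_support) {
            next_level[[length(next_level) + 1L]] <- cand
            next_mask[[length(next_mask) + 1L]] <- mask
            out_items[[length(out_items) + 1L]] <- cand
            out_supp <- c(out_supp, s)
          }
        }
      }
    }
    for (it in next_level) assign(itemset_key(it), TRUE, envir = freq_keys)
    level <- next_level
    level_mask <- next_mask
    k <- k + 1L
  }
  structure(
    list(items = lapply(out_items, sort), support = unname(out_supp),
         n_transactions = n),
    class = "frequent_itemsets"
  )
}

#' @export
print.frequent_itemsets <- function(x, ...) {
  cat(sprintf("frequent_itemsets: %d sets over %d transactions\n",
              length(x$items), x$n_transactions))
  invisible(x)
}

all_nonempty_proper_subsets <- function(items) {
  m <- length(items)
  out <- list()
  for (code in seq_len(2^m - 2)) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
    out[[length(out) + 1L]] <- items[sel]
  }
  out
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2, all antecedent -> consequent
#' partitions are scored: confidence = supp(A and C) / supp(A) and
#' lift = confidence / supp(C). Rules meeting both thresholds are kept.
#' The defaults are the study presets for ~400-sample tables: support
#' 0.0625, confidence 0.25, lift 1.2 (lift > 1 marks co-occurrence above
#' independence; independent item pairs sit at lift 1 and are removed).
#' Rule support follows the A-union-C convention.
#'
#' @param itemsets a \code{\link{apriori}} result
#' @param min_confidence minimum confidence
#' @param min_lift minimum lift
#' @return an object of class \code{rule_set}: data.frame with columns
#'   antecedent, consequent (comma-joined sorted items), support,
#'   confidence, lift, sorted by decreasing lift
#' @export
generate_rules <- function(itemsets, min_confidence = 0.25, min_lift = 1.2) {
  stopifnot(inherits(itemsets, "frequent_itemsets"))
  supp_of <- stats::setNames(itemsets$support,
                             vapply(itemsets$items, itemset_key, ""))
  rows <- list()
  for (i in seq_along(itemsets$items)) {
    items <- itemsets$items[[i]]
    if (length(items) < 2) next
    s_all <- itemsets$support[i]
    for (A in all_nonempty_proper_subsets(items)) {
      C <- setdiff(items, A)
      sA <- supp_of[[itemset_key(A)]]
      sC <- supp_of[[itemset_key(C)]]
      conf <- s_all / sA
      lift <- conf / sC
      if (conf >= min_confidence && lift >= min_lift) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(sort(A), collapse = ","),
          consequent = paste(sort(C), collapse = ","),
          support = s_all, confidence = conf, lift = lift,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antecedent = character(0), consequent = character(0),
               support = numeric(0), confidence = numeric(0),
               lift = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$lift, -out$confidence, out$antecedent,
                   out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Mine association rules in one step
#'
#' Convenience wrapper: \code{\link{apriori}} followed by
#' \code{\link{generate_rules}} at the study preset cutoffs.
#'
#' @param transactions a \code{\link{transaction_set}}
#' @param min_support,min_confidence,min_lift thresholds
#' @param max_len maximum itemset size
#' @return a \code{rule_set}
#' @export
mine_rules <- function(transactions, min_support = 0.0625,
                       min_confidence = 0.25, min_lift = 1.2,
                       max_len = 3L) {
  generate_rules(apriori(transactions, min_support, max_len),
                 min_confidence, min_lift)
}

rule_item_pairs <- function(rules) {
  if (!nrow(rules)) {
    return(data.frame(from = character(0), to = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(rules)), function(i) {
    ants <- strsplit(rules$antecedent[i], ",", fixed = TRUE)[[1]]
    cons <- strsplit(rules$consequent[i], ",", fixed = TRUE)[[1]]
    expand.grid(from = ants, to = cons, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[
      , , drop = FALSE] |>
      transform(support = rules$support[i],
                confidence = rules$confidence[i], lift = rules$lift[i])
  })
  do.call(rbind, rows)
}

#' Export a rule network for Cytoscape
#'
#' Writes the antecedent-item -> consequent-item graph in two formats a
#' Cytoscape session can load: SIF (\code{<prefix>.sif}, interaction type
#' \code{assoc}) and GraphML (\code{<prefix>.graphml}) with support,
#' confidence and lift as edge attributes. Parallel item pairs from
#' different rules keep the strongest (highest lift) edge.
#'
#' @param rules a non-empty \code{\link{generate_rules}} result
#' @param prefix output path prefix
#' @return character vector of the two file paths, invisibly
#' @export
export_network <- function(rules, prefix) {
  stopifnot(inherits(rules, "rule_set"))
  if (!nrow(rules)) stop("empty rule set")
  edges <- rule_item_pairs(rules)
  edges <- edges[order(-edges$lift), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  sif_path <- paste0(prefix, ".sif")
  gml_path <- paste0(prefix, ".graphml")
  ok <- tryCatch({
    writeLines(paste(edges$from, "assoc", edges$to, sep = "\t"), sif_path)
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, gml_path, format = "graphml")
    TRUE
  }, error = function(e) {
    stop("network export failed for prefix '", prefix, "': ",
         conditionMessage(e))
  })
  invisible(c(sif_path, gml_path))
}

#' Write rules as TSV
#' @param rules a \code{rule_set}
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_rules <- function(rules, path) {
  utils::write.table(as.data.frame(rules), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
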