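# Independent oracles used across test files. Deliberately written as plain
# loops over definitions, sharing no code with the implementation paths they
# check.

# PQN by direct evaluation of the quotient-median definition
oracle_pqn_factors <- function(X, reference) {
  factors <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    q <- c()
    for (j in seq_len(ncol(X))) {
      if (reference[j] > 0) q <- c(q, X[i, j] / reference[j])
    }
    factors[i] <- median(q)
  }
  factors
}

oracle_pqn_reference <- function(X) {
  A <- X / rowSums(X)
  ref <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) ref[j] <- median(A[, j])
  ref
}

# scalar ANOVA kernel evaluated term by term
oracle_anova <- function(x, y, sigma, d) {
  s <- 0
  for (k in seq_along(x)) s <- s + exp(-sigma * (x[k] - y[k])^2)
  s^d
}

# explicit-loop double centering
oracle_center <- function(K) {
  n <- nrow(K)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- K[i, j] - mean(K[i, ]) - mean(K[, j]) + mean(K)
    }
  }
  out
}

# exhaustive frequent-itemset enumeration over the whole powerset
oracle_itemsets <- function(tx_items, min_support, max_len) {
  universe <- sort(unique(unlist(tx_items)))
  n <- length(tx_items)
  out_items <- list()
  out_supp <- numeric(0)
  for (size in seq_len(min(max_len, length(universe)))) {
    combos <- utils::combn(universe, size, simplify = FALSE)
    for (s in combos) {
      cnt <- sum(vapply(tx_items, function(t) all(s %in% t), logical(1)))
      if (cnt / n >= min_support) {
        out_items[[length(out_items) + 1L]] <- s
        out_supp <- c(out_supp, cnt / n)
      }
    }
  }
  list(items = out_items, support = out_supp)
}

# exhaustive rule enumeration from an exhaustive itemset list
oracle_rules <- function(tx_items, min_support, min_confidence, min_lift,
                         max_len) {
  fi <- oracle_itemsets(tx_items, min_support, max_len)
  key <- function(s) paste(sort(s), collapse = "|")
  supp <- stats::setNames(fi$support, vapply(fi$items, key, ""))
  rows <- list()
  for (i in seq_along(fi$items)) {
    s <- fi$items[[i]]
    m <- length(s)
    if (m < 2) next
    for (code in seq_len(2^m - 2)) {
      sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
      A <- s[sel]
      C <- s[!sel]
      conf <- fi$support[i] / supp[[key(A)]]
      lift <- conf / supp[[key(C)]]
      if (conf >= min_confidence && lift >= min_lift) {
        rows[[length(rows) + 1L]] <- paste(
          paste(sort(A), collapse = ","), "->",
          paste(sort(C), collapse = ","),
          sprintf("%.10f %.10f %.10f", fi$support[i], conf, lift))
      }
    }
  }
  sort(unlist(rows))
}

rule_strings <- function(rules) {
  if (!nrow(rules)) return(character(0))
  sort(sprintf("%s -> %s %.10f %.10f %.10f", rules$antecedent,
               rules$consequent, rules$support, rules$confidence,
               rules$lift))
}

# Kruskal-Wallis by direct rank-sum arithmetic
oracle_kw <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (g in unique(groups)) {
    Rj <- sum(r[groups == g])
    nj <- sum(groups == g)
    H <- H + Rj^2 / nj
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  tie_tab <- table(values)
  H / (1 - sum(tie_tab^3 - tie_tab) / (N^3 - N))
}

# does any rule mention both members of a planted pair (either polarity)?
pair_in_rules <- function(rules, met, nut) {
  if (!nrow(rules)) return(FALSE)
  joined <- paste(rules$antecedent, rules$consequent, sep = ",")
  any(grepl(paste0("(^|,)", met, "="), joined) &
        grepl(paste0("(^|,)", nut, "="), joined))
}

random_transactions <- function(n_tx, n_items, seed) {
  set.seed(seed)
  items <- paste0("i", seq_len(n_items))
  transaction_set(lapply(seq_len(n_tx), function(i) {
    k <- sample(1:min(6, n_items), 1)
    sample(items, k)
  }))
}
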