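test_that("median-split discretization implements the strict rule", {
  fm <- feature_matrix(cbind(a = c(1, 2, 3)), sample_ids = c("s1", "s2", "s3"))
  tx <- discretize(fm)
  expect_equal(tx$items[[1]], "a=low")
  expect_equal(tx$items[[2]], character(0))
  expect_equal(tx$items[[3]], "a=high")
  # constant variable emits nothing
  fm2 <- feature_matrix(cbind(a = c(5, 5, 5), b = c(1, 2, 3)))
  expect_message(tx2 <- discretize(fm2), "constant")
  expect_false(any(grepl("^a=", unlist(tx2$items))))
})

test_that("tertile scheme splits 1..9 into 3/3/3 (brute-force check)", {
  fm <- feature_matrix(cbind(v = 1:9))
  tx <- discretize(fm, scheme = 3)
  got <- unlist(tx$items)
  expect_equal(unname(table(got)[c("v=q1", "v=q2", "v=q3")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  # brute force: each sample lands in the bin of its own empirical tertile
  q <- quantile(1:9, c(1 / 3, 2 / 3))
  for (i in 1:9) {
    expected <- if (i <= q[1]) "v=q1" else if (i <= q[2]) "v=q2" else "v=q3"
    expect_equal(tx$items[[i]], expected)
  }
})

test_that("apriori matches exhaustive enumeration on a small worked case", {
  tx <- transaction_set(list(
    c("A", "B"), c("A", "C"), c("A", "B", "C"), c("B"),
    c("A", "B", "D"), c("D", "E"), c("A"), c("B", "C")))
  fi <- apriori(tx, min_support = 2 / 8, max_len = 5)
  oracle <- oracle_itemsets(tx$items, 2 / 8, 5)
  key <- function(s) paste(sort(s), collapse = "|")
  got <- sort(paste(vapply(fi$items, key, ""), fi$support))
  want <- sort(paste(vapply(oracle$items, key, ""), oracle$support))
  expect_equal(got, want)
  # support accounting for a singleton: A appears in 5 of 8 transactions
  expect_equal(fi$support[vapply(fi$items, identical, TRUE, "A")], 5 / 8)
  # min_support = 1 keeps only universally present itemsets
  all_tx <- transaction_set(list(c("X", "Y"), c("X", "Y", "Z"), c("X", "Y")))
  fi1 <- apriori(all_tx, 1.0)
  expect_setequal(vapply(fi1$items, key, ""), c("X", "Y", "X|Y"))
  expect_error(apriori(transaction_set(list()), 0.5), "empty")
  expect_error(apriori(tx, 0), "min_support")
})

test_that("apriori equals brute force on random transaction sets and
           satisfies downward closure and order invariance", {
  key <- function(s) paste(sort(s), collapse = "|")
  for (trial in 1:10) {
    tx <- random_transactions(n_tx = 25, n_items = 9, seed = 100 + trial)
    ms <- sample(c(0.1, 0.15, 0.2), 1)
    fi <- apriori(tx, ms, max_len = 4)
    oracle <- oracle_itemsets(tx$items, ms, 4)
    expect_equal(sort(paste(vapply(fi$items, key, ""),
                            sprintf("%.10f", fi$support))),
                 sort(paste(vapply(oracle$items, key, ""),
                            sprintf("%.10f", oracle$support))))
    # downward closure
    keys <- vapply(fi$items, key, "")
    for (s in fi$items) {
      if (length(s) < 2) next
      for (drop_i in seq_along(s)) {
        expect_true(key(s[-drop_i]) %in% keys)
      }
    }
    # transaction order invariance
    set.seed(trial)
    shuf <- transaction_set(sample(tx$items))
    fi2 <- apriori(shuf, ms, max_len = 4)
    expect_equal(sort(paste(vapply(fi2$items, key, ""), fi2$support)),
                 sort(paste(vapply(fi$items, key, ""), fi$support)))
  }
})

test_that("generate_rules equals brute-force partition enumeration", {
  for (trial in 1:6) {
    tx <- random_transactions(n_tx = 16, n_items = 7, seed = 200 + trial)
    fi <- apriori(tx, 0.15, max_len = 4)
    rules <- generate_rules(fi, min_confidence = 0.3, min_lift = 1.1)
    expect_equal(rule_strings(rules),
                 oracle_rules(tx$items, 0.15, 0.3, 1.1, 4))
  }
})

test_that("perfectly coupled items: confidence 1, lift 1/supp", {
  # A present iff B present, in half of transactions
  tx <- transaction_set(c(replicate(8, c("A", "B"), simplify = FALSE),
                          replicate(8, "C", simplify = FALSE)))
  rules <- mine_rules(tx, min_support = 0.2, min_confidence = 0.5,
                      min_lift = 1)
  ab <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_equal(ab$confidence, 1)
  expect_equal(ab$lift, 1 / 0.5)
})

test_that("statistically independent items sit at lift 1 and are removed by
           the 1.2 cutoff", {
  # exact independence by construction: 4n transactions with all sign
  # combinations of A and B at their marginal frequencies
  blocks <- c(replicate(4, c("A", "B"), simplify = FALSE),
              replicate(4, "A", simplify = FALSE),
              replicate(4, "B", simplify = FALSE),
              replicate(4, "none", simplify = FALSE))
  tx <- transaction_set(blocks)
  fi <- apriori(tx, 0.05, max_len = 2)
  free <- generate_rules(fi, min_confidence = 0, min_lift = 0)
  ab <- free[free$antecedent == "A" & free$consequent == "B", ]
  expect_equal(ab$lift, 1)
  cut <- generate_rules(fi, min_confidence = 0.25, min_lift = 1.2)
  expect_false(any(cut$antecedent == "A" & cut$consequent == "B"))
})

test_that("raising any threshold yields a subset of the rules", {
  tx <- random_transactions(n_tx = 40, n_items = 8, seed = 300)
  base <- mine_rules(tx, 0.05, 0.2, 1.0, max_len = 3)
  for (args in list(c(0.15, 0.2, 1.0), c(0.05, 0.5, 1.0),
                    c(0.05, 0.2, 1.5))) {
    tighter <- mine_rules(tx, args[1], args[2], args[3], max_len = 3)
    expect_true(all(rule_strings(tighter) %in% rule_strings(base)))
  }
})

test_that("network export writes SIF and round-trippable GraphML", {
  rules <- data.frame(antecedent = c("A,B", "C"), consequent = c("C", "D"),
                      support = c(0.3, 0.2), confidence = c(0.8, 0.5),
                      lift = c(1.6, 1.3), stringsAsFactors = FALSE)
  class(rules) <- c("rule_set", "data.frame")
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(rules, prefix)
  sif <- read.delim(paste0(prefix, ".sif"), header = FALSE)
  expect_equal(nrow(sif), 3)  # A->C, B->C, C->D
  expect_true(all(sif$V2 == "assoc"))
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::E(g)$lift), c(1.3, 1.6, 1.6))
  empty <- rules[0, ]
  class(empty) <- c("rule_set", "data.frame")
  expect_error(export_network(empty, prefix), "empty")
})

test_that("transactions round-trip through basket text format", {
  tx <- transaction_set(list(c("a", "b"), "c", character(0)))
  path <- withr::local_tempfile()
  write_transactions(tx, path)
  back <- read_transactions(path)
  expect_equal(back$items, tx$items)
})
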