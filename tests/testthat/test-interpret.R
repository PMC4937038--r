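test_that("AUC handles perfect separation, ties and the null", {
  labels <- c(rep("1", 3), rep("-1", 3))
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), labels)$auc, 1)
  # hand-built list with one cross-class tie: concordant pairs 7, ties 1 -> 7.5/9
  scores <- c(0.9, 0.5, 0.4, 0.5, 0.3, 0.1)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, auc_brute(scores, labels))
  expect_equal(r$auc, 7.5 / 9)
  set.seed(31)
  big <- rnorm(400)
  lab_big <- rep(c("1", "-1"), 200)
  expect_lt(abs(roc_auc(big, lab_big)$auc - 0.5), 0.08)
})

test_that("AUC equals brute-force concordance counting on random instances", {
  set.seed(32)
  for (i in 1:100) {
    n_pos <- sample(2:25, 1); n_neg <- sample(2:25, 1)
    scores <- round(rnorm(n_pos + n_neg), sample(0:2, 1))  # induce ties
    labels <- c(rep("1", n_pos), rep("-1", n_neg))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_brute(scores, labels), tolerance = 1e-12)
    expect_lte(r$ci_low, r$auc + 1e-12)
    expect_gte(r$ci_high, r$auc - 1e-12)
  }
})

test_that("identical scores degrade gracefully to chance", {
  expect_warning(r <- roc_auc(rep(0.5, 10), rep(c("1", "-1"), 5)), "identical")
  expect_identical(r$auc, 0.5)
  expect_true(r$degenerate)
})

test_that("Welch t-tests match a hand-computed 3v3 example and t.test", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  # manual Welch: means 2 and 5, variances 1 and 13
  se <- sqrt(1 / 3 + 13 / 3)
  t_manual <- (2 - 5) / se
  df_manual <- (1 / 3 + 13 / 3)^2 / ((1 / 3)^2 / 2 + (13 / 3)^2 / 2)
  p_manual <- 2 * pt(abs(t_manual), df_manual, lower.tail = FALSE)
  ft <- make_ft(cbind(f = c(a, b)), labels = rep(c("1", "-1"), each = 3), ids = "f")
  res <- feature_t_tests(ft)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p, p_manual, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  ft2 <- make_ft(cbind(f = c(a, a)), labels = rep(c("1", "-1"), each = 3), ids = "f")
  expect_equal(feature_t_tests(ft2)$p, 1)
})

test_that("a planted strong effect is detected with high power at n = 111", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    m <- cbind(f = c(rnorm(55, 1.5 / 2), rnorm(56, -1.5 / 2)))
    ft <- make_ft(m, labels = c(rep("1", 55), rep("-1", 56)), ids = "f")
    feature_t_tests(ft)$p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("correlation networks keep signed edges meeting the threshold", {
  set.seed(33)
  base <- rnorm(60)
  m <- cbind(a = base, b = base + rnorm(60, sd = 0.1), c = -base + rnorm(60, sd = 0.1),
             d = rnorm(60))
  ft <- make_ft(m, labels = rep(c("1", "-1"), 30), ids = colnames(m))
  net <- correlation_network(ft, colnames(m), threshold = 0.5)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("a b", "a c", "b c"))
  expect_true(all(abs(net$edges$r) >= 0.5))
  sign_ab <- net$edges$r[net$edges$from == "a" & net$edges$to == "b"]
  sign_ac <- net$edges$r[net$edges$from == "a" & net$edges$to == "c"]
  expect_gt(sign_ab, 0); expect_lt(sign_ac, 0)
  # duplicated pair has r exactly 1; impossible threshold empties the graph
  ft2 <- make_ft(cbind(x = base, y = base), rep(c("1", "-1"), 30), c("x", "y"))
  expect_equal(correlation_network(ft2, c("x", "y"))$edges$r, 1)
  expect_identical(nrow(correlation_network(ft, colnames(m), threshold = 1.01)$edges), 0L)
})

test_that("a synthetic correlated block forms a positive triangle", {
  ft <- generate_dataset(synth_spec(60, 60, 5, cluster_sizes = 3,
                                    within_cluster_r = 0.9, seed = 34))
  ids <- feature_ids(ft)[1:3]
  net <- correlation_network(ft, ids, threshold = 0.5)
  expect_identical(nrow(net$edges), 3L)
  expect_true(all(net$edges$r > 0))
})

test_that("equal-width bins split {0..4} at 1, 2, 3 and cover every sample", {
  ft <- make_ft(cbind(f = c(0, 1, 2, 3, 4), g = c(10, 20, 30, 40, 50)),
                labels = c("1", "1", "1", "-1", "-1"), ids = c("f", "g"))
  tr <- discretize_equal_width(ft, c("f", "g"), n_bins = 4)
  expect_equal(tr$bins$f, c(1, 2, 3))
  expect_true(all(lengths(tr$transactions) == 2))
  # value on a cut belongs to the lower (right-closed) interval
  expect_identical(tr$transactions[[2]][1], "f=(-inf - 1]")
  expect_identical(tr$transactions[[5]][1], "f=(3 - inf)")
})

test_that("bin membership matches a brute-force recount on random data", {
  set.seed(35)
  m <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  ft <- make_ft(m, labels = rep(c("1", "-1"), 20), ids = colnames(m))
  tr <- discretize_equal_width(ft, colnames(m), n_bins = 4)
  for (f in colnames(m)) {
    cuts <- tr$bins[[f]]
    labels_seen <- vapply(tr$transactions, `[`, "", match(f, colnames(m)))
    bin_order <- sort(unique(labels_seen))  # not bin-ordered; map via recount
    for (i in seq_len(nrow(m))) {
      expected_bin <- sum(m[i, f] > cuts) + 1
      lows <- c(-Inf, cuts); highs <- c(cuts, Inf)
      # the assigned item's interval must contain the value
      expect_true(m[i, f] > lows[expected_bin] || expected_bin == 1)
      expect_lte(m[i, f], highs[expected_bin])
      # and all samples in the same bin carry the same item label
      same_bin <- which(vapply(m[, f], function(v) sum(v > cuts) + 1, 0) == expected_bin)
      expect_identical(unique(labels_seen[same_bin]), labels_seen[i])
    }
  }
})

test_that("constant features collapse to one flagged interval", {
  ft <- make_ft(cbind(flat = rep(3, 6), v = rnorm(6)),
                labels = rep(c("1", "-1"), 3), ids = c("flat", "v"))
  expect_warning(tr <- discretize_equal_width(ft, c("flat", "v")), "constant")
  expect_identical(unique(vapply(tr$transactions, `[`, "", 1)), "flat=(-inf - inf)")
})

test_that("a deterministic implication mines with confidence 1", {
  trs <- list(c("A", "B"), c("A", "B"), c("A", "B", "C"), c("C"), c("B"))
  rules <- mine_rules(trs, min_support = 0.2, min_confidence = 0.9)
  ab <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_identical(nrow(ab), 1L)
  expect_identical(ab$confidence, 1)
  expect_equal(ab$support, 3 / 5)
})

test_that("supports and confidences equal brute-force enumeration on a toy", {
  trs <- list(c("x", "y", "z"), c("x", "y"), c("x", "z"), c("y", "z"),
              c("x", "y", "z"), c("z"))
  oracle <- itemsets_brute(trs, min_support = 1 / 6)
  rules <- mine_rules(trs, min_support = 1 / 6, min_confidence = 0)
  for (i in seq_len(nrow(rules))) {
    ante <- strsplit(rules$antecedent[i], " & ", fixed = TRUE)[[1]]
    full <- sort(c(ante, rules$consequent[i]))
    expect_equal(rules$support[i], oracle[[paste(full, collapse = "|")]])
    expect_equal(rules$confidence[i],
                 oracle[[paste(full, collapse = "|")]] /
                   oracle[[paste(sort(ante), collapse = "|")]])
  }
  # every frequent itemset of size >= 2 appears as at least one rule
  n_freq2 <- sum(lengths(strsplit(names(oracle), "|", fixed = TRUE)) >= 2)
  expect_gte(nrow(rules), n_freq2)
})

test_that("raising min_support never adds rules and zero support is rejected", {
  trs <- list(c("x", "y"), c("x", "y"), c("x"), c("y"))
  lo <- mine_rules(trs, 0.25, 0.5)
  hi <- mine_rules(trs, 0.5, 0.5)
  expect_lte(nrow(hi), nrow(lo))
  key <- function(df) paste(df$antecedent, df$consequent)
  expect_true(all(key(hi) %in% key(lo)))
  expect_error(mine_rules(trs, 0, 0.5), "positive")
})
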