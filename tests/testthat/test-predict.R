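test_that("confusion metric identities hold on random matrices", {
  set.seed(24)
  for (i in 1:20) {
    cm <- as.list(rmultinom(1, sample(20:200, 1), c(0.3, 0.2, 0.3, 0.2))[, 1])
    names(cm) <- c("tp", "fp", "tn", "fn")
    rep <- confusion_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
    n <- cm$tp + cm$fp + cm$tn + cm$fn
    if (cm$tp + cm$fn > 0) expect_equal(rep$sensitivity, cm$tp / (cm$tp + cm$fn))
    if (cm$tn + cm$fp > 0) expect_equal(rep$specificity, cm$tn / (cm$tn + cm$fp))
    expect_equal(rep$accuracy, (cm$tp + cm$tn) / n)
    expect_equal(rep$misclassification, 1 - rep$accuracy)
    if (cm$tp + cm$fp > 0) expect_equal(rep$precision, cm$tp / (cm$tp + cm$fp))
  }
})

test_that("degenerate denominators yield flagged NA, and bad counts error", {
  rep <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(rep$sensitivity))
  expect_true(is.na(rep$precision))
  expect_true(rep$undefined[["sensitivity"]])
  expect_error(confusion_metrics(-1, 0, 1, 0), "non-negative")
  expect_identical(confusion_metrics(3, 0, 3, 3)$sensitivity, 0.5)
  full <- confusion_metrics(5, 0, 6, 0)
  expect_identical(full$accuracy, 1)
  expect_identical(full$misclassification, 0)
})

test_that("a perfectly separable toy is classified without error at any subset size", {
  set.seed(25)
  m <- cbind(sig1 = rep(c(4, -4), each = 12) + rnorm(24, sd = 0.2),
             sig2 = rep(c(-4, 4), each = 12) + rnorm(24, sd = 0.2),
             n1 = rnorm(24), n2 = rnorm(24))
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 12), ids = colnames(m))
  out <- rf_predict_nested(ft, colnames(m), subset_sizes = c(4, 2),
                           replications = 3, n_trees = 100, seed = 2,
                           rank_loocv = FALSE)
  for (rep in out$reports) expect_equal(rep$accuracy, 1)
  expect_setequal(out$ranking[1:2], c("sig1", "sig2"))
})

test_that("nested evaluation is reproducible and skips oversized subsets", {
  set.seed(26)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("f", 1:6)))
  m[, 1] <- m[, 1] + rep(c(1.5, -1.5), each = 10)
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 10), ids = colnames(m))
  expect_warning(out <- rf_predict_nested(ft, colnames(m), subset_sizes = c(10, 3),
                                          replications = 1, n_trees = 100,
                                          seed = 5, rank_loocv = FALSE),
                 "skipped")
  expect_named(out$reports, "3")
  out2 <- suppressWarnings(rf_predict_nested(ft, colnames(m), subset_sizes = c(10, 3),
                                             replications = 1, n_trees = 100,
                                             seed = 5, rank_loocv = FALSE))
  expect_identical(out$reports[["3"]]$confusion, out2$reports[["3"]]$confusion)
})

test_that("backwards elimination concentrates on planted features", {
  planted_hits <- noise_hits <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    m <- cbind(matrix(rep(c(0.75, -0.75), each = n / 2), n, 5) +
                 matrix(rnorm(n * 5), n, 5),
               matrix(rnorm(n * 43), n, 43))
    colnames(m) <- c(paste0("sig", 1:5), paste0("n", sprintf("%02d", 1:43)))
    ft <- make_ft(m, labels = rep(c("1", "-1"), each = n / 2), ids = colnames(m))
    vs <- varsel_rf(ft, colnames(m), replications = 5, n_trees = 200, seed = s)
    expect_gte(sum(grepl("^sig", vs$stable_features)), 1)
    planted_hits <- planted_hits + sum(grepl("^sig", vs$stable_features))
    noise_hits <- noise_hits + sum(!grepl("^sig", vs$stable_features))
  }
  # 5 planted among 48: the stable intersection is dominated by them even
  # though noise outnumbers signal almost 9:1
  expect_gte(planted_hits, 3 * max(noise_hits, 1))
})

test_that("the elimination path shrinks by the drop fraction and tracks OOB", {
  set.seed(27)
  m <- cbind(sig = rep(c(2, -2), each = 10) + rnorm(20, sd = 0.4),
             n1 = rnorm(20), n2 = rnorm(20), n3 = rnorm(20))
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 10), ids = colnames(m))
  vs <- varsel_rf(ft, colnames(m), drop_frac = 0.25, replications = 1,
                  n_trees = 200, seed = 9)
  expect_identical(vs$paths[[1]]$size, c(4, 3, 2))
  expect_true("sig" %in% vs$per_replicate[[1]])
})

test_that("the logistic pipeline prunes duplicates and enforces max |r|", {
  set.seed(28)
  x <- rep(c(1.2, -1.2), each = 20) + rnorm(40, sd = 0.8)
  m <- cbind(a = x, b = x, c = rnorm(40), d = rnorm(40), e = rnorm(40))
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 20), ids = colnames(m))
  tr <- logistic_pipeline(ft, colnames(m), entry_p = 0.9)
  # exactly one of the duplicated pair survives stage 2
  expect_identical(sum(c("a", "b") %in% tr$shortlist), 1L)
  cm <- abs(cor(ft$intensities[, tr$shortlist])); diag(cm) <- 0
  expect_lte(max(cm), 0.5)
})

test_that("an informative feature survives to the final logistic model", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    m <- cbind(sig = rep(c(1.6, -1.6), each = 15) + rnorm(30, sd = 0.9),
               matrix(rnorm(30 * 10), 30, 10))
    colnames(m) <- c("sig", paste0("n", 1:10))
    ft <- make_ft(m, labels = rep(c("1", "-1"), each = 15), ids = colnames(m))
    tr <- logistic_pipeline(ft, colnames(m))
    "sig" %in% tr$final_terms
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("complete separation is flagged and still yields a finite p-value", {
  m <- cbind(sep = c(rep(5, 8), rep(-5, 8)) + rnorm(16, sd = 0.01),
             n1 = rnorm(16), n2 = rnorm(16))
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 8), ids = colnames(m))
  tr <- logistic_pipeline(ft, colnames(m))
  row <- tr$stage1[tr$stage1$feature == "sep", ]
  expect_true(row$separated)
  expect_true(is.finite(row$p))
  expect_true("sep" %in% tr$entry_survivors)
  expect_true("sep" %in% tr$shortlist)
})

test_that("held-out logistic probabilities match per-fold refits", {
  set.seed(29)
  x <- rnorm(12)
  y <- rep(c("1", "-1"), 6)
  m <- cbind(f = x + ifelse(y == "1", 0.8, -0.8))
  ft <- make_ft(m, labels = y, ids = "f")
  probs <- loocv_probabilities(ft, "f", model = "logistic")
  for (i in c(1, 5, 12)) {
    df <- data.frame(y = as.integer(y[-i] == "1"), f = m[-i, 1])
    fit <- glm(y ~ f, data = df, family = binomial())
    manual <- predict(fit, newdata = data.frame(f = m[i, 1]), type = "response")
    expect_equal(unname(probs[i]), unname(manual), tolerance = 1e-8)
  }
})

test_that("held-out probabilities separate a clean two-feature toy", {
  set.seed(30)
  m <- cbind(f1 = rep(c(2, -2), each = 10) + rnorm(20, sd = 0.3),
             f2 = rep(c(-2, 2), each = 10) + rnorm(20, sd = 0.3))
  y <- rep(c("1", "-1"), each = 10)
  ft <- make_ft(m, labels = y, ids = colnames(m))
  for (model in c("logistic", "rf", "svm")) {
    probs <- loocv_probabilities(ft, colnames(m), model = model)
    expect_true(all((probs > 0.5) == (y == "1")), info = model)
  }
})
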