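test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(6)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("f", 1:6)))
  labels <- rep(c("1", "-1"), 10)
  ft <- make_ft(m, labels = labels, ids = colnames(m))
  rk <- anova_rank(ft)
  for (f in colnames(m)) {
    tt <- t.test(m[labels == "1", f], m[labels == "-1", f], var.equal = TRUE)
    expect_equal(unname(rk$extra$f_statistic[f]), unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(unname(rk$scores[f]), tt$p.value, tolerance = 1e-10)
  }
  # p-values ascend along the ranking
  expect_true(!is.unsorted(rk$scores))
})

test_that("attached BH adjustment matches the step-up definition", {
  set.seed(8)
  m <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(NULL, paste0("f", 1:12)))
  m[, 1] <- m[, 1] + rep(c(1.5, 0), each = 15)
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 15), ids = colnames(m))
  rk <- anova_rank(ft)
  expect_equal(unname(rk$extra$p_adjusted),
               unname(bh_brute(rk$scores)), tolerance = 1e-12)
})

test_that("a null feature keeps a large ANOVA p-value across repetitions", {
  meds <- vapply(1:50, function(s) {
    set.seed(s)
    m <- matrix(rnorm(111), 111, 1, dimnames = list(NULL, "f"))
    ft <- make_ft(m, labels = c(rep("1", 55), rep("-1", 56)), ids = "f")
    anova_rank(ft)$scores[["f"]]
  }, numeric(1))
  expect_gt(median(meds), 0.25)
})

test_that("a zero within-group-variance feature gets p = 0, not dropped", {
  m <- cbind(sep = rep(c(1, 2), each = 5), noise = rnorm(10))
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 5), ids = colnames(m))
  rk <- anova_rank(ft)
  expect_identical(unname(rk$scores["sep"]), 0)
  expect_length(rk$ordered_features, 2)
})

test_that("random-forest importance puts a separating feature first", {
  firsts <- vapply(1:10, function(s) {
    set.seed(s)
    m <- cbind(matrix(rnorm(30 * 20), 30, 20),
               sig = rep(c(3, -3), each = 15) + rnorm(30, sd = 0.3))
    colnames(m) <- c(paste0("n", 1:20), "sig")
    ft <- make_ft(m, labels = rep(c("1", "-1"), each = 15), ids = colnames(m))
    rk <- rf_rank(ft, "MdAcc", n_trees = 200, replicates = 3, seed = s)
    gini <- rk$extra$orderings$MdGini
    (rk$ordered_features[1] == "sig") + (gini[1] == "sig")
  }, numeric(1))
  expect_gte(sum(firsts), 18)   # both metrics, nearly every repetition
})

test_that("forest importance is centered near zero under permuted labels", {
  set.seed(42)
  means <- vapply(1:5, function(s) {
    m <- matrix(rnorm(40 * 15), 40, 15, dimnames = list(NULL, paste0("f", 1:15)))
    ft <- make_ft(m, labels = sample(rep(c("1", "-1"), 20)), ids = colnames(m))
    rk <- rf_rank(ft, "MdAcc", n_trees = 300, replicates = 1, seed = s)
    mean(rk$extra$importance[, "MeanDecreaseAccuracy"])
  }, numeric(1))
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(5) + 0.01)
})

test_that("forest rankings are reproducible for a fixed seed", {
  set.seed(77)
  m <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("f", 1:10)))
  ft <- make_ft(m, labels = rep(c("1", "-1"), 15), ids = colnames(m))
  a <- rf_rank(ft, "MdGini", n_trees = 100, replicates = 2, seed = 5)
  b <- rf_rank(ft, "MdGini", n_trees = 100, replicates = 2, seed = 5)
  expect_identical(a$ordered_features, b$ordered_features)
  expect_identical(a$extra$oob_errors, b$extra$oob_errors)
})

test_that("the SVM weight ranking finds the informative feature on a toy", {
  set.seed(10)
  m <- cbind(sig = rep(c(1.5, -1.5), each = 10) + rnorm(20, sd = 0.4),
             noise = rnorm(20))
  ft <- uv_scale(make_ft(m, labels = rep(c("1", "-1"), each = 10),
                         ids = colnames(m)))
  rk <- svm_rfe_rank(ft, "W")
  expect_identical(rk$ordered_features[1], "sig")
  expect_gt(rk$scores[["sig"]], rk$scores[["noise"]])
})

test_that("an unscaled table triggers a warning, then proceeds", {
  set.seed(11)
  m <- matrix(rnorm(20 * 3, sd = 5), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  ft <- make_ft(m, labels = rep(c("1", "-1"), 10), ids = colnames(m))
  expect_warning(rk <- svm_rfe_rank(ft, "W"), "scaled")
  expect_length(rk$ordered_features, 3)
})

test_that("kappa is 1 for perfect agreement and ~0 for majority voting", {
  truth <- c(rep("1", 55), rep("-1", 56))
  expect_identical(metastab:::cohen_kappa(truth, truth), 1)
  expect_lt(abs(metastab:::cohen_kappa(rep("-1", 111), truth)), 1e-12)
})

test_that("drop-one SVM-RFE reproduces a direct backward-elimination loop", {
  set.seed(12)
  m <- cbind(a = rep(c(2, -2), each = 10) + rnorm(20, sd = 0.3),
             b = rep(c(1, -1), each = 10) + rnorm(20, sd = 0.6),
             c = rnorm(20), d = rnorm(20))
  ft <- uv_scale(make_ft(m, labels = rep(c("1", "-1"), each = 10),
                         ids = colnames(m)))
  x <- ft$intensities
  y <- factor(ft$labels, levels = c("-1", "1"))
  # independent elimination loop calling the SVM directly
  active <- colnames(x); elim <- character(0)
  while (length(active) > 1) {
    fit <- e1071::svm(x[, active, drop = FALSE], y, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- abs(drop(t(fit$coefs) %*% fit$SV))[active]
    worst <- active[order(w, active)][1]
    elim <- c(elim, worst)
    active <- setdiff(active, worst)
  }
  oracle_order <- c(active, rev(elim))
  rk <- svm_rfe_rank(ft, "Acc", elimination_fraction = 1 / ncol(m))
  # survivors at the optimal size keep their |w| order; the eliminated tail
  # must match the oracle exactly
  expect_identical(rk$ordered_features[3:4], oracle_order[3:4])
  expect_setequal(rk$ordered_features[1:2], oracle_order[1:2])
  expect_identical(rk$ordered_features[1], "a")
})

test_that("the RFE schedule halves (rounded up) and the path records metrics", {
  set.seed(14)
  m <- matrix(rnorm(20 * 100), 20, 100, dimnames = list(NULL, sprintf("f%03d", 1:100)))
  m[, 1] <- m[, 1] + rep(c(2, -2), each = 10)
  ft <- uv_scale(make_ft(m, labels = rep(c("1", "-1"), each = 10),
                         ids = colnames(m)))
  rk <- svm_rfe_rank(ft, "Acc", elimination_fraction = 0.5)
  expect_identical(rk$extra$path$size, c(100, 50, 25, 13, 7, 4, 2, 1))
  expect_true(all(rk$extra$path$acc >= 0 & rk$extra$path$acc <= 1))
  expect_true(all(rk$extra$path$kappa <= 1))
})

test_that("RF-RFE keeps a planted feature and is seed-reproducible", {
  set.seed(15)
  m <- cbind(sig = rep(c(2, -2), each = 12) + rnorm(24, sd = 0.5),
             matrix(rnorm(24 * 15), 24, 15))
  colnames(m) <- c("sig", paste0("n", 1:15))
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 12), ids = colnames(m))
  a <- rf_rfe_rank(ft, "Acc", n_trees = 200, replicates = 2, seed = 4)
  b <- rf_rfe_rank(ft, "Acc", n_trees = 200, replicates = 2, seed = 4)
  expect_identical(a$ordered_features, b$ordered_features)
  expect_lte(match("sig", a$ordered_features), 3)
  expect_identical(sort(names(a$extra$rankings)), c("Acc", "Kappa"))
})

test_that("take_top honors its contract", {
  set.seed(16)
  m <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  rk <- anova_rank(make_ft(m, labels = rep(c("1", "-1"), 10), ids = colnames(m)))
  expect_identical(take_top(rk, 5), rk$ordered_features)
  expect_identical(take_top(rk, 1), rk$ordered_features[1])
  expect_error(take_top(rk, 0), "positive")
  expect_error(take_top(rk, 6), "exceeds")
})

test_that("the ANOVA top set under the null has binomially plausible size", {
  set.seed(17)
  m <- matrix(rnorm(40 * 1000), 40, 1000, dimnames = list(NULL, sprintf("f%04d", 1:1000)))
  ft <- make_ft(m, labels = rep(c("1", "-1"), 20), ids = colnames(m))
  n_top <- anova_rank(ft, p_cut = 0.1)$extra$n_top
  expect_gt(n_top, 100 - 4 * sqrt(90))
  expect_lt(n_top, 100 + 4 * sqrt(90))
})

test_that("every ranking is a permutation of the input features", {
  set.seed(18)
  m <- matrix(rnorm(24 * 12), 24, 12, dimnames = list(NULL, paste0("f", 1:12)))
  m[, 1] <- m[, 1] + rep(c(1, -1), each = 12)
  ft <- make_ft(m, labels = rep(c("1", "-1"), each = 12), ids = colnames(m))
  sc <- uv_scale(ft)
  rks <- list(anova_rank(ft),
              rf_rank(ft, "MdAcc", n_trees = 100, replicates = 1, seed = 1),
              svm_rfe_rank(sc, "W"),
              svm_rfe_rank(sc, "Kappa", elimination_fraction = 0.5),
              rf_rfe_rank(ft, "Kappa", n_trees = 100, replicates = 1, seed = 1))
  for (rk in rks) expect_setequal(rk$ordered_features, colnames(m))
})

test_that("ANOVA ranking is invariant under per-feature affine rescaling", {
  set.seed(19)
  m <- matrix(rnorm(30 * 8) + 5, 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  labels <- rep(c("1", "-1"), 15)
  ft <- make_ft(m, labels = labels, ids = colnames(m))
  m2 <- sweep(sweep(m, 2, runif(8, 0.5, 4), "*"), 2, runif(8, -3, 3), "+")
  ft2 <- make_ft(m2, labels = labels, ids = colnames(m))
  expect_identical(anova_rank(ft)$ordered_features,
                   anova_rank(ft2)$ordered_features)
})
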