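# Prediction routes on the consensus subset, plus evaluation machinery.

#' Performance metrics from a confusion matrix
#'
#' Computes the six evaluation metrics from true/false positive/negative
#' counts: sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
#' (tp+tn)/n, precision tp/(tp+fp), misclassification 1 - accuracy, and an
#' optional out-of-bag error. A zero denominator yields `NA` (flagged in
#' `undefined`), never a silent 0.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @param oob_error optional OOB error of the underlying forest.
#' @param n_features,model_id optional bookkeeping fields.
#' @return A list of class `eval_report`.
#' @examples
#' confusion_metrics(tp = 42, fp = 9, tn = 47, fn = 13)$misclassification
#' @export
confusion_metrics <- function(tp, fp, tn, fn, oob_error = NA_real_,
                              n_features = NA_integer_, model_id = "") {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("confusion counts must be integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / n
  prec <- safe_div(tp, tp + fp)
  undefined <- c(sensitivity = tp + fn == 0, specificity = tn + fp == 0,
                 precision = tp + fp == 0)
  structure(list(confusion = as.list(counts), n = n,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 precision = prec, misclassification = 1 - acc,
                 oob_error = oob_error, n_features = n_features,
                 model_id = model_id, undefined = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report%s: acc %.3f, sens %s, spec %s, prec %s, ",
                     "misclassification %.1f%%%s\n"),
              if (nzchar(x$model_id)) paste0(" [", x$model_id, "]") else "",
              x$accuracy, format(x$sensitivity, digits = 3),
              format(x$specificity, digits = 3), format(x$precision, digits = 3),
              100 * x$misclassification,
              if (is.na(x$oob_error)) "" else sprintf(", OOB %.3f", x$oob_error)))
  invisible(x)
}

confusion_from_predictions <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  list(tp = sum(pred == CASE_LABEL & truth == CASE_LABEL),
       fp = sum(pred == CASE_LABEL & truth == CONTROL_LABEL),
       tn = sum(pred == CONTROL_LABEL & truth == CONTROL_LABEL),
       fn = sum(pred == CONTROL_LABEL & truth == CASE_LABEL))
}

# ridge-penalized logistic fit (IRLS); lambda > 0 keeps coefficients and
# Wald p-values finite under complete separation
ridge_logit <- function(X, y01, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    grad <- crossprod(X, y01 - mu) - pen %*% beta
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  list(coef = drop(beta), se = se, p = 2 * stats::pnorm(-abs(z)))
}

# univariable logistic p-value with separation fallback
univariable_logit_p <- function(x, y01, ridge_lambda = 1e-4) {
  fit <- suppressWarnings(stats::glm(y01 ~ x, family = stats::binomial()))
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated) {
    rf <- ridge_logit(matrix(x, ncol = 1), y01, lambda = ridge_lambda)
    list(p = rf$p[2], coef = rf$coef[2], separated = TRUE)
  } else {
    s <- summary(fit)$coefficients
    list(p = s[2, 4], coef = s[2, 1], separated = FALSE)
  }
}

#' Leave-one-out predicted class probabilities
#'
#' For each sample, the chosen model is refit on the remaining n-1 samples
#' and the held-out sample's probability of the Case class ("1") is
#' recorded. These out-of-fold probabilities feed ROC construction.
#'
#' @param table a [feature_table] with at least 2 samples per class.
#' @param features feature ids entering the model.
#' @param model `"logistic"` (default), `"rf"` or `"svm"`.
#' @param n_trees forest size for `model = "rf"`.
#' @param seed seed for the forest fits (the other models are deterministic).
#' @return Named numeric vector of per-sample Case probabilities.
#' @export
loocv_probabilities <- function(table, features, model = c("logistic", "rf", "svm"),
                                n_trees = 500, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(table, "feature_table"))
  if (any(table(table$labels) < 2)) stop("need at least 2 samples per class", call. = FALSE)
  x <- table$intensities[, features, drop = FALSE]
  y <- label_factor(table$labels)
  y01 <- as.integer(table$labels == CASE_LABEL)
  n <- nrow(x)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; xte <- x[i, , drop = FALSE]
    probs[i] <- switch(model,
      logistic = {
        df <- data.frame(y = y01[-i], xtr)
        fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
        if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
          rf <- ridge_logit(xtr, y01[-i])
          1 / (1 + exp(-(rf$coef[1] + drop(xte %*% rf$coef[-1]))))
        } else {
          stats::predict(fit, newdata = data.frame(xte), type = "response")
        }
      },
      rf = {
        set.seed(fan_seed(seed, i))
        fit <- randomForest::randomForest(xtr, y[-i], ntree = n_trees)
        stats::predict(fit, xte, type = "prob")[, CASE_LABEL]
      },
      svm = {
        fit <- e1071::svm(xtr, y[-i], kernel = "linear", cost = 1,
                          probability = TRUE, scale = FALSE)
        attr(stats::predict(fit, xte, probability = TRUE),
             "probabilities")[, CASE_LABEL]
      })
  }
  stats::setNames(probs, rownames(x))
}

# one stratified train/test split evaluation of a forest
rf_split_eval <- function(x, y, split_frac, n_trees, mtry, seed) {
  set.seed(seed)
  idx_case <- which(y == CASE_LABEL); idx_ctrl <- which(y == CONTROL_LABEL)
  tr <- c(sample(idx_case, round(split_frac * length(idx_case))),
          sample(idx_ctrl, round(split_frac * length(idx_ctrl))))
  te <- setdiff(seq_along(y), tr)
  yf <- label_factor(y)
  rf <- randomForest::randomForest(x[tr, , drop = FALSE], yf[tr],
                                   ntree = n_trees, mtry = mtry)
  pred <- as.character(stats::predict(rf, x[te, , drop = FALSE]))
  cm <- confusion_from_predictions(pred, y[te])
  oob <- rf_oob_stats(rf, yf[tr])$oob
  c(unlist(cm), oob = oob)
}

#' Random-forest prediction on nested top-k consensus subsets
#'
#' Ranks the consensus features by leave-one-out-averaged permutation
#' importance (MdAcc over the LOOCV refits), derives nested subsets of the
#' requested sizes from that single ranking, and evaluates each subset by
#' `replications` stratified train/test splits (75% training by default),
#' reporting the mean confusion counts, the six metrics and the mean OOB
#' error of the evaluation forests.
#'
#' @param table a [feature_table].
#' @param consensus feature ids of the consensus subset.
#' @param subset_sizes nested subset sizes; sizes exceeding the consensus
#'   size are skipped with a warning.
#' @param split_frac training fraction per split (stratified by class).
#' @param replications number of random splits per subset size.
#' @param n_trees forest size.
#' @param seed master seed.
#' @param rank_loocv rank by LOOCV-averaged importance (default); if
#'   `FALSE`, a single full-data forest's importance is used.
#' @return A list with `ranking` (ordered consensus features) and `reports`
#'   (one [confusion_metrics] `eval_report` per subset size, averaged
#'   counts rounded to integers for the confusion, metrics averaged over
#'   splits).
#' @export
rf_predict_nested <- function(table, consensus,
                              subset_sizes = c(48, 40, 30, 20, 10, 5),
                              split_frac = 0.75, replications = 100,
                              n_trees = 2000, seed = 1, rank_loocv = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(consensus, feature_ids(table))
  if (length(missing)) stop("consensus features absent from table: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  x <- table$intensities[, consensus, drop = FALSE]
  y <- table$labels
  yf <- label_factor(y)
  p <- ncol(x)
  mtry <- min(default_mtry(p), p)
  # MdAcc ranking of the consensus features
  if (rank_loocv) {
    imp_sum <- stats::setNames(numeric(p), colnames(x))
    for (i in seq_len(nrow(x))) {
      set.seed(fan_seed(seed, 500000L + i))
      rf <- randomForest::randomForest(x[-i, , drop = FALSE], yf[-i],
                                       ntree = n_trees, mtry = mtry,
                                       importance = TRUE)
      imp_sum <- imp_sum + randomForest::importance(rf, scale = FALSE)[, "MeanDecreaseAccuracy"]
    }
    imp <- imp_sum / nrow(x)
  } else {
    set.seed(fan_seed(seed, 500000L))
    rf <- randomForest::randomForest(x, yf, ntree = n_trees, mtry = mtry,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, scale = FALSE)[, "MeanDecreaseAccuracy"]
  }
  ranking <- colnames(x)[order(-imp, colnames(x))]
  reports <- list()
  for (k in subset_sizes) {
    if (k > p) {
      warning(sprintf("subset size %d exceeds consensus size %d; skipped", k, p),
              call. = FALSE)
      next
    }
    feats <- ranking[seq_len(k)]
    xk <- x[, feats, drop = FALSE]
    mk <- min(default_mtry(k), k)
    res <- vapply(seq_len(replications), function(r) {
      rf_split_eval(xk, y, split_frac, n_trees, mk, fan_seed(seed, 1000L * k + r))
    }, numeric(5))
    means <- rowMeans(res)
    rep_k <- confusion_metrics(tp = round(means["tp"]), fp = round(means["fp"]),
                               tn = round(means["tn"]), fn = round(means["fn"]),
                               oob_error = means[["oob"]], n_features = k,
                               model_id = sprintf("%d-Rf-acc", k))
    # metrics averaged over splits (not recomputed from rounded counts)
    per_split_acc <- (res["tp", ] + res["tn", ]) / colSums(res[c("tp", "fp", "tn", "fn"), , drop = FALSE])
    rep_k$accuracy <- mean(per_split_acc)
    rep_k$misclassification <- 1 - rep_k$accuracy
    rep_k$sensitivity <- mean(res["tp", ] / (res["tp", ] + res["fn", ]))
    rep_k$specificity <- mean(res["tn", ] / (res["tn", ] + res["fp", ]))
    rep_k$precision <- mean(res["tp", ] / (res["tp", ] + res["fp", ]), na.rm = TRUE)
    reports[[as.character(k)]] <- rep_k
  }
  list(ranking = ranking, importance = imp[ranking], reports = reports)
}

#' Backwards variable elimination with random forests
#'
#' Per replicate: fit a forest on the current variables, rank by permutation
#' importance, drop the least important `drop_frac` of variables, refit, and
#' track the OOB error along the path; the variable set at the minimum OOB
#' error (smallest such set on ties) is that replicate's selection. Across
#' replicates the intersection of the selected sets is returned as the
#' stable set (an empty intersection is reported, not an error).
#'
#' @param table a [feature_table].
#' @param consensus candidate feature ids (at least 2).
#' @param drop_frac fraction of variables dropped per elimination round.
#' @param replications number of independent elimination runs.
#' @param n_trees forest size.
#' @param seed master seed.
#' @return A list: `stable_features`, `per_replicate` (list of selected
#'   sets), `paths` (per-replicate data frames of size and OOB error).
#' @export
varsel_rf <- function(table, consensus, drop_frac = 0.2, replications = 100,
                      n_trees = 2000, seed = 1) {
  stopifnot(inherits(table, "feature_table"), length(consensus) >= 2)
  x <- table$intensities[, consensus, drop = FALSE]
  yf <- label_factor(table$labels)
  one_run <- function(rseed) {
    active <- colnames(x)
    path <- list()
    counter <- 0L
    best <- NULL
    repeat {
      counter <- counter + 1L
      set.seed(fan_seed(rseed, counter))
      rf <- randomForest::randomForest(x[, active, drop = FALSE], yf,
                                       ntree = n_trees,
                                       mtry = min(default_mtry(length(active)), length(active)),
                                       importance = TRUE)
      oob <- rf_oob_stats(rf, yf)$oob
      path[[counter]] <- c(size = length(active), oob = oob)
      # minimum-OOB (0-s.e.) rule; ties resolved toward the smaller set
      if (is.null(best) || oob <= best$oob) best <- list(oob = oob, set = active)
      if (length(active) <= 2) break
      imp <- randomForest::importance(rf, scale = FALSE)[, "MeanDecreaseAccuracy"]
      n_drop <- max(1L, floor(length(active) * drop_frac))
      n_drop <- min(n_drop, length(active) - 2L)
      active <- setdiff(active, active[order(imp, active)][seq_len(n_drop)])
    }
    list(set = best$set, path = as.data.frame(do.call(rbind, path)))
  }
  runs <- lapply(seq_len(replications), function(r) one_run(fan_seed(seed, r)))
  sets <- lapply(runs, `[[`, "set")
  stable <- Reduce(intersect, sets)
  if (length(stable) == 0) message("empty intersection across replicates")
  list(stable_features = sort(stable), per_replicate = sets,
       paths = lapply(runs, `[[`, "path"))
}

#' Logistic-regression selection pipeline
#'
#' Four stages on the consensus subset: (1) univariable logistic fits, keep
#' features with coefficient p < `entry_p` (complete separation is handled
#' by a small ridge penalty so the recorded p-value stays finite; the
#' feature is flagged and retained, since separation means perfect
#' univariable discrimination);
#' (2) collinearity pruning — while any pairwise |r| exceeds `max_r`, the
#' member of the worst pair with the larger mean |r| to the other survivors
#' is removed; (3) if more than `shortlist` remain, the feature with the
#' smallest |point-biserial correlation with the outcome| (ties: larger
#' univariable p) is dropped until `shortlist` remain; (4) the multiple
#' logistic model on the shortlist is reduced by bidirectional stepwise AIC.
#'
#' @param table a [feature_table].
#' @param consensus candidate feature ids.
#' @param entry_p univariable entry threshold (default 0.25).
#' @param max_r maximum tolerated pairwise |r| (default 0.5).
#' @param shortlist features entering the multiple model (default 10).
#' @param ridge_lambda ridge penalty used only for separated univariable fits.
#' @return A list of class `logit_trace`: `stage1` (data frame of features,
#'   p-values, separation flags, survivors), `stage2_log` and `stage3_log`
#'   (elimination records with criterion values), `shortlist`, `final_model`
#'   (the reduced `glm`), `final_terms`, and `aic` of the final model.
#' @export
logistic_pipeline <- function(table, consensus, entry_p = 0.25, max_r = 0.5,
                              shortlist = 10, ridge_lambda = 1e-4) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(consensus, feature_ids(table))
  if (length(missing)) stop("consensus features absent from table: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  consensus <- sort(consensus)   # documented tie order: lexicographic
  x <- table$intensities[, consensus, drop = FALSE]
  y01 <- as.integer(table$labels == CASE_LABEL)

  # stage 1: univariable fits
  uni <- lapply(consensus, function(f) univariable_logit_p(x[, f], y01, ridge_lambda))
  stage1 <- data.frame(feature = consensus,
                       p = vapply(uni, `[[`, 0, "p"),
                       coef = vapply(uni, `[[`, 0, "coef"),
                       separated = vapply(uni, `[[`, TRUE, "separated"),
                       stringsAsFactors = FALSE)
  # a separated feature discriminates perfectly; its penalized Wald p is
  # conservative (the ridge flattens the information), so it is kept
  survivors <- stage1$feature[stage1$p < entry_p | stage1$separated]
  if (length(survivors) == 0) stop("no feature passes the univariable entry threshold",
                                   call. = FALSE)
  entry_survivors <- survivors
  uni_p <- stats::setNames(stage1$p, stage1$feature)

  # stage 2: correlation pruning to max |r| <= max_r
  stage2_log <- list()
  while (length(survivors) > 1) {
    cm <- abs(stats::cor(x[, survivors, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= max_r) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- survivors[worst]
    means <- vapply(pair, function(f) mean(cm[f, setdiff(survivors, f)]), numeric(1))
    drop_id <- if (means[1] > means[2]) pair[1]
      else if (means[2] > means[1]) pair[2] else sort(pair)[1]
    stage2_log[[length(stage2_log) + 1]] <-
      data.frame(feature = drop_id, partner = setdiff(pair, drop_id),
                 max_abs_r = max(cm), stringsAsFactors = FALSE)
    survivors <- setdiff(survivors, drop_id)
  }
  stage2_log <- if (length(stage2_log)) do.call(rbind, stage2_log) else
    data.frame(feature = character(), partner = character(), max_abs_r = numeric())

  # stage 3: down to the shortlist by outcome correlation, then p-value
  stage3_log <- list()
  outcome_r <- abs(stats::cor(x[, survivors, drop = FALSE], y01))[, 1]
  while (length(survivors) > shortlist) {
    r_now <- outcome_r[survivors]
    p_now <- uni_p[survivors]
    ord <- order(r_now, -p_now, survivors)
    drop_id <- survivors[ord[1]]
    stage3_log[[length(stage3_log) + 1]] <-
      data.frame(feature = drop_id, outcome_r = r_now[[drop_id]],
                 p = p_now[[drop_id]], stringsAsFactors = FALSE)
    survivors <- setdiff(survivors, drop_id)
  }
  stage3_log <- if (length(stage3_log)) do.call(rbind, stage3_log) else
    data.frame(feature = character(), outcome_r = numeric(), p = numeric())

  # stage 4: multiple model reduced by bidirectional stepwise AIC
  df <- data.frame(y = y01, x[, survivors, drop = FALSE], check.names = FALSE)
  full <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  reduced <- suppressWarnings(stats::step(full, direction = "both", trace = 0))
  final_terms <- setdiff(names(stats::coef(reduced)), "(Intercept)")
  final_terms <- gsub("^`|`$", "", final_terms)

  structure(list(stage1 = stage1, entry_survivors = entry_survivors,
                 stage2_log = stage2_log, stage3_log = stage3_log,
                 shortlist = survivors, final_model = reduced,
                 final_terms = final_terms, aic = stats::AIC(reduced)),
            class = "logit_trace")
}

#' @export
print.logit_trace <- function(x, ...) {
  cat(sprintf(paste0("logit_trace: %d/%d past univariable entry, %d removed by ",
                     "correlation pruning, shortlist %d, final model %d term(s) ",
                     "(AIC %.1f)\n"),
              length(x$entry_survivors), nrow(x$stage1), nrow(x$stage2_log),
              length(x$shortlist), length(x$final_terms), x$aic))
  if (length(x$final_terms)) cat("  terms:", paste(x$final_terms, collapse = ", "), "\n")
  invisible(x)
}
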