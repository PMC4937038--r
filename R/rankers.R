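# The ten feature-ranking routes feeding the stability stage:
#   no filter:          RF-MdAcc, RF-MdGini, SVM-RFE-W, ANOVA-p
#   correlation filter: Cor-RF-MdAcc, Cor-RF-MdGini, Cor-RF-RFE-Acc, Cor-RF-RFE-Kap
#   MI filter:          MI-SVM-RFE-Acc, MI-SVM-RFE-Kap

TECHNIQUE_IDS <- c("RF-MdAcc", "RF-MdGini", "Cor-RF-MdAcc", "Cor-RF-MdGini",
                   "Cor-RF-RFE-Acc", "Cor-RF-RFE-Kap", "MI-SVM-RFE-Acc",
                   "MI-SVM-RFE-Kap", "SVM-RFE-W", "ANOVA-p")

ranking_result <- function(method_id, ordered_features, scores, score_direction,
                           extra = list()) {
  stopifnot(length(ordered_features) == length(scores),
            !anyDuplicated(ordered_features),
            score_direction %in% c("ascending", "descending"))
  structure(list(method_id = method_id,
                 ordered_features = as.character(ordered_features),
                 scores = stats::setNames(as.numeric(scores), ordered_features),
                 score_direction = score_direction,
                 extra = extra),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("ranking_result [%s]: %d features, scores %s\n", x$method_id,
              length(x$ordered_features), x$score_direction))
  utils::head(data.frame(rank = seq_along(x$ordered_features),
                         feature = x$ordered_features,
                         score = unname(x$scores)), 5) |> print()
  invisible(x)
}

#' Keep a restricted set of features
#'
#' @param table a [feature_table].
#' @param ids feature ids to keep (order preserved as given).
#' @return A [feature_table] on the selected columns.
#' @export
subset_features <- function(table, ids) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(ids, feature_ids(table))
  if (length(missing)) stop("unknown feature id(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  feature_table(table$intensities[, ids, drop = FALSE], labels = table$labels)
}

# vectorized one-way two-group ANOVA p-values (F test); a feature with zero
# within-group variance but distinct class means gets F = Inf hence p = 0
anova_p_values <- function(m, labels, statistic = FALSE) {
  y <- label_factor(labels)
  n <- nrow(m)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- n - n1
  m1 <- colMeans(m[g1, , drop = FALSE])
  m2 <- colMeans(m[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((m - matrix(ifelse(g1, 1, 0)) %*% t(m1) -
                    matrix(ifelse(g1, 0, 1)) %*% t(m2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- NaN
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  if (statistic) list(f = f, p = p) else p
}

#' Rank features by one-way ANOVA p-value
#'
#' Per-feature two-group one-way ANOVA F-test, features ordered by ascending
#' p-value (for two groups, F is exactly the squared pooled-variance t
#' statistic). Benjamini-Hochberg adjusted p-values are attached, and the
#' features with p below `p_cut` form this route's retained top set.
#'
#' @param table a [feature_table] with both classes present.
#' @param p_cut retention threshold on the raw p-value (default 0.1).
#' @return A `ranking_result` (`score_direction = "ascending"`, scores are
#'   p-values) with `extra$p_adjusted`, `extra$f_statistic` and
#'   `extra$n_top`.
#' @export
anova_rank <- function(table, p_cut = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2) stop("both classes must be present", call. = FALSE)
  res <- anova_p_values(table$intensities, table$labels, statistic = TRUE)
  ids <- feature_ids(table)
  ord <- order(res$p, ids)
  padj <- stats::p.adjust(res$p, method = "BH")
  ranking_result("ANOVA-p", ids[ord], res$p[ord], "ascending",
                 extra = list(p_adjusted = stats::setNames(padj[ord], ids[ord]),
                              f_statistic = stats::setNames(res$f[ord], ids[ord]),
                              n_top = sum(res$p < p_cut)))
}

default_mtry <- function(p, warn = FALSE) {
  m <- 2L * as.integer(ceiling(sqrt(p)))
  if (m > p) {
    if (warn) warning(sprintf("mtry %d exceeds feature count %d; clipped", m, p),
                      call. = FALSE)
    m <- p
  }
  m
}

rf_oob_stats <- function(rf, y) {
  pred <- rf$predicted
  ok <- !is.na(pred)
  if (!all(ok)) message(sum(!ok), " sample(s) never out-of-bag, excluded from OOB error")
  list(oob = mean(pred[ok] != y[ok]),
       acc = mean(pred[ok] == y[ok]),
       kappa = cohen_kappa(pred[ok], y[ok]),
       n_excluded = sum(!ok))
}

#' Rank features by random-forest importance
#'
#' Trains `replicates` independent forests (`n_trees` trees each,
#' `mtry = 2 * ceiling(sqrt(p))` capped at p) and keeps the replicate with
#' the smallest out-of-bag error; its permutation importance (mean decrease
#' in OOB accuracy, `MdAcc`) or total Gini-impurity decrease (`MdGini`)
#' orders the features. Deterministic for a fixed seed: replicate r draws
#' its stream from the master seed by a counter scheme.
#'
#' @param table a [feature_table] with both classes present.
#' @param metric `"MdAcc"` or `"MdGini"`.
#' @param n_trees trees per forest (default 2000).
#' @param mtry variables tried per split; `NULL` for the 2*ceiling(sqrt(p)) rule.
#' @param replicates independent forests to train (default 50).
#' @param seed master seed.
#' @return A `ranking_result` with the selected replicate's importance as
#'   scores; `extra$orderings` holds both metrics' orderings from the same
#'   best-OOB forest, `extra$oob_errors` the per-replicate OOB errors.
#' @export
rf_rank <- function(table, metric = c("MdAcc", "MdGini"), n_trees = 2000,
                    mtry = NULL, replicates = 50, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "feature_table"), n_trees >= 1)
  if (length(unique(table$labels)) < 2) stop("both classes must be present", call. = FALSE)
  x <- table$intensities
  y <- label_factor(table$labels)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- default_mtry(p, warn = TRUE) else if (mtry > p) {
    warning("mtry exceeds feature count; clipped", call. = FALSE)
    mtry <- p
  }
  best <- NULL
  oob_errors <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(fan_seed(seed, r))
    rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                     importance = TRUE)
    st <- rf_oob_stats(rf, y)
    oob_errors[r] <- st$oob
    if (is.null(best) || st$oob < best$oob) {
      best <- list(oob = st$oob, imp = randomForest::importance(rf, scale = FALSE), replicate = r)
    }
  }
  ids <- colnames(x)
  acc_scores <- best$imp[, "MeanDecreaseAccuracy"]
  gini_scores <- best$imp[, "MeanDecreaseGini"]
  orderings <- list(MdAcc = ids[order(-acc_scores, ids)],
                    MdGini = ids[order(-gini_scores, ids)])
  scores <- if (metric == "MdAcc") acc_scores else gini_scores
  ord <- orderings[[metric]]
  ranking_result(paste0("RF-", metric), ord, scores[ord], "descending",
                 extra = list(orderings = orderings,
                              importance = best$imp,
                              oob_errors = oob_errors,
                              best_replicate = best$replicate))
}

# linear-kernel SVM hyperplane weights, one value per feature
svm_weights <- function(x, y, cost = 1) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  drop(t(fit$coefs) %*% fit$SV)[colnames(x)]
}

# pooled LOOCV accuracy and kappa of a linear SVM on the given columns
loocv_svm_metrics <- function(x, y, cost = 1) {
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- e1071::svm(x[-i, , drop = FALSE], y[-i], kernel = "linear",
                      cost = cost, scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }
  c(acc = mean(pred == as.character(y)), kappa = cohen_kappa(pred, y))
}

#' Rank features with a linear SVM, optionally by recursive elimination
#'
#' `metric = "W"` ranks by the absolute hyperplane weights of a single
#' linear-SVM fit (cost 1) on the full table. `metric = "Acc"`/`"Kappa"`
#' runs recursive feature elimination: each round refits the SVM on the
#' surviving features, scores the subset by pooled leave-one-out accuracy
#' or Cohen's kappa, and drops the `elimination_fraction` of features with
#' the smallest |w| (at least one). The final order is the elimination
#' order, survivors first; within the metric-optimal subset, features are
#' ordered by |w| at that size. Expects a unit-variance-scaled table (see
#' [uv_scale]) and warns, then proceeds, if columns are not unit-sd.
#'
#' @param table a [feature_table], UV-scaled.
#' @param metric `"W"`, `"Acc"` or `"Kappa"`.
#' @param elimination_fraction fraction of surviving features dropped per
#'   round (default 0.5, i.e. halving); use `1/p` to drop one per round.
#' @param cost SVM cost parameter (default 1, no tuning).
#' @return A `ranking_result`. For the RFE metrics, `extra$path` records
#'   per-round subset size, LOOCV accuracy and kappa; `extra$best_size` the
#'   metric-optimal size; `extra$rankings` the orderings under both RFE
#'   metrics (they share the elimination path).
#' @export
svm_rfe_rank <- function(table, metric = c("W", "Acc", "Kappa"),
                         elimination_fraction = 0.5, cost = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2) stop("both classes must be present", call. = FALSE)
  if (!is_uv_scaled(table)) {
    warning("table does not look unit-variance scaled; proceeding anyway", call. = FALSE)
  }
  x <- table$intensities
  y <- label_factor(table$labels)
  ids <- colnames(x)
  if (metric == "W") {
    w <- abs(svm_weights(x, y, cost))
    ord <- ids[order(-w, ids)]
    return(ranking_result("SVM-RFE-W", ord, w[ord], "descending"))
  }
  active <- ids
  eliminated <- character(0)          # chronological, worst first
  path <- list()
  repeat {
    w <- abs(svm_weights(x[, active, drop = FALSE], y, cost))
    mets <- loocv_svm_metrics(x[, active, drop = FALSE], y, cost)
    path[[length(path) + 1]] <- list(size = length(active), acc = mets[["acc"]],
                                     kappa = mets[["kappa"]], members = active,
                                     w = w)
    if (length(active) == 1) break
    n_drop <- max(1L, floor(length(active) * elimination_fraction))
    n_drop <- min(n_drop, length(active) - 1L)
    drop_ids <- active[order(w[active], active)][seq_len(n_drop)]
    eliminated <- c(eliminated, drop_ids)
    active <- setdiff(active, drop_ids)
  }
  build <- function(metric_name) {
    key <- if (metric_name == "Acc") "acc" else "kappa"
    vals <- vapply(path, function(r) r[[key]], numeric(1))
    sizes <- vapply(path, function(r) r$size, numeric(1))
    best <- which(vals == max(vals))
    best <- best[which.min(sizes[best])]       # ties: most parsimonious subset
    members <- path[[best]]$members
    wb <- path[[best]]$w
    inside <- members[order(-wb[members], members)]
    outside <- rev(eliminated[seq_len(length(ids) - length(members))])
    ordered <- c(inside, outside)
    ranking_result(paste0("SVM-RFE-", metric_name), ordered,
                   rev(seq_along(ordered)), "descending",
                   extra = list(best_size = length(members),
                                path = data.frame(size = sizes, acc = vapply(path, `[[`, 0, "acc"),
                                                  kappa = vapply(path, `[[`, 0, "kappa"))))
  }
  out <- build(metric)
  out$extra$rankings <- list(Acc = build("Acc")$ordered_features,
                             Kappa = build("Kappa")$ordered_features)
  out
}

#' Rank features by recursive elimination with random forests
#'
#' As [svm_rfe_rank] but the inner model is a forest and per-round
#' importances are the permutation (MdAcc) importance. Each of `replicates`
#' runs follows its own elimination path; subset quality per round is the
#' forest's accuracy/kappa on out-of-bag predictions (`cv = "oob"`, the
#' forest's built-in leave-out estimate) or pooled leave-one-out
#' cross-validation (`cv = "loocv"`). The replicate whose best round
#' maximizes the chosen metric provides the returned ordering.
#'
#' @param table a [feature_table].
#' @param metric `"Acc"` or `"Kappa"`.
#' @param n_trees,replicates,seed forest size, elimination replicates,
#'   master seed.
#' @param elimination_fraction fraction dropped per round (default halving).
#' @param cv `"oob"` (default) or `"loocv"`.
#' @return A `ranking_result`; `extra$rankings` carries the orderings under
#'   both metrics, `extra$best_size` the optimal subset size.
#' @export
rf_rfe_rank <- function(table, metric = c("Acc", "Kappa"), n_trees = 2000,
                        replicates = 50, elimination_fraction = 0.5,
                        cv = c("oob", "loocv"), seed = 1) {
  metric <- match.arg(metric)
  cv <- match.arg(cv)
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2) stop("both classes must be present", call. = FALSE)
  x <- table$intensities
  y <- label_factor(table$labels)
  ids <- colnames(x)
  run_path <- function(rseed) {
    active <- ids
    eliminated <- character(0)
    rounds <- list()
    counter <- 0L
    repeat {
      counter <- counter + 1L
      set.seed(fan_seed(rseed, counter))
      rf <- randomForest::randomForest(x[, active, drop = FALSE], y,
                                       ntree = n_trees,
                                       mtry = min(default_mtry(length(active)), length(active)),
                                       importance = TRUE)
      imp <- randomForest::importance(rf, scale = FALSE)[, "MeanDecreaseAccuracy"]
      names(imp) <- active
      if (cv == "oob") {
        st <- rf_oob_stats(rf, y)
        acc <- st$acc; kap <- st$kappa
      } else {
        pred <- character(length(y))
        for (i in seq_along(y)) {
          set.seed(fan_seed(rseed, counter * 1000L + i))
          f2 <- randomForest::randomForest(x[-i, active, drop = FALSE], y[-i],
                                           ntree = n_trees,
                                           mtry = min(default_mtry(length(active)), length(active)))
          pred[i] <- as.character(stats::predict(f2, x[i, active, drop = FALSE]))
        }
        acc <- mean(pred == as.character(y)); kap <- cohen_kappa(pred, y)
      }
      rounds[[length(rounds) + 1]] <- list(size = length(active), acc = acc,
                                           kappa = kap, members = active, imp = imp)
      if (length(active) == 1) break
      n_drop <- max(1L, floor(length(active) * elimination_fraction))
      n_drop <- min(n_drop, length(active) - 1L)
      drop_ids <- active[order(imp[active], active)][seq_len(n_drop)]
      eliminated <- c(eliminated, drop_ids)
      active <- setdiff(active, drop_ids)
    }
    list(rounds = rounds, eliminated = eliminated)
  }
  paths <- lapply(seq_len(replicates), function(r) run_path(fan_seed(seed, r)))
  build <- function(metric_name) {
    key <- if (metric_name == "Acc") "acc" else "kappa"
    best_of <- vapply(paths, function(p) max(vapply(p$rounds, `[[`, 0, key)), numeric(1))
    pb <- paths[[which.max(best_of)]]
    vals <- vapply(pb$rounds, `[[`, 0, key)
    sizes <- vapply(pb$rounds, function(r) r$size, numeric(1))
    best <- which(vals == max(vals))
    best <- best[which.min(sizes[best])]
    members <- pb$rounds[[best]]$members
    imp <- pb$rounds[[best]]$imp
    inside <- members[order(-imp[members], members)]
    outside <- rev(pb$eliminated[seq_len(length(ids) - length(members))])
    list(ordered = c(inside, outside), best_size = length(members),
         replicate = which.max(best_of))
  }
  sel <- build(metric)
  both <- list(Acc = build("Acc")$ordered, Kappa = build("Kappa")$ordered)
  ranking_result(paste0("RF-RFE-", metric), sel$ordered,
                 rev(seq_along(sel$ordered)), "descending",
                 extra = list(rankings = both, best_size = sel$best_size,
                              best_replicate = sel$replicate, cv = cv))
}

#' Retain the first n ranked features
#'
#' @param ranking a `ranking_result`.
#' @param n how many features to keep; must be positive and at most the
#'   ranking length.
#' @return Character vector of the n best feature ids.
#' @export
take_top <- function(ranking, n) {
  stopifnot(inherits(ranking, "ranking_result"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (n > length(ranking$ordered_features)) {
    stop(sprintf("n = %d exceeds ranking length %d", n,
                 length(ranking$ordered_features)), call. = FALSE)
  }
  ranking$ordered_features[seq_len(n)]
}

#' Run the full ten-technique selection suite
#'
#' Applies the ten ranking routes to one table: random-forest importance
#' (MdAcc/MdGini) and a single-fit linear-SVM weight ranking on the raw
#' table, ANOVA p-values, forests after the 0.95-correlation filter
#' (importance and RFE variants), and SVM-RFE after the mutual-information
#' filter. SVM routes see the unit-variance-scaled table. Each route's top
#' set is cut at the configured sizes: 178 for the unfiltered machine
#' learning routes, the p < 0.1 count for ANOVA, 200 after a filter (capped
#' at the filtered subset size).
#'
#' @param table a [feature_table].
#' @param config a [default_config()] list controlling thresholds, forest
#'   sizes and replicate counts.
#' @return A list with `rankings` (named `ranking_result`s), `top_sets`
#'   (named character vectors, one per technique) and `filters` (the two
#'   `filter_result`s).
#' @export
run_technique_suite <- function(table, config = default_config()) {
  stopifnot(inherits(table, "feature_table"))
  cfg <- config
  p <- ncol(table$intensities)
  scaled <- uv_scale(table)
  rankings <- list()

  rf_full <- rf_rank(table, "MdAcc", n_trees = cfg$n_trees,
                     replicates = cfg$rf_replicates, seed = fan_seed(cfg$seed, 11))
  rankings[["RF-MdAcc"]] <- rf_full
  rankings[["RF-MdGini"]] <- ranking_result(
    "RF-MdGini", rf_full$extra$orderings$MdGini,
    rf_full$extra$importance[rf_full$extra$orderings$MdGini, "MeanDecreaseGini"],
    "descending")
  rankings[["SVM-RFE-W"]] <- svm_rfe_rank(scaled, "W")
  rankings[["ANOVA-p"]] <- anova_rank(table, p_cut = cfg$anova_p)

  cor_filter <- correlation_filter(table, cfg$cor_threshold)
  cor_table <- subset_features(table, cor_filter$retained)
  rf_cor <- rf_rank(cor_table, "MdAcc", n_trees = cfg$n_trees,
                    replicates = cfg$rf_replicates, seed = fan_seed(cfg$seed, 12))
  rankings[["Cor-RF-MdAcc"]] <- ranking_result("Cor-RF-MdAcc",
                                               rf_cor$ordered_features,
                                               rf_cor$scores, "descending")
  rankings[["Cor-RF-MdGini"]] <- ranking_result(
    "Cor-RF-MdGini", rf_cor$extra$orderings$MdGini,
    rf_cor$extra$importance[rf_cor$extra$orderings$MdGini, "MeanDecreaseGini"],
    "descending")
  rfe_cor <- rf_rfe_rank(cor_table, "Acc", n_trees = cfg$n_trees,
                         replicates = cfg$rfe_replicates,
                         elimination_fraction = cfg$elimination_fraction,
                         seed = fan_seed(cfg$seed, 13))
  rankings[["Cor-RF-RFE-Acc"]] <- ranking_result(
    "Cor-RF-RFE-Acc", rfe_cor$extra$rankings$Acc,
    rev(seq_along(rfe_cor$extra$rankings$Acc)), "descending")
  rankings[["Cor-RF-RFE-Kap"]] <- ranking_result(
    "Cor-RF-RFE-Kap", rfe_cor$extra$rankings$Kappa,
    rev(seq_along(rfe_cor$extra$rankings$Kappa)), "descending")

  mi_filter <- mutual_info_filter(table, cfg$mi_threshold)
  mi_scaled <- uv_scale(subset_features(table, mi_filter$retained))
  svm_mi <- svm_rfe_rank(mi_scaled, "Acc",
                         elimination_fraction = cfg$elimination_fraction)
  rankings[["MI-SVM-RFE-Acc"]] <- ranking_result(
    "MI-SVM-RFE-Acc", svm_mi$extra$rankings$Acc,
    rev(seq_along(svm_mi$extra$rankings$Acc)), "descending")
  rankings[["MI-SVM-RFE-Kap"]] <- ranking_result(
    "MI-SVM-RFE-Kap", svm_mi$extra$rankings$Kappa,
    rev(seq_along(svm_mi$extra$rankings$Kappa)), "descending")

  n_unf <- min(cfg$top_n_unfiltered, p)
  n_fil <- cfg$top_n_filtered
  sizes <- list(
    "RF-MdAcc" = n_unf, "RF-MdGini" = n_unf, "SVM-RFE-W" = n_unf,
    "ANOVA-p" = rankings[["ANOVA-p"]]$extra$n_top,
    "Cor-RF-MdAcc" = min(n_fil, length(cor_filter$retained)),
    "Cor-RF-MdGini" = min(n_fil, length(cor_filter$retained)),
    "Cor-RF-RFE-Acc" = min(n_fil, length(cor_filter$retained)),
    "Cor-RF-RFE-Kap" = min(n_fil, length(cor_filter$retained)),
    "MI-SVM-RFE-Acc" = min(n_fil, length(mi_filter$retained)),
    "MI-SVM-RFE-Kap" = min(n_fil, length(mi_filter$retained)))
  top_sets <- list()
  for (id in TECHNIQUE_IDS) {
    if (sizes[[id]] >= 1) top_sets[[id]] <- take_top(rankings[[id]], sizes[[id]])
    else warning("technique ", id, " retained no features; omitted from the context",
                 call. = FALSE)
  }
  list(rankings = rankings, top_sets = top_sets,
       filters = list(cor = cor_filter, mi = mi_filter))
}

#' Stability-consensus feature selection
#'
#' Convenience wrapper: runs the ten-technique suite, assembles the
#' feature-by-technique presence/absence context, and returns the features
#' selected by at least `config$consensus_k` techniques together with the
#' context, the stability degrees, and (optionally) the concept lattice.
#'
#' @param table a [feature_table].
#' @param config a [default_config()] list.
#' @param lattice also derive the concept lattice (default `TRUE`).
#' @return A list with `suite`, `context`, `degrees`, `consensus` and
#'   optionally `lattice`.
#' @export
select_stable_features <- function(table, config = default_config(), lattice = TRUE) {
  suite <- run_technique_suite(table, config)
  ctx <- build_context(suite$top_sets)
  out <- list(suite = suite, context = ctx,
              degrees = stability_degrees(ctx),
              consensus = consensus_select(ctx, config$consensus_k))
  if (lattice) out$lattice <- derive_concepts(ctx)
  out
}
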