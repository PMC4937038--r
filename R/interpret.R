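# ROC/AUC, univariate confirmation tests, correlation networks and
# association rules on discretized intensities.

#' Empirical ROC curve with AUC, DeLong interval and best operating point
#'
#' AUC is the empirical (Mann-Whitney) probability that a Case sample
#' scores above a Control sample, ties counted half. The confidence
#' interval uses the DeLong variance estimator; the reported operating
#' point maximizes Youden's J (sensitivity + specificity - 1). If all
#' scores are identical the AUC is 0.5 with a degenerate interval, flagged.
#'
#' @param probabilities per-sample scores (higher = more Case-like).
#' @param labels per-sample class labels ("1"/"-1"); both classes required.
#' @param conf_level confidence level for the DeLong interval.
#' @return A list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `sensitivity_at_best`, `specificity_at_best`, `n_pos`, `n_neg`,
#'   `degenerate`, and `curve` (a data frame of fpr/tpr/threshold).
#' @export
roc_auc <- function(probabilities, labels, conf_level = 0.95) {
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  stopifnot(length(probabilities) == length(labels))
  n_pos <- sum(labels == CASE_LABEL)
  n_neg <- sum(labels == CONTROL_LABEL)
  if (length(unique(probabilities)) == 1) {
    warning("all scores identical; AUC is the chance value 0.5", call. = FALSE)
    return(structure(list(auc = 0.5, ci_low = 0.5, ci_high = 0.5,
                          sensitivity_at_best = NA_real_,
                          specificity_at_best = NA_real_,
                          n_pos = n_pos, n_neg = n_neg, degenerate = TRUE,
                          curve = data.frame(fpr = c(0, 1), tpr = c(0, 1),
                                             threshold = c(Inf, -Inf))),
                     class = "roc_result"))
  }
  r <- pROC::roc(response = labels, predictor = probabilities,
                 levels = c(CONTROL_LABEL, CASE_LABEL), direction = "<",
                 quiet = TRUE)
  ci <- pROC::ci.auc(r, method = "delong", conf.level = conf_level)
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("sensitivity", "specificity", "threshold"),
                       transpose = FALSE)
  if (nrow(best) > 1) best <- best[1, , drop = FALSE]
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                      threshold = r$thresholds)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 sensitivity_at_best = best$sensitivity,
                 specificity_at_best = best$specificity,
                 n_pos = n_pos, n_neg = n_neg, degenerate = FALSE,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (%.3f-%.3f), %d pos / %d neg%s\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Welch two-sample t-tests per feature
#'
#' @param table a [feature_table] with at least 2 samples per class.
#' @param features feature ids to test (default all).
#' @return Data frame with columns `feature`, `t`, `p` (two-sided); a
#'   feature with zero variance in both groups gets `NA` in both columns.
#' @export
feature_t_tests <- function(table, features = feature_ids(table)) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table(table$labels) < 2)) stop("need at least 2 samples per class", call. = FALSE)
  case <- table$labels == CASE_LABEL
  out <- lapply(features, function(f) {
    a <- table$intensities[case, f]
    b <- table$intensities[!case, f]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(feature = f, t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(a, b)
    data.frame(feature = f, t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Pearson correlation network of selected features
#'
#' All pairwise Pearson correlations among the listed features; undirected
#' edges are kept where |r| meets the threshold, with the signed r retained
#' (positive and negative edge classes). Zero-variance features are
#' excluded with a warning.
#'
#' @param table a [feature_table].
#' @param features node feature ids (at least 2).
#' @param threshold minimum |r| for an edge (default 0.5).
#' @return A list of class `correlation_network`: `nodes`, `edges` (data
#'   frame `from`/`to`/`r`), `threshold`, and `graph` (an igraph object
#'   with edge attributes `r` and `sign`).
#' @export
correlation_network <- function(table, features, threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"), length(features) >= 2)
  x <- table$intensities[, features, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance feature(s) excluded: ",
            paste(features[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  cm <- stats::cor(x)
  idx <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(cm)[idx[, 1]], to = colnames(cm)[idx[, 2]],
                      r = cm[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = colnames(cm)))
  if (nrow(edges) > 0) {
    g <- igraph::set_edge_attr(g, "sign", value = ifelse(edges$r >= 0, "positive", "negative"))
  }
  structure(list(nodes = colnames(cm), edges = edges, threshold = threshold,
                 graph = g),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges at |r| >= %.2f\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' @rdname correlation_network
#' @param network a `correlation_network`.
#' @param path output GraphML file.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "correlation_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Equal-width discretization into transaction items
#'
#' Splits each feature's observed range into `n_bins` equal-width
#' intervals; the lowest interval is open at -Inf and the highest at +Inf
#' so out-of-range values are still covered. Each sample becomes a
#' transaction holding exactly one item per feature, labelled
#' `"feature=(lo - hi]"` (the printed style used for mined associations).
#' A constant feature collapses to a single-interval item and is flagged
#' with a warning.
#'
#' @param table a [feature_table].
#' @param features feature ids to discretize.
#' @param n_bins number of ranges per feature (default 4, minimum 2).
#' @return A list of class `transaction_set`: `transactions` (list of item
#'   character vectors, one per sample), `items` (all item labels), `bins`
#'   (per-feature inner cut points).
#' @export
discretize_equal_width <- function(table, features, n_bins = 4) {
  stopifnot(inherits(table, "feature_table"))
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  x <- table$intensities[, features, drop = FALSE]
  bins <- list()
  item_mat <- matrix("", nrow(x), ncol(x), dimnames = dimnames(x))
  fmt <- function(v) sprintf("%.6g", v)
  for (f in features) {
    v <- x[, f]
    lo <- min(v); hi <- max(v)
    if (lo == hi) {
      warning("constant feature '", f, "': single-interval item", call. = FALSE)
      bins[[f]] <- numeric(0)
      item_mat[, f] <- paste0(f, "=(-inf - inf)")
      next
    }
    cuts <- seq(lo, hi, length.out = n_bins + 1)[-c(1, n_bins + 1)]
    bins[[f]] <- cuts
    edges_lo <- c(-Inf, cuts)
    edges_hi <- c(cuts, Inf)
    lab <- sprintf("%s=(%s - %s]", f,
                   ifelse(is.finite(edges_lo), fmt(edges_lo), "-inf"),
                   ifelse(is.finite(edges_hi), fmt(edges_hi), "inf"))
    lab[length(lab)] <- sub("\\]$", ")", lab[length(lab)])
    # intervals are right-closed: a value exactly on a cut belongs below it
    idx <- vapply(v, function(val) sum(val > cuts) + 1L, integer(1))
    item_mat[, f] <- lab[idx]
  }
  structure(list(transactions = lapply(seq_len(nrow(item_mat)),
                                       function(i) unname(item_mat[i, ])),
                 items = sort(unique(as.vector(item_mat))),
                 bins = bins, features = features, n_bins = n_bins),
            class = "transaction_set")
}

#' Mine association rules with Apriori
#'
#' Classic Apriori: level-wise frequent-itemset search over the transaction
#' items (supports computed exactly as transaction fractions), then
#' single-consequent rule generation. Rules are filtered by minimum support
#' and confidence and sorted by confidence then support.
#'
#' @param transactions a `transaction_set` from [discretize_equal_width],
#'   or a plain list of item character vectors.
#' @param min_support minimum itemset support; must be positive (a zero
#'   threshold is rejected as a combinatorial-blowup guard).
#' @param min_confidence minimum rule confidence.
#' @param max_len maximum itemset size explored (default 4).
#' @return Data frame with columns `antecedent` (items joined by " & "),
#'   `consequent`, `support`, `confidence`, `n_items`.
#' @export
mine_rules <- function(transactions, min_support, min_confidence, max_len = 4) {
  if (inherits(transactions, "transaction_set")) transactions <- transactions$transactions
  stopifnot(is.list(transactions), length(transactions) > 0)
  if (min_support <= 0) stop("min_support must be positive", call. = FALSE)
  if (min_confidence < 0 || min_confidence > 1) stop("min_confidence must lie in [0, 1]",
                                                     call. = FALSE)
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  # item x transaction incidence
  inc <- vapply(transactions, function(tr) items %in% tr, logical(length(items)))
  if (length(items) == 1L) inc <- matrix(inc, nrow = 1)
  rownames(inc) <- items
  support_of <- function(idx) mean(colSums(inc[idx, , drop = FALSE]) == length(idx))

  freq <- list()   # per level: list of integer index vectors
  supp <- list()
  lvl1 <- which(rowMeans(inc) >= min_support)
  freq[[1]] <- lapply(lvl1, function(i) i)
  supp[[1]] <- rowMeans(inc)[lvl1]
  k <- 1
  while (length(freq[[k]]) > 0 && k < max_len) {
    prev <- freq[[k]]
    cand <- list()
    seen <- character(0)
    # join step: unions of same-level itemsets differing in one element
    for (i in seq_along(prev)) {
      for (j in seq_along(prev)) {
        if (j <= i) next
        u <- sort(union(prev[[i]], prev[[j]]))
        if (length(u) != k + 1) next
        key <- paste(u, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        # prune: every k-subset must be frequent
        subs_ok <- all(vapply(seq_along(u), function(d) {
          paste(u[-d], collapse = ",") %in%
            vapply(prev, paste, "", collapse = ",")
        }, logical(1)))
        if (subs_ok) cand[[length(cand) + 1]] <- u
      }
    }
    sups <- vapply(cand, support_of, numeric(1))
    keep <- sups >= min_support
    freq[[k + 1]] <- cand[keep]
    supp[[k + 1]] <- sups[keep]
    k <- k + 1
  }

  sup_lookup <- new.env(parent = emptyenv())
  for (lv in seq_along(freq)) {
    for (i in seq_along(freq[[lv]])) {
      assign(paste(freq[[lv]][[i]], collapse = ","), supp[[lv]][[i]], envir = sup_lookup)
    }
  }
  rules <- list()
  for (lv in seq_along(freq)) {
    if (lv < 2) next
    for (i in seq_along(freq[[lv]])) {
      s <- freq[[lv]][[i]]
      s_sup <- supp[[lv]][[i]]
      for (d in seq_along(s)) {
        ante <- s[-d]
        a_sup <- get(paste(ante, collapse = ","), envir = sup_lookup)
        conf <- s_sup / a_sup
        if (conf >= min_confidence) {
          rules[[length(rules) + 1]] <- data.frame(
            antecedent = paste(items[ante], collapse = " & "),
            consequent = items[s[d]],
            support = s_sup, confidence = conf, n_items = length(s),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rules)) do.call(rbind, rules) else
    data.frame(antecedent = character(), consequent = character(),
               support = numeric(), confidence = numeric(), n_items = integer())
  out <- out[order(-out$confidence, -out$support, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  out
}
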