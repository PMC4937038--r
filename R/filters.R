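# Redundancy and dependency filters applied before ranking.

new_filter_result <- function(retained, removed, threshold, method) {
  structure(list(retained = retained, removed = removed,
                 threshold = threshold, method = method),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result (%s, threshold %.3g): %d retained, %d removed\n",
              x$method, x$threshold, length(x$retained), nrow(x$removed)))
  invisible(x)
}

#' Remove redundant features by pairwise Pearson correlation
#'
#' Greedy elimination of highly correlated ions: while any feature pair
#' exceeds the threshold in absolute Pearson correlation, the pair with the
#' largest |r| is located and the member with the larger mean absolute
#' correlation to all remaining features is dropped (ties broken by
#' feature-id order). On exit no retained pair has |r| above the threshold.
#' This reproduces the mean-|r| heuristic of the redundancy filter commonly
#' used on metabolomics tables; an exhaustive search for the largest
#' admissible subset is intractable at ~1200 features.
#'
#' @param table a [feature_table] with at least 3 samples.
#' @param threshold absolute-correlation cutoff in (0, 1]; default 0.95.
#' @return A `filter_result` with `retained` (ordered feature ids),
#'   `removed` (data frame: feature, partner, statistic) and the settings.
#' @export
correlation_filter <- function(table, threshold = 0.95) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$intensities) < 3) stop("need at least 3 samples", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]", call. = FALSE)
  sds <- apply(table$intensities, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s), correlation undefined: ",
         paste(colnames(table$intensities)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cm <- abs(stats::cor(table$intensities))
  diag(cm) <- 0
  ids <- colnames(cm)
  alive <- rep(TRUE, ncol(cm))
  removed <- list()
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (max(sub) <= threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, , drop = TRUE]
    pair <- rownames(sub)[worst]
    # candidate with the larger mean |r| to all other retained features goes
    means <- vapply(pair, function(f) {
      others <- setdiff(rownames(sub), f)
      mean(cm[f, others])
    }, numeric(1))
    drop_id <- if (means[1] > means[2]) pair[1]
      else if (means[2] > means[1]) pair[2]
      else sort(pair)[1]
    keep_id <- setdiff(pair, drop_id)
    removed[[drop_id]] <- data.frame(feature = drop_id, partner = keep_id,
                                     statistic = max(sub), stringsAsFactors = FALSE)
    alive[match(drop_id, ids)] <- FALSE
  }
  removed_df <- if (length(removed)) do.call(rbind, unname(removed)) else
    data.frame(feature = character(), partner = character(), statistic = numeric())
  new_filter_result(ids[alive], removed_df, threshold, "correlation")
}

#' Feature-by-feature mutual information matrix
#'
#' Gaussian (correlation-based) estimator in nats:
#' `MI(i, j) = -0.5 * log(1 - r_ij^2)`, with a zero diagonal by convention.
#' Deterministic and parameter-free; exactly 0 for uncorrelated features and
#' infinite for exactly collinear ones.
#'
#' @param table a [feature_table].
#' @return A symmetric non-negative matrix with feature-id dimnames.
#' @export
mutual_info_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  sds <- apply(table$intensities, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(table$intensities)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(table$intensities)
  mi <- -0.5 * log(pmax(1 - r^2, 0))
  diag(mi) <- 0
  mi
}

#' Remove dependent features by average mutual information
#'
#' Each feature is scored by its average mutual information (Gaussian
#' estimator, see [mutual_info_matrix]) over all other features, diagonal
#' excluded. Features whose average MI is *below* the threshold are
#' retained: high average MI marks a feature as dependent on many others
#' and it is filtered out.
#'
#' @param table a [feature_table] with at least 3 samples.
#' @param threshold average-MI cutoff in nats; default 0.02.
#' @return A `filter_result`; `removed$statistic` holds the average MI of
#'   each discarded feature.
#' @export
mutual_info_filter <- function(table, threshold = 0.02) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$intensities) < 3) stop("need at least 3 samples", call. = FALSE)
  mi <- mutual_info_matrix(table)
  p <- ncol(mi)
  avg <- rowSums(mi) / (p - 1)
  keep <- avg < threshold
  removed_df <- data.frame(feature = names(avg)[!keep],
                           partner = rep(NA_character_, sum(!keep)),
                           statistic = unname(avg[!keep]),
                           stringsAsFactors = FALSE)
  new_filter_result(names(avg)[keep], removed_df, threshold, "mutual_information")
}
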