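# Fixture builders and independent brute-force oracles used across tests.

make_ft <- function(m, labels, ids = colnames(m)) {
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(m)))
  feature_table(m, labels = labels,
                sample_ids = paste0("s", seq_len(nrow(m))),
                feature_ids = ids)
}

# two columns with an exact prescribed sample correlation, plus optional
# independent noise columns (Gram-Schmidt construction)
exact_r_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- scale(stats::rnorm(n))[, 1]
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- scale(z)[, 1]
  cbind(x, r * x + sqrt(1 - r^2) * z)
}

# all formal concepts of a binary matrix by closing every attribute subset
concepts_brute <- function(inc) {
  m <- ncol(inc)
  keys <- character(0)
  concepts <- list()
  for (code in 0:(2^m - 1)) {
    b <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    if (length(b) == 0) extent <- seq_len(nrow(inc))
    else extent <- which(rowSums(inc[, b, drop = FALSE]) == length(b))
    if (length(extent) == 0) intent <- seq_len(m)
    else intent <- which(colSums(inc[extent, , drop = FALSE]) == length(extent))
    key <- paste(intent, collapse = ",")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      concepts[[length(concepts) + 1]] <- list(extent = extent, intent = intent)
    }
  }
  concepts
}

# vectorized exhaustive oracle: the closures of all 2^m attribute subsets,
# returned as the set of distinct intent keys ("i,j,k" over sorted indices)
closure_keys_brute <- function(inc) {
  m <- ncol(inc)
  codes <- 0:(2^m - 1)
  mask <- vapply(codes, function(code) as.integer(bitwAnd(code, 2^(seq_len(m) - 1)) > 0),
                 integer(m))
  sizes <- colSums(mask)
  counts <- inc %*% mask                       # objects x subsets
  ext <- counts == matrix(sizes, nrow(inc), length(codes), byrow = TRUE)
  ext_sizes <- colSums(ext)
  int_counts <- t(inc) %*% ext                 # attributes x subsets
  int <- int_counts == matrix(ext_sizes, m, length(codes), byrow = TRUE)
  unique(apply(int, 2, function(col) paste(which(col), collapse = ",")))
}

# empirical AUC by exhaustive concordant/tied pair counting
auc_brute <- function(scores, labels) {
  pos <- scores[labels == "1"]
  neg <- scores[labels == "-1"]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive frequent itemsets: support of every non-empty item subset
itemsets_brute <- function(transactions, min_support, max_len = 4) {
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  out <- list()
  for (k in seq_len(min(max_len, length(items)))) {
    sets <- utils::combn(items, k, simplify = FALSE)
    for (s in sets) {
      sup <- mean(vapply(transactions, function(tr) all(s %in% tr), logical(1)))
      if (sup >= min_support) out[[paste(s, collapse = "|")]] <- sup
    }
  }
  out
}

# step-up FDR adjustment computed directly from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
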