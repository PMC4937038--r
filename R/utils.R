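# Internal helpers shared across modules.

CASE_LABEL <- "1"
CONTROL_LABEL <- "-1"

#' @keywords internal
#' @noRd
normalize_labels <- function(x, what = "label") {
  x <- as.character(x)
  # accept the Unicode minus sign printed in many reports alongside ASCII "-1"
  x <- gsub("−", "-", x, fixed = TRUE)
  x <- trimws(x)
  bad <- !(x %in% c(CASE_LABEL, CONTROL_LABEL))
  if (any(bad)) {
    stop(sprintf("invalid class %s at position(s) %s: %s (labels must be \"1\" or \"-1\")",
                 what, paste(which(bad), collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

# factor with control first so "1" (Case) is the positive/second level
label_factor <- function(labels) {
  factor(labels, levels = c(CONTROL_LABEL, CASE_LABEL))
}

# replicate r of a run gets its own deterministic stream from the master
# seed (double arithmetic: counters can exceed integer range before the mod)
fan_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(r)) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Cohen's kappa: observed vs chance-expected agreement
cohen_kappa <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  stopifnot(length(pred) == length(truth))
  n <- length(truth)
  po <- mean(pred == truth)
  lev <- union(unique(pred), unique(truth))
  pe <- sum(vapply(lev, function(l) mean(pred == l) * mean(truth == l), numeric(1)))
  if (abs(1 - pe) < .Machine$double.eps) return(ifelse(po >= 1, 1, 0))
  (po - pe) / (1 - pe)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x != as.integer(x) || x <= 0) {
    stop(sprintf("%s must be a single positive integer", name), call. = FALSE)
  }
  as.integer(x)
}
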