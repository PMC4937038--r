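#' Construct a case-control feature table
#'
#' The pipeline's central container: a samples x features intensity matrix
#' with unique sample and feature identifiers and a binary class label per
#' sample ("1" = Case, "-1" = Control; the Unicode minus form "−1" is
#' accepted and normalized).
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#' @param labels character vector of per-sample class labels, length `nrow(intensities)`.
#' @param sample_ids,feature_ids unique identifier vectors; default to the
#'   matrix dimnames.
#' @return An object of class `feature_table` with components `intensities`
#'   (a named matrix) and `labels`.
#' @examples
#' x <- matrix(rexp(12) + 1, 4, 3)
#' ft <- feature_table(x, labels = c("1", "1", "-1", "-1"),
#'                     sample_ids = paste0("S", 1:4),
#'                     feature_ids = paste0("mz_", 1:3))
#' ft
#' @export
feature_table <- function(intensities, labels, sample_ids = rownames(intensities),
                          feature_ids = colnames(intensities)) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  if (is.null(feature_ids)) stop("feature_ids are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(intensities)) {
    stop("sample_ids length does not match the row count", call. = FALSE)
  }
  if (length(feature_ids) != ncol(intensities)) {
    stop("feature_ids length does not match the column count", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature ids: ", paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) != nrow(intensities)) {
    stop("labels length does not match the sample count", call. = FALSE)
  }
  labels <- normalize_labels(labels)
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite with no missing values", call. = FALSE)
  }
  dimnames(intensities) <- list(sample_ids, feature_ids)
  structure(list(intensities = intensities, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(CASE_LABEL, CONTROL_LABEL)))
  cat(sprintf("feature_table: %d samples x %d features (%d Case / %d Control)\n",
              nrow(x$intensities), ncol(x$intensities),
              tab[[CASE_LABEL]], tab[[CONTROL_LABEL]]))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
feature_ids <- function(x) colnames(x$intensities)

#' @rdname feature_table
#' @export
sample_ids <- function(x) rownames(x$intensities)

#' Read and write feature tables as delimited text
#'
#' The interchange layout is one row per sample: `sample_id`, `class`
#' (the literal "1" or "-1"), then one numeric column per feature, with a
#' header of feature ids. Values are written with 17 significant digits so
#' a write/read round trip reproduces the numeric values exactly.
#'
#' @param path file path.
#' @param delimiter field separator; tab by default, comma accepted.
#' @return `read_feature_table` returns a [feature_table];
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 3) stop("expected sample_id, class and at least one feature column", call. = FALSE)
  if (!identical(colnames(df)[1:2], c("sample_id", "class"))) {
    stop("header must start with 'sample_id' and 'class', got: ",
         paste(colnames(df)[1:2], collapse = ", "), call. = FALSE)
  }
  feats <- colnames(df)[-(1:2)]
  vals <- suppressWarnings(vapply(df[-(1:2)], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, feats))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row %d, feature '%s'",
                 bad[1, 1], feats[bad[1, 2]]), call. = FALSE)
  }
  labels <- tryCatch(normalize_labels(df$class, what = "label"),
                     error = function(e) {
                       stop(sprintf("%s (sample id(s): %s)", conditionMessage(e),
                                    paste(df$sample_id[!(gsub("−", "-", df$class) %in%
                                                           c("1", "-1"))], collapse = ", ")),
                            call. = FALSE)
                     })
  feature_table(vals, labels = labels, sample_ids = df$sample_id, feature_ids = feats)
}

#' @rdname read_feature_table
#' @param table a [feature_table].
#' @export
write_feature_table <- function(table, path, delimiter = "\t") {
  stopifnot(inherits(table, "feature_table"))
  m <- table$intensities
  txt <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m))
  out <- cbind(sample_id = rownames(m), class = table$labels, txt)
  colnames(out) <- c("sample_id", "class", colnames(m))
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write formal contexts in the Burmeister .cxt dialect
#'
#' Layout: a line `B`, a blank line, the object count, the attribute count,
#' a blank line, one line per object name, one per attribute name, then one
#' incidence line per object made of `X`/`.` characters.
#'
#' @param context a [formal_context].
#' @param path file path.
#' @return `read_cxt` returns a [formal_context]; `write_cxt` returns
#'   `path` invisibly. Reading a file written by `write_cxt` reproduces the
#'   context exactly.
#' @export
write_cxt <- function(context, path) {
  stopifnot(inherits(context, "formal_context"))
  inc <- context$incidence
  if (length(inc) == 0) stop("refusing to write an empty context", call. = FALSE)
  rows <- apply(inc, 1, function(r) paste(ifelse(r > 0, "X", "."), collapse = ""))
  lines <- c("B", "", nrow(inc), ncol(inc), "", rownames(inc), colnames(inc), rows)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cxt
#' @export
read_cxt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1 || trimws(lines[1]) != "B") {
    stop("not a Burmeister context: first line must be 'B'", call. = FALSE)
  }
  nums <- lines[-1]
  nums <- nums[nzchar(trimws(nums))]
  n_obj <- suppressWarnings(as.integer(trimws(nums[1])))
  n_att <- suppressWarnings(as.integer(trimws(nums[2])))
  if (is.na(n_obj) || is.na(n_att) || n_obj < 1 || n_att < 1) {
    stop("malformed object/attribute counts", call. = FALSE)
  }
  rest <- nums[-(1:2)]
  if (length(rest) != n_obj + n_att + n_obj) {
    stop(sprintf("expected %d name/incidence lines, found %d",
                 n_obj + n_att + n_obj, length(rest)), call. = FALSE)
  }
  objects <- rest[seq_len(n_obj)]
  attributes <- rest[n_obj + seq_len(n_att)]
  inc_lines <- rest[n_obj + n_att + seq_len(n_obj)]
  inc <- matrix(0L, n_obj, n_att, dimnames = list(objects, attributes))
  for (i in seq_len(n_obj)) {
    chars <- strsplit(inc_lines[i], "")[[1]]
    if (length(chars) != n_att) {
      line_no <- 1 + which(lines == inc_lines[i])[1] - 1
      stop(sprintf("incidence row for object '%s' has %d characters, expected %d (line %d)",
                   objects[i], length(chars), n_att, line_no), call. = FALSE)
    }
    if (!all(chars %in% c("X", "x", "."))) {
      stop(sprintf("invalid incidence character in row for object '%s'", objects[i]),
           call. = FALSE)
    }
    inc[i, ] <- as.integer(chars %in% c("X", "x"))
  }
  formal_context(objects, attributes, inc)
}

#' Workflow constants
#'
#' Bundles the thresholds and replication counts used across the pipeline:
#' correlation-filter cutoff 0.95, mutual-information cutoff 0.02 (nats),
#' consensus threshold of 6 techniques, ANOVA retention p < 0.1, logistic
#' entry p < 0.25 with collinearity pruning to max |r| 0.5, top-set sizes
#' (200 after a filter, 178 without one), 2000-tree forests with
#' mtry = 2 * ceiling(sqrt(p)), 50 selection replicates and 100 prediction
#' replications. Any component can be overridden, e.g. to run the whole
#' workflow at a smaller computational scale.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @examples
#' cfg <- default_config(n_trees = 200, rf_replicates = 5)
#' cfg$cor_threshold
#' @export
default_config <- function(...) {
  cfg <- list(
    cor_threshold = 0.95,
    mi_threshold = 0.02,
    consensus_k = 6L,
    anova_p = 0.1,
    logistic_entry_p = 0.25,
    logistic_max_r = 0.5,
    logistic_shortlist = 10L,
    top_n_filtered = 200L,
    top_n_unfiltered = 178L,
    n_trees = 2000L,
    rf_replicates = 50L,
    rfe_replicates = 50L,
    elimination_fraction = 0.5,
    predict_replications = 100L,
    split_frac = 0.75,
    subset_sizes = c(48L, 40L, 30L, 20L, 10L, 5L),
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "),
                              call. = FALSE)
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$cor_threshold > 0, cfg$cor_threshold <= 1,
            cfg$mi_threshold > 0, cfg$consensus_k >= 1,
            cfg$n_trees >= 1, cfg$rf_replicates >= 1,
            cfg$predict_replications >= 1)
  structure(cfg, class = "run_config")
}
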