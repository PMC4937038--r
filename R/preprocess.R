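#' Unit-variance scaling
#'
#' Divides each feature column by its sample (n-1) standard deviation so
#' every variable has the same chance to contribute to scale-sensitive
#' models (the linear SVM routes). By default columns are not mean-centered,
#' matching the divide-by-sd definition used for these data; `center = TRUE`
#' gives conventional autoscaling. Tree-based rankers and ANOVA are
#' scale-invariant and are normally run on the raw table.
#'
#' @param table a [feature_table]; every feature needs non-zero variance.
#' @param center also subtract the column mean (default `FALSE`).
#' @return A new [feature_table] with unit-sd columns; the input is not
#'   modified. Scaling is idempotent when `center = FALSE`.
#' @examples
#' ft <- generate_dataset(synth_spec(5, 5, 3, seed = 1))
#' apply(uv_scale(ft)$intensities, 2, sd)
#' @export
uv_scale <- function(table, center = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$intensities
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance feature(s): ", paste(colnames(m)[zero], collapse = ", "),
         call. = FALSE)
  }
  scaled <- sweep(m, 2, sds, "/")
  if (center) scaled <- sweep(scaled, 2, colMeans(scaled), "-")
  out <- feature_table(scaled, labels = table$labels)
  attr(out, "uv_scaled") <- TRUE
  out
}

# TRUE when every column already has sample sd within tol of 1
is_uv_scaled <- function(table, tol = 1e-6) {
  all(abs(apply(table$intensities, 2, stats::sd) - 1) <= tol)
}
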