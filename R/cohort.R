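# Published summaries of the GAZEL serum case-control analysis this
# workflow was developed on. The cohort's raw feature table is not public;
# these printed tables are the reference inputs the package can recompute
# derived quantities from.

#' Reference tables from the GAZEL serum cohort analysis
#'
#' `cohort_rank_table()` returns the published ranks of the 11 best
#' predictive m/z features under the ten selection techniques (NA where a
#' feature did not appear in a technique's ranking).
#' `cohort_model_errors()` returns the published per-model AUC (with 95%
#' CI) and false positive/negative counts of the five final predictive
#' models on the 111-sample cohort. `cohort_top_sizes()` gives the
#' top-set size each technique retained (178 for the unfiltered machine
#' learning routes, 200 after a filter, 107 for ANOVA at p < 0.1), and
#' `cohort_counts()` the dataset-level counts (sample sizes, feature
#' counts surviving each filter, ANOVA/BH-significant counts, consensus
#' and concept-lattice sizes).
#'
#' @return A data frame (`cohort_rank_table`, `cohort_model_errors`), a
#'   named integer vector (`cohort_top_sizes`) or a named list
#'   (`cohort_counts`).
#' @examples
#' cohort_rank_table()["m/z 145", ]
#' @export
cohort_rank_table <- function() {
  path <- system.file("extdata", "gazel_rank_table.tsv", package = "metastab",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "NA")
  rownames(df) <- df$feature
  as.matrix(df[, -1])
}

#' @rdname cohort_rank_table
#' @export
cohort_model_errors <- function() {
  path <- system.file("extdata", "gazel_model_errors.tsv", package = "metastab",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}

#' @rdname cohort_rank_table
#' @export
cohort_top_sizes <- function() {
  c("RF-MdAcc" = 178L, "RF-MdGini" = 178L, "SVM-RFE-W" = 178L, "ANOVA-p" = 107L,
    "Cor-RF-MdAcc" = 200L, "Cor-RF-MdGini" = 200L, "Cor-RF-RFE-Acc" = 200L,
    "Cor-RF-RFE-Kap" = 200L, "MI-SVM-RFE-Acc" = 200L, "MI-SVM-RFE-Kap" = 200L)
}

#' @rdname cohort_rank_table
#' @export
cohort_counts <- function() {
  list(n_samples = 111L, n_case = 55L, n_control = 56L, n_features = 1195L,
       n_after_cor_filter = 963L, n_after_mi_filter = 590L,
       n_anova_p_below_01 = 107L, n_bh_significant = 52L,
       n_consensus = 48L, n_concepts = 276L, consensus_k = 6L)
}
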