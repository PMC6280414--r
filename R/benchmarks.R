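# Bundled reference tables: published evaluation results of the four
# methods on four UCI biomedical datasets, and those datasets' class counts.

#' Published benchmark scores of the four methods
#'
#' Trial-averaged test scores (G-mean, AUC, F-measure) reported for
#' PGM-ELM, W-ELM, SMOTE-ELM and H-ELM on four UCI biomedical datasets
#' (breast cancer diagnostic, Indian liver patient, diabetic retinopathy
#' Debrecen, Pima diabetes). Used as the worked input for the rank
#' statistics.
#'
#' @param metric one of `"g_mean"`, `"auc"`, `"f_measure"`.
#' @return numeric matrix, rows = datasets, columns = methods.
#' @examples
#' friedman_rank_test(benchmark_scores("g_mean"))
#' @export
benchmark_scores <- function(metric = c("g_mean", "auc", "f_measure")) {
  metric <- match.arg(metric)
  df <- utils::read.csv(system.file("extdata", "benchmark_scores.csv",
                                    package = "pgmelm"))
  datasets <- unique(df$dataset)
  methods <- unique(df$method)
  m <- matrix(NA_real_, length(datasets), length(methods),
              dimnames = list(datasets, methods))
  m[cbind(df$dataset, df$method)] <- df[[metric]]
  m
}

#' Class counts of the reference UCI biomedical datasets
#'
#' @return data frame with columns `dataset`, `attributes`, `minority`,
#'   `majority`, `train`, `test`.
#' @export
benchmark_counts <- function() {
  utils::read.csv(system.file("extdata", "dataset_counts.csv",
                              package = "pgmelm"))
}
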