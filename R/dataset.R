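#' Construct an imbalanced two-class dataset
#'
#' Bundles a numeric feature matrix with binary labels and the derived class
#' counts used throughout the package: the minority count \eqn{N^+} (label 1),
#' the majority count \eqn{N^-} (label 0), the total \eqn{N = N^+ + N^-}, the
#' feature count \eqn{M}, and the imbalance ratio \eqn{IR = N^+/N^-}.
#'
#' @param X numeric matrix or data frame, one row per sample.
#' @param y binary label vector; 1 marks the minority (positive/diseased)
#'   class, 0 the majority class.
#' @return an object of class `imb_dataset`: a list with elements `X`, `y`,
#'   `n`, `n_pos`, `n_neg`, `m`, `ir`.
#' @examples
#' ds <- imb_dataset(matrix(rnorm(40), 20), rep(c(1, 0), c(5, 15)))
#' ds$ir  # 5/15
#' @export
imb_dataset <- function(X, y) {
  X <- check_matrix(X)
  y <- check_binary_labels(y)
  if (nrow(X) != length(y)) {
    stop_pgm("nrow(X) (%d) must equal length(y) (%d)", nrow(X), length(y),
             class = "pgmelm_shape_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  structure(
    list(X = X, y = y, n = length(y), n_pos = n_pos, n_neg = n_neg,
         m = ncol(X), ir = if (n_neg > 0) n_pos / n_neg else NA_real_),
    class = "imb_dataset"
  )
}

#' @export
print.imb_dataset <- function(x, ...) {
  cat(sprintf(
    "<imb_dataset> %d samples x %d features | minority %d, majority %d, IR = %.4g\n",
    x$n, x$m, x$n_pos, x$n_neg, x$ir))
  invisible(x)
}

#' Read an imbalanced dataset from a delimited text file
#'
#' Expects a header row, numeric feature columns, and one binary label column
#' (minority = 1, majority = 0).
#'
#' @param path CSV/TSV file path; the delimiter is inferred from the
#'   extension (`.tsv` means tab, anything else comma).
#' @param label_col name of the label column (default `"label"`).
#' @return an [imb_dataset].
#' @export
read_dataset <- function(path, label_col = "label") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df)) {
    stop_pgm("label column '%s' not found in %s", label_col, path,
             class = "pgmelm_io_error")
  }
  y <- df[[label_col]]
  X <- as.matrix(df[setdiff(names(df), label_col)])
  imb_dataset(X, y)
}

#' Write an imbalanced dataset as CSV
#'
#' @param ds an [imb_dataset] or `balanced_dataset`.
#' @param path output file path.
#' @param label_col label column name.
#' @return `path`, invisibly. Balanced datasets gain a logical `synthetic`
#'   column marking generated rows.
#' @export
write_dataset <- function(ds, path, label_col = "label") {
  if (inherits(ds, "balanced_dataset")) {
    df <- as.data.frame(ds$X)
    df[[label_col]] <- ds$y
    df$synthetic <- ds$generated_mask
  } else {
    df <- as.data.frame(ds$X)
    df[[label_col]] <- ds$y
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
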