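# Friedman omnibus test and Nemenyi critical difference for comparing
# classifiers across multiple datasets.

# Studentized-range-based Nemenyi q values (two-tailed, infinite d.f.),
# k = 2..10. q_{0.05, 4} = 2.569 and CD = q * sqrt(k(k+1)/(6N)).
nemenyi_q <- list(
  "0.05" = c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728, `6` = 2.850,
             `7` = 2.949, `8` = 3.031, `9` = 3.102, `10` = 3.164),
  "0.1"  = c(`2` = 1.645, `3` = 2.052, `4` = 2.291, `5` = 2.459, `6` = 2.589,
             `7` = 2.693, `8` = 2.780, `9` = 2.855, `10` = 2.920)
)

#' Friedman rank test over a datasets-by-methods score table
#'
#' Ranks the methods within each dataset (rank 1 = best, ties averaged) and
#' tests whether the average ranks could have arisen under exchangeable
#' performance, with the chi-square statistic
#' \eqn{\chi^2_F = \frac{12 N}{k(k+1)} \sum_j (R_j - \frac{k+1}{2})^2}
#' on `k - 1` degrees of freedom (`k` methods, `N` datasets).
#'
#' @param scores numeric matrix, rows = datasets, columns = methods; no
#'   missing entries, at least 2 of each.
#' @param higher_is_better if `TRUE` (default) larger scores rank better.
#' @return object of class `rank_summary`: `avg_ranks` (named), `ranks`
#'   (per-dataset matrix), `statistic`, `df`, `p_value`, `k`, `n_datasets`.
#' @export
friedman_rank_test <- function(scores, higher_is_better = TRUE) {
  scores <- check_matrix(scores, "scores")
  k <- ncol(scores); N <- nrow(scores)
  if (k < 2 || N < 2) {
    stop_pgm("need at least 2 methods and 2 datasets (got %d x %d)", N, k,
             class = "pgmelm_spec_error")
  }
  if (is.null(colnames(scores))) colnames(scores) <- paste0("method", seq_len(k))
  R <- t(apply(scores, 1, function(r) rank(if (higher_is_better) -r else r)))
  avg <- colMeans(R)
  stat <- 12 * N / (k * (k + 1)) * sum((avg - (k + 1) / 2)^2)
  structure(list(avg_ranks = avg, ranks = R, statistic = stat, df = k - 1,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 k = k, n_datasets = N),
            class = "rank_summary")
}

#' Nemenyi critical difference
#'
#' Two methods differ significantly when their average ranks differ by more
#' than \eqn{CD = q_{\alpha,k} \sqrt{k(k+1)/(6N)}}, with \eqn{q} from the
#' studentized-range-based Nemenyi table.
#'
#' @param k number of methods (2..10, the tabulated range).
#' @param n_datasets number of datasets (>= 2).
#' @param alpha significance level, 0.05 or 0.10 (the tabulated levels).
#' @return scalar critical difference.
#' @examples
#' nemenyi_cd(4, 4)  # 2.345
#' @export
nemenyi_cd <- function(k, n_datasets, alpha = 0.05) {
  key <- as.character(alpha)
  if (!key %in% names(nemenyi_q)) {
    stop_pgm("alpha = %s not tabulated (use 0.05 or 0.1)", alpha,
             class = "pgmelm_unsupported_alpha")
  }
  qs <- nemenyi_q[[key]]
  if (k < 2 || n_datasets < 2) {
    stop_pgm("need k >= 2 and n_datasets >= 2", class = "pgmelm_spec_error")
  }
  if (!as.character(k) %in% names(qs)) {
    stop_pgm("k = %d outside the tabulated range 2..10", k,
             class = "pgmelm_unsupported_alpha")
  }
  unname(qs[as.character(k)]) * sqrt(k * (k + 1) / (6 * n_datasets))
}

#' Attach the Nemenyi critical difference and pairwise decisions
#'
#' @param summary a `rank_summary` from [friedman_rank_test()].
#' @param alpha significance level (0.05 or 0.10).
#' @return the summary with fields `cd`, `alpha`, and a logical matrix
#'   `significant` (`|rank_i - rank_j| > CD`, symmetric, FALSE diagonal).
#' @export
add_nemenyi <- function(summary, alpha = 0.05) {
  stopifnot(inherits(summary, "rank_summary"))
  cd <- nemenyi_cd(summary$k, summary$n_datasets, alpha)
  dif <- abs(outer(summary$avg_ranks, summary$avg_ranks, "-"))
  sig <- dif > cd
  diag(sig) <- FALSE
  summary$cd <- cd
  summary$alpha <- alpha
  summary$significant <- sig
  summary
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("<rank_summary> %d methods over %d datasets\n", x$k, x$n_datasets))
  cat("  average ranks:",
      paste(sprintf("%s = %.3g", names(x$avg_ranks), x$avg_ranks),
            collapse = ", "), "\n")
  cat(sprintf("  chi-square = %.4g (df %d), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$cd)) {
    cat(sprintf("  Nemenyi CD (alpha %.2f) = %.4g\n", x$alpha, x$cd))
  }
  invisible(x)
}

#' Plain-text critical-difference diagram description
#'
#' Orders the methods by average rank and lists which pairs fall within one
#' critical difference of each other.
#'
#' @param summary a `rank_summary` with the CD attached ([add_nemenyi()]).
#' @return character vector of description lines, invisibly; also printed.
#' @export
cd_diagram_text <- function(summary) {
  stopifnot(inherits(summary, "rank_summary"), !is.null(summary$cd))
  ord <- order(summary$avg_ranks)
  lines <- c(sprintf("CD = %.4g at alpha = %.2f (%d methods, %d datasets)",
                     summary$cd, summary$alpha, summary$k, summary$n_datasets),
             sprintf("%d. %s (avg rank %.3g)", seq_along(ord),
                     names(summary$avg_ranks)[ord], summary$avg_ranks[ord]))
  pairs <- which(!summary$significant & upper.tri(summary$significant),
                 arr.ind = TRUE)
  if (nrow(pairs)) {
    lines <- c(lines, "not separated (within CD):",
               apply(pairs, 1, function(ij) {
                 sprintf("  %s ~ %s", rownames(summary$significant)[ij[1]],
                         colnames(summary$significant)[ij[2]])
               }))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Read a datasets-by-methods score table from CSV
#'
#' First column = dataset names, remaining columns = one method each.
#'
#' @param path CSV path.
#' @return numeric matrix with dataset rownames and method colnames.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}
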