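# End-to-end Monte-Carlo experiment driver and cross-dataset comparison.

eval_predictions <- function(pred, y_test) {
  cm <- confusion(y_test, pred$labels)
  rep <- classification_report(cm)
  auc <- tryCatch(roc_auc(pred$scores, y_test)$auc, error = function(e) NA_real_)
  c(tpr = rep$tpr, tnr = rep$tnr, g_mean = rep$g_mean,
    f_measure = rep$f_measure, auc = auc)
}

fit_and_eval <- function(method, train, test, threshold, config, C,
                         n_hidden, l1, iters, seed) {
  if (method == "pgm-elm") {
    fit <- pgmelm(train, threshold = threshold, config = config, C = C,
                  l1 = l1, iters = iters, seed = seed)
    return(eval_predictions(predict(fit, test$X), test$y))
  }
  scaler <- standardizer_fit(train$X)
  Xs <- standardizer_apply(scaler, train$X)
  Xs_test <- standardizer_apply(scaler, test$X)
  pred <- switch(
    method,
    "w-elm" = predict(welm_fit(Xs, train$y, n_hidden = n_hidden, C = C,
                               seed = seed), Xs_test),
    "smote-elm" = {
      ds_s <- imb_dataset(Xs, train$y)
      k <- min(5L, ds_s$n_pos - 1L)
      bal <- smote_oversample(ds_s, k = k, seed = derive_seed(seed, 3L))
      predict(elm_fit(bal$X, bal$y, n_hidden = n_hidden, C = C, seed = seed),
              Xs_test)
    },
    "h-elm" = predict(helm_fit(Xs, train$y, C = C, l1 = l1, iters = iters,
                               seed = seed), Xs_test),
    "elm" = predict(elm_fit(Xs, train$y, n_hidden = n_hidden, C = C,
                            seed = seed), Xs_test),
    stop_pgm("unknown method '%s'", method, class = "pgmelm_spec_error")
  )
  eval_predictions(pred, test$y)
}

#' Run a Monte-Carlo classification experiment on one dataset
#'
#' For each of `trials` repetitions: draw a fresh stratified train/test
#' split, fit every requested method on the training part (standardization,
#' PCA and GAN balancing are refit inside the trial on that trial's training
#' split only), and evaluate on the held-out part. Reported metrics are
#' averaged over trials; per-trial seeds derive deterministically from
#' `master_seed`, so the whole report is a pure function of its
#' configuration.
#'
#' @param ds an [imb_dataset] with the raw features.
#' @param n_train training-set size per trial.
#' @param methods subset of `"pgm-elm"`, `"w-elm"`, `"smote-elm"`, `"h-elm"`,
#'   `"elm"`.
#' @param trials number of Monte-Carlo repetitions (default 20).
#' @param threshold PCA cumulative-contribution cutoff for PGM-ELM.
#' @param config [gan_config()] for the balancing stage.
#' @param C ridge coefficient shared by all methods.
#' @param n_hidden hidden nodes of the single-layer baselines (default 100).
#' @param l1,iters autoencoder settings for the multilayer methods.
#' @param master_seed integer master seed.
#' @param stratified stratify the splits (default `TRUE`).
#' @return object of class `experiment_report`: `results` (one row per
#'   trial x method), `summary` (trial-averaged metrics per method), and
#'   `config` (everything needed to reproduce the run).
#' @export
run_experiment <- function(ds, n_train,
                           methods = c("pgm-elm", "w-elm", "smote-elm", "h-elm"),
                           trials = 20, threshold = 0.85,
                           config = gan_config(), C = 1, n_hidden = 100,
                           l1 = 1e-3, iters = 50, master_seed = 1,
                           stratified = TRUE) {
  stopifnot(inherits(ds, "imb_dataset"))
  if (trials < 1) stop_pgm("trials must be >= 1", class = "pgmelm_spec_error")
  methods <- match.arg(methods, c("pgm-elm", "w-elm", "smote-elm", "h-elm", "elm"),
                       several.ok = TRUE)
  rows <- vector("list", trials * length(methods))
  i <- 0L
  for (t in seq_len(trials)) {
    seed_t <- derive_seed(master_seed, t)
    parts <- split_dataset(ds, n_train, seed = seed_t, stratified = stratified)
    for (method in methods) {
      i <- i + 1L
      metrics <- tryCatch(
        fit_and_eval(method, parts$train, parts$test, threshold, config, C,
                     n_hidden, l1, iters, seed = derive_seed(seed_t, 7L)),
        error = function(e) {
          stop_pgm("method '%s' failed in trial %d: %s", method, t,
                   conditionMessage(e), class = "pgmelm_stage_error")
        })
      rows[[i]] <- data.frame(trial = t, method = method, t(metrics))
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    results[c("tpr", "tnr", "g_mean", "f_measure", "auc")],
    by = list(method = results$method),
    FUN = function(x) mean(x, na.rm = TRUE))
  structure(list(results = results, summary = summary,
                 config = list(n_train = n_train, methods = methods,
                               trials = trials, threshold = threshold,
                               gan = unclass(config), C = C,
                               n_hidden = n_hidden, l1 = l1, iters = iters,
                               master_seed = master_seed,
                               stratified = stratified,
                               n = ds$n, m = ds$m, n_pos = ds$n_pos,
                               n_neg = ds$n_neg)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d trials x %d methods (train %d of %d samples)\n",
              x$config$trials, length(x$config$methods), x$config$n_train,
              x$config$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare methods across several experiment reports
#'
#' Builds the datasets-by-methods table of trial-averaged scores and applies
#' the Friedman test plus the Nemenyi critical difference.
#'
#' @param reports named list of `experiment_report`s (names = dataset
#'   labels), all sharing the same method set; or a ready numeric matrix
#'   (rows = datasets, columns = methods).
#' @param metric which averaged metric to rank (default `"g_mean"`).
#' @param alpha Nemenyi significance level (default 0.05).
#' @return a `rank_summary` with CD attached; the score table is in field
#'   `scores`.
#' @export
compare_methods <- function(reports, metric = "g_mean", alpha = 0.05) {
  if (is.matrix(reports)) {
    tab <- reports
  } else {
    stopifnot(length(reports) >= 2, !is.null(names(reports)))
    meth_sets <- lapply(reports, function(r) sort(r$summary$method))
    if (length(unique(vapply(meth_sets, paste, "", collapse = ","))) != 1) {
      stop_pgm("reports do not share a common method set",
               class = "pgmelm_alignment_error")
    }
    tab <- t(vapply(reports, function(r) {
      stats::setNames(r$summary[[metric]], r$summary$method)
    }, stats::setNames(numeric(length(meth_sets[[1]])), meth_sets[[1]])))
  }
  out <- add_nemenyi(friedman_rank_test(tab), alpha)
  out$scores <- tab
  out
}

#' Write an experiment report to disk
#'
#' Serializes the per-trial results as CSV and the summary plus full
#' configuration as JSON.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem (default `"experiment"`).
#' @return character vector of the two paths written, invisibly.
#' @export
write_experiment <- function(report, dir, stem = "experiment") {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_trials.csv"))
  js <- file.path(dir, paste0(stem, "_summary.json"))
  utils::write.csv(report$results, csv, row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary, config = report$config),
                       js, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(c(csv, js))
}
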