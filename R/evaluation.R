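stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < n_folds && length(idx) < 2) {
      stop_user("stratification failure: class '", cls,
                "' too small; try fewer folds")
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

rank_auc <- function(score, label) {
  # Mann-Whitney form; equals the trapezoidal ROC AUC (ties averaged)
  pos <- score[label == 1]
  neg <- score[label == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated ROC evaluation of a biomarker panel
#'
#' Relative abundances of the panel taxa are the features; samples are
#' split into stratified folds, a logistic scorer is fit on each training
#' split, and held-out scores are pooled into a single trapezoidal ROC
#' AUC (per-fold AUCs are also reported).
#'
#' @param table a [count_table].
#' @param metadata aligned metadata with a two-level `group`.
#' @param panel character vector of taxon IDs (must be taxa of the table).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return list(auc, fold_aucs, mean_fold_auc, n_folds, panel, seed,
#'   roc_points) where `roc_points` holds the pooled ROC curve as
#'   (fpr, tpr) pairs.
#' @export
netroc <- function(table, metadata, panel, n_folds = 10L, seed = NULL) {
  al <- align_samples(table, metadata)
  missing <- setdiff(panel, taxon_ids(al$table))
  if (length(missing)) stop_user("panel taxa absent from table: ",
                                 paste(utils::head(missing, 5), collapse = ", "))
  y <- as.integer(al$metadata$group == "stress")
  if (length(unique(y)) < 2) stop_user("both classes must be present")
  n <- length(y)
  if (n < n_folds) stop_user("more folds than samples; try fewer folds")
  X <- relative_abundance(al$table)[, panel, drop = FALSE]
  with_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    pooled <- rep(NA_real_, n)
    fold_aucs <- rep(NA_real_, n_folds)
    for (k in seq_len(n_folds)) {
      test <- fold == k
      if (length(unique(y[test])) < 2) {
        stop_user("fold ", k, " contains a single class; try fewer folds")
      }
      df_tr <- data.frame(y = y[!test], X[!test, , drop = FALSE])
      df_te <- data.frame(X[test, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                         family = stats::binomial()))
      pooled[test] <- suppressWarnings(
        stats::predict(fit, newdata = df_te, type = "response"))
      fold_aucs[k] <- rank_auc(pooled[test], y[test])
    }
    roc_obj <- pROC::roc(response = y, predictor = pooled,
                         levels = c(0, 1), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc_obj))
    pts <- data.frame(fpr = rev(1 - roc_obj$specificities),
                      tpr = rev(roc_obj$sensitivities))
    list(auc = auc, fold_aucs = fold_aucs, mean_fold_auc = mean(fold_aucs),
         n_folds = as.integer(n_folds), panel = panel, seed = seed,
         roc_points = pts)
  })
}

#' Benchmark biomarker scores against synthetic ground truth
#'
#' Precision and recall of the `q < alpha` call set against the planted
#' drivers, plus the rank AUC of the score against the driver indicator.
#'
#' @param scores biomarker data.frame with `taxon`, `nmss` and optionally
#'   `q_value`.
#' @param truth ground-truth list from [simulate_counts] (uses
#'   `truth$drivers`).
#' @param alpha significance level for the call set (default 0.05).
#' @return data.frame(metric, value) with precision, recall, rank_auc,
#'   n_called, n_drivers.
#' @export
benchmark_against_truth <- function(scores, truth, alpha = 0.05) {
  if (is.null(truth$drivers)) stop_user("ground truth with drivers required")
  is_driver <- as.integer(scores$taxon %in% truth$drivers)
  called <- if ("q_value" %in% names(scores)) {
    !is.na(scores$q_value) & scores$q_value < alpha
  } else {
    rep(FALSE, nrow(scores))
  }
  tp <- sum(called & is_driver == 1)
  precision <- if (sum(called)) tp / sum(called) else NA_real_
  recall <- if (sum(is_driver)) tp / sum(is_driver) else NA_real_
  auc <- rank_auc(scores$nmss[!is.na(scores$nmss)],
                  is_driver[!is.na(scores$nmss)])
  data.frame(metric = c("precision", "recall", "rank_auc", "n_called", "n_drivers"),
             value = c(precision, recall, auc, sum(called), sum(is_driver)),
             stringsAsFactors = FALSE)
}
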