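#' Confusion counts with drowsy as the positive class
#'
#' @param truth,predicted Character vectors over \code{{alert, drowsy}}.
#' @return List with integer fields \code{tp}, \code{fn}, \code{tn},
#'   \code{fp} (a drowsy epoch predicted drowsy is a true positive).
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  ok <- c("alert", "drowsy")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'alert' or 'drowsy'", call. = FALSE)
  }
  list(
    tp = sum(truth == "drowsy" & predicted == "drowsy"),
    fn = sum(truth == "drowsy" & predicted == "alert"),
    tn = sum(truth == "alert" & predicted == "alert"),
    fp = sum(truth == "alert" & predicted == "drowsy")
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' TPR = TP/(TP+FN), TNR = TN/(TN+FP) and
#' accuracy = (TP+TN)/(TP+TN+FP+FN), all reported as percentages at full
#' precision (round only for display). A metric whose denominator is
#' zero is returned as \code{NA} and named in the \code{undefined}
#' field rather than silently propagating NaN.
#'
#' @param counts List or vector with fields \code{tp, fn, tn, fp}.
#' @return List with \code{tpr}, \code{tnr}, \code{accuracy} (percent)
#'   and \code{undefined} (character vector of undefined metrics).
#' @export
classification_metrics <- function(counts) {
  c_ <- lapply(counts[c("tp", "fn", "tn", "fp")], as.numeric)
  if (any(vapply(c_, function(v) length(v) != 1 || !is.finite(v) || v < 0,
                 logical(1)))) {
    stop("counts must be non-negative numbers tp, fn, tn, fp", call. = FALSE)
  }
  total <- c_$tp + c_$fn + c_$tn + c_$fp
  if (total < 1) stop("empty confusion table", call. = FALSE)
  undefined <- character(0)
  tpr <- if (c_$tp + c_$fn > 0) 100 * c_$tp / (c_$tp + c_$fn) else {
    undefined <- c(undefined, "tpr"); NA_real_
  }
  tnr <- if (c_$tn + c_$fp > 0) 100 * c_$tn / (c_$tn + c_$fp) else {
    undefined <- c(undefined, "tnr"); NA_real_
  }
  list(tpr = tpr, tnr = tnr, accuracy = 100 * (c_$tp + c_$tn) / total,
       undefined = undefined)
}

#' Stratified k-fold cross-validation for one subject
#'
#' Splits one subject's feature rows into k stratified folds (per-fold
#' class proportions within one row of the overall proportions), trains
#' the MLP — including the hidden-size sweep — on each set of k-1 folds,
#' predicts the held-out fold, and accumulates confusion counts. Both
#' per-fold metrics and pooled-count metrics are reported: the fold
#' average and the pooled estimate can differ when folds are uneven, so
#' both are labeled explicitly.
#'
#' @param rows Feature rows for one subject (both classes present).
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving fold assignment and training.
#' @param ... Passed to [train_drowsiness_mlp()] (e.g. \code{hidden_sizes}).
#' @return An \code{eval_report}: list with \code{subject_id}, \code{k},
#'   \code{seed}, \code{per_fold} (data frame of counts and metrics),
#'   \code{pooled} counts, \code{pooled_metrics}, \code{fold_mean_metrics}
#'   and \code{predictions} (row-aligned predicted labels).
#' @export
kfold <- function(rows, k = 10L, seed = 1L, ...) {
  stopifnot(is.data.frame(rows), "label" %in% names(rows))
  n <- nrow(rows)
  if (n < k) {
    stop(sprintf("only %d rows for k = %d folds; use a smaller k", n, k),
         call. = FALSE)
  }
  labels <- as.character(rows$label)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present for cross-validation", call. = FALSE)
  }
  folds <- stratified_folds(labels, k, derive_seed(seed, 9000L))
  predicted <- character(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- train_drowsiness_mlp(rows[!test, , drop = FALSE],
                                  seed = derive_seed(seed, f), ...)
    pred <- predict_drowsiness(model, rows[test, , drop = FALSE])
    predicted[test] <- pred$label
    cc <- confusion_counts(labels[test], pred$label)
    m <- classification_metrics(cc)
    per_fold[[f]] <- data.frame(
      fold = f, tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
      tpr = m$tpr, tnr = m$tnr, accuracy = m$accuracy
    )
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- list(tp = sum(per_fold$tp), fn = sum(per_fold$fn),
                 tn = sum(per_fold$tn), fp = sum(per_fold$fp))
  structure(
    list(
      subject_id = as.character(rows$subject_id[1] %||% "unknown"),
      k = as.integer(k), seed = as.integer(seed),
      per_fold = per_fold,
      pooled = pooled,
      pooled_metrics = classification_metrics(pooled),
      fold_mean_metrics = list(
        tpr = mean(per_fold$tpr, na.rm = TRUE),
        tnr = mean(per_fold$tnr, na.rm = TRUE),
        accuracy = mean(per_fold$accuracy)
      ),
      predictions = predicted
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$pooled_metrics
  cat(sprintf("<eval_report> subject %s, %d-fold CV (seed %d): TPR %.2f%%, TNR %.2f%%, accuracy %.2f%% (pooled)\n",
              x$subject_id, x$k, x$seed, m$tpr, m$tnr, m$accuracy))
  invisible(x)
}

#' Cohort-level averages of per-subject metrics
#'
#' Unweighted arithmetic means of the per-subject TPR, TNR and accuracy
#' values — each subject counts equally regardless of epoch count, the
#' convention for per-subject performance tables of person-dependent
#' classifiers.
#'
#' @param reports Either a list of [kfold()] reports (pooled metrics are
#'   averaged) or a data frame with per-subject columns among
#'   \code{tpr}, \code{tnr}, \code{accuracy}.
#' @return List with \code{mean_tpr}, \code{mean_tnr},
#'   \code{mean_accuracy}, \code{n_subjects} and the \code{per_subject}
#'   data frame that was averaged.
#' @export
cohort_summary <- function(reports) {
  if (is.data.frame(reports)) {
    df <- reports
  } else {
    if (!is.list(reports) || length(reports) == 0) {
      stop("need at least one evaluation report", call. = FALSE)
    }
    df <- do.call(rbind, lapply(reports, function(r) {
      stopifnot(inherits(r, "eval_report"))
      data.frame(subject_id = r$subject_id,
                 tpr = r$pooled_metrics$tpr,
                 tnr = r$pooled_metrics$tnr,
                 accuracy = r$pooled_metrics$accuracy,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0) stop("need at least one subject row", call. = FALSE)
  mean_of <- function(col) if (col %in% names(df)) mean(df[[col]]) else NA_real_
  list(mean_tpr = mean_of("tpr"), mean_tnr = mean_of("tnr"),
       mean_accuracy = mean_of("accuracy"),
       n_subjects = nrow(df), per_subject = df)
}

#' Write an evaluation report as CSV
#'
#' One row per fold plus a final \code{pooled} row, mirroring the
#' per-subject performance-table columns (TPR, TNR, accuracy).
#'
#' @param report An [kfold()] report.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  pf <- report$per_fold
  pooled <- data.frame(
    fold = "pooled", tp = report$pooled$tp, fn = report$pooled$fn,
    tn = report$pooled$tn, fp = report$pooled$fp,
    tpr = report$pooled_metrics$tpr, tnr = report$pooled_metrics$tnr,
    accuracy = report$pooled_metrics$accuracy
  )
  pf$fold <- as.character(pf$fold)
  out <- rbind(pf, pooled)
  out <- cbind(subject_id = report$subject_id, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
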