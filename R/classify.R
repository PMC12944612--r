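mlp_feature_names <- c("p_iaf", "p_tf", "p_3hz", "p_4hz", "ratio_r")

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin over k folds, so per-fold class proportions match the
# overall proportions to within one row. Returns an integer fold id per row.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

feature_matrix <- function(rows) {
  missing_cols <- setdiff(mlp_feature_names, names(rows))
  if (length(missing_cols)) {
    stop(sprintf("feature rows lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(rows[mlp_feature_names])
  if (any(!is.finite(m))) stop("non-finite feature value", call. = FALSE)
  m
}

fit_mlp_once <- function(x, y01, size, seed, decay, maxit) {
  with_local_seed(seed, {
    nnet::nnet(x = x, y = y01, size = size, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE)
  })
}

#' Train the per-subject drowsiness MLP
#'
#' Fits a single-hidden-layer perceptron (5 spectral features in, one
#' drowsiness score out) for one subject, sweeping the hidden-layer size
#' over \code{hidden_sizes} (default 5, 10, 15, 20, 25 neurons). For each
#' candidate size the internal stratified cross-validation accuracy on
#' the training rows is computed; the size with the highest accuracy
#' wins, with ties going to the smaller network, and the winner is refit
#' on all rows. Features are z-scored with center/scale learned from the
#' training rows only and stored inside the model, so no scaling
#' information leaks across folds.
#'
#' The network's sigmoid output is mapped to a score in (-1, 1)
#' (an affine relabeling of the logistic output onto a tanh-type scale);
#' class coding is alert = -1, drowsy = +1 and the decision threshold
#' defaults to 0.
#'
#' @param rows Feature rows for one subject (data frame with columns
#'   \code{p_iaf, p_tf, p_3hz, p_4hz, ratio_r} and \code{label}).
#' @param hidden_sizes Candidate hidden-layer sizes.
#' @param seed Integer seed; fixes initial weights and internal fold
#'   assignment, making training deterministic.
#' @param decision_threshold Score threshold for predicting drowsy
#'   (default 0; a score exactly at the threshold predicts alert).
#' @param decay,maxit Weight decay and iteration cap passed to the
#'   optimizer.
#' @param inner_k Folds for the internal size-selection CV (default 3).
#' @return A \code{drowsiness_mlp} model object.
#' @export
train_drowsiness_mlp <- function(rows, hidden_sizes = c(5L, 10L, 15L, 20L, 25L),
                                 seed = 1L, decision_threshold = 0,
                                 decay = 1e-3, maxit = 300, inner_k = 3L) {
  stopifnot(is.data.frame(rows), "label" %in% names(rows))
  labels <- as.character(rows$label)
  tab <- table(factor(labels, levels = c("alert", "drowsy")))
  if (any(tab == 0)) {
    stop("cannot train one-class model: need both alert and drowsy rows",
         call. = FALSE)
  }
  if (any(tab < 2)) {
    stop("need at least 2 rows per class to train", call. = FALSE)
  }
  if (length(unique(rows$subject_id %||% "one")) > 1) {
    stop("train on a single subject's rows (the model is person-dependent)",
         call. = FALSE)
  }
  hidden_sizes <- sort(unique(as.integer(hidden_sizes)))
  x <- feature_matrix(rows)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)
  y01 <- as.numeric(labels == "drowsy")

  k <- min(inner_k, min(tab))
  folds <- stratified_folds(labels, k, derive_seed(seed, 0L))
  cv_acc <- vapply(seq_along(hidden_sizes), function(si) {
    h <- hidden_sizes[si]
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_mlp_once(xs[tr, , drop = FALSE], y01[tr], h,
                          derive_seed(seed, si * 100L + f), decay, maxit)
      p <- as.numeric(stats::predict(fit, xs[!tr, , drop = FALSE]))
      pred <- (2 * p - 1) > decision_threshold
      correct <- correct + sum(pred == (y01[!tr] == 1))
    }
    correct / length(y01)
  }, numeric(1))

  best <- hidden_sizes[which.max(cv_acc)]  # ties -> first, i.e. smallest size
  fit <- fit_mlp_once(xs, y01, best, derive_seed(seed, 1L), decay, maxit)

  structure(
    list(
      format_version = 1L,
      subject_id = as.character(rows$subject_id[1] %||% "unknown"),
      hidden_size = best,
      sweep = data.frame(hidden_size = hidden_sizes, cv_accuracy = cv_acc),
      fit = fit,
      center = center, scale = scale_,
      decision_threshold = decision_threshold,
      seed = as.integer(seed)
    ),
    class = "drowsiness_mlp"
  )
}

#' @export
print.drowsiness_mlp <- function(x, ...) {
  cat(sprintf("<drowsiness_mlp> subject %s: %d hidden neurons (swept %s), threshold %g\n",
              x$subject_id, x$hidden_size,
              paste(x$sweep$hidden_size, collapse = "/"), x$decision_threshold))
  invisible(x)
}

#' Predict vigilance state for feature rows
#'
#' Applies the model's stored z-scaling and network to each row
#' independently: a score above the decision threshold predicts
#' \code{drowsy}, otherwise (including exactly at the threshold)
#' \code{alert}.
#'
#' @param model A [train_drowsiness_mlp()] model.
#' @param rows Feature rows (data frame with the five feature columns).
#' @return Data frame with columns \code{label} and \code{score}
#'   (score in (-1, 1)).
#' @export
predict_drowsiness <- function(model, rows) {
  stopifnot(inherits(model, "drowsiness_mlp"))
  x <- feature_matrix(rows)
  xs <- scale(x, center = model$center, scale = model$scale)
  score <- 2 * as.numeric(stats::predict(model$fit, xs)) - 1
  data.frame(
    label = ifelse(score > model$decision_threshold, "drowsy", "alert"),
    score = score,
    stringsAsFactors = FALSE
  )
}

#' Save / load a trained model
#'
#' Single-file serialization with a versioned header; [load_model()]
#' refuses files that were not written by [save_model()] or carry an
#' unknown format version.
#'
#' @param model A \code{drowsiness_mlp}.
#' @param path File path.
#' @return [load_model()] returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "drowsiness_mlp"))
  saveRDS(list(magic = "drowseeg-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("%s: not a drowseeg model file", path), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$magic, "drowseeg-model")) {
    stop(sprintf("%s: not a drowseeg model file", path), call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop(sprintf("%s: unsupported model format version %s", path, obj$version),
         call. = FALSE)
  }
  obj$model
}
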