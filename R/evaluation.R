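#' Confusion-matrix metrics for binary classification
#'
#' Computes TP/TN/FP/FN and the four standard metrics: sensitivity
#' `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, overall accuracy
#' `ACC = (TP+TN)/total`, and their geometric mean `GM = sqrt(SN * SP)`.
#' GM is the headline metric under class imbalance: with few positives,
#' ACC is dominated by (and nearly equal to) SP, while GM collapses as
#' soon as either class is neglected.
#'
#' @param y_true True labels; both classes must be present (otherwise the
#'   dependent metric is undefined and an error names it).
#' @param y_pred Predicted labels, same length and label set.
#' @param positive Label of the positive class. Defaults to the second
#'   factor level of `y_true` (or the alphabetically larger of the two
#'   labels).
#' @return An `eval_report`: list with `tp`, `tn`, `fp`, `fn`, `sn`,
#'   `sp`, `gm`, `acc`, `positive` and `n`.
#' @examples
#' truth <- factor(rep(c("neg", "pos"), c(4, 4)))
#' pred <- factor(c("neg", "neg", "neg", "pos", "pos", "pos", "pos", "neg"))
#' confusion_metrics(truth, pred)
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if (is.factor(y_true)) {
      levels(y_true)[nlevels(y_true)]
    } else {
      max(unique(as.character(y_true)))
    }
  }
  yt <- as.character(y_true) == positive
  yp <- as.character(y_pred) == positive
  if (!any(yt)) {
    stop("sensitivity undefined: no positive ('", positive,
      "') samples in y_true",
      call. = FALSE
    )
  }
  if (all(yt)) {
    stop("specificity undefined: no negative samples in y_true",
      call. = FALSE
    )
  }
  tp <- sum(yt & yp)
  fn <- sum(yt & !yp)
  tn <- sum(!yt & !yp)
  fp <- sum(!yt & yp)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn,
      sn = sn, sp = sp, gm = sqrt(sn * sp),
      acc = (tp + tn) / length(yt),
      positive = positive, n = length(yt)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation (%d samples, positive = '%s')\n", x$n, x$positive
  ))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf(
    "  SN %.3f  SP %.3f  GM %.3f  ACC %.3f\n",
    x$sn, x$sp, x$gm, x$acc
  ))
  if (!is.null(x$folds)) {
    cat(" ", length(x$folds), "folds; per-fold GM:",
      paste(sprintf("%.3f", vapply(x$folds, `[[`, 0, "gm")),
        collapse = " "
      ), "\n"
    )
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of a model pipeline
#'
#' Assigns samples to `folds` stratified folds by seed, fits the pipeline
#' on each training split, predicts the held-out split, and pools the
#' held-out predictions into a single [confusion_metrics()] report with a
#' per-fold breakdown. Everything the pipeline does — including any
#' resampling configured inside it — happens on the training split only,
#' so the held-out metrics are never contaminated by synthetic copies of
#' test samples.
#'
#' @param spec A pipeline specification: list with `fit(X, y, seed)`
#'   returning a model and `predict(model, X)` returning labels; see
#'   [ensemble_pipeline()].
#' @param X Numeric feature matrix.
#' @param y Binary labels; each class must have at least `folds` members.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment and per-fold fits.
#' @param positive Positive-class label (default: second factor level).
#' @return An `eval_report` with a `folds` element (per-fold reports) and
#'   a `fold_id` element (the assignment).
#' @export
crossvalidate <- function(spec, X, y, folds = 10L, seed = 1L,
                          positive = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (folds < 2L) stop("folds must be at least 2", call. = FALSE)
  counts <- table(y)
  if (min(counts) < folds) {
    stop(
      "class '", names(counts)[which.min(counts)], "' has ",
      min(counts), " members: fewer than folds = ", folds,
      call. = FALSE
    )
  }
  if (is.null(positive)) positive <- levels(y)[2L]
  fold_id <- with_seed(seed, stratified_folds(y, folds))
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    model <- spec$fit(X[!test, , drop = FALSE], y[!test], seed + f)
    pred[test] <- as.character(
      spec$predict(model, X[test, , drop = FALSE])
    )
  }
  report <- confusion_metrics(y, pred, positive = positive)
  report$folds <- lapply(seq_len(folds), function(f) {
    confusion_metrics(y[fold_id == f], pred[fold_id == f],
      positive = positive
    )
  })
  report$fold_id <- fold_id
  report
}

#' Pipeline specification: optional resampling + selective ensemble
#'
#' Packages the training recipe used by [crossvalidate()]: optionally
#' rebalance the training data with [hybrid_resample()], then fit
#' [train_ensemble()]. When a `plan` is given, its seed is offset by the
#' per-fold seed so folds are resampled independently but reproducibly.
#'
#' @param plan A [resampling_plan()], or `NULL` for no resampling.
#' @param pool Learner pool (default [default_learner_pool()]).
#' @param K,target_accuracy,step,mode,folds Passed to [train_ensemble()].
#' @param positive Positive-class label passed through to prediction.
#' @return A list with `fit(X, y, seed)` and `predict(model, X)`.
#' @export
ensemble_pipeline <- function(plan = NULL, pool = default_learner_pool(),
                              K = 9L, target_accuracy = 1, step = 0.05,
                              mode = "out_of_fold", folds = 5L,
                              positive = NULL) {
  list(
    fit = function(X, y, seed = 1L) {
      if (!is.null(plan)) {
        fold_plan <- plan
        fold_plan$seed <- plan$seed + seed
        rs <- hybrid_resample(X, y, fold_plan)
        X <- rs$X
        y <- rs$y
      }
      train_ensemble(X, y,
        pool = pool, K = K,
        target_accuracy = target_accuracy, step = step,
        mode = mode, folds = folds, seed = seed,
        positive = positive
      )
    },
    predict = function(model, X) predict(model, X)$label,
    positive = positive
  )
}
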