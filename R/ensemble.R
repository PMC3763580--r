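# Stratified fold assignment (1..k per sample). Uses the ambient RNG;
# callers are expected to wrap in with_seed().
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit a learner pool and record its correctness pattern
#'
#' Fits every learner in `pool` on `(X, y)` and builds the binary result
#' matrix `R`: `R[i, j] = 1` iff learner `i` classified training sample
#' `j` correctly. With `mode = "out_of_fold"` (default) the correctness
#' flags come from internal stratified cross-validation predictions, so
#' memorising learners (e.g. 1-nearest-neighbour) are not credited with
#' perfect rows; `mode = "resubstitution"` scores each learner on the
#' very samples it was fitted on.
#'
#' A learner whose fit fails is dropped from the pool with a warning; at
#' least two learners must survive.
#'
#' @param pool Named list of [base_learner()] objects.
#' @param X Numeric feature matrix.
#' @param y Binary labels (coerced to a two-level factor).
#' @param mode `"out_of_fold"` or `"resubstitution"`.
#' @param folds Internal folds for out-of-fold mode (default 5; reduced
#'   automatically if a class is smaller).
#' @param seed Integer seed covering fold assignment and any stochastic
#'   learners.
#' @return A `result_matrix` object: list with `R` (0/1 matrix, one row
#'   per surviving learner), `fits` (full-data fitted models),
#'   `accuracy` (row means of `R`) and `levels`.
#' @export
build_result_matrix <- function(pool, X, y,
                                mode = c("out_of_fold", "resubstitution"),
                                folds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) {
    stop("y must have exactly two classes", call. = FALSE)
  }
  n <- length(y)
  counts <- table(y)
  if (mode == "out_of_fold" && min(counts) < 2L) {
    warning("a class has < 2 members; falling back to resubstitution",
      call. = FALSE
    )
    mode <- "resubstitution"
  }

  with_seed(seed, {
    fits <- list()
    preds <- list()
    failed <- character()
    fold <- if (mode == "out_of_fold") {
      stratified_folds(y, min(folds, min(counts)))
    }
    for (lrn in pool) {
      ok <- TRUE
      fit <- tryCatch(lrn$fit(X, y), error = function(e) {
        ok <<- FALSE
        e
      })
      if (!ok) {
        warning("learner '", lrn$name, "' failed to fit: ",
          conditionMessage(fit), "; excluded from pool",
          call. = FALSE
        )
        failed <- c(failed, lrn$name)
        next
      }
      p <- tryCatch(
        if (mode == "resubstitution") {
          as.character(lrn$predict(fit, X))
        } else {
          out <- character(n)
          for (f in unique(fold)) {
            m <- lrn$fit(X[fold != f, , drop = FALSE], y[fold != f])
            out[fold == f] <-
              as.character(lrn$predict(m, X[fold == f, , drop = FALSE]))
          }
          out
        },
        error = function(e) e
      )
      if (inherits(p, "error")) {
        warning("learner '", lrn$name, "' failed to predict: ",
          conditionMessage(p), "; excluded from pool",
          call. = FALSE
        )
        failed <- c(failed, lrn$name)
        next
      }
      fits[[lrn$name]] <- fit
      preds[[lrn$name]] <- p
    }
    if (length(fits) < 2L) {
      stop("fewer than 2 learners survived fitting", call. = FALSE)
    }
    R <- do.call(rbind, lapply(preds, function(p) as.integer(p == y)))
    rownames(R) <- names(preds)
    structure(
      list(
        R = R, fits = fits, accuracy = rowMeans(R),
        levels = levels(y), mode = mode, excluded = failed
      ),
      class = "result_matrix"
    )
  })
}

#' Cluster base learners by their correctness patterns
#'
#' Treats each learner's row of the result matrix as a point in `{0,1}^m`
#' and clusters the rows with K-means (`K_eff = min(K, pool size)`).
#' Learners that succeed and fail on the same samples land in the same
#' cluster, so picking one candidate per cluster yields a behaviourally
#' diverse slate.
#'
#' @param R Binary result matrix (learners x samples), e.g.
#'   `build_result_matrix(...)$R`.
#' @param K Requested number of clusters (default 9).
#' @param seed Integer seed for the K-means initialization.
#' @return Named integer vector of cluster ids, one per learner.
#' @export
cluster_classifiers <- function(R, K = 9L, seed = 1L) {
  if (is.null(dim(R)) || nrow(R) == 0L || ncol(R) == 0L) {
    stop("R must be a nonempty learner x sample matrix", call. = FALSE)
  }
  K_eff <- min(K, nrow(R))
  km <- kmeans_lloyd(R * 1, K = K_eff, iter = 25L, seed = seed)
  stats::setNames(km$assignment, rownames(R))
}

#' Majority-vote committee accuracy from a result matrix
#'
#' For binary classification a committee's vote on sample `j` is correct
#' exactly when more than half its members are correct on `j` (a wrong
#' member necessarily votes for the one other class). Split votes on an
#' even committee follow the most accurate member.
#'
#' @param R Binary result matrix.
#' @param members Row names or indices of the committee.
#' @param accuracy Per-learner accuracies used for tie-breaking
#'   (default: row means of `R`).
#' @return Fraction of samples the committee votes correctly.
#' @export
committee_accuracy <- function(R, members, accuracy = rowMeans(R)) {
  mean(committee_correct(R, members, accuracy))
}

committee_correct <- function(R, members, accuracy = rowMeans(R)) {
  if (is.character(members)) members <- match(members, rownames(R))
  sub <- R[members, , drop = FALSE]
  votes <- colSums(sub)
  nm <- length(members)
  correct <- votes > nm / 2
  tie <- votes == nm / 2
  if (any(tie)) {
    best <- members[which.max(accuracy[members])]
    correct[tie] <- R[best, tie] == 1
  }
  correct
}

# Mean pairwise agreement: fraction of samples on which two members'
# correctness flags coincide, averaged over member pairs. A singleton
# committee has agreement 1 by convention, so any genuinely different
# second member lowers it.
mean_pairwise_agreement <- function(R, members) {
  if (is.character(members)) members <- match(members, rownames(R))
  nm <- length(members)
  if (nm < 2L) {
    return(1)
  }
  pairs <- utils::combn(members, 2L)
  mean(apply(pairs, 2L, function(p) mean(R[p[1L], ] == R[p[2L], ])))
}

#' Select a voting committee by circulating forward selection (CEFS)
#'
#' From each correctness-pattern cluster the most accurate learner is
#' nominated; candidates are sorted by descending accuracy and the best
#' seeds the committee. Each remaining candidate joins only if it
#' strictly raises the committee's majority-vote accuracy *and* strictly
#' lowers mean pairwise agreement (i.e. adds a genuinely complementary
#' error profile). Passes over the candidates circulate until the
#' committee accuracy reaches the current target; an unmet target is
#' relaxed by `step` and the circulation resumes, stopping once the
#' target falls to the best accuracy achieved or no candidates remain.
#'
#' @param clusters Named cluster assignment from [cluster_classifiers()].
#' @param R Binary result matrix the clusters were derived from.
#' @param target_accuracy Initial committee-accuracy goal (default 1).
#' @param step Relaxation applied to an unmet target (default 0.05).
#' @return A `cefs_selection`: list with `cc` (committee member names in
#'   order of admission), `achieved_accuracy`, `agreement`,
#'   `final_target`, `accuracy` (per-learner) and `candidates`.
#' @export
cefs_select <- function(clusters, R, target_accuracy = 1, step = 0.05) {
  acc <- rowMeans(R)
  cand <- integer()
  for (cl in sort(unique(clusters))) {
    members <- which(clusters == cl)
    cand <- c(cand, members[which.max(acc[members])])
  }
  if (length(cand) == 0L) stop("empty candidate list", call. = FALSE)
  cand <- cand[order(-acc[cand], cand)]

  cc <- cand[1L]
  remaining <- cand[-1L]
  cur_acc <- committee_accuracy(R, cc, acc)
  cur_agr <- 1
  target <- target_accuracy

  while (cur_acc < target) {
    repeat {
      added <- FALSE
      for (cd in remaining) {
        trial <- c(cc, cd)
        t_acc <- committee_accuracy(R, trial, acc)
        t_agr <- mean_pairwise_agreement(R, trial)
        if (t_acc > cur_acc && t_agr < cur_agr) {
          cc <- trial
          cur_acc <- t_acc
          cur_agr <- t_agr
          remaining <- setdiff(remaining, cd)
          added <- TRUE
        }
        if (cur_acc >= target) break
      }
      if (!added || cur_acc >= target) break
    }
    if (cur_acc >= target) break
    target <- target - step
    if (target < cur_acc || length(remaining) == 0L || target < 0) {
      break
    }
  }

  structure(
    list(
      cc = rownames(R)[cc],
      achieved_accuracy = cur_acc,
      agreement = cur_agr,
      final_target = target,
      accuracy = acc,
      candidates = rownames(R)[cand]
    ),
    class = "cefs_selection"
  )
}

#' Train the selective voting ensemble
#'
#' End-to-end training: fit the learner pool and its result matrix
#' ([build_result_matrix()]), cluster the correctness patterns
#' ([cluster_classifiers()]), and pick the voting committee
#' ([cefs_select()]). The returned model predicts by majority vote of the
#' committee, exposing the positive-vote share as a confidence score.
#'
#' @inheritParams build_result_matrix
#' @param K Initial number of correctness-pattern clusters (default 9).
#' @param target_accuracy,step CEFS schedule (defaults 1 and 0.05).
#' @param positive Label treated as the positive class (default: second
#'   factor level of `y`).
#' @return A `selective_ensemble` model.
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- matrix(rnorm(120), 60, 2)
#' y <- factor(ifelse(X[, 1] + rnorm(60, sd = .3) > 0, "pos", "neg"))
#' fit <- train_ensemble(X, y, seed = 7)
#' predict(fit, X[1:3, ])
#' }
#' @export
train_ensemble <- function(X, y, pool = default_learner_pool(), K = 9L,
                           target_accuracy = 1, step = 0.05,
                           mode = c("out_of_fold", "resubstitution"),
                           folds = 5L, seed = 1L, positive = NULL) {
  y <- factor(y)
  if (is.null(positive)) positive <- levels(y)[2L]
  rm <- build_result_matrix(pool, X, y,
    mode = mode, folds = folds,
    seed = seed
  )
  clusters <- cluster_classifiers(rm$R, K = K, seed = seed + 1L)
  sel <- cefs_select(clusters, rm$R,
    target_accuracy = target_accuracy,
    step = step
  )
  structure(
    list(
      fits = rm$fits,
      pool = pool[names(rm$fits)],
      cc = sel$cc,
      selection = sel,
      learner_accuracy = rm$accuracy,
      levels = rm$levels,
      positive = positive,
      mode = rm$mode,
      K = K,
      seed = seed
    ),
    class = "selective_ensemble"
  )
}

#' Predict with a trained selective ensemble
#'
#' Each committee member votes; the label is the majority vote and
#' `vote_fraction` the share of members voting for the positive class —
#' usable as a prediction probability. An even split follows the
#' committee member with the highest training accuracy.
#'
#' @param object A `selective_ensemble` from [train_ensemble()].
#' @param newdata Numeric feature matrix with the training columns.
#' @param ... Unused.
#' @return Data frame with columns `id`, `label` (factor on the training
#'   levels) and `vote_fraction`.
#' @export
predict.selective_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (length(object$cc) == 0L) stop("model has an empty committee")
  votes <- vapply(
    object$cc,
    function(nm) {
      as.character(object$pool[[nm]]$predict(object$fits[[nm]], newdata)) ==
        object$positive
    },
    logical(nrow(newdata))
  )
  votes <- matrix(votes, nrow = nrow(newdata)) # n x |CC|
  frac <- rowMeans(votes)
  lab <- ifelse(frac > 0.5, object$positive,
    setdiff(object$levels, object$positive)
  )
  tie <- frac == 0.5
  if (any(tie)) {
    best <- object$cc[which.max(object$learner_accuracy[object$cc])]
    neg <- setdiff(object$levels, object$positive)
    lab[tie] <- ifelse(votes[tie, match(best, object$cc)],
      object$positive, neg
    )
  }
  data.frame(
    id = if (is.null(rownames(newdata))) {
      seq_len(nrow(newdata))
    } else {
      rownames(newdata)
    },
    label = factor(lab, levels = object$levels),
    vote_fraction = frac,
    stringsAsFactors = FALSE
  )
}

#' @export
print.selective_ensemble <- function(x, ...) {
  cat("Selective voting ensemble\n")
  cat("  pool:", length(x$fits), "fitted learners (", x$mode, "results )\n")
  cat(
    "  committee:", paste(x$cc, collapse = ", "),
    sprintf(
      "\n  committee accuracy on result matrix: %.3f\n",
      x$selection$achieved_accuracy
    )
  )
  invisible(x)
}
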