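#' Define a base learner
#'
#' A base learner is a named pair of closures: `fit(X, y)` returning a
#' fitted object and `predict(model, X)` returning a label per row of `X`.
#' `y` is always a two-level factor; predictions may be returned as factor
#' or character, using the same labels.
#'
#' @param name Unique learner name.
#' @param fit Function `(X, y) -> model`.
#' @param predict Function `(model, X) -> labels`.
#' @return A `base_learner` object.
#' @seealso [default_learner_pool()]
#' @export
base_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
    class = "base_learner"
  )
}

# Stable, syntactic column names shared by fit and predict wrappers so
# learners that go through formulas/data frames see identical variables.
as_learn_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df
}

svm_learner <- function(name, kernel) {
  base_learner(
    name,
    fit = function(X, y) e1071::svm(X, y, kernel = kernel, scale = FALSE),
    predict = function(m, X) stats::predict(m, X)
  )
}

rpart_learner <- function(name, split = "gini", maxdepth = 30L,
                          cp = 0.01, minsplit = 20L) {
  ctl <- rpart::rpart.control(
    maxdepth = maxdepth, cp = cp,
    minsplit = minsplit, xval = 0L
  )
  base_learner(
    name,
    fit = function(X, y) {
      rpart::rpart(.y ~ .,
        data = cbind(.y = y, as_learn_df(X)),
        method = "class", control = ctl,
        parms = list(split = split)
      )
    },
    predict = function(m, X) {
      stats::predict(m, as_learn_df(X), type = "class")
    }
  )
}

knn_learner <- function(name, k) {
  base_learner(
    name,
    fit = function(X, y) list(X = X, y = y, k = min(k, nrow(X))),
    predict = function(m, X) {
      class::knn(m$X, X, m$y, k = m$k, use.all = TRUE)
    }
  )
}

ranger_learner <- function(name, num.trees, mtry_frac = NULL) {
  base_learner(
    name,
    fit = function(X, y) {
      mtry <- if (is.null(mtry_frac)) NULL else max(1L, floor(sqrt(ncol(X))))
      ranger::ranger(
        x = as_learn_df(X), y = y,
        num.trees = num.trees, mtry = mtry,
        num.threads = 1L, seed = sample.int(.Machine$integer.max, 1L)
      )
    },
    predict = function(m, X) {
      stats::predict(m, data = as_learn_df(X), num.threads = 1L)$predictions
    }
  )
}

# Error-minimising single-feature threshold rule: scans every feature for
# the cut that minimises training misclassifications, each side labelled
# by its majority class.
one_rule_fit <- function(X, y) {
  n <- nrow(X)
  lv <- levels(y)
  tot1 <- sum(y == lv[1])
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ox <- order(x)
    xs <- x[ox]
    c1 <- cumsum(y[ox] == lv[1])
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L]
    if (!any(valid)) next
    errL <- pmin(c1[i], i - c1[i])
    errR <- pmin(tot1 - c1[i], (n - i) - (tot1 - c1[i]))
    err <- ifelse(valid, errL + errR, Inf)
    b <- which.min(err)
    if (err[b] < best$err) {
      left1 <- c1[b] >= b - c1[b] # majority label left of cut
      right1 <- (tot1 - c1[b]) >= (n - b) - (tot1 - c1[b])
      best <- list(
        err = err[b], feature = j,
        threshold = (xs[b] + xs[b + 1L]) / 2,
        left = lv[if (left1) 1L else 2L],
        right = lv[if (right1) 1L else 2L]
      )
    }
  }
  if (!is.finite(best$err)) {
    # all features constant: majority rule
    best <- list(
      err = min(tot1, n - tot1), feature = 1L, threshold = Inf,
      left = lv[if (tot1 >= n - tot1) 1L else 2L], right = lv[1L]
    )
  }
  best$levels <- lv
  best
}

one_rule_predict <- function(m, X) {
  ifelse(X[, m$feature] <= m$threshold, m$left, m$right)
}

#' The default pool of 18 heterogeneous base learners
#'
#' A deliberately diverse pool mixing margin classifiers, instance-based
#' learners, trees, rule learners, probabilistic and baseline models:
#' linear-kernel SVM (`smo`), RBF-kernel SVM (`svm_rbf`), logistic
#' regression (`logistic`), 1/5/10-nearest-neighbour (`ib1`, `ib5`,
#' `ib10`), a coarse depth-2 tree standing in for a decision table
#' (`decision_table`), a heavily penalised depth-2 information-gain tree
#' standing in for a conjunctive rule (`conjunctive_rule`), a
#' single-feature threshold rule (`one_rule`), a CART tree (`cart`), a
#' pruned depth-4 tree standing in for a RIPPER-style rule inducer
#' (`ripper`), a constant majority-class predictor (`zero_rule`), a
#' single fully random tree (`random_tree`), naive Bayes (`naive_bayes`),
#' a 100-tree random forest (`random_forest`), a decision stump
#' (`decision_stump`), an information-gain tree in the C4.5 family
#' (`j48`), and a ridge-regularised logistic model standing in for a
#' functional tree (`functional_tree`).
#'
#' @return Named list of 18 [base_learner()] objects.
#' @export
default_learner_pool <- function() {
  pool <- list(
    svm_learner("smo", kernel = "linear"),
    svm_learner("svm_rbf", kernel = "radial"),
    base_learner(
      "logistic",
      fit = function(X, y) {
        suppressWarnings(stats::glm(.y ~ .,
          data = cbind(.y = y, as_learn_df(X)),
          family = stats::binomial()
        ))
      },
      predict = function(m, X) {
        p <- suppressWarnings(
          stats::predict(m, as_learn_df(X), type = "response")
        )
        lv <- levels(m$model$.y)
        ifelse(p > 0.5, lv[2L], lv[1L])
      }
    ),
    knn_learner("ib1", k = 1L),
    knn_learner("ib5", k = 5L),
    knn_learner("ib10", k = 10L),
    rpart_learner("decision_table", maxdepth = 2L, cp = 0.01, minsplit = 10L),
    rpart_learner("conjunctive_rule",
      split = "information", maxdepth = 2L,
      cp = 0.05, minsplit = 20L
    ),
    base_learner("one_rule", fit = one_rule_fit, predict = one_rule_predict),
    rpart_learner("cart", maxdepth = 30L, cp = 0.01),
    rpart_learner("ripper", maxdepth = 4L, cp = 0.02, minsplit = 10L),
    base_learner(
      "zero_rule",
      fit = function(X, y) {
        counts <- table(y)
        names(counts)[which.max(counts)] # tie -> first level
      },
      predict = function(m, X) rep(m, nrow(X))
    ),
    ranger_learner("random_tree", num.trees = 1L, mtry_frac = "sqrt"),
    base_learner(
      "naive_bayes",
      fit = function(X, y) e1071::naiveBayes(as_learn_df(X), y),
      predict = function(m, X) {
        stats::predict(m, as_learn_df(X), eps = 1e-6, threshold = 1e-6)
      }
    ),
    ranger_learner("random_forest", num.trees = 100L),
    rpart_learner("decision_stump", maxdepth = 1L, cp = 0, minsplit = 2L),
    rpart_learner("j48", split = "information", maxdepth = 30L, cp = 0.01),
    base_learner(
      "functional_tree",
      fit = function(X, y) {
        # convergence chatter on tiny folds is expected for a base
        # learner; the committee selection discounts weak fits anyway
        suppressWarnings(glmnet::glmnet(X, y,
          family = "binomial", alpha = 0,
          lambda = 0.01
        ))
      },
      predict = function(m, X) {
        drop(suppressWarnings(stats::predict(m, X, type = "class")))
      }
    )
  )
  stats::setNames(pool, vapply(pool, `[[`, "", "name"))
}
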