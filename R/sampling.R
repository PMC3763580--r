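#' Create a resampling plan
#'
#' Bundles the parameters of the hybrid rebalancing scheme: the minority
#' class is grown to `minority_target` rows by SMOTE interpolation and the
#' majority class is shrunk to `majority_target` rows by K-means cluster
#' undersampling. Defaults echo a rebuilt training set of roughly 2000
#' rows per class.
#'
#' @param minority_target Rows the minority class should have after SMOTE
#'   oversampling (must be at least the current minority count).
#' @param majority_target Rows the majority class should have after
#'   cluster undersampling (at most the current majority count).
#' @param smote_k Number of nearest minority neighbours SMOTE interpolates
#'   towards (default 5; must be smaller than the minority count).
#' @param kmeans_iter Maximum Lloyd iterations for the undersampler.
#' @param seed Integer seed; fully determines the resampled set.
#' @return A `resampling_plan` object.
#' @seealso [hybrid_resample()]
#' @export
resampling_plan <- function(minority_target = 2000L,
                            majority_target = 2000L,
                            smote_k = 5L,
                            kmeans_iter = 10L,
                            seed = 1L) {
  stopifnot(
    minority_target >= 1L, majority_target >= 1L,
    smote_k >= 1L, kmeans_iter >= 1L
  )
  structure(
    list(
      minority_target = as.integer(minority_target),
      majority_target = as.integer(majority_target),
      smote_k = as.integer(smote_k),
      kmeans_iter = as.integer(kmeans_iter),
      seed = as.integer(seed)
    ),
    class = "resampling_plan"
  )
}

# n x k matrix of squared Euclidean distances between rows of A and B.
sq_dist <- function(A, B) {
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) -
    2 * tcrossprod(A, B) +
    matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE)
  pmax(d2, 0)
}

#' SMOTE oversampling of a minority class
#'
#' Grows a minority feature matrix to `target` rows. Each synthetic row is
#' `x + u * (x_nn - x)` for a uniformly drawn `u` in `[0, 1]`, where `x`
#' is a randomly chosen original row and `x_nn` one of its `k` nearest
#' minority neighbours under Euclidean distance — i.e. a random point on
#' the segment between a minority sample and a close minority neighbour,
#' so no synthetic sample leaves the local convex structure of the class.
#'
#' @param X Numeric matrix of minority-class rows (at least 2).
#' @param target Total rows after oversampling; `target >= nrow(X)`.
#' @param k Nearest-neighbour count; `k < nrow(X)`.
#' @param seed Integer seed; output is deterministic given it.
#' @return Numeric matrix of `target` rows: the originals followed by the
#'   synthetic rows, with a `provenance` attribute
#'   (`"original"`/`"synthetic"` per row).
#' @export
smote_oversample <- function(X, target, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("SMOTE needs at least 2 minority rows", call. = FALSE)
  if (k >= n) {
    stop("smote_k (", k, ") must be smaller than the minority count (",
      n, ")",
      call. = FALSE
    )
  }
  if (target < n) {
    stop("minority_target (", target, ") is below the current minority ",
      "count (", n, "); SMOTE only adds rows",
      call. = FALSE
    )
  }
  n_syn <- target - n
  if (n_syn == 0L) {
    return(structure(X, provenance = rep("original", n)))
  }
  d2 <- sq_dist(X, X)
  diag(d2) <- Inf
  # k nearest neighbours per row, ties by lowest index
  nn <- apply(d2, 1L, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn, ncol = 1L) else t(nn)
  syn <- with_seed(seed, {
    parent <- sample.int(n, n_syn, replace = TRUE)
    nbr <- nn[cbind(parent, sample.int(k, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    X[parent, , drop = FALSE] +
      u * (X[nbr, , drop = FALSE] - X[parent, , drop = FALSE])
  })
  rownames(syn) <- sprintf("smote_%d", seq_len(n_syn))
  structure(
    rbind(X, syn),
    provenance = c(rep("original", n), rep("synthetic", n_syn))
  )
}

# Seeded K-means++ centre selection: the first centre is a random row,
# each further centre a row drawn with probability proportional to its
# squared distance from the nearest centre already chosen. Spreads the
# initial centres across the data so well-separated clusters each
# receive one, which plain uniform seeding frequently misses.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], , drop = TRUE])^2)
  for (k in seq_len(K - 1L)) {
    d2[centers[seq_len(k)]] <- 0
    centers[k + 1L] <- if (sum(d2) > 0) {
      sample.int(n, 1L, prob = d2)
    } else {
      # all remaining rows coincide with a centre; take any unused row
      setdiff(seq_len(n), centers[seq_len(k)])[1L]
    }
    d2 <- pmin(
      d2,
      rowSums(sweep(X, 2L, X[centers[k + 1L], , drop = TRUE])^2)
    )
  }
  X[centers, , drop = FALSE]
}

# Seeded Lloyd K-means over K-means++ initial centres; assignment
# minimises squared Euclidean distance with ties going to the lowest
# cluster index; an emptied cluster is re-seeded with the point currently
# farthest from its own centroid. Returns the final assignment
# (guaranteed to use all K clusters when n >= K) and centroids.
kmeans_lloyd <- function(X, K, iter = 10L, seed = 1L) {
  n <- nrow(X)
  stopifnot(K >= 1L, K <= n)
  with_seed(seed, {
    centers <- kmeanspp_init(X, K)
    assign <- integer(n)
    for (it in seq_len(iter)) {
      d2 <- sq_dist(X, centers)
      assign <- max.col(-d2, ties.method = "first")
      own <- d2[cbind(seq_len(n), assign)]
      empty <- which(tabulate(assign, K) == 0L)
      for (e in empty) {
        far <- which.max(own)
        assign[far] <- e
        centers[e, ] <- X[far, , drop = FALSE]
        own[far] <- 0
      }
      sums <- rowsum(X, assign, reorder = FALSE)
      counts <- tabulate(assign, K)
      new_centers <- centers
      new_centers[as.integer(rownames(sums)), ] <- sums / counts[as.integer(rownames(sums))]
      if (max(abs(new_centers - centers)) < 1e-10) {
        centers <- new_centers
        break
      }
      centers <- new_centers
    }
    list(assignment = assign, centers = centers)
  })
}

#' K-means cluster undersampling of a majority class
#'
#' Shrinks a majority feature matrix to `target` rows while preserving
#' coverage of the class distribution: the rows are clustered into
#' `target` K-means clusters (squared Euclidean distance, at most `iter`
#' Lloyd iterations, seeded initialization from `target` distinct input
#' rows) and each cluster contributes the original row closest to its
#' centroid. Every output row is therefore a verbatim input row — no
#' majority sample is ever fabricated.
#'
#' @param X Numeric matrix of majority-class rows.
#' @param target Rows to keep; `1 <= target <= nrow(X)`.
#' @param iter Maximum Lloyd iterations.
#' @param seed Integer seed.
#' @return Numeric matrix of `target` input rows (original row order),
#'   with an `indices` attribute giving their row numbers in `X`.
#' @export
kmeans_undersample <- function(X, target, iter = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (target < 1L) stop("majority_target must be positive", call. = FALSE)
  if (target > n) {
    stop("majority_target (", target, ") exceeds the majority count (",
      n, ")",
      call. = FALSE
    )
  }
  if (target == n) {
    return(structure(X, indices = seq_len(n)))
  }
  km <- kmeans_lloyd(X, K = target, iter = iter, seed = seed)
  own <- sq_dist(X, km$centers)[cbind(seq_len(n), km$assignment)]
  # closest member per cluster; deterministic tie-break by row index
  ord <- order(km$assignment, own, seq_len(n))
  reps <- ord[!duplicated(km$assignment[ord])]
  reps <- sort(reps)
  if (length(reps) < target) {
    # degenerate geometry left clusters unfillable; pad with the next
    # closest distinct rows
    extra <- setdiff(order(own), reps)
    reps <- sort(c(reps, extra[seq_len(target - length(reps))]))
  }
  structure(X[reps, , drop = FALSE], indices = reps)
}

#' Hybrid rebalancing: SMOTE up, cluster-undersample down
#'
#' Rebalances a binary-labelled feature matrix: the rarer class is grown
#' by [smote_oversample()] to `plan$minority_target` and the commoner
#' class shrunk by [kmeans_undersample()] to `plan$majority_target`; the
#' result is shuffled. Oversampling alone would amplify noise at extreme
#' imbalance and undersampling alone would starve the training set; the
#' combination meets in the middle.
#'
#' @param X Numeric feature matrix.
#' @param y Binary label vector (factor, character, or numeric with two
#'   distinct values), one per row of `X`. The rarer label is the
#'   minority; an exact tie takes the alphabetically first label as
#'   minority.
#' @param plan A [resampling_plan()].
#' @return A `resampled_set`: list with `X` (matrix), `y` (factor with the
#'   input's levels), `provenance` (`"original"`/`"synthetic"` per row)
#'   and `plan`.
#' @export
hybrid_resample <- function(X, y, plan = resampling_plan()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) {
    stop("y must have exactly two classes, got ", nlevels(y), call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("each class needs at least 2 members", call. = FALSE)
  }
  minority <- levels(y)[which.min(counts)] # ties -> first level
  majority <- setdiff(levels(y), minority)
  Xmin <- X[y == minority, , drop = FALSE]
  Xmaj <- X[y == majority, , drop = FALSE]

  up <- smote_oversample(Xmin, plan$minority_target,
    k = plan$smote_k, seed = plan$seed
  )
  down <- kmeans_undersample(Xmaj, plan$majority_target,
    iter = plan$kmeans_iter, seed = plan$seed + 1L
  )

  X_out <- rbind(up, down)
  y_out <- factor(
    c(
      rep(minority, nrow(up)),
      rep(majority, nrow(down))
    ),
    levels = levels(y)
  )
  prov <- c(attr(up, "provenance"), rep("original", nrow(down)))
  perm <- with_seed(plan$seed + 2L, sample.int(nrow(X_out)))
  structure(
    list(
      X = X_out[perm, , drop = FALSE],
      y = y_out[perm],
      provenance = prov[perm],
      minority = minority,
      plan = plan
    ),
    class = "resampled_set"
  )
}

#' @export
print.resampled_set <- function(x, ...) {
  cat("Resampled set:", nrow(x$X), "rows x", ncol(x$X), "features\n")
  print(table(class = x$y, provenance = x$provenance))
  invisible(x)
}
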