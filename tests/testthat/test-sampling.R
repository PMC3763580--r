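test_that("SMOTE with target = n returns the input unchanged", {
  X <- matrix(rnorm(30), 10, 3)
  out <- smote_oversample(X, 10, k = 3, seed = 1)
  expect_equal(unname(out[1:10, ]), unname(X))
  expect_equal(attr(out, "provenance"), rep("original", 10))
})

test_that("SMOTE between identical points reproduces the point", {
  X <- matrix(rep(c(1, 2, 3), each = 3), 3, 3)
  out <- smote_oversample(X, 10, k = 1, seed = 4)
  for (i in 4:10) expect_equal(unname(out[i, ]), c(1, 2, 3))
})

test_that("every synthetic row lies on a parent-to-neighbour segment", {
  set.seed(17)
  X <- matrix(rnorm(40), 20, 2)
  k <- 4
  # neighbour lists recomputed independently of the implementation
  d <- as.matrix(dist(X))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[1:k]))
  for (seed in 1:20) {
    out <- smote_oversample(X, 25, k = k, seed = seed)
    syn <- out[21:25, , drop = FALSE]
    for (i in seq_len(nrow(syn))) {
      on_segment <- FALSE
      for (p in 1:20) {
        for (q in nn[p, ]) {
          dx <- X[q, ] - X[p, ]
          # reconstruct u coordinate-wise and check consistency
          u <- (syn[i, ] - X[p, ]) / dx
          u <- u[is.finite(u)]
          if (length(u) > 0 && diff(range(u)) < 1e-8 &&
            u[1] >= 0 && u[1] <= 1) {
            resid <- syn[i, ] - (X[p, ] + u[1] * dx)
            if (max(abs(resid)) < 1e-8) on_segment <- TRUE
          }
        }
      }
      expect_true(on_segment)
    }
  }
})

test_that("SMOTE validates its preconditions", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(smote_oversample(X, 5, k = 3), "below the current")
  expect_error(smote_oversample(X, 20, k = 10), "smaller than")
  expect_error(smote_oversample(X[1, , drop = FALSE], 5, k = 1), "at least 2")
})

test_that("undersampling with target = n keeps everything", {
  X <- matrix(rnorm(24), 8, 3)
  out <- kmeans_undersample(X, 8, seed = 2)
  expect_equal(unname(out), unname(X), ignore_attr = TRUE)
})

test_that("undersampling returns one verbatim representative per planted cluster", {
  set.seed(99)
  centers <- matrix(c(0, 0, 50, 0, 0, 50, 50, 50, 25, 90), 5, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:5, function(i) {
    sweep(matrix(rnorm(60, sd = 0.5), 30, 2), 2, centers[i, ], `+`)
  }))
  planted <- rep(1:5, each = 30)
  for (seed in c(1, 7, 42)) {
    out <- kmeans_undersample(X, 5, iter = 20, seed = seed)
    idx <- attr(out, "indices")
    expect_length(idx, 5)
    # verbatim input rows
    expect_equal(unname(out), unname(X[idx, ]), ignore_attr = TRUE)
    # exactly one representative from each planted cluster
    expect_setequal(planted[idx], 1:5)
  }
})

test_that("undersampler output size and subset contract hold off the easy path", {
  set.seed(123)
  X <- matrix(rnorm(200), 50, 4)
  out <- kmeans_undersample(X, 18, seed = 5)
  expect_equal(nrow(out), 18)
  idx <- attr(out, "indices")
  expect_equal(anyDuplicated(idx), 0L)
  expect_true(all(idx %in% 1:50))
  expect_error(kmeans_undersample(X, 51), "exceeds")
  expect_error(kmeans_undersample(X, 0), "positive")
})

test_that("the seeded Lloyd clustering agrees with stats::kmeans on separated data", {
  set.seed(31)
  X <- rbind(
    matrix(rnorm(40, mean = 0, sd = .3), 20, 2),
    matrix(rnorm(40, mean = 10, sd = .3), 20, 2),
    matrix(rnorm(40, mean = 20, sd = .3), 20, 2)
  )
  ours <- cytosel:::kmeans_lloyd(X, 3, iter = 25, seed = 8)$assignment
  ref <- stats::kmeans(X, 3, nstart = 5)$cluster
  # same partition up to label permutation
  expect_equal(length(unique(paste(ours, ref))), 3L)
})

test_that("hybrid resampling hits the plan targets exactly", {
  set.seed(11)
  X <- rbind(
    matrix(rnorm(20 * 6, mean = 1), 20, 6),
    matrix(rnorm(400 * 6), 400, 6)
  )
  y <- rep(c("pos", "neg"), c(20, 400))
  plan <- resampling_plan(
    minority_target = 60, majority_target = 50,
    seed = 3
  )
  rs <- hybrid_resample(X, y, plan)
  expect_equal(as.vector(table(rs$y)[c("pos", "neg")]), c(60, 50))
  # no synthetic majority rows; all majority rows verbatim from input
  maj <- rs$X[rs$y == "neg", ]
  expect_true(all(rs$provenance[rs$y == "neg"] == "original"))
  key <- function(m) apply(round(m, 10), 1, paste, collapse = ",")
  expect_true(all(key(maj) %in% key(X[21:420, ])))
  expect_true(all(rs$provenance %in% c("original", "synthetic")))
  # class ratio near 1
  expect_lt(abs(60 / 50 - 1), 0.25)
})

test_that("a no-op plan reduces hybrid resampling to a shuffle", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  rownames(X) <- paste0("r", 1:20)
  y <- rep(c("a", "b"), c(8, 12))
  plan <- resampling_plan(minority_target = 8, majority_target = 12, smote_k = 3)
  rs <- hybrid_resample(X, y, plan)
  expect_equal(nrow(rs$X), 20)
  expect_setequal(rownames(rs$X), rownames(X))
  expect_equal(rs$X[order(rownames(rs$X)), ], X[order(rownames(X)), ])
  expect_true(all(rs$provenance == "original"))
  expect_equal(as.vector(table(rs$y)), c(8, 12))
})

test_that("resampling is byte-identical across runs with the same seed", {
  set.seed(77)
  X <- matrix(rnorm(300), 100, 3)
  y <- rep(c("m", "M"), c(15, 85))
  plan <- resampling_plan(40, 30, smote_k = 4, seed = 123)
  a <- hybrid_resample(X, y, plan)
  b <- hybrid_resample(X, y, plan)
  expect_identical(a, b)
  c2 <- hybrid_resample(X, y, resampling_plan(40, 30, smote_k = 4, seed = 124))
  expect_false(identical(a$X, c2$X))
})

test_that("hybrid resampling rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(hybrid_resample(X, rep("a", 10)), "two classes")
  expect_error(
    hybrid_resample(X, rep(c("a", "b"), c(1, 9)), resampling_plan(5, 5)),
    "at least 2"
  )
})
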