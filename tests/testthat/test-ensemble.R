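# deterministic toy learners
const_learner <- function(name, label) {
  base_learner(name,
    fit = function(X, y) label,
    predict = function(m, X) rep(m, nrow(X))
  )
}
sign_learner <- function(name) {
  base_learner(name,
    fit = function(X, y) levels(y),
    predict = function(m, X) ifelse(X[, 1] > 0, m[2], m[1])
  )
}
failing_learner <- base_learner("broken",
  fit = function(X, y) stop("nope"),
  predict = function(m, X) NULL
)

sep_data <- function(n = 40) {
  X <- cbind(c(-seq_len(n / 2), seq_len(n / 2)), 0)
  y <- factor(rep(c("a", "b"), each = n / 2))
  list(X = X, y = y)
}

test_that("result matrix rows reflect learner correctness", {
  d <- sep_data(40)
  pool <- list(
    perfect = sign_learner("perfect"),
    baseline = const_learner("baseline", "a")
  )
  rm <- build_result_matrix(pool, d$X, d$y, mode = "resubstitution", seed = 1)
  expect_equal(unname(rm$R["perfect", ]), rep(1L, 40))
  expect_equal(unname(rm$accuracy["baseline"]), 0.5)
  expect_true(all(rm$R %in% 0:1))
})

test_that("a margin classifier beats the constant baseline on separable data", {
  set.seed(4)
  X <- rbind(
    matrix(rnorm(40, mean = -3), 20, 2),
    matrix(rnorm(40, mean = 3), 20, 2)
  )
  y <- factor(rep(c("a", "b"), each = 20))
  pool <- default_learner_pool()[c("smo", "zero_rule")]
  rm <- build_result_matrix(pool, X, y, mode = "out_of_fold", seed = 2)
  expect_gt(rm$accuracy["smo"], rm$accuracy["zero_rule"])
})

test_that("out-of-fold mode denies memorisers the perfect row", {
  set.seed(9)
  X <- matrix(rnorm(80), 40, 2)
  y <- factor(sample(c("a", "b"), 40, replace = TRUE)) # pure noise
  pool <- default_learner_pool()[c("ib1", "zero_rule")]
  resub <- build_result_matrix(pool, X, y, mode = "resubstitution", seed = 3)
  oof <- build_result_matrix(pool, X, y, mode = "out_of_fold", seed = 3)
  expect_equal(unname(resub$accuracy["ib1"]), 1) # memorised
  expect_lt(oof$accuracy["ib1"], 0.8) # honest estimate
})

test_that("failing learners are excluded with a warning, small pools error", {
  d <- sep_data(20)
  pool <- list(
    broken = failing_learner,
    perfect = sign_learner("perfect"),
    baseline = const_learner("baseline", "a")
  )
  rm <- NULL
  expect_warning(
    rm <- build_result_matrix(pool, d$X, d$y, mode = "resubstitution", seed = 1),
    "broken"
  )
  expect_equal(nrow(rm$R), 2L)
  expect_error(
    suppressWarnings(build_result_matrix(
      list(broken = failing_learner, perfect = sign_learner("p")),
      d$X, d$y,
      mode = "resubstitution", seed = 1
    )),
    "fewer than 2"
  )
})

test_that("classifier clustering groups by correctness pattern", {
  r <- c(1, 0, 1, 1, 0, 1, 0, 1)
  R <- rbind(a = r, b = r, c = 1 - r)
  cl <- cluster_classifiers(R, K = 2, seed = 1)
  expect_equal(cl[["a"]], cl[["b"]]) # identical rows share a cluster
  expect_false(cl[["a"]] == cl[["c"]]) # complementary rows split
  # K_eff capping: 3 learners with K = 9 -> 3 singletons
  cl9 <- cluster_classifiers(R[c(1, 3), ], K = 9, seed = 1)
  expect_equal(length(unique(cl9)), 2L)
  R3 <- rbind(a = c(1, 0, 1), b = c(0, 1, 1), c = c(1, 1, 0))
  expect_equal(length(unique(cluster_classifiers(R3, K = 9, seed = 2))), 3L)
})

test_that("CEFS keeps a perfect learner and stops at the initial target", {
  R <- rbind(
    perfect = rep(1, 8),
    good = c(1, 1, 1, 1, 1, 1, 0, 0),
    bad = c(1, 0, 0, 0, 1, 0, 0, 0)
  )
  sel <- cefs_select(cluster_classifiers(R, K = 9, seed = 1), R)
  expect_true("perfect" %in% sel$cc)
  expect_equal(sel$achieved_accuracy, 1)
  expect_equal(sel$final_target, 1)
})

test_that("a pool of identical learners yields a singleton committee", {
  r <- c(1, 1, 0, 1, 0, 1, 1, 0)
  R <- rbind(a = r, b = r, c = r, d = r)
  sel <- cefs_select(cluster_classifiers(R, K = 4, seed = 2), R)
  expect_length(sel$cc, 1L)
  expect_equal(sel$achieved_accuracy, mean(r))
})

# explicit vote-counting enumeration, independent of the implementation
enumerate_accuracy <- function(R, members) {
  acc <- rowMeans(R)
  correct <- 0
  for (j in seq_len(ncol(R))) {
    votes_right <- 0
    for (i in members) votes_right <- votes_right + R[i, j]
    if (votes_right * 2 > length(members)) {
      correct <- correct + 1
    } else if (votes_right * 2 == length(members)) {
      best <- members[1]
      for (i in members) if (acc[i] > acc[best]) best <- i
      correct <- correct + R[best, j]
    }
  }
  correct / ncol(R)
}

test_that("majority-vote accuracy matches exhaustive enumeration on a toy matrix", {
  R <- rbind(
    c1 = c(1, 1, 1, 0),
    c2 = c(1, 0, 1, 1),
    c3 = c(0, 1, 1, 1)
  )
  subsets <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  for (s in subsets) {
    expect_equal(
      committee_accuracy(R, s),
      unname(enumerate_accuracy(R, s)),
      info = paste(s, collapse = ",")
    )
  }
  # all three learners together are perfect under majority vote
  expect_equal(enumerate_accuracy(R, 1:3), 1)
  # the CEFS trace is consistent with the enumeration of its own committee
  sel <- cefs_select(cluster_classifiers(R, K = 3, seed = 1), R)
  expect_equal(
    sel$achieved_accuracy,
    unname(enumerate_accuracy(R, match(sel$cc, rownames(R))))
  )
})

test_that("selection never returns a committee worse than its seed", {
  set.seed(55)
  for (rep in 1:20) {
    R <- matrix(rbinom(10 * 30, 1, runif(1, 0.3, 0.9)), 10, 30)
    rownames(R) <- paste0("l", 1:10)
    cl <- cluster_classifiers(R, K = 4, seed = rep)
    sel <- cefs_select(cl, R)
    best_single <- max(rowMeans(R)[sel$candidates])
    expect_gte(sel$achieved_accuracy, best_single)
  }
})

manual_model <- function(cc_specs, accs) {
  pool <- lapply(names(cc_specs), function(nm) const_learner(nm, cc_specs[[nm]]))
  names(pool) <- names(cc_specs)
  structure(
    list(
      fits = lapply(cc_specs, identity),
      pool = pool,
      cc = names(cc_specs),
      learner_accuracy = accs,
      levels = c("neg", "pos"),
      positive = "pos",
      selection = list(achieved_accuracy = NA),
      mode = "resubstitution"
    ),
    class = "selective_ensemble"
  )
}

test_that("ensemble voting: unanimity, strict majority, and the tie rule", {
  X <- matrix(0, 4, 2)
  unan <- predict(manual_model(
    list(a = "pos", b = "pos"),
    c(a = .9, b = .8)
  ), X)
  expect_true(all(unan$label == "pos"))
  expect_true(all(unan$vote_fraction == 1))

  maj <- predict(manual_model(
    list(a = "pos", b = "pos", c = "neg"),
    c(a = .9, b = .8, c = .7)
  ), X)
  expect_true(all(maj$label == "pos"))
  expect_equal(maj$vote_fraction, rep(2 / 3, 4))

  # 2-member split: the more accurate member decides
  tie1 <- predict(manual_model(
    list(a = "pos", b = "neg"),
    c(a = .9, b = .5)
  ), X)
  expect_true(all(tie1$label == "pos"))
  expect_equal(tie1$vote_fraction, rep(0.5, 4))
  tie2 <- predict(manual_model(
    list(a = "pos", b = "neg"),
    c(a = .5, b = .9)
  ), X)
  expect_true(all(tie2$label == "neg"))
})

test_that("a singleton committee reproduces its learner's predictions", {
  d <- sep_data(30)
  pool <- list(
    perfect = sign_learner("perfect"),
    baseline = const_learner("baseline", "a")
  )
  model <- train_ensemble(d$X, d$y,
    pool = pool, mode = "resubstitution",
    seed = 1
  )
  expect_equal(model$cc, "perfect")
  pred <- predict(model, d$X)
  expect_equal(as.character(pred$label), as.character(d$y))
})

test_that("training is deterministic given the seed", {
  set.seed(88)
  X <- rbind(
    matrix(rnorm(60, -1), 30, 2),
    matrix(rnorm(60, 1), 30, 2)
  )
  y <- factor(rep(c("neg", "pos"), each = 30))
  pool <- default_learner_pool()[c(
    "smo", "logistic", "decision_stump",
    "zero_rule", "random_tree"
  )]
  m1 <- train_ensemble(X, y, pool = pool, seed = 10)
  m2 <- train_ensemble(X, y, pool = pool, seed = 10)
  expect_identical(m1$cc, m2$cc)
  expect_identical(predict(m1, X), predict(m2, X))
})
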