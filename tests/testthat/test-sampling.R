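test_that("triplet count formula equals brute-force enumeration", {
  for (N in 2:5) for (M in 2:5) {
    labels <- rep(seq_len(N) - 1L, each = M)
    expect_equal(count_possible_triplets(N, M), nrow(enumerate_triplets(labels)),
                 info = sprintf("N=%d M=%d", N, M))
  }
  expect_error(count_possible_triplets(1, 5), "at least 2")
  expect_error(count_possible_triplets(3, 1), "at least 2")
})

test_that("triplet count is asymmetric in classes vs members", {
  expect_equal(count_possible_triplets(2, 3), 36)
  expect_equal(count_possible_triplets(3, 2), 24)
})

test_that("PK batch plans are valid, seeded, and exhaustive at K = all classes", {
  labels <- rep(0:3, each = 6)
  plan <- sample_pk_batch(labels, K = 4, L = 1, seed = 3)
  expect_equal(plan$class_ids, 0:3)
  expect_equal(lengths(plan$member_ids), rep(1L, 4))
  expect_equal(sort(unique(labels[plan$indices])), 0:3)
  expect_identical(plan, sample_pk_batch(labels, K = 4, L = 1, seed = 3))
  expect_error(sample_pk_batch(labels, K = 5, L = 1, seed = 1), "classes")
})

test_that("class draws are uniform across seeds", {
  labels <- rep(0:3, each = 5)
  hits <- numeric(4)
  for (s in 1:1000) {
    plan <- sample_pk_batch(labels, K = 2, L = 2, seed = s)
    hits[plan$class_ids + 1] <- hits[plan$class_ids + 1] + 1
  }
  expect_true(all(abs(hits / 1000 - 0.5) < 0.05))
})

test_that("batch-hard mining equals exhaustive hardest-pair search", {
  set.seed(21)
  for (rep in 1:6) {
    n_cls <- sample(2:4, 1)
    L <- sample(2:4, 1)
    labels <- rep(seq_len(n_cls) - 1L, each = L)
    B <- length(labels)
    X <- matrix(rnorm(B * 5), B, 5)
    M <- if (rep %% 2 == 0) diag(5) else random_psd(5, rep)
    plan <- sample_pk_batch(labels, K = n_cls, L = L, seed = rep)
    mined <- mine_hard_triplets(embedding_batch(X, labels), M, plan)
    expect_equal(nrow(mined), B)
    dist <- function(i, j) {
      d <- X[i, ] - X[j, ]
      as.numeric(d %*% M %*% d)
    }
    for (r in seq_len(nrow(mined))) {
      a <- mined[r, 1]
      same <- setdiff(which(labels == labels[a]), a)
      diff <- which(labels != labels[a])
      dp <- vapply(same, dist, numeric(1), i = a)
      dn <- vapply(diff, dist, numeric(1), i = a)
      expect_equal(unname(mined[r, 2]), same[which.max(dp)])
      expect_equal(unname(mined[r, 3]), diff[which.min(dn)])
    }
  }
})

test_that("mining on the unit-square fixture finds the known hardest pairs", {
  # class 0 at (0,0), (1,0); class 1 at (0,1), (1,1)
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  labels <- c(0, 0, 1, 1)
  plan <- sample_pk_batch(labels, K = 2, L = 2, seed = 1)
  mined <- mine_hard_triplets(embedding_batch(X, labels), diag(2), plan)
  # every anchor: positive is the other same-class corner (distance 1),
  # negative the corner straight above/below (distance 1, lowest index on tie)
  expect_equal(mined[mined[, 1] == 1, ], c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(mined[mined[, 1] == 4, ], c(4L, 3L, 2L), ignore_attr = TRUE)
})

test_that("tied distances break to the lowest index deterministically", {
  X <- matrix(1, 6, 3)                    # all embeddings identical
  labels <- rep(0:1, each = 3)
  plan <- sample_pk_batch(labels, K = 2, L = 3, seed = 2)
  mined <- mine_hard_triplets(embedding_batch(X, labels), diag(3), plan)
  for (r in seq_len(nrow(mined))) {
    a <- mined[r, 1]
    expect_equal(unname(mined[r, 2]), min(setdiff(which(labels == labels[a]), a)))
    expect_equal(unname(mined[r, 3]), min(which(labels != labels[a])))
  }
})

test_that("mining is invariant to positive rescaling of the metric", {
  set.seed(33)
  labels <- rep(0:2, each = 3)
  X <- matrix(rnorm(9 * 4), 9, 4)
  plan <- sample_pk_batch(labels, K = 3, L = 3, seed = 5)
  a <- mine_hard_triplets(embedding_batch(X, labels), diag(4), plan)
  b <- mine_hard_triplets(embedding_batch(X, labels), 7.3 * diag(4), plan)
  expect_identical(a, b)
})

test_that("singleton classes are skipped; all-singleton batches signal empty", {
  X <- matrix(rnorm(12), 4, 3)
  labels <- c(0, 0, 1, 2)
  plan <- matriplet:::full_batch_plan(labels)
  mined <- mine_hard_triplets(embedding_batch(X, labels), diag(3), plan)
  expect_equal(sort(unique(mined[, 1])), c(1L, 2L))   # only class 0 anchors
  lone <- matriplet:::full_batch_plan(c(0, 1))
  expect_warning(
    out <- mine_hard_triplets(embedding_batch(matrix(rnorm(4), 2, 2), c(0, 1)),
                              diag(2), lone),
    "single member")
  expect_equal(nrow(out), 0)
})
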