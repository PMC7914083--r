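# Central oracle of the module: analytic gradients must match central
# finite differences of the loss on randomized fixtures.

fd_feature_grad <- function(X, tri, M, cfg, h = 1e-5) {
  G <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    G[i, j] <- (improved_triplet_loss(Xp, tri, M, cfg)$total -
                  improved_triplet_loss(Xm, tri, M, cfg)$total) / (2 * h)
  }
  G
}

fd_metric_grad_entry <- function(X, tri, M, cfg, i, j, h = 1e-6) {
  E <- matrix(0, nrow(M), ncol(M))
  E[i, j] <- h; E[j, i] <- E[j, i] + h      # symmetric perturbation
  (improved_triplet_loss(X, tri, M + E, cfg)$total -
     improved_triplet_loss(X, tri, M - E, cfg)$total) / (2 * h)
}

random_fixture <- function(seed, n = 6, d = 4, n_tri = 3) {
  set.seed(seed)
  labels <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  tri <- t(vapply(seq_len(n_tri), function(i) {
    a <- sample(n, 1)
    p <- sample(setdiff(which(labels == labels[a]), a), 1)
    g <- sample(which(labels != labels[a]), 1)
    c(a, p, g)
  }, integer(3)))
  list(X = X, tri = tri, M = random_psd(d, seed + 100))
}

test_that("Mahalanobis distance matches direct matrix arithmetic", {
  expect_equal(mahalanobis_distance(c(1, 2), c(4, 6), diag(2)), 9 + 16)
  expect_equal(mahalanobis_distance(c(1, 3), c(1, 3), random_psd(2, 1)), 0)
  expect_equal(mahalanobis_distance(c(1, 0), c(0, 1),
                                    rbind(c(2, 1), c(1, 2))), 2)
  expect_error(mahalanobis_distance(c(1, 0, 0), c(0, 1), diag(2)), "mismatch")
})

test_that("original triplet loss reproduces the scalar cases", {
  # satisfied triplet: positive coincides, negative beyond the margin
  X <- rbind(c(0, 0), c(0, 0), c(2, 0))
  expect_equal(original_triplet_loss(X, rbind(c(1, 2, 3)), margin = 0.5), 0)
  # fully degenerate triplet contributes exactly the margin
  X2 <- matrix(0, 3, 2)
  expect_equal(original_triplet_loss(X2, rbind(c(1, 2, 3)), margin = 0.7), 0.7)
  # d+^2 = 1, d-^2 = 4, margin 0.5 -> hinge inactive
  X3 <- rbind(c(0, 0), c(1, 0), c(-2, 0))
  expect_equal(original_triplet_loss(X3, rbind(c(1, 2, 3)), margin = 0.5), 0)
})

test_that("ratio-form loss reproduces the scalar cases", {
  # B = 0 (anchor = positive), A = 2*alpha -> D_x = -1, hinged; mu = 0
  a <- 0.8
  X <- rbind(c(0, 0), c(0, 0), c(sqrt(2 * a), 0))
  rep1 <- improved_triplet_loss(X, rbind(c(1, 2, 3)), diag(2),
                                loss_config(margin = a, mu = 0))
  expect_equal(rep1$per_triplet_Dx, -1)
  expect_equal(rep1$total, 0)
  expect_equal(rep1$active_count, 0)
  # M = I, mu = 0, alpha = 1: far negative inactive, near negative 0.5
  X2 <- rbind(c(0, 0), c(0, 1), c(3, 0))
  r_far <- improved_triplet_loss(X2, rbind(c(1, 2, 3)), diag(2),
                                 loss_config(1, 0))
  expect_equal(r_far$per_triplet_Dx, 1 - 9 / 2)
  expect_equal(r_far$total, 0)
  X2[3, ] <- c(1, 0)
  r_near <- improved_triplet_loss(X2, rbind(c(1, 2, 3)), diag(2),
                                  loss_config(1, 0))
  expect_equal(r_near$total, 0.5)
  expect_equal(r_near$active_count, 1)
  # hinge boundary: A = B + alpha exactly -> D_x = 0
  X3 <- rbind(c(0, 0), c(1, 0), c(sqrt(2), 0))
  r_b <- improved_triplet_loss(X3, rbind(c(1, 2, 3)), diag(2), loss_config(1, 0))
  expect_equal(r_b$per_triplet_Dx, 0, tolerance = 1e-12)
})

test_that("pairwise term adds mu times the anchor-positive distance", {
  X <- rbind(c(0, 0), c(0, 2), c(5, 0))
  r <- improved_triplet_loss(X, rbind(c(1, 2, 3)), diag(2),
                             loss_config(margin = 1, mu = 0.25))
  expect_equal(r$per_triplet_Dp, 4)
  expect_equal(r$total, max(0, 1 - 25 / 5) + 0.25 * 4)
  expect_error(improved_triplet_loss(X, matrix(0, 0, 3), diag(2)), "nonempty")
  # alpha = 0 with coincident anchor/positive must be guarded
  X0 <- rbind(c(0, 0), c(0, 0), c(1, 0))
  expect_error(improved_triplet_loss(X0, rbind(c(1, 2, 3)), diag(2),
                                     loss_config(0, 0)), "positive")
})

test_that("loss is nonnegative for PSD metrics and nonnegative mu", {
  for (s in 1:8) {
    fx <- random_fixture(s)
    r <- improved_triplet_loss(fx$X, fx$tri, fx$M, loss_config(0.5, 0.2))
    expect_gte(r$total, 0)
  }
})

test_that("with M = I and mu = 0 the loss ranks triplets by the Euclidean ratio", {
  set.seed(44)
  fx <- random_fixture(44, n = 8, n_tri = 6)
  cfg <- loss_config(1, 0)
  r <- improved_triplet_loss(fx$X, fx$tri, diag(4), cfg)
  ratio <- vapply(seq_len(nrow(fx$tri)), function(i) {
    a <- fx$tri[i, 1]; p <- fx$tri[i, 2]; g <- fx$tri[i, 3]
    sum((fx$X[a, ] - fx$X[g, ])^2) / (sum((fx$X[a, ] - fx$X[p, ])^2) + 1)
  }, numeric(1))
  expect_equal(order(r$per_triplet_Dx), order(-ratio))
})

test_that("analytic feature gradients match finite differences", {
  worst <- 0
  for (s in 1:8) {
    fx <- random_fixture(s)
    cfg <- loss_config(0.7, 0.3)
    G <- loss_grad_features(fx$X, fx$tri, fx$M, cfg)$grad_features
    FD <- fd_feature_grad(fx$X, fx$tri, fx$M, cfg)
    denom <- pmax(abs(FD), 1e-6)
    worst <- max(worst, max(abs(G - FD) / denom))
  }
  expect_lt(worst, 1e-4)
})

test_that("inactive triplets with mu = 0 give exactly zero feature gradient", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 0))   # negative far: hinge off
  G <- loss_grad_features(X, rbind(c(1, 2, 3)), diag(2),
                          loss_config(1, 0))$grad_features
  expect_equal(G, matrix(0, 3, 2))
})

test_that("coincident anchor/positive zeroes the pairwise gradient on the pair", {
  X <- rbind(c(1, 1), c(1, 1), c(3, 0))
  G <- loss_grad_features(X, rbind(c(1, 2, 3)), diag(2),
                          loss_config(1, 0.5))$grad_features
  # pairwise pull (M + M^T)(f_a - f_p) vanishes when the pair coincides
  rep0 <- improved_triplet_loss(X, rbind(c(1, 2, 3)), diag(2), loss_config(1, 0.5))
  if (rep0$active_count == 0) expect_equal(G[2, ], c(0, 0))
})

test_that("analytic metric gradients match finite differences and are symmetric", {
  worst <- 0
  for (s in 1:8) {
    fx <- random_fixture(s)
    cfg <- loss_config(0.7, 0.3)
    Gm <- loss_grad_metric(fx$X, fx$tri, fx$M, cfg)$grad_metric
    expect_equal(Gm, t(Gm))
    for (k in 1:4) {
      i <- sample(4, 1); j <- sample(4, 1)
      fd <- fd_metric_grad_entry(fx$X, fx$tri, fx$M, cfg, i, j)
      an <- Gm[i, j] + Gm[j, i]
      worst <- max(worst, abs(fd - an) / max(abs(fd), 1e-6))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("a lone satisfied pair reduces the metric gradient to mu * C_plus", {
  X <- rbind(c(0, 0), c(1, 2), c(50, 0))     # hinge far inactive
  Gm <- loss_grad_metric(X, rbind(c(1, 2, 3)), diag(2),
                         loss_config(1, 1))$grad_metric
  dap <- c(-1, -2)
  expect_equal(Gm, dap %o% dap)
})

test_that("PSD projection truncates negative eigenvalues", {
  expect_equal(psd_project(diag(c(3, -2)))$M, diag(c(3, 0)))
  A <- random_psd(4, 2)
  expect_equal(psd_project(A)$M, A, tolerance = 1e-10)
  expect_error(psd_project(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("PSD projection is idempotent and PSD within tolerance", {
  set.seed(12)
  for (s in 1:5) {
    S <- matrix(rnorm(25), 5, 5)
    P1 <- psd_project(S)
    expect_equal(P1$M, t(P1$M))
    expect_gte(min(eigen(P1$M, symmetric = TRUE)$values), -1e-8)
    P2 <- psd_project(P1$M)
    expect_equal(P2$M, P1$M, tolerance = 1e-10)
  }
})

test_that("projection equals the matrix-absolute-value identity (independent route)", {
  # P(S) = (S + (S^2)^{1/2}) / 2 with the square root from a Denman-Beavers
  # iteration -- no eigendecomposition involved.
  db_sqrt <- function(A, iters = 60) {
    Y <- A; Z <- diag(nrow(A))
    for (i in seq_len(iters)) {
      Yn <- 0.5 * (Y + solve(Z))
      Z <- 0.5 * (Z + solve(Y))
      Y <- Yn
    }
    Y
  }
  set.seed(19)
  for (s in 1:4) {
    S <- matrix(rnorm(25), 5, 5)
    S <- (S + t(S)) / 2
    oracle <- (S + db_sqrt(S %*% S)) / 2
    expect_equal(psd_project(S)$M, oracle, tolerance = 1e-7)
  }
})

test_that("alternating optimization respects null updates and the PSD contract", {
  fx <- planted_features(10, 3, 0.3, seed = 6)
  cfg0 <- train_config(lr_w = 0, lr_M = 0, outer_iters = 3L, seed = 1)
  res0 <- optimize_alternating(list(features = fx$X, labels = fx$labels), cfg = cfg0)
  expect_equal(res0$M$M, diag(3))
  expect_equal(diff(range(res0$history$loss)), 0, tolerance = 1e-12)
  cfg <- train_config(lr_M = 0.05, outer_iters = 5L, seed = 1)
  res <- optimize_alternating(list(features = fx$X, labels = fx$labels), cfg = cfg)
  expect_gte(min(res$M$eig_values), -1e-8)
  expect_error(optimize_alternating(list(features = fx$X,
                                         labels = rep(0, nrow(fx$X))),
                                    cfg = cfg), "two classes")
})

test_that("metric learning separates a linearly separable feature set", {
  fx <- planted_features(25, 4, 0.25, seed = 17)
  cfg <- train_config(lr_M = 0.05, outer_iters = 50L, metric_steps = 5L, seed = 2)
  res <- optimize_alternating(list(features = fx$X, labels = fx$labels), cfg = cfg)
  expect_lt(utils::tail(res$history$loss, 1), res$history$loss[1])
  M <- res$M
  n <- nrow(fx$X)
  D <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    mahalanobis_distance(fx$X[i, ], fx$X[j, ], M)
  }))
  same <- outer(fx$labels, fx$labels, "==") & upper.tri(D)
  cross <- outer(fx$labels, fx$labels, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[cross]))
})
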