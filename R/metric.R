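# Mahalanobis-distance triplet learning. The loss on a triplet
# (anchor a, positive p, negative n) with A = ||f(a)-f(n)||^2_M and
# B = ||f(a)-f(p)||^2_M is
#   L = mean( max(0, D_x) + mu * D_p ),  D_x = 1 - A / (B + alpha),  D_p = B,
# so the hinge activates exactly when the negative is insufficiently
# separated (A < B + alpha), and the pairwise term shrinks intraclass
# variance. Gradients are the chain rule through the ratio:
#   dD_x/dA = -1/(B+alpha),  dD_x/dB = A/(B+alpha)^2,
# with d||f_i-f_j||^2_M / d f_i = (M + M^T)(f_i - f_j) for the features and
# d||f_i-f_j||^2_M / dM = (f_i-f_j)(f_i-f_j)^T for the metric; both paths
# are validated against central finite differences in the test suite.
# M stays on the PSD cone by eigenvalue truncation after every metric step.

#' Metric matrix wrapper
#'
#' Symmetric matrix with its eigendecomposition cached after projection.
#'
#' @param M Square numeric matrix (symmetrized on construction).
#' @return Object of class \code{metric_matrix}.
#' @export
metric_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || !all(is.finite(M))) {
    stopf("`M` must be a finite square matrix")
  }
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  structure(list(M = M, eig_values = e$values, eig_vectors = e$vectors),
            class = "metric_matrix")
}

#' @keywords internal
#' @noRd
as_metric <- function(M) {
  if (inherits(M, "metric_matrix")) M$M else as.matrix(M)
}

#' Squared Mahalanobis distance
#'
#' \code{(f_i - f_j)^T M (f_i - f_j)}; the squared Euclidean distance when
#' \code{M} is the identity.
#'
#' @param f_i,f_j Numeric d-vectors.
#' @param M A \code{\link{metric_matrix}} or plain d x d matrix (PSD for a
#'   nonnegative result).
#' @return Nonnegative scalar (for PSD \code{M}).
#' @export
mahalanobis_distance <- function(f_i, f_j, M) {
  Mm <- as_metric(M)
  if (length(f_i) != length(f_j) || length(f_i) != nrow(Mm)) {
    stopf("dimension mismatch between features and metric")
  }
  d <- f_i - f_j
  as.numeric(d %*% Mm %*% d)
}

#' Loss configuration
#'
#' @param margin Triplet margin alpha >= 0 (the separation interval between
#'   similar and dissimilar pairs in the ratio denominator).
#' @param mu Pairwise balance weight mu >= 0.
#' @return List of class \code{loss_config}.
#' @export
loss_config <- function(margin = 1.0, mu = 0.1) {
  if (!is.finite(margin) || margin < 0 || !is.finite(mu) || mu < 0) {
    stopf("`margin` and `mu` must be finite and nonnegative")
  }
  structure(list(margin = margin, mu = mu), class = "loss_config")
}

#' @keywords internal
#' @noRd
triplet_matrix <- function(triplets) {
  if (is.list(triplets) && !is.data.frame(triplets)) {
    triplets <- do.call(rbind, lapply(triplets, function(t) {
      unlist(t[c("anchor", "positive", "negative")], use.names = FALSE)
    }))
  }
  tm <- as.matrix(triplets)
  if (ncol(tm) != 3L || nrow(tm) == 0L) {
    stopf("`triplets` must be a nonempty set of (anchor, positive, negative) index triples")
  }
  storage.mode(tm) <- "integer"
  tm
}

# Per-triplet A (anchor-negative) and B (anchor-positive) squared distances
# plus the difference vectors, shared by loss and both gradient paths.
#' @keywords internal
#' @noRd
triplet_terms <- function(X, tm, Mm) {
  dap <- X[tm[, 1], , drop = FALSE] - X[tm[, 2], , drop = FALSE]
  dan <- X[tm[, 1], , drop = FALSE] - X[tm[, 3], , drop = FALSE]
  list(dap = dap, dan = dan,
       B = rowSums((dap %*% Mm) * dap),
       A = rowSums((dan %*% Mm) * dan))
}

#' Original (Euclidean, additive-margin) triplet loss
#'
#' The classic baseline \code{sum_i max(0, D(a,p) - D(a,n) + alpha)} with
#' squared Euclidean distances, provided for ablation against the
#' ratio-form loss.
#'
#' @param embeddings An \code{\link{embedding_batch}} or n x d matrix.
#' @param triplets Index triples (matrix with columns anchor/positive/
#'   negative, or a list of such triples).
#' @param margin Margin alpha.
#' @return Scalar loss.
#' @export
original_triplet_loss <- function(embeddings, triplets, margin = 1.0) {
  X <- if (inherits(embeddings, "embedding_batch")) embeddings$vectors else as.matrix(embeddings)
  tm <- triplet_matrix(triplets)
  if (max(tm) > nrow(X) || min(tm) < 1L) stopf("triplet index out of range")
  tt <- triplet_terms(X, tm, diag(ncol(X)))
  sum(pmax(0, tt$B - tt$A + margin))
}

#' Improved ratio-form triplet loss with pairwise constraint
#'
#' @param embeddings An \code{\link{embedding_batch}} or n x d matrix.
#' @param triplets Index triples (see \code{\link{original_triplet_loss}}).
#' @param M Metric matrix (PSD).
#' @param cfg A \code{\link{loss_config}}.
#' @return Object of class \code{triplet_loss_report}: \code{total},
#'   per-triplet \code{Dx} and \code{Dp}, \code{active_count} (triplets with
#'   a positive hinge), and \code{n}.
#' @export
improved_triplet_loss <- function(embeddings, triplets, M, cfg = loss_config()) {
  X <- if (inherits(embeddings, "embedding_batch")) embeddings$vectors else as.matrix(embeddings)
  tm <- triplet_matrix(triplets)
  if (max(tm) > nrow(X) || min(tm) < 1L) stopf("triplet index out of range")
  Mm <- as_metric(M)
  tt <- triplet_terms(X, tm, Mm)
  denom <- tt$B + cfg$margin
  if (any(denom <= 0)) {
    stopf("degenerate ratio: B + alpha must be positive (alpha = 0 with coincident anchor/positive)")
  }
  Dx <- 1 - tt$A / denom
  structure(list(total = mean(pmax(0, Dx) + cfg$mu * tt$B),
                 per_triplet_Dx = Dx, per_triplet_Dp = tt$B,
                 active_count = sum(Dx > 0), n = nrow(tm)),
            class = "triplet_loss_report")
}

#' @export
print.triplet_loss_report <- function(x, ...) {
  cat(sprintf("Triplet loss %.6f over %d triplets (%d active)\n",
              x$total, x$n, x$active_count))
  invisible(x)
}

#' Analytic loss gradient with respect to the feature vectors
#'
#' Chain rule through \code{D_x} and \code{D_p}: active triplets (hinge
#' \code{D_x > 0}) contribute through the ratio derivatives acting on
#' \code{(M + M^T)} feature differences; inactive triplets contribute zero
#' through the triplet term, while the pairwise term always contributes
#' \code{mu * (M + M^T)(f_a - f_p)}.
#'
#' @inheritParams improved_triplet_loss
#' @return Object of class \code{gradient_bundle}: \code{grad_features}
#'   (n x d, accumulated over every role each point plays), per-triplet
#'   ratio coefficients \code{gA}/\code{gB}, and \code{active}.
#' @export
loss_grad_features <- function(embeddings, triplets, M, cfg = loss_config()) {
  X <- if (inherits(embeddings, "embedding_batch")) embeddings$vectors else as.matrix(embeddings)
  tm <- triplet_matrix(triplets)
  Mm <- as_metric(M)
  Mt <- Mm + t(Mm)
  tt <- triplet_terms(X, tm, Mm)
  n <- nrow(tm)
  denom <- tt$B + cfg$margin
  if (any(denom <= 0)) stopf("degenerate ratio: B + alpha must be positive")
  Dx <- 1 - tt$A / denom
  act <- as.numeric(Dx > 0)
  gA <- -1 / denom                       # dDx/dA
  gB <- tt$A / denom^2                   # dDx/dB
  Gap <- tt$dap %*% Mt                   # row i: (M+M^T)(f_a - f_p)
  Gan <- tt$dan %*% Mt
  G <- matrix(0, nrow(X), ncol(X))
  coA <- act * gA / n
  coB <- (act * gB + cfg$mu) / n
  for (i in seq_len(n)) {
    a <- tm[i, 1]; p <- tm[i, 2]; ng <- tm[i, 3]
    G[a, ]  <- G[a, ]  + coA[i] * Gan[i, ] + coB[i] * Gap[i, ]
    G[ng, ] <- G[ng, ] - coA[i] * Gan[i, ]
    G[p, ]  <- G[p, ]  - coB[i] * Gap[i, ]
  }
  structure(list(grad_features = G, gA = gA, gB = gB, active = act, n = n),
            class = "gradient_bundle")
}

#' Analytic loss gradient with respect to the metric matrix
#'
#' Per active triplet \code{dD_x/dM = gA * C_an + gB * C_ap} with the outer
#' products \code{C_ij = (f_i - f_j)(f_i - f_j)^T}; \code{dD_p/dM = C_ap}
#' always, weighted by \code{mu}; averaged over triplets.
#'
#' @inheritParams improved_triplet_loss
#' @return Object of class \code{gradient_bundle} with the symmetric
#'   \code{grad_metric} (d x d) plus the per-triplet coefficients.
#' @export
loss_grad_metric <- function(embeddings, triplets, M, cfg = loss_config()) {
  X <- if (inherits(embeddings, "embedding_batch")) embeddings$vectors else as.matrix(embeddings)
  tm <- triplet_matrix(triplets)
  Mm <- as_metric(M)
  tt <- triplet_terms(X, tm, Mm)
  n <- nrow(tm)
  denom <- tt$B + cfg$margin
  if (any(denom <= 0)) stopf("degenerate ratio: B + alpha must be positive")
  Dx <- 1 - tt$A / denom
  act <- as.numeric(Dx > 0)
  gA <- -1 / denom
  gB <- tt$A / denom^2
  # sum_i wAn_i dan_i dan_i^T + wAp_i dap_i dap_i^T, as weighted crossproducts
  wAn <- act * gA / n
  wAp <- (act * gB + cfg$mu) / n
  Gm <- crossprod(tt$dan * wAn, tt$dan) + crossprod(tt$dap * wAp, tt$dap)
  structure(list(grad_metric = (Gm + t(Gm)) / 2, gA = gA, gB = gB,
                 active = act, n = n),
            class = "gradient_bundle")
}

#' Projection onto the PSD cone
#'
#' Symmetrizes, eigendecomposes \code{M = V D V^T}, zeroes every negative
#' eigenvalue, and reassembles — the Frobenius-nearest PSD matrix, applied
#' after every metric gradient step.
#'
#' @param M_raw Square numeric matrix.
#' @return A \code{\link{metric_matrix}} with all eigenvalues >= 0.
#' @export
psd_project <- function(M_raw) {
  M_raw <- as_metric(M_raw)
  if (!all(is.finite(M_raw))) stopf("`M_raw` must have finite entries")
  S <- (M_raw + t(M_raw)) / 2
  e <- eigen(S, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  P <- e$vectors %*% (pos * t(e$vectors))
  out <- metric_matrix((P + t(P)) / 2)
  out$eig_values <- pos
  out$eig_vectors <- e$vectors
  out
}

#' Training configuration for the alternating optimizer
#'
#' @param margin,mu Loss parameters (see \code{\link{loss_config}}).
#' @param lr_w Learning rate for the network weights (stage 1).
#' @param lr_M Step size for the projected metric gradient descent (stage 2).
#' @param momentum SGD momentum for stage 1.
#' @param weight_decay L2 penalty on the network weights.
#' @param outer_iters Number of alternating outer iterations.
#' @param inner_batches Stage-1 mini-batches per outer iteration.
#' @param metric_steps Stage-2 projected gradient steps per outer iteration.
#' @param batch_K,batch_L Classes per batch and images per class.
#' @param lr_decay,lr_milestones Multiply \code{lr_w} by \code{lr_decay} at
#'   each milestone iteration (empty = constant rate).
#' @param seed Integer seed driving batch sampling.
#' @return List of class \code{train_config}.
#' @export
train_config <- function(margin = 1.0, mu = 0.1, lr_w = 0.01, lr_M = 0.01,
                         momentum = 0, weight_decay = 0, outer_iters = 20L,
                         inner_batches = 2L, metric_steps = 5L,
                         batch_K = 2L, batch_L = 8L,
                         lr_decay = 1, lr_milestones = integer(0), seed = 1L) {
  structure(list(margin = margin, mu = mu, lr_w = lr_w, lr_M = lr_M,
                 momentum = momentum, weight_decay = weight_decay,
                 outer_iters = as.integer(outer_iters),
                 inner_batches = as.integer(inner_batches),
                 metric_steps = as.integer(metric_steps),
                 batch_K = as.integer(batch_K), batch_L = as.integer(batch_L),
                 lr_decay = lr_decay, lr_milestones = as.integer(lr_milestones),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter-tree helpers for SGD ----------------------------------------

#' @keywords internal
#' @noRd
is_param_leaf <- function(x) is.list(x) && !is.null(x$W)

#' @keywords internal
#' @noRd
sgd_update <- function(params, grads, vel, lr, momentum, wd) {
  step <- function(p, g, v) {
    if (is_param_leaf(p)) {
      v$W <- momentum * v$W - lr * (g$dW + wd * p$W)
      v$b <- momentum * v$b - lr * g$db
      p$W <- p$W + v$W
      p$b <- p$b + v$b
      return(list(p = p, v = v))
    }
    for (i in seq_along(p)) {
      nm <- names(p)[i]
      named <- !is.null(nm) && nzchar(nm)
      gi <- if (named) g[[nm]] else g[[i]]
      vi <- if (named) v[[nm]] else v[[i]]
      if (is.list(p[[i]]) && !is.null(gi)) {
        r <- step(p[[i]], gi, vi)
        p[[i]] <- r$p
        v[[i]] <- r$v
      }
    }
    list(p = p, v = v)
  }
  step(params, grads, vel)
}

#' @keywords internal
#' @noRd
zero_like <- function(params) {
  z <- function(p) {
    if (is_param_leaf(p)) return(list(W = p$W * 0, b = p$b * 0))
    if (is.list(p)) return(lapply(p, function(el) if (is.list(el)) z(el) else NULL))
    NULL
  }
  z(params)
}

#' @keywords internal
#' @noRd
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (!is.null(a$dW)) return(list(dW = a$dW + b$dW, db = a$db + b$db))
  out <- a
  nm <- if (!is.null(names(a))) names(a) else seq_along(a)
  for (i in seq_along(a)) out[[i]] <- grad_add(a[[i]], b[[i]])
  out
}

# ---- alternating optimization ----------------------------------------------

#' Two-stage alternating optimization of network weights and metric
#'
#' Per outer iteration: stage 1 fixes \code{M} and runs mini-batch momentum
#' SGD on the network weights through the feature gradients of the loss and
#' backpropagation (skipped for the identity extractor); stage 2 fixes the
#' weights, recomputes embeddings, and takes projected gradient steps on
#' \code{M}, re-projecting onto the PSD cone after every step. \code{M}
#' starts at the identity unless \code{M0} is given. Batches are K-class x
#' L-image plans mined for batch-hard triplets under the current \code{M}.
#'
#' @param data A \code{\link{labeled_image_set}} (requires \code{backbone}),
#'   or a list with \code{features} (n x d matrix) and \code{labels} for the
#'   identity extractor (tabular/feature inputs; stage 1 is then a no-op).
#' @param backbone \code{\link{build_backbone}} parameters, or \code{NULL}
#'   for the identity extractor.
#' @param M0 Initial metric (default identity).
#' @param cfg A \code{\link{train_config}}.
#' @return List with the updated \code{backbone}, the learned \code{M}
#'   (a \code{\link{metric_matrix}}), and a \code{history} data frame
#'   (iteration, loss, active_triplets) of full-data loss before each
#'   iteration plus the final state.
#' @export
optimize_alternating <- function(data, backbone = NULL, M0 = NULL,
                                 cfg = train_config()) {
  if (inherits(data, "labeled_image_set") ||
      (is.list(data) && !is.null(data$images))) {
    if (is.null(backbone)) stopf("image data requires backbone parameters")
    labels <- data$labels
    imgs <- data$images
    get_X <- function() embed(imgs, backbone)$vectors
    d <- backbone$config$embed_dim
  } else if (is.list(data) && !is.null(data$features)) {
    feats <- as.matrix(data$features)
    labels <- as.integer(data$labels)
    get_X <- function() feats
    d <- ncol(feats)
  } else {
    stopf("`data` must be a labeled_image_set or list(features, labels)")
  }
  if (length(labels) < 2L || length(unique(labels)) < 2L) {
    stopf("training needs at least two classes with members")
  }
  identity_extractor <- is.null(backbone)
  lcfg <- loss_config(cfg$margin, cfg$mu)
  M <- if (is.null(M0)) metric_matrix(diag(d)) else {
    if (inherits(M0, "metric_matrix")) M0 else metric_matrix(M0)
  }
  vel <- if (!identity_extractor) zero_like(backbone) else NULL
  lr_w <- cfg$lr_w
  history <- data.frame(iteration = integer(0), loss = numeric(0),
                        active_triplets = integer(0))
  full_loss <- function() {
    X <- get_X()
    plan <- full_batch_plan(labels)
    tr <- mine_hard_triplets(embedding_batch(X, labels), M, plan)
    if (length(tr) == 0L) return(list(total = NA_real_, active_count = NA_integer_))
    improved_triplet_loss(X, tr, M, lcfg)
  }
  bseed <- cfg$seed
  for (it in seq_len(cfg$outer_iters)) {
    rep0 <- full_loss()
    history <- rbind(history, data.frame(iteration = it - 1L, loss = rep0$total,
                                         active_triplets = rep0$active_count))
    if (it %in% cfg$lr_milestones) lr_w <- lr_w * cfg$lr_decay
    # ---- stage 1: M fixed, SGD on network weights
    if (!identity_extractor && lr_w > 0) {
      for (bb in seq_len(cfg$inner_batches)) {
        bseed <- (bseed * 69069 + 1) %% 2147483647
        plan <- sample_pk_batch(labels, cfg$batch_K, cfg$batch_L, seed = bseed)
        bidx <- plan$indices
        fwd <- lapply(imgs[bidx], backbone_fwd_one, params = backbone)
        Xb <- t(vapply(fwd, `[[`, numeric(d), "embedding"))
        eb <- embedding_batch(Xb, labels[bidx])
        lplan <- local_plan(plan)
        tr <- mine_hard_triplets(eb, M, lplan)
        if (length(tr) == 0L) next
        gb <- loss_grad_features(eb, tr, M, lcfg)
        agg <- NULL
        for (j in seq_along(bidx)) {
          de <- gb$grad_features[j, ]
          if (all(de == 0)) next
          g1 <- backbone_bwd_one(fwd[[j]]$cache, de, backbone)
          agg <- if (is.null(agg)) g1 else grad_add(agg, g1)
        }
        if (is.null(agg)) next
        r <- sgd_update(backbone, agg, vel, lr_w, cfg$momentum, cfg$weight_decay)
        backbone <- r$p; vel <- r$v
      }
    }
    # ---- stage 2: weights fixed, projected gradient descent on M over
    # freshly sampled K x L batches (hardness stays batch-local)
    X <- get_X()
    eb <- embedding_batch(X, labels)
    for (ms in seq_len(cfg$metric_steps)) {
      bseed <- (bseed * 69069 + 1) %% 2147483647
      plan <- sample_pk_batch(labels, cfg$batch_K, cfg$batch_L, seed = bseed)
      tr <- suppressWarnings(mine_hard_triplets(eb, M, plan))
      if (length(tr) == 0L) next
      gm <- loss_grad_metric(eb$vectors, tr, M, lcfg)
      M <- psd_project(M$M - cfg$lr_M * gm$grad_metric)
    }
  }
  repF <- full_loss()
  history <- rbind(history, data.frame(iteration = cfg$outer_iters,
                                       loss = repF$total,
                                       active_triplets = repF$active_count))
  list(backbone = backbone, M = M, history = history)
}

# Batch plan covering the whole labeled set (each class, all members).
#' @keywords internal
#' @noRd
full_batch_plan <- function(labels) {
  cls <- sort(unique(labels))
  members <- lapply(cls, function(cl) which(labels == cl))
  structure(list(class_ids = cls, member_ids = members,
                 K = length(cls), L = max(lengths(members)),
                 indices = unlist(members)),
            class = "batch_plan")
}

# Re-index a batch plan to positions within its own batch.
#' @keywords internal
#' @noRd
local_plan <- function(plan) {
  pos <- seq_along(plan$indices)
  lens <- lengths(plan$member_ids)
  members <- split(pos, rep(seq_along(lens), lens))
  structure(list(class_ids = plan$class_ids, member_ids = members,
                 K = plan$K, L = plan$L, indices = pos),
            class = "batch_plan")
}
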