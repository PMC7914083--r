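# Triplet enumeration and batch-hard mining. Materializing every possible
# triplet is infeasible (N(N-1)M^2(M-1) grows fast), so training samples
# K classes x L images per batch and keeps, per anchor, only the hardest
# positive (farthest same-class member) and hardest negative (nearest
# different-class member) under the current Mahalanobis metric.

#' Count all possible triplets
#'
#' With \code{N} classes of \code{M} images each, the number of distinct
#' (anchor, positive, negative) triplets is \code{N(N-1) M^2 (M-1)}.
#'
#' @param n_classes Number of classes N (>= 2).
#' @param per_class Images per class M (>= 2).
#' @return The triplet count as a double (counts overflow integers quickly).
#' @export
count_possible_triplets <- function(n_classes, per_class) {
  if (!is.numeric(n_classes) || n_classes < 2 || n_classes != round(n_classes) ||
      !is.numeric(per_class) || per_class < 2 || per_class != round(per_class)) {
    stopf("need at least 2 classes and 2 images per class for any triplet to exist")
  }
  N <- as.numeric(n_classes); M <- as.numeric(per_class)
  N * (N - 1) * M^2 * (M - 1)
}

#' Sample a K-class x L-image batch plan
#'
#' Draws \code{K} distinct classes uniformly, then \code{L} members per class
#' (without replacement when the class has at least \code{L} members, with
#' replacement otherwise; duplicates are collapsed at mining time).
#'
#' @param labels Integer label vector for the full dataset.
#' @param K Number of classes per batch.
#' @param L Images per class.
#' @param seed Integer seed; equal seeds give identical plans.
#' @return Object of class \code{batch_plan} with \code{class_ids},
#'   \code{member_ids} (list of index vectors into \code{labels}), \code{K},
#'   \code{L}, and the flattened \code{indices}.
#' @export
sample_pk_batch <- function(labels, K, L, seed = 1L) {
  labels <- as.integer(labels)
  assert_scalar_count(K, "K"); assert_scalar_count(L, "L")
  cls <- sort(unique(labels))
  if (length(cls) < K) {
    stopf("batch needs K = %d classes but only %d exist", K, length(cls))
  }
  with_seed(seed, {
    chosen <- sort(sample(cls, K))
    members <- lapply(chosen, function(cl) {
      pool <- which(labels == cl)
      if (length(pool) >= L) sample(pool, L) else sample(pool, L, replace = TRUE)
    })
    structure(list(class_ids = chosen, member_ids = members,
                   K = as.integer(K), L = as.integer(L),
                   indices = unlist(members)),
              class = "batch_plan")
  })
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("Batch plan: K = %d classes x L = %d images (%d total)\n",
              x$K, x$L, length(x$indices)))
  invisible(x)
}

#' Batch-hard triplet mining
#'
#' For every image in the batch, forms one triplet: the positive is the
#' same-class member at maximal Mahalanobis distance from the anchor, the
#' negative the different-class member at minimal distance; ties break to
#' the lowest index. Anchors whose class contributes a single distinct
#' member are skipped (no positive exists).
#'
#' @param embeddings An \code{\link{embedding_batch}} (or n x d matrix)
#'   covering every index the plan references.
#' @param M Metric matrix defining hardness (a \code{\link{metric_matrix}}
#'   or plain PSD matrix).
#' @param plan A \code{\link{batch_plan}}.
#' @return Matrix with columns \code{anchor}, \code{positive},
#'   \code{negative} (dataset indices); zero rows, with a warning, when every
#'   anchor was skipped.
#' @export
mine_hard_triplets <- function(embeddings, M, plan) {
  X <- if (inherits(embeddings, "embedding_batch")) embeddings$vectors else as.matrix(embeddings)
  stopifnot(inherits(plan, "batch_plan"))
  Mm <- as_metric(M)
  members <- lapply(plan$member_ids, function(ix) sort(unique(ix)))
  idx <- unlist(members)
  if (max(idx) > nrow(X)) stopf("plan references rows beyond the embedding batch")
  grp <- rep(seq_along(members), lengths(members))
  B <- length(idx)
  Xb <- X[idx, , drop = FALSE]
  G <- Xb %*% Mm %*% t(Xb)                 # squared distances via Gram matrix
  q <- diag(G)
  D <- outer(q, q, "+") - G - t(G)
  triplets <- matrix(0L, 0L, 3L, dimnames = list(NULL, c("anchor", "positive", "negative")))
  for (a in seq_len(B)) {
    same <- which(grp == grp[a] & seq_len(B) != a)
    if (length(same) == 0L) next
    diff <- which(grp != grp[a])
    if (length(diff) == 0L) next
    p <- same[which.max(D[a, same])]       # which.max/min tie-break: first =
    ng <- diff[which.min(D[a, diff])]      # lowest index (members sorted)
    triplets <- rbind(triplets, c(idx[a], idx[p], idx[ng]))
  }
  if (nrow(triplets) == 0L) {
    warning("no triplet could be mined: every class contributed a single member",
            call. = FALSE)
  }
  triplets
}
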