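# End-to-end workflow: preprocess -> embed -> mine -> alternating
# optimization -> nearest-centroid classification under the learned metric.
# matriplet() is the single fitting entry point; the returned object carries
# the trained backbone, the metric matrix M, per-class centroids, and the
# training history, with the usual modelling methods on top.

#' Full training configuration
#'
#' Bundles the backbone preset, preprocessing switches, loss/optimizer
#' settings, and the attention head options.
#'
#' @param preset \code{"desk"} (default): 64x64 inputs, desk backbone,
#'   20 outer iterations, lr 0.02 on the weights and 0.05 on the metric,
#'   2x8 batches — the scale every example and test runs at.
#'   \code{"jsrt-full"}: the chest-radiograph schedule
#'   (2048x2048 inputs, full-width backbone, initial lr 0.01
#'   decayed x0.1 at iterations 50 and 80, 160 iterations, 16x8 = 128-image
#'   batches, plain SGD) — shipped for fidelity; training it needs GPU-scale
#'   compute. \code{"wbcd"}: the cytology-table schedule (identity
#'   extractor, lr 0.001, 2x8 = 16-row batches, momentum 0.3, weight decay
#'   4e-4).
#' @param ... Named overrides of any field (e.g. \code{outer_iters},
#'   \code{margin}, \code{enhance}, \code{rounds}).
#' @return List of class \code{mt_config}.
#' @export
mt_config <- function(preset = c("desk", "jsrt-full", "wbcd"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    "desk" = list(
      input_size = 64L, backbone_preset = "desk", enhance = FALSE,
      margin = 1.0, mu = 0.1, lr_w = 0.02, lr_M = 0.05, momentum = 0,
      weight_decay = 0, outer_iters = 20L, inner_batches = 4L,
      metric_steps = 5L, batch_K = 2L, batch_L = 8L,
      lr_decay = 1, lr_milestones = integer(0),
      rounds = 2L, attention_k = 16L, use_attention = FALSE),
    "jsrt-full" = list(
      input_size = 2048L, backbone_preset = "full", enhance = TRUE,
      margin = 1.0, mu = 0.1, lr_w = 0.01, lr_M = 0.01, momentum = 0,
      weight_decay = 0, outer_iters = 160L, inner_batches = 1L,
      metric_steps = 5L, batch_K = 16L, batch_L = 8L,
      lr_decay = 0.1, lr_milestones = c(50L, 80L),
      rounds = 2L, attention_k = 64L, use_attention = FALSE),
    "wbcd" = list(
      input_size = NA_integer_, backbone_preset = NA_character_, enhance = FALSE,
      margin = 1.0, mu = 0.1, lr_w = 0.001, lr_M = 0.01, momentum = 0.3,
      weight_decay = 4e-4, outer_iters = 50L, inner_batches = 1L,
      metric_steps = 5L, batch_K = 2L, batch_L = 8L,
      lr_decay = 1, lr_milestones = integer(0),
      rounds = 2L, attention_k = 16L, use_attention = FALSE))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config fields: %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$preset <- preset
  structure(cfg, class = "mt_config")
}

#' @keywords internal
#' @noRd
as_train_config <- function(cfg, seed) {
  train_config(margin = cfg$margin, mu = cfg$mu, lr_w = cfg$lr_w,
               lr_M = cfg$lr_M, momentum = cfg$momentum,
               weight_decay = cfg$weight_decay, outer_iters = cfg$outer_iters,
               inner_batches = cfg$inner_batches, metric_steps = cfg$metric_steps,
               batch_K = cfg$batch_K, batch_L = cfg$batch_L,
               lr_decay = cfg$lr_decay, lr_milestones = cfg$lr_milestones,
               seed = seed)
}

#' @keywords internal
#' @noRd
preprocess_set <- function(x, config) {
  imgs <- lapply(x$images, function(im) {
    if (isTRUE(config$enhance)) im <- equalize_histogram(im)
    resize_normalize(im, config$input_size)
  })
  list(images = imgs, labels = x$labels, ids = x$ids)
}

#' Fit a Mahalanobis-metric triplet classifier
#'
#' Trains the embedding network (for image input) and the metric matrix by
#' two-stage alternating optimization of the ratio-form triplet loss with
#' pairwise constraint, then stores one embedding centroid per class for
#' nearest-centroid classification under the learned metric.
#'
#' @param x Training data: a \code{\link{labeled_image_set}}, a
#'   \code{\link{tabular_set}} (complete rows only; see
#'   \code{\link{drop_missing}}), or a numeric feature matrix with
#'   \code{labels}. Tabular/matrix input uses the identity extractor: only
#'   the metric is learned.
#' @param labels Integer class labels when \code{x} is a plain matrix.
#' @param config An \code{\link{mt_config}}.
#' @param seed Integer seed controlling initialization and batch sampling;
#'   fixing it makes training bit-reproducible.
#' @return Object of class \code{matriplet}: the trained \code{backbone}
#'   (NULL for the identity extractor), metric \code{M}, class
#'   \code{centroids}, training \code{history}, the attention head, and the
#'   configuration.
#' @export
#' @examples
#' \donttest{
#' set <- generate_blob_images(2, 20, 64, 1.0, seed = 7)
#' fit <- matriplet(set, config = mt_config(outer_iters = 3L), seed = 1)
#' predict(fit, set)
#' }
matriplet <- function(x, labels = NULL, config = mt_config(), seed = 1L) {
  stopifnot(inherits(config, "mt_config"))
  tcfg <- as_train_config(config, seed)
  if (inherits(x, "labeled_image_set")) {
    if (length(unique(x$labels)) < 2L || min(table(x$labels)) < 2L) {
      stopf("training needs >= 2 classes with >= 2 images each")
    }
    pp <- preprocess_set(x, config)
    backbone <- build_backbone(backbone_config(config$backbone_preset), seed = seed)
    res <- optimize_alternating(list(images = pp$images, labels = pp$labels),
                                backbone = backbone, M0 = NULL, cfg = tcfg)
    emb <- embed(pp$images, res$backbone, labels = pp$labels)
    train_ids <- x$ids
    extractor <- "backbone"
  } else {
    if (inherits(x, "tabular_set")) {
      if (any(!stats::complete.cases(x$records))) {
        stopf("tabular input contains missing values; apply drop_missing() first")
      }
      feats <- as.matrix(x$records)
      labels <- x$labels
      train_ids <- x$ids
    } else {
      feats <- as.matrix(x)
      if (is.null(labels)) stopf("`labels` required for matrix input")
      train_ids <- rownames(feats)
    }
    res <- optimize_alternating(list(features = feats, labels = labels),
                                backbone = NULL, M0 = NULL, cfg = tcfg)
    emb <- embedding_batch(feats, as.integer(labels))
    extractor <- "identity"
  }
  cls <- sort(unique(emb$labels))
  centroids <- t(vapply(cls, function(cl) {
    colMeans(emb$vectors[emb$labels == cl, , drop = FALSE])
  }, numeric(ncol(emb$vectors))))
  rownames(centroids) <- cls
  att <- NULL
  if (extractor == "backbone") {
    ncl <- length(cls)
    cch <- utils::tail(res$backbone$config$widths, 1L)
    att <- list(
      params = attention_params(d = cch, k = config$attention_k,
                                vocab_size = ncl, seed = seed),
      category_memory = matrix(with_seed(seed + 1L,
                                         stats::runif(ncl * cch, -0.1, 0.1)),
                               ncl, cch),
      rounds = config$rounds)
  }
  structure(list(backbone = if (extractor == "backbone") res$backbone else NULL,
                 M = res$M, centroids = centroids, classes = cls,
                 history = res$history, attention = att, config = config,
                 extractor = extractor, train_ids = train_ids, seed = seed),
            class = "matriplet")
}

#' @keywords internal
#' @noRd
model_embed <- function(object, x) {
  if (object$extractor == "backbone") {
    if (inherits(x, "labeled_image_set")) {
      pp <- preprocess_set(x, object$config)
      embed(pp$images, object$backbone, labels = pp$labels)
    } else {
      if (is.matrix(x)) x <- list(x)
      imgs <- lapply(x, function(im) {
        if (isTRUE(object$config$enhance)) im <- equalize_histogram(im)
        resize_normalize(im, object$config$input_size)
      })
      embed(imgs, object$backbone)
    }
  } else {
    feats <- if (inherits(x, "tabular_set")) {
      if (any(!stats::complete.cases(x$records))) {
        stopf("input contains missing values; apply drop_missing() first")
      }
      as.matrix(x$records)
    } else {
      as.matrix(x)
    }
    lab <- if (inherits(x, "tabular_set")) x$labels else NULL
    embedding_batch(feats, lab)
  }
}

#' Nearest-centroid classification under the learned metric
#'
#' Embeds the inputs and assigns each to the class whose stored centroid is
#' nearest in Mahalanobis distance; ties go to the lowest class id.
#'
#' @param model A fitted \code{\link{matriplet}} object.
#' @param x New images (\code{labeled_image_set}, list of matrices, or a
#'   single matrix) or features/tabular rows for identity-extractor models.
#' @return List with \code{labels} (predicted class ids) and \code{scores}
#'   (n x K matrix of squared Mahalanobis distances to each centroid).
#' @export
classify_nearest_centroid <- function(model, x) {
  stopifnot(inherits(model, "matriplet"))
  if (is.null(model$centroids) || nrow(model$centroids) == 0L) {
    stopf("model has no stored class centroids")
  }
  emb <- model_embed(model, x)
  X <- emb$vectors
  C <- model$centroids
  Mm <- as_metric(model$M)
  XC <- X %*% Mm %*% t(C)
  qx <- rowSums((X %*% Mm) * X)
  qc <- rowSums((C %*% Mm) * C)
  D <- outer(qx, qc, "+") - 2 * XC
  pred <- model$classes[apply(D, 1, which.min)]   # which.min: lowest id on ties
  colnames(D) <- model$classes
  list(labels = pred, scores = D)
}

#' @rdname classify_nearest_centroid
#' @param object A fitted \code{matriplet} model.
#' @param newdata Data to classify.
#' @param type \code{"class"} for labels, \code{"distance"} for the distance
#'   matrix, \code{"posterior"} for softmax(-distance) class probabilities.
#' @param ... Unused.
#' @export
predict.matriplet <- function(object, newdata,
                              type = c("class", "distance", "posterior"), ...) {
  type <- match.arg(type)
  out <- classify_nearest_centroid(object, newdata)
  switch(type,
         class = out$labels,
         distance = out$scores,
         posterior = t(apply(-out$scores, 1, softmax)))
}

#' Evaluate a fitted model on labeled data
#'
#' @param model A fitted \code{\link{matriplet}} object.
#' @param data A \code{\link{labeled_image_set}} or \code{\link{tabular_set}}
#'   disjoint from the training data (an id overlap triggers a warning).
#' @return Object of class \code{matriplet_eval}: \code{accuracy},
#'   \code{per_class_accuracy}, \code{confusion_counts} (true x predicted),
#'   \code{n_eval}.
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(model, "matriplet"))
  labels <- if (inherits(data, "labeled_image_set") || inherits(data, "tabular_set")) {
    data$labels
  } else {
    stopf("`data` must be a labeled_image_set or tabular_set")
  }
  if (length(labels) == 0L) stopf("`data` is empty")
  if (!is.null(data$ids) && !is.null(model$train_ids)) {
    leaked <- intersect(data$ids, model$train_ids)
    if (length(leaked)) {
      warning(sprintf("%d evaluation ids were seen in training", length(leaked)),
              call. = FALSE)
    }
  }
  pred <- classify_nearest_centroid(model, data)$labels
  lev <- sort(unique(c(model$classes, labels)))
  conf <- table(true = factor(labels, lev), predicted = factor(pred, lev))
  per_class <- diag(conf) / pmax(rowSums(conf), 1L)
  structure(list(accuracy = mean(pred == labels),
                 per_class_accuracy = per_class,
                 confusion_counts = conf, n_eval = length(labels)),
            class = "matriplet_eval")
}

#' @export
print.matriplet_eval <- function(x, ...) {
  cat(sprintf("Accuracy %.4f over %d samples\n", x$accuracy, x$n_eval))
  print(x$confusion_counts)
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits indices class by class so both parts keep the label proportions.
#'
#' @param labels Integer label vector.
#' @param train_frac Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(labels, train_frac = 0.5, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stopf("`train_frac` must be in (0, 1)")
  with_seed(seed, {
    tr <- unlist(lapply(sort(unique(labels)), function(cl) {
      pool <- which(labels == cl)
      sample(pool, max(1L, round(train_frac * length(pool))))
    }))
    list(train = sort(tr), test = setdiff(seq_along(labels), tr))
  })
}

# ---- attention coupling -----------------------------------------------------

#' Final convolutional feature map of an image
#'
#' Runs the stem and residual stages only, returning the map whose spatial
#' positions serve as visual fact memory for the attention encoder.
#'
#' @param image Numeric matrix with values in \code{[0, 1]}.
#' @param params \code{\link{build_backbone}} parameters.
#' @return Array of dim \code{(H, W, C)}.
#' @export
backbone_conv_map <- function(image, params) {
  x <- array(image, c(dim(image), 1L))
  st <- conv_fwd(x, params$stem)
  x <- maxpool_fwd(relu_fwd(st$out)$out)$out
  for (stage in params$stages) for (blk in stage) x <- block_fwd(x, blk)$out
  x
}

#' Attention-encode an image through the trained backbone
#'
#' Couples the attention encoder to the metric model: the final conv map's
#' spatial positions (flattened row vectors of channels) form the visual
#' fact memory, a per-class table forms the category memory, the query is
#' the recurrent encoding of the region sequence, and the discriminative
#' decoder scores one single-token candidate per class.
#'
#' @param model A fitted \code{\link{matriplet}} image model (the attention
#'   head is built at fit time).
#' @param image Numeric matrix in \code{[0, 255]} (preprocessed like the
#'   training images).
#' @return List with the \code{encoder_state} and the decoder
#'   \code{posterior} over classes.
#' @export
attention_encode_image <- function(model, image) {
  stopifnot(inherits(model, "matriplet"))
  if (is.null(model$attention)) stopf("model has no attention head (identity extractor)")
  if (isTRUE(model$config$enhance)) image <- equalize_histogram(image)
  im <- resize_normalize(image, model$config$input_size)
  map <- backbone_conv_map(im, model$backbone)
  d <- dim(map)
  regions <- matrix(map, d[1] * d[2], d[3])       # R x C region vectors
  att <- model$attention
  banks <- memory_banks(att$category_memory, regions)
  V_fc <- encode_input(regions, att$params)
  st <- multi_round_encode(V_fc, banks, att$params, att$rounds)
  dec <- discriminative_decode(st$encoded,
                               as.list(seq_along(model$classes)), att$params)
  list(state = st, posterior = dec$posterior,
       class = model$classes[which.max(dec$posterior)])
}

# ---- standard modelling methods --------------------------------------------

#' @export
print.matriplet <- function(x, ...) {
  cat("Mahalanobis-metric triplet classifier\n")
  cat(sprintf("  extractor: %s%s\n", x$extractor,
              if (x$extractor == "backbone")
                sprintf(" (%s preset, %d-d embedding)",
                        x$backbone$config$preset, x$backbone$config$embed_dim)
              else ""))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  metric: %dx%d, rank %d\n", nrow(x$M$M), ncol(x$M$M),
              sum(x$M$eig_values > 1e-8 * max(x$M$eig_values, 1e-12))))
  h <- x$history
  if (nrow(h) >= 2L) {
    cat(sprintf("  loss: %.4f -> %.4f over %d iterations\n",
                h$loss[1], h$loss[nrow(h)], max(h$iteration)))
  }
  invisible(x)
}

#' @export
summary.matriplet <- function(object, ...) {
  print(object)
  ev <- object$M$eig_values
  cat("\nMetric eigenvalue spectrum (top 5):\n")
  print(round(utils::head(sort(ev, decreasing = TRUE), 5), 5))
  if (object$extractor == "backbone") {
    cat(sprintf("\nBackbone parameters: %d\n", backbone_n_params(object$backbone)))
  }
  cat("\nTraining history (first/last rows):\n")
  h <- object$history
  print(utils::head(h, 2)); print(utils::tail(h, 2))
  invisible(object)
}

#' Extract the learned metric matrix
#'
#' @param object A fitted \code{\link{matriplet}} object.
#' @param ... Unused.
#' @return The d x d Mahalanobis matrix M.
#' @export
coef.matriplet <- function(object, ...) object$M$M

#' Plot the training loss history
#'
#' @param x A fitted \code{\link{matriplet}} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.matriplet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$iteration, h$loss, type = "b", pch = 19,
                 xlab = "outer iteration", ylab = "triplet loss",
                 main = "Alternating optimization", ...)
  invisible(x)
}
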