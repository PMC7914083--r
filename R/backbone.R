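# Residual convolutional embedding network with spatial pyramid pooling.
# Feature maps are arrays of dim (H, W, C). Convolutions run as im2col
# matrix products; the patch-index tables are cached per geometry so both
# the forward and the backward (col2im scatter-add) passes stay vectorized.
# Topology follows the bottleneck-residual design: a stem conv + max pool,
# four residual stages of 1x1 / 3x3 / 1x1 bottleneck blocks with ReLU after
# every convolution, then SPP over a fixed set of grid levels, a fully
# connected embedding layer, and L2 normalization onto the unit sphere.

.conv_cache <- new.env(parent = emptyenv())

#' Backbone architecture descriptor
#'
#' @param preset \code{"desk"} (default): 64x64 inputs, stem of 16 7x7
#'   kernels, stage widths 16/32/64/128 with one bottleneck block each,
#'   square stride 2 at the last three stages, SPP levels 1/2/4, 32-d
#'   embedding — the full topology at a scale a CPU exercises in seconds.
#'   \code{"full"}: 2048x2048 inputs, stem of 128 7x7 kernels stride 1x1
#'   with 2x2 max pool, four stages of 3/4/6/3 blocks, stride 2x2 at the
#'   third/fourth stage entry and 2x1 at the fifth, SPP levels 1/2/4/8 over
#'   a 2048-channel map (85 bins), 800-d embedding. \code{"tiny"}: a
#'   minimal net for gradient checking.
#' @param ... Named overrides of any descriptor field.
#' @return List of class \code{backbone_config}.
#' @export
backbone_config <- function(preset = c("desk", "full", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(input_size = 64L, stem_filters = 16L, stem_kernel = 7L,
                stem_stride = c(1L, 1L), pool = 2L,
                widths = c(16L, 32L, 64L, 128L), blocks = c(1L, 1L, 1L, 1L),
                strides = list(c(1L, 1L), c(2L, 2L), c(2L, 2L), c(2L, 2L)),
                spp_levels = c(1L, 2L, 4L), embed_dim = 32L),
    full = list(input_size = 2048L, stem_filters = 128L, stem_kernel = 7L,
                 stem_stride = c(1L, 1L), pool = 2L,
                 widths = c(256L, 512L, 1024L, 2048L), blocks = c(3L, 4L, 6L, 3L),
                 strides = list(c(1L, 1L), c(2L, 2L), c(2L, 2L), c(2L, 1L)),
                 spp_levels = c(1L, 2L, 4L, 8L), embed_dim = 800L),
    tiny = list(input_size = 16L, stem_filters = 2L, stem_kernel = 3L,
                stem_stride = c(1L, 1L), pool = 2L,
                widths = c(4L), blocks = c(1L),
                strides = list(c(2L, 2L)),
                spp_levels = c(1L, 2L), embed_dim = 3L))
  over <- list(...)
  cfg[names(over)] <- over
  if (length(cfg$widths) != length(cfg$blocks) ||
      length(cfg$widths) != length(cfg$strides)) {
    stopf("`widths`, `blocks` and `strides` must have one entry per stage")
  }
  cfg$preset <- preset
  structure(cfg, class = "backbone_config")
}

#' Initialize backbone parameters
#'
#' He-normal convolution weights and zero biases, drawn under \code{seed};
#' identical seeds give identical parameter bytes.
#'
#' @param config A \code{\link{backbone_config}}.
#' @param seed Integer seed.
#' @return Nested parameter list of class \code{backbone_params}.
#' @export
build_backbone <- function(config = backbone_config(), seed = 1L) {
  if (!inherits(config, "backbone_config")) stopf("`config` must be a backbone_config")
  with_seed(seed, {
    cin <- 1L
    stem <- conv_init(config$stem_kernel, config$stem_kernel, cin,
                      config$stem_filters, config$stem_stride,
                      (config$stem_kernel - 1L) %/% 2L)
    cin <- config$stem_filters
    stages <- vector("list", length(config$widths))
    for (s in seq_along(config$widths)) {
      out <- config$widths[s]
      mid <- max(out %/% 4L, 2L)
      blocks <- vector("list", config$blocks[s])
      for (b in seq_len(config$blocks[s])) {
        st <- if (b == 1L) config$strides[[s]] else c(1L, 1L)
        blk <- list(
          conv1 = conv_init(1L, 1L, cin, mid, c(1L, 1L), 0L),
          conv2 = conv_init(3L, 3L, mid, mid, st, 1L),
          conv3 = conv_init(1L, 1L, mid, out, c(1L, 1L), 0L))
        if (cin != out || any(st != 1L)) {
          blk$proj <- conv_init(1L, 1L, cin, out, st, 0L)
        }
        blocks[[b]] <- blk
        cin <- out
      }
      stages[[s]] <- blocks
    }
    spp_len <- cin * sum(config$spp_levels^2)
    fc <- list(W = matrix(stats::rnorm(config$embed_dim * spp_len,
                                       0, sqrt(2 / spp_len)),
                          config$embed_dim, spp_len),
               b = numeric(config$embed_dim))
    structure(list(config = config, stem = stem, stages = stages, fc = fc),
              class = "backbone_params")
  })
}

#' @keywords internal
#' @noRd
conv_init <- function(kh, kw, cin, cout, stride, pad) {
  list(W = matrix(stats::rnorm(kh * kw * cin * cout, 0,
                               sqrt(2 / (kh * kw * cin))),
                  kh * kw * cin, cout),
       b = numeric(cout),
       kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad))
}

# ---- im2col machinery -------------------------------------------------------

#' @keywords internal
#' @noRd
conv_indices <- function(H, W, C, kh, kw, sh, sw, pad) {
  key <- paste(H, W, C, kh, kw, sh, sw, pad, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% sh + 1L
  Wo <- (Wp - kw) %/% sw + 1L
  npos <- Ho * Wo
  oi <- rep(seq_len(Ho), Wo); oj <- rep(seq_len(Wo), each = Ho)
  bi <- (oi - 1L) * sh; bj <- (oj - 1L) * sw       # 0-based top-left in padded
  grid <- expand.grid(dh = seq_len(kh), dw = seq_len(kw), c = seq_len(C))
  K <- nrow(grid)
  idx <- matrix(0L, npos, K)
  plane <- Hp * Wp
  for (m in seq_len(K)) {
    idx[, m] <- bi + grid$dh[m] + (bj + grid$dw[m] - 1L) * Hp +
      (grid$c[m] - 1L) * plane
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, K = K)
  .conv_cache[[key]] <- out
  out
}

#' @keywords internal
#' @noRd
pad_map <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

#' @keywords internal
#' @noRd
conv_fwd <- function(x, ly) {
  d <- dim(x)
  ci <- conv_indices(d[1], d[2], d[3], ly$kh, ly$kw,
                     ly$stride[1], ly$stride[2], ly$pad)
  xp <- pad_map(x, ly$pad)
  patches <- xp[ci$idx]
  dim(patches) <- dim(ci$idx)
  out <- patches %*% ly$W
  out <- out + rep(ly$b, each = nrow(out))
  list(out = array(out, c(ci$Ho, ci$Wo, ly$cout)),
       cache = list(patches = patches, ci = ci, dims = d, ly = ly))
}

#' @keywords internal
#' @noRd
conv_bwd <- function(dout, cache) {
  ci <- cache$ci; ly <- cache$ly; d <- cache$dims
  dm <- matrix(dout, ci$Ho * ci$Wo, ly$cout)
  dW <- crossprod(cache$patches, dm)
  db <- colSums(dm)
  dpatch <- dm %*% t(ly$W)
  acc <- rowsum(as.vector(dpatch), group = as.vector(ci$idx))
  dxp <- numeric(ci$Hp * ci$Wp * d[3])
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, c(ci$Hp, ci$Wp, d[3]))
  dx <- dxp[ly$pad + seq_len(d[1]), ly$pad + seq_len(d[2]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

#' @keywords internal
#' @noRd
relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)

#' @keywords internal
#' @noRd
maxpool_fwd <- function(x) {
  d <- dim(x)
  Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L; C <- d[3]
  ci <- conv_indices(Ho * 2L, Wo * 2L, C, 2L, 2L, 2L, 2L, 0L)
  xt <- x[seq_len(Ho * 2L), seq_len(Wo * 2L), , drop = FALSE]
  patches <- xt[ci$idx]
  dim(patches) <- dim(ci$idx)                     # npos x (4*C), (dh,dw) fastest
  pa <- array(patches, c(Ho * Wo, 4L, C))
  mx <- pa[, 1L, ]; wh <- array(1L, c(Ho * Wo, C))
  dim(mx) <- c(Ho * Wo, C)
  for (q in 2:4) {
    sl <- pa[, q, ]; dim(sl) <- c(Ho * Wo, C)
    upd <- sl > mx
    mx[upd] <- sl[upd]
    wh[upd] <- q
  }
  list(out = array(mx, c(Ho, Wo, C)),
       cache = list(ci = ci, wh = wh, dims = d, Ho = Ho, Wo = Wo, C = C))
}

#' @keywords internal
#' @noRd
maxpool_bwd <- function(dout, cache) {
  ci <- cache$ci; d <- cache$dims
  npos <- cache$Ho * cache$Wo
  pos <- rep(seq_len(npos), cache$C)
  colsel <- (rep(seq_len(cache$C), each = npos) - 1L) * 4L + as.vector(cache$wh)
  lin <- ci$idx[cbind(pos, colsel)]
  acc <- rowsum(as.vector(dout), group = lin)
  dx <- numeric(d[1] * d[2] * d[3])
  # trimmed (even) region indices map 1:1 into the full map when dims are even
  dxt <- numeric((cache$Ho * 2L) * (cache$Wo * 2L) * cache$C)
  dxt[as.integer(rownames(acc))] <- acc
  dxt <- array(dxt, c(cache$Ho * 2L, cache$Wo * 2L, cache$C))
  dxf <- array(0, d)
  dxf[seq_len(cache$Ho * 2L), seq_len(cache$Wo * 2L), ] <- dxt
  dxf
}

# ---- spatial pyramid pooling ------------------------------------------------

#' Spatial pyramid max pooling
#'
#' Partitions an \code{H x W x C} feature map into an \code{l x l} grid for
#' every level \code{l}, max-pools each cell per channel, and concatenates
#' the results. Bin edges are the half-open \code{floor(i*H/l)} partitions,
#' so the cells tile the full map and the output length \code{C * sum(l^2)}
#' is independent of H and W.
#'
#' @param feature_map Array of dim \code{(H, W, C)}, or a matrix (C = 1).
#' @param levels Integer vector of grid levels, e.g. \code{c(1, 2, 4, 8)}.
#' @return Numeric vector of length \code{C * sum(levels^2)}; per level the
#'   cells are laid out column-major, channels outermost.
#' @export
#' @examples
#' spp_pool(array(rnorm(2 * 8 * 8), c(8, 8, 2)), c(1, 2))
spp_pool <- function(feature_map, levels) {
  if (is.matrix(feature_map)) {
    feature_map <- array(feature_map, c(dim(feature_map), 1L))
  }
  d <- dim(feature_map)
  if (length(d) != 3L) stopf("`feature_map` must be an (H, W, C) array")
  levels <- as.integer(levels)
  if (length(levels) == 0L || any(levels < 1L)) stopf("`levels` must be positive")
  if (d[1] < max(levels) || d[2] < max(levels)) {
    stopf("feature map (%dx%d) smaller than the largest level (%d)",
          d[1], d[2], max(levels))
  }
  spp_fwd(feature_map, levels)$out
}

#' @keywords internal
#' @noRd
spp_fwd <- function(x, levels) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  out <- numeric(C * sum(levels^2))
  argmax <- integer(length(out))                  # linear index into x
  k <- 0L
  for (l in levels) {
    re <- floor(seq_len(l) * H / l); rs <- c(1L, head(re, -1L) + 1L)
    ce <- floor(seq_len(l) * W / l); cs <- c(1L, head(ce, -1L) + 1L)
    for (ch in seq_len(C)) {
      off <- (ch - 1L) * H * W
      for (b in seq_len(l)) {
        for (a in seq_len(l)) {
          rows <- rs[a]:re[a]; cols <- cs[b]:ce[b]
          sub <- x[rows, cols, ch]
          w <- which.max(sub)
          k <- k + 1L
          out[k] <- sub[w]
          ri <- rows[1] + (w - 1L) %% length(rows)
          cj <- cols[1] + (w - 1L) %/% length(rows)
          argmax[k] <- off + ri + (cj - 1L) * H
        }
      }
    }
  }
  list(out = out, cache = list(argmax = argmax, dims = d))
}

#' @keywords internal
#' @noRd
spp_bwd <- function(dout, cache) {
  dx <- numeric(prod(cache$dims))
  acc <- rowsum(dout, group = cache$argmax)
  dx[as.integer(rownames(acc))] <- acc
  array(dx, cache$dims)
}

# ---- full network -----------------------------------------------------------

#' @keywords internal
#' @noRd
block_fwd <- function(x, blk) {
  c1 <- conv_fwd(x, blk$conv1); r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1$out, blk$conv2); r2 <- relu_fwd(c2$out)
  c3 <- conv_fwd(r2$out, blk$conv3)
  if (!is.null(blk$proj)) {
    pr <- conv_fwd(x, blk$proj)
    sc <- pr$out
  } else {
    pr <- NULL
    sc <- x
  }
  r3 <- relu_fwd(c3$out + sc)
  list(out = r3$out,
       cache = list(c1 = c1$cache, m1 = r1$mask, c2 = c2$cache, m2 = r2$mask,
                    c3 = c3$cache, pr = if (is.null(pr)) NULL else pr$cache,
                    m3 = r3$mask))
}

#' @keywords internal
#' @noRd
block_bwd <- function(dout, cache) {
  dsum <- dout * cache$m3
  b3 <- conv_bwd(dsum, cache$c3)
  b2 <- conv_bwd(b3$dx * cache$m2, cache$c2)
  b1 <- conv_bwd(b2$dx * cache$m1, cache$c1)
  g <- list(conv1 = list(dW = b1$dW, db = b1$db),
            conv2 = list(dW = b2$dW, db = b2$db),
            conv3 = list(dW = b3$dW, db = b3$db))
  if (!is.null(cache$pr)) {
    bp <- conv_bwd(dsum, cache$pr)
    g$proj <- list(dW = bp$dW, db = bp$db)
    dx <- b1$dx + bp$dx
  } else {
    dx <- b1$dx + dsum
  }
  list(dx = dx, grads = g)
}

#' @keywords internal
#' @noRd
backbone_fwd_one <- function(img, params) {
  x <- array(img, c(dim(img), 1L))
  st <- conv_fwd(x, params$stem); rs <- relu_fwd(st$out)
  mp <- maxpool_fwd(rs$out)
  x <- mp$out
  stage_caches <- vector("list", length(params$stages))
  for (s in seq_along(params$stages)) {
    bl <- vector("list", length(params$stages[[s]]))
    for (b in seq_along(params$stages[[s]])) {
      f <- block_fwd(x, params$stages[[s]][[b]])
      x <- f$out
      bl[[b]] <- f$cache
    }
    stage_caches[[s]] <- bl
  }
  sp <- spp_fwd(x, params$config$spp_levels)
  v <- as.vector(params$fc$W %*% sp$out) + params$fc$b
  nv <- sqrt(sum(v^2))
  e <- if (nv > 1e-12) v / nv else v
  list(embedding = e,
       cache = list(stem = st$cache, stem_mask = rs$mask, mp = mp$cache,
                    stages = stage_caches, spp = sp$cache, spp_out = sp$out,
                    v = v, nv = nv, e = e))
}

#' @keywords internal
#' @noRd
backbone_bwd_one <- function(cache, de, params) {
  # back through L2 normalization: dv = (de - e (e.de)) / ||v||
  nv <- max(cache$nv, 1e-12)
  dv <- (de - cache$e * sum(cache$e * de)) / nv
  gfc <- list(dW = dv %o% cache$spp_out, db = dv)
  dspp <- as.vector(crossprod(params$fc$W, dv))
  dx <- spp_bwd(dspp, cache$spp)
  gst <- vector("list", length(cache$stages))
  for (s in rev(seq_along(cache$stages))) {
    bl <- vector("list", length(cache$stages[[s]]))
    for (b in rev(seq_along(cache$stages[[s]]))) {
      r <- block_bwd(dx, cache$stages[[s]][[b]])
      dx <- r$dx
      bl[[b]] <- r$grads
    }
    gst[[s]] <- bl
  }
  dx <- maxpool_bwd(dx, cache$mp)
  bs <- conv_bwd(dx * cache$stem_mask, cache$stem)
  list(stem = list(dW = bs$dW, db = bs$db), stages = gst, fc = gfc)
}

#' Embed a batch of images
#'
#' Runs each image through the convolutional stages, spatial pyramid
#' pooling, the fully connected embedding layer, and L2 normalization, so
#' every returned row lies on the unit sphere. Any square input large enough
#' that the final feature map covers the largest SPP level is accepted; SPP
#' makes the embedding length independent of input size.
#'
#' @param images List of numeric matrices with values in \code{[0, 1]} (see
#'   \code{\link{resize_normalize}}).
#' @param params A \code{\link{build_backbone}} parameter set.
#' @param labels Optional integer labels stored alongside the vectors.
#' @return Object of class \code{embedding_batch}: \code{vectors}
#'   (n x embed_dim), \code{labels}, \code{norms}.
#' @export
embed <- function(images, params, labels = NULL) {
  if (inherits(images, "labeled_image_set")) {
    labels <- images$labels
    images <- images$images
  }
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || length(images) == 0L) stopf("`images` must be nonempty")
  down <- backbone_downsample(params$config)
  minsz <- max(params$config$spp_levels) * down
  for (im in images) {
    if (!is.matrix(im)) stopf("each image must be a matrix")
    if (nrow(im) < minsz || ncol(im) < minsz) {
      stopf("input %dx%d too small: the final map must cover the largest SPP level (min %d)",
            nrow(im), ncol(im), minsz)
    }
  }
  vecs <- t(vapply(images, function(im) backbone_fwd_one(im, params)$embedding,
                   numeric(params$config$embed_dim)))
  embedding_batch(vecs, labels)
}

#' Construct an embedding batch
#'
#' @param vectors n x d numeric matrix of embedding vectors.
#' @param labels Optional integer labels.
#' @return Object of class \code{embedding_batch}.
#' @export
embedding_batch <- function(vectors, labels = NULL) {
  vectors <- as.matrix(vectors)
  structure(list(vectors = vectors, labels = labels,
                 norms = sqrt(rowSums(vectors^2))),
            class = "embedding_batch")
}

#' @keywords internal
#' @noRd
backbone_downsample <- function(config) {
  f <- config$pool * config$stem_stride[1]
  for (st in config$strides) f <- f * st[1]
  as.integer(f)
}

#' Total trainable parameter count of a backbone
#'
#' @param params A \code{\link{build_backbone}} parameter set.
#' @return Integer count of weights and biases.
#' @export
backbone_n_params <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) n <<- n + length(x$W) + length(x$b)
      for (el in x) if (is.list(el)) walk(el)
    }
  }
  walk(params[c("stem", "stages", "fc")])
  n
}
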