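# Seeded generators for the two data regimes the classifier targets:
# nodule-like grayscale images (bright Gaussian blobs over a textured
# background) and WBCD-style ordinal tables with injected missing values.
# These emulate the statistical structure of the real databases (chest
# radiographs with/without nodules; 9-feature cytology records); they are
# synthetic stand-ins, not samples of either database.

#' Generate synthetic nodule-like blob images
#'
#' Produces \code{n_classes * n_per_class} grayscale images. Class 0 contains
#' only a low-frequency textured background (the "no nodule" analogue); class
#' \code{c >= 1} additionally contains \code{c} bright Gaussian blobs (capped
#' at 3) whose amplitude scales with \code{contrast}, emulating nodules of
#' 5-40 mm relative diameter. Intensities are integers in \code{[0, 255]} and
#' the output is bitwise-reproducible under \code{seed}.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Images per class (>= 1).
#' @param size Image side length in pixels (>= 32).
#' @param contrast Blob amplitude scale in \code{(0, 1]}; 1 gives blobs about
#'   120 gray levels above the background mean.
#' @param seed Integer seed; equal seeds give identical image bytes.
#' @return A \code{\link{labeled_image_set}} with labels \code{0..n_classes-1}.
#' @export
#' @examples
#' set <- generate_blob_images(2, 5, 64, 1.0, seed = 7)
#' table(set$labels)
generate_blob_images <- function(n_classes, n_per_class, size, contrast = 1.0,
                                 seed = 1L) {
  assert_scalar_count(n_classes, "n_classes", min = 2L)
  assert_scalar_count(n_per_class, "n_per_class", min = 1L)
  assert_scalar_count(size, "size", min = 32L)
  if (!is.numeric(contrast) || length(contrast) != 1L ||
      contrast <= 0 || contrast > 1) {
    stopf("`contrast` must be a single value in (0, 1]")
  }
  with_seed(seed, {
    images <- vector("list", n_classes * n_per_class)
    labels <- integer(length(images))
    k <- 0L
    co <- seq_len(size) - 0.5
    for (cls in seq_len(n_classes) - 1L) {
      for (j in seq_len(n_per_class)) {
        k <- k + 1L
        img <- blob_background(size, co)
        n_blobs <- min(cls, 3L)
        for (b in seq_len(n_blobs)) {
          cx <- stats::runif(1, 0.2 * size, 0.8 * size)
          cy <- stats::runif(1, 0.2 * size, 0.8 * size)
          sg <- stats::runif(1, 0.05 * size, 0.12 * size)
          amp <- contrast * stats::runif(1, 90, 150)
          img <- img + amp * outer(exp(-(co - cy)^2 / (2 * sg^2)),
                                   exp(-(co - cx)^2 / (2 * sg^2)))
        }
        images[[k]] <- round(pmin(pmax(img, 0), 255))
        labels[k] <- cls
      }
    }
    labeled_image_set(images, labels,
                      sprintf("img_s%d_%05d", as.integer(seed), seq_along(images)))
  })
}

# Low-frequency cosine texture plus pixel noise, mean ~ 80, clipped later.
#' @keywords internal
#' @noRd
blob_background <- function(size, co) {
  img <- matrix(80, size, size)
  for (w in 1:3) {                      # a few random low-frequency waves
    fx <- stats::runif(1, 0.5, 2.5) * pi / size
    fy <- stats::runif(1, 0.5, 2.5) * pi / size
    ph <- stats::runif(2, 0, 2 * pi)
    img <- img + 8 * outer(cos(fy * co + ph[1]), cos(fx * co + ph[2]))
  }
  img + matrix(stats::rnorm(size^2, 0, 6), size, size)
}

#' Generate a synthetic WBCD-style ordinal table
#'
#' Emulates fine-needle-aspiration cytology records: nine ordinal features on
#' the 1-10 scale, benign-like rows drawn low on the scale (mean about 3) and
#' malignant-like rows high (mean about 7), mirroring how the nine cytological
#' features separate the two diagnoses in the Wisconsin database.
#'
#' @param n_benign Number of benign-like rows (label 0), >= 0.
#' @param n_malignant Number of malignant-like rows (label 1), >= 0.
#' @param seed Integer seed.
#' @return A \code{\link{tabular_set}}; no missing values (see
#'   \code{\link{inject_missing}}).
#' @export
#' @examples
#' tab <- generate_tabular(458, 241, seed = 1)
#' nrow(tab$records)  # 699
generate_tabular <- function(n_benign, n_malignant, seed = 1L) {
  if (!is.numeric(n_benign) || n_benign < 0 || n_benign != round(n_benign) ||
      !is.numeric(n_malignant) || n_malignant < 0 ||
      n_malignant != round(n_malignant)) {
    stopf("row counts must be nonnegative integers")
  }
  n_benign <- as.integer(n_benign); n_malignant <- as.integer(n_malignant)
  with_seed(seed, {
    draw <- function(n, mean, sd) {
      m <- matrix(stats::rnorm(n * 9L, mean, sd), n, 9L)
      matrix(pmin(pmax(round(m), 1L), 10L), n, 9L)
    }
    rec <- rbind(draw(n_benign, 3, 1.6), draw(n_malignant, 7, 1.8))
    rec <- as.data.frame(rec)
    if (nrow(rec) == 0L) rec <- as.data.frame(matrix(integer(0), 0L, 9L))
    tabular_set(rec, rep(c(0L, 1L), c(n_benign, n_malignant)))
  })
}

#' Generate features separable only along a planted direction
#'
#' Two classes of isotropic Gaussian features whose means sit at \code{+v}
#' and \code{-v} for a random unit direction \code{v}: every discriminative
#' bit of signal lies along \code{v}, so a correctly learned Mahalanobis
#' metric must concentrate its dominant eigenvector there. The default
#' shape (200 per class, 4 dimensions, noise sd 0.3) keeps the planted
#' direction statistically identifiable: the sample-covariance error that
#' tilts any whitening-style estimator scales like sqrt(d/N).
#'
#' @param n_per_class Samples per class.
#' @param d Feature dimension.
#' @param noise_sd Isotropic noise standard deviation.
#' @param seed Integer seed.
#' @return List with \code{features} (2n x d), \code{labels} (0/1), and the
#'   planted unit \code{direction}.
#' @export
generate_planted_features <- function(n_per_class = 200L, d = 4L,
                                      noise_sd = 0.3, seed = 1L) {
  assert_scalar_count(n_per_class, "n_per_class")
  assert_scalar_count(d, "d", min = 2L)
  with_seed(seed, {
    v <- stats::rnorm(d)
    v <- v / sqrt(sum(v^2))
    noise <- matrix(stats::rnorm(2 * n_per_class * d, 0, noise_sd),
                    2 * n_per_class, d)
    mu <- rbind(matrix(v, n_per_class, d, byrow = TRUE),
                -matrix(v, n_per_class, d, byrow = TRUE))
    list(features = noise + mu, labels = rep(0:1, each = n_per_class),
         direction = v)
  })
}

#' Inject missing values into a tabular set
#'
#' Marks exactly \code{n_rows} distinct rows as incomplete by replacing one or
#' two of their feature values with the missing marker (\code{NA} in memory,
#' \code{"?"} on disk); all other rows are untouched.
#'
#' @param table A \code{\link{tabular_set}}.
#' @param n_rows Number of rows to receive missing markers
#'   (\code{0 <= n_rows <= nrow}).
#' @param seed Integer seed.
#' @return A \code{tabular_set} with \code{n_rows} incomplete rows.
#' @export
inject_missing <- function(table, n_rows, seed = 1L) {
  stopifnot(inherits(table, "tabular_set"))
  n <- nrow(table$records)
  if (!is.numeric(n_rows) || n_rows < 0 || n_rows != round(n_rows)) {
    stopf("`n_rows` must be a nonnegative integer")
  }
  if (n_rows > n) stopf("`n_rows` (%d) exceeds the number of rows (%d)", n_rows, n)
  if (n_rows == 0L) return(table)
  with_seed(seed, {
    rows <- sample.int(n, n_rows)
    rec <- table$records
    for (r in rows) {
      cols <- sample.int(9L, sample(1:2, 1L))
      rec[r, cols] <- NA
    }
    tabular_set(rec, table$labels, table$ids)
  })
}

#' Drop rows with missing values
#'
#' Removes every record containing a missing marker, preserving the order of
#' the remaining rows — the treatment of incomplete samples as invalid data
#' (e.g. 699 Wisconsin records with 16 incomplete rows retain 683).
#'
#' @param table A \code{\link{tabular_set}}.
#' @return A \code{tabular_set} containing only complete rows.
#' @export
drop_missing <- function(table) {
  stopifnot(inherits(table, "tabular_set"))
  keep <- stats::complete.cases(table$records)
  tabular_set(table$records[keep, , drop = FALSE],
              table$labels[keep], table$ids[keep])
}
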