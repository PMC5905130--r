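# Trainable three-class pixel classifier (Seed / SeedEdge / Background).
#
# Features cover intensity (Gaussian-smoothed), edges (gradient magnitude,
# Laplacian-of-Gaussian) and texture (local variance) at four scales, the
# smallest set spanning the intensity/texture/edge feature families used by
# interactive pixel-classification tools.  The plane order is fixed and
# versioned; a classifier refuses to predict on a mismatched feature version.

FEATURE_VERSION <- "xoseed-features-v1"
FEATURE_SCALES <- c(1, 2, 4, 8)
PIXEL_CLASSES <- c("Seed", "SeedEdge", "Background")

gauss_kernel <- function(sigma) {
  k <- ceiling(3 * sigma)
  x <- seq(-k, k)
  g <- exp(-x^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

# Convolution with reflected boundaries: pad by the kernel radius with
# mirrored rows/columns, filter (FFT), crop.
conv_reflect <- function(x, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  k <- min(k, nr - 1L, nc - 1L)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  xp <- x[ri, ci]
  yp <- EBImage::filter2(xp, kern, boundary = "circular")
  as.matrix(yp)[k + seq_len(nr), k + seq_len(nc)]
}

shift_mat <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  x[ri, ci]
}

#' Per-pixel feature stack for pixel classification
#'
#' Computes four feature families at each scale `sigma`: Gaussian-smoothed
#' intensity, gradient magnitude of the smoothed image (central differences),
#' Laplacian of the smoothed image (4-neighbour stencil) and local intensity
#' variance (`E[x^2] - E[x]^2` under the same Gaussian window).  Boundaries
#' are handled by reflection.  With the default four scales the stack has 16
#' planes in a fixed, versioned order.
#'
#' @param image 2-D numeric matrix with finite values on a [0, 1] scale.
#' @param scales Smoothing scales (sigma, pixels).
#' @return 3-D array `nrow x ncol x (4 * length(scales))` with named planes
#'   and attribute `feature_version`.
#' @examples
#' f <- compute_features(matrix(runif(64^2), 64, 64))
#' dim(f)
#' @export
compute_features <- function(image, scales = FEATURE_SCALES) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a 2-D numeric matrix", call. = FALSE)
  if (any(!is.finite(image)))
    stop("'image' contains non-finite values", call. = FALSE)
  if (min(image) < -1e-3 || max(image) > 1 + 1e-3)
    stop("'image' must be on a [0, 1] intensity scale", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  planes <- vector("list", 4L * length(scales))
  nms <- character(length(planes))
  lap_kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  i <- 0L
  for (s in scales) {
    kern <- gauss_kernel(s)
    g <- conv_reflect(image, kern)
    gx <- (shift_mat(g, 1L, 0L) - shift_mat(g, -1L, 0L)) / 2
    gy <- (shift_mat(g, 0L, 1L) - shift_mat(g, 0L, -1L)) / 2
    grad <- sqrt(gx^2 + gy^2)
    lap <- conv_reflect(g, lap_kern)
    v <- pmax(conv_reflect(image^2, kern) - g^2, 0)
    planes[i + 1:4] <- list(g, grad, lap, v)
    nms[i + 1:4] <- paste0(c("gauss_s", "grad_s", "laplace_s", "var_s"), s)
    i <- i + 4L
  }
  out <- array(unlist(planes, use.names = FALSE), dim = c(nr, nc, i),
               dimnames = list(NULL, NULL, nms))
  attr(out, "feature_version") <- FEATURE_VERSION
  attr(out, "scales") <- scales
  out
}

feature_matrix <- function(stack) {
  m <- matrix(stack, ncol = dim(stack)[3])
  colnames(m) <- dimnames(stack)[[3]]
  m
}

#' Train the Seed/SeedEdge/Background pixel classifier
#'
#' Fits a random forest on the feature stacks of one or more bright-field
#' images at the pixels marked in sparse user label images (scribbles):
#' 0 = unlabeled, 1 = Seed, 2 = SeedEdge, 3 = Background.  Every class must
#' be represented.  Out-of-bag pixel accuracy is reported.
#'
#' @param images A matrix or list of 2-D intensity matrices.
#' @param labels Matching label image(s), integer values 0-3.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `sqrt` of the plane count.
#' @param max_depth Depth limit; 0 (default) means unlimited.
#' @param scales Feature scales, passed to [compute_features()].
#' @param seed RNG seed for the forest (training is reproducible).
#' @return A `pixel_classifier` object (forest, feature version, parameters,
#'   out-of-bag accuracy).
#' @export
train_pixel_classifier <- function(images, labels, n_trees = 100L,
                                   mtry = NULL, max_depth = 0L,
                                   scales = FEATURE_SCALES, seed = 0L) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(labels)) labels <- list(labels)
  if (length(images) != length(labels))
    stop("'images' and 'labels' must have the same length", call. = FALSE)
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; lab <- labels[[i]]
    if (!identical(dim(img), dim(lab)))
      stop("image ", i, " and its label image differ in shape", call. = FALSE)
    if (any(!(lab %in% 0:3)))
      stop("label images may only contain 0 (unlabeled), 1 (Seed), ",
           "2 (SeedEdge), 3 (Background)", call. = FALSE)
    idx <- which(lab > 0L)
    if (!length(idx)) next
    fm <- feature_matrix(compute_features(img, scales))
    xs[[length(xs) + 1L]] <- fm[idx, , drop = FALSE]
    ys[[length(ys) + 1L]] <- lab[idx]
  }
  y <- unlist(ys)
  if (is.null(y) || !length(y))
    stop("no labeled pixels found", call. = FALSE)
  missing <- setdiff(1:3, unique(y))
  if (length(missing))
    stop("no labeled pixels for class ",
         paste(sQuote(PIXEL_CLASSES[missing]), collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(do.call(rbind, xs))
  y <- factor(PIXEL_CLASSES[y], levels = PIXEL_CLASSES)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  forest <- ranger::ranger(x = x, y = y, num.trees = n_trees, mtry = mtry,
                           max.depth = max_depth, probability = TRUE,
                           seed = seed, num.threads = 1L,
                           verbose = FALSE)
  oob_class <- PIXEL_CLASSES[max.col(forest$predictions, ties.method = "first")]
  structure(list(forest = forest,
                 feature_version = FEATURE_VERSION,
                 scales = scales,
                 params = list(n_trees = n_trees, mtry = mtry,
                               max_depth = max_depth, seed = seed),
                 n_train = length(y),
                 oob_accuracy = mean(oob_class == as.character(y))),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("Seed/SeedEdge/Background pixel classifier: %d trees, ",
                     "mtry %d, %d training pixels\n"),
              x$params$n_trees, x$params$mtry, x$n_train))
  cat(sprintf("  feature stack %s (scales %s), OOB pixel accuracy %.4f\n",
              x$feature_version, paste(x$scales, collapse = "/"),
              x$oob_accuracy))
  invisible(x)
}

#' Per-pixel class probabilities
#'
#' Applies a trained [train_pixel_classifier()] forest to an image, returning
#' one probability plane per class (`Seed`, `SeedEdge`, `Background`).  The
#' image's feature stack must match the version the classifier was trained
#' against.
#'
#' @param clf A `pixel_classifier`.
#' @param image 2-D intensity matrix on [0, 1].
#' @return Array `nrow x ncol x 3` of probabilities summing to 1 per pixel.
#' @export
predict_pixels <- function(clf, image) {
  stopifnot(inherits(clf, "pixel_classifier"))
  stack <- compute_features(image, clf$scales)
  if (!identical(attr(stack, "feature_version"), clf$feature_version))
    stop("feature-stack version mismatch: classifier was trained against ",
         clf$feature_version, call. = FALSE)
  fm <- as.data.frame(feature_matrix(stack))
  pr <- stats::predict(clf$forest, data = fm, num.threads = 1L,
                       verbose = FALSE)$predictions
  pr <- pr[, PIXEL_CLASSES, drop = FALSE]
  array(pr, dim = c(nrow(image), ncol(image), 3L),
        dimnames = list(NULL, NULL, PIXEL_CLASSES))
}

#' Sparse training scribbles from synthetic ground truth
#'
#' Converts a [generate_scene()] ground truth into a sparse label image the
#' way a user would scribble: a sample of seed-interior pixels (class 1),
#' rim pixels (class 2) and background pixels including debris (class 3).
#'
#' @param scene A `seed_scene`.
#' @param n_per_class Pixels sampled per class.
#' @param seed RNG seed.
#' @return Integer label matrix with values 0-3.
#' @export
scribble_labels <- function(scene, n_per_class = 2000L, seed = 0L) {
  stopifnot(inherits(scene, "seed_scene"))
  lab <- scene$truth$label_mask
  rim <- scene$truth$rim_mask
  out <- matrix(0L, nrow(lab), ncol(lab))
  pools <- list(which(lab > 0L & !rim), which(rim),
                which(lab == 0L))
  with_seed(seed, {
    for (cls in 1:3) {
      pool <- pools[[cls]]
      take <- pool[sample.int(length(pool), min(n_per_class, length(pool)))]
      out[take] <- cls
    }
  })
  out
}
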