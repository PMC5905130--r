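test_that("feature stack has the documented shape and degenerate limits", {
  img <- matrix(0.5, 40, 50)
  f <- compute_features(img)
  expect_equal(dim(f), c(40L, 50L, 16L))
  expect_true(all(is.finite(f)))
  expect_identical(attr(f, "feature_version"), "xoseed-features-v1")
  # constant image: gradient, Laplacian and variance planes are all zero
  nm <- dimnames(f)[[3]]
  for (p in grep("grad|laplace|var", nm)) {
    expect_lt(max(abs(f[, , p])), 1e-10)
  }
  # and every Gaussian plane reproduces the constant
  for (p in grep("gauss", nm)) expect_equal(f[, , p], img)
  # a single bright pixel keeps its peak and its mass under smoothing
  img2 <- matrix(0, 41, 41); img2[21, 21] <- 1
  f2 <- compute_features(img2, scales = 1)
  g <- f2[, , "gauss_s1"]
  expect_equal(which.max(g), which.max(img2))
  expect_equal(sum(g), 1, tolerance = 1e-6)
  expect_error(compute_features(array(0, c(3, 3, 3))), "2-D")
  expect_error(compute_features(matrix(c(NA, 1, 1, 1), 2, 2)), "finite")
})

test_that("in-seed smoothed intensity is darker than background", {
  sc <- tiny_scene()
  f <- compute_features(sc$images$white, scales = 2)
  g <- f[, , "gauss_s2"]
  inside <- sc$truth$label_mask > 0L
  expect_lt(mean(g[inside]), mean(g[!inside]))
})

test_that("training requires every class and is reproducible", {
  sc <- tiny_scene()
  lab <- scribble_labels(sc, n_per_class = 300L, seed = 1L)
  lab2 <- lab
  lab2[lab2 == 2L] <- 0L
  expect_error(train_pixel_classifier(sc$images$white, lab2, n_trees = 5L),
               "SeedEdge")
  expect_error(train_pixel_classifier(sc$images$white, lab[1:10, 1:10]),
               "shape")
  a <- train_pixel_classifier(sc$images$white, lab, n_trees = 20L, seed = 4L)
  b <- train_pixel_classifier(sc$images$white, lab, n_trees = 20L, seed = 4L)
  pa <- predict_pixels(a, sc$images$white[1:60, 1:60])
  pb <- predict_pixels(b, sc$images$white[1:60, 1:60])
  expect_identical(pa, pb)
})

test_that("probabilities are a proper simplex and version-checked", {
  prob <- tiny_prob()
  sums <- apply(prob, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(min(prob) >= 0)
  clf <- tiny_clf()
  clf$feature_version <- "other"
  expect_error(predict_pixels(clf, tiny_scene()$images$white), "version")
})

test_that("pixelwise accuracy on noise-free fixtures reaches 0.99", {
  sc <- clean_scene()
  prob <- predict_pixels(clean_clf(), sc$images$white)
  pred <- apply(prob, c(1, 2), which.max)
  acc <- mean(pred == truth_pixel_classes(sc))
  expect_gte(acc, 0.99)
})

test_that("prediction is translation-equivariant away from boundaries", {
  clf <- tiny_clf()
  base <- function(cx, cy) {
    img <- matrix(0.85, 90, 90)
    dx <- outer(seq_len(90) - cx, rep(1, 90))
    dy <- outer(rep(1, 90), seq_len(90) - cy)
    full <- (dx / 8)^2 + (dy / 5)^2 <= 1
    inner <- (dx / 6)^2 + (dy / 3)^2 <= 1
    img[full] <- 0.25
    img[inner] <- 0.40
    img
  }
  p1 <- apply(predict_pixels(clf, base(40, 40)), c(1, 2), which.max)
  p2 <- apply(predict_pixels(clf, base(52, 47)), c(1, 2), which.max)
  # compare corresponding windows around the two positions
  w1 <- p1[(40 - 14):(40 + 14), (40 - 14):(40 + 14)]
  w2 <- p2[(52 - 14):(52 + 14), (47 - 14):(47 + 14)]
  expect_gte(mean(w1 == w2), 0.98)
})
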