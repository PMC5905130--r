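test_that("object means are exact on constant regions", {
  mask <- matrix(0L, 10, 10)
  mask[2:4, 2:4] <- 1L
  mask[7:9, 6:9] <- 2L
  rfp <- matrix(0.3, 10, 10)
  gfp <- matrix(0.05, 10, 10)
  gfp[7:9, 6:9] <- 0.5
  df <- measure_seeds(mask, rfp, gfp)
  expect_equal(df$object_id, 1:2)
  expect_equal(df$area, c(9L, 12L))
  expect_equal(df$mean_red, c(0.3, 0.3))
  expect_equal(df$mean_green, c(0.05, 0.5))
  expect_equal(df$centroid_row, c(3, 8))
  expect_equal(df$centroid_col, c(3, 7.5))
  expect_equal(nrow(measure_seeds(matrix(0L, 5, 5), matrix(0, 5, 5),
                                  matrix(0, 5, 5))), 0L)
  expect_error(measure_seeds(mask, rfp[1:5, ], gfp), "shape")
})

test_that("classification uses inclusive thresholds", {
  df <- data.frame(object_id = 1:4, area = 10,
                   mean_red = c(0.15, 0.12, 0.119, 0.05),
                   mean_green = c(0.05, 0.077, 0.0769, 0.2))
  out <- classify_seeds(df, fluor_thresholds(0.12, 0.077))
  expect_equal(out$seed_class,
               c("RED_ONLY", "BOTH", "NONE", "GREEN_ONLY"))
  cc <- count_classes(out)
  expect_equal(sum(cc), nrow(df))
  expect_equal(cc[["both"]], 1)
})

test_that("raising the red threshold never adds red-positive seeds", {
  sc <- tiny_scene()
  mask <- segment_seeds(predict_pixels(tiny_clf(), sc$images$white))
  rec <- measure_seeds(mask, sc$images$rfp, sc$images$gfp)
  red_pos <- function(thr) {
    cc <- count_classes(classify_seeds(rec, fluor_thresholds(thr, 0.077)))
    cc[["red_only"]] + cc[["both"]]
  }
  thr_grid <- c(0.02, 0.05, 0.12, 0.2, 0.5, 0.9)
  expect_true(all(diff(vapply(thr_grid, red_pos, numeric(1))) <= 0))
})

test_that("swapping channels and thresholds swaps the single-color classes", {
  sc <- tiny_scene()
  mask <- segment_seeds(predict_pixels(tiny_clf(), sc$images$white))
  thr <- fluor_thresholds(0.12, 0.077)
  a <- count_classes(classify_seeds(
    measure_seeds(mask, sc$images$rfp, sc$images$gfp), thr))
  b <- count_classes(classify_seeds(
    measure_seeds(mask, sc$images$gfp, sc$images$rfp),
    fluor_thresholds(0.077, 0.12)))
  expect_equal(a[["red_only"]], b[["green_only"]])
  expect_equal(a[["green_only"]], b[["red_only"]])
  expect_equal(a[["both"]], b[["both"]])
  expect_equal(a[["none"]], b[["none"]])
})

test_that("per-seed classes match ground truth on the default fixture", {
  sc <- tiny_scene()
  mask <- segment_seeds(predict_pixels(tiny_clf(), sc$images$white))
  rec <- classify_seeds(measure_seeds(mask, sc$images$rfp, sc$images$gfp))
  m <- match_to_truth(mask, sc$truth$label_mask)
  pred <- rec$seed_class[match(m$matches$pred, rec$object_id)]
  truth <- sc$truth$seeds$true_class[m$matches$truth]
  expect_equal(mean(pred == truth), 1)
})

test_that("high autofluorescence forces the green threshold up", {
  sc <- generate_scene(tiny_spec(autofluorescence_level = 0.1,
                                 carrier_signal_mean = 0.35,
                                 rng_seed = 77L))
  lab <- sc$truth$label_mask
  rec <- measure_seeds(lab, sc$images$rfp, sc$images$gfp)
  tr <- sc$truth$seeds
  # default green threshold now misclassifies green non-carriers ...
  def <- classify_seeds(rec, fluor_thresholds(0.12, 0.077))
  green_pos_def <- def$seed_class %in% c("GREEN_ONLY", "BOTH")
  expect_gt(sum(green_pos_def & !tr$green), 0)
  # ... and a retuned threshold above the autofluorescence floor fixes it
  tuned <- classify_seeds(rec, fluor_thresholds(0.2, 0.2))
  expect_equal(tuned$seed_class, tr$true_class)
})
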