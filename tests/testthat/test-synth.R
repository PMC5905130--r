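test_that("scene generation is deterministic for a fixed spec", {
  sp <- tiny_spec(rng_seed = 5L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$images, b$images)
  expect_identical(a$truth$label_mask, b$truth$label_mask)
  expect_identical(a$truth$seeds, b$truth$seeds)
})

test_that("ground truth is consistent with the genetic model", {
  sc <- tiny_scene()
  tr <- sc$truth$seeds
  expect_equal(nrow(tr), sc$spec$n_seeds)
  expect_equal(max(sc$truth$label_mask), sc$spec$n_seeds)
  # dominance: class follows from the carrier flags
  expect_true(all((tr$true_class == "BOTH") == (tr$red & tr$green)))
  expect_true(all((tr$true_class == "NONE") == (!tr$red & !tr$green)))
  # carrier flags follow from the gametes
  red_gam <- c(GR = TRUE, nn = FALSE, Gn = FALSE, nR = TRUE)
  expect_equal(tr$red, unname(red_gam[tr$gamete1] | red_gam[tr$gamete2]))
  # no recombination -> no single-colored seeds
  sc0 <- generate_scene(tiny_spec(r_true = 0, rng_seed = 6L))
  expect_false(any(sc0$truth$seeds$true_class %in%
                     c("RED_ONLY", "GREEN_ONLY")))
})

test_that("noise-free bright field thresholds exactly to the seed support", {
  sc <- generate_scene(clean_spec(rng_seed = 31L))
  dark <- sc$images$white < sc$spec$background_level - 0.2
  expect_identical(unname(dark), unname(sc$truth$label_mask > 0L))
})

test_that("fluorescence is separable at the default thresholds", {
  sc <- tiny_scene()
  tr <- sc$truth$seeds
  lab <- sc$truth$label_mask
  mr <- vapply(tr$seed_id, function(k) mean(sc$images$rfp[lab == k]),
               numeric(1))
  mg <- vapply(tr$seed_id, function(k) mean(sc$images$gfp[lab == k]),
               numeric(1))
  expect_true(all(mr[tr$red] >= 0.12) && all(mr[!tr$red] < 0.12))
  expect_true(all(mg[tr$green] >= 0.077) && all(mg[!tr$green] < 0.077))
})

test_that("pooled genotype tallies converge to the model fractions", {
  tallies <- c(RED_ONLY = 0, GREEN_ONLY = 0, BOTH = 0, NONE = 0)
  n_tot <- 0L
  for (i in 1:10) {
    sc <- generate_scene(scene_spec(width = 648, height = 486,
                                    n_seeds = 400, r_true = 0.16,
                                    rng_seed = 200L + i))
    tab <- table(factor(sc$truth$seeds$true_class, levels = names(tallies)))
    tallies <- tallies + as.numeric(tab)
    n_tot <- n_tot + nrow(sc$truth$seeds)
  }
  p <- seed_class_probs(0.16)
  expect_gt(stats::chisq.test(tallies, p = p)$p.value, 0.01)
  # single-color tally within 3 binomial SE of expectation
  f <- p[["RED_ONLY"]] + p[["GREEN_ONLY"]]
  expect_lt(abs(sum(tallies[1:2]) - n_tot * f),
            3 * sqrt(n_tot * f * (1 - f)))
})

test_that("invalid scene specs are rejected", {
  expect_error(tiny_spec(carrier_signal_mean = 0.05,
                         autofluorescence_level = 0.04), "separable")
  expect_error(tiny_spec(background_level = 1.4), "0, 1")
  expect_error(tiny_spec(r_true = 0.7), "0, 0.5")
  # impossible packing fails with advice rather than hanging
  expect_error(generate_scene(scene_spec(width = 60, height = 60,
                                         n_seeds = 200)),
               "lower n_seeds")
})

test_that("fixture sets are written completely and reproducibly", {
  td <- withr::local_tempdir()
  sp <- tiny_spec(n_seeds = 20L, rng_seed = 41L)
  man <- write_fixture_set(sp, 3L, td, sample_id = "FX")
  expect_equal(nrow(man), 3L)
  tifs <- list.files(td, pattern = "\\.tif$")
  expect_length(tifs, 3L * 4L)  # white/rfp/gfp + mask per image
  gt <- attr(man, "ground_truth")
  expect_true(file.exists(gt))
  first <- readBin(gt, "raw", file.size(gt))
  # mask TIFF round-trips the label values
  m <- tiff::readTIFF(man$mask[1])
  sc <- generate_scene(sp)
  expect_identical(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
                   sc$truth$label_mask)
  # re-run: byte-identical ground truth
  write_fixture_set(sp, 3L, td, sample_id = "FX")
  expect_identical(readBin(gt, "raw", file.size(gt)), first)
})
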