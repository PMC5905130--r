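r_grid <- seq(0, 0.5, by = 0.01)

test_that("gamete frequencies follow the coupling-phase model", {
  expect_equal(unclass(gamete_freqs(0))[1:4],
               c(GR = 0.5, nn = 0.5, Gn = 0, nR = 0))
  expect_equal(unclass(gamete_freqs(0.5))[1:4],
               c(GR = 0.25, nn = 0.25, Gn = 0.25, nR = 0.25))
  expect_equal(unclass(gamete_freqs(0.16))[1:4],
               c(GR = 0.42, nn = 0.42, Gn = 0.08, nR = 0.08))
  for (r in r_grid) expect_equal(sum(gamete_freqs(r)), 1)
  expect_error(gamete_freqs(-0.01), "0, 0.5")
  expect_error(gamete_freqs(0.51), "0, 0.5")
})

test_that("expected seed-class fractions match the closed form and sum to 1", {
  expect_equal(seed_class_probs(0),
               c(RED_ONLY = 0, GREEN_ONLY = 0, BOTH = 0.75, NONE = 0.25))
  # frozen values from the 16-pair enumeration oracle
  expect_equal(seed_class_probs(0.16),
               c(RED_ONLY = 0.0736, GREEN_ONLY = 0.0736, BOTH = 0.6764,
                 NONE = 0.1764),
               tolerance = 1e-12)
  expect_equal(seed_class_probs(0.5),
               c(RED_ONLY = 0.1875, GREEN_ONLY = 0.1875, BOTH = 0.5625,
                 NONE = 0.0625),
               tolerance = 1e-12)
  for (r in r_grid) expect_equal(sum(seed_class_probs(r)), 1)
})

test_that("closed form agrees with the brute-force gamete-pair enumeration", {
  for (r in r_grid) {
    expect_lt(max(abs(seed_class_probs(r) - seed_class_probs_enum(r))),
              1e-12)
    expect_equal(sum(seed_class_probs_enum(r)), 1)
  }
  expect_equal(seed_class_probs_enum(0.16)[["NONE"]], 0.42^2)
})

test_that("single-color fraction rises and NONE falls with r", {
  f <- vapply(r_grid, function(r) {
    p <- seed_class_probs(r)
    p[["RED_ONLY"]] + p[["GREEN_ONLY"]]
  }, numeric(1))
  nn <- vapply(r_grid, function(r) seed_class_probs(r)[["NONE"]],
               numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(nn) < 0))
})

test_that("estimator inverts the model exactly (round trip)", {
  for (r in r_grid) {
    fit <- xo_fit(as_seed_counts(seed_class_probs(r) * 10000))
    expect_lt(abs(fit$r_hat - r), 1e-12)
  }
  # worked example: f = 0.1472 -> r = 0.16 exactly
  fit <- xo_fit(seed_counts(736, 736, 6764, 1764))
  expect_equal(fit$f_single, 0.1472)
  expect_equal(fit$r_hat, 0.16)
  expect_equal(xo_fit(seed_counts(0, 0, 75, 25))$r_hat, 0)
  expect_equal(xo_fit(seed_counts(1875, 1875, 5625, 625))$r_hat, 0.5)
})

test_that("estimator rejects out-of-model and empty inputs", {
  expect_error(xo_fit(seed_counts(40, 40, 10, 10)), "0.375")
  expect_error(xo_fit(seed_counts(0, 0, 0, 0)), "empty")
  expect_error(seed_counts(-1, 0, 5, 5), "non-negative")
})

test_that("map functions reproduce hand computations and their ordering", {
  expect_equal(map_distance(0, "identity"), 0)
  expect_equal(map_distance(0, "haldane"), 0)
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0.16, "haldane"), -50 * log(0.68))
  expect_equal(map_distance(0.16, "haldane"), 19.283, tolerance = 1e-3)
  expect_equal(map_distance(0.16, "kosambi"), 25 * log(1.32 / 0.68))
  expect_equal(map_distance(0.16, "kosambi"), 16.582, tolerance = 1e-3)
  expect_identical(map_distance(0.5, "haldane"), Inf)
  expect_identical(map_distance(0.5, "kosambi"), Inf)
  rr <- r_grid[r_grid > 0 & r_grid < 0.5]
  h <- map_distance(rr, "haldane")
  k <- map_distance(rr, "kosambi")
  i <- map_distance(rr, "identity")
  expect_true(all(h >= k) && all(k >= i))
  # all three agree in the small-r limit
  expect_equal(map_distance(1e-6, "haldane") / (100 * 1e-6), 1,
               tolerance = 1e-4)
  expect_equal(map_distance(1e-6, "kosambi") / (100 * 1e-6), 1,
               tolerance = 1e-4)
})

test_that("F2 simulator conserves totals, respects r = 0, and is reproducible", {
  x <- simulate_f2(0, 1000, seed = 1)
  expect_equal(x[["red_only"]] + x[["green_only"]], 0)
  expect_equal(sum(x), 1000)
  for (r in c(0.05, 0.25, 0.5)) {
    expect_equal(sum(simulate_f2(r, 777, seed = 2)), 777)
  }
  expect_identical(simulate_f2(0.16, 5000, seed = 3),
                   simulate_f2(0.16, 5000, seed = 3))
  expect_identical(simulate_f2(0.16, 5000, seed = 3, method = "gamete"),
                   simulate_f2(0.16, 5000, seed = 3, method = "gamete"))
})

test_that("both simulation routes recover r from large samples", {
  for (m in c("multinomial", "gamete")) {
    fit <- xo_fit(simulate_f2(0.16, 200000, seed = 7, method = m))
    expect_lt(abs(fit$r_hat - 0.16), 0.005)
  }
})

test_that("estimator is unbiased with delta-method standard errors", {
  set.seed(1)
  r_hats <- replicate(500, xo_fit(simulate_f2(0.16, 5000))$r_hat)
  p <- seed_class_probs(0.16)
  f <- p[["RED_ONLY"]] + p[["GREEN_ONLY"]]
  se_pred <- sqrt(f * (1 - f) / 5000) / sqrt(1 - 2 * f)
  expect_lt(abs(mean(r_hats) - 0.16), 2 * se_pred / sqrt(500))
  expect_lt(abs(sd(r_hats) / se_pred - 1), 0.2)
})

test_that("xo_fit behaves as a standard model object", {
  fit <- xo_fit(seed_counts(736, 736, 6764, 1764))
  expect_s3_class(fit, "xo_fit")
  expect_equal(unname(coef(fit)), 0.16)
  expect_equal(dim(vcov(fit)), c(1L, 1L))
  ci <- confint(fit)
  expect_true(ci[1] < 0.16 && 0.16 < ci[2])
  expect_equal(sum(predict(fit)), 1)
  expect_equal(unname(predict(fit, type = "count")),
               unname(seed_class_probs(0.16) * 10000))
  expect_equal(unname(residuals(fit)), rep(0, 4), tolerance = 1e-9)
  sim <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(nrow(sim), 3L)
  expect_true(all(rowSums(sim) == 10000))
  expect_output(print(fit), "recombination fraction")
  s <- summary(fit)
  expect_output(print(s), "Goodness of fit")
  expect_equal(s$chisq, 0, tolerance = 1e-9)
})
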