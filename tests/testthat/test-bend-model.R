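test_that("predict_rf matches the kinked-rod geometry oracle", {
  # hand values
  expect_equal(predict_rf(0, 0.90, 123), 0.90)
  expect_equal(predict_rf(1, 0.90, 37), 0.90)
  expect_equal(predict_rf(0.5, 1.0, 0), 1.0)
  expect_equal(predict_rf(0.5, 1.0, 90), 0.5)
  expect_equal(predict_rf(0.25, 1.0, 60), 0.8125)
  # squared end-to-end distance of a kinked unit rod, explicit 2-D geometry
  set.seed(11)
  for (i in 1:50) {
    x <- runif(1); K <- runif(1, 0.5, 1.2); th <- runif(1, 0, 179)
    expect_equal(predict_rf(x, K, th), K * kink_endtoend_sq(x, th),
                 tolerance = 1e-12)
  }
})

test_that("predict_rf obeys mirror symmetry, theta monotonicity and limits", {
  x <- seq(0, 1, by = 0.05)
  set.seed(12)
  for (i in 1:20) {
    K <- runif(1, 0.5, 1.2); th <- runif(1, 0, 179)
    expect_equal(predict_rf(x, K, th), predict_rf(1 - x, K, th), tolerance = 1e-12)
  }
  # non-increasing in theta at interior x; equal at the ends
  thetas <- seq(0, 179, by = 1)
  interior <- vapply(thetas, function(t) predict_rf(0.3, 1, t), numeric(1))
  expect_true(all(diff(interior) <= 0))
  ends <- vapply(thetas, function(t) predict_rf(0, 1, t), numeric(1))
  expect_equal(ends, rep(1, length(thetas)))
  # theta = 0 gives a flat profile equal to K
  expect_equal(predict_rf(x, 0.87, 0), rep(0.87, length(x)))
})

test_that("predict_rf validates its domain", {
  expect_error(predict_rf(-0.1, 1, 10), class = "etsdyn_validation_error")
  expect_error(predict_rf(0.5, 1, 180), class = "etsdyn_validation_error")
  expect_error(predict_rf(0.5, 0, 10), class = "etsdyn_validation_error")
})

test_that("fit_profile recovers generating parameters from noise-free data", {
  x <- flexure_displacement(make_series())
  p <- mobility_profile(x, predict_rf(x, 0.95, 50), label = "noise-free")
  fit <- fit_profile(p)
  expect_equal(fit$K, 0.95, tolerance = 1e-6)
  expect_equal(fit$theta, 50, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$df, 9L)
  # oracle equivalence: data generated by the geometry oracle fit identically
  po <- oracle_profile(x, 0.88, 72)
  fo <- fit_profile(po)
  expect_equal(fo$K, 0.88, tolerance = 1e-6)
  expect_equal(fo$theta, 72, tolerance = 1e-6)
})

test_that("a flat profile fits K at the data level with theta at the boundary", {
  x <- seq(0.05, 0.95, length.out = 8)
  fit <- fit_profile(mobility_profile(x, rep(0.9, 8), label = "flat"))
  expect_equal(fit$K, 0.9, tolerance = 1e-8)
  expect_equal(fit$theta, 0, tolerance = 1e-4)
})

test_that("narrow-x profiles warn about identifiability but still fit", {
  x <- seq(0.4, 0.6, length.out = 6)
  p <- mobility_profile(x, predict_rf(x, 0.9, 60), label = "narrow")
  expect_warning(fit <- fit_profile(p), "identified")
  expect_s3_class(fit, "bend_fit")
})

test_that("k_from_ends equals the fitted K and isolates non-bend effects", {
  x <- flexure_displacement(make_series())
  f1 <- fit_profile(mobility_profile(x, predict_rf(x, 0.92, 40), label = "a"))
  f2 <- fit_profile(mobility_profile(x, predict_rf(x, 0.92, 80), label = "b"))
  f3 <- fit_profile(mobility_profile(x, predict_rf(x, 0.85, 40), label = "c"))
  expect_equal(k_from_ends(f1), f1$K)
  # same K, different theta: identical end readings
  expect_equal(k_from_ends(f1), k_from_ends(f2), tolerance = 1e-6)
  # K shifted by delta: end readings shift by delta
  expect_equal(k_from_ends(f1) - k_from_ends(f3), 0.07, tolerance = 1e-6)
})

test_that("confidence band collapses, is symmetric, and isolates var(K) at the ends", {
  x <- flexure_displacement(make_series())
  withr::with_seed(21, {
    mu <- predict_rf(x, 0.93, 70)
    m <- mu + rnorm(11, 0, 0.005)
  })
  fit <- fit_profile(mobility_profile(x, m, 0.005, 4, label = "noisy"))
  band <- confidence_band(fit, seq(0, 1, by = 0.1))
  # mirror symmetry of the band
  expect_equal(band$upper, rev(band$upper), tolerance = 1e-9)
  expect_equal(band$lower, rev(band$lower), tolerance = 1e-9)
  # width at x = 0 depends only on var(K): zero out the theta terms numerically
  fit_k_only <- fit
  fit_k_only$covariance[2, ] <- 0
  fit_k_only$covariance[, 2] <- 0
  b0 <- confidence_band(fit, 0)
  b0k <- confidence_band(fit_k_only, 0)
  expect_equal(b0$upper - b0$lower, b0k$upper - b0k$lower, tolerance = 1e-12)
  expect_equal(b0$upper - b0$lower,
               2 * qt(0.975, fit$df) * sqrt(fit$covariance[1, 1]),
               tolerance = 1e-12)
  # zero covariance collapses the band to the prediction
  fit0 <- fit
  fit0$covariance[] <- 0
  bz <- confidence_band(fit0, c(0, 0.3, 0.5))
  expect_equal(bz$lower, bz$fit)
  expect_equal(bz$upper, bz$fit)
  # singular covariance errors
  fitNA <- fit
  fitNA$covariance[] <- NA_real_
  expect_error(confidence_band(fitNA), class = "etsdyn_fit_error")
})

test_that("Monte-Carlo: delta-method CIs cover generating parameters", {
  x <- flexure_displacement(make_series())
  mu <- predict_rf(x, 0.93, 70)
  withr::with_seed(31, {
    hits <- replicate(200, {
      reps <- matrix(rnorm(11 * 4, rep(mu, each = 4), 0.005 * 2), nrow = 4)
      # the design SE (0.005) is known, so it enters as the weight rather
      # than a noisy 3-df per-point estimate
      p <- mobility_profile(x, colMeans(reps), 0.005, 4)
      fit <- fit_profile(p)
      c(K = fit$ci95["K", 1] <= 0.93 && 0.93 <= fit$ci95["K", 2],
        theta = fit$ci95["theta", 1] <= 70 && 70 <= fit$ci95["theta", 2])
    })
  })
  expect_gte(mean(hits["K", ]), 0.90)
  expect_gte(mean(hits["theta", ]), 0.90)
})

test_that("compare_profiles: identical data give F = 0, p = 1", {
  x <- flexure_displacement(make_series())
  withr::with_seed(41, {
    m <- predict_rf(x, 0.9, 55) + rnorm(11, 0, 0.005)
  })
  a <- mobility_profile(x, m, 0.005, 4, label = "a")
  b <- mobility_profile(x, m, 0.005, 4, label = "b (copy)")
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$f_stat, 0, tolerance = 1e-6)
  expect_equal(cmp$p_value, 1, tolerance = 1e-6)
  expect_equal(cmp$verdict, "indistinguishable")
  expect_gte(cmp$rss_global, cmp$rss_separate - 1e-12)
})

test_that("compare_profiles distinguishes distinct complexes; F matches brute force", {
  x <- flexure_displacement(make_series())
  spec <- scenario_spec("test", bend = list(high = c(K = 0.92, theta = 40),
                                            low = c(K = 0.85, theta = 80)),
                        seed = 51)
  pr <- gen_mobility_profiles(spec)
  cmp <- compare_profiles(pr$high, pr$low)
  expect_equal(cmp$verdict, "distinguishable")
  expect_lt(cmp$p_value, 0.001)
  # brute-force oracle: independently minimized RSS via optim + geometry model
  ya <- pr$high$points$rf_mean; yb <- pr$low$points$rf_mean
  fa <- oracle_fit(x, ya, start = c(0.92, 40))
  fb <- oracle_fit(x, yb, start = c(0.85, 80))
  fg <- oracle_fit(c(x, x), c(ya, yb), start = c(0.9, 60))
  rss_sep <- fa$value + fb$value
  f_oracle <- ((fg$value - rss_sep) / 2) / (rss_sep / 18)
  expect_equal(cmp$f_stat, f_oracle, tolerance = 1e-4)
  expect_equal(cmp$rss_separate, rss_sep, tolerance = 1e-8)
})

test_that("compare_profiles works on mismatched x grids and rejects empty input", {
  xa <- seq(0.05, 0.95, length.out = 11)
  xb <- seq(0.1, 0.9, length.out = 9)
  a <- mobility_profile(xa, predict_rf(xa, 0.9, 50) + 0.001, label = "a")
  b <- mobility_profile(xb, predict_rf(xb, 0.9, 50) - 0.001, label = "b")
  expect_s3_class(compare_profiles(a, b), "bend_comparison")
  expect_error(compare_profiles(a, list()), class = "etsdyn_validation_error")
})

test_that("mobility TSV round-trips profiles by label", {
  spec <- scenario_pu1_like(seed = 3)
  pr <- gen_mobility_profiles(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mobility_tsv(pr, path)
  back <- read_mobility_tsv(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$points$rf_mean, pr$high$points$rf_mean, tolerance = 1e-9)
  expect_equal(back[[2]]$points$rf_se, pr$low$points$rf_se, tolerance = 1e-9)
})
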