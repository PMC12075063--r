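test_that("Gaussian curve fitting recovers generating parameters", {
  set.seed(2)
  v <- rnorm(5000, 12000, 3000)
  f1 <- fit_gaussians(histogram_volumes(v[v > 0]), 1)
  expect_lt(abs(f1$mu - 12000), 300)
  expect_lt(abs(f1$sigma - 3000), 300)

  d <- sample_volume_mixture(5000, list(w = 0.3, mean1 = 4000, sd1 = 1200,
                                        mean2 = 15000, sd2 = 4000), seed = 3)
  f2 <- fit_gaussians(histogram_volumes(d$volume_um3), 2)
  expect_lt(abs(f2$mu[1] - 4000), 500)
  expect_lt(abs(f2$mu[2] - 15000), 500)
  expect_true(f2$mu[1] < f2$threshold_um3 && f2$threshold_um3 < f2$mu[2])

  expect_error(fit_gaussians(histogram_volumes(numeric(0)), 1), "all-zero")
  expect_error(fit_gaussians(histogram_volumes(rep(1500, 40)), 2),
               "nonzero bins")
})

test_that("modality assessment separates one from two peaks", {
  set.seed(5)
  v1 <- rnorm(1000, 12000, 3000)
  expect_identical(as.integer(assess_modality(histogram_volumes(v1[v1 > 0]))), 1L)

  d2 <- sample_volume_mixture(1000, list(w = 0.3, mean1 = 4000, sd1 = 1300,
                                         mean2 = 15000, sd2 = 4000), seed = 6)
  k2 <- assess_modality(histogram_volumes(d2$volume_um3))
  expect_identical(as.integer(k2), 2L)
  expect_gt(attr(k2, "delta_bic"), 10)

  # underpowered n = 50: a recorded decision, never an error
  d3 <- sample_volume_mixture(50, list(w = 0.3, mean1 = 4000, sd1 = 1200,
                                       mean2 = 15000, sd2 = 4000), seed = 7)
  k3 <- assess_modality(histogram_volumes(d3$volume_um3))
  expect_true(as.integer(k3) %in% c(1L, 2L))
  expect_true(!is.null(attr(k3, "fit1")))
})

test_that("the intersection threshold matches analytic and grid oracles", {
  sym <- structure(list(n_components = 2L, A = c(100, 100),
                        mu = c(4000, 12000), sigma = c(2000, 2000)),
                   class = "mixture_fit")
  expect_equal(intersection_threshold(sym), 8000)  # symmetry: exact midpoint

  ft <- structure(list(n_components = 2L, A = c(200, 300),
                       mu = c(4000, 15000), sigma = c(1200, 4000)),
                  class = "mixture_fit")
  thr <- intersection_threshold(ft)
  xs <- seq(4000, 15000, by = 1)
  gg <- abs(200 * exp(-(xs - 4000)^2 / (2 * 1200^2)) -
              300 * exp(-(xs - 15000)^2 / (2 * 4000^2)))
  expect_lt(abs(thr - xs[which.min(gg)]), 5)

  # heavy overlap with no crossing between the means: fallback, flagged
  ov <- structure(list(n_components = 2L, A = c(300, 50),
                       mu = c(8000, 10000), sigma = c(4000, 800)),
                  class = "mixture_fit")
  out <- intersection_threshold(ov)
  expect_true(isTRUE(attr(out, "fallback")))
  expect_true(out > 8000 && out < 10000)

  one <- structure(list(n_components = 1L, A = 1, mu = 1, sigma = 1),
                   class = "mixture_fit")
  expect_error(intersection_threshold(one), "two-component")
})

test_that("classification splits records at the threshold", {
  rec <- data.frame(volume_um3 = c(1, 2, 3))
  cl <- classify_somas(rec, 2.5)
  expect_equal(cl$small_fraction, 2 / 3)
  # ties go to alpha ("smaller than the threshold" is gamma)
  cl2 <- classify_somas(data.frame(volume_um3 = c(2.5, 3)), 2.5)
  expect_identical(as.character(cl2$calls$class),
                   rep("putative_alpha", 2))
  expect_identical(classify_somas(rec, 0.5)$small_fraction, 0)
  # empty input: missing fraction, not zero
  cl0 <- classify_somas(rec[0, , drop = FALSE], 10)
  expect_true(is.na(cl0$small_fraction))
  expect_error(classify_somas(rec, -1), "threshold")
  # partition: gamma + alpha = total; monotone in the threshold
  d <- sample_volume_mixture(400, list(w = 0.4, mean1 = 4000, sd1 = 1200,
                                       mean2 = 15000, sd2 = 4000), seed = 8)
  rec2 <- data.frame(volume_um3 = d$volume_um3)
  fr <- vapply(c(2000, 6000, 10000, 20000),
               function(t) classify_somas(rec2, t)$small_fraction, 0)
  expect_true(all(diff(fr) >= 0))
  cla <- classify_somas(rec2, 7000)$calls
  expect_identical(sum(cla$class == "putative_gamma") +
                     sum(cla$class == "putative_alpha"), 400L)
})

test_that("the threshold is invariant under count rescaling", {
  d <- sample_volume_mixture(3000, list(w = 0.3, mean1 = 4000, sd1 = 1200,
                                        mean2 = 15000, sd2 = 4000), seed = 9)
  h <- histogram_volumes(d$volume_um3)
  f <- fit_gaussians(h, 2)
  h3 <- h
  h3$counts <- h$counts * 5L
  f3 <- fit_gaussians(h3, 2)
  expect_equal(f3$threshold_um3, f$threshold_um3, tolerance = 1e-4)
  expect_equal(f3$A, f$A * 5, tolerance = 1e-3)
})

test_that("sphere tables and regional summaries are consistent", {
  calls <- data.frame(id = 1:4, volume_um3 = c(4188.790205, 500, 900, 1200),
                      cz_um = c(10, 10, 90, 90), cy_um = 10, cx_um = 10,
                      class = factor(c("putative_alpha", "putative_gamma",
                                       "putative_gamma", "putative_gamma"),
                                     levels = c("putative_gamma",
                                                "putative_alpha")))
  tab <- spatial_call_table(calls,
                            boxes = data.frame(name = c("rostral", "caudal"),
                                               z0 = c(0, 50), z1 = c(50, 100),
                                               y0 = 0, y1 = 100,
                                               x0 = 0, x1 = 100))
  expect_equal(tab$spheres$radius_um[1], 10, tolerance = 1e-6)
  expect_identical(tab$regions$n_gamma, c(1L, 2L))
  expect_identical(tab$regions$n_alpha, c(1L, 0L))
  # all-gamma input: single-class table
  tab2 <- spatial_call_table(calls[2:4, ])
  expect_identical(unique(as.character(tab2$spheres$class)), "putative_gamma")
})

test_that("classification recovers the generating weight over replicates", {
  # 100 replicates at n = 1000, w = 0.3, well-separated mixture
  fr <- recover_small_fraction(0.3, 1000, n_replicates = 100, seed = 500)
  expect_gte(fr$mean_small_fraction, 0.28)
  expect_lte(fr$mean_small_fraction, 0.32)
})
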