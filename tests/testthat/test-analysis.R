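# Downstream statistics: ring gradients, effect sizes, object features,
# event-rate and data-rate accounting, display standardization.

test_that("ring gradient is zero for uniform nuclei and matches the
           closed-form line through constructed fractional profiles", {
  nuc <- disk(40, 40, 20.5, 20.5, 24)
  lt <- matrix(0, 40, 40); lt[nuc] <- 3
  gr <- ring_lifetime_gradient(lt, nuc)
  expect_true(gr$defined)
  expect_equal(gr$fractional_values, rep(1, 4))
  expect_equal(gr$gradient_percent, 0)
  # radial profile engineered to hit fractional values (0.94, 0.98, 1.02, 1.06):
  # a line through equally spaced exact points has slope 0.16 per unit
  # normalized distance, hence a gradient of 0.16 * 0.75 * 100 = +12
  dn <- flimflow:::edge_distance_norm(nuc)
  ring <- flimflow:::ring_index(dn[nuc], 4L)
  target <- c(0.94, 0.98, 1.02, 1.06)
  vals <- matrix(0, 40, 40)
  vals[nuc] <- target[ring]
  # normalize so ring means / overall mean equal the target fractions
  vals[nuc] <- vals[nuc] / mean(vals[nuc])
  gr_up <- ring_lifetime_gradient(vals, nuc)
  expect_equal(gr_up$gradient_percent, 12, tolerance = 0.1)
  rev_vals <- matrix(0, 40, 40)
  rev_vals[nuc] <- rev(target)[ring]
  rev_vals[nuc] <- rev_vals[nuc] / mean(rev_vals[nuc])
  expect_equal(ring_lifetime_gradient(rev_vals, nuc)$gradient_percent, -12,
               tolerance = 0.1)
})

test_that("ring gradient is scale invariant and undefined on tiny masks", {
  nuc <- disk(30, 30, 15.5, 15.5, 18)
  set.seed(2)
  lt <- matrix(0, 30, 30); lt[nuc] <- runif(sum(nuc), 2, 4)
  g1 <- ring_lifetime_gradient(lt, nuc)$gradient_percent
  g2 <- ring_lifetime_gradient(lt * 7.3, nuc)$gradient_percent
  expect_equal(g1, g2, tolerance = 1e-12)
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_false(ring_lifetime_gradient(lt[1:10, 1:10], tiny)$defined)
  expect_false(ring_lifetime_gradient(lt, nuc * 0)$defined)
})

test_that("Cohen's d and its standard error follow the pooled-SD formulas", {
  # hand-evaluated example: means 1 and 0, both SDs sqrt(2), n = 2 each
  es <- cohens_d(c(0, 2), c(-1, 1))
  expect_equal(es$d, 1 / sqrt(2), tolerance = 1e-12)
  n <- 4
  expect_equal(es$se,
               sqrt(((n - 1) / (n - 3)) * (4 / n) * (1 + es$d^2 / 8)),
               tolerance = 1e-12)
  # identical samples
  set.seed(1); x <- rnorm(50)
  expect_equal(cohens_d(x, x)$d, 0)
  # antisymmetry under swap, se unchanged
  y <- rnorm(40, mean = 0.4)
  expect_equal(cohens_d(x, y)$d, -cohens_d(y, x)$d, tolerance = 1e-12)
  expect_equal(cohens_d(x, y)$se, cohens_d(y, x)$se, tolerance = 1e-12)
  # invariance under common affine rescaling
  expect_equal(cohens_d(3 + 2 * x, 3 + 2 * y)$d, cohens_d(x, y)$d,
               tolerance = 1e-12)
  # zero pooled SD flags an undefined result
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))$d))
})

test_that("object features report nucleus counts, select the rounder nucleus,
           and give zero lifetime CV for uniform objects", {
  # one cell (dark in bright-field) holding two nuclei of different shape
  bf <- matrix(1, 60, 60)
  cell <- disk(60, 60, 30, 30, 46)
  bf[cell] <- 0.2
  fl <- matrix(0, 60, 60)
  round_nuc <- disk(60, 60, 20, 30, 12)
  long_nuc <- disk(60, 60, 42, 24, 8) | disk(60, 60, 42, 30, 8) |
    disk(60, 60, 42, 36, 8)          # elongated blob
  fl[round_nuc] <- 1; fl[long_nuc] <- 1
  lt <- matrix(NA_real_, 60, 60)
  lt[round_nuc | long_nuc] <- 3.1
  feats <- extract_objects(fake_flim_event(bf, fl, lt))
  expect_equal(nrow(feats), 1L)
  expect_equal(feats$n_nuclei, 2L)
  round_shape <- flimflow:::mask_shape(round_nuc)
  long_shape <- flimflow:::mask_shape(long_nuc)
  expect_lt(round_shape$eccentricity, long_shape$eccentricity)
  expect_equal(feats$nucleus_area, round_shape$area)
  expect_lt(feats$nucleus_eccentricity, 0.3)
  expect_equal(feats$cv_lifetime_pixels, 0)
  expect_equal(feats$mean_lifetime_ns, 3.1)
  # empty event
  expect_equal(nrow(extract_objects(fake_flim_event(matrix(0, 8, 8),
                                                    matrix(0, 8, 8),
                                                    matrix(NA_real_, 8, 8)))), 0L)
})

test_that("event rates count recognizable images against elapsed time", {
  at <- seq(1e-4, 1e-2, length.out = 100)
  r <- event_rate_stats(at, rep(TRUE, 100), total_duration_s = 0.01)
  expect_equal(r$actual_rate_eps, 10000)
  expect_equal(r$mean_rate_eps, 10000)
  r0 <- event_rate_stats(at, rep(FALSE, 100), total_duration_s = 0.01)
  expect_equal(r0$actual_rate_eps, 0)
  expect_true(r0$actual_rate_eps <= r0$mean_rate_eps)
  expect_error(event_rate_stats(numeric(0), logical(0)), "empty")
  expect_error(event_rate_stats(1, TRUE, total_duration_s = 0), "zero elapsed")
})

test_that("rate reports include instantaneous windows and an exponential
           least-absolute-residual fit of the inter-arrival tail", {
  dt <- 20.48e-6
  at <- simulate_arrivals(20000, 0.3, dt, seed = 5)
  rec <- rep(c(TRUE, TRUE, FALSE), length.out = length(at))
  r <- event_rate_stats(at, rec, total_duration_s = 0.3, dead_time_s = dt)
  expect_equal(length(r$instantaneous_rates_eps), length(at) %/% 100)
  expect_lt(r$actual_rate_eps, r$mean_rate_eps)
  # fitted exponential rate close to the candidate rate
  expect_equal(r$inter_arrival_fit$rate, 20000, tolerance = 0.15)
})

test_that("recognizability gates on eccentricity with the bead/cell presets", {
  f1 <- data.frame(eccentricity = c(0.8, 0.65))
  expect_false(is_recognizable(f1, 0.6))
  expect_true(is_recognizable(f1, 0.72))
  expect_false(is_recognizable(f1[0, , drop = FALSE], 0.72))
})

test_that("data-generation arithmetic reproduces the instrument's worked
           examples (MB = 2^20 bytes, bytes per event floored)", {
  beads <- data_generation_rate(11297, 11)
  expect_equal(beads$effective_event_time_s * 1e6, 2.6819, tolerance = 1e-4)
  expect_identical(beads$bytes_per_event, 3352)
  expect_equal(beads$data_rate_mb_s, 108.3, tolerance = 0.05)
  cells <- data_generation_rate(10371, 22)
  expect_equal(cells$data_rate_mb_s, 198.9, tolerance = 0.05)
  expect_equal(data_generation_rate(0, 11)$data_rate_mb_s, 0)
  expect_error(data_generation_rate(100, -1), "positive")
})

test_that("lifetime display standardization removes an injected column slope
           and returns median +/- 1.6 IQR bounds", {
  nuc <- disk(40, 40, 20.5, 20.5, 26)
  set.seed(9)
  base <- matrix(3, 40, 40) + matrix(rnorm(1600, sd = 0.05), 40)
  flat <- standardize_lifetime_image(base, nuc)
  expect_lt(abs(flat$slope_per_column), 0.005)
  slope <- 0.04
  tilted <- base + slope * matrix(seq_len(40), 40, 40, byrow = TRUE)
  st <- standardize_lifetime_image(tilted, nuc)
  expect_equal(st$slope_per_column, slope, tolerance = 0.01 * slope + 0.005)
  # residual slope below 1% of the injected slope
  resid <- st$image
  idx <- which(nuc, arr.ind = TRUE)
  fit <- lm(resid[nuc] ~ idx[, 2])
  expect_lt(abs(coef(fit)[2]), 0.01 * slope)
  v <- st$image[nuc]
  expect_equal(st$scale_low, median(v) - 1.6 * (quantile(v, 0.75) - quantile(v, 0.25)),
               ignore_attr = TRUE)
  # constant image collapses to the median and is flagged
  const <- standardize_lifetime_image(matrix(2, 40, 40), nuc)
  expect_true(const$degenerate)
  expect_equal(const$scale_low, const$scale_high)
  expect_error(standardize_lifetime_image(base, nuc * 0), "degenerate")
})

test_that("multinucleate percentages carry Wilson score intervals", {
  z <- qnorm(0.975)
  none <- multinucleate_fraction(data.frame(n_nuclei = rep(1, 100)))
  expect_equal(none$percent, 0)
  expect_equal(none$ci_low, 0)
  expect_equal(none$ci_high, 100 * z^2 / (100 + z^2), tolerance = 1e-9)
  expect_equal(none$ci_high, 3.70, tolerance = 0.01)
  all_multi <- multinucleate_fraction(data.frame(n_nuclei = rep(2, 10)))
  expect_equal(all_multi$percent, 100)
  expect_equal(all_multi$ci_high, 100)
  # x = 10 of n = 100 against the closed-form Wilson bounds
  ten <- multinucleate_fraction(data.frame(n_nuclei = rep(c(2, 1), c(10, 90))))
  p <- 0.1; n <- 100
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  expect_equal(ten$percent, 10)
  expect_equal(ten$ci_low, 100 * (ctr - half), tolerance = 1e-9)
  expect_equal(ten$ci_high, 100 * (ctr + half), tolerance = 1e-9)
  expect_error(multinucleate_fraction(data.frame(n_nuclei = integer(0))), "empty")
})
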