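make_gain_plate <- function(low, gain = 2, offset = 0, ceiling = Inf) {
  high_raw <- gain * low + offset
  data.frame(plate = 1L, row = 1L, col = seq_along(low),
             size = 1, fluor_low = low,
             fluor_high = pmin(high_raw, ceiling),
             saturated_high = as.integer(high_raw > ceiling))
}

test_that("gain consolidation prefers high gain and calibrates saturated colonies", {
  # exact affine relation, nothing saturated: output is the high-gain value
  pl <- make_gain_plate(c(10, 20, 30, 40))
  out <- consolidate_gains(pl)
  expect_equal(out$fluor, pl$fluor_high)
  expect_equal(attr(out, "calibration")$gain_factor, 2, tolerance = 1e-12)

  # a colony saturated in high gain falls back to the calibrated low gain
  pl2 <- make_gain_plate(c(10, 20, 30, 1000), ceiling = 100)
  out2 <- consolidate_gains(pl2)
  expect_equal(out2$fluor[4], 2 * 1000, tolerance = 1e-9)
  expect_equal(out2$fluor[1:3], pl2$fluor_high[1:3])

  # too few calibration points
  pl3 <- make_gain_plate(c(10, 20, 30), ceiling = 50)
  expect_error(consolidate_gains(pl3), "unsaturated")
})

test_that("gain calibration recovers a noisy gain factor within 2%", {
  set.seed(41)
  low <- runif(200, 10, 500)
  high <- 3.5 * low + 40 + rnorm(200, 0, 5)
  pl <- data.frame(plate = 1L, row = 1L, col = 1:200, size = 1,
                   fluor_low = low, fluor_high = high,
                   saturated_high = 0L)
  cal <- attr(consolidate_gains(pl), "calibration")
  expect_lt(abs(cal$gain_factor - 3.5) / 3.5, 0.02)
})

test_that("group normalization divides by the reference mean", {
  lay <- make_layout(2, "fluor4x4")
  tr <- make_array_truth(2, seed = 1)
  pl <- simulate_fluor_array(tr, lay, noise_cv = 0, spatial_type = "flat")
  pl <- consolidate_gains(pl)
  norm <- normalize_group(pl, lay)
  # reference colonies normalize to exactly 1 in a noiseless flat plate
  expect_equal(norm$nfluor[norm$role == "reference"],
               rep(1, sum(norm$role == "reference")), tolerance = 1e-12)
  # doubling every raw value leaves normalized values unchanged
  pl2 <- pl
  pl2$fluor <- pl2$fluor * 2
  norm2 <- normalize_group(pl2, lay)
  expect_equal(norm2$nfluor, norm$nfluor, tolerance = 1e-12)
})

test_that("group normalization cuts spatial variation at least 5-fold", {
  # constant-abundance strains across a strong smooth field, no noise
  n <- 60
  lay <- make_layout(n, "fluor4x4")
  tr <- make_array_truth(n, state_probs = c(not_detected = 0, degraded = 0,
                                            partially_degraded = 0,
                                            not_affected = 1),
                         abundance_range = c(4, 4), seed = 2)
  pl <- simulate_fluor_array(tr, lay, noise_cv = 0, spatial_type = "gradient",
                             spatial_amplitude = 0.2, seed = 3)
  pl <- consolidate_gains(pl)
  norm <- normalize_group(pl, lay)
  raw <- merge(pl, lay, by = c("plate", "row", "col"))
  raw_minus <- raw$fluor[raw$role == "sample_minus"]
  norm_minus <- norm$nfluor[norm$role == "sample_minus"]
  cv <- function(v) sd(v) / mean(v)
  expect_gt(cv(raw_minus) / cv(norm_minus), 5)
})

test_that("strain summaries behave at the fixed points", {
  # plus replicates identical to minus replicates
  s <- summarize_strain(c(2, 2.1, 1.9), c(2, 2.1, 1.9), bkg = 0.5)
  expect_equal(s$fold, 1)
  expect_equal(s$p, 1)

  # plus at background: fold collapses to 0
  s2 <- summarize_strain(rep(0.5, 3) + c(0, 1e-9, -1e-9),
                         c(2, 2.05, 1.95), bkg = 0.5)
  expect_lt(s2$fold, 0.01)

  # negative background-corrected minus mean leaves the fold undefined
  s3 <- summarize_strain(c(0.4, 0.41, 0.39), c(0.3, 0.31, 0.29), bkg = 0.5)
  expect_true(is.na(s3$fold))
})

test_that("simulated fold estimates land within 3 SE of truth", {
  set.seed(43)
  fold_true <- 0.3
  ests <- replicate(100, {
    minus <- 4 * (1 + rnorm(3, 0, 0.1))
    plus <- 4 * fold_true * (1 + rnorm(6, 0, 0.1))
    summarize_strain(plus + 1, minus + 1, bkg = 1)$fold
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - fold_true), 3 * se)
})

test_that("degradation rules assign the printed categories", {
  thr <- degradation_thresholds()
  mk <- function(rm, rp, fold, q)
    data.frame(mng_over_bkg_minus = rm, mng_over_bkg_plus = rp,
               fold = fold, q = q)
  expect_identical(classify_degradation(mk(1.1, 1.0, 1, 0.5), thr),
                   "not_detected")
  expect_identical(classify_degradation(mk(4.0, 1.1, 0.03, 0.001), thr),
                   "degraded")
  expect_identical(classify_degradation(mk(6.0, 2.5, 0.30, 0.01), thr),
                   "partially_degraded")
  expect_identical(classify_degradation(mk(6.0, 2.5, 0.90, 0.01), thr),
                   "not_affected")
  # non-significant depletion is not called
  expect_identical(classify_degradation(mk(6.0, 2.5, 0.30, 0.20), thr),
                   "not_affected")
})

test_that("classification partitions and is monotone in fold_max", {
  set.seed(44)
  n <- 200
  s <- data.frame(mng_over_bkg_minus = runif(n, 0.8, 8),
                  mng_over_bkg_plus = runif(n, 0.8, 8),
                  fold = runif(n, 0, 1.2),
                  q = runif(n))
  cats <- classify_degradation(s)
  expect_true(all(cats %in% c("not_detected", "degraded",
                              "partially_degraded", "not_affected")))
  expect_equal(length(cats), n)

  loose <- classify_degradation(s, degradation_thresholds(fold_max = 0.7))
  strict <- classify_degradation(s, degradation_thresholds(fold_max = 0.3))
  depleted <- c("degraded", "partially_degraded")
  # raising fold_max can only move strains into the depleted classes
  expect_true(all(cats[strict %in% depleted] %in% depleted |
                    cats[strict %in% depleted] == "not_detected"))
  expect_true(all(loose[cats %in% depleted] %in% depleted))
})

test_that("detection-limit calibration inverts exact and noisy lines", {
  # exact unit line log(F) = log(A): the limit equals the threshold
  a <- c(1, 10, 100, 1000, 1e4)
  cal <- calibrate_detection_limit(a, a, threshold = 10, seed = 1)
  expect_equal(cal$limit, 10, tolerance = 1e-9)
  expect_equal(cal$ci_low, cal$ci_high)
  # doubling the threshold doubles the limit on the unit line
  cal2 <- calibrate_detection_limit(a, a, threshold = 20, seed = 1)
  expect_equal(cal2$limit, 2 * cal$limit, tolerance = 1e-9)
  expect_error(calibrate_detection_limit(c(-1, a[-1]), a))
})

test_that("bootstrap intervals cover the true detection limit", {
  true_slope <- 0.8; true_int <- -1.5; thr <- 1.2
  true_limit <- exp((log(thr) - true_int) / true_slope)
  set.seed(45)
  hits <- replicate(100, {
    a <- exp(runif(12, log(50), log(5e4)))
    f <- exp(true_int + true_slope * log(a) + rnorm(12, 0, 0.4))
    cal <- calibrate_detection_limit(a, f, threshold = thr, n_boot = 400)
    cal$ci_low <= true_limit && true_limit <= cal$ci_high
  })
  expect_gte(mean(hits), 0.9)
})

test_that("planted degradation states are recovered on a synthetic array", {
  n <- 240
  tr <- make_array_truth(n, seed = 46)
  lay <- make_layout(n, "fluor4x4")
  pl <- simulate_fluor_array(tr, lay, noise_cv = 0.1, ceiling = 6000,
                             seed = 47)
  res <- analyze_fluor(pl, lay)
  planted <- tr$state[match(res$orf, tr$orf)]
  expect_gte(mean(planted == res$category), 0.9)
})
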