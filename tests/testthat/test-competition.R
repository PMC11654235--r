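test_that("gating assigns each event to exactly one class", {
  ctrl <- data.frame(mng = c(5, 8, 10), mcherry = c(4, 9, 7))
  # all sample events below both control maxima
  s1 <- data.frame(mng = c(1, 2, 3), mcherry = c(1, 2, 3))
  g1 <- gate_events(s1, ctrl)
  expect_equal(g1$n_wt, 3L)
  expect_equal(g1$n_total, 3L)
  expect_equal(g1$n_mng + g1$n_mcherry + g1$n_double + g1$n_wt, g1$n_total)

  # one event above the mNG threshold only
  s2 <- data.frame(mng = c(11, 2), mcherry = c(3, 3))
  expect_equal(gate_events(s2, ctrl)$n_mng, 1L)

  # double positive
  s3 <- data.frame(mng = 100, mcherry = 100)
  expect_equal(gate_events(s3, ctrl)$n_double, 1L)

  # empty sample flagged
  g0 <- gate_events(s1[0, ], ctrl)
  expect_identical(g0$flag, "empty_sample")
  expect_equal(g0$n_total, 0L)
  expect_error(gate_events(s1, ctrl[0, ]))
})

test_that("gating a 3-decade mixture misclassifies under 1% of events", {
  set.seed(21)
  ev <- make_labelled_events(5000, 5000)
  ctrl <- simulate_control_events(10000, seed = 22)
  g <- gate_events(ev[, c("mng", "mcherry")], ctrl)
  # truth: 5000 mng-positives, 5000 unstained
  err <- (abs(g$n_mng - 5000) + abs(g$n_wt - 5000)) / 10000
  expect_lt(err, 0.01)
})

test_that("zero-intercept slope reproduces exact constructions", {
  # flat ratio
  s <- data.frame(day = 0:3, n_mng = rep(5000, 4), n_mcherry = rep(5000, 4))
  expect_equal(estimate_alpha(s)$alpha, 0)

  # exact line through the origin with slope ln 2
  s2 <- data.frame(day = 0:3, n_mng = 1000 * 2^(0:3),
                   n_mcherry = rep(1000, 4))
  f2 <- estimate_alpha(s2)
  expect_equal(f2$alpha, log(2), tolerance = 1e-12)
  expect_equal(f2$se_alpha, 0, tolerance = 1e-9)
  expect_equal(f2$r2, 1)
  expect_identical(f2$flag, "ok")
})

test_that("slope estimator is antisymmetric and scale invariant", {
  set.seed(31)
  for (i in 1:10) {
    s <- data.frame(day = 0:3,
                    n_mng = rpois(4, 4000) + 1,
                    n_mcherry = rpois(4, 6000) + 1)
    a <- estimate_alpha(s, "n_mng", "n_mcherry")$alpha
    b <- estimate_alpha(s, "n_mcherry", "n_mng")$alpha
    expect_equal(a, -b, tolerance = 1e-12)
    s10 <- s; s10$n_mng <- s10$n_mng * 10; s10$n_mcherry <- s10$n_mcherry * 10
    expect_equal(estimate_alpha(s10)$alpha, a, tolerance = 1e-12)
  }
})

test_that("zero-intercept slope equals brute-force least squares", {
  set.seed(32)
  for (i in 1:5) {
    s <- data.frame(day = 0:4,
                    n_mng = rpois(5, 3000) + 1,
                    n_mcherry = rpois(5, 3000) + 1)
    fit <- estimate_alpha(s)
    y <- fit$y; t <- fit$t
    brute <- oracle_slope_grid(y, t)
    expect_lt(abs(fit$alpha - brute), 1e-9)
  }
})

test_that("zero counts trigger the pseudocount rule; short series flagged", {
  s <- data.frame(day = 0:3, n_mng = c(5000, 4000, 3000, 0),
                  n_mcherry = c(5000, 6000, 7000, 10000))
  f <- estimate_alpha(s)
  expect_identical(f$flag, "pseudocount_used")
  expect_true(is.finite(f$alpha))

  s1 <- data.frame(day = 0:1, n_mng = c(5000, 4000),
                   n_mcherry = c(5000, 6000))
  f1 <- estimate_alpha(s1)
  expect_identical(f1$flag, "insufficient")
  expect_true(is.na(f1$alpha))
})

test_that("alpha_fit methods are coherent", {
  s <- data.frame(day = 0:3, n_mng = c(5000, 5600, 6100, 6900),
                  n_mcherry = c(5000, 4300, 3800, 3300))
  f <- estimate_alpha(s)
  expect_s3_class(f, "alpha_fit")
  expect_named(coef(f), "alpha")
  expect_equal(length(residuals(f)), f$n_timepoints)
  expect_equal(predict(f, data.frame(day = 2)), 2 * f$alpha)
  ci <- confint(f)
  expect_true(ci[1] < f$alpha && f$alpha < ci[2])
  expect_output(print(f), "alpha")
  expect_output(print(summary(f)), "CI")
})

test_that("doubling-time conversion reproduces the decision thresholds", {
  expect_equal(alpha_from_doubling_diff(0), 0)
  a5 <- alpha_from_doubling_diff(0.05, T = 4.5, interval = 24)
  a20 <- alpha_from_doubling_diff(0.20, T = 4.5, interval = 24)
  expect_equal(a5, 24 * log(2) * (1 / 4.5 - 1 / 4.725), tolerance = 1e-12)
  expect_lt(abs(a5 - 0.175) / 0.175, 0.01)
  expect_lt(abs(a20 - 0.611) / 0.611, 0.01)
  # inverse round-trip
  expect_equal(doubling_diff_from_alpha(a5), 0.05, tolerance = 1e-12)
  expect_equal(doubling_diff_from_alpha(a20), 0.20, tolerance = 1e-12)
})

test_that("bias classification is exhaustive with neutral boundaries", {
  thr <- bias_thresholds()
  expect_identical(classify_bias(0.3, thr), "N_loser")
  expect_identical(classify_bias(-0.2, thr), "C_loser")
  expect_identical(classify_bias(0.175, thr), "neutral")
  expect_identical(classify_bias(-0.175, thr), "neutral")
  set.seed(33)
  a <- rnorm(100, 0, 0.4)
  cls <- classify_bias(a, thr)
  expect_true(all(cls %in% c("N_loser", "C_loser", "neutral")))
  expect_equal(sum(cls == "N_loser"), sum(a > 0.175))
})

test_that("triple competitions decompose additively", {
  # noiseless exponential construction with three growth rates
  r <- c(A = 0.5, B = 0.3, wt = 0.1)
  t <- 0:3
  s <- data.frame(day = t,
                  n_mng = 1000 * exp(r["A"] * t),
                  n_mcherry = 1000 * exp(r["B"] * t),
                  n_wt = 1000 * exp(r["wt"] * t))
  fits <- fit_triple(s)
  a <- coef(fits)
  expect_equal(unname(a["mng_vs_mcherry"]),
               unname(a["mng_vs_wt"] - a["mcherry_vs_wt"]),
               tolerance = 1e-12)
  expect_equal(unname(a["mng_vs_mcherry"]), unname(r["A"] - r["B"]),
               tolerance = 1e-12)

  # identical counts: all three slopes zero
  s0 <- data.frame(day = 0:3, n_mng = rep(4000, 4),
                   n_mcherry = rep(4000, 4), n_wt = rep(2000, 4))
  expect_true(all(abs(coef(fit_triple(s0))) < 1e-12))
})

test_that("tagged strains outgrow a slower wild type in triples", {
  # both marked strains unburdened, wild type 5% slower
  m <- growth_model(delta = 0, wt_delta = 0.05)
  set.seed(34)
  alphas <- replicate(50, {
    sim <- simulate_competition(m, days = 3, wild_type = TRUE,
                                events = FALSE)
    coef(fit_triple(sim$counts))[c("mng_vs_wt", "mcherry_vs_wt")]
  })
  expect_gt(median(alphas), 0)
  # and the marker-pair slope stays near zero
  set.seed(35)
  pair <- replicate(50, {
    sim <- simulate_competition(m, days = 3, wild_type = TRUE,
                                events = FALSE)
    coef(fit_triple(sim$counts))["mng_vs_mcherry"]
  })
  expect_lt(abs(mean(pair)), 3 * sd(pair) / sqrt(length(pair)))
})
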