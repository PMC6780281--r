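# Method-comparison statistics against independent oracles and closed forms.

test_that("paired_series validates its invariants", {
  expect_error(paired_series(c(1, 1, 2), c(80, 81, 82), c(80, 81, 82)),
               "increasing")
  expect_error(paired_series(1:3, c(80, -1, 82), c(80, 81, 82)), "> 0")
  expect_error(paired_series(1:3, c(80, 81, 82), c(80, NA, 82)), "finite")
})

test_that("pearson_with_ci is exact on a line and always contains r", {
  x <- seq(1, 10)
  p <- paired_series(x, x * 3 + 2, (x * 3 + 2) * 2 + 1)
  pc <- pearson_with_ci(p)
  expect_equal(pc$r, 1)
  for (seed in 1:20) {
    rp <- random_pairs(80, seed)
    pc <- pearson_with_ci(rp)
    expect_true(pc$ci_low <= pc$r && pc$r <= pc$ci_high)
    expect_equal(pc$r, bf_pearson(rp$ref, rp$test), tolerance = 1e-9)
    ci <- bf_fisher_ci(pc$r, nrow(rp))
    expect_equal(c(pc$ci_low, pc$ci_high), ci, tolerance = 1e-9)
  }
  expect_error(pearson_with_ci(paired_series(1:10, rep(80, 10),
                                             rnorm(10, 80, 1) + 0:9)),
               "constant")
})

test_that("the Fisher CI narrows with n at fixed r", {
  rp <- random_pairs(60, 4)
  r <- cor(rp$ref, rp$test)
  w1 <- diff(fisher_ci(r, 60))
  w2 <- diff(fisher_ci(r, 240))
  w3 <- diff(fisher_ci(r, 5000))
  expect_true(w1 > w2 && w2 > w3)
})

test_that("the Fisher CI has near-nominal coverage", {
  rho <- 0.8
  n <- 1000
  set.seed(42)
  covered <- vapply(1:200, function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- fisher_ci(cor(x, y), n)
    ci[1] <= rho && rho <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("bland_altman matches hand computation and the direct oracle", {
  p <- paired_series(1:4, c(90, 70, 80, 80), c(80, 80, 80, 80))
  # diffs are {-10, +10, 0, 0}: sd = sqrt(200/3), LoA = +/- 16.00
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(round(ba$loa_high, 2), 16.00)
  expect_equal(round(ba$loa_low, 2), -16.00)
  ident <- paired_series(1:5, rep(85, 5), rep(85, 5))
  bi <- bland_altman(ident)
  expect_equal(c(bi$bias, bi$loa_low, bi$loa_high), c(0, 0, 0))
  expect_error(bland_altman(paired_series(1, 80, 80)), "at least 2")
})

test_that("steiger_test agrees with an independent coding of the formula", {
  expect_equal(steiger_test(0.7, 0.7, 0.5, 100)$z, 0)
  expect_equal(steiger_test(0.7, 0.7, 0.5, 100)$p, 1)
  set.seed(12)
  for (i in 1:25) {
    ra <- runif(1, -0.9, 0.9); rb <- runif(1, -0.9, 0.9)
    rab <- runif(1, 0, 0.9); n <- sample(20:500, 1)
    got <- steiger_test(ra, rb, rab, n)
    want <- bf_steiger(ra, rb, rab, n)
    expect_equal(got$z, unname(want["z"]), tolerance = 1e-9)
    expect_equal(got$p, unname(want["p"]), tolerance = 1e-9)
  }
})

test_that("compare_dependent_correlations wires the empirical r_AB", {
  set.seed(3)
  n <- 200
  t <- 1:n
  ref <- pmax(rnorm(n, 85, 15), 10)
  a <- pmax(ref + rnorm(n, 0, 8), 5)
  b <- pmax(ref + rnorm(n, 0, 16), 5)
  pa <- paired_series(t, ref, a)
  pb <- paired_series(t, ref, b)
  got <- compare_dependent_correlations(pa, pb)
  expect_equal(got$r_ab, cor(a, b), tolerance = 1e-12)
  expect_gt(got$z, 0)  # a correlates better
  pb_bad <- paired_series(t + 0.5, ref, b)
  expect_error(compare_dependent_correlations(pa[1:100, ], pb[1:99, ]),
               "lengths differ")
})

test_that("four-quadrant concordance handles constructed cases exactly", {
  # 9 samples at 60-s cadence -> 8 delta pairs; mean(ref) = 100, zone = 10
  d_ref <- c(1, -30, 25, 28, -26, 24, 30, -2)
  d_test <- c(2, -25, 30, -22, -30, 27, -25, 1)
  # pairs 1 and 8 sit inside the zone; of the remaining 6, pairs
  # 2,3,5,6 are concordant and 4,7 are not -> 4/6 = 66.67%
  base <- 100 - mean(cumsum(c(0, d_ref))) + cumsum(c(0, d_ref))
  ref <- base - mean(base) + 100
  test <- ref[1] + cumsum(c(0, d_test))
  t <- seq(0, by = 60, length.out = 9)
  fq <- four_quadrant_concordance(paired_series(t, ref, test),
                                  delta_interval_s = 60)
  expect_equal(fq$n_excluded, 2L)
  expect_equal(fq$n_used, 6L)
  expect_equal(fq$concordance_rate, 100 * 4 / 6, tolerance = 1e-9)
  # all-positive deltas outside the zone
  up <- cumsum(rep(30, 10)) + 50
  fq2 <- four_quadrant_concordance(paired_series(seq(0, 540, 60), up,
                                                 up + 5),
                                   delta_interval_s = 60)
  expect_equal(fq2$concordance_rate, 100)
  # flat series: every delta inside the zone -> undefined rate
  fl <- paired_series(seq(0, 540, 60), rep(80, 10), rep(82, 10))
  fq3 <- four_quadrant_concordance(fl, delta_interval_s = 60)
  expect_true(is.na(fq3$concordance_rate))
  expect_identical(fq3$n_used, 0L)
  # too short for any delta pair: an error
  expect_error(four_quadrant_concordance(paired_series(1:3, 80:82, 81:83),
                                         delta_interval_s = 60),
               "too short")
})

test_that("performance errors match their definitions", {
  p <- paired_series(1, 110, 100)
  pe <- performance_errors(p)
  expect_equal(pe$mdpe, 0.10)
  # PE set {-0.2, 0.1, 0.3}
  p3 <- paired_series(1:3, c(80, 110, 130), c(100, 100, 100))
  pe3 <- performance_errors(p3)
  expect_equal(pe3$mdpe, 0.1)
  expect_equal(pe3$mdape, 0.2)
  ident <- paired_series(1:4, rep(90, 4), rep(90, 4))
  pi4 <- performance_errors(ident)
  expect_equal(c(pi4$mdpe, pi4$mdape, pi4$rmse), c(0, 0, 0))
})

test_that("mdape >= |mdpe| and rmse = 0 iff identical, on random inputs", {
  for (seed in 1:50) {
    rp <- random_pairs(31, seed + 100)
    pe <- performance_errors(rp)
    expect_gte(pe$mdape, abs(pe$mdpe))
    expect_gt(pe$rmse, 0)
  }
})

test_that("phase_report stratifies, pools deltas and marks small cells NA", {
  set.seed(5)
  n <- 120
  t <- seq(2, by = 2, length.out = n)
  ref <- pmax(85 + cumsum(rnorm(n, 0, 3)), 20)
  test <- pmax(ref + rnorm(n, 0, 5), 10)
  ph <- rep(c("pre-anhepatic", "anhepatic"), each = n / 2)
  p <- paired_series(t, ref, test, factor(ph, levels = levels(phase_at(0, phase_schedule()))))
  rep2 <- phase_report(p, eval_config(delta_interval_s = 20))
  expect_s3_class(rep2, "sv_eval_report")
  ov <- rep2[rep2$phase == "overall", ]
  expect_equal(ov$n, sum(rep2$n[rep2$phase != "overall"]))
  # pooled delta pairs never span the phase boundary: 2 phases lose one
  # boundary-crossing stretch each relative to the naive count
  expect_equal(ov$n_delta_used + ov$n_delta_excluded,
               sum(rep2$n_delta_used[rep2$phase != "overall"] +
                     rep2$n_delta_excluded[rep2$phase != "overall"]))

  # single-phase input: overall row equals the phase row
  p1 <- paired_series(t, ref, test,
                      factor(rep("reperfusion", n),
                             levels = levels(p$phase)))
  r1 <- phase_report(p1, eval_config(delta_interval_s = 20))
  expect_equal(r1[r1$phase == "reperfusion", -1],
               r1[r1$phase == "overall", -1], tolerance = 1e-12,
               ignore_attr = TRUE)

  # a 3-record phase cannot support a correlation -> NA cell
  ph3 <- c(rep("pre-anhepatic", n - 3), rep("reperfusion", 3))
  p3 <- paired_series(t, ref, test, factor(ph3, levels = levels(p$phase)))
  r3 <- phase_report(p3, eval_config(delta_interval_s = 20))
  expect_true(is.na(r3$r[r3$phase == "reperfusion"]))
  expect_false(is.na(r3$bias[r3$phase == "reperfusion"]))
})

test_that("a 0.027 correlation gap is decisive at the published cohort size", {
  # at n = 491,353, r(ref, A) = 0.840 vs r(ref, B) = 0.813 is significant
  # at p < 0.001 whatever the correlation between the two estimators
  for (rab in seq(0, 0.95, by = 0.05)) {
    st <- steiger_test(0.840, 0.813, rab, 491353L)
    expect_lt(st$p, 0.001)
  }
  # while the same gap at n = 100 is not
  expect_gt(steiger_test(0.840, 0.813, 0.5, 100L)$p, 0.05)
})
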