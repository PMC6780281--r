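# Synthetic hemodynamic generator: distributions, Windkessel physics,
# determinism, file round trips.

test_that("generate_cohort returns valid profiles and honours the seed", {
  one <- generate_cohort(1, seed = 5)
  expect_length(one, 1)
  p <- one[[1]]
  expect_s3_class(p, "sv_patient_profile")
  expect_gt(p$compliance, 0)
  expect_gt(p$resistance, 0)
  expect_true(p$hr_baseline >= 40 && p$hr_baseline <= 180)
  expect_true(p$resp_period >= 4 && p$resp_period <= 8)
  expect_true(p$svv_fraction >= 0 && p$svv_fraction <= 0.3)

  a <- generate_cohort(8, seed = 11)
  b <- generate_cohort(8, seed = 11)
  expect_identical(a, b)
  expect_error(generate_cohort(0), "positive")
})

test_that("cohort resistance follows the configured distribution", {
  cohort <- generate_cohort(100, seed = 3)
  res <- vapply(cohort, `[[`, numeric(1), "resistance")
  # oracle: Monte-Carlo mean of the configured truncated normal
  set.seed(99)
  draws <- rnorm(4e5, 858.8, 323.6)
  draws <- draws[draws >= 300 & draws <= 1800]
  expect_lt(abs(mean(res) - mean(draws)), 3 * 323.6 / sqrt(100))
  # affine coefficients must actually vary across patients
  expect_gt(sd(vapply(cohort, `[[`, numeric(1), "scale_w_true")), 0.01)
  expect_gt(sd(vapply(cohort, `[[`, numeric(1), "scale_b_true")), 0.5)
})

test_that("simulated cases are bit-identical under the same seed", {
  a <- quick_case(seed = 21)
  b <- quick_case(seed = 21)
  expect_identical(a$abp, b$abp)
  expect_identical(a$sv_ref, b$sv_ref)
  expect_identical(a$sv_competitor, b$sv_competitor)
  c2 <- quick_case(seed = 22)
  expect_false(identical(a$sv_ref, c2$sv_ref))
})

test_that("per-beat ejection volume is conserved within 0.1%", {
  case <- quick_case(duration_s = 60, seed = 3, keep_flow = TRUE)
  dt <- case$flow_dt
  for (j in seq(2, nrow(case$beats), by = 5)) {
    b <- case$beats[j, ]
    i0 <- round(b$t_onset / dt)
    n_ej <- floor(b$t_ej / dt)
    seg <- case$flow[(i0 + 1):(i0 + n_ej + 1)]
    vol <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt
    expect_lt(abs(vol - b$sv_wave) / b$sv_wave, 1e-3)
  }
})

test_that("pressure decays exponentially when ejection stops", {
  # zero inflow: dP/dt = -P/(RC) has the closed form P0 * exp(-t/(RC))
  n <- 4000
  R <- 0.7; C <- 1.6; p0 <- 95
  p <- svwave:::wk_rk4(numeric(2 * n + 1), rep(R, n), C, 1e-3, p0)
  t <- (0:n) * 1e-3
  expect_lt(max(abs(p - p0 * exp(-t / (R * C)))), 1e-9)
})

test_that("steady conditions give identical pulse pressure", {
  # constant targets, no modulation, no jitter, HR 80 (period = 75 samples
  # exactly at 100 Hz) -> periodic steady state after the initial transient
  pr <- patient_profile("P001", svv_fraction = 0, hr_baseline = 83.8)
  sc <- flat_schedule(120, hr = 80)
  case <- simulate_case(pr, sc, seed = 1, walk_frac = 0, hr_jitter_bpm = 0,
                        ref_noise_sd = 0)
  pp <- case$beats$pp
  late <- pp[(length(pp) - 40):(length(pp) - 1)]
  expect_lt(max(late) - min(late), 1e-6)
})

test_that("simulated pressure stays within physiological bounds", {
  for (seed in 1:3) {
    pr <- generate_cohort(1, seed = seed)[[1]]
    case <- simulate_case(pr, phase_schedule(600), seed = seed)
    s <- case$abp$segments[[1]]$samples
    expect_gt(min(s), 20)
    expect_lt(max(s), 300)
    # series time stamps lie within the waveform span
    span <- c(0, 600)
    for (ser in list(case$sv_true, case$sv_ref, case$sv_competitor)) {
      expect_true(all(ser$time_s >= span[1] & ser$time_s <= span[2]))
    }
  }
})

test_that("respiratory modulation shows up at 1/resp_period", {
  pr <- patient_profile("P001", svv_fraction = 0.08, resp_period = 5.5)
  sc <- flat_schedule(600)
  case <- simulate_case(pr, sc, seed = 9)
  # resample the beat series to a uniform grid and locate the spectral peak
  dt <- 0.25
  g <- seq(0, 600 - dt, by = dt)
  x <- approx(case$sv_true$time_s, case$sv_true$sv_ml, xout = g, rule = 2)$y
  sp <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_along(g) - 1) / (length(g) * dt)
  half <- freqs > 0 & freqs <= 1 / (2 * dt)
  # ignore the slow random-walk band; respiration lives near 0.18 Hz
  band <- half & freqs > 0.05
  peak <- freqs[band][which.max(sp[band])]
  expect_lt(abs(peak - 1 / 5.5), 1 / 600 + 1e-9)
})

test_that("long-run SV time average matches the configured target", {
  pr <- patient_profile("P001", sv_baseline = 84.8)
  sc <- flat_schedule(3600, sv = 88.5, spread = 23.5)
  case <- simulate_case(pr, sc, seed = 4)
  n <- nrow(case$beats)
  sigma <- 0.3 * 23.5
  phi <- exp(-mean(case$beats$period) / 45)
  # OU time-average SD: (sigma/sqrt(n)) * sqrt((1+phi)/(1-phi))
  bound <- 3 * sigma / sqrt(n) * sqrt((1 + phi) / (1 - phi))
  target <- 88.5 * 84.8 / 84.8
  expect_lt(abs(mean(case$beats$sv_true) - target), bound)
})

test_that("true SV is an affine distortion of the waveform SV", {
  pr <- patient_profile("P001", scale_w_true = 1.3, scale_b_true = -8)
  case <- simulate_case(pr, phase_schedule(60), seed = 2)
  expect_equal(case$beats$sv_true,
               1.3 * case$beats$sv_wave - 8, tolerance = 1e-12)
})

test_that("cases round-trip through the CSV/JSON format", {
  dir <- file.path(tempdir(), "svwave_roundtrip")
  unlink(dir, recursive = TRUE)
  case <- quick_case(duration_s = 60, seed = 13)
  write_case(case, dir)
  back <- read_case(dir, "P001")
  expect_equal(back$profile, case$profile, tolerance = 1e-9)
  sc <- case$schedule
  expect_equal(back$schedule$start_s, sc$start_s, tolerance = 1e-9)

  w0 <- make_windows(case$abp, case$sv_ref, case$schedule)
  w1 <- make_windows(back$abp, back$sv_ref, back$schedule)
  expect_identical(ncol(w0$x), ncol(w1$x))
  expect_equal(w0$meta$t0, w1$meta$t0, tolerance = 1e-9)
  expect_lt(max(abs(w0$x - w1$x)), 1e-6)       # 6-decimal fixed point
  expect_lt(max(abs(w0$meta$sv_ref - w1$meta$sv_ref)), 1e-6)
})

test_that("schedule validation rejects malformed phase sets", {
  expect_error(phase_schedule(fractions = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(phase_schedule(fractions = c(0.5, 0.2, 0.2, 0.2)), "sum")
  sc <- phase_schedule(100)
  sc2 <- sc[c(2, 1, 3, 4), ]
  expect_error(svwave:::validate_schedule(sc2), "canonical")
  expect_error(simulate_case(patient_profile("x"), phase_schedule(50),
                             duration_s = 100),
               "cover")
})
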