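# Network construction, calibration layer, prediction, post-processing.

test_that("model_config enforces the architectural invariants", {
  expect_error(model_config(n_blocks = 8, input_len = 1000), "2\\^n_blocks")
  expect_error(model_config(kernel_size = 4), "odd")
  expect_error(model_config(channels_per_block = c(4, 4)), "per block")
  cfg <- model_config()
  expect_identical(cfg$input_len / 2^cfg$n_blocks, 4)
})

test_that("block arithmetic: halving schedule and concat channel counts", {
  cfg <- model_config(channels_per_block = c(4, 4, 8, 8, 8, 8, 16, 16))
  d <- svwave:::model_dims(cfg)
  expect_identical(d$out_len, 4)
  # with concat skips: in_channels(k) = channels(k-1) + in_channels(k-1)
  expect_identical(d$in_channels, c(1L, 5L, 9L, 17L, 25L, 33L, 41L, 57L))
  expect_identical(d$flat_len, 4L * (16L + 57L))
  d2 <- svwave:::model_dims(model_config(skip_mode = "none"))
  expect_identical(d2$in_channels[2], 4L)
})

test_that("the forward pass returns one scalar per window", {
  cfg <- model_config(seed = 2)
  m <- build_model(cfg)
  w <- structure(list(x = matrix(rnorm(1024 * 7, 90, 15), 1024),
                      meta = data.frame(patient_id = "a", t0 = 1:7),
                      window_samples = 1024L, fs = 100, stride_s = 2),
                 class = "sv_windows")
  out <- predict_svcnn(m, w)
  expect_length(out, 7)
  expect_true(all(is.finite(out)))
  # pure function: repeated calls agree bit-exactly
  expect_identical(out, predict_svcnn(m, w))
  # wrong window length is refused
  w2 <- w; w2$x <- w$x[1:512, ]
  expect_error(predict_svcnn(m, w2), "input length")
})

test_that("apply_isc performs the per-patient affine map", {
  isc <- isc_table(c("a", "b"), w = c(1, 1.2), b = c(0, -5))
  expect_identical(apply_isc(80, "a", isc), 80)
  expect_identical(apply_isc(80, "b", isc), 80 * 1.2 - 5)
  expect_identical(apply_isc(80, "unknown", isc), 80)  # identity default
  expect_error(isc_table("a", w = -1, b = 0), "> 0")
})

test_that("calibrate_isc recovers exact and least-squares solutions", {
  pred <- c(70, 80, 90, 100)
  cal <- calibrate_isc(pred, 2 * pred + 5)
  expect_equal(cal$w, 2, tolerance = 1e-12)
  expect_equal(cal$b, 5, tolerance = 1e-12)
  # one-point rule
  cal1 <- calibrate_isc(80, 86)
  expect_identical(c(cal1$w, cal1$b), c(1, 6))
  # 50 noisy pairs against the normal equations
  set.seed(8)
  p <- rnorm(50, 85, 12)
  r <- 1.4 * p - 6 + rnorm(50, 0, 4)
  cal2 <- calibrate_isc(p, r)
  X <- cbind(1, p)
  beta <- solve(t(X) %*% X, t(X) %*% r)
  expect_lt(abs(cal2$b - beta[1]), 1e-9)
  expect_lt(abs(cal2$w - beta[2]), 1e-9)
  expect_error(calibrate_isc(numeric(0), numeric(0)), "at least one")
})

test_that("calibration gain is exactly scale-equivariant", {
  set.seed(9)
  p <- rnorm(30, 80, 10)
  r <- 1.1 * p + 3 + rnorm(30, 0, 2)
  for (cc in c(0.5, 2, 3.7)) {
    a <- calibrate_isc(p, r)
    b <- calibrate_isc(p, cc * r)
    expect_equal(b$w, cc * a$w, tolerance = 1e-12)
  }
})

test_that("postprocessing is identity by default and median-filters spikes", {
  s <- data.frame(time_s = seq(0, 40, by = 2), sv_ml = 85)
  expect_identical(postprocess_sv(s), s)
  expect_equal(postprocess_sv(s, "moving_median", 6)$sv_ml, s$sv_ml)
  sp <- s; sp$sv_ml[10] <- 140  # single-sample spike
  out <- postprocess_sv(sp, "moving_median", 6)
  expect_equal(out$sv_ml[10], 85)
  expect_equal(out$sv_ml[c(8, 12)], c(85, 85))
  expect_error(postprocess_sv(s, "lowess"), "arg")
  expect_error(postprocess_sv(s, "moving_median", 0.5), "cadence")
})

test_that("predict_sv honours ISC precedence and empty input", {
  cfg <- model_config(seed = 4)
  m <- build_model(cfg)
  m$out_center <- 80
  w <- structure(list(x = matrix(rnorm(1024 * 5, 90, 15), 1024),
                      meta = data.frame(patient_id = "u", t0 = 1:5),
                      window_samples = 1024L, fs = 100, stride_s = 2),
                 class = "sv_windows")
  raw <- predict_svcnn(m, w)
  p_ident <- predict_sv(m, w, isc_override = c(1, 0))
  expect_equal(p_ident$sv_ml, raw, tolerance = 1e-12)
  p_aff <- predict_sv(m, w, isc_override = c(1.5, -3))
  expect_equal(p_aff$sv_ml, raw * 1.5 - 3, tolerance = 1e-12)
  # unknown patient without override: identity ISC
  expect_equal(predict_sv(m, w)$sv_ml, raw, tolerance = 1e-12)
  w_empty <- subset_empty <- w
  w_empty$x <- w$x[, 0, drop = FALSE]; w_empty$meta <- w$meta[0, ]
  expect_identical(nrow(predict_sv(m, w_empty)), 0L)
})

test_that("training is deterministic and can overfit a small set", {
  pr <- generate_cohort(2, seed = 6)
  sc <- phase_schedule(130)
  wl <- lapply(pr, function(p) {
    case <- simulate_case(p, sc, seed = 17, ref_noise_sd = 0)
    make_windows(case$abp, case$sv_ref, sc)
  })
  w <- bind_windows(wl)
  w <- svwave:::subset_windows(w, seq_len(100))
  cfg <- model_config(seed = 5, max_epochs = 120, batch_size = 10,
                      learning_rate = 3e-3, fc_hidden = 128, val_frac = 0)
  m1 <- train_svnet(w, cfg = cfg, quiet = TRUE)
  expect_lt(m1$train_rms, 1)
  m2 <- train_svnet(w, cfg = cfg, quiet = TRUE)
  expect_identical(m1$val_rms, m2$val_rms)
  expect_identical(m1$params, m2$params)
  # trained ISC gains respect the clamp
  expect_true(all(m1$isc$w >= 0.2 & m1$isc$w <= 5))
  expect_error(train_svnet(svwave:::subset_windows(w, integer(0)), cfg = cfg),
               "empty")
})

test_that("single-patient training warns and freezes the ISC", {
  case <- simulate_case(patient_profile("P1"), phase_schedule(80), seed = 3)
  w <- make_windows(case$abp, case$sv_ref, case$schedule)
  cfg <- model_config(seed = 1, max_epochs = 1, batch_size = 16,
                      val_frac = 0)
  expect_warning(m <- train_svnet(w, cfg = cfg, quiet = TRUE),
                 "unidentifiable")
  expect_identical(unname(m$isc$w), 1)
  expect_identical(unname(m$isc$b), 0)
})

test_that("checkpoints round-trip and detect corruption", {
  m <- build_model(model_config(seed = 11))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  payload <- readRDS(f)
  payload$isc <- isc_table("x", 2, 1)
  saveRDS(payload, f)
  expect_error(load_model(f), "hash")
})
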