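# Waveform loading, resampling, windowing arithmetic, cohort splitting.

write_wave_csv <- function(t, p, path = tempfile(fileext = ".csv")) {
  data.table::fwrite(data.frame(time_s = t, abp_mmhg = p), path)
  path
}

test_that("load_waveform passes a 100 Hz file through unchanged", {
  t <- (0:2999) / 100
  p <- 90 + 20 * sin(2 * pi * 1.3 * t)
  w <- load_waveform(write_wave_csv(t, p))
  expect_s3_class(w, "sv_waveform")
  expect_length(w$segments, 1)
  expect_length(w$segments[[1]]$samples, 3000)
  expect_equal(w$fs, 100)
  expect_equal(w$segments[[1]]$samples, p, tolerance = 1e-12)
})

test_that("load_waveform resamples other rates by linear interpolation", {
  t <- (0:2499) / 500  # 5 s at 500 Hz
  p <- 80 + 25 * sin(2 * pi * 1 * t)
  w <- load_waveform(write_wave_csv(t, p), expected_fs = 100)
  s <- w$segments[[1]]
  expect_length(s$samples, 500)
  t_out <- s$t_start + (seq_along(s$samples) - 1) / 100
  expect_lt(max(abs(s$samples - (80 + 25 * sin(2 * pi * t_out)))), 1e-3)
})

test_that("load_waveform reports malformed files with the offending row", {
  t <- (0:99) / 100
  p <- rep(80, 100)
  t2 <- t; t2[51] <- t2[49]  # non-monotone at row 51
  expect_error(load_waveform(write_wave_csv(t2, p)), "row 51")
  f <- tempfile(fileext = ".csv")
  writeLines("time_s,abp_mmhg", f)
  expect_error(load_waveform(f), "empty")
  p3 <- p; p3[1:10] <- NA  # 10% missing
  expect_error(load_waveform(write_wave_csv(t, p3)), "missing")
})

test_that("long gaps split the record and short gaps are interpolated", {
  t <- c((0:1499) / 100, (0:1499) / 100 + 16)  # 1-s hole at t = 15
  p <- 90 + 10 * sin(2 * pi * t)
  w <- load_waveform(write_wave_csv(t, p))
  expect_length(w$segments, 2)
  # windows never mix samples across the gap
  ref <- data.frame(time_s = seq(0, 31, by = 2), sv_ml = 80)
  win <- make_windows(w, ref)
  expect_true(all(win$meta$t0 <= 15 | win$meta$t0 >= 16 + 10.23))
  # a 0.2-s missing run inside one segment is interpolated, not split
  p2 <- p; p2[300:319] <- NA
  w2 <- load_waveform(write_wave_csv(t, p2))
  expect_length(w2$segments, 2)
  expect_false(anyNA(w2$segments[[1]]$samples))
})

test_that("window count formula matches brute-force enumeration", {
  set.seed(42)
  for (i in 1:100) {
    T <- runif(1, 5, 400)
    stride <- sample(c(0.5, 1, 2, 4, 5), 1)
    # oracle: slide the end point explicitly
    n_bf <- 0L; t0 <- 10.24
    while (t0 <= T + 1e-9) { n_bf <- n_bf + 1L; t0 <- t0 + stride }
    expect_identical(window_count(T, stride), as.numeric(n_bf))
  }
})

test_that("make_windows yields the enumerated windows and pairs references", {
  fs <- 100
  mk <- function(T) waveform_record("P1", fs, t_start = 0,
                                    samples = rnorm(round(T * fs), 90, 8))
  dense <- data.frame(time_s = seq(0, 500, by = 2), sv_ml = 85)
  w1 <- make_windows(mk(10.24), dense)
  expect_identical(ncol(w1$x), 1L)
  w3 <- make_windows(mk(14.24), dense)
  expect_identical(ncol(w3$x), 3L)
  expect_equal(diff(w3$meta$t0), c(2, 2), tolerance = 1e-9)
  expect_identical(nrow(w3$x), 1024L)
  # shorter than one window: empty, not an error
  w0 <- make_windows(mk(8), dense)
  expect_identical(ncol(w0$x), 0L)
  # no reference in tolerance: dropped with a count
  far <- data.frame(time_s = 1000, sv_ml = 85)
  suppressMessages(wd <- make_windows(mk(20), far))
  expect_identical(ncol(wd$x), 0L)
  expect_gt(wd$n_dropped, 0)
})

test_that("windows contain the right samples with t0 as last-sample time", {
  fs <- 100
  samples <- seq_len(2000)  # sample value == sample index
  wave <- waveform_record("P1", fs, t_start = 0, samples = samples)
  ref <- data.frame(time_s = seq(0, 20, by = 2), sv_ml = 85)
  w <- make_windows(wave, ref)
  expect_equal(w$x[, 1], 1:1024)
  expect_equal(w$x[, 2], 201:1224)  # 2-s stride = 200 samples
  expect_equal(w$meta$t0[1], 1023 / fs)
})

test_that("split_cohort is deterministic, disjoint and covering", {
  ids <- sprintf("P%03d", 1:10)
  sp <- split_cohort(ids, c(0.8, 0, 0.2), seed = 7)
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 0)
  expect_length(sp$test_ids, 2)
  expect_identical(sp, split_cohort(ids, c(0.8, 0, 0.2), seed = 7))
  expect_false(identical(sp$train_ids,
                         split_cohort(ids, c(0.8, 0, 0.2), seed = 8)$train_ids))
  expect_identical(sort(c(sp$train_ids, sp$test_ids)), sort(ids))
  expect_error(split_cohort("P1", c(0.5, 0.25, 0.25)), "fewer ids")
  expect_error(split_cohort(ids, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("a 65-patient cohort splits 34/31 at the study fractions", {
  ids <- sprintf("P%03d", 1:65)
  sp <- split_cohort(ids, c(0.52, 0, 0.48), seed = 1)
  expect_length(sp$train_ids, 34)
  expect_length(sp$test_ids, 31)
})

test_that("window datasets round-trip through the container directory", {
  case <- quick_case(duration_s = 60, seed = 2)
  w <- make_windows(case$abp, case$sv_ref, case$schedule)
  dir <- file.path(tempdir(), "svwave_ds")
  unlink(dir, recursive = TRUE)
  write_window_dataset(list(P001 = w), dir, extra = list(config_hash = "x"))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "dropped_windows.log")))
  back <- read_window_dataset(dir)
  expect_identical(back$P001$x, w$x)
  expect_identical(back$P001$meta$sv_ref, w$meta$sv_ref)
})
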