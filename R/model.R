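# Network definition, per-patient calibration (ISC), prediction.

#' Model and training configuration
#'
#' The network is `n_blocks` blocks of convolution (odd `kernel_size`, same
#' padding, ReLU) followed by a factor-2 max pool; with
#' `skip_mode = "concat"` each block's input is the channel concatenation of
#' the previous block's pooled output and the previous block's input passed
#' through the same factor-2 max pool, so the stated halving of the spatial
#' length per block is preserved. After `n_blocks` blocks an `input_len` of
#' 1024 is reduced to `input_len / 2^n_blocks` (= 4) and a two-layer fully
#' connected head maps the flattened activations to one scalar per window.
#'
#' Defaults are sized so that a desk-scale cohort (a dozen two-hour cases)
#' trains in minutes on one CPU core; widen `channels_per_block` and
#' `fc_hidden` for larger experiments.
#'
#' @param n_blocks number of conv+pool blocks (default 8).
#' @param input_len window length in samples; `input_len / 2^n_blocks` must
#'   be a positive integer.
#' @param kernel_size odd convolution kernel length (default 5).
#' @param channels_per_block integer vector, one output-channel count per
#'   block.
#' @param skip_mode `"concat"` (default) or `"none"`.
#' @param fc_hidden hidden units of the fully connected head.
#' @param learning_rate Adam learning rate for the shared weights.
#' @param isc_lr_mult learning-rate multiplier for the per-patient
#'   calibration parameters (two scalars per patient vs. thousands of shared
#'   weights).
#' @param batch_size minibatch size.
#' @param max_epochs training epochs (best-validation epoch is kept).
#' @param val_frac patient-level fraction of the training group held out for
#'   validation when no explicit validation set is given.
#' @param seed master seed for initialization, shuffling and splits.
#' @param norm_center,norm_scale fixed input standardization
#'   `(x - norm_center)/norm_scale` in mmHg (80/40 covers typical arterial
#'   pressures).
#' @return list of class `sv_model_config`.
#' @export
model_config <- function(n_blocks = 8, input_len = 1024, kernel_size = 5,
                         channels_per_block = c(4, 4, 8, 8, 8, 8, 16, 16),
                         skip_mode = c("concat", "none"), fc_hidden = 64,
                         learning_rate = 1e-3, isc_lr_mult = 10,
                         batch_size = 256, max_epochs = 8, val_frac = 0.2,
                         seed = 1L, norm_center = 80, norm_scale = 40) {
  skip_mode <- match.arg(skip_mode)
  assert_that(is_count(n_blocks) && n_blocks >= 1, "n_blocks must be >= 1")
  assert_that(is_count(input_len) && input_len >= 2,
              "input_len must be a positive integer")
  reduced <- input_len / 2^n_blocks
  assert_that(reduced == round(reduced) && reduced >= 1,
              "input_len / 2^n_blocks must be a positive integer (got %g)",
              reduced)
  assert_that(is_count(kernel_size) && kernel_size %% 2 == 1,
              "kernel_size must be odd")
  assert_that(length(channels_per_block) == n_blocks &&
                all(channels_per_block >= 1) &&
                all(channels_per_block == round(channels_per_block)),
              "channels_per_block must give one positive count per block")
  assert_that(is_count(fc_hidden) && fc_hidden >= 1, "fc_hidden must be >= 1")
  assert_that(is_number(learning_rate) && learning_rate > 0,
              "learning_rate must be > 0")
  assert_that(is_number(isc_lr_mult) && isc_lr_mult > 0,
              "isc_lr_mult must be > 0")
  assert_that(is_count(batch_size) && batch_size >= 1,
              "batch_size must be >= 1")
  assert_that(is_count(max_epochs) && max_epochs >= 1,
              "max_epochs must be >= 1")
  assert_that(is_number(val_frac) && val_frac >= 0 && val_frac < 1,
              "val_frac must be in [0, 1)")
  assert_that(is_count(seed), "seed must be an integer")
  assert_that(is_number(norm_scale) && norm_scale > 0,
              "norm_scale must be > 0")
  structure(list(n_blocks = as.integer(n_blocks),
                 input_len = as.integer(input_len),
                 kernel_size = as.integer(kernel_size),
                 channels_per_block = as.integer(channels_per_block),
                 skip_mode = skip_mode, fc_hidden = as.integer(fc_hidden),
                 learning_rate = learning_rate, isc_lr_mult = isc_lr_mult,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), val_frac = val_frac,
                 seed = as.integer(seed), norm_center = norm_center,
                 norm_scale = norm_scale),
            class = "sv_model_config")
}

#' Per-block channel and length arithmetic for a configuration
#' @param cfg an [model_config()].
#' @return list with `in_channels`, `out_len` (spatial length before the
#'   head) and `flat_len` (flattened feature length).
#' @keywords internal
model_dims <- function(cfg) {
  cin <- integer(cfg$n_blocks)
  cin[1] <- 1L
  if (cfg$n_blocks > 1) {
    for (k in 2:cfg$n_blocks) {
      cin[k] <- cfg$channels_per_block[k - 1] +
        if (cfg$skip_mode == "concat") cin[k - 1] else 0L
    }
  }
  out_len <- cfg$input_len / 2^cfg$n_blocks
  c_final <- cfg$channels_per_block[cfg$n_blocks] +
    if (cfg$skip_mode == "concat") cin[cfg$n_blocks] else 0L
  list(in_channels = cin, out_len = out_len,
       flat_len = as.integer(out_len * c_final))
}

#' Build an untrained model
#'
#' Initializes all weights (He-scaled Gaussian, seeded from `cfg$seed`) and
#' an empty calibration table.
#'
#' @param cfg an [model_config()].
#' @return list of class `sv_model` with elements `params`, `cfg`, `isc`
#'   ([isc_table()]), `out_center`, `epoch`, `train_rms`, `val_rms`,
#'   `history`.
#' @export
build_model <- function(cfg) {
  assert_that(inherits(cfg, "sv_model_config"),
              "cfg must be a model_config()")
  dims <- model_dims(cfg)
  with_seed(derive_seed(cfg$seed, "init"), {
    conv_w <- vector("list", cfg$n_blocks)
    conv_b <- vector("list", cfg$n_blocks)
    for (k in seq_len(cfg$n_blocks)) {
      fan_in <- dims$in_channels[k] * cfg$kernel_size
      conv_w[[k]] <- matrix(rnorm(cfg$channels_per_block[k] * fan_in,
                                  sd = sqrt(2 / fan_in)),
                            nrow = cfg$channels_per_block[k])
      conv_b[[k]] <- numeric(cfg$channels_per_block[k])
    }
    fc1_w <- matrix(rnorm(cfg$fc_hidden * dims$flat_len,
                          sd = sqrt(2 / dims$flat_len)),
                    nrow = cfg$fc_hidden)
    fc2_w <- matrix(rnorm(cfg$fc_hidden, sd = sqrt(1 / cfg$fc_hidden)),
                    nrow = 1)
    params <- list(conv_w = conv_w, conv_b = conv_b, fc1_w = fc1_w,
                   fc1_b = numeric(cfg$fc_hidden), fc2_w = fc2_w,
                   fc2_b = numeric(1))
    structure(list(params = params, cfg = cfg, isc = isc_table(),
                   out_center = 0, epoch = 0L, train_rms = NA_real_,
                   val_rms = NA_real_, history = data.frame(),
                   rng_seed = cfg$seed),
              class = "sv_model")
  })
}

#' @export
print.sv_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf("<sv_model: %d blocks, %d parameters, %d calibrated patient(s), epoch %d, val RMS %.3f mL>\n",
              x$cfg$n_blocks, np, nrow(x$isc), x$epoch, x$val_rms))
  invisible(x)
}

#' Individual scale coefficient (ISC) table
#'
#' Per-patient affine calibration `sv = sv_cnn * w + b`; patients absent
#' from the table use the identity `(w, b) = (1, 0)`.
#'
#' @param patient_id character ids.
#' @param w gains (> 0).
#' @param b offsets, mL.
#' @return data.frame of class `sv_isc_table`.
#' @export
isc_table <- function(patient_id = character(0), w = numeric(0),
                      b = numeric(0)) {
  assert_that(length(patient_id) == length(w) &&
                length(w) == length(b), "patient_id, w, b lengths differ")
  assert_that(all(w > 0), "all ISC gains must be > 0")
  structure(data.frame(patient_id = as.character(patient_id), w = w, b = b,
                       stringsAsFactors = FALSE),
            class = c("sv_isc_table", "data.frame"))
}

# (w, b) rows for each requested id; identity for unknown ids
isc_lookup <- function(isc, ids) {
  m <- match(ids, isc$patient_id)
  cbind(w = ifelse(is.na(m), 1, isc$w[m]),
        b = ifelse(is.na(m), 0, isc$b[m]))
}

#' Apply the per-patient affine calibration
#'
#' @param sv_cnn raw network SV predictions, mL.
#' @param patient_id patient id (recycled); unknown ids get `(1, 0)`.
#' @param isc an [isc_table()].
#' @return calibrated SV, mL.
#' @export
apply_isc <- function(sv_cnn, patient_id, isc) {
  assert_that(is.numeric(sv_cnn) && all(is.finite(sv_cnn)),
              "sv_cnn must be finite numeric")
  assert_that(inherits(isc, "sv_isc_table"), "isc must be an isc_table()")
  wb <- isc_lookup(isc, rep_len(as.character(patient_id), length(sv_cnn)))
  unname(sv_cnn * wb[, "w"] + wb[, "b"])
}

#' Fit the calibration pair (w, b) for one unseen patient
#'
#' With two or more (prediction, reference) pairs, ordinary least squares of
#' the reference on the prediction; with exactly one pair, `w = 1` and
#' `b = reference - prediction`. The gain is clamped to `[0.2, 5]`.
#'
#' @param pred raw network SV predictions, mL.
#' @param ref matching reference SV values, mL.
#' @return list with `w`, `b`, `n`.
#' @export
calibrate_isc <- function(pred, ref) {
  assert_that(is.numeric(pred) && is.numeric(ref) &&
                length(pred) == length(ref), "pred/ref lengths differ")
  assert_that(length(pred) >= 1, "at least one calibration pair required")
  assert_that(all(is.finite(pred)) && all(is.finite(ref)),
              "calibration pairs must be finite")
  if (length(pred) == 1L) {
    return(list(w = 1, b = ref - pred, n = 1L))
  }
  vx <- sum((pred - mean(pred))^2)
  if (vx < 1e-12) {  # degenerate: constant predictions, fall back to offset
    return(list(w = 1, b = mean(ref) - mean(pred), n = length(pred)))
  }
  w <- sum((pred - mean(pred)) * (ref - mean(ref))) / vx
  w <- min(max(w, 0.2), 5)
  b <- mean(ref) - w * mean(pred)
  list(w = w, b = b, n = length(pred))
}

#' Raw (uncalibrated) network predictions for a window set
#' @param model an `sv_model`.
#' @param windows an `sv_windows`.
#' @param chunk forward-pass batch size.
#' @return numeric vector of SV_CNN, mL (one per window).
#' @export
predict_svcnn <- function(model, windows, chunk = 512L) {
  assert_that(inherits(model, "sv_model"), "model must be an sv_model")
  assert_that(inherits(windows, "sv_windows"),
              "windows must be an sv_windows")
  cfg <- model$cfg
  assert_that(nrow(windows$x) == cfg$input_len,
              "window length %d does not match the model input length %d",
              nrow(windows$x), cfg$input_len)
  n <- ncol(windows$x)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    xb <- (windows$x[, s:e, drop = FALSE] - cfg$norm_center) / cfg$norm_scale
    out[s:e] <- cnn_forward(xb, model$params, cfg$kernel_size,
                            cfg$skip_mode == "concat")
  }
  out + model$out_center
}

#' Calibrated SV predictions for a window set
#'
#' One prediction per window at its `t0`. The calibration applied is, in
#' order of precedence: `isc_override` if given; the patient's entry in the
#' trained ISC table; the identity `(1, 0)` for unseen patients.
#'
#' @param model a trained `sv_model`.
#' @param windows an `sv_windows`.
#' @param isc_override optional `c(w, b)` applied to every window.
#' @param postprocess `"none"` (default) or `"moving_median"`.
#' @param postprocess_width_s width of the post-processing window, s.
#' @return data.frame `patient_id`, `time_s`, `sv_ml`.
#' @export
predict_sv <- function(model, windows, isc_override = NULL,
                       postprocess = "none", postprocess_width_s = 6) {
  raw <- predict_svcnn(model, windows)
  if (length(raw) == 0) {
    return(data.frame(patient_id = character(0), time_s = numeric(0),
                      sv_ml = numeric(0)))
  }
  sv <- if (!is.null(isc_override)) {
    assert_that(is.numeric(isc_override) && length(isc_override) == 2L,
                "isc_override must be c(w, b)")
    raw * isc_override[1] + isc_override[2]
  } else {
    apply_isc(raw, windows$meta$patient_id, model$isc)
  }
  out <- data.frame(patient_id = windows$meta$patient_id,
                    time_s = windows$meta$t0, sv_ml = sv,
                    stringsAsFactors = FALSE)
  if (!identical(postprocess, "none")) {
    parts <- split(seq_len(nrow(out)), out$patient_id)
    for (ix in parts) {
      out$sv_ml[ix] <- postprocess_sv(out[ix, c("time_s", "sv_ml")],
                                      method = postprocess,
                                      width_s = postprocess_width_s)$sv_ml
    }
  }
  out
}

#' Post-process a predicted SV series
#'
#' `method = "none"` returns the input unchanged; `"moving_median"` replaces
#' each value by the median of all values within a centered window of
#' `width_s` seconds.
#'
#' @param series data.frame with `time_s` and `sv_ml`.
#' @param method `"none"` or `"moving_median"`.
#' @param width_s window width, s (must be at least the series cadence).
#' @return data.frame like `series`.
#' @export
postprocess_sv <- function(series, method = c("none", "moving_median"),
                           width_s = 6) {
  method <- match.arg(method)
  assert_that(is.data.frame(series) &&
                all(c("time_s", "sv_ml") %in% names(series)),
              "series must have time_s and sv_ml")
  if (method == "none" || nrow(series) < 2) return(series)
  cadence <- stats::median(diff(series$time_s))
  assert_that(is_number(width_s) && width_s >= cadence,
              "width_s (%g) must be at least the series cadence (%g)",
              width_s, cadence)
  t <- series$time_s
  v <- series$sv_ml
  half <- width_s / 2
  lo <- findInterval(t - half, t) + 1L
  hi <- findInterval(t + half, t)
  out <- vapply(seq_along(t),
                function(i) stats::median(v[lo[i]:hi[i]]), numeric(1))
  series$sv_ml <- out
  series
}

#' Save a trained model checkpoint
#'
#' Stores parameters, configuration, ISC table and a manifest hash; loading
#' verifies the hash and [predict_sv()] refuses windows whose length does
#' not match the stored configuration.
#' @param model an `sv_model`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "sv_model"), "model must be an sv_model")
  payload <- unclass(model)
  payload$manifest_hash <- object_hash(list(payload$params, payload$cfg,
                                            payload$isc))
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path checkpoint file.
#' @return an `sv_model`.
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), "checkpoint not found: %s", path)
  payload <- readRDS(path)
  h <- payload$manifest_hash
  payload$manifest_hash <- NULL
  assert_that(identical(h, object_hash(list(payload$params, payload$cfg,
                                            payload$isc))),
              "checkpoint %s is corrupt (manifest hash mismatch)", path)
  class(payload) <- "sv_model"
  payload
}
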