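# Joint training of the network and the per-patient calibration.

# one Adam update over an arbitrarily nested list of numeric arrays
adam_update <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_update(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, beta1, beta2,
                       eps)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# RMS of (prediction - reference) after per-patient OLS calibration;
# used for validation so that scale is not conflated with waveform skill
calibrated_rms <- function(raw, meta) {
  resid <- unlist(lapply(split(seq_along(raw), meta$patient_id),
                         function(ix) {
    cal <- calibrate_isc(raw[ix], meta$sv_ref[ix])
    raw[ix] * cal$w + cal$b - meta$sv_ref[ix]
  }), use.names = FALSE)
  sqrt(mean(resid^2))
}

#' Train the network and the per-patient calibration jointly
#'
#' Minimizes the RMS error between the calibrated prediction
#' `SV_scaled = SV_CNN * w_i + b_i` and the reference SV jointly over the
#' shared network weights and the per-training-patient `(w_i, b_i)` (all
#' initialized to the identity), with Adam; the calibration parameters use
#' a `isc_lr_mult`-times larger learning rate and the gain is kept in
#' `[0.2, 5]`. Validation RMS is recorded every epoch (computed after
#' per-patient OLS calibration of the validation predictions, since
#' validation patients do not own trained coefficients) and the
#' best-validation-epoch parameters are returned.
#'
#' @param windows training `sv_windows` (must cover at least two patients
#'   for the calibration to be identifiable; with one patient the ISC is
#'   frozen at the identity with a warning).
#' @param val_windows validation `sv_windows`, or NULL to split
#'   `cfg$val_frac` of the training patients out (patient level, seeded).
#' @param cfg an [model_config()].
#' @param quiet suppress per-epoch logging.
#' @return a trained `sv_model` (best validation epoch), with `history`
#'   holding per-epoch train/validation RMS.
#' @export
train_svnet <- function(windows, val_windows = NULL, cfg = model_config(),
                        quiet = FALSE) {
  assert_that(inherits(windows, "sv_windows"),
              "windows must be an sv_windows")
  assert_that(ncol(windows$x) > 0, "empty training set")
  assert_that(inherits(cfg, "sv_model_config"), "cfg must be a model_config()")
  assert_that(nrow(windows$x) == cfg$input_len,
              "window length %d does not match cfg$input_len %d",
              nrow(windows$x), cfg$input_len)

  if (is.null(val_windows) && cfg$val_frac > 0) {
    ids <- unique(windows$meta$patient_id)
    if (length(ids) >= 2) {
      sp <- split_cohort(ids, c(1 - cfg$val_frac, cfg$val_frac, 0),
                         seed = derive_seed(cfg$seed, "valsplit"))
      val_windows <- subset_windows(windows, patients = sp$val_ids)
      windows <- subset_windows(windows, patients = sp$train_ids)
    }
  }

  patients <- unique(windows$meta$patient_id)
  freeze_isc <- length(patients) < 2
  if (freeze_isc) {
    warning("training windows cover a single patient; ",
            "ISC is unidentifiable and stays frozen at (1, 0)")
  }

  model <- build_model(cfg)
  model$out_center <- mean(windows$meta$sv_ref)
  pidx <- match(windows$meta$patient_id, patients) - 1L  # 0-based for C++
  isc_w <- rep(1, length(patients))
  isc_b <- rep(0, length(patients))

  opt <- list(m = zeros_like(model$params), v = zeros_like(model$params))
  opt_isc <- list(mw = isc_w * 0, vw = isc_w * 0, mb = isc_b * 0,
                  vb = isc_b * 0)
  n <- ncol(windows$x)
  skip <- cfg$skip_mode == "concat"
  best <- list(val = Inf, params = model$params, isc_w = isc_w,
               isc_b = isc_b, epoch = 0L)
  history <- vector("list", cfg$max_epochs)
  step <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)),
                     sample.int(n))
    sse <- 0
    b_start <- seq(1L, n, by = cfg$batch_size)
    for (s in b_start) {
      e <- min(s + cfg$batch_size - 1L, n)
      ix <- ord[s:e]
      xb <- (windows$x[, ix, drop = FALSE] - cfg$norm_center) /
        cfg$norm_scale
      res <- tryCatch(
        cnn_train_batch(xb, model$params, cfg$kernel_size,
                        windows$meta$sv_ref[ix], pidx[ix], isc_w, isc_b,
                        model$out_center, skip),
        error = function(err) {
          stop(sprintf("training diverged at epoch %d: %s", epoch,
                       conditionMessage(err)), call. = FALSE)
        })
      step <- step + 1L
      sse <- sse + res$loss^2 * length(ix)
      upd <- adam_update(model$params, res$grads, opt$m, opt$v,
                         cfg$learning_rate, step)
      model$params <- upd$p; opt$m <- upd$m; opt$v <- upd$v
      if (!freeze_isc) {
        lr2 <- cfg$learning_rate * cfg$isc_lr_mult
        uw <- adam_update(isc_w, res$g_isc_w, opt_isc$mw, opt_isc$vw, lr2,
                          step)
        ub <- adam_update(isc_b, res$g_isc_b, opt_isc$mb, opt_isc$vb, lr2,
                          step)
        isc_w <- pmin(pmax(uw$p, 0.2), 5)
        isc_b <- ub$p
        opt_isc <- list(mw = uw$m, vw = uw$v, mb = ub$m, vb = ub$v)
      }
    }
    train_rms <- sqrt(sse / n)
    val_rms <- if (!is.null(val_windows) && ncol(val_windows$x) > 0) {
      m_tmp <- model
      calibrated_rms(predict_svcnn(m_tmp, val_windows), val_windows$meta)
    } else {
      train_rms
    }
    history[[epoch]] <- data.frame(epoch = epoch, train_rms = train_rms,
                                   val_rms = val_rms)
    if (!quiet) {
      log_msg("INFO", "epoch %d/%d: train RMS %.3f mL, val RMS %.3f mL",
              epoch, cfg$max_epochs, train_rms, val_rms)
    }
    if (val_rms < best$val) {
      best <- list(val = val_rms, params = model$params, isc_w = isc_w,
                   isc_b = isc_b, epoch = epoch, train = train_rms)
    }
  }

  model$params <- best$params
  model$isc <- isc_table(patients, best$isc_w, best$isc_b)
  model$epoch <- best$epoch
  model$train_rms <- best$train
  model$val_rms <- best$val
  model$history <- do.call(rbind, history)
  model
}
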