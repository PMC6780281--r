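# Synthetic hemodynamic cohort generator.
#
# Each case is built beat by beat: true stroke volume follows a bounded
# Ornstein-Uhlenbeck walk around phase-specific targets, modulated by a
# ventilation-coupled sinusoid; the arterial pressure waveform is rendered
# by driving a two-element Windkessel with a half-sine ejection flow whose
# per-beat volume is the *waveform* SV, an affine distortion
# (sv_true - b_i)/w_i of the true SV, so that the waveform alone
# under-determines true SV without per-patient calibration.

PHASE_NAMES <- c("pre-anhepatic", "anhepatic", "reperfusion", "post-reperfusion")

# cohort-level hemodynamic targets (liver-transplant phase means/SDs)
PHASE_DEFAULTS <- list(
  frac        = c(0.430, 0.127, 0.018, 0.425),
  sv_mean     = c(88.5, 75.3, 85.7, 83.8),
  sv_spread   = c(23.5, 24.0, 25.2, 25.1),
  hr_mean     = c(82.8, 88.2, 86.5, 83.4),
  svr_mean    = c(850.0, 910.3, 749.9, 856.9),
  instability = c(0.05, 0.08, 0.30, 0.07)
)
COHORT_SV_MEAN <- 84.8
COHORT_HR_MEAN <- 83.8
COHORT_SVR_MEAN <- 858.8
COHORT_SVR_SD <- 323.6
MMHG_S_PER_ML <- 1333.22  # dyne*s/cm^5 per mmHg*s/mL

#' Surgical phase schedule
#'
#' Ordered, contiguous intervals for the four liver-transplant phases
#' (pre-anhepatic, anhepatic, reperfusion, post-reperfusion) together with
#' the per-phase hemodynamic targets used by the simulator: mean stroke
#' volume (mL), SV spread (mL), mean heart rate (bpm), mean systemic
#' vascular resistance (dyne·s/cm^5), and a dimensionless instability
#' factor scaling within-phase SVR swings.
#'
#' Defaults reproduce the phase duration shares and phase-wise SV/HR/SVR
#' summary statistics of an intraoperative liver-transplant cohort;
#' reperfusion is brief (~2% of the case) and the most unstable.
#'
#' @param duration_s total case duration in seconds (default 7200).
#' @param fractions length-4 duration fractions, summing to 1.
#' @param sv_mean,sv_spread,hr_mean,svr_mean,instability length-4 numeric
#'   per-phase parameters in canonical phase order.
#' @return a `data.frame` of class `sv_phase_schedule` with one row per
#'   phase: `phase`, `start_s`, `end_s` and the target columns.
#' @export
phase_schedule <- function(duration_s = 7200,
                           fractions = PHASE_DEFAULTS$frac,
                           sv_mean = PHASE_DEFAULTS$sv_mean,
                           sv_spread = PHASE_DEFAULTS$sv_spread,
                           hr_mean = PHASE_DEFAULTS$hr_mean,
                           svr_mean = PHASE_DEFAULTS$svr_mean,
                           instability = PHASE_DEFAULTS$instability) {
  assert_that(is_number(duration_s) && duration_s > 0,
              "duration_s must be a positive number")
  for (v in list(fractions, sv_mean, sv_spread, hr_mean, svr_mean,
                 instability)) {
    assert_that(is.numeric(v) && length(v) == 4L && all(is.finite(v)),
                "phase parameters must be length-4 finite numerics")
  }
  assert_that(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  assert_that(all(fractions > 0), "all four phases must have positive duration")
  edges <- c(0, cumsum(fractions)) * duration_s
  edges[5] <- duration_s
  sched <- data.frame(
    phase = factor(PHASE_NAMES, levels = PHASE_NAMES),
    start_s = edges[1:4], end_s = edges[2:5],
    sv_mean = sv_mean, sv_spread = sv_spread, hr_mean = hr_mean,
    svr_mean = svr_mean, instability = instability,
    stringsAsFactors = FALSE
  )
  class(sched) <- c("sv_phase_schedule", "data.frame")
  validate_schedule(sched)
  sched
}

#' @keywords internal
validate_schedule <- function(schedule) {
  assert_that(is.data.frame(schedule) &&
                all(c("phase", "start_s", "end_s") %in% names(schedule)),
              "schedule must have phase/start_s/end_s columns")
  assert_that(nrow(schedule) == 4L &&
                identical(as.character(schedule$phase), PHASE_NAMES),
              "schedule must contain the four canonical phases in order")
  assert_that(all(schedule$end_s > schedule$start_s),
              "phase intervals must be strictly increasing")
  assert_that(all(abs(schedule$start_s[-1] - schedule$end_s[-4]) < 1e-9),
              "phase intervals must be contiguous and non-overlapping")
  invisible(schedule)
}

#' Phase label at given times
#' @param t_s numeric times (s).
#' @param schedule an `sv_phase_schedule`.
#' @return factor of phase names (levels in canonical order).
#' @export
phase_at <- function(t_s, schedule) {
  validate_schedule(schedule)
  idx <- findInterval(t_s, c(schedule$start_s, schedule$end_s[4]),
                      rightmost.closed = TRUE, all.inside = TRUE)
  factor(PHASE_NAMES[idx], levels = PHASE_NAMES)
}

#' Patient hemodynamic profile
#'
#' @param patient_id character id.
#' @param compliance arterial compliance, mL/mmHg (> 0).
#' @param resistance baseline systemic vascular resistance, dyne·s/cm^5 (> 0).
#' @param hr_baseline baseline heart rate, bpm, in \[40, 180\].
#' @param sv_baseline baseline stroke volume, mL (> 0).
#' @param scale_w_true,scale_b_true the patient's true affine map from
#'   waveform-implied SV to true SV: `sv_true = w * sv_wave + b`.
#' @param resp_period ventilator period, s, in \[4, 8\].
#' @param svv_fraction respiratory SV modulation amplitude, in \[0, 0.3\].
#' @return list of class `sv_patient_profile`.
#' @export
patient_profile <- function(patient_id, compliance = 1.8, resistance = 858.8,
                            hr_baseline = 83.8, sv_baseline = 84.8,
                            scale_w_true = 1, scale_b_true = 0,
                            resp_period = 5.5, svv_fraction = 0.045) {
  assert_that(is.character(patient_id) && length(patient_id) == 1L &&
                nzchar(patient_id), "patient_id must be a non-empty string")
  assert_that(is_number(compliance) && compliance > 0,
              "compliance must be > 0")
  assert_that(is_number(resistance) && resistance > 0,
              "resistance must be > 0")
  assert_that(is_number(hr_baseline) && hr_baseline >= 40 &&
                hr_baseline <= 180, "hr_baseline must lie in [40, 180] bpm")
  assert_that(is_number(sv_baseline) && sv_baseline > 0,
              "sv_baseline must be > 0")
  assert_that(is_number(scale_w_true) && scale_w_true > 0,
              "scale_w_true must be > 0")
  assert_that(is_number(scale_b_true), "scale_b_true must be a number")
  assert_that(is_number(resp_period) && resp_period >= 4 && resp_period <= 8,
              "resp_period must lie in [4, 8] s")
  assert_that(is_number(svv_fraction) && svv_fraction >= 0 &&
                svv_fraction <= 0.3, "svv_fraction must lie in [0, 0.3]")
  structure(list(patient_id = patient_id, compliance = compliance,
                 resistance = resistance, hr_baseline = hr_baseline,
                 sv_baseline = sv_baseline, scale_w_true = scale_w_true,
                 scale_b_true = scale_b_true, resp_period = resp_period,
                 svv_fraction = svv_fraction),
            class = "sv_patient_profile")
}

# draw from a normal, resampling outside [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a cohort of patient profiles
#'
#' Draws per-patient hemodynamic parameters from configured distributions.
#' Resistance is drawn from the cohort distribution (mean 858.8, SD 323.6
#' dyne·s/cm^5, truncated to \[300, 1800\]); the affine coefficients
#' (`scale_w_true`, `scale_b_true`) vary across patients so that the
#' per-patient calibration layer has signal to recover.
#'
#' @param n_patients number of profiles (>= 1).
#' @param schedule_template schedule the cohort will be simulated under
#'   (kept for provenance; profiles do not depend on it).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list of [patient_profile()] objects.
#' @export
generate_cohort <- function(n_patients, schedule_template = phase_schedule(),
                            seed = 1L) {
  assert_that(is_count(n_patients) && n_patients >= 1,
              "n_patients must be a positive integer")
  validate_schedule(schedule_template)
  with_seed(derive_seed(seed, "cohort"), {
    out <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      resistance <- rnorm_trunc(1, COHORT_SVR_MEAN, COHORT_SVR_SD, 300, 1800)
      r_wk <- resistance / MMHG_S_PER_ML
      # SVR and cardiac output are physiologically coupled (SVR is defined
      # through MAP/CO): redraw the flow-side parameters until the implied
      # mean pressure and pulse pressure are realistic, leaving the
      # resistance marginal exactly as configured
      ok <- FALSE
      sv <- COHORT_SV_MEAN; hr <- COHORT_HR_MEAN; compliance <- 1.8
      for (try in 1:200) {
        sv <- rnorm_trunc(1, COHORT_SV_MEAN, 18, 45, 140)
        hr <- rnorm_trunc(1, COHORT_HR_MEAN, 12, 50, 130)
        compliance <- min(max(exp(rnorm(1, log(1.8), 0.25)), 0.8), 4)
        map <- (sv * hr / 60) * r_wk
        pp <- sv / compliance
        if (map >= 55 && map <= 115 && pp >= 25 && pp <= 75) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {  # extreme resistance draw: pick the flow side to fit
        sv <- min(max(85 * 60 / (hr * r_wk), 45), 140)
        compliance <- min(max(sv / 45, 0.8), 4)
      }
      w <- min(max(exp(rnorm(1, 0, 0.15)), 0.6), 1.7)
      b <- min(max(rnorm(1, 0, 7), -15), 15)
      resp <- runif(1, 4.8, 6.2)
      svv <- rnorm_trunc(1, 0.045, 0.015, 0.01, 0.12)
      out[[i]] <- patient_profile(sprintf("P%03d", i),
                                  compliance = compliance,
                                  resistance = resistance,
                                  hr_baseline = hr, sv_baseline = sv,
                                  scale_w_true = w, scale_b_true = b,
                                  resp_period = resp, svv_fraction = svv)
    }
    out
  })
}

#' Simulate one case: ABP waveform, true SV, noisy reference, competitor
#'
#' Beat-by-beat true SV follows a bounded OU walk around the phase target
#' (scaled by the patient's `sv_baseline`), multiplied by
#' `1 + svv_fraction * sin(2*pi*t/resp_period)`. Each beat's pressure is the
#' response of a two-element Windkessel (RK4 at 1 kHz, decimated to
#' `fs_out`) to a half-sine ejection flow whose integral is the beat's
#' waveform SV `(sv_true - scale_b_true)/scale_w_true`. The reference
#' series is a causal moving average of true SV over `ref_horizon_s` plus
#' Gaussian noise, sampled every `ref_cadence_s`; the competitor is a
#' deliberately crude pulse-pressure surrogate whose error grows as
#' instantaneous SVR departs from the cohort mean (it exists only to give
#' the evaluation statistics a second estimator; it models no real device).
#'
#' @param profile a [patient_profile()].
#' @param schedule an [phase_schedule()] spanning `[0, duration_s]`.
#' @param duration_s case duration, s (>= 30); defaults to the schedule end.
#' @param seed integer seed (bit-identical regeneration guaranteed).
#' @param ref_horizon_s causal averaging horizon of the reference, s.
#' @param ref_noise_sd reference noise SD, mL.
#' @param ref_cadence_s reference sampling cadence, s.
#' @param fs_out output waveform rate, Hz (internal integration is 1 kHz).
#' @param walk_frac OU marginal SD as a fraction of the phase SV spread.
#' @param walk_tau_s OU correlation time, s.
#' @param hr_jitter_bpm bound on the AR(1) heart-rate deviation, bpm.
#' @param keep_flow keep the internal 2-kHz ejection flow (for diagnostics;
#'   large).
#' @return list of class `sv_sim_case` with elements `profile`, `schedule`,
#'   `abp` (an `sv_waveform`), `sv_true`, `sv_ref`, `sv_competitor`
#'   (data.frames `time_s`, `sv_ml`), `beats` (per-beat internals), `seed`.
#' @export
simulate_case <- function(profile, schedule = NULL, duration_s = NULL,
                          seed = 1L, ref_horizon_s = 60, ref_noise_sd = 3,
                          ref_cadence_s = 2, fs_out = 100, walk_frac = 0.3,
                          walk_tau_s = 45, hr_jitter_bpm = 5,
                          keep_flow = FALSE) {
  assert_that(inherits(profile, "sv_patient_profile"),
              "profile must be a patient_profile()")
  if (is.null(schedule)) {
    schedule <- phase_schedule(duration_s = if (is.null(duration_s)) 7200
                               else duration_s)
  }
  validate_schedule(schedule)
  if (is.null(duration_s)) duration_s <- schedule$end_s[4]
  assert_that(is_number(duration_s) && duration_s >= 30,
              "duration_s must be >= 30 s")
  assert_that(abs(schedule$start_s[1]) < 1e-9 &&
                schedule$end_s[4] >= duration_s - 1e-9,
              "schedule must cover [0, duration_s]")
  assert_that(1000 %% fs_out == 0, "fs_out must divide 1000 Hz")

  with_seed(derive_seed(seed, paste0("case:", profile$patient_id)), {
    ## ---- per-beat processes -------------------------------------------
    hr_scale <- profile$hr_baseline / COHORT_HR_MEAN
    sv_scale <- profile$sv_baseline / COHORT_SV_MEAN
    svr_scale <- profile$resistance / COHORT_SVR_MEAN
    phi_h <- 0.9
    hr_sd <- hr_jitter_bpm / 2.5

    n_guess <- ceiling(duration_s * 3) + 10
    t_on <- numeric(n_guess); hr <- numeric(n_guess)
    sv_true <- numeric(n_guess); sv_wave <- numeric(n_guess)
    svr <- numeric(n_guess); t_ej <- numeric(n_guess)
    period <- numeric(n_guess)

    # pre-draw innovations in fixed order for reproducibility
    z_hr <- rnorm(n_guess); z_walk <- rnorm(n_guess); z_svr <- rnorm(n_guess)

    t <- 0; n <- 0L
    d_hr <- 0; w_walk <- 0; e_svr <- 0
    prev_sigma <- NA_real_
    while (t < duration_s) {
      n <- n + 1L
      ph <- findInterval(t, c(schedule$start_s, schedule$end_s[4]),
                         rightmost.closed = TRUE, all.inside = TRUE)
      hr_target <- schedule$hr_mean[ph] * hr_scale
      sv_target <- schedule$sv_mean[ph] * sv_scale
      sigma_w <- walk_frac * schedule$sv_spread[ph]
      svr_target <- schedule$svr_mean[ph] * svr_scale

      d_hr <- phi_h * d_hr + sqrt(1 - phi_h^2) * hr_sd * z_hr[n]
      d_hr <- min(max(d_hr, -hr_jitter_bpm), hr_jitter_bpm)
      hr_n <- min(max(hr_target + d_hr, 40), 180)
      T_b <- 60 / hr_n

      if (!is.na(prev_sigma) && prev_sigma > 0) {
        w_walk <- w_walk * sigma_w / prev_sigma  # keep walk scale continuous
      }
      phi_w <- exp(-T_b / walk_tau_s)
      w_walk <- phi_w * w_walk +
        sigma_w * sqrt(1 - phi_w^2) * z_walk[n]
      w_walk <- min(max(w_walk, -3 * sigma_w), 3 * sigma_w)
      prev_sigma <- sigma_w

      phi_e <- exp(-T_b / 30)
      inst <- schedule$instability[ph]
      e_svr <- phi_e * e_svr + inst * sqrt(1 - phi_e^2) * z_svr[n]
      e_svr <- min(max(e_svr, -2 * inst), 2 * inst)

      resp_mod <- 1 + profile$svv_fraction *
        sin(2 * pi * t / profile$resp_period)
      s_true <- min(max((sv_target + w_walk) * resp_mod, 30), 222)

      t_on[n] <- t
      hr[n] <- hr_n
      period[n] <- T_b
      sv_true[n] <- s_true
      sv_wave[n] <- max((s_true - profile$scale_b_true) /
                          profile$scale_w_true, 10)
      # baroreflex-like floor: resistance never drops so far that the
      # implied mean pressure falls below ~32 mmHg
      svr_floor <- 32 * MMHG_S_PER_ML * 60 / (sv_wave[n] * hr_n)
      svr[n] <- min(max(svr_target * (1 + e_svr), svr_floor, 250), 2500)
      t_ej[n] <- min(max(T_b / 3, 0.2), 0.4)
      t <- t + T_b
    }
    idx <- seq_len(n)
    beats <- data.frame(t_onset = t_on[idx], period = period[idx],
                        hr = hr[idx], t_ej = t_ej[idx],
                        sv_true = sv_true[idx], sv_wave = sv_wave[idx],
                        svr = svr[idx])

    ## ---- render pressure ----------------------------------------------
    dt <- 1e-3
    n_steps <- round(duration_s / dt)
    flow <- numeric(2L * n_steps + 1L)  # half-step grid, spacing dt/2
    half_dt <- dt / 2
    len <- pmin(pmax(floor(beats$t_ej / half_dt), 1L),
                pmax(floor(beats$period / half_dt) - 1L, 1L))
    start_idx <- round(beats$t_onset / half_dt)  # 0-based grid position
    all_idx <- sequence(len, from = start_idx + 1L)  # 1-based into flow
    beat_of <- rep.int(idx, len)
    rel_t <- (all_idx - 1L) * half_dt - beats$t_onset[beat_of]
    q0 <- beats$sv_wave * pi / (2 * beats$t_ej)
    keep <- all_idx <= length(flow)
    flow[all_idx[keep]] <- (q0[beat_of] *
                              sin(pi * rel_t / beats$t_ej[beat_of]))[keep]

    t_steps <- (seq_len(n_steps) - 1L) * dt
    beat_step <- findInterval(t_steps, beats$t_onset)
    r_wk <- (beats$svr / MMHG_S_PER_ML)[beat_step]
    p0 <- (beats$sv_wave[1] * beats$hr[1] / 60) * r_wk[1]
    pressure <- wk_rk4(flow, r_wk, profile$compliance, dt, p0)

    dec <- as.integer(1000 / fs_out)
    abp <- pressure[seq(1L, n_steps + 1L, by = dec)]
    abp_t <- (seq_along(abp) - 1L) / fs_out
    wave <- waveform_record(profile$patient_id, fs = fs_out, t_start = 0,
                            samples = abp)

    ## ---- pulse pressure per beat (for the competitor) -----------------
    beat_of_samp <- findInterval(abp_t, beats$t_onset)
    pp <- as.numeric(tapply(abp, beat_of_samp, max) -
                       tapply(abp, beat_of_samp, min))
    beats$pp <- pp[seq_len(n)]

    ## ---- reference and competitor series ------------------------------
    t_ref <- seq(ref_cadence_s, duration_s, by = ref_cadence_s)
    cs <- cumsum(beats$sv_true)
    hi <- findInterval(t_ref, beats$t_onset)
    lo <- findInterval(t_ref - ref_horizon_s, beats$t_onset)
    cnt <- pmax(hi - lo, 1L)
    ref_mean <- (cs[hi] - ifelse(lo > 0, cs[pmax(lo, 1L)], 0)) / cnt
    sv_ref <- pmax(ref_mean + rnorm(length(t_ref), 0, ref_noise_sd), 15)

    eta <- numeric(n)
    z_eta <- rnorm(n)
    e <- 0
    for (j in seq_len(n)) {
      phi <- exp(-beats$period[j] / 30)
      e <- phi * e + 0.07 * sqrt(1 - phi^2) * z_eta[j]
      eta[j] <- e
    }
    svr_fac <- (beats$svr / COHORT_SVR_MEAN)^0.6
    calib <- beats$t_onset <= 120
    k_i <- mean(beats$sv_true[calib]) /
      mean((beats$pp * svr_fac)[calib])
    comp_beat <- k_i * beats$pp * svr_fac * (1 + eta[seq_len(n)])
    csc <- cumsum(comp_beat)
    hi2 <- findInterval(t_ref, beats$t_onset)
    lo2 <- findInterval(t_ref - 10, beats$t_onset)  # 10-s device smoothing
    cnt2 <- pmax(hi2 - lo2, 1L)
    sv_comp <- pmax((csc[hi2] - ifelse(lo2 > 0, csc[pmax(lo2, 1L)], 0)) /
                      cnt2, 5)

    out <- list(
      profile = profile, schedule = schedule,
      abp = wave,
      sv_true = data.frame(time_s = beats$t_onset, sv_ml = beats$sv_true),
      sv_ref = data.frame(time_s = t_ref, sv_ml = sv_ref),
      sv_competitor = data.frame(time_s = t_ref, sv_ml = sv_comp),
      beats = beats, seed = seed,
      params = list(ref_horizon_s = ref_horizon_s,
                    ref_noise_sd = ref_noise_sd,
                    ref_cadence_s = ref_cadence_s, fs_out = fs_out,
                    walk_frac = walk_frac, walk_tau_s = walk_tau_s,
                    hr_jitter_bpm = hr_jitter_bpm)
    )
    if (keep_flow) {
      out$flow <- flow
      out$flow_dt <- half_dt
    }
    class(out) <- "sv_sim_case"
    out
  })
}

#' @export
print.sv_sim_case <- function(x, ...) {
  cat(sprintf("<sv_sim_case %s: %.0f s, %d beats, %d reference samples>\n",
              x$profile$patient_id, x$schedule$end_s[4], nrow(x$beats),
              nrow(x$sv_ref)))
  invisible(x)
}

#' Write a simulated case to disk
#'
#' Writes `<id>_abp.csv` (`time_s`, `abp_mmhg`), `<id>_sv.csv`
#' (`time_s`, `sv_ml`, `source` in true/ref/competitor) and
#' `<id>_meta.json` (profile, schedule, seed, generator parameters).
#' Times are seconds from case start, 6-decimal fixed point.
#'
#' @param case an `sv_sim_case`.
#' @param dir output directory (created if absent).
#' @return the case id, invisibly.
#' @export
write_case <- function(case, dir) {
  assert_that(inherits(case, "sv_sim_case"), "case must be an sv_sim_case")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- case$profile$patient_id
  seg <- case$abp$segments[[1]]
  abp_dt <- data.table::data.table(
    time_s = sprintf("%.6f", seg$t_start + (seq_along(seg$samples) - 1) /
                       case$abp$fs),
    abp_mmhg = sprintf("%.6f", seg$samples))
  data.table::fwrite(abp_dt, file.path(dir, paste0(id, "_abp.csv")))
  sv_dt <- data.table::data.table(
    time_s = sprintf("%.6f", c(case$sv_true$time_s, case$sv_ref$time_s,
                               case$sv_competitor$time_s)),
    sv_ml = sprintf("%.6f", c(case$sv_true$sv_ml, case$sv_ref$sv_ml,
                              case$sv_competitor$sv_ml)),
    source = c(rep("true", nrow(case$sv_true)),
               rep("ref", nrow(case$sv_ref)),
               rep("competitor", nrow(case$sv_competitor))))
  data.table::fwrite(sv_dt, file.path(dir, paste0(id, "_sv.csv")))
  meta <- list(profile = unclass(case$profile),
               schedule = as.list(as.data.frame(lapply(case$schedule, function(c2)
                 if (is.factor(c2)) as.character(c2) else c2))),
               seed = case$seed, params = case$params)
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(id)
}

#' Read a case written by [write_case()]
#'
#' @param dir directory containing the case files.
#' @param id patient id.
#' @return list with `abp` (an `sv_waveform`), `sv_true`, `sv_ref`,
#'   `sv_competitor`, `profile`, `schedule`, `seed`.
#' @export
read_case <- function(dir, id) {
  meta_path <- file.path(dir, paste0(id, "_meta.json"))
  assert_that(file.exists(meta_path), "no meta file for case '%s' in %s",
              id, dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sched <- as.data.frame(meta$schedule, stringsAsFactors = FALSE)
  sched$phase <- factor(sched$phase, levels = PHASE_NAMES)
  class(sched) <- c("sv_phase_schedule", "data.frame")
  validate_schedule(sched)
  pr <- do.call(patient_profile, meta$profile)
  abp <- load_waveform(file.path(dir, paste0(id, "_abp.csv")),
                       expected_fs = meta$params$fs_out, patient_id = id)
  sv <- data.table::fread(file.path(dir, paste0(id, "_sv.csv")),
                          data.table = FALSE)
  pick <- function(src) {
    d <- sv[sv$source == src, c("time_s", "sv_ml")]
    rownames(d) <- NULL
    d
  }
  list(profile = pr, schedule = sched, abp = abp,
       sv_true = pick("true"), sv_ref = pick("ref"),
       sv_competitor = pick("competitor"), seed = meta$seed,
       params = meta$params)
}
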