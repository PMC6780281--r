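# Waveform file IO, resampling, window construction, cohort splitting.

#' Uniformly sampled arterial waveform record
#'
#' A waveform is stored as one or more gap-free segments, each with a start
#' time and pressure samples on a uniform grid at `fs` Hz (sample `i` of a
#' segment is at `t_start + (i - 1)/fs`). Artifact gaps split a recording
#' into independent segments; windows never span segments.
#'
#' @param patient_id character id.
#' @param fs sampling rate, Hz (> 0).
#' @param t_start start time of the (single) segment, seconds.
#' @param samples pressure samples, mmHg (used when `segments` is NULL).
#' @param segments alternatively, a list of `list(t_start=, samples=)`.
#' @return list of class `sv_waveform`.
#' @export
waveform_record <- function(patient_id, fs, t_start = 0, samples = NULL,
                            segments = NULL) {
  assert_that(is_number(fs) && fs > 0, "fs must be a positive number")
  if (is.null(segments)) {
    assert_that(is.numeric(samples) && length(samples) > 0,
                "samples must be a non-empty numeric vector")
    segments <- list(list(t_start = t_start, samples = as.numeric(samples)))
  }
  assert_that(length(segments) > 0 &&
                all(vapply(segments, function(s)
                  length(s$samples) > 0 && !anyNA(s$samples), logical(1))),
              "all segments must be non-empty with no missing values")
  structure(list(patient_id = patient_id, fs = fs, segments = segments),
            class = "sv_waveform")
}

#' @export
print.sv_waveform <- function(x, ...) {
  n <- sum(vapply(x$segments, function(s) length(s$samples), numeric(1)))
  cat(sprintf("<sv_waveform %s: %d samples @ %g Hz in %d segment(s)>\n",
              x$patient_id, n, x$fs, length(x$segments)))
  invisible(x)
}

#' Load an arterial waveform from a two-column text file
#'
#' Expects columns time (s) and pressure (mmHg). The time base must be
#' strictly increasing. Short missing runs (at most `max_gap_s`) are linearly
#' interpolated; longer missing or flat-line runs split the recording into
#' independent segments. If the input rate differs from `expected_fs`, each
#' segment is resampled by linear interpolation.
#'
#' @param path file path (CSV/TSV; any header naming two numeric columns).
#' @param expected_fs target sampling rate, Hz (default 100).
#' @param patient_id id to attach (default: file name stem).
#' @param max_gap_s gaps/flat-lines longer than this split the record, s.
#' @return an [waveform_record()] (`sv_waveform`).
#' @export
load_waveform <- function(path, expected_fs = 100, patient_id = NULL,
                          max_gap_s = 0.5) {
  assert_that(file.exists(path), "file not found: %s", path)
  d <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  if (nrow(d) == 0) abort_arg("format error: empty file %s", path)
  assert_that(ncol(d) >= 2, "format error: %s must have two numeric columns",
              path)
  t <- suppressWarnings(as.numeric(d[[1]]))
  p <- suppressWarnings(as.numeric(d[[2]]))
  if (anyNA(t)) {
    abort_arg("format error in %s: non-numeric time at row %d", path,
              which(is.na(t))[1])
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    abort_arg("format error in %s: non-monotone time at row %d", path,
              which(dt <= 0)[1] + 1L)
  }
  na_frac <- mean(is.na(p))
  if (na_frac > 0.05) {
    abort_arg("format error in %s: %.1f%% missing samples (> 5%%), first at row %d",
              path, 100 * na_frac, which(is.na(p))[1])
  }
  if (is.null(patient_id)) {
    patient_id <- sub("(_abp)?\\.[^.]*$", "", basename(path))
  }

  dt_med <- stats::median(dt)
  # samples to drop: long NA runs and long flat-line runs
  drop <- rep(FALSE, length(p))
  r <- rle(is.na(p))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] * dt_med > max_gap_s) {
      drop[starts[i]:ends[i]] <- TRUE
    }
  }
  rf <- rle(ifelse(is.na(p), NA_real_, p))
  ends_f <- cumsum(rf$lengths); starts_f <- ends_f - rf$lengths + 1L
  for (i in seq_along(rf$lengths)) {
    if (!is.na(rf$values[i]) && (rf$lengths[i] - 1L) * dt_med > max_gap_s) {
      drop[starts_f[i]:ends_f[i]] <- TRUE
    }
  }
  keep <- which(!drop)
  assert_that(length(keep) > 1, "format error: no usable samples in %s", path)
  t <- t[keep]; p <- p[keep]

  # segment breaks where the kept time base jumps
  brk <- which(diff(t) > max_gap_s + dt_med)
  seg_start <- c(1L, brk + 1L)
  seg_end <- c(brk, length(t))
  segments <- vector("list", length(seg_start))
  for (s in seq_along(seg_start)) {
    ts <- t[seg_start[s]:seg_end[s]]
    ps <- p[seg_start[s]:seg_end[s]]
    if (anyNA(ps)) {  # short gaps: linear interpolation inside the segment
      ok <- !is.na(ps)
      ps <- approx(ts[ok], ps[ok], xout = ts, rule = 2)$y
    }
    t_out <- seq(ts[1], ts[length(ts)], by = 1 / expected_fs)
    ps_out <- if (abs(dt_med - 1 / expected_fs) < 1e-9 &&
                  length(t_out) == length(ts)) {
      ps
    } else {
      approx(ts, ps, xout = t_out)$y
    }
    segments[[s]] <- list(t_start = ts[1], samples = ps_out)
  }
  waveform_record(patient_id, fs = expected_fs, segments = segments)
}

#' Number of sliding windows in a gap-free record
#'
#' `floor((T - window_s)/stride_s) + 1` for a record of duration `T`
#' seconds (zero when shorter than one window).
#' @param duration_s record duration, s.
#' @param stride_s window stride, s (default 2).
#' @param window_s window length, s (default 10.24).
#' @export
window_count <- function(duration_s, stride_s = 2, window_s = 10.24) {
  assert_that(is.numeric(duration_s) && all(duration_s >= 0),
              "duration_s must be non-negative")
  assert_that(is_number(stride_s) && stride_s > 0, "stride_s must be > 0")
  pmax(0, floor((duration_s - window_s) / stride_s + 1e-9) + 1)
}

#' Hours of coverage implied by a record count at a fixed cadence
#' @param n_records number of records.
#' @param stride_s record cadence, s (default 2).
#' @return hours.
#' @export
coverage_hours <- function(n_records, stride_s = 2) {
  n_records * stride_s / 3600
}

#' Build windowed input records from a waveform and a reference series
#'
#' Slides a `window_samples`-sample window (10.24 s at 100 Hz) along each
#' gap-free segment with stride `stride_s`; a window's `t0` is the timestamp
#' of its last sample and the window covers `(t0 - window_samples/fs, t0]`.
#' Each window is paired with the reference sample nearest `t0` within
#' `ref_tol_s`; windows without a reference in tolerance are dropped and
#' counted.
#'
#' @param wave an `sv_waveform`.
#' @param ref reference SV series: data.frame with `time_s`, `sv_ml`.
#' @param schedule optional [phase_schedule()] for phase labels.
#' @param stride_s stride, s (default 2); must be a multiple of `1/fs`.
#' @param window_samples samples per window (default 1024).
#' @param ref_tol_s pairing tolerance, s (default 1, half the stride).
#' @param competitor optional second series (`time_s`, `sv_ml`) paired the
#'   same way (NA when absent).
#' @return object of class `sv_windows`: `x` (matrix `window_samples` x n),
#'   `meta` (data.frame `patient_id`, `t0`, `sv_ref`, `phase`,
#'   `sv_competitor`), `n_dropped`, plus `fs`, `window_samples`, `stride_s`.
#' @export
make_windows <- function(wave, ref, schedule = NULL, stride_s = 2,
                         window_samples = 1024, ref_tol_s = 1,
                         competitor = NULL) {
  assert_that(inherits(wave, "sv_waveform"), "wave must be an sv_waveform")
  assert_that(is.data.frame(ref) && all(c("time_s", "sv_ml") %in% names(ref)),
              "ref must be a data.frame with time_s and sv_ml")
  assert_that(is_number(stride_s) && stride_s > 0, "stride_s must be > 0")
  stride_n <- stride_s * wave$fs
  assert_that(abs(stride_n - round(stride_n)) < 1e-9,
              "stride_s must be a multiple of one sample period")
  stride_n <- as.integer(round(stride_n))
  assert_that(is_count(window_samples) && window_samples >= 2,
              "window_samples must be an integer >= 2")

  xs <- list(); metas <- list(); dropped <- 0L
  for (seg in wave$segments) {
    n <- length(seg$samples)
    if (n < window_samples) next
    ends <- seq.int(window_samples, n, by = stride_n)
    t0 <- seg$t_start + (ends - 1) / wave$fs
    if (nrow(ref) == 0) {
      dropped <- dropped + length(t0)
      next
    }
    # nearest reference within tolerance
    j <- findInterval(t0, ref$time_s)
    j_lo <- pmax(j, 1L)
    j_hi <- pmin(j + 1L, nrow(ref))
    d_lo <- abs(ref$time_s[j_lo] - t0)
    d_hi <- abs(ref$time_s[j_hi] - t0)
    j_best <- ifelse(d_lo <= d_hi, j_lo, j_hi)
    d_best <- pmin(d_lo, d_hi)
    ok <- d_best <= ref_tol_s
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    ends <- ends[ok]; t0 <- t0[ok]; j_best <- j_best[ok]
    idx <- outer(seq_len(window_samples) - window_samples, ends, `+`)
    x <- matrix(seg$samples[idx], nrow = window_samples)
    comp <- rep(NA_real_, length(t0))
    if (!is.null(competitor) && nrow(competitor) > 0) {
      jc <- findInterval(t0, competitor$time_s)
      jc_lo <- pmax(jc, 1L); jc_hi <- pmin(jc + 1L, nrow(competitor))
      dc_lo <- abs(competitor$time_s[jc_lo] - t0)
      dc_hi <- abs(competitor$time_s[jc_hi] - t0)
      jc_best <- ifelse(dc_lo <= dc_hi, jc_lo, jc_hi)
      okc <- pmin(dc_lo, dc_hi) <= ref_tol_s
      comp[okc] <- competitor$sv_ml[jc_best[okc]]
    }
    xs[[length(xs) + 1L]] <- x
    metas[[length(metas) + 1L]] <- data.frame(
      patient_id = wave$patient_id, t0 = t0, sv_ref = ref$sv_ml[j_best],
      phase = if (is.null(schedule)) factor(rep(NA_character_, length(t0)),
                                            levels = PHASE_NAMES)
              else phase_at(t0, schedule),
      sv_competitor = comp, stringsAsFactors = FALSE)
  }
  if (dropped > 0) {
    log_msg("INFO", "make_windows(%s): dropped %d window(s) without a reference within %.2f s",
            wave$patient_id, dropped, ref_tol_s)
  }
  x <- if (length(xs)) do.call(cbind, xs) else
    matrix(numeric(0), nrow = window_samples, ncol = 0)
  meta <- if (length(metas)) do.call(rbind, metas) else
    data.frame(patient_id = character(0), t0 = numeric(0),
               sv_ref = numeric(0),
               phase = factor(character(0), levels = PHASE_NAMES),
               sv_competitor = numeric(0))
  rownames(meta) <- NULL
  structure(list(x = x, meta = meta, n_dropped = dropped, fs = wave$fs,
                 window_samples = window_samples, stride_s = stride_s),
            class = "sv_windows")
}

#' Concatenate window sets from several cases
#' @param window_list list of `sv_windows` with identical geometry.
#' @return a single `sv_windows`.
#' @export
bind_windows <- function(window_list) {
  assert_that(length(window_list) > 0, "window_list must be non-empty")
  assert_that(all(vapply(window_list, inherits, logical(1), "sv_windows")),
              "all elements must be sv_windows")
  ws <- unique(vapply(window_list, function(w) w$window_samples, numeric(1)))
  assert_that(length(ws) == 1L, "window geometries differ")
  structure(list(
    x = do.call(cbind, lapply(window_list, `[[`, "x")),
    meta = do.call(rbind, lapply(window_list, `[[`, "meta")),
    n_dropped = sum(vapply(window_list, `[[`, numeric(1), "n_dropped")),
    fs = window_list[[1]]$fs, window_samples = ws,
    stride_s = window_list[[1]]$stride_s), class = "sv_windows")
}

#' @export
print.sv_windows <- function(x, ...) {
  cat(sprintf("<sv_windows: %d windows x %d samples, %d patient(s), %d dropped>\n",
              ncol(x$x), x$window_samples,
              length(unique(x$meta$patient_id)), x$n_dropped))
  invisible(x)
}

# subset an sv_windows by window index or by patient id
subset_windows <- function(w, idx = NULL, patients = NULL) {
  if (!is.null(patients)) idx <- which(w$meta$patient_id %in% patients)
  out <- w
  out$x <- w$x[, idx, drop = FALSE]
  out$meta <- w$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Patient-level train/validation/test split
#'
#' Splits patient ids (never individual windows) into disjoint sets with
#' largest-remainder rounding of the requested fractions, deterministically
#' for a given seed.
#'
#' @param ids character vector of patient ids (unique).
#' @param fractions length-3 numeric (train, val, test) summing to 1.
#' @param seed integer seed.
#' @return list of class `sv_cohort_split` with `train_ids`, `val_ids`,
#'   `test_ids`.
#' @export
split_cohort <- function(ids, fractions, seed = 1L) {
  assert_that(is.character(ids) && length(ids) > 0 && !anyDuplicated(ids),
              "ids must be unique non-empty character")
  assert_that(is.numeric(fractions) && length(fractions) == 3L &&
                all(fractions >= 0), "fractions must be length-3 non-negative")
  assert_that(abs(sum(fractions) - 1) <= 1e-9, "fractions must sum to 1")
  n_parts <- sum(fractions > 0)
  assert_that(length(ids) >= n_parts,
              "fewer ids (%d) than non-empty partitions (%d)",
              length(ids), n_parts)
  counts <- allocate_counts(length(ids), fractions)
  # guarantee each requested partition gets at least one id
  while (any(counts == 0 & fractions > 0)) {
    i <- which(counts == 0 & fractions > 0)[1]
    j <- which.max(counts)
    counts[i] <- counts[i] + 1L
    counts[j] <- counts[j] - 1L
  }
  shuffled <- with_seed(derive_seed(seed, "split"), sample(ids))
  cuts <- cumsum(counts)
  structure(list(
    train_ids = sort(shuffled[seq_len(counts[1])]),
    val_ids = if (counts[2] > 0) sort(shuffled[(cuts[1] + 1):cuts[2]])
              else character(0),
    test_ids = if (counts[3] > 0) sort(shuffled[(cuts[2] + 1):cuts[3]])
               else character(0)), class = "sv_cohort_split")
}

#' Write a windowed dataset directory
#'
#' One directory per cohort: a JSON manifest, one array file per case, and
#' a plain-text log of dropped-window counts.
#' @param windows_by_case named list of `sv_windows` (one per patient).
#' @param dir output directory.
#' @param extra optional list merged into the manifest (e.g. config hash).
#' @return the manifest, invisibly.
#' @export
write_window_dataset <- function(windows_by_case, dir, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(windows_by_case)
  assert_that(!is.null(ids) && all(nzchar(ids)),
              "windows_by_case must be a named list")
  for (id in ids) {
    saveRDS(windows_by_case[[id]], file.path(dir, paste0(id, "_windows.rds")),
            version = 3)
  }
  manifest <- c(list(
    cases = ids,
    n_windows = vapply(windows_by_case, function(w) ncol(w$x), numeric(1)),
    n_dropped = vapply(windows_by_case, `[[`, numeric(1), "n_dropped"),
    window_samples = windows_by_case[[1]]$window_samples,
    fs = windows_by_case[[1]]$fs,
    stride_s = windows_by_case[[1]]$stride_s), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(sprintf("%s\t%d", ids, manifest$n_dropped),
             file.path(dir, "dropped_windows.log"))
  invisible(manifest)
}

#' Read a windowed dataset directory written by [write_window_dataset()]
#' @param dir dataset directory.
#' @param ids subset of case ids (default: all in the manifest).
#' @return named list of `sv_windows`.
#' @export
read_window_dataset <- function(dir, ids = NULL) {
  mf <- file.path(dir, "manifest.json")
  assert_that(file.exists(mf), "no dataset manifest in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(ids)) ids <- manifest$cases
  out <- lapply(ids, function(id)
    readRDS(file.path(dir, paste0(id, "_windows.rds"))))
  names(out) <- ids
  out
}
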