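# End-to-end orchestration: simulate -> dataset -> train -> predict ->
# evaluate, with per-stage manifests, config hashing and a single seed.

#' Default pipeline configuration
#'
#' Desk-scale defaults: 16 simulated patients (12 train / 4 test), two-hour
#' cases, the default model configuration, trend interval 60 s and a 10%
#' exclusion zone. Every random process in a run derives from `seed`.
#'
#' @param work_dir working directory for run artifacts.
#' @param seed master seed.
#' @return nested list of class `sv_run_config`.
#' @export
default_config <- function(work_dir = file.path(tempdir(), "svwave_run"),
                           seed = 1L) {
  cfg <- list(
    paths = list(work_dir = work_dir),
    seed = as.integer(seed),
    hemosim = list(n_train = 12L, n_test = 4L, duration_s = 7200,
                   ref_horizon_s = 60, ref_noise_sd = 3, ref_cadence_s = 2,
                   fs_out = 100),
    dataset = list(stride_s = 2, window_samples = 1024L, ref_tol_s = 1),
    model = list(n_blocks = 8L, input_len = 1024L, kernel_size = 5L,
                 channels_per_block = c(4L, 4L, 8L, 8L, 8L, 8L, 16L, 16L),
                 skip_mode = "concat", fc_hidden = 64L,
                 learning_rate = 2e-3, isc_lr_mult = 10, batch_size = 256L,
                 max_epochs = 10L, val_frac = 0.2),
    evaluate = list(delta_interval_s = 60, exclusion_fraction = 0.10,
                    exclusion_mode = "both", isc_mode = "calibrate",
                    n_calib = 300L, postprocess = "none",
                    postprocess_width_s = 6, plots = TRUE)
  )
  class(cfg) <- c("sv_run_config", "list")
  cfg
}

#' Read / write a run configuration (YAML)
#'
#' The YAML round-trips losslessly: `read_run_config(write_run_config(x))`
#' reproduces `x`.
#' @param config an `sv_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  cfg <- utils::modifyList(base, cfg)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("sv_run_config", "list")
  cfg
}

# stable hash of the configuration subset a stage depends on; downstream
# stages accumulate the upstream subsets so artifacts can be reused when
# only later-stage settings change
config_hash <- function(config, stage = "evaluate") {
  keep <- list(seed = config$seed, hemosim = config$hemosim)
  if (stage %in% c("dataset", "train", "predict", "evaluate")) {
    keep$dataset <- config$dataset
  }
  if (stage %in% c("train", "predict", "evaluate")) {
    keep$model <- config$model
  }
  if (stage %in% c("predict", "evaluate")) {
    keep$evaluate <- config$evaluate
  }
  object_hash(keep)
}

stage_manifest_path <- function(dir, stage) {
  file.path(dir, sprintf("%s_manifest.json", stage))
}

write_stage_manifest <- function(dir, stage, config, extra = list()) {
  m <- c(list(stage = stage, config_hash = config_hash(config, stage),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("svwave")),
              r_version = as.character(getRversion())), extra)
  jsonlite::write_json(m, stage_manifest_path(dir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(m)
}

stage_done <- function(dir, stage, config) {
  p <- stage_manifest_path(dir, stage)
  if (!file.exists(p)) return(FALSE)
  m <- jsonlite::read_json(p)
  identical(m$config_hash, unname(config_hash(config, stage)))
}

require_stage <- function(dir, stage, config, needed_by) {
  p <- stage_manifest_path(dir, stage)
  assert_that(file.exists(p),
              "stage '%s' needs outputs of stage '%s': run it first",
              needed_by, stage)
  m <- jsonlite::read_json(p)
  assert_that(identical(m$config_hash, unname(config_hash(config, stage))),
              "refusing to mix artifacts: '%s' outputs were produced under a different configuration",
              stage)
  invisible(TRUE)
}

as_model_config <- function(config) {
  m <- config$model
  model_config(n_blocks = m$n_blocks, input_len = m$input_len,
               kernel_size = m$kernel_size,
               channels_per_block = unlist(m$channels_per_block),
               skip_mode = m$skip_mode, fc_hidden = m$fc_hidden,
               learning_rate = m$learning_rate, isc_lr_mult = m$isc_lr_mult,
               batch_size = m$batch_size, max_epochs = m$max_epochs,
               val_frac = m$val_frac, seed = derive_seed(config$seed, "model"))
}

#' Run the simulation-to-evaluation pipeline
#'
#' Stages: `simulate` (synthetic cohort written as per-case CSV/JSON),
#' `dataset` (windowed records from the written files), `train` (joint
#' network + ISC training on the training patients), `predict` (test-patient
#' predictions under the configured ISC mode) and `evaluate`
#' (phase-stratified method comparison of the network and the crude
#' competitor against the reference, plus correlation against the
#' simulator's true SV). Each stage writes a manifest containing the
#' configuration hash; re-running an unchanged stage is a logged no-op, and
#' a stage refuses inputs produced under a different configuration.
#'
#' @param config an `sv_run_config` (see [default_config()]) or a path to a
#'   YAML file.
#' @param stages subset of
#'   `c("simulate", "dataset", "train", "predict", "evaluate")`.
#' @param force re-run stages even when their manifests are current.
#' @return list with artifact paths and, after `evaluate`, the report
#'   tables; invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "dataset", "train",
                                    "predict", "evaluate"),
                         force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(inherits(config, "sv_run_config"),
              "config must be an sv_run_config or a YAML path")
  all_stages <- c("simulate", "dataset", "train", "predict", "evaluate")
  assert_that(all(stages %in% all_stages), "unknown stage name")
  stages <- all_stages[all_stages %in% stages]

  wd <- config$paths$work_dir
  dirs <- list(cases = file.path(wd, "cases"),
               dataset = file.path(wd, "dataset"),
               model = file.path(wd, "model"),
               predictions = file.path(wd, "predictions"),
               report = file.path(wd, "report"))
  for (d in dirs) if (!dir.exists(d)) dir.create(d, recursive = TRUE)

  hs <- config$hemosim
  n_all <- hs$n_train + hs$n_test
  schedule <- phase_schedule(duration_s = hs$duration_s)
  cohort <- generate_cohort(n_all, schedule, seed = config$seed)
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  split <- split_cohort(ids, c(hs$n_train / n_all, 0, hs$n_test / n_all),
                        seed = config$seed)
  out <- list(config = config, dirs = dirs, split = split)

  if ("simulate" %in% stages) {
    if (!force && stage_done(dirs$cases, "simulate", config)) {
      log_msg("INFO", "simulate: outputs current, skipping")
    } else {
      for (pr in cohort) {
        case <- simulate_case(pr, schedule, seed = config$seed,
                              ref_horizon_s = hs$ref_horizon_s,
                              ref_noise_sd = hs$ref_noise_sd,
                              ref_cadence_s = hs$ref_cadence_s,
                              fs_out = hs$fs_out)
        write_case(case, dirs$cases)
      }
      write_stage_manifest(dirs$cases, "simulate", config,
                           list(cases = ids))
      log_msg("INFO", "simulate: wrote %d cases", n_all)
    }
  }

  if ("dataset" %in% stages) {
    require_stage(dirs$cases, "simulate", config, "dataset")
    if (!force && stage_done(dirs$dataset, "dataset", config)) {
      log_msg("INFO", "dataset: outputs current, skipping")
    } else {
      ds <- config$dataset
      wbc <- list()
      for (id in ids) {
        case <- read_case(dirs$cases, id)
        wbc[[id]] <- make_windows(case$abp, case$sv_ref, case$schedule,
                                  stride_s = ds$stride_s,
                                  window_samples = ds$window_samples,
                                  ref_tol_s = ds$ref_tol_s,
                                  competitor = case$sv_competitor)
      }
      write_window_dataset(wbc, dirs$dataset,
                           extra = list(config_hash = config_hash(config)))
      write_stage_manifest(dirs$dataset, "dataset", config)
      log_msg("INFO", "dataset: %d windows across %d cases",
              sum(vapply(wbc, function(w) ncol(w$x), numeric(1))), n_all)
    }
  }

  ckpt <- file.path(dirs$model, "checkpoint.rds")
  if ("train" %in% stages) {
    require_stage(dirs$dataset, "dataset", config, "train")
    if (!force && stage_done(dirs$model, "train", config)) {
      log_msg("INFO", "train: checkpoint current, skipping")
    } else {
      wbc <- read_window_dataset(dirs$dataset, split$train_ids)
      train_w <- bind_windows(wbc)
      model <- train_svnet(train_w, val_windows = NULL,
                           cfg = as_model_config(config))
      save_model(model, ckpt)
      write_stage_manifest(dirs$model, "train", config,
                           list(best_epoch = model$epoch,
                                val_rms = model$val_rms))
      log_msg("INFO", "train: best epoch %d, val RMS %.2f mL", model$epoch,
              model$val_rms)
    }
  }

  pred_path <- file.path(dirs$predictions, "predictions.csv")
  if ("predict" %in% stages) {
    require_stage(dirs$model, "train", config, "predict")
    if (!force && stage_done(dirs$predictions, "predict", config)) {
      log_msg("INFO", "predict: outputs current, skipping")
    } else {
      ev <- config$evaluate
      model <- load_model(ckpt)
      wbc <- read_window_dataset(dirs$dataset, split$test_ids)
      preds <- list()
      for (id in split$test_ids) {
        w <- wbc[[id]]
        raw <- predict_svcnn(model, w)
        wb <- if (identical(ev$isc_mode, "calibrate")) {
          nc <- min(ev$n_calib, length(raw))
          cal <- calibrate_isc(raw[seq_len(nc)], w$meta$sv_ref[seq_len(nc)])
          c(cal$w, cal$b)
        } else {
          c(1, 0)
        }
        p <- data.frame(patient_id = id, time_s = w$meta$t0,
                        sv_ml = raw * wb[1] + wb[2], sv_raw = raw,
                        isc_w = wb[1], isc_b = wb[2],
                        stringsAsFactors = FALSE)
        if (!identical(ev$postprocess, "none")) {
          p$sv_ml <- postprocess_sv(
            data.frame(time_s = p$time_s, sv_ml = p$sv_ml),
            method = ev$postprocess,
            width_s = ev$postprocess_width_s)$sv_ml
        }
        preds[[id]] <- p
      }
      pred <- do.call(rbind, preds)
      rownames(pred) <- NULL
      data.table::fwrite(pred, pred_path)
      write_stage_manifest(dirs$predictions, "predict", config,
                           list(isc_mode = ev$isc_mode))
      log_msg("INFO", "predict: %d predictions for %d test patients",
              nrow(pred), length(split$test_ids))
    }
  }

  if ("evaluate" %in% stages) {
    require_stage(dirs$predictions, "predict", config, "evaluate")
    ev <- config$evaluate
    ecfg <- eval_config(delta_interval_s = ev$delta_interval_s,
                        exclusion_fraction = ev$exclusion_fraction,
                        exclusion_mode = ev$exclusion_mode)
    pred <- data.table::fread(pred_path, data.table = FALSE)
    wbc <- read_window_dataset(dirs$dataset, split$test_ids)

    true_sv_by_id <- lapply(split$test_ids, function(id) {
      sv <- data.table::fread(file.path(dirs$cases, paste0(id, "_sv.csv")),
                              data.table = FALSE)
      sv[sv$source == "true", c("time_s", "sv_ml")]
    })
    names(true_sv_by_id) <- split$test_ids

    build_pairs <- function(test_col) {
      parts <- lapply(seq_along(split$test_ids), function(i) {
        id <- split$test_ids[i]
        w <- wbc[[id]]
        p <- pred[pred$patient_id == id, ]
        stopifnot(nrow(p) == nrow(w$meta))
        tv <- if (test_col == "model") p$sv_ml else w$meta$sv_competitor
        keep <- is.finite(tv) & tv > 0
        # offset per patient so pooled t stays strictly increasing
        data.frame(t = w$meta$t0[keep] + (i - 1) * 1e7,
                   ref = w$meta$sv_ref[keep], test = tv[keep],
                   phase = w$meta$phase[keep], true_sv = approx(
                     true_sv_by_id[[id]]$time_s, true_sv_by_id[[id]]$sv_ml,
                     xout = w$meta$t0, rule = 2)$y[keep])
      })
      do.call(rbind, parts)
    }
    dl <- build_pairs("model")
    cp <- build_pairs("competitor")
    shared <- intersect(dl$t, cp$t)
    dl <- dl[dl$t %in% shared, ]
    cp <- cp[cp$t %in% shared, ]
    pairs_dl <- paired_series(dl$t, dl$ref, dl$test, dl$phase)
    pairs_cp <- paired_series(cp$t, cp$ref, cp$test, cp$phase)

    rep_dl <- phase_report(pairs_dl, ecfg)
    rep_cp <- phase_report(pairs_cp, ecfg)
    comparison <- do.call(rbind, lapply(rep_dl$phase, function(ph) {
      sub_a <- if (ph == "overall") pairs_dl else
        pairs_dl[which(pairs_dl$phase == ph), ]
      sub_b <- if (ph == "overall") pairs_cp else
        pairs_cp[which(pairs_cp$phase == ph), ]
      if (nrow(sub_a) < 4 || stats::var(sub_a$ref) == 0) {
        return(data.frame(phase = ph, z = NA_real_, p = NA_real_))
      }
      st <- compare_dependent_correlations(sub_a, sub_b)
      data.frame(phase = ph, z = st$z, p = st$p)
    }))
    r_truth_dl <- cor(dl$true_sv, dl$test)
    r_truth_cp <- cor(cp$true_sv, cp$test)

    jt <- file.path(dirs$report, "eval_report.json")
    ct <- file.path(dirs$report, "eval_report.csv")
    write_eval_report(rep_dl, jt, ct, competitor = rep_cp,
                      comparison = comparison,
                      extra = list(isc_mode = ev$isc_mode,
                                   r_vs_true_sv = round(r_truth_dl, 4),
                                   r_vs_true_sv_competitor =
                                     round(r_truth_cp, 4)))
    if (isTRUE(ev$plots)) {
      suppressMessages({
        ggplot2::ggsave(file.path(dirs$report, "scatter.pdf"),
                        plot_scatter(pairs_dl), width = 7, height = 5)
        ggplot2::ggsave(file.path(dirs$report, "bland_altman.pdf"),
                        plot_bland_altman(pairs_dl), width = 7, height = 5)
        ggplot2::ggsave(file.path(dirs$report, "four_quadrant.pdf"),
                        plot_four_quadrant(pairs_dl, ecfg), width = 6,
                        height = 6)
      })
    }
    write_stage_manifest(dirs$report, "evaluate", config)
    log_msg("INFO", "evaluate: overall r=%.3f (model) vs r=%.3f (competitor)",
            rep_dl$r[rep_dl$phase == "overall"],
            rep_cp$r[rep_cp$phase == "overall"])
    out$report <- rep_dl
    out$report_competitor <- rep_cp
    out$comparison <- comparison
    out$r_vs_true <- c(model = r_truth_dl, competitor = r_truth_cp)
    out$report_json <- jt
    out$report_csv <- ct
    out$pairs <- list(model = pairs_dl, competitor = pairs_cp,
                      true_sv = dl$true_sv)
  }
  invisible(out)
}
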