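# Report serialization (JSON + table-shaped CSV) and comparison figures.

# rounding convention for reports: r to 3 decimals, mL quantities to 2,
# rates/percentages to 2
round_report <- function(rep) {
  r3 <- c("r", "ci_low", "ci_high")
  r2 <- c("bias", "sd_diff", "loa_low", "loa_high", "concordance_rate",
          "rmse")
  r4 <- c("mdpe", "mdape")
  for (cn in intersect(r3, names(rep))) rep[[cn]] <- round(rep[[cn]], 3)
  for (cn in intersect(r2, names(rep))) rep[[cn]] <- round(rep[[cn]], 2)
  for (cn in intersect(r4, names(rep))) rep[[cn]] <- round(rep[[cn]], 4)
  rep
}

#' Write an evaluation report as JSON and a table-shaped CSV
#'
#' The CSV has phases as rows and statistics as columns; when two reports
#' are given (test estimator and competitor) their columns are interleaved
#' and a dependent-correlation p-value column is added. Output is rounded
#' (r to 3 decimals, mL and % to 2) and contains no timestamps, so
#' identical runs produce byte-identical files.
#'
#' @param report an `sv_eval_report` (the estimator under test).
#' @param path_json,path_csv output paths (NULL to skip either).
#' @param competitor optional second `sv_eval_report` on the same records.
#' @param comparison optional data.frame `phase`, `z`, `p` from
#'   [compare_dependent_correlations()] per phase.
#' @param extra named list of scalars stored in the JSON (e.g. settings:
#'   ISC mode, trend interval).
#' @return list with the rounded tables, invisibly.
#' @export
write_eval_report <- function(report, path_json = NULL, path_csv = NULL,
                              competitor = NULL, comparison = NULL,
                              extra = list()) {
  assert_that(inherits(report, "sv_eval_report"),
              "report must be an sv_eval_report")
  main <- round_report(as.data.frame(report))
  comp <- if (!is.null(competitor)) round_report(as.data.frame(competitor))
  cmp <- if (!is.null(comparison)) {
    data.frame(phase = comparison$phase, z = round(comparison$z, 3),
               p = signif(comparison$p, 3))
  }
  payload <- c(list(settings = c(attr(report, "config"), extra),
                    estimator = main),
               if (!is.null(comp)) list(competitor = comp),
               if (!is.null(cmp)) list(correlation_comparison = cmp))
  if (!is.null(path_json)) {
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(path_csv)) {
    tab <- main
    names(tab) <- c("phase", paste0("test_", names(main)[-1]))
    if (!is.null(comp)) {
      ctab <- comp
      names(ctab) <- c("phase", paste0("competitor_", names(comp)[-1]))
      tab <- merge(tab, ctab, by = "phase", sort = FALSE)
      if (!is.null(cmp)) tab <- merge(tab, cmp, by = "phase", sort = FALSE)
    }
    data.table::fwrite(tab, path_csv)
  }
  invisible(payload)
}

#' Scatter plot of test against reference SV
#' @param pairs an [paired_series()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_scatter <- function(pairs, title = "Reference vs predicted SV") {
  df <- as.data.frame(pairs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$test,
                                   colour = .data$phase)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Reference SV (mL)", y = "Predicted SV (mL)",
                  title = title, colour = "phase") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#' @param pairs an [paired_series()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pairs, title = "Bland-Altman") {
  ba <- bland_altman(pairs)
  df <- data.frame(m = (pairs$ref + pairs$test) / 2,
                   d = pairs$test - pairs$ref, phase = pairs$phase)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d,
                                   colour = .data$phase)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.5) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_low, ba$loa_high),
                        linetype = c(1, 2, 2)) +
    ggplot2::labs(x = "Mean of methods (mL)", y = "Difference (mL)",
                  title = title, colour = "phase") +
    ggplot2::theme_minimal()
}

#' Four-quadrant trend plot with the central exclusion zone
#' @param pairs an [paired_series()].
#' @param config an [eval_config()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_four_quadrant <- function(pairs, config = eval_config(),
                               title = "Four-quadrant trend analysis") {
  d <- trend_deltas(pairs, config$delta_interval_s, config$pair_tol_s)
  zone <- config$exclusion_fraction * mean(pairs$ref)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d_ref, y = .data$d_test)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::annotate("rect", xmin = -zone, xmax = zone, ymin = -zone,
                      ymax = zone, colour = "red", fill = NA) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = expression(Delta * " reference SV (mL)"),
                  y = expression(Delta * " predicted SV (mL)"),
                  title = title) +
    ggplot2::theme_minimal()
}
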