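# Method-comparison statistics: correlation with Fisher CI, dependent
# correlation comparison (Steiger), Bland-Altman, four-quadrant trend
# concordance with a central exclusion zone, and performance-error metrics,
# with phase stratification.

#' Aligned reference/test SV series
#'
#' @param t strictly increasing times, s.
#' @param sv_reference reference SV, mL (finite, > 0).
#' @param sv_test test SV, mL (finite, > 0).
#' @param phase optional phase labels (factor or character).
#' @return data.frame of class `sv_paired_series` with columns `t`, `ref`,
#'   `test`, `phase`.
#' @export
paired_series <- function(t, sv_reference, sv_test, phase = NULL) {
  assert_that(is.numeric(t) && length(t) > 0, "t must be non-empty numeric")
  assert_that(length(sv_reference) == length(t) &&
                length(sv_test) == length(t),
              "t, sv_reference, sv_test lengths differ")
  assert_that(all(diff(t) > 0), "t must be strictly increasing")
  assert_that(all(is.finite(sv_reference)) && all(sv_reference > 0),
              "sv_reference must be finite and > 0")
  assert_that(all(is.finite(sv_test)) && all(sv_test > 0),
              "sv_test must be finite and > 0")
  if (is.null(phase)) {
    phase <- factor(rep(NA_character_, length(t)))
  }
  assert_that(length(phase) == length(t), "phase length differs")
  structure(data.frame(t = t, ref = sv_reference, test = sv_test,
                       phase = as.factor(phase)),
            class = c("sv_paired_series", "data.frame"))
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' `z = atanh(r)` with standard error `1/sqrt(n - 3)`; the interval is
#' `tanh(z -/+ z_{1-alpha/2}/sqrt(n - 3))`.
#'
#' @param r Pearson correlation.
#' @param n number of pairs (> 3).
#' @param alpha two-sided level (default 0.05 for a 95% CI).
#' @return c(ci_low, ci_high).
#' @export
fisher_ci <- function(r, n, alpha = 0.05) {
  assert_that(is_number(r) && abs(r) <= 1, "r must be in [-1, 1]")
  assert_that(is_count(n) && n > 3, "n must be an integer > 3")
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - alpha / 2)
  c(ci_low = tanh(z - q * se), ci_high = tanh(z + q * se))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param pairs an [paired_series()] (or data.frame with `ref`, `test`).
#' @param alpha two-sided level (default 0.05 for a 95% CI).
#' @return list `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_with_ci <- function(pairs, alpha = 0.05) {
  n <- nrow(pairs)
  assert_that(n >= 4, "need at least 4 pairs (got %d)", n)
  assert_that(stats::var(pairs$ref) > 0 && stats::var(pairs$test) > 0,
              "undefined correlation: constant input")
  r <- cor(pairs$ref, pairs$test)
  ci <- fisher_ci(min(max(r, -1), 1), n, alpha)
  list(r = r, ci_low = unname(ci[1]), ci_high = unname(ci[2]), n = n)
}

#' Steiger's z-test for two dependent overlapping correlations
#'
#' Compares `r(ref, A)` with `r(ref, B)` when A and B are measured on the
#' same records as the shared reference, using Steiger's (1980) modification
#' with the back-transformed mean correlation.
#'
#' @param r_a,r_b the two correlations sharing one variable.
#' @param r_ab correlation between the two non-shared variables.
#' @param n number of records.
#' @return list `z`, `p` (two-sided).
#' @export
steiger_test <- function(r_a, r_b, r_ab, n) {
  assert_that(is_number(r_a) && is_number(r_b) && is_number(r_ab),
              "correlations must be single numbers")
  assert_that(all(abs(c(r_a, r_b, r_ab)) <= 1), "correlations must be in [-1, 1]")
  assert_that(is_count(n) && n > 3, "n must be an integer > 3")
  z_a <- atanh(r_a)
  z_b <- atanh(r_b)
  rm2 <- (r_a^2 + r_b^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (z_a - z_b) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare two estimators' correlations against a shared reference
#'
#' @param pairs_a,pairs_b [paired_series()] objects with identical `t` and
#'   `ref` (the shared reference coordinate).
#' @param r_ab optional correlation between the two test series; computed
#'   from the data when NULL.
#' @return list `z`, `p`, `r_a`, `r_b`, `r_ab`, `n`.
#' @export
compare_dependent_correlations <- function(pairs_a, pairs_b, r_ab = NULL) {
  assert_that(nrow(pairs_a) == nrow(pairs_b),
              "series lengths differ (%d vs %d)", nrow(pairs_a),
              nrow(pairs_b))
  assert_that(max(abs(pairs_a$t - pairs_b$t)) < 1e-9 &&
                max(abs(pairs_a$ref - pairs_b$ref)) < 1e-9,
              "series must share the same reference coordinate")
  r_a <- cor(pairs_a$ref, pairs_a$test)
  r_b <- cor(pairs_b$ref, pairs_b$test)
  if (is.null(r_ab)) r_ab <- cor(pairs_a$test, pairs_b$test)
  st <- steiger_test(r_a, r_b, r_ab, nrow(pairs_a))
  c(st, list(r_a = r_a, r_b = r_b, r_ab = r_ab, n = nrow(pairs_a)))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = test - reference`; bias is `mean(d)` and the 95% limits
#' of agreement are `bias +/- 1.96 * SD(d)` with the sample SD (n - 1).
#'
#' @param pairs an [paired_series()].
#' @return list `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(pairs) {
  n <- nrow(pairs)
  assert_that(n >= 2, "need at least 2 pairs (got %d)", n)
  d <- pairs$test - pairs$ref
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s, n = n)
}

# delta pairs `delta_interval_s` apart (nearest sample within pair_tol_s)
trend_deltas <- function(pairs, delta_interval_s, pair_tol_s) {
  t <- pairs$t
  target <- t + delta_interval_s
  j <- findInterval(target, t)
  j_lo <- pmax(j, 1L)
  j_hi <- pmin(j + 1L, length(t))
  d_lo <- abs(t[j_lo] - target)
  d_hi <- abs(t[j_hi] - target)
  j_best <- ifelse(d_lo <= d_hi, j_lo, j_hi)
  ok <- pmin(d_lo, d_hi) <= pair_tol_s & j_best > seq_along(t)
  i <- which(ok)
  data.frame(d_ref = pairs$ref[j_best[i]] - pairs$ref[i],
             d_test = pairs$test[j_best[i]] - pairs$test[i])
}

#' Four-quadrant trend concordance with a central exclusion zone
#'
#' Changes are computed between measurements `delta_interval_s` seconds
#' apart. Pairs whose reference and test changes both (default; see
#' `exclusion_mode`) fall inside a central square of half-width
#' `exclusion_fraction` times the mean reference SV are excluded; the
#' concordance rate is the percentage of remaining pairs whose changes share
#' the same sign.
#'
#' @param pairs an [paired_series()].
#' @param delta_interval_s trend interval, s (default 60).
#' @param exclusion_fraction half-width of the exclusion zone as a fraction
#'   of the mean reference SV (default 0.10).
#' @param exclusion_mode exclude when `"both"` (default) or `"either"` of
#'   the two changes lies inside the zone.
#' @param pair_tol_s tolerance when matching samples `delta_interval_s`
#'   apart, s.
#' @return list `concordance_rate` (%; NA when every pair is excluded),
#'   `n_used`, `n_excluded`, `zone_half_width`.
#' @export
four_quadrant_concordance <- function(pairs, delta_interval_s = 60,
                                      exclusion_fraction = 0.10,
                                      exclusion_mode = c("both", "either"),
                                      pair_tol_s = 1) {
  exclusion_mode <- match.arg(exclusion_mode)
  assert_that(is_number(delta_interval_s) && delta_interval_s > 0,
              "delta_interval_s must be > 0")
  d <- trend_deltas(pairs, delta_interval_s, pair_tol_s)
  assert_that(nrow(d) >= 1,
              "series too short for any delta pair at interval %g s",
              delta_interval_s)
  zone <- exclusion_fraction * mean(pairs$ref)
  inside <- if (exclusion_mode == "both") {
    abs(d$d_ref) < zone & abs(d$d_test) < zone
  } else {
    abs(d$d_ref) < zone | abs(d$d_test) < zone
  }
  used <- d[!inside, , drop = FALSE]
  n_used <- nrow(used)
  rate <- if (n_used == 0) NA_real_ else
    100 * mean(sign(used$d_ref) == sign(used$d_test))
  list(concordance_rate = rate, n_used = n_used, n_excluded = sum(inside),
       zone_half_width = zone)
}

#' Performance-error metrics (MDPE, MDAPE, RMSE)
#'
#' Performance error of record j is
#' `PE_j = (reference_j - test_j) / test_j` (the prediction is the
#' denominator). MDPE is the median PE (bias), MDAPE the median absolute
#' PE (accuracy), RMSE the root-mean-square difference in mL.
#'
#' @param pairs an [paired_series()]; `test` must be strictly positive.
#' @return list `mdpe`, `mdape`, `rmse`, `n`.
#' @export
performance_errors <- function(pairs) {
  assert_that(nrow(pairs) >= 1, "empty series")
  assert_that(all(pairs$test > 0), "predicted SV must be > 0 (denominator)")
  pe <- (pairs$ref - pairs$test) / pairs$test
  list(mdpe = median(pe), mdape = median(abs(pe)),
       rmse = sqrt(mean((pairs$ref - pairs$test)^2)), n = nrow(pairs))
}

#' Evaluation configuration for phase-stratified reports
#'
#' @param delta_interval_s trend-analysis interval, s. Consecutive 2-s
#'   records differ mostly by noise, so the default compares measurements
#'   60 s apart; reports state the interval used.
#' @param exclusion_fraction central exclusion zone half-width as a fraction
#'   of the mean reference SV.
#' @param exclusion_mode `"both"` or `"either"` (which deltas must be inside
#'   the zone to exclude the pair).
#' @param alpha level for correlation CIs.
#' @param pair_tol_s pairing tolerance for trend deltas, s.
#' @export
eval_config <- function(delta_interval_s = 60, exclusion_fraction = 0.10,
                        exclusion_mode = c("both", "either"), alpha = 0.05,
                        pair_tol_s = 1) {
  exclusion_mode <- match.arg(exclusion_mode)
  list(delta_interval_s = delta_interval_s,
       exclusion_fraction = exclusion_fraction,
       exclusion_mode = exclusion_mode, alpha = alpha,
       pair_tol_s = pair_tol_s)
}

# one row of statistics; NA cells where n is below a statistic's minimum
eval_row <- function(pairs, config) {
  out <- list(n = nrow(pairs), r = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, bias = NA_real_, sd_diff = NA_real_,
              loa_low = NA_real_, loa_high = NA_real_,
              concordance_rate = NA_real_, n_delta_used = 0L,
              n_delta_excluded = 0L, mdpe = NA_real_, mdape = NA_real_,
              rmse = NA_real_)
  if (nrow(pairs) >= 4 && stats::var(pairs$ref) > 0 &&
        stats::var(pairs$test) > 0) {
    pc <- pearson_with_ci(pairs, alpha = config$alpha)
    out[c("r", "ci_low", "ci_high")] <- pc[c("r", "ci_low", "ci_high")]
  }
  if (nrow(pairs) >= 2) {
    ba <- bland_altman(pairs)
    out[c("bias", "sd_diff", "loa_low", "loa_high")] <-
      ba[c("bias", "sd_diff", "loa_low", "loa_high")]
  }
  if (nrow(pairs) >= 1) {
    pe <- performance_errors(pairs)
    out[c("mdpe", "mdape", "rmse")] <- pe[c("mdpe", "mdape", "rmse")]
  }
  d <- trend_deltas(pairs, config$delta_interval_s, config$pair_tol_s)
  if (nrow(d) >= 1) {
    zone <- config$exclusion_fraction * mean(pairs$ref)
    inside <- if (config$exclusion_mode == "both") {
      abs(d$d_ref) < zone & abs(d$d_test) < zone
    } else {
      abs(d$d_ref) < zone | abs(d$d_test) < zone
    }
    used <- d[!inside, , drop = FALSE]
    out$n_delta_used <- nrow(used)
    out$n_delta_excluded <- sum(inside)
    out$concordant <- sum(sign(used$d_ref) == sign(used$d_test))
    out$concordance_rate <- if (nrow(used) == 0) NA_real_ else
      100 * out$concordant / nrow(used)
  } else {
    out$concordant <- 0L
  }
  out
}

#' Phase-stratified method-comparison report
#'
#' Computes every statistic per surgical phase and overall. Trend deltas
#' never span a phase boundary: the overall concordance pools the per-phase
#' delta pairs. Cells whose phase has too few records for a statistic are
#' reported as NA. Correlation and Bland-Altman for the overall row are
#' computed on the pooled records.
#'
#' @param pairs an [paired_series()] with phase labels.
#' @param config an [eval_config()].
#' @return data.frame of class `sv_eval_report`: one row per phase plus
#'   `overall`; attributes `config` and `n_total`.
#' @export
phase_report <- function(pairs, config = eval_config()) {
  assert_that(inherits(pairs, "sv_paired_series"),
              "pairs must be a paired_series()")
  phases <- levels(droplevels(pairs$phase[!is.na(pairs$phase)]))
  rows <- list()
  pooled_used <- 0L; pooled_excluded <- 0L; pooled_concordant <- 0L
  for (ph in phases) {
    sub <- pairs[which(pairs$phase == ph), , drop = FALSE]
    r <- eval_row(sub, config)
    pooled_used <- pooled_used + r$n_delta_used
    pooled_excluded <- pooled_excluded + r$n_delta_excluded
    pooled_concordant <- pooled_concordant + r$concordant
    r$concordant <- NULL
    rows[[ph]] <- data.frame(phase = ph, r, stringsAsFactors = FALSE)
  }
  overall <- eval_row(pairs, config)
  if (length(phases) > 0) {  # never let overall deltas span a boundary
    overall$n_delta_used <- pooled_used
    overall$n_delta_excluded <- pooled_excluded
    overall$concordance_rate <- if (pooled_used == 0) NA_real_ else
      100 * pooled_concordant / pooled_used
  }
  overall$concordant <- NULL
  rows[["overall"]] <- data.frame(phase = "overall", overall,
                                  stringsAsFactors = FALSE)
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "config") <- config
  attr(rep, "n_total") <- nrow(pairs)
  class(rep) <- c("sv_eval_report", "data.frame")
  rep
}
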