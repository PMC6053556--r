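#' Tie-corrected Spearman rank correlation with t-approximation p-value
#'
#' Wraps [stats::cor.test()] (`method = "spearman"`, asymptotic): rho is the
#' Pearson correlation of average ranks (ties averaged) and the p-value comes
#' from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom — appropriate for over-dispersed, non-normal
#' count data.
#'
#' @param x,y paired non-negative counts.
#' @return A list with `rho`, `p`, `df` (`n - 2`) and `n`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(1, 2, 3, 4))$rho
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs for a rank correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: one margin has zero variance", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, df = n - 2L, n = n)
}

#' Fisher's variance-stabilizing transformation of a correlation
#'
#' @param rho correlation coefficient(s), strictly inside (-1, 1).
#' @return `atanh(rho)`.
#' @examples
#' fisher_z(0.84)  # 1.22 to 2 dp
#' @export
fisher_z <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop("`rho` must lie strictly within (-1, 1)", call. = FALSE)
  }
  atanh(rho)
}

#' Least-squares regression through the origin
#'
#' Fits `y = b * x` with no intercept via [stats::lm()], the standard way to
#' compare device counts with observer counts on a 1:1 scale: the slope is
#' `sum(x * y) / sum(x^2)`, its standard error uses residual degrees of
#' freedom `n - 1`, and the confidence interval uses the matching t quantile
#' (set `normal_ci = TRUE` to force the 1.96-style normal multiplier).
#'
#' @param x observer counts (not all zero).
#' @param y device counts.
#' @param ci_level confidence level for the slope interval.
#' @param normal_ci use a normal instead of a t multiplier.
#' @return A list with `slope`, `slope_se`, `ci_low`, `ci_high`, `df`
#'   (`n - 1`) and `n`.
#' @examples
#' through_origin_fit(1:5, 2 * (1:5))$slope
#' @export
through_origin_fit <- function(x, y, ci_level = 0.95, normal_ci = FALSE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs to fit a slope", call. = FALSE)
  if (all(x == 0)) stop("degenerate fit: all observer counts are zero", call. = FALSE)
  fit <- stats::lm(y ~ 0 + x)
  # suppress summary.lm's "essentially perfect fit" chatter in the exact case
  est <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(est[1, 1])
  se <- unname(est[1, 2])
  mult <- if (normal_ci) stats::qnorm(1 - (1 - ci_level) / 2) else
    stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  list(slope = slope, slope_se = se,
       ci_low = slope - mult * se, ci_high = slope + mult * se,
       df = n - 1L, n = n)
}

#' Extract paired observer/device session counts for one recorder option
#'
#' @param campaign a `bittern_campaign`.
#' @param device_channel the recorder channel (`"MONO"` or `"STEREO"`).
#' @param observer_channel the reference channel, normally `"OBS"`.
#' @return A tibble of sessions where both channels ran concurrently:
#'   `session_id`, `observer_count`, `device_count` (zero-call sessions
#'   count as 0).
#' @export
paired_counts <- function(campaign, device_channel,
                          observer_channel = "OBS") {
  stopifnot(inherits(campaign, "bittern_campaign"))
  have <- strsplit(campaign$sessions$channels_present, "+", fixed = TRUE)
  keep <- vapply(have, function(chs) {
    all(c(device_channel, observer_channel) %in% chs)
  }, logical(1))
  ids <- campaign$sessions$session_id[keep]
  count_in <- function(sid, ch) {
    sum(campaign$calls$session_id == sid & campaign$calls$channel == ch)
  }
  tibble::tibble(
    session_id = ids,
    observer_count = vapply(ids, count_in, integer(1), ch = observer_channel),
    device_count = vapply(ids, count_in, integer(1), ch = device_channel)
  )
}

new_calibration_result <- function(option, pairs, ci_level = 0.95) {
  x <- pairs$observer_count
  y <- pairs$device_count
  rho_stats <- tryCatch(spearman_cor(x, y),
                        error = function(e) list(rho = NA_real_, p = NA_real_,
                                                 df = length(x) - 2L,
                                                 n = length(x)))
  fit <- through_origin_fit(x, y, ci_level = ci_level)
  structure(list(
    option = option,
    rho = rho_stats$rho,
    z = if (is.na(rho_stats$rho) || abs(rho_stats$rho) >= 1) NA_real_ else
      fisher_z(rho_stats$rho),
    p = rho_stats$p,
    df = rho_stats$df,
    n = rho_stats$n,
    slope = fit$slope, slope_se = fit$slope_se,
    ci_low = fit$ci_low, ci_high = fit$ci_high,
    note = if (is.na(rho_stats$rho)) "rho undefined (zero-variance margin)" else NA_character_,
    pairs = pairs
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s (n = %d)\n", x$option, x$n))
  cat(sprintf("  rho = %s  z = %s  p = %s  df = %d\n",
              format(round(x$rho, 3)), format(round(x$z, 3)),
              format.pval(x$p, digits = 3), x$df))
  cat(sprintf("  through-origin slope = %.3f (SE %.3f), 95%% CI [%.3f, %.3f]\n",
              x$slope, x$slope_se, x$ci_low, x$ci_high))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Device-versus-observer calibration table across recorder options
#'
#' For each recorder-by-processing option, pairs every concurrent session's
#' observer call count with the device call count and reports the
#' tie-corrected Spearman rho with Fisher z and t-approximation p, plus the
#' through-origin slope with SE and confidence interval — one row per
#' option. Options without any paired session are dropped with a warning.
#'
#' @param campaign a `bittern_campaign`.
#' @param options character vector of option labels to tabulate.
#' @param channel_map named character vector mapping option label to the
#'   campaign channel holding that option's counts.
#' @param ci_level slope confidence level.
#' @return A tibble with columns `option`, `z`, `rho`, `p`, `df`, `n`,
#'   `slope`, `slope_se`, `ci_low`, `ci_high`.
#' @examples
#' camp <- simulate_campaign(campaign_spec(seed = 7))
#' calibration_table(camp)
#' @export
calibration_table <- function(campaign,
                              options = c("MONO-VISUAL", "MONO-AUDIBLE",
                                          "STEREO-VISUAL", "STEREO-AUDIBLE"),
                              channel_map = c(`MONO-VISUAL` = "MONO",
                                              `MONO-AUDIBLE` = "MONO",
                                              `STEREO-VISUAL` = "STEREO",
                                              `STEREO-AUDIBLE` = "STEREO"),
                              ci_level = 0.95) {
  rows <- lapply(options, function(opt) {
    ch <- channel_map[[opt]]
    if (is.null(ch)) stop("no channel mapping for option ", opt, call. = FALSE)
    pairs <- paired_counts(campaign, ch)
    if (nrow(pairs) == 0) {
      warning("option ", opt, " has no paired sessions; omitted", call. = FALSE)
      return(NULL)
    }
    r <- new_calibration_result(opt, pairs, ci_level = ci_level)
    tibble::tibble(option = opt, z = r$z, rho = r$rho, p = r$p, df = r$df,
                   n = r$n, slope = r$slope, slope_se = r$slope_se,
                   ci_low = r$ci_low, ci_high = r$ci_high)
  })
  dplyr::bind_rows(rows)
}

#' Calibrate stereo-audible individual counts against observer counts
#'
#' For every session with a stereo recording, counts individuals on the
#' recording with [assign_stereo_audible()] and pairs that against the
#' field-observer minimum count from [assign_observer()] (or the true number
#' of calling birds when `use_truth = TRUE` on simulated data), then reports
#' the same rank-correlation and through-origin-slope statistics as
#' [calibration_table()].
#'
#' @param campaign a `bittern_campaign` whose sessions include a STEREO
#'   channel.
#' @param use_truth pair against `truth_n_calling` instead of the observer
#'   estimate (simulated campaigns only).
#' @param bearing_threshold_deg passed to [assign_observer()].
#' @param ci_level slope confidence level.
#' @return A `calibration_result` (with `pairs` attached).
#' @export
individuals_calibration <- function(campaign, use_truth = FALSE,
                                    bearing_threshold_deg = 10,
                                    ci_level = 0.95) {
  stopifnot(inherits(campaign, "bittern_campaign"))
  need <- if (use_truth) "STEREO" else c("STEREO", "OBS")
  have <- strsplit(campaign$sessions$channels_present, "+", fixed = TRUE)
  keep <- vapply(have, function(chs) all(need %in% chs), logical(1))
  ids <- campaign$sessions$session_id[keep]
  if (length(ids) == 0) stop("no sessions carry a STEREO channel", call. = FALSE)
  device <- vapply(ids, function(sid) {
    d <- campaign$calls[campaign$calls$session_id == sid &
                          campaign$calls$channel == "STEREO", , drop = FALSE]
    assign_stereo_audible(d)$n_individuals
  }, integer(1))
  observer <- if (use_truth) {
    campaign$sessions$truth_n_calling[keep]
  } else {
    vapply(ids, function(sid) {
      d <- campaign$calls[campaign$calls$session_id == sid &
                            campaign$calls$channel == "OBS", , drop = FALSE]
      d <- d[order(d$time_s), , drop = FALSE]
      assign_observer(d, bearing_threshold_deg)$n_individuals
    }, integer(1))
  }
  pairs <- tibble::tibble(session_id = ids,
                          observer_count = as.integer(observer),
                          device_count = device)
  new_calibration_result("STEREO-AUDIBLE individuals", pairs,
                         ci_level = ci_level)
}

#' Scatter plot of device versus observer counts with through-origin fit
#'
#' @param pairs tibble with `observer_count` and `device_count` (as returned
#'   by [paired_counts()] or attached to a `calibration_result`).
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_calibration <- function(pairs, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_calibration() needs the ggplot2 package", call. = FALSE)
  }
  fit <- through_origin_fit(pairs$observer_count, pairs$device_count)
  ggplot2::ggplot(pairs, ggplot2::aes(observer_count, device_count)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = fit$slope, intercept = 0, colour = "steelblue") +
    ggplot2::geom_count(alpha = 0.6) +
    ggplot2::labs(x = "Observer count", y = "Device count", title = title,
                  subtitle = sprintf("through-origin slope = %.2f (SE %.2f)",
                                     fit$slope, fit$slope_se)) +
    ggplot2::theme_minimal()
}
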