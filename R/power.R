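#' Two-sided permutation test for a difference in mean session counts
#'
#' Permutes group labels of the pooled counts and compares the observed
#' difference in means against the permutation distribution. The observed
#' statistic is included in the reference set, so the Monte-Carlo p-value is
#' `(1 + #{|T*| >= |T_obs|}) / (n_perm + 1)` and can never fall below
#' `1 / (n_perm + 1)`. With `n_perm = "exhaustive"` all distinct label
#' assignments are enumerated and the p-value is the exact proportion of
#' assignments at least as extreme.
#'
#' @param counts_a,counts_b non-empty numeric vectors of session counts.
#' @param n_perm number of random permutations, or `"exhaustive"`.
#' @param seed optional integer seed (random permutations only).
#' @return The two-sided p-value.
#' @examples
#' permutation_mean_diff_test(c(0, 0, 0, 0), c(100, 100, 100, 100),
#'                            n_perm = "exhaustive")  # 2/70
#' @export
permutation_mean_diff_test <- function(counts_a, counts_b, n_perm = 999,
                                       seed = NULL) {
  if (length(counts_a) == 0 || length(counts_b) == 0) {
    stop("both count vectors must be non-empty", call. = FALSE)
  }
  na <- length(counts_a)
  pooled <- c(counts_a, counts_b)
  n <- length(pooled)
  t_obs <- mean(counts_a) - mean(counts_b)
  tol <- 1e-8 * (abs(t_obs) + 1)
  if (identical(n_perm, "exhaustive")) {
    if (choose(n, na) > 5e5) {
      stop("exhaustive enumeration infeasible for this sample size", call. = FALSE)
    }
    splits <- utils::combn(n, na)
    t_all <- apply(splits, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    return(mean(abs(t_all) >= abs(t_obs) - tol))
  }
  stop_if_not_count(n_perm, "n_perm", min = 1L)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      i <- sample.int(n, na)
      if (abs(mean(pooled[i]) - mean(pooled[-i])) >= abs(t_obs) - tol) {
        hits <- hits + 1L
      }
    }
    (1 + hits) / (n_perm + 1)
  })
}

#' Specification for a simulation-based power analysis
#'
#' @param design a [monitoring_design()]; each simulated campaign comprises
#'   `n_stations * n_occasions` sessions.
#' @param baseline_rate expected detected call sequences per session under
#'   the baseline.
#' @param effect proportional change in calling rate to detect (e.g. `0.10`
#'   or `-0.10` for a 10 percent shift); must exceed -1.
#' @param alpha significance level.
#' @param n_replicates Monte-Carlo replicates.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(design = monitoring_design(), baseline_rate = 3,
                       effect = 0.10, alpha = 0.05, n_replicates = 500,
                       n_perm = 199, seed = 1) {
  stopifnot(inherits(design, "monitoring_design"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (effect <= -1) stop("`effect` must exceed -1", call. = FALSE)
  stop_if_not_count(n_replicates, "n_replicates", min = 1L)
  structure(list(design = design, baseline_rate = baseline_rate,
                 effect = effect, alpha = alpha,
                 n_replicates = n_replicates, n_perm = n_perm, seed = seed),
            class = "power_spec")
}

#' Estimate power to detect a proportional change in calling rate
#'
#' For each replicate, two campaigns of `n_stations * n_occasions` sessions
#' are simulated under the survey model's session-count law
#' ([simulate_session_counts()]): one at the baseline rate, one at
#' `baseline_rate * (1 + effect)`. The two sets of session counts are
#' compared with [permutation_mean_diff_test()] and power is the fraction of
#' replicates rejecting at `alpha`.
#'
#' @param spec a [power_spec()].
#' @return An object of class `power_result`: `power`, `mc_se`
#'   (`sqrt(power * (1 - power) / n_replicates)`), `n_replicates` and the
#'   spec.
#' @examples
#' estimate_power(power_spec(monitoring_design(n_stations = 10),
#'                           n_replicates = 50, seed = 1))
#' @export
estimate_power <- function(spec = power_spec()) {
  stopifnot(inherits(spec, "power_spec"))
  s <- spec$design$n_stations * spec$design$n_occasions
  with_seed(spec$seed, {
    reject <- logical(spec$n_replicates)
    for (r in seq_len(spec$n_replicates)) {
      a <- simulate_session_counts(s, spec$baseline_rate)
      b <- simulate_session_counts(s, spec$baseline_rate * (1 + spec$effect))
      p <- permutation_mean_diff_test(a, b, n_perm = spec$n_perm)
      reject[r] <- p <= spec$alpha
    }
    pw <- mean(reject)
    structure(list(power = pw,
                   mc_se = sqrt(pw * (1 - pw) / spec$n_replicates),
                   n_replicates = spec$n_replicates, spec = spec),
              class = "power_result")
  })
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> power = %.3f (MC SE %.3f) | effect %+.0f%%, %d x %d sessions, alpha %.2f\n",
    x$power, x$mc_se, 100 * x$spec$effect, x$spec$design$n_stations,
    x$spec$design$n_occasions, x$spec$alpha))
  invisible(x)
}

#' Power over a grid of effects and design sizes
#'
#' @param spec base [power_spec()]; grid values override its `effect` and
#'   design `n_occasions` / `n_stations`.
#' @param effects,n_occasions,n_stations vectors of grid values.
#' @return A tibble with one row per grid point: `effect`, `n_stations`,
#'   `n_occasions`, `power`, `mc_se`.
#' @export
power_grid <- function(spec = power_spec(),
                       effects = spec$effect,
                       n_occasions = spec$design$n_occasions,
                       n_stations = spec$design$n_stations) {
  grid <- expand.grid(effect = effects, n_stations = n_stations,
                      n_occasions = n_occasions)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- monitoring_design(n_stations = grid$n_stations[i],
                           n_occasions = grid$n_occasions[i],
                           count_duration_min = spec$design$count_duration_min,
                           years = spec$design$years)
    sp <- power_spec(d, baseline_rate = spec$baseline_rate,
                     effect = grid$effect[i], alpha = spec$alpha,
                     n_replicates = spec$n_replicates, n_perm = spec$n_perm,
                     seed = spec$seed + i)
    res <- estimate_power(sp)
    tibble::tibble(effect = grid$effect[i], n_stations = grid$n_stations[i],
                   n_occasions = grid$n_occasions[i],
                   power = res$power, mc_se = res$mc_se)
  })
  dplyr::bind_rows(rows)
}
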