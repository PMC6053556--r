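# Independent brute-force oracles, deliberately written from scratch against
# the documented rules rather than sharing code with the package internals.

# circular bearing difference, re-derived
o_circ <- function(a, b) {
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

# circular mean via complex arithmetic (different route than the package)
o_cmean <- function(deg) {
  z <- mean(complex(modulus = 1, argument = deg * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

# brute-force observer-criteria assignment: clusters kept as raw data frames,
# acceptance re-evaluated from the member rows every time. Expects calls in
# processing (time) order with no duplicated timestamps.
oracle_assign_observer <- function(calls, thr = 10, soft_start = TRUE) {
  lev <- c(low = 1, med = 2, high = 3)
  calls <- as.data.frame(calls)
  members <- list()  # list of data frames
  assignment <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    dists <- rep(Inf, length(members))
    for (j in seq_along(members)) {
      m <- members[[j]]
      ref <- o_cmean(m$bearing_deg)
      d <- o_circ(row$bearing_deg, ref)
      if (d > thr) next
      seen_vols <- unique(m$volume_class)
      vol_ok <- row$volume_class %in% seen_vols
      if (!vol_ok && soft_start && nrow(m) == 1 &&
          abs(lev[row$volume_class] - lev[m$volume_class]) == 1 &&
          d <= thr / 2) {
        vol_ok <- TRUE
      }
      if (!vol_ok) next
      if (nrow(m) >= 2 && !(row$boom_count %in% m$boom_count)) next
      dists[j] <- d
    }
    if (all(!is.finite(dists))) {
      members[[length(members) + 1]] <- row
      assignment[i] <- length(members)
    } else {
      j <- which.min(dists)  # first minimum = lowest cluster id
      members[[j]] <- rbind(members[[j]], row)
      assignment[i] <- j
    }
  }
  list(n = length(members), assignment = assignment)
}

# exhaustive distinct (volume, direction) pair count
oracle_stereo_count <- function(calls) {
  if (nrow(calls) == 0) return(0L)
  combos <- character(0)
  for (i in seq_len(nrow(calls))) {
    cm <- paste0(calls$volume_class[i], "|", calls$stereo_channel[i])
    if (!cm %in% combos) combos <- c(combos, cm)
  }
  length(combos)
}

# average ranks by hand, then Pearson's r by the sum formulas
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# through-origin slope by direct 1-D minimisation of the residual sum of
# squares, SE from the textbook formula
oracle_through_origin <- function(x, y) {
  rss <- function(b) sum((y - b * x)^2)
  span <- max(abs(y)) / max(abs(x[x != 0])) + 1
  slope <- stats::optimize(rss, interval = c(-span, span), tol = 1e-12)$minimum
  n <- length(x)
  se <- sqrt(rss(slope) / (n - 1) / sum(x^2))
  list(slope = slope, se = se)
}

# random small call sets for oracle cross-checks
random_calls <- function(n_calls, stereo = FALSE) {
  calls <- data.frame(
    time_s = sort(sample(seq(0, 9000) / 10, n_calls)),
    bearing_deg = runif(n_calls, 0, 360) %% 360,
    volume_class = sample(c("low", "med", "high"), n_calls, replace = TRUE),
    boom_count = 1L + rpois(n_calls, 2)
  )
  if (stereo) {
    calls$stereo_channel <- sample(c("left", "right"), n_calls, replace = TRUE)
  }
  calls
}
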