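# internal helpers shared across modules

#' @importFrom stats rpois runif rnorm rbinom rgamma coef pt qt
#' @importFrom utils read.delim write.csv read.csv
NULL

# round half away from zero; display convention for all printed currency
# and percentage cells (base round() would give 112.5 -> 112, not 113)
round_display <- function(x) sign(x) * floor(abs(x) + 0.5)

# circular absolute difference between bearings, in [0, 180]
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# circular mean of bearings, in [0, 360)
circ_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  m %% 360
}

# evaluate `code` under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

VOLUME_LEVELS <- c("low", "med", "high")
CHANNEL_LEVELS <- c("OBS", "MONO", "STEREO")
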