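#' Simulate a population of calling male bitterns around a listening station
#'
#' Each simulated bird ("agent") sits at a fixed bearing and distance from the
#' listening point and calls at its own expected rate per 15-min session.
#' Bearings are uniform on a configurable arc: a station in the middle of a
#' large wetland hears birds over the full 360 degrees, while a station on a
#' straight edge hears at most 180 degrees in front of the recorder.
#'
#' Each male is given a characteristic number of booms per call sequence,
#' drawn once per bird from a shifted Poisson (`1 + rpois(boom_mean - 1)`).
#' Within-individual boom counts are stereotyped: every sequence the bird
#' emits repeats its characteristic count (see [simulate_session()] for
#' optional per-call jitter). This mirrors how field observers use boom
#' counts as an individual cue.
#'
#' @param n_birds number of calling males (>= 0).
#' @param spatial_extent arc, in degrees (0, 360], over which bearings are
#'   drawn uniformly starting at 0.
#' @param seed optional integer seed; the current RNG state is restored
#'   afterwards.
#' @param distance_range range (m) for uniform bird-to-station distances.
#' @param call_rate_mean expected call sequences per 15-min session, averaged
#'   over birds; per-bird rates are Gamma-distributed around it.
#' @param call_rate_shape Gamma shape for between-bird call-rate heterogeneity.
#' @param boom_mean population mean booms per call sequence (>= 1).
#' @param loudness source loudness scalar common to all birds.
#'
#' @return A tibble with one row per bird: `id`, `bearing_deg`, `distance_m`,
#'   `call_rate`, `boom_mean` (the bird's characteristic booms per sequence)
#'   and `loudness`.
#' @examples
#' simulate_population(6, spatial_extent = 180, seed = 1)
#' @export
simulate_population <- function(n_birds,
                                spatial_extent = 360,
                                seed = NULL,
                                distance_range = c(100, 1000),
                                call_rate_mean = 3,
                                call_rate_shape = 4,
                                boom_mean = 3,
                                loudness = 1) {
  stop_if_not_count(n_birds, "n_birds")
  if (!is.numeric(spatial_extent) || spatial_extent <= 0 || spatial_extent > 360) {
    stop("`spatial_extent` must be in (0, 360]", call. = FALSE)
  }
  if (boom_mean < 1) stop("`boom_mean` must be >= 1", call. = FALSE)
  with_seed(seed, {
    tibble::tibble(
      id = seq_len(n_birds),
      bearing_deg = (stats::runif(n_birds) * spatial_extent) %% 360,
      distance_m = stats::runif(n_birds, distance_range[1], distance_range[2]),
      call_rate = stats::rgamma(n_birds, shape = call_rate_shape,
                                rate = call_rate_shape / call_rate_mean),
      boom_mean = 1L + stats::rpois(n_birds, max(boom_mean - 1, 0)),
      loudness = rep_len(loudness, n_birds)
    )
  })
}

#' Detection and annotation-noise model for a survey channel
#'
#' Describes how an observer or a recorder channel imperfectly registers the
#' call sequences actually emitted: per-channel detection probability
#' (optionally distance-dependent), wrapped-Gaussian bearing jitter, and
#' adjacent-class volume misclassification.
#'
#' @param p_detect named vector or list over channels (`OBS`, `MONO`,
#'   `STEREO`). Each element is either a probability in \[0, 1\] or a
#'   function of distance (m) returning probabilities.
#' @param bearing_noise_sd sd (degrees) of bearing jitter applied
#'   independently per detected copy.
#' @param volume_misclass_p probability that a perceived volume class flips
#'   to an adjacent class (`low`/`high` flip to `med`; `med` flips either way).
#' @param volume_cuts two increasing cut points on received level
#'   (`loudness / (distance_m / 100)^2`) separating `low`/`med`/`high`.
#'
#' @return An object of class `detection_spec`.
#' @examples
#' detection_spec(p_detect = c(OBS = 1, MONO = 0.67, STEREO = 0.9))
#' @export
detection_spec <- function(p_detect = c(OBS = 1, MONO = 1, STEREO = 1),
                           bearing_noise_sd = 5,
                           volume_misclass_p = 0,
                           volume_cuts = c(0.04, 0.25)) {
  p_detect <- as.list(p_detect)
  if (is.null(names(p_detect)) || !all(names(p_detect) %in% CHANNEL_LEVELS)) {
    stop("`p_detect` must be named with channels among OBS, MONO, STEREO",
         call. = FALSE)
  }
  for (p in p_detect) {
    if (is.numeric(p) && (p < 0 || p > 1)) {
      stop("detection probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (bearing_noise_sd < 0) stop("`bearing_noise_sd` must be >= 0", call. = FALSE)
  if (volume_misclass_p < 0 || volume_misclass_p > 1) {
    stop("`volume_misclass_p` must lie in [0, 1]", call. = FALSE)
  }
  if (length(volume_cuts) != 2 || diff(volume_cuts) <= 0) {
    stop("`volume_cuts` must be two increasing cut points", call. = FALSE)
  }
  structure(list(p_detect = p_detect,
                 bearing_noise_sd = bearing_noise_sd,
                 volume_misclass_p = volume_misclass_p,
                 volume_cuts = volume_cuts),
            class = "detection_spec")
}

# detection probability for a channel at given distances
detect_p_of <- function(detection, channel, distance_m) {
  p <- detection$p_detect[[channel]]
  if (is.null(p)) p <- 1
  if (is.function(p)) p <- p(distance_m) else p <- rep_len(p, length(distance_m))
  pmin(pmax(p, 0), 1)
}

# received-level volume classification: inverse-square attenuation
volume_class_of <- function(loudness, distance_m, cuts) {
  received <- loudness / (distance_m / 100)^2
  out <- rep("high", length(received))
  out[received < cuts[2]] <- "med"
  out[received < cuts[1]] <- "low"
  out
}

# flip volume classes to an adjacent class with probability p
misclassify_volume <- function(volume_class, p) {
  if (p <= 0 || length(volume_class) == 0) return(volume_class)
  flip <- stats::runif(length(volume_class)) < p
  up <- stats::runif(length(volume_class)) < 0.5
  out <- volume_class
  out[flip & volume_class == "low"] <- "med"
  out[flip & volume_class == "high"] <- "med"
  out[flip & volume_class == "med"] <- ifelse(up[flip & volume_class == "med"],
                                              "high", "low")
  out
}

#' Stereo channel implied by a call bearing and recorder orientation
#'
#' A two-microphone recorder splits the horizon into a left and a right
#' half-plane about its heading axis. Bearings strictly in the half-plane to
#' the left of the heading map to `"left"`; all others, including bearings
#' exactly on the heading axis (dead ahead or dead astern), map to `"right"`
#' (documented tie-break).
#'
#' @param bearing_deg call bearing(s), degrees.
#' @param recorder_heading_deg recorder forward heading, degrees.
#' @return Character vector of `"left"` / `"right"`.
#' @examples
#' stereo_channel_of(c(90, 270, 0), recorder_heading_deg = 0)
#' @export
stereo_channel_of <- function(bearing_deg, recorder_heading_deg = 0) {
  if (!all(is.finite(bearing_deg)) || !all(is.finite(recorder_heading_deg))) {
    stop("bearings and heading must be finite", call. = FALSE)
  }
  rel <- (bearing_deg - recorder_heading_deg) %% 360
  out <- rep("right", length(rel))
  out[rel > 180 & rel < 360] <- "left"
  out
}

#' Simulate one 15-minute call-count session
#'
#' Each bird emits a Poisson number of call sequences (mean `call_rate`) at
#' uniform times within the session. Every emitted sequence is then
#' independently detected on each requested channel with that channel's
#' detection probability; detected copies carry jittered bearings, a
#' (possibly misclassified) volume class, the bird's boom count, and — for
#' the STEREO channel — a left/right assignment from the true geometry via
#' [stereo_channel_of()].
#'
#' @param agents tibble from [simulate_population()].
#' @param detection a [detection_spec()].
#' @param channels non-empty subset of `c("OBS", "MONO", "STEREO")`.
#' @param seed optional integer seed.
#' @param station_id,occasion session labels.
#' @param recorder_heading_deg stereo recorder heading, degrees.
#' @param duration_min session length in minutes.
#' @param boom_jitter_p probability that an individual call deviates by one
#'   boom from the bird's characteristic count (default 0: stereotyped).
#'
#' @return An object of class `count_session`: a list with `station_id`,
#'   `occasion`, `duration_min`, `channels_present`, `calls` (named list of
#'   per-channel tibbles sorted by `time_s`) and `truth_n_calling` (number of
#'   birds that emitted at least one sequence).
#' @examples
#' pop <- simulate_population(4, seed = 1)
#' simulate_session(pop, detection_spec(), seed = 2)
#' @export
simulate_session <- function(agents,
                             detection = detection_spec(),
                             channels = c("OBS", "MONO", "STEREO"),
                             seed = NULL,
                             station_id = "S001",
                             occasion = 1L,
                             recorder_heading_deg = 0,
                             duration_min = 15,
                             boom_jitter_p = 0) {
  if (length(channels) == 0) stop("`channels` must be non-empty", call. = FALSE)
  if (!all(channels %in% CHANNEL_LEVELS)) {
    stop("`channels` must be a subset of OBS, MONO, STEREO", call. = FALSE)
  }
  with_seed(seed, {
    n_seq <- if (nrow(agents) > 0) stats::rpois(nrow(agents), agents$call_rate) else integer(0)
    idx <- rep(seq_len(nrow(agents)), n_seq)
    n_total <- length(idx)
    boom <- agents$boom_mean[idx]
    if (boom_jitter_p > 0 && n_total > 0) {
      jit <- stats::runif(n_total) < boom_jitter_p
      boom <- pmax(1L, boom + ifelse(stats::runif(n_total) < 0.5, -1L, 1L) * jit)
    }
    emitted <- tibble::tibble(
      truth_id = if (n_total) agents$id[idx] else integer(0),
      time_s = stats::runif(n_total, 0, duration_min * 60),
      bearing_true = agents$bearing_deg[idx],
      distance_m = agents$distance_m[idx],
      boom_count = as.integer(boom),
      volume_true = volume_class_of(agents$loudness[idx], agents$distance_m[idx],
                                    detection$volume_cuts)
    )
    calls <- lapply(channels, function(ch) {
      p <- detect_p_of(detection, ch, emitted$distance_m)
      keep <- if (n_total) stats::runif(n_total) < p else logical(0)
      det <- emitted[keep, , drop = FALSE]
      k <- nrow(det)
      bearing <- (det$bearing_true +
                    stats::rnorm(k, 0, detection$bearing_noise_sd)) %% 360
      vol <- misclassify_volume(det$volume_true, detection$volume_misclass_p)
      out <- tibble::tibble(
        time_s = det$time_s,
        bearing_deg = bearing,
        volume_class = vol,
        boom_count = det$boom_count,
        stereo_channel = if (ch == "STEREO") {
          stereo_channel_of(det$bearing_true, recorder_heading_deg)
        } else {
          rep(NA_character_, k)
        },
        truth_id = det$truth_id
      )
      out[order(out$time_s), , drop = FALSE]
    })
    names(calls) <- channels
    structure(list(
      station_id = station_id,
      occasion = as.integer(occasion),
      duration_min = duration_min,
      channels_present = channels,
      calls = calls,
      truth_n_calling = sum(n_seq > 0)
    ), class = "count_session")
  })
}

#' @export
print.count_session <- function(x, ...) {
  cat(sprintf("<count_session> station %s, occasion %d (%g min)\n",
              x$station_id, x$occasion, x$duration_min))
  for (ch in x$channels_present) {
    cat(sprintf("  %-6s %3d call sequences\n", ch, nrow(x$calls[[ch]])))
  }
  cat(sprintf("  true number of calling birds: %d\n", x$truth_n_calling))
  invisible(x)
}

#' Specification of a paired observer/recorder campaign
#'
#' Defaults describe a 137-session campaign in which 43 sessions run all
#' three channels concurrently (OBS + MONO + STEREO), 80 pair an observer
#' with a mono recorder, and 14 pair an observer with a stereo recorder,
#' cycled over stations at least 400 m apart.
#'
#' @param n_three_way sessions with OBS + MONO + STEREO.
#' @param n_obs_mono sessions with OBS + MONO.
#' @param n_obs_stereo sessions with OBS + STEREO.
#' @param station_count number of distinct stations to cycle over.
#' @param seed integer seed driving the whole campaign.
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(n_three_way = 43,
                          n_obs_mono = 80,
                          n_obs_stereo = 14,
                          station_count = 40,
                          seed = 1) {
  stop_if_not_count(n_three_way, "n_three_way")
  stop_if_not_count(n_obs_mono, "n_obs_mono")
  stop_if_not_count(n_obs_stereo, "n_obs_stereo")
  stop_if_not_count(station_count, "station_count", min = 1L)
  structure(list(n_three_way = n_three_way, n_obs_mono = n_obs_mono,
                 n_obs_stereo = n_obs_stereo, station_count = station_count,
                 seed = seed),
            class = "campaign_spec")
}

#' Simulate a full paired call-count campaign
#'
#' Generates the sessions described by a [campaign_spec()]: for each session
#' a fresh local population of calling birds is drawn (`Poisson(birds_lambda)`
#' birds within earshot), a session is simulated on the session's channel
#' subset, and results are collected into flat sessions/calls tables ready
#' for export, assignment and calibration.
#'
#' @param spec a [campaign_spec()].
#' @param detection a [detection_spec()].
#' @param birds_lambda Poisson mean of the per-session number of birds within
#'   earshot.
#' @param ... further arguments passed to [simulate_population()]
#'   (e.g. `spatial_extent`, `call_rate_mean`).
#'
#' @return An object of class `bittern_campaign`: a list of two tibbles,
#'   `$sessions` (`session_id`, `station_id`, `occasion`, `channels_present`,
#'   `truth_n_calling`) and `$calls` (one row per detected call sequence with
#'   `session_id`, `channel`, `time_s`, `bearing_deg`, `volume_class`,
#'   `boom_count`, `stereo_channel`, `truth_id`).
#' @examples
#' camp <- simulate_campaign(campaign_spec(seed = 42))
#' nrow(camp$sessions)
#' @export
simulate_campaign <- function(spec = campaign_spec(),
                              detection = detection_spec(),
                              birds_lambda = 2.5,
                              ...) {
  stopifnot(inherits(spec, "campaign_spec"))
  subsets <- c(rep(list(c("OBS", "MONO", "STEREO")), spec$n_three_way),
               rep(list(c("OBS", "MONO")), spec$n_obs_mono),
               rep(list(c("OBS", "STEREO")), spec$n_obs_stereo))
  n <- length(subsets)
  if (n == 0) {
    return(as_campaign(
      tibble::tibble(session_id = character(0), station_id = character(0),
                     occasion = integer(0), channels_present = character(0),
                     truth_n_calling = integer(0)),
      tibble::tibble(session_id = character(0), station_id = character(0),
                     occasion = integer(0), channel = character(0),
                     time_s = numeric(0), bearing_deg = numeric(0),
                     volume_class = character(0), boom_count = integer(0),
                     stereo_channel = character(0), truth_id = integer(0))
    ))
  }
  with_seed(spec$seed, {
    sessions <- vector("list", n)
    calls <- vector("list", n)
    for (i in seq_len(n)) {
      sid <- sprintf("C%03d", i)
      station <- sprintf("S%02d", ((i - 1L) %% spec$station_count) + 1L)
      occ <- ((i - 1L) %/% spec$station_count) + 1L
      pop <- simulate_population(stats::rpois(1, birds_lambda), ...)
      ses <- simulate_session(pop, detection, channels = subsets[[i]],
                              station_id = station, occasion = occ)
      sessions[[i]] <- tibble::tibble(
        session_id = sid, station_id = station, occasion = occ,
        channels_present = paste(subsets[[i]], collapse = "+"),
        truth_n_calling = ses$truth_n_calling
      )
      per_ch <- lapply(subsets[[i]], function(ch) {
        d <- ses$calls[[ch]]
        tibble::tibble(session_id = sid, station_id = station, occasion = occ,
                       channel = ch, d)
      })
      calls[[i]] <- dplyr::bind_rows(per_ch)
    }
    as_campaign(dplyr::bind_rows(sessions), dplyr::bind_rows(calls))
  })
}

#' Assemble a campaign object from sessions and calls tables
#'
#' @param sessions tibble with `session_id`, `station_id`, `occasion`,
#'   `channels_present` (`"+"`-separated), `truth_n_calling` (may be `NA`
#'   for real data).
#' @param calls tibble with one row per detected call sequence.
#' @return An object of class `bittern_campaign`.
#' @export
as_campaign <- function(sessions, calls) {
  need_s <- c("session_id", "station_id", "occasion", "channels_present")
  need_c <- c("session_id", "channel", "time_s", "bearing_deg",
              "volume_class", "boom_count")
  if (!all(need_s %in% names(sessions))) {
    stop("sessions table is missing required columns", call. = FALSE)
  }
  if (nrow(calls) > 0 && !all(need_c %in% names(calls))) {
    stop("calls table is missing required columns", call. = FALSE)
  }
  if (!"truth_n_calling" %in% names(sessions)) sessions$truth_n_calling <- NA_integer_
  structure(list(sessions = tibble::as_tibble(sessions),
                 calls = tibble::as_tibble(calls)),
            class = "bittern_campaign")
}

#' @export
print.bittern_campaign <- function(x, ...) {
  comp <- table(x$sessions$channels_present)
  cat(sprintf("<bittern_campaign> %d sessions, %d detected call sequences\n",
              nrow(x$sessions), nrow(x$calls)))
  for (nm in names(comp)) cat(sprintf("  %-18s %d\n", nm, comp[[nm]]))
  invisible(x)
}

#' Session-level call-count totals under the survey model
#'
#' The marginal law of a session's total detected call count under
#' [simulate_session()] with constant detection probability: birds'
#' Poisson emissions thinned by detection are again Poisson, so the session
#' total is `Poisson(rate * p_detect)`. Used by the power module, where only
#' session totals matter and materialising full sessions would be wasteful.
#'
#' @param n_sessions number of sessions to draw.
#' @param rate expected emitted call sequences per session (summed over
#'   birds).
#' @param p_detect constant detection probability.
#' @param seed optional integer seed.
#' @return Integer vector of length `n_sessions`.
#' @export
simulate_session_counts <- function(n_sessions, rate, p_detect = 1, seed = NULL) {
  stop_if_not_count(n_sessions, "n_sessions")
  if (rate < 0 || p_detect < 0 || p_detect > 1) {
    stop("`rate` must be >= 0 and `p_detect` in [0, 1]", call. = FALSE)
  }
  with_seed(seed, stats::rpois(n_sessions, rate * p_detect))
}
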