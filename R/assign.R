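#' Minimum number of calling individuals from field-observer criteria
#'
#' Streams call sequences in temporal order, maintaining a set of candidate
#' birds ("clusters"). A call founds a new bird only if no existing cluster
#' accepts it; where uncertainty exists the call is merged, so the result is
#' a conservative minimum count. A cluster accepts a call when all of:
#'
#' * the circular bearing difference to the cluster's reference bearing (the
#'   running circular mean of its member bearings) is at most
#'   `bearing_threshold_deg`;
#' * the call's volume class has already been seen in the cluster, or — the
#'   "soft start", on by default — the cluster has a single member, the class
#'   is adjacent (`low`–`med` or `med`–`high`), and the bearing difference is
#'   within half the threshold;
#' * the call's boom count is not *consistently* different: a call is
#'   boom-incompatible only when the cluster already has at least two members
#'   and the call's boom count matches none of the counts seen there (one
#'   observation is never treated as consistent evidence).
#'
#' When several clusters accept, the call joins the one with the smallest
#' circular bearing difference (ties broken towards the lowest cluster id).
#' Calls sharing an identical timestamp are processed in a canonical order
#' (by bearing, then volume class, then boom count), so their input order
#' cannot affect the result.
#'
#' @param calls data frame of call sequences sorted by `time_s`, with columns
#'   `time_s`, `bearing_deg` (in \[0, 360)), `volume_class` (`low`/`med`/
#'   `high`) and `boom_count`.
#' @param bearing_threshold_deg bearing difference (degrees) beyond which a
#'   call is a new bird; default 10.
#' @param soft_start logical; enable the single-member adjacent-volume
#'   acceptance described above.
#' @return An object of class `assignment_result`: `n_individuals`,
#'   `method`, `assignment` (cluster id per call, in input order) and
#'   `clusters`, a tibble with `cluster_id`, `n_calls`,
#'   `reference_bearing_deg`, `volume_classes` and `boom_counts`.
#' @examples
#' calls <- tibble::tibble(time_s = c(10, 60), bearing_deg = c(0, 20),
#'                         volume_class = "med", boom_count = 3L)
#' assign_observer(calls)$n_individuals
#' @export
assign_observer <- function(calls, bearing_threshold_deg = 10,
                            soft_start = TRUE) {
  calls <- as.data.frame(calls)
  need <- c("time_s", "bearing_deg", "volume_class", "boom_count")
  if (!all(need %in% names(calls))) {
    stop("`calls` must have columns time_s, bearing_deg, volume_class, boom_count",
         call. = FALSE)
  }
  n <- nrow(calls)
  if (n > 0) {
    if (is.unsorted(calls$time_s)) {
      stop("`calls` must be sorted by time_s", call. = FALSE)
    }
    if (any(calls$bearing_deg < 0 | calls$bearing_deg >= 360)) {
      stop("bearings must lie in [0, 360)", call. = FALSE)
    }
    if (!all(calls$volume_class %in% VOLUME_LEVELS)) {
      stop("volume classes must be low, med or high", call. = FALSE)
    }
  }
  # canonical order: time, then bearing/volume/booms among tied timestamps
  ord <- order(calls$time_s, calls$bearing_deg,
               match(calls$volume_class, VOLUME_LEVELS), calls$boom_count)
  clusters <- list()   # each: list(bearings, volumes, booms, ref)
  assignment <- integer(n)
  for (i in ord) {
    b <- calls$bearing_deg[i]
    v <- calls$volume_class[i]
    k <- calls$boom_count[i]
    best <- 0L
    best_d <- Inf
    for (j in seq_along(clusters)) {
      cl <- clusters[[j]]
      d <- circ_diff_deg(b, cl$ref)
      if (d > bearing_threshold_deg) next
      vol_ok <- v %in% cl$volumes ||
        (soft_start && length(cl$bearings) == 1L &&
           volume_adjacent(v, cl$volumes) && d <= bearing_threshold_deg / 2)
      if (!vol_ok) next
      boom_ok <- !(length(cl$bearings) >= 2L && !(k %in% cl$booms))
      if (!boom_ok) next
      if (d < best_d) {   # strict: ties keep the lowest cluster id
        best_d <- d
        best <- j
      }
    }
    if (best == 0L) {
      clusters[[length(clusters) + 1L]] <-
        list(bearings = b, volumes = v, booms = k, ref = b)
      assignment[i] <- length(clusters)
    } else {
      cl <- clusters[[best]]
      cl$bearings <- c(cl$bearings, b)
      cl$volumes <- union(cl$volumes, v)
      cl$booms <- union(cl$booms, k)
      cl$ref <- circ_mean_deg(cl$bearings)
      clusters[[best]] <- cl
      assignment[i] <- best
    }
  }
  new_assignment_result(clusters, assignment, method = "observer_criteria")
}

volume_adjacent <- function(a, b) {
  abs(match(a, VOLUME_LEVELS) - match(b, VOLUME_LEVELS)) == 1L
}

new_assignment_result <- function(clusters, assignment, method) {
  tab <- tibble::tibble(
    cluster_id = seq_along(clusters),
    n_calls = vapply(clusters, function(cl) length(cl$bearings), integer(1)),
    reference_bearing_deg = vapply(clusters, function(cl) cl$ref, numeric(1)),
    volume_classes = vapply(clusters, function(cl)
      paste(sort(cl$volumes), collapse = ","), character(1)),
    boom_counts = vapply(clusters, function(cl)
      paste(sort(cl$booms), collapse = ","), character(1))
  )
  structure(list(n_individuals = length(clusters), method = method,
                 assignment = assignment, clusters = tab),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> method = %s: %d individual(s) from %d call(s)\n",
              x$method, x$n_individuals, length(x$assignment)))
  if (x$n_individuals > 0) print(x$clusters)
  invisible(x)
}

#' Minimum calling individuals from stereo volume-by-direction criteria
#'
#' When listening to a stereo recording, a call is attributed to a new
#' individual only if its (volume class, ear) combination has not been heard
#' before; otherwise it is merged with the earlier bird (conservative
#' minimum-count convention). With three volume classes and two ears the
#' method can never distinguish more than six birds — see
#' [distinguishable_capacity()].
#'
#' @param calls data frame with columns `volume_class` (`low`/`med`/`high`)
#'   and `stereo_channel` (`left`/`right`); no call may have a missing
#'   channel.
#' @return An `assignment_result` with `method = "stereo_audible"`; clusters
#'   group calls by (volume, direction) combination.
#' @examples
#' calls <- tibble::tibble(volume_class = c("high", "high", "low"),
#'                         stereo_channel = c("left", "left", "right"))
#' assign_stereo_audible(calls)$n_individuals
#' @export
assign_stereo_audible <- function(calls) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  if (n > 0) {
    if (!"stereo_channel" %in% names(calls) ||
        any(is.na(calls$stereo_channel))) {
      stop("every call must carry a stereo_channel (left/right)", call. = FALSE)
    }
    if (!all(calls$stereo_channel %in% c("left", "right"))) {
      stop("`stereo_channel` must be left or right", call. = FALSE)
    }
    if (!all(calls$volume_class %in% VOLUME_LEVELS)) {
      stop("volume classes must be low, med or high", call. = FALSE)
    }
  }
  if (n == 0) {
    return(new_assignment_result(list(), integer(0), method = "stereo_audible"))
  }
  combo <- paste(calls$volume_class, calls$stereo_channel, sep = "/")
  ids <- match(combo, unique(combo))
  clusters <- lapply(unique(combo), function(cm) {
    members <- which(combo == cm)
    list(bearings = if ("bearing_deg" %in% names(calls)) {
      calls$bearing_deg[members]
    } else {
      rep(NA_real_, length(members))
    },
    volumes = unique(calls$volume_class[members]),
    booms = if ("boom_count" %in% names(calls)) {
      unique(calls$boom_count[members])
    } else {
      integer(0)
    },
    ref = NA_real_)
  })
  res <- new_assignment_result(clusters, ids, method = "stereo_audible")
  res$clusters$reference_bearing_deg <- NA_real_
  res$clusters$combination <- unique(combo)
  res
}

#' Maximum number of individuals distinguishable by class combinations
#'
#' A discrimination rule based on crossing categorical cues can separate at
#' most as many individuals as there are cue combinations; with three volume
#' classes and two direction classes this ceiling is six.
#'
#' @param n_volume_classes,n_direction_classes positive integers.
#' @return The product, as an integer.
#' @examples
#' distinguishable_capacity(3, 2)
#' @export
distinguishable_capacity <- function(n_volume_classes, n_direction_classes) {
  stop_if_not_count(n_volume_classes, "n_volume_classes", min = 1L)
  stop_if_not_count(n_direction_classes, "n_direction_classes", min = 1L)
  as.integer(n_volume_classes * n_direction_classes)
}

#' Apply an individual-assignment method to every session of a campaign
#'
#' @param campaign a `bittern_campaign`.
#' @param method `"observer_criteria"` (uses each session's OBS calls) or
#'   `"stereo_audible"` (uses STEREO calls).
#' @param bearing_threshold_deg passed to [assign_observer()].
#' @return A tibble with `session_id`, `channel`, `method`, `n_individuals`.
#' @export
assign_campaign <- function(campaign,
                            method = c("observer_criteria", "stereo_audible"),
                            bearing_threshold_deg = 10) {
  stopifnot(inherits(campaign, "bittern_campaign"))
  method <- match.arg(method)
  channel <- if (method == "observer_criteria") "OBS" else "STEREO"
  keep <- grepl(channel, campaign$sessions$channels_present, fixed = TRUE)
  ids <- campaign$sessions$session_id[keep]
  n_ind <- vapply(ids, function(sid) {
    d <- campaign$calls[campaign$calls$session_id == sid &
                          campaign$calls$channel == channel, , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    if (method == "observer_criteria") {
      assign_observer(d, bearing_threshold_deg)$n_individuals
    } else {
      assign_stereo_audible(d)$n_individuals
    }
  }, integer(1))
  tibble::tibble(session_id = ids, channel = channel, method = method,
                 n_individuals = unname(n_ind))
}
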