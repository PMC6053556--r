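#' Export / import a campaign as plain CSV
#'
#' Writes `sessions.csv` (one row per session) and `calls.csv` (one row per
#' detected call sequence) into `dir`. The export is byte-stable: the same
#' campaign always produces identical files.
#'
#' @param campaign a `bittern_campaign` (see [simulate_campaign()],
#'   [as_campaign()]).
#' @param dir directory to write into (created if absent).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "bittern_campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(campaign$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$calls, file.path(dir, "calls.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(dir) {
  s <- file.path(dir, "sessions.csv")
  k <- file.path(dir, "calls.csv")
  if (!file.exists(s) || !file.exists(k)) {
    stop("`dir` must contain sessions.csv and calls.csv", call. = FALSE)
  }
  as_campaign(utils::read.csv(s, stringsAsFactors = FALSE),
              utils::read.csv(k, stringsAsFactors = FALSE))
}

#' Read a Raven-style selection table of annotated call sequences
#'
#' Parses the tab-separated selection tables produced when annotating
#' spectrograms, requiring the standard columns `Selection`, `Channel` and
#' `Begin Time (s)`, plus extension columns holding the listener's volume
#' class and boom count. Raven channel numbers map to stereo sides
#' (1 = left, 2 = right).
#'
#' @param path path to a tab-separated selection table.
#' @param volume_col,boom_col,bearing_col names of the extension columns for
#'   volume class, boom count and (optionally) bearing; `bearing_col = NULL`
#'   yields `NA` bearings (bearings are not observable from a recording).
#' @return A tibble of call sequences sorted by time: `time_s`,
#'   `stereo_channel`, `volume_class`, `boom_count`, `bearing_deg`.
#' @export
read_raven <- function(path, volume_col = "Volume", boom_col = "Booms",
                       bearing_col = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Selection", "Channel", "Begin Time (s)")
  missing_cols <- setdiff(c(need, volume_col, boom_col), names(d))
  if (length(missing_cols) > 0) {
    stop("selection table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vol <- tolower(trimws(d[[volume_col]]))
  if (!all(vol %in% VOLUME_LEVELS)) {
    stop("volume classes must be low, med or high", call. = FALSE)
  }
  ch <- as.integer(d[["Channel"]])
  if (!all(ch %in% c(1L, 2L))) {
    stop("`Channel` must be 1 (left) or 2 (right)", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = as.numeric(d[["Begin Time (s)"]]),
    stereo_channel = ifelse(ch == 1L, "left", "right"),
    volume_class = vol,
    boom_count = as.integer(d[[boom_col]]),
    bearing_deg = if (is.null(bearing_col)) NA_real_ else as.numeric(d[[bearing_col]])
  )
  out[order(out$time_s), , drop = FALSE]
}
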