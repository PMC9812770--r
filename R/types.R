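#' Multichannel LFP recording
#'
#' Container for one area's LFP block. Bad channels are flagged through
#' `channel_ok`, never dropped, so sample indices stay aligned to the session
#' clock.
#'
#' @param samples numeric matrix, channels x time (microvolts).
#' @param rate sampling rate (samples/s, nominally 1018).
#' @param area one of `"PFC"`, `"M1"`, `"HPC"`.
#' @param channel_ok logical vector, one flag per channel (default all good).
#' @param t0 session-clock time of the first sample (s).
#' @return object of class `recording`.
#' @export
recording <- function(samples, rate, area, channel_ok = NULL, t0 = 0) {
  samples <- as.matrix(samples)
  area <- match.arg(area, c("PFC", "M1", "HPC"))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  if (is.null(channel_ok)) channel_ok <- rep(TRUE, nrow(samples))
  if (length(channel_ok) != nrow(samples))
    stop("channel_ok length must equal the channel count")
  if (any(!is.finite(samples)))
    stop("all samples must be finite")
  structure(list(samples = samples, rate = rate, area = area,
                 channel_ok = as.logical(channel_ok), t0 = t0),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %d ch (%d good) x %d samples @ %.1f Hz, t0=%.3f s>\n",
              x$area, nrow(x$samples), sum(x$channel_ok), ncol(x$samples),
              x$rate, x$t0))
  invisible(x)
}

EVENT_KINDS <- c("SO", "SPINDLE", "SWR")

#' Typed oscillation event table
#'
#' One row per detected event. For SOs, `t_onset` holds the down-state peak
#' time and `t_peak` the up-state trough time (with amplitudes in
#' `peak_amp`/`trough_amp`); for spindles and SWRs `t_onset`/`t_end` are the
#' lower-threshold crossings and `t_peak` the envelope maximum. Timestamps
#' are stored at microsecond precision.
#'
#' @param kind character vector in `c("SO","SPINDLE","SWR")`.
#' @param area character vector in `c("PFC","M1","HPC")`.
#' @param t_onset,t_peak,t_end event times (s), `t_onset <= t_peak <= t_end`.
#' @param peak_amp,trough_amp optional kind-specific amplitudes.
#' @return data.frame of class `event_table`, sorted by `t_onset`.
#' @export
event_table <- function(kind = character(0), area = character(0),
                        t_onset = numeric(0), t_peak = numeric(0),
                        t_end = numeric(0), peak_amp = NA_real_,
                        trough_amp = NA_real_) {
  n <- length(t_onset)
  if (n > 0L && (!all(kind %in% EVENT_KINDS)))
    stop("unknown event kind: ", paste(setdiff(kind, EVENT_KINDS), collapse = ", "))
  d <- data.frame(kind = as.character(kind), area = as.character(area),
                  t_onset = round(t_onset, 6), t_peak = round(t_peak, 6),
                  t_end = round(t_end, 6),
                  peak_amp = rep_len(peak_amp, n),
                  trough_amp = rep_len(trough_amp, n))
  if (n > 0L) {
    if (any(d$t_onset > d$t_peak + 1e-9) || any(d$t_peak > d$t_end + 1e-9))
      stop("events must satisfy t_onset <= t_peak <= t_end")
    d <- d[order(d$t_onset), , drop = FALSE]
    rownames(d) <- NULL
  }
  structure(d, class = c("event_table", "data.frame"))
}

#' Per-unit spike trains
#'
#' @param units list of entries, each `list(unit_id=, area=, times=)` with
#'   spike times in seconds, nondecreasing.
#' @return object of class `spike_train_set`.
#' @export
spike_train_set <- function(units) {
  for (u in units) {
    stopifnot(is.character(u$unit_id), u$area %in% c("PFC", "M1", "HPC"))
    if (is.unsorted(u$times)) stop("spike times must be nondecreasing: ", u$unit_id)
  }
  structure(list(units = units), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set: %d units, %d spikes>\n", length(x$units),
              sum(vapply(x$units, function(u) length(u$times), integer(1)))))
  invisible(x)
}

#' Reach-trial table
#'
#' @param trial_id integer trial ids.
#' @param reach_onset reach onset times (s).
#' @param pellet_touch pellet-touch times (s) or `NA`.
#' @param success logical success flags.
#' @param hand `"L"`, `"R"` or `"X"` (no try).
#' @return data.frame of class `trial_table`.
#' @export
trial_table <- function(trial_id, reach_onset, pellet_touch = NA_real_,
                        success = NA, hand = "L") {
  n <- length(trial_id)
  pellet_touch <- rep_len(pellet_touch, n)
  bad <- !is.na(pellet_touch) & pellet_touch < reach_onset
  if (any(bad)) stop("pellet_touch must be >= reach_onset")
  if (!all(hand %in% c("L", "R", "X"))) stop("hand must be L, R or X")
  structure(data.frame(trial_id = trial_id, reach_onset = reach_onset,
                       pellet_touch = pellet_touch,
                       success = rep_len(as.logical(success), n),
                       hand = rep_len(hand, n)),
            class = c("trial_table", "data.frame"))
}

#' Session manifest
#'
#' Labels the pre-training sleep, training and post-training sleep blocks of
#' one recording day. Blocks must be disjoint and in that order.
#'
#' @param animal_id animal identifier.
#' @param day recording day (integer, >= 1).
#' @param pre_sleep,training,post_sleep two-element numeric `c(start, end)` (s).
#' @return object of class `session_manifest`.
#' @export
session_manifest <- function(animal_id, day, pre_sleep, training, post_sleep) {
  stopifnot(day >= 1)
  blocks <- list(pre_sleep = pre_sleep, training = training,
                 post_sleep = post_sleep)
  for (b in blocks) if (length(b) != 2L || b[2] <= b[1])
    stop("each block must be c(start, end) with start < end")
  if (!(pre_sleep[2] <= training[1] && training[2] <= post_sleep[1]))
    stop("blocks must be ordered pre_sleep < training < post_sleep and disjoint")
  structure(list(animal_id = animal_id, day = as.integer(day), blocks = blocks),
            class = "session_manifest")
}
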