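#' Interval sets
#'
#' An `interval_set` is a sorted list of non-overlapping half-open intervals
#' `[start, end)` in seconds on the session clock. They represent NREMS
#' bouts, analysis windows and sleep-block extents.
#'
#' @param start,end numeric vectors of equal length; `start < end` elementwise.
#' @return A data.frame of class `interval_set` with columns `start`, `end`,
#'   sorted by `start`.
#' @examples
#' iv <- interval_set(c(0, 10), c(6, 16))
#' interval_duration(iv)
#' @export
interval_set <- function(start = numeric(0), end = numeric(0)) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval bounds must be finite")
  if (any(end <= start))
    stop("intervals must satisfy start < end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("intervals must be non-overlapping")
  structure(data.frame(start = start, end = end),
            class = c("interval_set", "data.frame"))
}

#' @rdname interval_set
#' @param x an `interval_set`.
#' @export
interval_duration <- function(x) sum(x$end - x$start)

#' Membership of time points in an interval set
#'
#' @param t numeric vector of times (s).
#' @param x an `interval_set`.
#' @return logical vector, TRUE where `t` falls inside some `[start, end)`.
#' @export
in_intervals <- function(t, x) {
  if (nrow(x) == 0L) return(rep(FALSE, length(t)))
  i <- findInterval(t, x$start)
  ok <- i >= 1L
  ok[ok] <- t[ok] < x$end[i[ok]]
  ok
}

#' Map between session time and gap-excised (concatenated) time
#'
#' Circular permutations of event trains must stay inside NREMS, so shuffles
#' operate on the concatenated coordinate in which the intervals of `x` are
#' abutted end to end starting at 0.
#'
#' @param t times (s) inside `x` (session clock for `to_concat`, concatenated
#'   clock in `[0, interval_duration(x))` for `from_concat`).
#' @param x an `interval_set`.
#' @return numeric vector of mapped times.
#' @export
to_concat_time <- function(t, x) {
  if (nrow(x) == 0L) stop("empty interval set")
  offs <- cumsum(c(0, head(x$end - x$start, -1L)))
  i <- findInterval(t, x$start)
  if (any(i < 1L) || any(t >= x$end[i]))
    stop("times outside the interval set")
  offs[i] + (t - x$start[i])
}

#' @rdname to_concat_time
#' @export
from_concat_time <- function(t, x) {
  if (nrow(x) == 0L) stop("empty interval set")
  lens <- x$end - x$start
  offs <- cumsum(c(0, head(lens, -1L)))
  tot <- sum(lens)
  if (any(t < 0) || any(t >= tot)) stop("concatenated times out of range")
  i <- findInterval(t, offs)
  x$start[i] + (t - offs[i])
}

#' Intersect an interval set with a single window
#'
#' @param x an `interval_set`.
#' @param lo,hi window bounds (s).
#' @return an `interval_set` clipped to `[lo, hi)`.
#' @export
clip_intervals <- function(x, lo, hi) {
  s <- pmax(x$start, lo); e <- pmin(x$end, hi)
  keep <- e > s
  interval_set(s[keep], e[keep])
}

# union of possibly overlapping [start, end) pairs -> interval_set
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(interval_set())
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  outs <- c(); oute <- c()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  interval_set(c(outs, ms), c(oute, me))
}
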