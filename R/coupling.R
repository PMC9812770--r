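# Cross-area event-coupling statistics. Lags follow the convention
# lag = target - reference (positive: target after reference); a coupling
# value is the percentage of target events whose lag to the nearest
# reference falls inside a closed window. Null levels come from circular
# permutation on NREMS-concatenated time.

#' Nearest-reference lags
#'
#' Each target event is linked to its closest reference; equidistant ties
#' break toward the earlier reference (giving a positive lag).
#'
#' @param targets,references event times (s).
#' @return list with `lags` (one per target, `target - nearest reference`),
#'   `n_targets`.
#' @export
nearest_lags <- function(targets, references) {
  if (length(references) == 0L) stop("empty reference set")
  refs <- sort(references)
  i <- findInterval(targets, refs)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(refs))
  d_lo <- abs(targets - refs[lo])
  d_hi <- abs(targets - refs[hi])
  pick <- ifelse(i < 1L, hi, ifelse(d_lo <= d_hi, lo, hi)) # tie -> earlier
  list(lags = targets - refs[pick], n_targets = length(targets))
}

#' Coupling fraction within a window
#'
#' @param lagset output of [nearest_lags()].
#' @param window `c(lo, hi)` (s); closed at both ends.
#' @return list: `value` (percent, `NA` when there are no targets, with
#'   `flag = "undefined"`), `n`, `window`.
#' @export
coupling_fraction <- function(lagset, window) {
  n <- lagset$n_targets
  if (n == 0L)
    return(list(value = NA_real_, n = 0L, window = window, flag = "undefined"))
  hit <- lagset$lags >= window[1] & lagset$lags <= window[2]
  list(value = 100 * mean(hit), n = n, window = window, flag = NULL)
}

#' Pairwise coupling measures
#'
#' `pfc_m1_so_coupling`: percent of M1 SO up-states within +/-0.2 s of the
#' nearest PFC SO up-state. `so_swr_coupling`: percent of SWR peaks within
#' +/-0.75 s of the nearest SO up-state. `so_spindle_coupling`: percent of
#' spindle peaks within the asymmetric nesting window (-0.5, +1.0 s) of the
#' nearest SO up-state.
#'
#' @param pfc_up,m1_up,so_up,swr_peaks,spindle_peaks event times (s).
#' @param window coupling window `c(lo, hi)` (s).
#' @return as [coupling_fraction()].
#' @export
pfc_m1_so_coupling <- function(pfc_up, m1_up, window = c(-0.2, 0.2)) {
  coupling_fraction(nearest_lags(m1_up, pfc_up), window)
}

#' @rdname pfc_m1_so_coupling
#' @export
so_swr_coupling <- function(so_up, swr_peaks, window = c(-0.75, 0.75)) {
  coupling_fraction(nearest_lags(swr_peaks, so_up), window)
}

#' @rdname pfc_m1_so_coupling
#' @export
so_spindle_coupling <- function(so_up, spindle_peaks, window = c(-0.5, 1.0)) {
  coupling_fraction(nearest_lags(spindle_peaks, so_up), window)
}

#' Post-minus-pre coupling difference (percentage points)
#'
#' @param post,pre coupling summaries (outputs of [coupling_fraction()]).
#' @return signed difference `post$value - pre$value`.
#' @export
delta_coupling <- function(post, pre) {
  if (is.na(post$value) || is.na(pre$value))
    stop("delta undefined: one side has no events")
  post$value - pre$value
}

#' Triple / quadruple coupling
#'
#' Percent of SWRs with at least one SO up-state AND one spindle peak within
#' `window` of the SWR peak; in `"quadruple"` mode the SO must additionally
#' be a PFC-M1-coupled SO (its up-state within `pfc_m1_window` of a PFC SO
#' up-state).
#'
#' @param swr_peaks,so_up,spindle_peaks event times (s).
#' @param mode `"triple"` or `"quadruple"`.
#' @param pfc_up PFC SO up-states (required for `"quadruple"`).
#' @param window locking window around the SWR peak (s).
#' @param pfc_m1_window PFC-M1 SO coupling window (s).
#' @return as [coupling_fraction()].
#' @export
multi_coupling <- function(swr_peaks, so_up, spindle_peaks,
                           mode = c("triple", "quadruple"), pfc_up = NULL,
                           window = c(-1, 1), pfc_m1_window = c(-0.2, 0.2)) {
  mode <- match.arg(mode)
  if (length(swr_peaks) == 0L) stop("empty SWR set")
  sos <- sort(so_up)
  if (mode == "quadruple") {
    if (is.null(pfc_up)) stop("quadruple coupling needs PFC SO up-states")
    lg <- nearest_lags(sos, pfc_up)$lags
    sos <- sos[lg >= pfc_m1_window[1] & lg <= pfc_m1_window[2]]
  }
  has_near <- function(x, evs) {
    if (length(evs) == 0L) return(rep(FALSE, length(x)))
    lg <- nearest_lags(x, evs)$lags
    lg >= window[1] & lg <= window[2]
  }
  hit <- has_near(swr_peaks, sos) & has_near(swr_peaks, sort(spindle_peaks))
  list(value = 100 * mean(hit), n = length(swr_peaks), window = window,
       flag = NULL)
}

#' Circular-permutation null distribution
#'
#' The shuffled train's times are mapped to NREMS-concatenated time (gaps
#' excised), rotated by one uniform offset modulo the total NREMS duration,
#' mapped back, and the metric recomputed; repeated `reps` times. Rotation
#' preserves event counts and the inter-event-interval multiset, so the null
#' mean converges to the window-coverage fraction of the fixed train.
#'
#' @param metric_fn function(shuffled_times) -> coupling summary (a list
#'   with a `value` element), e.g. a closure over the fixed reference train.
#' @param shuffle_times event times (s) of the train being shuffled.
#' @param nrems NREMS `interval_set` (all times must fall inside).
#' @param reps number of rotations.
#' @param seed RNG seed.
#' @return list: `values` (percent per rep), `mean`, `sd`, `reps`, `seed`.
#' @export
circular_null <- function(metric_fn, shuffle_times, nrems, reps = 1000,
                          seed = 1) {
  if (length(shuffle_times) == 0L) stop("empty shuffle train")
  stopifnot(reps >= 1)
  tc <- to_concat_time(shuffle_times, nrems)
  tot <- interval_duration(nrems)
  set.seed(seed)
  offs <- stats::runif(reps, 0, tot)
  vals <- vapply(offs, function(o) {
    shifted <- sort((tc + o) %% tot)
    metric_fn(from_concat_time(shifted, nrems))$value
  }, numeric(1))
  list(values = vals, mean = mean(vals), sd = stats::sd(vals), reps = reps,
       seed = seed)
}

#' Analytic window-coverage fraction
#'
#' Fraction of NREMS-concatenated time covered by `[ref + lo, ref + hi]`
#' windows around the reference train (windows wrapped circularly and
#' unioned). This is the expected coupling under a uniform (circularly
#' shuffled) target train and serves as the chance-coincidence rate.
#'
#' @param references reference event times (s), inside `nrems`.
#' @param window `c(lo, hi)` (s).
#' @param nrems NREMS `interval_set`.
#' @return coverage fraction in `[0, 1]`.
#' @export
window_coverage <- function(references, window, nrems) {
  if (length(references) == 0L) return(0)
  tot <- interval_duration(nrems)
  rc <- to_concat_time(references, nrems)
  s <- rc + window[1]; e <- rc + window[2]
  # wrap pieces into [0, tot)
  pieces_s <- c(); pieces_e <- c()
  for (i in seq_along(s)) {
    a <- s[i]; b <- e[i]
    if (b - a >= tot) return(1)
    a <- a %% tot; b2 <- a + (e[i] - s[i])
    if (b2 <= tot) {
      pieces_s <- c(pieces_s, a); pieces_e <- c(pieces_e, b2)
    } else {
      pieces_s <- c(pieces_s, a, 0); pieces_e <- c(pieces_e, tot, b2 - tot)
    }
  }
  iv <- merge_intervals(pieces_s, pieces_e)
  interval_duration(iv) / tot
}

#' Subsampled PFC-M1 SO coupling
#'
#' Controls for reference-rate differences: per repetition, `n_sub` PFC SOs
#' are drawn without replacement and the coupling recomputed; the mean over
#' repetitions is reported.
#'
#' @param pfc_up,m1_up SO up-state times (s).
#' @param n_sub subsample size (fixed across sessions).
#' @param reps repetitions.
#' @param seed RNG seed.
#' @param window coupling window (s).
#' @return list as [circular_null()], or with `flag = "too_few_references"`
#'   and the unsubsampled value when `length(pfc_up) < n_sub`.
#' @export
subsampled_coupling <- function(pfc_up, m1_up, n_sub = 100, reps = 1000,
                                seed = 1, window = c(-0.2, 0.2)) {
  if (length(pfc_up) < n_sub) {
    full <- pfc_m1_so_coupling(pfc_up, m1_up, window)
    return(list(values = full$value, mean = full$value, sd = NA_real_,
                reps = 0L, seed = seed, flag = "too_few_references"))
  }
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    sub <- sample(pfc_up, n_sub)
    pfc_m1_so_coupling(sub, m1_up, window)$value
  }, numeric(1))
  list(values = vals, mean = mean(vals), sd = stats::sd(vals), reps = reps,
       seed = seed, flag = NULL)
}

#' Label SWR conditions and draw SWR- epochs
#'
#' An SWR is `so_plus` iff an M1 SO up-state occurs in
#' `(onset, onset + horizon]`. The SWR- condition is a set of random
#' `horizon`-long epochs whose full extent lies inside NREMS, one per SWR;
#' epochs may overlap each other.
#'
#' @param swr_onsets SWR onset times (s).
#' @param m1_so_up M1 SO up-state times (s).
#' @param nrems NREMS `interval_set`.
#' @param seed RNG seed.
#' @param horizon epoch length (s).
#' @return list: `so_plus` (logical per SWR), `swr_minus_onsets` (numeric,
#'   length = number of SWRs).
#' @export
label_swr_conditions <- function(swr_onsets, m1_so_up, nrems, seed = 1,
                                 horizon = 1) {
  so_plus <- vapply(swr_onsets, function(o)
    any(m1_so_up > o & m1_so_up <= o + horizon), logical(1))
  lens <- nrems$end - nrems$start
  feas <- lens - horizon
  if (all(feas <= 0)) stop("NREMS too short to place SWR- epochs")
  ok <- which(feas > 0)
  set.seed(seed)
  iv <- sample(ok, length(swr_onsets), replace = TRUE,
               prob = feas[ok] / sum(feas[ok]))
  onsets <- nrems$start[iv] + stats::runif(length(iv), 0, feas[iv])
  list(so_plus = so_plus, swr_minus_onsets = onsets)
}
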