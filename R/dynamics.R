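# Across-day metric time courses: tertile resolution, Gaussian smoothing
# with end padding, min-max normalization, sigmoid / piecewise / change-point
# fits, and two-stage logistic classification.

#' Split session items into contiguous tertiles
#'
#' Items (trials or sleep events, time-ordered) are split into three
#' contiguous thirds; remainder items go to the last tertile (31 items ->
#' 10/10/11).
#'
#' @param n number of items.
#' @return integer vector of tertile indices (1-3), length `n`.
#' @export
tertile_split <- function(n) {
  base <- n %/% 3L
  rep(1:3, times = c(base, base, n - 2L * base))
}

#' Per-tertile metric series across days
#'
#' @param sessions list with one element per day: a list of time-ordered
#'   item values (whatever `metric_fn` consumes).
#' @param metric_fn function(items) -> scalar metric for one tertile.
#' @return data.frame `day`, `tertile`, `value`; sessions with fewer than 3
#'   items replicate the session-level value across tertiles and are
#'   flagged in the `flag` column.
#' @export
tertile_series <- function(sessions, metric_fn) {
  out <- NULL
  for (d in seq_along(sessions)) {
    items <- sessions[[d]]
    n <- length(items)
    if (n < 3L) {
      v <- metric_fn(items)
      out <- rbind(out, data.frame(day = d, tertile = 1:3, value = v,
                                   flag = "replicated"))
    } else {
      idx <- tertile_split(n)
      for (k in 1:3) {
        v <- metric_fn(items[idx == k])
        out <- rbind(out, data.frame(day = d, tertile = k, value = v,
                                     flag = NA_character_))
      }
    }
  }
  out
}

#' Smooth and normalize a tertile series
#'
#' The series is padded at each end with that end's 2-day mean (6 tertile
#' values), convolved with a Gaussian kernel spanning 9 tertiles (3 days;
#' kernel sigma `(9-1)/5` tertiles, the standard Gaussian-window
#' convention), then min-max normalized to `[0, 1]`.
#'
#' @param x numeric series (tertile-resolved, day-ordered).
#' @param kernel_tertiles kernel span (odd integer).
#' @param pad_tertiles pad length at each end.
#' @return list: `smoothed`, `normalized`, `flag` (`"constant"` when
#'   normalization is undefined; `normalized` is then `NA`).
#' @export
smooth_normalize <- function(x, kernel_tertiles = 9, pad_tertiles = 6) {
  n <- length(x)
  pad_lo <- rep(mean(x[seq_len(min(pad_tertiles, n))]), pad_tertiles)
  pad_hi <- rep(mean(x[seq.int(max(1L, n - pad_tertiles + 1L), n)]), pad_tertiles)
  xp <- c(pad_lo, x, pad_hi)
  half <- (kernel_tertiles - 1L) / 2
  sigma <- (kernel_tertiles - 1L) / 5
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  sm_full <- stats::filter(xp, k, sides = 2)
  sm <- as.numeric(sm_full[(pad_tertiles + 1L):(pad_tertiles + n)])
  rng <- range(sm)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
    return(list(smoothed = sm, normalized = rep(NA_real_, n), flag = "constant"))
  list(smoothed = sm, normalized = (sm - rng[1]) / diff(rng), flag = NULL)
}

#' Four-parameter sigmoid fit
#'
#' Least-squares fit of `L + (U - L) / (1 + exp(-k (x - x_mid)))` by
#' Levenberg-Marquardt with a multi-start grid over `x_mid` (1-day spacing)
#' and box constraints (`L, U` in `bounds`, `x_mid` within the data range,
#' `|k| <= k_max`); the best-SSE start wins.
#'
#' @param x day coordinate (e.g. day + (tertile - 1)/3).
#' @param y normalized metric values.
#' @param range optional fit range `c(lo, hi)` in days (e.g. days 3-11).
#' @param bounds lower/upper bounds for `L` and `U`.
#' @param k_max slope bound.
#' @return list: `U`, `L`, `x_mid`, `k`, `r2`, `direction`
#'   (`"rise"`/`"drop"`), `fitted`, `flag` (`"no_transition"` when the fit
#'   explains essentially nothing or the slope is ~0).
#' @export
fit_sigmoid <- function(x, y, range = NULL, bounds = c(-0.5, 1.5),
                        k_max = 20) {
  if (!is.null(range)) {
    keep <- x >= range[1] & x <= range[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 8L) stop("need at least 8 samples in fit range")
  sig <- function(p, x) p[2] + (p[1] - p[2]) / (1 + exp(-p[4] * (x - p[3])))
  lo <- c(bounds[1], bounds[1], min(x), -k_max)
  hi <- c(bounds[2], bounds[2], max(x), k_max)
  best <- NULL
  for (x0 in seq(ceiling(min(x)), floor(max(x)), by = 1)) {
    for (k0 in c(-2, 2)) {
      start <- c(U = max(y), L = min(y), x_mid = x0, k = k0)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start,
                           fn = function(p) y - sig(p, x),
                           lower = lo, upper = hi,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from every start")
  p <- best$fit$par
  fitted <- sig(p, x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  rising <- (p[["U"]] - p[["L"]]) * p[["k"]] > 0
  resid_sd <- stats::sd(best$fit$fvec)
  flag <- if (abs(p[["k"]]) < 1e-3 || (!is.na(r2) && r2 < 0.1) ||
              abs(p[["U"]] - p[["L"]]) < 4 * resid_sd) "no_transition" else NULL
  list(U = p[["U"]], L = p[["L"]], x_mid = p[["x_mid"]], k = p[["k"]],
       r2 = r2, direction = if (rising) "rise" else "drop",
       fitted = fitted, flag = flag)
}

#' Moving-window transition scan
#'
#' For each window size, the OLS slope over every window of consecutive
#' days is computed; the baseline distribution is the slopes of windows
#' lying entirely within `baseline_days` (when the window is too wide for
#' that, the first window's slope alone, with zero spread). The transition
#' day (for that size) is the end day of the first window whose slope
#' strictly exceeds baseline mean + `baseline_sd` s.d. The reported day is
#' the value agreed across sizes, else the modal day with
#' `flag = "disagreement"`.
#'
#' @param values per-day metric values (day 1..n).
#' @param window_sizes window lengths in days.
#' @param baseline_days days whose window slopes form the baseline.
#' @param baseline_sd threshold in baseline s.d. above the baseline mean.
#' @return list: `day` (`NA` when no window departs from baseline, with
#'   `flag = "no_transition"`), `per_size`, `flag`.
#' @export
transition_scan <- function(values, window_sizes = 3:7, baseline_days = 1:4,
                            baseline_sd = 2) {
  n <- length(values)
  if (n < max(window_sizes)) stop("series shorter than the largest window")
  per_size <- integer(0)
  for (w in window_sizes) {
    starts <- seq_len(n - w + 1L)
    slopes <- vapply(starts, function(s) {
      yy <- values[s:(s + w - 1L)]
      stats::coef(stats::lm(yy ~ seq_len(w)))[2L]
    }, numeric(1))
    ends <- starts + w - 1L
    base <- slopes[ends <= max(baseline_days)]
    if (length(base) == 0L) base <- slopes[1L]
    thr <- mean(base) + baseline_sd * stats::sd(base)
    if (!is.finite(thr)) thr <- mean(base)
    exceed <- which(slopes > thr + 1e-8 * max(1, abs(thr)))
    per_size[as.character(w)] <- if (length(exceed)) ends[exceed[1L]] else NA_integer_
  }
  if (all(is.na(per_size)))
    return(list(day = NA_integer_, per_size = per_size, flag = "no_transition"))
  tab <- table(per_size[!is.na(per_size)])
  modal <- as.integer(names(tab)[which.max(tab)])
  flag <- if (length(tab) > 1L || anyNA(per_size)) "disagreement" else NULL
  list(day = modal, per_size = per_size, flag = flag)
}

#' Piecewise-linear segment fits
#'
#' Independent OLS per segment; optionally the last segment is truncated at
#' the series argmax to isolate the rising phase (plateau excluded).
#'
#' @param x day coordinate; `y` metric values.
#' @param breakpoints day values splitting the segments (a point `d` starts
#'   a new segment at `x >= d`).
#' @param truncate_last_at_max truncate the final segment at the argmax of `y`.
#' @return data.frame: one row per segment with `from`, `to`, `slope`,
#'   `intercept`, `n`.
#' @export
piecewise_slopes <- function(x, y, breakpoints, truncate_last_at_max = FALSE) {
  edges <- c(-Inf, sort(breakpoints), Inf)
  out <- NULL
  n_seg <- length(edges) - 1L
  for (s in seq_len(n_seg)) {
    keep <- x >= edges[s] & x < edges[s + 1L]
    xs <- x[keep]; ys <- y[keep]
    if (s == n_seg && truncate_last_at_max && length(ys) > 0L) {
      cut <- which.max(ys)
      xs <- xs[seq_len(cut)]; ys <- ys[seq_len(cut)]
    }
    if (length(xs) < 3L) stop("segment ", s, " has fewer than 3 samples")
    co <- stats::coef(stats::lm(ys ~ xs))
    out <- rbind(out, data.frame(from = min(xs), to = max(xs),
                                 slope = co[[2L]], intercept = co[[1L]],
                                 n = length(xs)))
  }
  rownames(out) <- NULL
  out
}

#' Single change-point by mean shift
#'
#' Exhaustive search over all split indices for the split minimizing the
#' total residual error about the two segment means; ties break to the
#' earliest index.
#'
#' @param x numeric series (length >= 4).
#' @return list: `index` (first index of the post-change segment),
#'   `pre_mean`, `post_mean`, `residual`, `flag` (`"degenerate"` when every
#'   split is equally good).
#' @export
change_point <- function(x) {
  n <- length(x)
  if (n < 4L) stop("series too short for change-point analysis")
  sse <- function(v) sum((v - mean(v))^2)
  tot <- vapply(2:n, function(i) sse(x[1:(i - 1L)]) + sse(x[i:n]), numeric(1))
  best <- which(tot <= min(tot) + 1e-12)[1L]
  idx <- best + 1L
  flag <- if (max(tot) - min(tot) < 1e-12) "degenerate" else NULL
  list(index = idx, pre_mean = mean(x[1:(idx - 1L)]),
       post_mean = mean(x[idx:n]), residual = tot[best], flag = flag)
}

#' Day-to-day success-rate change
#'
#' `change(d) = rate(d) - mean(rate(d-2), rate(d-1))`; the rates of the two
#' days before day 1 are taken as zero.
#'
#' @param rates per-day success rates (day 1..n).
#' @return numeric vector of changes, same length.
#' @export
success_rate_change <- function(rates) {
  padded <- c(0, 0, rates)
  vapply(seq_along(rates), function(d)
    rates[d] - mean(padded[c(d, d + 1L)]), numeric(1))
}

#' Two-stage logistic staging model
#'
#' Sessions are tagged stage I/II around the grand-midpoint (per-animal
#' median of the PFC-M1 coupling rise midpoint and the delta SO-SWR coupling
#' drop midpoint); logistic regression then predicts P(stage II) from the
#' two coupling values.
#'
#' @param day session day per row.
#' @param dso_swr per-session delta SO-SWR coupling values.
#' @param pfc_m1 per-session PFC-M1 SO coupling values.
#' @param rise_mid,drop_mid sigmoid midpoints (days).
#' @return list: `grand_midpoint`, `stage` (1/2 per session),
#'   `coefficients`, `prob` (per-session P(stage II)), `flag`
#'   (`"separation"` when the classes are perfectly separable).
#' @export
stage_model <- function(day, dso_swr, pfc_m1, rise_mid, drop_mid) {
  gm <- stats::median(c(rise_mid, drop_mid))
  stage <- ifelse(day > gm, 2L, 1L)
  if (length(unique(stage)) < 2L)
    stop("degenerate labels: all sessions fall in one stage")
  d <- data.frame(y = stage == 2L, dso_swr = dso_swr, pfc_m1 = pfc_m1)
  flag <- NULL
  fit <- withCallingHandlers(
    stats::glm(y ~ dso_swr + pfc_m1, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        flag <<- "separation"
      invokeRestart("muffleWarning")
    })
  list(grand_midpoint = gm, stage = stage,
       coefficients = stats::coef(fit),
       prob = stats::fitted(fit), flag = flag)
}
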