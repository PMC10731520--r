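#' Motion energy of a video ROI
#'
#' Movement inside a region of interest is quantified as the absolute value
#' of the temporal gradient of the ROI's mean pixel value:
#' `energy(t) = |x(t+1) - x(t)|`, one sample shorter than the video.
#'
#' @param roi_mean_trace numeric vector of per-frame ROI mean pixel values.
#' @param clock optional per-frame timestamps (s); energy sample i is stamped
#'   at `clock[i]`.
#' @param roi_id label for the ROI.
#' @return object of class `motion_energy`: list with `clock`, `energy`,
#'   `roi_id`.
#' @export
motion_energy <- function(roi_mean_trace, clock = NULL, roi_id = "roi") {
  n <- length(roi_mean_trace)
  if (n < 2L) stopf("need at least 2 samples")
  clock <- clock %||% seq_len(n) - 1
  me <- list(clock = clock[-n], energy = abs(diff(roi_mean_trace)),
             roi_id = roi_id)
  class(me) <- "motion_energy"
  me
}

#' Detect behavior bouts from an ROI motion-energy trace
#'
#' The motion energy is smoothed by convolution with a Gaussian kernel
#' (sigma = 25 video frames, reflect padding) and thresholded at the
#' mean + 1 SD of the smoothed trace; contiguous supra-threshold runs become
#' movement bouts. Because the threshold is a mean + SD of the same trace,
#' detection is invariant to affine rescaling of the energy.
#'
#' @param me a [motion_energy()] object.
#' @param sigma_frames Gaussian smoothing sigma in frames.
#' @param n_sd threshold is mean + `n_sd` * SD of the smoothed trace.
#' @param channel,mouse labels forwarded to the [event_series()].
#' @param valid optional logical vector marking observable samples (e.g. the
#'   moving mouse only during the together phase); threshold statistics use
#'   valid samples only.
#' @return an [event_series()] on the energy clock.
#' @export
detect_events <- function(me, sigma_frames = 25, n_sd = 1,
                          channel = "whisker", mouse = "stationary",
                          valid = NULL) {
  stopifnot(inherits(me, "motion_energy"))
  x <- me$energy
  if (length(x) < 3 * sigma_frames)
    stopf("trace too short (%d samples) for sigma = %g frames smoothing",
          length(x), sigma_frames)
  valid <- valid %||% rep(TRUE, length(x))
  sm <- conv_reflect(x, gauss_kernel(sigma_frames))
  mu <- mean(sm[valid]); s <- stats::sd(sm[valid])
  above <- sm > mu + n_sd * s & valid
  event_series(me$clock, binary = above, channel = channel, mouse = mouse,
               valid = valid)
}

interval_samples <- function(clock, window) {
  if (window[2L] <= window[1L]) stopf("empty window")
  w <- which(clock >= window[1L] & clock < window[2L])
  if (!length(w)) stopf("window [%g, %g) contains no samples", window[1L],
                        window[2L])
  w
}

#' Fraction of time spent behaving in a window
#'
#' @param es an [event_series()].
#' @param window `(start_s, end_s)` interval; default the full clock span.
#' @return fraction in \[0, 1\]: active valid samples / valid samples.
#' @export
percent_time_behaving <- function(es, window = NULL) {
  window <- window %||% c(es$clock[1L],
                          es$clock[length(es$clock)] + 1 / es$fs)
  w <- interval_samples(es$clock, window)
  w <- w[es$valid[w]]
  if (!length(w)) stopf("no valid samples in window")
  mean(es$binary[w])
}

#' Cross-correlation of two binary behavior vectors
#'
#' Pearson correlation of the two mean-subtracted binary vectors at every
#' integer-sample lag within `+/- max_lag_s`, each lag computed on the
#' overlapping span only (overlap normalization). A positive lag means `b`
#' lags `a` (`b` shifted later matches `a`).
#'
#' @param a,b [event_series()] objects on a common clock.
#' @param max_lag_s maximum lag (s); the default 30 s covers the slow
#'   envelope of interactive behavior coordination.
#' @param window optional `(start_s, end_s)` restriction (e.g. the together
#'   phase).
#' @return data.frame with columns `lag_s` and `r` (NA where either vector
#'   is constant on the overlap).
#' @export
crosscorr_binary <- function(a, b, max_lag_s = 30, window = NULL) {
  if (length(a$clock) != length(b$clock))
    stopf("series must share a clock")
  idx <- if (is.null(window)) seq_along(a$clock) else
    interval_samples(a$clock, window)
  va <- as.numeric(a$binary[idx]); vb <- as.numeric(b$binary[idx])
  ok <- a$valid[idx] & b$valid[idx]
  va[!ok] <- NA; vb[!ok] <- NA
  fs <- a$fs
  lags <- seq(-round(max_lag_s * fs), round(max_lag_s * fs))
  n <- length(va)
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      x <- va[(1L + k):n]; y <- vb[1L:(n - k)]
    } else {
      x <- va[1L:(n + k)]; y <- vb[(1L - k):n]
    }
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  data.frame(lag_s = lags / fs, r = r)
}

#' Jaccard similarity of two binary behavior vectors
#'
#' Intersection over union of the active samples within a window; defined as
#' 0 when the union is empty.
#'
#' @param a,b [event_series()] on a common clock.
#' @param window optional `(start_s, end_s)` interval.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(a, b, window = NULL) {
  if (length(a$clock) != length(b$clock))
    stopf("series must share a clock")
  idx <- if (is.null(window)) seq_along(a$clock) else
    interval_samples(a$clock, window)
  ok <- a$valid[idx] & b$valid[idx]
  x <- a$binary[idx][ok]; y <- b$binary[idx][ok]
  u <- sum(x | y)
  if (u == 0L) return(0)
  sum(x & y) / u
}

#' Extract behavior events for every mouse and channel of a session
#'
#' Runs [motion_energy()] and [detect_events()] on each ROI trace of a
#' preprocessed session. The moving mouse's channels are marked valid only
#' during the together phase (it is out of the behavior frame otherwise).
#'
#' @param pre a `preprocessed_session`.
#' @param ... passed to [detect_events()].
#' @return nested list `[mouse][channel]` of [event_series()].
#' @export
session_behavior_events <- function(pre, ...) {
  stopifnot(inherits(pre, "preprocessed_session"))
  tog <- phase_window(pre$phase_schedule, "together")
  res <- list()
  for (m in names(pre$behavior$traces)) {
    for (ch in names(pre$behavior$traces[[m]])) {
      me <- motion_energy(pre$behavior$traces[[m]][[ch]],
                          clock = pre$behavior$timestamps,
                          roi_id = paste(m, ch, sep = "_"))
      valid <- if (m == "moving")
        me$clock >= tog[1L] & me$clock < tog[2L]
      else rep(TRUE, length(me$clock))
      res[[m]][[ch]] <- detect_events(me, channel = ch, mouse = m,
                                      valid = valid, ...)
    }
  }
  res
}

#' Write / read behavior events as CSV
#'
#' Columns: `mouse`, `channel`, `onset_s`, `offset_s`, `duration_s`.
#'
#' @param events nested list `[mouse][channel]` of [event_series()].
#' @param path CSV file path.
#' @export
write_events_csv <- function(events, path) {
  rows <- list()
  for (m in names(events)) {
    for (ch in names(events[[m]])) {
      ev <- events[[m]][[ch]]$events
      if (nrow(ev))
        rows[[length(rows) + 1L]] <- cbind(mouse = m, channel = ch, ev)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mouse = character(0), channel = character(0),
               onset_s = numeric(0), offset_s = numeric(0),
               duration_s = numeric(0))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
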