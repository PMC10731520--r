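#' Binary behavior event series
#'
#' A behavior channel (whisker or forelimb movement of one mouse) represented
#' three ways that are kept mutually consistent: a sample clock, a binary
#' vector that is TRUE exactly while a movement bout is ongoing, and the
#' bout list (onset, offset, duration). Samples are interpreted as covering
#' `[clock[i], clock[i] + dt)`.
#'
#' @param clock numeric timestamps (s), uniformly spaced.
#' @param binary logical vector, same length as `clock`. Exactly one of
#'   `binary` or `events` must be supplied.
#' @param events data.frame with columns `onset_s`, `offset_s` (bouts may be
#'   unordered or overlapping; they are merged and sorted).
#' @param channel behavior channel label, e.g. `"whisker"` or `"forelimb"`.
#' @param mouse mouse label, e.g. `"stationary"` or `"moving"`.
#' @param valid optional logical vector marking where the channel is
#'   observable (the moving mouse is only in frame during the together
#'   phase); defaults to everywhere.
#' @return object of class `event_series` with fields `clock`, `binary`,
#'   `events`, `channel`, `mouse`, `valid`, `fs`.
#' @export
event_series <- function(clock, binary = NULL, events = NULL,
                         channel = "whisker", mouse = "stationary",
                         valid = NULL) {
  if (length(clock) < 1L) stopf("empty clock")
  dt <- if (length(clock) > 1L) stats::median(diff(clock)) else 1
  if (is.null(binary) == is.null(events))
    stopf("supply exactly one of 'binary' or 'events'")
  if (is.null(binary)) {
    events <- normalize_events(events)
    binary <- events_to_binary(events, clock)
  } else {
    if (length(binary) != length(clock))
      stopf("'binary' and 'clock' lengths differ")
    binary <- as.logical(binary)
    events <- binary_to_events(binary, clock, dt)
  }
  valid <- valid %||% rep(TRUE, length(clock))
  es <- list(clock = as.numeric(clock), binary = binary, events = events,
             channel = channel, mouse = mouse, valid = as.logical(valid),
             fs = 1 / dt)
  class(es) <- "event_series"
  es
}

# Merge overlapping/touching bouts, sort, compute durations.
normalize_events <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0)))
  }
  if (any(events$offset_s <= events$onset_s))
    stopf("events must have positive duration")
  o <- order(events$onset_s)
  on <- events$onset_s[o]; off <- events$offset_s[o]
  mo <- on[1L]; mf <- off[1L]; ro <- numeric(0); rf <- numeric(0)
  for (i in seq_along(on)[-1L]) {
    if (on[i] <= mf) {
      mf <- max(mf, off[i])
    } else {
      ro <- c(ro, mo); rf <- c(rf, mf); mo <- on[i]; mf <- off[i]
    }
  }
  ro <- c(ro, mo); rf <- c(rf, mf)
  data.frame(onset_s = ro, offset_s = rf, duration_s = rf - ro)
}

events_to_binary <- function(events, clock) {
  b <- rep(FALSE, length(clock))
  for (i in seq_len(nrow(events))) {
    b <- b | (clock >= events$onset_s[i] & clock < events$offset_s[i])
  }
  b
}

binary_to_events <- function(binary, clock, dt) {
  r <- rle(as.logical(binary))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    onset_s = clock[starts[keep]],
    offset_s = clock[ends[keep]] + dt,
    duration_s = r$lengths[keep] * dt
  )
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("Event series [%s / %s]: %d samples at %.1f Hz, %d bouts (%.1f%% active)\n",
              x$mouse, x$channel, length(x$clock), x$fs, nrow(x$events),
              100 * mean(x$binary[x$valid])))
  invisible(x)
}

#' Ethogram plot of one or more event series
#'
#' Draws each series as a horizontal raster row with filled bars over bout
#' spans, the standard way behavior segmentations are displayed.
#'
#' @param x an `event_series` or list of them.
#' @param ... passed to [graphics::plot()].
#' @export
plot.event_series <- function(x, ...) {
  series <- if (inherits(x, "event_series")) list(x) else x
  n <- length(series)
  graphics::plot(NULL, xlim = range(series[[1L]]$clock), ylim = c(0, n),
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (i in seq_len(n)) {
    es <- series[[i]]
    if (nrow(es$events)) {
      graphics::rect(es$events$onset_s, n - i + 0.1, es$events$offset_s,
                     n - i + 0.9, col = "grey30", border = NA)
    }
    graphics::mtext(paste(es$mouse, es$channel), side = 2, at = n - i + 0.5,
                    las = 2, cex = 0.7)
  }
  invisible(x)
}

#' Generate ground-truth behavior bouts for a paired session
#'
#' Bout onsets for each mouse and behavior channel are drawn as independent
#' Poisson processes at `event_rate_hz` with exponentially distributed
#' durations (mean `mean_bout_s`). During the together phase only, each
#' stationary-mouse bout additionally triggers a moving-mouse bout with
#' probability `coupling`, at a lag drawn uniformly from `coupling_lag_s` —
#' the seconds-scale behavioral coordination two interacting mice show.
#' Outside the together phase the two mice are independent by construction.
#'
#' @param params a [session_params()] object.
#' @return object of class `ground_truth`: a list with `events` (nested list
#'   `[mouse][channel]` of [event_series()] on the behavior clock),
#'   `driven_region_map` (channel -> cortical region name), `hemo_trace`
#'   (shared slow artifact on the brain clock, unit SD), and
#'   `dropped_frame_indices` (per camera).
#' @export
generate_events <- function(params) {
  stopifnot(inherits(params, "session_params"))
  if (params$event_rate_hz < 0 || params$mean_bout_s <= 0)
    stopf("event rate must be >= 0 and mean bout duration > 0")
  set.seed(derive_seed(params$seed, 1L))
  dur <- params$duration_s
  clock <- seq(0, dur - 1e-9, by = 1 / params$fs_behavior)
  tog <- phase_window(params$phase_schedule, "together")

  draw_bouts <- function() {
    n <- stats::rpois(1L, params$event_rate_hz * dur)
    if (n == 0L) {
      return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
    }
    on <- sort(stats::runif(n, 0, dur))
    d <- stats::rexp(n, 1 / params$mean_bout_s)
    data.frame(onset_s = on, offset_s = pmin(on + d, dur))
  }

  mice <- c("stationary", "moving")
  channels <- c("whisker", "forelimb")
  raw <- list()
  for (m in mice) for (ch in channels) raw[[m]][[ch]] <- draw_bouts()

  # coupled triggering: stationary (A) bouts during together trigger moving
  # (B) bouts in the same channel
  if (params$coupling > 0) {
    for (ch in channels) {
      a <- raw$stationary[[ch]]
      in_tog <- a$onset_s >= tog[1L] & a$onset_s < tog[2L]
      trig <- in_tog & stats::runif(nrow(a)) < params$coupling
      if (any(trig)) {
        lag <- stats::runif(sum(trig), params$coupling_lag_s[1L],
                            params$coupling_lag_s[2L])
        on <- a$onset_s[trig] + lag
        d <- stats::rexp(sum(trig), 1 / params$mean_bout_s)
        extra <- data.frame(onset_s = on, offset_s = pmin(on + d, dur))
        extra <- extra[extra$onset_s < dur, , drop = FALSE]
        raw$moving[[ch]] <- rbind(raw$moving[[ch]], extra)
      }
    }
  }

  events <- list()
  for (m in mice) {
    for (ch in channels) {
      ev <- raw[[m]][[ch]]
      ev <- ev[ev$offset_s > ev$onset_s, , drop = FALSE]
      events[[m]][[ch]] <- event_series(clock, events = ev, channel = ch,
                                        mouse = m)
    }
  }

  # shared slow hemodynamic artifact on the brain clock: low-pass filtered
  # white noise (< ~0.1 Hz), scaled to unit SD
  nbr <- length(seq(0, dur - 1e-9, by = 1 / params$fs_brain))
  lp <- signal::butter(2, 0.1 / (params$fs_brain / 2), type = "low")
  h <- filtfilt_mat(matrix(stats::rnorm(nbr)), lp$b, lp$a)[, 1L]
  h <- h / stats::sd(h)

  drop_idx <- function(n) {
    k <- round(params$drop_frac * n)
    if (k < 1L) return(integer(0))
    sort(sample(2:(n - 1L), k))
  }
  nbeh <- length(clock)
  dropped <- list(
    brain_stationary = drop_idx(nbr),
    brain_moving = drop_idx(nbr),
    behavior = drop_idx(nbeh)
  )

  gt <- list(
    events = events,
    driven_region_map = c(whisker = "pBC", forelimb = "FL"),
    hemo_trace = h,
    dropped_frame_indices = dropped,
    together_window = tog
  )
  class(gt) <- "ground_truth"
  gt
}
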