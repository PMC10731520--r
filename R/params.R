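#' Default trial phase schedule
#'
#' The standard paired-session timeline: the mice start 14 cm apart, the
#' moving mouse is translated toward the stationary mouse 2 minutes after
#' imaging begins (~27.5 s of stage motion), the pair interacts face-to-face
#' for 2 minutes, and the stage then returns the moving mouse for a final
#' 2-minute separated period.
#'
#' @param separate_s duration of each separated phase (s).
#' @param translate_s duration of each stage translation (s).
#' @param together_s duration of the interaction ("together") phase (s).
#' @return data.frame with columns `phase`, `start_s`, `end_s` covering the
#'   whole trial with the labels `separate1`, `translate_in`, `together`,
#'   `translate_out`, `separate2`.
#' @export
default_phase_schedule <- function(separate_s = 120, translate_s = 27.5,
                                   together_s = 120) {
  lens <- c(separate_s, translate_s, together_s, translate_s, separate_s)
  ends <- cumsum(lens)
  data.frame(
    phase = c("separate1", "translate_in", "together", "translate_out",
              "separate2"),
    start_s = c(0, ends[-5L]),
    end_s = ends,
    stringsAsFactors = FALSE
  )
}

#' Look up a phase interval in a schedule
#'
#' @param schedule a phase schedule data.frame.
#' @param phase phase label, e.g. `"together"`.
#' @return `(start_s, end_s)` numeric pair.
#' @export
phase_window <- function(schedule, phase) {
  i <- match(phase, schedule$phase)
  if (is.na(i)) stopf("unknown phase '%s'", phase)
  c(schedule$start_s[i], schedule$end_s[i])
}

validate_phase_schedule <- function(schedule, duration_s) {
  need <- c("phase", "start_s", "end_s")
  if (!all(need %in% names(schedule)))
    stopf("phase schedule needs columns %s", paste(need, collapse = ", "))
  if (any(schedule$end_s <= schedule$start_s))
    stopf("phase schedule has non-positive phase durations")
  if (nrow(schedule) > 1L &&
      any(abs(schedule$start_s[-1L] - schedule$end_s[-nrow(schedule)]) > 1e-9))
    stopf("phases must be ordered, non-overlapping and contiguous")
  if (abs(schedule$start_s[1L]) > 1e-9 ||
      abs(schedule$end_s[nrow(schedule)] - duration_s) > 1e-9)
    stopf("phase schedule must cover [0, duration_s] exactly")
  invisible(schedule)
}

#' Parameters of a synthetic paired imaging session
#'
#' Bundles every knob of the two-mouse session generator: acquisition rates,
#' image geometry, the trial phase schedule, behavioral bout statistics, the
#' interaction coupling, signal/artifact/noise amplitudes and the dropped
#' frame rate. Defaults reproduce the standard acquisition conditions
#' (28.9 frames/s brain cameras, 90 frames/s behavior camera, ~0.1% dropped
#' frames, 2 min separate / ~27.5 s translation / 2 min together schedule).
#'
#' @param duration_s total trial length (s). Defaults to the phase schedule
#'   span.
#' @param fs_brain brain camera frame rate (frames/s).
#' @param fs_behavior behavior camera frame rate (frames/s).
#' @param image_size brain image side length in pixels (square frames);
#'   64 is the full-scale default, smaller values are convenient for tests.
#' @param phase_schedule data.frame as from [default_phase_schedule()].
#' @param event_rate_hz Poisson rate of behavior bout onsets per mouse per
#'   channel (whisker, forelimb).
#' @param mean_bout_s mean of the exponential bout-duration distribution (s).
#' @param coupling probability in \[0,1\] that a stationary-mouse bout
#'   triggers a time-locked moving-mouse bout during the together phase.
#' @param coupling_lag_s two-element range (s) of the uniform trigger lag.
#' @param response_gain peak dF/F0 of the calcium transient each bout evokes
#'   in its driven region.
#' @param global_frac fraction of `response_gain` applied uniformly across
#'   the whole masked cortex for every bout, emulating the widespread
#'   movement-related activation that accompanies the somatotopically
#'   focused response (the global cortical signal rises with behavior).
#' @param partner_gain peak dF/F0 evoked in a mouse's own cortex by the
#'   partner's bouts during the together phase (direct touch-driven drive,
#'   used by the encoding-model analyses). Default 0: by default the only
#'   social pathway is behavioral triggering via `coupling`, so interbrain
#'   correlation at `coupling = 0` is at chance. Set to `response_gain` for
#'   open-interaction encoding sessions and 0 for barrier ("mesh") sessions.
#' @param hemo_gain amplitude (dF/F0 units) of the shared slow hemodynamic
#'   artifact injected identically into green and blue channels.
#' @param noise_sd per-pixel per-frame sensor noise, as a fraction of
#'   baseline intensity.
#' @param drop_frac fraction of randomly dropped camera frames (default
#'   0.001, i.e. 0.1%).
#' @param gfp_mode logical; emulate an activity-independent fluorophore
#'   control animal (response and partner gains forced to 0, hemodynamic
#'   artifact retained).
#' @param kernel_rise_s,kernel_decay_s calcium kernel time constants (s).
#' @param blob_sigma_px spatial sigma of the Gaussian region footprint at
#'   `image_size = 64` (scaled proportionally for other sizes).
#' @param led_lead_s dark lead-in before the illumination LEDs switch on (s),
#'   used downstream for cross-camera synchronization.
#' @param seed integer seed making the whole session reproducible.
#' @return object of class `session_params`.
#' @export
session_params <- function(duration_s = NULL,
                           fs_brain = 28.9,
                           fs_behavior = 90,
                           image_size = 64L,
                           phase_schedule = default_phase_schedule(),
                           event_rate_hz = 0.1,
                           mean_bout_s = 2,
                           coupling = 0.6,
                           coupling_lag_s = c(0, 1),
                           response_gain = 0.05,
                           global_frac = 0.3,
                           partner_gain = 0,
                           hemo_gain = 0.01,
                           noise_sd = 0.02,
                           drop_frac = 0.001,
                           gfp_mode = FALSE,
                           kernel_rise_s = 0.2,
                           kernel_decay_s = 1.5,
                           blob_sigma_px = 3,
                           led_lead_s = 1,
                           seed = 1L) {
  duration_s <- duration_s %||% max(phase_schedule$end_s)
  assert_scalar_num(duration_s, "duration_s", lo = 1)
  assert_scalar_num(fs_brain, "fs_brain", lo = 1)
  assert_scalar_num(fs_behavior, "fs_behavior", lo = 1)
  assert_scalar_num(event_rate_hz, "event_rate_hz", lo = 0)
  assert_scalar_num(mean_bout_s, "mean_bout_s")
  if (mean_bout_s <= 0) stopf("'mean_bout_s' must be > 0")
  assert_scalar_num(coupling, "coupling", lo = 0, hi = 1)
  assert_scalar_num(drop_frac, "drop_frac", lo = 0, hi = 0.05)
  assert_scalar_num(response_gain, "response_gain", lo = 0)
  assert_scalar_num(global_frac, "global_frac", lo = 0)
  assert_scalar_num(hemo_gain, "hemo_gain", lo = 0)
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  validate_phase_schedule(phase_schedule, duration_s)
  if (length(coupling_lag_s) != 2L || diff(coupling_lag_s) < 0 ||
      any(coupling_lag_s < 0))
    stopf("'coupling_lag_s' must be a nondecreasing nonnegative pair")
  if (isTRUE(gfp_mode)) {
    response_gain <- 0
    partner_gain <- 0
  }
  p <- list(
    duration_s = duration_s, fs_brain = fs_brain, fs_behavior = fs_behavior,
    image_size = as.integer(image_size), phase_schedule = phase_schedule,
    event_rate_hz = event_rate_hz, mean_bout_s = mean_bout_s,
    coupling = coupling, coupling_lag_s = coupling_lag_s,
    response_gain = response_gain, global_frac = global_frac,
    partner_gain = partner_gain,
    hemo_gain = hemo_gain, noise_sd = noise_sd, drop_frac = drop_frac,
    gfp_mode = isTRUE(gfp_mode), kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s, blob_sigma_px = blob_sigma_px,
    led_lead_s = led_lead_s, seed = as.integer(seed)
  )
  class(p) <- "session_params"
  p
}

#' @export
print.session_params <- function(x, ...) {
  cat("Synthetic paired-session parameters\n")
  cat(sprintf("  duration %.1f s, brain %.1f fps (%dx%d px), behavior %.0f fps\n",
              x$duration_s, x$fs_brain, x$image_size, x$image_size,
              x$fs_behavior))
  cat(sprintf("  bouts: rate %.3g Hz, mean %.2g s; coupling %.2f (lag %g-%g s)\n",
              x$event_rate_hz, x$mean_bout_s, x$coupling,
              x$coupling_lag_s[1], x$coupling_lag_s[2]))
  cat(sprintf("  gains: response %.3g, partner %.3g, hemo %.3g; noise %.3g; drop %.2g%%%s\n",
              x$response_gain, x$partner_gain, x$hemo_gain, x$noise_sd,
              100 * x$drop_frac, if (x$gfp_mode) " [GFP mode]" else ""))
  invisible(x)
}
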