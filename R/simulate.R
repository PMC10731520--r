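#' Double-exponential calcium impulse response
#'
#' Difference-of-exponentials kernel (default 0.2 s rise, 1.5 s decay)
#' emulating the slow kinetics of the GCaMP6s indicator, normalized to unit
#' peak so gains are expressed directly as peak dF/F0.
#'
#' @param fs sampling rate (frames/s).
#' @param rise_s,decay_s time constants (s).
#' @param length_s kernel support (s); default 6 decay constants.
#' @return numeric vector, kernel sampled at `fs` starting at lag 0.
#' @export
calcium_kernel <- function(fs, rise_s = 0.2, decay_s = 1.5,
                           length_s = 6 * decay_s) {
  t <- seq(0, length_s, by = 1 / fs)
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h / max(h)
}

# causal FIR convolution, y[t] = sum_j k[j] x[t-j+1], zero initial history
conv_causal <- function(x, k) {
  nk <- length(k)
  y <- stats::filter(c(numeric(nk - 1L), x), k, method = "convolution",
                     sides = 1L)
  as.numeric(y[-seq_len(nk - 1L)])
}

# Synthetic window geometry: the square field of view spans `fov_mm`
# (10.2 mm full scale) and bregma sits on the vertical midline at 45% depth.
synthetic_key_points <- function(image_size, fov_mm = 10.2) {
  mm_per_px <- fov_mm / image_size
  cx <- (image_size - 1) / 2
  by <- 0.45 * (image_size - 1)
  key_points(
    bregma_px = c(cx, by),
    sinus_px = c(cx, by + 4 / mm_per_px),
    ob_frontal_px = c(cx, by - 3.2 / mm_per_px)
  )
}

# circular transcranial mask inscribed in the frame
synthetic_mask <- function(image_size) {
  c0 <- (image_size + 1) / 2
  r <- 0.49 * image_size
  d <- outer(seq_len(image_size) - c0, seq_len(image_size) - c0,
             function(y, x) sqrt(x^2 + y^2))
  d <= r
}

# unit-peak Gaussian blob (length H*W vector) at 0-based pixel (x, y)
region_blob <- function(image_size, x, y, sigma) {
  g <- outer(
    exp(-((seq_len(image_size) - 1 - y)^2) / (2 * sigma^2)),
    exp(-((seq_len(image_size) - 1 - x)^2) / (2 * sigma^2))
  )
  as.numeric(g)
}

#' Raw image stack from one camera channel
#'
#' @param frames T x H x W array of nonnegative intensities.
#' @param timestamps per-frame acquisition times (s), strictly increasing.
#' @param channel_label `"green_gcamp"` or `"blue_reflectance"`.
#' @return object of class `raw_stack`.
#' @export
raw_stack <- function(frames, timestamps,
                      channel_label = c("green_gcamp", "blue_reflectance")) {
  channel_label <- match.arg(channel_label)
  d <- dim(frames)
  if (length(d) != 3L || d[1L] < 2L || d[2L] < 1L || d[3L] < 1L)
    stopf("'frames' must be a T x H x W array with T >= 2")
  if (length(timestamps) != d[1L]) stopf("one timestamp per frame required")
  if (any(diff(timestamps) <= 0)) stopf("timestamps must be strictly increasing")
  if (any(frames < 0)) stopf("negative intensities in raw stack")
  s <- list(frames = frames, timestamps = as.numeric(timestamps),
            channel_label = channel_label)
  class(s) <- "raw_stack"
  s
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Raw %s stack: %d frames of %dx%d, %.1f-%.1f s\n",
              x$channel_label, d[1L], d[2L], d[3L],
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Render a raw paired session from ground-truth events
#'
#' Produces the signals the cameras would record. Each mouse's green channel
#' carries a baseline plus, for every behavior channel, the bout-onset train
#' convolved with the calcium kernel, painted onto bilateral Gaussian
#' footprints of the driven region; the shared slow hemodynamic artifact is
#' injected identically into green and blue channels (so channel subtraction
#' cancels it), plus independent per-pixel sensor noise. During the together
#' phase the partner's bouts additionally drive the subject's own region at
#' `partner_gain`. A dark lead-in precedes the LED switching on (used for
#' synchronization), frames listed in the ground truth are dropped with
#' timestamps preserved, and behavior ROI traces fluctuate frame-to-frame
#' while a bout is ongoing so ROI motion energy is sustained across the bout.
#'
#' @param params a [session_params()] object.
#' @param truth the matching [generate_events()] output.
#' @return object of class `raw_session`: brain stacks per mouse and
#'   channel, behavior ROI traces, mask, key-points, placed regions, and the
#'   phase schedule.
#' @export
render_session <- function(params, truth) {
  stopifnot(inherits(params, "session_params"))
  if (!inherits(truth, "ground_truth"))
    stopf("'truth' must come from generate_events()")
  nb_expect <- length(truth$hemo_trace)
  tb <- seq(0, params$duration_s - 1e-9, by = 1 / params$fs_brain)
  if (length(tb) != nb_expect)
    stopf("params and truth disagree on frame count; regenerate the truth")
  set.seed(derive_seed(params$seed, 2L))

  n <- params$image_size
  npix <- n * n
  mask <- synthetic_mask(n)
  kp <- synthetic_key_points(n)
  tr <- fit_transform(kp)
  regions <- rbind(place_regions(tr, default_regions("right"), mask),
                   place_regions(tr, default_regions("left"), mask))
  sigma <- params$blob_sigma_px * n / 64
  kern <- calcium_kernel(params$fs_brain, params$kernel_rise_s,
                         params$kernel_decay_s)
  tog <- truth$together_window
  fs <- params$fs_brain
  nb <- length(tb)
  n_lead <- round(params$led_lead_s * fs)

  onset_train <- function(onsets) {
    v <- numeric(nb)
    if (length(onsets)) {
      idx <- pmin(nb, floor(onsets * fs) + 1L)
      for (i in idx) v[i] <- v[i] + 1
    }
    v
  }
  mask_vec <- as.numeric(mask)
  # somatotopic footprint plus a diffuse cortex-wide component: movement
  # engages broad dorsal cortex, not only the driven region
  blob_for <- function(region_name) {
    r <- regions[regions$name == region_name, , drop = FALSE]
    b <- params$global_frac * mask_vec
    for (i in seq_len(nrow(r)))
      b <- b + region_blob(n, r$x_px[i], r$y_px[i], sigma)
    b
  }

  mice <- c("stationary", "moving")
  other <- c(stationary = "moving", moving = "stationary")
  channels <- names(truth$driven_region_map)
  baseline <- c(green = 100, blue = 80)
  hemo <- params$hemo_gain * truth$hemo_trace

  brain <- list()
  for (m in mice) {
    sig <- matrix(0, nb, npix)
    for (ch in channels) {
      own <- truth$events[[m]][[ch]]$events$onset_s
      trace <- params$response_gain * conv_causal(onset_train(own), kern)
      po <- truth$events[[other[[m]]]][[ch]]$events$onset_s
      po <- po[po >= tog[1L] & po < tog[2L]]
      if (params$partner_gain > 0 && length(po))
        trace <- trace +
          params$partner_gain * conv_causal(onset_train(po), kern)
      if (any(trace != 0))
        sig <- sig + trace %o% blob_for(truth$driven_region_map[[ch]])
    }
    cam_drop <- truth$dropped_frame_indices[[paste0("brain_", m)]]
    mk_stack <- function(frac_signal, base, label) {
      f <- base * (1 + frac_signal + hemo +
                     matrix(stats::rnorm(nb * npix, 0, params$noise_sd),
                            nb, npix))
      f[f < 0] <- 0
      dark <- matrix(abs(stats::rnorm(n_lead * npix, 0.01 * base,
                                      0.005 * base)), n_lead, npix)
      allf <- rbind(dark, f)
      ts <- (seq_len(n_lead + nb) - 1) / fs
      if (length(cam_drop)) {
        keep <- setdiff(seq_len(n_lead + nb), n_lead + cam_drop)
        allf <- allf[keep, , drop = FALSE]
        ts <- ts[keep]
      }
      raw_stack(tp_to_stack(allf, n, n), ts, label)
    }
    brain[[m]] <- list(
      green = mk_stack(sig, baseline[["green"]], "green_gcamp"),
      blue = mk_stack(0, baseline[["blue"]], "blue_reflectance")
    )
  }

  # behavior ROI traces: the ROI mean jumps up/down every frame while a bout
  # is ongoing (movement), with small camera noise everywhere; the moving
  # mouse is only in frame during the together phase
  beh_clock <- truth$events$stationary$whisker$clock
  nbe <- length(beh_clock)
  n_lead_b <- round(params$led_lead_s * params$fs_behavior)
  bout_amp <- 2
  traces <- list()
  for (m in mice) {
    traces[[m]] <- list()
    for (ch in channels) {
      b <- truth$events[[m]][[ch]]$binary
      if (m == "moving")
        b <- b & beh_clock >= tog[1L] & beh_clock < tog[2L]
      zig <- rep_len(c(1, -1), nbe)
      tr_lit <- 50 + bout_amp * zig * b + stats::rnorm(nbe, 0, 0.3)
      full <- c(stats::rnorm(n_lead_b, 5, 0.3), tr_lit)
      traces[[m]][[ch]] <- full
    }
  }
  ts_b <- (seq_len(n_lead_b + nbe) - 1) / params$fs_behavior
  bdrop <- truth$dropped_frame_indices$behavior
  if (length(bdrop)) {
    keep <- setdiff(seq_len(n_lead_b + nbe), n_lead_b + bdrop)
    for (m in mice) for (ch in channels)
      traces[[m]][[ch]] <- traces[[m]][[ch]][keep]
    ts_b <- ts_b[keep]
  }

  sess <- list(
    params = params,
    brain = brain,
    behavior = list(timestamps = ts_b, fs = params$fs_behavior,
                    traces = traces),
    mask = mask,
    key_points = kp,
    regions = regions,
    phase_schedule = params$phase_schedule
  )
  class(sess) <- "raw_session"
  sess
}

#' @export
print.raw_session <- function(x, ...) {
  d <- dim(x$brain$stationary$green$frames)
  cat(sprintf("Raw paired session: %dx%d px, %d green frames/mouse, %.0f s, %d phases\n",
              d[2L], d[3L], d[1L], x$params$duration_s,
              nrow(x$phase_schedule)))
  invisible(x)
}

#' Generate a complete synthetic paired session
#'
#' Convenience wrapper running [generate_events()] then [render_session()].
#'
#' @param params a [session_params()] object.
#' @return list with elements `session` (a `raw_session`) and `truth`
#'   (the `ground_truth`).
#' @export
simulate_session <- function(params = session_params()) {
  truth <- generate_events(params)
  list(session = render_session(params, truth), truth = truth)
}
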