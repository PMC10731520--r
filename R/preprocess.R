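#' Fractional-change (dF/F0) image stack
#'
#' @param values T x H x W array of unitless dF/F0 values.
#' @param mask H x W logical in-window mask; masked-out pixels are held at 0
#'   and excluded from statistics.
#' @param fs frame rate (frames/s).
#' @param provenance ordered character vector of processing steps applied.
#' @return object of class `dff_stack`.
#' @export
dff_stack <- function(values, mask, fs, provenance = character(0)) {
  d <- dim(values)
  if (length(d) != 3L) stopf("'values' must be T x H x W")
  if (!identical(dim(mask), d[2:3])) stopf("mask shape must match frames")
  if (any(!is.finite(as_tp(values)[, as.vector(mask)])))
    stopf("non-finite dF/F0 values inside mask")
  s <- list(values = values, mask = mask, fs = fs, provenance = provenance)
  class(s) <- "dff_stack"
  s
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dF/F0 stack: %d frames of %dx%d at %.1f fps (%d masked px)\n",
              d[1L], d[2L], d[3L], x$fs, sum(x$mask)))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Detect the LED illumination onset used for camera synchronization
#'
#' The illumination LEDs switch on at trial start, producing a dark-to-lit
#' step in every camera's mean frame intensity; streams are cropped to this
#' frame so all cameras share a clock. The onset is the first frame whose
#' mean intensity exceeds the midpoint between the pre- and post-transition
#' plateau means.
#'
#' @param stack a `raw_stack`, or a numeric vector of per-frame mean
#'   intensities.
#' @param min_range minimum (max - min) mean-intensity excursion to accept a
#'   transition; default 20% of the maximum mean intensity.
#' @return integer frame index (1-based) of the first lit frame.
#' @export
detect_led_onset <- function(stack, min_range = NULL) {
  m <- if (inherits(stack, "raw_stack")) {
    rowMeans(as_tp(stack$frames))
  } else {
    as.numeric(stack)
  }
  rng <- max(m) - min(m)
  floor_ <- min_range %||% (0.2 * max(m))
  if (!is.finite(rng) || rng < floor_ || rng == 0)
    stopf("sync error: no illumination transition found (range %.3g < floor %.3g)",
          rng, floor_)
  mid0 <- (max(m) + min(m)) / 2
  lit <- m > mid0
  thr <- (mean(m[!lit]) + mean(m[lit])) / 2
  which(m > thr)[1L]
}

#' Crop a raw stack at its LED onset
#'
#' @param stack a `raw_stack`.
#' @param ... passed to [detect_led_onset()].
#' @return the stack cropped to start at the onset frame, timestamps
#'   re-zeroed at that frame.
#' @export
sync_to_led <- function(stack, ...) {
  i <- detect_led_onset(stack, ...)
  keep <- i:dim(stack$frames)[1L]
  raw_stack(stack$frames[keep, , , drop = FALSE],
            stack$timestamps[keep] - stack$timestamps[i],
            stack$channel_label)
}

#' Interpolate dropped camera frames back onto the nominal grid
#'
#' Cameras occasionally drop frames when writing to disk (~0.1% of frames);
#' gaps are identified from the timestamps (spacing > 1.5 nominal frame
#' periods) and the missing frames are reconstructed by per-pixel linear
#' interpolation between the flanking frames, yielding a uniformly sampled
#' stack.
#'
#' @param stack a `raw_stack`.
#' @param nominal_fs nominal frame rate (frames/s).
#' @return a uniformly sampled `raw_stack`.
#' @export
interpolate_dropped_frames <- function(stack, nominal_fs) {
  ts <- stack$timestamps
  dt <- 1 / nominal_fs
  n_out <- round((ts[length(ts)] - ts[1L]) / dt) + 1L
  grid <- ts[1L] + (seq_len(n_out) - 1L) * dt
  # match grid points to observed frames
  idx <- findInterval(grid + dt / 4, ts)
  idx[idx < 1L] <- 1L
  exact <- abs(ts[idx] - grid) <= dt / 4
  if (all(exact) && n_out == length(ts)) {
    out <- raw_stack(stack$frames, grid, stack$channel_label)
    return(out)
  }
  m <- as_tp(stack$frames)
  res <- matrix(0, n_out, ncol(m))
  res[exact, ] <- m[idx[exact], , drop = FALSE]
  miss <- which(!exact)
  for (g in miss) {
    lo <- findInterval(grid[g], ts)
    if (lo < 1L || lo >= length(ts)) {
      warnf("gap at sequence edge: replicating boundary frame")
      res[g, ] <- m[max(1L, min(lo, length(ts))), ]
    } else {
      w <- (grid[g] - ts[lo]) / (ts[lo + 1L] - ts[lo])
      res[g, ] <- (1 - w) * m[lo, ] + w * m[lo + 1L, ]
    }
  }
  d <- dim(stack$frames)
  raw_stack(tp_to_stack(res, d[2L], d[3L]), grid, stack$channel_label)
}

#' Convert a raw stack to dF/F0
#'
#' The baseline image F0 is the per-pixel temporal mean over the entire
#' recording; each frame is converted to (F - F0) / F0.
#'
#' @param stack a `raw_stack` (uniformly sampled).
#' @param mask H x W logical mask; default all pixels.
#' @return a `dff_stack` (masked-out pixels set to 0).
#' @export
compute_dff <- function(stack, mask = NULL) {
  d <- dim(stack$frames)
  mask <- mask %||% matrix(TRUE, d[2L], d[3L])
  m <- as_tp(stack$frames)
  f0 <- colMeans(m)
  bad <- which(f0 <= 0 & as.vector(mask))
  if (length(bad))
    stopf("degenerate pixels with F0 <= 0 inside mask: %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  v <- sweep(sweep(m, 2L, f0, "-"), 2L, pmax(f0, .Machine$double.eps), "/")
  v[, !as.vector(mask)] <- 0
  fs <- 1 / stats::median(diff(stack$timestamps))
  dff_stack(tp_to_stack(v, d[2L], d[3L]), mask, fs,
            provenance = c(paste0("dff[", stack$channel_label, "]")))
}

#' Clip extreme dF/F0 excursions
#'
#' Extreme values (window-edge pixels, small F0 denominators) are clamped to
#' a threshold before smoothing/filtering so they cannot smear into their
#' neighborhood: for GCaMP data the threshold is each pixel's temporal
#' mean +/- 3.5 SD; for reflectance data a fixed +/- 15% dF/F0 (far above
#' physiological reflectance changes). Idempotent on already-clipped data.
#'
#' @param dff a `dff_stack`.
#' @param mode `"gcamp"` (per-pixel mean +/- 3.5 SD) or `"reflectance"`
#'   (+/- 0.15, symmetric about zero).
#' @param n_sd SD multiplier for gcamp mode.
#' @param reflectance_limit absolute limit for reflectance mode.
#' @return the clipped `dff_stack`.
#' @export
clip_extremes <- function(dff, mode = c("gcamp", "reflectance"),
                          n_sd = 3.5, reflectance_limit = 0.15) {
  mode <- match.arg(mode)
  d <- dim(dff$values)
  v <- as_tp(dff$values)
  if (mode == "gcamp") {
    mu <- colMeans(v)
    sd_ <- sqrt(colMeans(v^2) - mu^2) * sqrt(nrow(v) / (nrow(v) - 1L))
    v <- clip_cols_cpp(v, mu - n_sd * sd_, mu + n_sd * sd_)
  } else {
    v <- clip_cols_cpp(v, rep(-reflectance_limit, ncol(v)),
                       rep(reflectance_limit, ncol(v)))
  }
  dff_stack(tp_to_stack(v, d[2L], d[3L]), dff$mask, dff$fs,
            c(dff$provenance, paste0("clip[", mode, "]")))
}

#' Hemodynamic correction by reflectance subtraction
#'
#' Blood-volume changes modulate both the fluorescence channel and the
#' near-isosbestic (440 nm) blue reflectance channel; subtracting the
#' reflectance dF/F0 from the fluorescence dF/F0 elementwise removes the
#' shared artifact.
#'
#' @param green,blue `dff_stack`s on the same clock and geometry.
#' @return corrected `dff_stack`; provenance records both parents.
#' @export
hemodynamic_correct <- function(green, blue) {
  if (!identical(dim(green$values), dim(blue$values)))
    stopf("alignment error: stack shapes differ")
  if (abs(green$fs - blue$fs) > 1e-6 * green$fs)
    stopf("alignment error: frame rates differ")
  dff_stack(green$values - blue$values, green$mask, green$fs,
            c(green$provenance,
              paste0("subtract[", utils::tail(blue$provenance, 1L), "]")))
}

#' Spatial smoothing and temporal band-pass filtering
#'
#' Each frame is smoothed with a sigma = 1 px Gaussian (separable
#' convolution, reflect padding), then every pixel's time series is filtered
#' with a 4th-order Butterworth band-pass (0.01-12 Hz by default) applied
#' zero-phase (forward-backward), so correlation and lag analyses see no
#' phase distortion. The per-pixel temporal mean (DC, outside the passband)
#' is removed before filtering.
#'
#' @param dff a `dff_stack`.
#' @param spatial_sigma Gaussian sigma in pixels.
#' @param band band-pass edges (Hz).
#' @param order Butterworth order.
#' @return filtered `dff_stack`.
#' @export
smooth_and_bandpass <- function(dff, spatial_sigma = 1,
                                band = c(0.01, 12), order = 4) {
  fs <- dff$fs
  if (fs / 2 <= band[2L])
    stopf("upper band edge %.3g Hz is not below Nyquist (%.3g Hz)", band[2L],
          fs / 2)
  d <- dim(dff$values)
  if (d[1L] / fs < 3 / band[1L])
    warnf("recording (%.1f s) shorter than 3x the longest filter time constant (%.1f s); filter transients may be large",
          d[1L] / fs, 3 / band[1L])
  v <- dff$values
  if (spatial_sigma > 0) v <- gaussian_blur_stack(v, spatial_sigma)
  m <- as_tp(v)
  m <- sweep(m, 2L, colMeans(m), "-")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  m <- filtfilt_mat(m, bf$b, bf$a)
  m[, !as.vector(dff$mask)] <- 0
  dff_stack(tp_to_stack(m, d[2L], d[3L]), dff$mask, fs,
            c(dff$provenance,
              sprintf("gauss[sigma=%g]", spatial_sigma),
              sprintf("butter[%g-%g Hz, order %d, zero-phase]",
                      band[1L], band[2L], order)))
}

# Separable Gaussian blur of every frame of a T x H x W array, reflect
# padding, kernel truncated at 4 sigma; compiled inner loop.
gaussian_blur_stack <- function(x, sigma) {
  gauss_blur_frames_cpp(x, dim(x), gauss_kernel(sigma))
}

#' Preprocess one mouse's dual-channel recording
#'
#' Runs the full, fixed-order pipeline on a pair of raw stacks: LED-onset
#' synchronization, dropped-frame interpolation, dF/F0 conversion, extreme
#' clipping (per channel mode), reflectance subtraction, then spatial
#' smoothing and temporal band-pass. Also returns the green channel processed
#' without subtraction (identically smoothed/filtered), since comparing
#' corrected and uncorrected results is a standard control.
#'
#' @param green,blue `raw_stack`s from the same camera.
#' @param mask H x W logical mask.
#' @param nominal_fs nominal frame rate (frames/s).
#' @param ... passed to [smooth_and_bandpass()].
#' @return list with `corrected` and `uncorrected_green` `dff_stack`s.
#' @export
preprocess_stack_pair <- function(green, blue, mask, nominal_fs, ...) {
  g <- interpolate_dropped_frames(sync_to_led(green), nominal_fs)
  b <- interpolate_dropped_frames(sync_to_led(blue), nominal_fs)
  nmin <- min(dim(g$frames)[1L], dim(b$frames)[1L])
  crop <- function(s) raw_stack(s$frames[seq_len(nmin), , , drop = FALSE],
                                s$timestamps[seq_len(nmin)], s$channel_label)
  g <- crop(g); b <- crop(b)
  gd <- clip_extremes(compute_dff(g, mask), "gcamp")
  bd <- clip_extremes(compute_dff(b, mask), "reflectance")
  corrected <- smooth_and_bandpass(hemodynamic_correct(gd, bd), ...)
  uncorrected <- smooth_and_bandpass(gd, ...)
  list(corrected = corrected, uncorrected_green = uncorrected)
}

#' Preprocess a whole paired session
#'
#' Applies [preprocess_stack_pair()] to both mice of a `raw_session` and
#' extracts the synchronized behavior clock (behavior traces cropped at the
#' behavior camera's LED onset).
#'
#' @param session a `raw_session`.
#' @param ... passed to [smooth_and_bandpass()].
#' @return object of class `preprocessed_session`: per-mouse `corrected` and
#'   `uncorrected_green` stacks, behavior traces on the synchronized clock,
#'   mask, placed regions, and the phase schedule.
#' @export
preprocess_session <- function(session, ...) {
  stopifnot(inherits(session, "raw_session"))
  fs <- session$params$fs_brain
  out <- list()
  for (m in names(session$brain)) {
    out[[m]] <- preprocess_stack_pair(session$brain[[m]]$green,
                                      session$brain[[m]]$blue,
                                      session$mask, fs, ...)
  }
  # behavior LED sync: use the whisker ROI trace (any ROI sees the step)
  beh <- session$behavior
  on_b <- detect_led_onset(beh$traces$stationary$whisker)
  keep <- on_b:length(beh$timestamps)
  traces <- lapply(beh$traces, function(tm)
    lapply(tm, function(v) v[keep]))
  res <- list(
    mice = out,
    behavior = list(timestamps = beh$timestamps[keep] -
                      beh$timestamps[on_b],
                    fs = beh$fs, traces = traces),
    mask = session$mask,
    regions = session$regions,
    phase_schedule = session$phase_schedule
  )
  class(res) <- "preprocessed_session"
  res
}
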