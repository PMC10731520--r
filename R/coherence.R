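#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw` by solving the classical symmetric tridiagonal eigenproblem
#' whose eigenvectors are the Slepian sequences. Tapers are unit-energy and
#' sign-fixed (positive mean for even orders, positive initial slope for odd
#' orders).
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers (at most `2*nw - 1` is sensible).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 5, k = 9) {
  if (k > n) stopf("more tapers than samples")
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t0 <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off <- seq_len(n - 1L) * (n - seq_len(n - 1L)) / 2
  A <- diag(diag_main)
  A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  A[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  ev <- eigen(A, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (j %% 2L == 1L) {
      if (sum(h[, j]) < 0) h[, j] <- -h[, j]
    } else {
      if (h[2L, j] - h[1L, j] < 0) h[, j] <- -h[, j]
    }
  }
  .taper_cache[[key]] <- h
  h
}

# solved tapers are reused across sliding windows and sessions
.taper_cache <- new.env(parent = emptyenv())

#' Time-varying multitaper coherence between two signals
#'
#' Magnitude-squared coherence estimated in sliding windows (default 45 s
#' with 22.5 s overlap) with DPSS multitaper spectral estimates
#' (time-bandwidth product 5, 9 tapers). Within each window, per-taper
#' cross- and auto-spectra are summed over tapers and combined as
#' `|sum S_ab|^2 / (sum S_aa * sum S_bb)`, which lies in \[0, 1\].
#'
#' @param a,b `global_signal`s or numeric vectors on a common clock.
#' @param fs sampling rate (required for bare vectors).
#' @param window_s window length (s).
#' @param overlap_s window overlap (s); the step is `window_s - overlap_s`.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return object of class `coherence_map`: list with `times` (window
#'   centers, s), `freqs` (Hz), `coherence` (time x freq matrix) and
#'   `params`.
#' @export
mt_coherence <- function(a, b, fs = NULL, window_s = 45, overlap_s = 22.5,
                         nw = 5, k = 9) {
  va <- if (inherits(a, "global_signal")) a$values else as.numeric(a)
  vb <- if (inherits(b, "global_signal")) b$values else as.numeric(b)
  fs <- fs %||% a$fs
  if (length(va) != length(vb)) stopf("signals differ in length")
  nwin <- round(window_s * fs)
  if (nwin > length(va)) stopf("window (%d samples) longer than signal (%d)",
                               nwin, length(va))
  step <- round((window_s - overlap_s) * fs)
  if (step < 1L) stopf("overlap must be smaller than the window")
  tapers <- dpss_tapers(nwin, nw, k)
  nf <- nwin %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / nwin
  starts <- seq(1L, length(va) - nwin + 1L, by = step)
  coh <- matrix(NA_real_, length(starts), nf)
  for (s in seq_along(starts)) {
    ia <- starts[s]:(starts[s] + nwin - 1L)
    xa <- va[ia] - mean(va[ia])
    xb <- vb[ia] - mean(vb[ia])
    Fa <- stats::mvfft(tapers * xa)[seq_len(nf), , drop = FALSE]
    Fb <- stats::mvfft(tapers * xb)[seq_len(nf), , drop = FALSE]
    sab <- rowSums(Fa * Conj(Fb))
    saa <- rowSums(Mod(Fa)^2)
    sbb <- rowSums(Mod(Fb)^2)
    coh[s, ] <- Mod(sab)^2 / (saa * sbb)
  }
  cm <- list(times = (starts - 1L + nwin / 2) / fs, freqs = freqs,
             coherence = coh,
             params = list(window_s = window_s, overlap_s = overlap_s,
                           nw = nw, k = k, fs = fs))
  class(cm) <- "coherence_map"
  cm
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("Multitaper coherence map: %d windows x %d freqs (0-%.2f Hz), NW=%g K=%d\n",
              nrow(x$coherence), ncol(x$coherence), max(x$freqs),
              x$params$nw, x$params$k))
  invisible(x)
}

#' @export
plot.coherence_map <- function(x, zlim = c(0, 1), fmax = NULL, ...) {
  keep <- if (is.null(fmax)) seq_along(x$freqs) else which(x$freqs <= fmax)
  graphics::image(x$times, x$freqs[keep], x$coherence[, keep, drop = FALSE],
                  zlim = zlim, xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Mean coherence in a time x frequency box
#'
#' Utility for summarizing a [mt_coherence()] map over a trial phase and a
#' frequency band.
#'
#' @param cm a `coherence_map`.
#' @param time_range `(start_s, end_s)` window-center range.
#' @param freq_range `(lo_hz, hi_hz)` band.
#' @return mean coherence over the selected cells.
#' @export
coherence_band_mean <- function(cm, time_range, freq_range) {
  ti <- cm$times >= time_range[1L] & cm$times <= time_range[2L]
  fi <- cm$freqs >= freq_range[1L] & cm$freqs <= freq_range[2L]
  if (!any(ti) || !any(fi)) stopf("empty time or frequency selection")
  mean(cm$coherence[ti, fi])
}
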