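#' Global cortical signal
#'
#' Per-frame spatial median of dF/F0 over all masked dorsal-cortex pixels —
#' a robust summary of whole-cortex activation.
#'
#' @param dff a `dff_stack`.
#' @return object of class `global_signal`: list with `values`, `fs`.
#' @export
global_signal <- function(dff) {
  if (!any(dff$mask)) stopf("empty mask")
  m <- as_tp(dff$values)[, as.vector(dff$mask), drop = FALSE]
  gs <- list(values = row_medians_cpp(m), fs = dff$fs)
  class(gs) <- "global_signal"
  gs
}

#' Region time series
#'
#' For each placed region, the per-frame median over the 5x5 pixel block
#' centered on the region's pixel location.
#'
#' @param dff a `dff_stack`.
#' @param rs a placed `region_set` (see [place_regions()]).
#' @param half half-width of the block (2 gives the standard 5x5 area).
#' @return regions x time matrix with region names as rownames.
#' @export
region_timeseries <- function(dff, rs, half = 2L) {
  d <- dim(dff$values)
  m <- as_tp(dff$values)
  out <- matrix(NA_real_, nrow(rs), d[1L], dimnames = list(rs$name, NULL))
  for (i in seq_len(nrow(rs))) {
    ys <- rs$y_px[i] + (-half):half + 1L
    xs <- rs$x_px[i] + (-half):half + 1L
    if (min(ys) < 1L || max(ys) > d[2L] || min(xs) < 1L || max(xs) > d[3L])
      stopf("region '%s': %dx%d block exceeds image bounds", rs$name[i],
            2L * half + 1L, 2L * half + 1L)
    if (!all(dff$mask[ys, xs]))
      stopf("region '%s': block not fully inside mask", rs$name[i])
    pix <- as.vector(outer(ys, (xs - 1L) * d[2L], "+"))
    out[i, ] <- row_medians_cpp(m[, pix, drop = FALSE])
  }
  out
}

# centered 60-s analysis window (samples) within a phase interval
analysis_window_idx <- function(n, fs, phase, analysis_window_s = 60,
                                position = c("center", "start")) {
  position <- match.arg(position)
  wlen <- round(analysis_window_s * fs)
  p0 <- round(phase[1L] * fs) + 1L
  p1 <- min(n, round(phase[2L] * fs))
  avail <- p1 - p0 + 1L
  if (avail < 2L) stopf("phase window contains no samples")
  wlen <- min(wlen, avail)
  s <- if (position == "center") p0 + (avail - wlen) %/% 2L else p0
  s:(s + wlen - 1L)
}

#' Interbrain correlation over a trial-phase window
#'
#' Pearson correlation between the two mice's global signals over a 1-minute
#' analysis window positioned (by default centered) within the given trial
#' phase.
#'
#' @param a,b `global_signal`s (or numeric vectors) on a common clock.
#' @param phase `(start_s, end_s)` of the phase.
#' @param analysis_window_s analysis window length (s).
#' @param fs sampling rate, required if `a` is a bare vector.
#' @return Pearson r, or NA if either signal is constant in the window.
#' @export
phase_pcc <- function(a, b, phase, analysis_window_s = 60, fs = NULL) {
  va <- if (inherits(a, "global_signal")) a$values else as.numeric(a)
  vb <- if (inherits(b, "global_signal")) b$values else as.numeric(b)
  fs <- fs %||% a$fs
  if (length(va) != length(vb)) stopf("signals differ in length")
  idx <- analysis_window_idx(length(va), fs, phase, analysis_window_s)
  x <- va[idx]; y <- vb[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to correlation
#' values before averaging or inference.
#'
#' @param r correlation(s) with |r| < 1.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stopf("fisher_z domain error: |r| must be < 1")
  atanh(r)
}

#' Trial-shuffled null distribution of interbrain correlation
#'
#' Destroys true simultaneity by pairing mouse-A's signal from one trial with
#' mouse-B's signal from a different trial: for every unordered pair of
#' distinct trials (i < j), the interaction-phase windows are correlated,
#' giving n(n-1)/2 null values (595 for 35 trials).
#'
#' @param pairs list of trials, each a list with elements `a` and `b`:
#'   the two mice's global-signal values already restricted to the
#'   interaction-phase analysis window.
#' @return numeric vector of length `choose(n, 2)`.
#' @export
shuffled_null <- function(pairs) {
  n <- length(pairs)
  if (n < 2L) stopf("need at least 2 trials for a shuffle null")
  lens <- c(vapply(pairs, function(p) length(p$a), 1L),
            vapply(pairs, function(p) length(p$b), 1L))
  L <- min(lens)
  if (any(lens != L))
    warnf("unequal window lengths; truncating all to %d samples", L)
  out <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      out[k] <- stats::cor(pairs[[i]]$a[seq_len(L)],
                           pairs[[j]]$b[seq_len(L)])
    }
  }
  out
}

pairwise_pcc <- function(A, B, idx) {
  X <- t(A[, idx, drop = FALSE]); Y <- t(B[, idx, drop = FALSE])
  miss <- mean(!stats::complete.cases(cbind(X, Y)))
  if (miss > 0.05)
    warnf("%.1f%% of samples incomplete in correlation window", 100 * miss)
  stats::cor(X, Y, use = "pairwise.complete.obs")
}

#' Inter- and intrabrain region correlation matrices
#'
#' For a phase window: `inter[i, j]` is the Pearson correlation between
#' region i of mouse A and region j of mouse B; `intra` matrices are the
#' within-mouse analogues (symmetric, unit diagonal). When both a `before`
#' and a `together` phase are given, the change matrices
#' (together - before) and each region's row mean against all partner
#' regions are also returned.
#'
#' @param tsA,tsB regions x time matrices (see [region_timeseries()]).
#' @param fs sampling rate (frames/s).
#' @param phases named list of `(start_s, end_s)` phase intervals (typically
#'   `before` and `together`).
#' @param analysis_window_s analysis window length (s).
#' @return object of class `correlation_matrices`: per-phase `inter`,
#'   `intraA`, `intraB`, plus `delta_inter` and `delta_row_mean` when both
#'   `before` and `together` phases are present.
#' @export
correlation_matrices <- function(tsA, tsB, fs, phases,
                                 analysis_window_s = 60) {
  if (!identical(dim(tsA), dim(tsB))) stopf("region matrices differ in shape")
  res <- list(phases = names(phases))
  for (ph in names(phases)) {
    idx <- analysis_window_idx(ncol(tsA), fs, phases[[ph]],
                               analysis_window_s)
    res[[ph]] <- list(
      inter = pairwise_pcc(tsA, tsB, idx),
      intraA = pairwise_pcc(tsA, tsA, idx),
      intraB = pairwise_pcc(tsB, tsB, idx)
    )
  }
  if (all(c("before", "together") %in% names(phases))) {
    res$delta_inter <- res$together$inter - res$before$inter
    res$delta_row_mean <- rowMeans(res$delta_inter)
  }
  class(res) <- "correlation_matrices"
  res
}

#' Seed-pixel correlation map
#'
#' Correlates the 5x5-block median trace at a seed region with every masked
#' pixel's trace over the full recording — the standard functional
#' connectivity map used to verify region placement.
#'
#' @param dff a `dff_stack`.
#' @param seed one row of a placed `region_set` (or any list with `x_px`,
#'   `y_px`, `name`).
#' @param half seed block half-width (2 = 5x5).
#' @return H x W matrix of correlations (NA outside the mask).
#' @export
seed_pixel_map <- function(dff, seed, half = 2L) {
  if (!any(dff$mask)) stopf("empty mask")
  d <- dim(dff$values)
  rs <- data.frame(name = seed$name[1L], x_px = seed$x_px[1L],
                   y_px = seed$y_px[1L])
  trace <- as.numeric(region_timeseries(dff, rs, half = half))
  m <- as_tp(dff$values)
  keep <- as.vector(dff$mask)
  r <- suppressWarnings(as.numeric(stats::cor(trace, m[, keep])))
  out <- matrix(NA_real_, d[2L], d[3L])
  out[dff$mask] <- r
  out
}
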