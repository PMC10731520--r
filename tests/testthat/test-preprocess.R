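# dF/F0 preprocessing: synchronization, interpolation, baseline, clipping,
# hemodynamic subtraction, and filtering.

mk_stack <- function(m, fs = 10) {
  # m: T x P matrix -> T x 1 x P stack
  raw_stack(array(m, c(nrow(m), 1, ncol(m))),
            timestamps = (seq_len(nrow(m)) - 1) / fs, "green_gcamp")
}

test_that("LED onset is the first frame above the plateau midpoint", {
  expect_identical(detect_led_onset(c(1, 1, 1, 100, 100)), 4L)
  expect_error(detect_led_onset(rep(5, 10)), "sync error")
  # noise robustness: additive sd-1 noise on 1/100 levels never moves it
  for (s in 1:25) {
    set.seed(s)
    m <- c(rep(1, 30), rep(100, 40)) + rnorm(70)
    expect_identical(detect_led_onset(m), 31L)
  }
})

test_that("sync_to_led crops and re-zeroes the clock", {
  m <- rbind(matrix(1, 5, 4), matrix(80, 20, 4))
  s <- sync_to_led(mk_stack(m))
  expect_identical(dim(s$frames)[1], 20L)
  expect_identical(s$timestamps[1], 0)
})

test_that("dropped-frame interpolation is linear on the nominal grid", {
  fs <- 10
  # no gaps: identity
  m <- matrix(runif(40, 1, 2), 10, 4)
  s <- mk_stack(m, fs)
  out <- interpolate_dropped_frames(s, fs)
  expect_equal(out$frames, s$frames, tolerance = 1e-12)
  # one dropped frame between values 10 and 20 -> inserted 15
  ts <- c(0, 0.1, 0.3, 0.4)
  s1 <- raw_stack(array(c(5, 10, 20, 25), c(4, 1, 1)), ts, "green_gcamp")
  o1 <- interpolate_dropped_frames(s1, fs)
  expect_identical(dim(o1$frames)[1], 5L)
  expect_equal(o1$frames[3, 1, 1], 15)
  expect_equal(diff(o1$timestamps), rep(0.1, 4), tolerance = 1e-9)
  # two consecutive dropped frames between 0 and 30 -> 10 and 20
  s2 <- raw_stack(array(c(0, 0, 30, 30), c(4, 1, 1)),
                  c(0, 0.1, 0.4, 0.5), "green_gcamp")
  o2 <- interpolate_dropped_frames(s2, fs)
  expect_equal(as.numeric(o2$frames[, 1, 1]), c(0, 0, 10, 20, 30, 30))
})

test_that("dF/F0 uses the whole-recording mean baseline", {
  cst <- mk_stack(matrix(7, 20, 3))
  expect_true(all(compute_dff(cst)$values == 0))
  two <- mk_stack(matrix(c(1, 3), 2, 1))
  expect_equal(as.numeric(compute_dff(two)$values), c(-0.5, 0.5))
  # scale invariance
  m <- matrix(runif(60, 1, 2), 20, 3)
  expect_equal(compute_dff(mk_stack(5 * m))$values,
               compute_dff(mk_stack(m))$values, tolerance = 1e-12)
  # degenerate pixels are reported
  z <- mk_stack(matrix(0, 5, 2))
  expect_error(compute_dff(z), "F0 <= 0")
})

test_that("clipping clamps at mean +/- 3.5 SD (gcamp) and +/- 15% (reflectance)", {
  x <- c(rnorm(500), 25)          # one wild outlier
  d <- make_dff(array(x, c(501, 1, 1)))
  cl <- clip_extremes(d, "gcamp")
  mu <- mean(x); s <- sd(x)
  expect_equal(max(cl$values), mu + 3.5 * s, tolerance = 1e-12)
  expect_true(all(cl$values >= mu - 3.5 * s - 1e-12))
  # effectively idempotent on clean (outlier-free) data: re-clipping moves
  # almost nothing because mean +/- 3.5 SD excludes ~0.05% of samples
  clean <- make_dff(array(rnorm(2000), c(2000, 1, 1)))
  c1 <- clip_extremes(clean, "gcamp")
  c2 <- clip_extremes(c1, "gcamp")
  expect_lt(mean(abs(c2$values - c1$values)), 1e-3)
  # constant series unchanged (SD 0)
  cst <- make_dff(array(0.3, c(10, 1, 1)))
  expect_equal(clip_extremes(cst, "gcamp")$values, cst$values)
  # reflectance mode is a fixed symmetric clamp
  r <- make_dff(array(c(0.4, -0.2, 0.1), c(3, 1, 1)))
  expect_equal(as.numeric(clip_extremes(r, "reflectance")$values),
               c(0.15, -0.15, 0.1))
})

test_that("hemodynamic correction is elementwise channel subtraction", {
  g <- make_dff(array(runif(24), c(4, 2, 3)))
  zero <- make_dff(array(0, c(4, 2, 3)))
  expect_equal(hemodynamic_correct(g, zero)$values, g$values)
  expect_true(all(hemodynamic_correct(g, g)$values == 0))
  g1 <- make_dff(array(0.05, c(4, 1, 1)))
  b1 <- make_dff(array(0.02, c(4, 1, 1)))
  expect_equal(as.numeric(hemodynamic_correct(g1, b1)$values),
               rep(0.03, 4), tolerance = 1e-12)
  expect_error(hemodynamic_correct(g, make_dff(array(0, c(4, 2, 2)))),
               "alignment")
})

test_that("matrix zero-phase filter matches signal::filtfilt", {
  bf <- signal::butter(4, c(0.01, 12) / (28.9 / 2), type = "pass")
  set.seed(1)
  x <- rnorm(4000)
  y_ref <- signal::filtfilt(bf, x)
  y <- duobrain:::filtfilt_mat(matrix(x), bf$b, bf$a)[, 1]
  expect_equal(y, y_ref, tolerance = 1e-6)
})

test_that("band-pass preserves a 1 Hz sinusoid within 1% and rejects DC", {
  fs <- 28.9
  t <- seq(0, 400 - 1e-9, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  d <- make_dff(array(rep(x, 4), c(length(t), 2, 2)), fs = fs)
  out <- smooth_and_bandpass(d, spatial_sigma = 0)
  core <- seq(round(0.25 * length(t)), round(0.75 * length(t)))
  expect_equal(sd(out$values[core, 1, 1]) / sd(x[core]), 1,
               tolerance = 0.01)
  # constant input: DC is outside the passband
  cst <- make_dff(array(3, c(length(t), 2, 2)), fs = fs)
  out0 <- smooth_and_bandpass(cst, spatial_sigma = 0)
  expect_lt(max(abs(out0$values)), 1e-8)
})

test_that("spatial smoothing blurs an impulse into the closed-form kernel", {
  # impulse at the center of a 15x15 frame: the radius-4 kernel support
  # stays clear of the borders, so the result is the separable closed form
  k <- duobrain:::gauss_kernel(1)
  st <- array(0, c(1, 15, 15)); st[1, 8, 8] <- 1
  out <- duobrain:::gaussian_blur_stack(st, 1)
  expect_equal(out[1, 8, 4:12], k * k[5], tolerance = 1e-12)  # central row
  expect_equal(out[1, 4:12, 8], k * k[5], tolerance = 1e-12)  # central col
  expect_equal(out[1, 6, 7], k[3] * k[4], tolerance = 1e-12)  # separable
  expect_equal(sum(out), 1, tolerance = 1e-12)                # normalized
})

test_that("adding a constant offset leaves the filtered output unchanged", {
  fs <- 28.9
  set.seed(3)
  v <- array(rnorm(2000 * 4, 0, 0.02), c(2000, 2, 2))
  a <- suppressWarnings(smooth_and_bandpass(make_dff(v, fs)))
  b <- suppressWarnings(smooth_and_bandpass(make_dff(v + 0.7, fs)))
  expect_equal(a$values, b$values, tolerance = 1e-6)
})

test_that("pipeline provenance records the fixed processing order", {
  p <- tiny_params(seed = 9L)
  sim <- simulate_session(p)
  pre <- preprocess_session(sim$session)
  prov <- pre$mice$stationary$corrected$provenance
  expect_match(prov[1], "^dff\\[green")
  expect_match(prov[2], "^clip\\[gcamp")
  expect_match(prov[3], "^subtract\\[clip\\[reflectance")
  expect_match(prov[4], "^gauss")
  expect_match(prov[5], "^butter")
})

test_that("correction cannot add variance in gfp-mode sessions", {
  run_var <- function(seed) {
    p <- session_params(image_size = 8L, gfp_mode = TRUE, seed = seed)
    pre <- preprocess_session(simulate_session(p)$session)
    mvec <- as.vector(pre$mask)
    c(corr = var(as.vector(duobrain:::as_tp(
        pre$mice$stationary$corrected$values)[, mvec])),
      raw = var(as.vector(duobrain:::as_tp(
        pre$mice$stationary$uncorrected_green$values)[, mvec])))
  }
  v <- run_var(21L)
  expect_lt(v["corr"], v["raw"])
})
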