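# Global/region signals, phase correlations, shuffle null, seed maps, and
# multitaper coherence.

test_that("global signal is the spatial median over the mask", {
  v <- array(2.5, c(6, 4, 4))
  expect_equal(global_signal(make_dff(v))$values, rep(2.5, 6))
  # robust to one extreme pixel among many
  v2 <- array(1, c(3, 10, 10)); v2[, 1, 1] <- 1e6
  expect_equal(global_signal(make_dff(v2))$values, rep(1, 3))
  # single-pixel mask returns that pixel's trace
  m1 <- matrix(FALSE, 4, 4); m1[2, 3] <- TRUE
  v3 <- array(rnorm(4 * 16), c(4, 4, 4))
  d3 <- dff_stack(v3, m1, 28.9)
  expect_equal(global_signal(d3)$values, v3[, 2, 3])
  expect_error(global_signal(dff_stack(v3, matrix(FALSE, 4, 4), 28.9)),
               "empty mask")
})

test_that("region time series use the median of exactly a 5x5 block", {
  # pixel value = |dx| + |dy| from the region center: the block median is
  # 2 for 5x5 but 1 for 3x3 and 3 for 7x7, pinning the footprint size
  n <- 16
  img <- outer(0:(n - 1), 0:(n - 1),
               function(y, x) abs(x - 8) + abs(y - 8))
  v <- array(0, c(3, n, n)); for (t in 1:3) v[t, , ] <- img
  rs <- data.frame(name = "probe", x_px = 8L, y_px = 8L)
  out <- region_timeseries(make_dff(v), rs)
  expect_equal(as.numeric(out), rep(2, 3))
  # uniform stack -> constant rows
  u <- array(0.7, c(5, n, n))
  expect_equal(as.numeric(region_timeseries(make_dff(u), rs)), rep(0.7, 5))
  # 24 zeros and one 1 -> median 0
  v1 <- array(0, c(2, n, n)); v1[, 8, 8] <- 1
  expect_equal(as.numeric(region_timeseries(make_dff(v1), rs)), c(0, 0))
  # bounds violations name the region
  rs_edge <- data.frame(name = "edge", x_px = 0L, y_px = 8L)
  expect_error(region_timeseries(make_dff(u), rs_edge), "edge")
})

test_that("phase PCC matches a hand-rolled covariance oracle", {
  set.seed(10)
  a <- rnorm(30); b <- rnorm(30)
  r <- phase_pcc(a, b, phase = c(0, 30), analysis_window_s = 30, fs = 1)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_equal(phase_pcc(a, a, c(0, 30), 30, fs = 1), 1, tolerance = 1e-12)
  expect_equal(phase_pcc(a, -a, c(0, 30), 30, fs = 1), -1,
               tolerance = 1e-12)
  expect_true(is.na(phase_pcc(a, rep(1, 30), c(0, 30), 30, fs = 1)))
})

test_that("fisher z is atanh with domain checks", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_error(fisher_z(1), "domain")
})

test_that("shuffle null enumerates unordered trial pairs", {
  mk_pairs <- function(n) lapply(seq_len(n), function(i) {
    set.seed(i); list(a = rnorm(50), b = rnorm(50))
  })
  expect_identical(length(shuffled_null(mk_pairs(2))), 1L)
  expect_identical(length(shuffled_null(mk_pairs(5))), 10L)
  for (n in c(3, 8, 17, 35, 50)) {
    expect_identical(length(shuffled_null(mk_pairs(n))),
                     as.integer(n * (n - 1) / 2))
  }
  expect_error(shuffled_null(mk_pairs(1)), "at least 2")
  # unequal lengths truncate with a warning
  pp <- mk_pairs(3); pp[[2]]$b <- pp[[2]]$b[1:30]
  expect_warning(shuffled_null(pp), "truncating")
})

test_that("correlation matrices have the required structure", {
  set.seed(11)
  tsA <- matrix(rnorm(10 * 1700), 10, 1700,
                dimnames = list(paste0("r", 1:10), NULL))
  phases <- list(before = c(0, 850), together = c(850, 1700))
  # identical inputs: inter equals intra of A, symmetric unit-diagonal intra
  cm <- correlation_matrices(tsA, tsA, fs = 1, phases = phases,
                             analysis_window_s = 850)
  expect_equal(cm$together$inter, cm$together$intraA, tolerance = 1e-12)
  expect_equal(unname(diag(cm$before$intraA)), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(cm$before$intraA, t(cm$before$intraA), tolerance = 1e-12)
  expect_true(all(abs(cm$together$inter) <= 1 + 1e-12))
  # independent white-noise regions stay inside the null band
  hits <- unlist(lapply(1:5, function(s) {
    set.seed(100 + s)
    A <- matrix(rnorm(10 * 1700), 10, 1700)
    B <- matrix(rnorm(10 * 1700), 10, 1700)
    cmi <- correlation_matrices(A, B, fs = 1, phases = phases,
                                analysis_window_s = 850)
    abs(cmi$together$inter) < 0.08
  }))
  expect_gte(mean(hits), 0.95)
  expect_equal(cm$delta_inter, cm$together$inter - cm$before$inter,
               tolerance = 1e-12)
  expect_equal(cm$delta_row_mean, rowMeans(cm$delta_inter),
               tolerance = 1e-12)
})

test_that("seed-pixel maps peak at the seeded source region", {
  # one Gaussian source blob + spatially white noise
  set.seed(12)
  n <- 24; T <- 800
  blob <- matrix(duobrain:::region_blob(n, 8, 15, 2), n, n)
  drive <- rnorm(T)
  v <- array(rnorm(T * n * n, 0, 0.3), c(T, n, n))
  for (t in seq_len(T)) v[t, , ] <- v[t, , ] + drive[t] * blob
  d <- make_dff(v)
  seed_rs <- list(name = "src", x_px = 8L, y_px = 15L)
  mp <- seed_pixel_map(d, seed_rs)
  expect_true(all(mp >= -1 - 1e-9 & mp <= 1 + 1e-9, na.rm = TRUE))
  expect_gt(mp[16, 9], 0.9)          # near self-correlation at the seed
  pk <- which(mp == max(mp, na.rm = TRUE), arr.ind = TRUE)
  expect_lte(max(abs(pk - c(16, 9))), 2)
})

test_that("dpss tapers are orthonormal and band-concentrated", {
  h <- dpss_tapers(512, nw = 5, k = 9)
  expect_equal(crossprod(h), diag(9), tolerance = 1e-8)
  # first taper concentrates nearly all energy inside |f| <= NW/n
  H <- abs(stats::mvfft(rbind(h, matrix(0, 3584, 9))))^2
  W <- 5 / 512
  inband <- seq_len(ceiling(W * 4096))
  conc <- sum(H[c(inband, 4096 - inband + 1), 1]) / sum(H[, 1])
  expect_gt(conc, 0.999)
})

test_that("multitaper coherence behaves at its analytic limits", {
  fs <- 28.9
  set.seed(13)
  x <- rnorm(4000)
  # self-coherence is 1 at every retained frequency
  cm <- mt_coherence(x, x, fs = fs, window_s = 45, overlap_s = 22.5)
  # windows start every 650 samples while a full 1301-sample window fits
  expect_equal(nrow(cm$coherence), 5L)
  expect_true(all(abs(cm$coherence - 1) < 1e-8))
  expect_identical(cm$params$k, 9)
  # independent white noise sits near the K-taper bias floor (~1/K),
  # far below 0.5
  mean_c <- mean(vapply(1:12, function(s) {
    set.seed(200 + s)
    a <- rnorm(2000); b <- rnorm(2000)
    mean(mt_coherence(a, b, fs = fs)$coherence)
  }, numeric(1)))
  expect_gt(mean_c, 0.5 / 9)
  expect_lt(mean_c, 2.5 / 9)
  # a pure delay does not change coherence magnitude (band-limited signal)
  bf <- signal::butter(4, 0.2, type = "low")
  s <- duobrain:::filtfilt_mat(matrix(rnorm(4300)), bf$b, bf$a)[, 1]
  a <- s[1:4000]; b <- s[16:4015]
  c_ab <- mt_coherence(a, b, fs = fs)
  c_aa <- mt_coherence(a, a, fs = fs)
  keep <- c_ab$freqs < 2   # inside the driven band
  expect_equal(mean(c_ab$coherence[, keep]), mean(c_aa$coherence[, keep]),
               tolerance = 0.05)
  expect_error(mt_coherence(rnorm(100), rnorm(100), fs = fs), "longer")
})

test_that("coherence parameters define the window geometry", {
  cm <- mt_coherence(rnorm(3000), rnorm(3000), fs = 28.9)
  step <- diff(cm$times)[1]
  expect_equal(step, 22.5, tolerance = 0.05)
  expect_equal(max(cm$freqs), 28.9 / 2, tolerance = 0.02)
})
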