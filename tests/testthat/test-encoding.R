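# Design matrix construction, SVD reduction, ridge fitting,
# cross-validated explained variance, and unique contributions.

test_that("behavior variables expand to ceiling(2*fs) post-event columns", {
  fs <- 28.9
  dm <- build_design_matrix(list(whisk = c(100L)), fs, 400L)
  expect_identical(ncol(dm$X), 58L)  # ceiling(2 * 28.9)
  for (l in c(0L, 10L, 57L)) {
    expect_equal(dm$X[100 + l, l + 1], 1)
    expect_equal(sum(dm$X[, l + 1]), 1)
  }
})

test_that("approach and leave kernels cover 5 s before/after the event", {
  fs <- 10
  dm <- build_design_matrix(list(approach = 80L, leave = 120L), fs, 300L)
  expect_identical(length(dm$column_groups$approach), 51L)  # -50..0
  expect_identical(length(dm$column_groups$leave), 51L)     # 0..50
  ap <- dm$X[, dm$column_groups$approach]
  expect_equal(which(ap[, 1] == 1), 30L)     # lag -50
  expect_equal(which(ap[, 51] == 1), 80L)    # lag 0
  lv <- dm$X[, dm$column_groups$leave]
  expect_equal(which(lv[, 51] == 1), 170L)   # lag +50
})

test_that("kernels never cross trial boundaries and empty variables are flagged", {
  fs <- 10
  # event 1 s before the boundary between two 100-sample trials
  dm <- build_design_matrix(list(a = 91L, b = integer(0)), fs, 200L,
                            trial_breaks = c(1L, 101L))
  ga <- dm$X[, dm$column_groups$a]
  expect_equal(sum(ga[1:100, ]), 10)      # lags 0..9 inside trial 1
  expect_equal(sum(ga[101:200, ]), 0)     # nothing bleeds into trial 2
  expect_identical(dm$empty, "b")
  expect_true(all(dm$X[, dm$column_groups$b] == 0))
  expect_error(build_design_matrix(list(a = 500L), fs, 200L), "outside")
})

test_that("svd reduction reproduces the full decomposition", {
  set.seed(20)
  # rank-1 data: one component reconstructs exactly
  u <- rnorm(60); v <- rnorm(40)
  Y1 <- u %o% v
  r1 <- svd_reduce(Y1, k = 5)
  rec <- r1$temporal %*% r1$spatial
  Yc <- sweep(Y1, 2, colMeans(Y1), "-")
  expect_equal(rec[, 1:40], Yc, tolerance = 1e-8)
  expect_lt(sum(r1$sv[-1]^2) / sum(r1$sv^2), 1e-12)
  # random matrix: truncation error equals the tail singular energy
  Y <- matrix(rnorm(50 * 500), 50, 500)
  expect_warning(r200 <- svd_reduce(Y, k = 200), "truncating")
  expect_identical(r200$k, 50L)
  k <- 20
  r <- svd_reduce(Y, k = k)
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  err <- sum((Yc - r$temporal %*% r$spatial)^2)
  sv_full <- svd(Yc)$d
  expect_equal(err, sum(sv_full[(k + 1):length(sv_full)]^2),
               tolerance = 1e-6)
  # temporal components are orthogonal with squared-singular-value norms
  G <- crossprod(r$temporal)
  expect_equal(G, diag(diag(G)), tolerance = 1e-6)
})

test_that("ridge regression matches its closed-form limits", {
  set.seed(21)
  X <- matrix(rnorm(200 * 12), 200, 12)
  B_true <- matrix(rnorm(12 * 3), 12, 3)
  Y <- X %*% B_true
  # lambda = 0 equals ordinary least squares (normal-equations oracle)
  ols <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(ridge_fit(X, Y, 0), ols, tolerance = 1e-8)
  # noiseless recovery at tiny lambda
  Bh <- ridge_fit(X, Y, 1e-8)
  expect_lt(max(abs(Bh - B_true)) / max(abs(B_true)), 1e-4)
  # penalty dominance
  expect_lt(max(abs(ridge_fit(X, Y, 1e12))), 1e-6)
  expect_error(ridge_fit(X, Y, -1), "lambda")
})

# deterministic ground-truth fixture: pixel data generated exactly from a
# two-variable design through spatial patterns
make_encoding_fixture <- function(noise = 0, n_time = 600L, fs = 10) {
  set.seed(22)
  on_a <- sort(sample(20:(n_time - 30), 12))
  on_b <- sort(sample(20:(n_time - 30), 12))
  dm <- build_design_matrix(list(va = on_a, vb = on_b), fs, n_time)
  npix <- 36
  Wa <- exp(-((seq_len(npix) - 8)^2) / 8)    # variable a drives pixels ~8
  Wb <- exp(-((seq_len(npix) - 28)^2) / 8)   # variable b drives pixels ~28
  ka <- exp(-(0:19) / 5)
  amp_a <- dm$X[, dm$column_groups$va] %*% ka[seq_len(20)]
  amp_b <- dm$X[, dm$column_groups$vb] %*% ka[seq_len(20)]
  Y <- amp_a %*% t(Wa) + amp_b %*% t(Wb)
  if (noise > 0) Y <- Y + matrix(rnorm(length(Y), 0, noise), nrow(Y))
  list(dm = dm, Y = Y, drive_a = 8, drive_b = 28)
}

test_that("noise-free model data give cross-validated R^2 near 1", {
  # the standard configuration: 200 components, 10 folds
  expect_identical(eval(formals(svd_reduce)$k), 200)
  expect_identical(eval(formals(cv_explained_variance)$folds), 10)
  fx <- make_encoding_fixture(noise = 0)
  red <- svd_reduce(fx$Y, k = 30)
  cv <- cv_explained_variance(red, fx$dm, folds = 10, lambda = 1e-6)
  driven <- c(4:12, 24:32)
  expect_true(all(cv$r2[driven] > 0.98))
})

test_that("unrelated noise gives R^2 near zero (possibly slightly negative)", {
  set.seed(23)
  fx <- make_encoding_fixture(noise = 0)
  red <- svd_reduce(matrix(rnorm(600 * 36), 600, 36), k = 30)
  cv <- cv_explained_variance(red, fx$dm, folds = 10, lambda = 1)
  expect_true(all(abs(cv$r2) < 0.25))
  # cross-validated R^2 on pure noise is centered slightly below zero
  expect_lt(abs(mean(cv$r2)), 0.1)
})

test_that("unique contributions localize to each variable's driven pixels", {
  fx <- make_encoding_fixture(noise = 0.05)
  red <- svd_reduce(fx$Y, k = 30)
  # a moderate penalty keeps the permuted regressor block from overfitting
  # (a near-zero penalty lets it actively hurt held-out prediction, pushing
  # the reduced model below the mean predictor)
  full <- cv_explained_variance(red, fx$dm, folds = 10, lambda = 1)
  ua <- unique_contribution(red, fx$dm, "va", folds = 10, lambda = 1,
                            seed = 31L, full = full)
  ub <- unique_contribution(red, fx$dm, "vb", folds = 10, lambda = 1,
                            seed = 32L, full = full)
  expect_equal(which.max(ua$dr2), fx$drive_a, tolerance = 2)
  expect_equal(which.max(ub$dr2), fx$drive_b, tolerance = 2)
  # each delta R^2 is bounded by the full R^2 up to the permutation
  # overfit cost: the shuffled block can push the reduced model below the
  # mean predictor by roughly ncol(block)/n_train, ~0.2 on this small
  # fixture. Negative delta R^2 stays within sampling noise.
  carry <- full$sstot > 0.01 * max(full$sstot)
  expect_true(all(ua$dr2[carry] <= full$r2[carry] + 0.2))
  expect_true(all(ua$dr2[carry] > -0.1))
  # a variable's unique contribution approaches the full R^2 where only it
  # drives the data
  expect_gt(ua$dr2[fx$drive_a], 0.8 * full$r2[fx$drive_a])
  # bit-exact reproducibility under a fixed permutation seed
  ua2 <- unique_contribution(red, fx$dm, "va", folds = 10, lambda = 1,
                             seed = 31L, full = full)
  expect_identical(ua$dr2, ua2$dr2)
  # permuting an all-zero variable changes nothing
  dm0 <- build_design_matrix(list(va = fx$dm$onsets$va, z = integer(0)),
                             10, 600L)
  f0 <- cv_explained_variance(red, dm0, folds = 10, lambda = 1)
  u0 <- unique_contribution(red, dm0, "z", folds = 10, lambda = 1,
                            seed = 33L, full = f0)
  expect_lt(max(abs(u0$dr2)), 1e-10)
})

test_that("the fitted model object exposes the standard methods", {
  p <- tiny_params(seed = 15L, coupling = 0.5)
  pre <- preprocess_session(simulate_session(p)$session)
  ev <- session_behavior_events(pre)
  fit <- encoding_model(pre, ev, k = 40, folds = 5, lambda = 10,
                        seed = 2L)
  expect_s3_class(fit, "encoding_model")
  expect_identical(fit$folds, 5)
  expect_output(print(fit), "Ridge-regression encoding model")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.encoding_model")
  expect_true(all(c("variable", "mean_dr2") %in% names(sm$variables)))
  B <- coef(fit)
  expect_identical(nrow(B), ncol(fit$design$X))
  pr <- predict(fit)
  expect_identical(dim(pr), dim(fit$reduced$temporal))
  expect_equal(pr + residuals(fit), fit$reduced$temporal,
               tolerance = 1e-10)
  px <- predict(fit, space = "pixels")
  expect_identical(ncol(px), sum(pre$mask))
  expect_true(all(fit$r2 <= 1 + 1e-9, na.rm = TRUE))
  expect_identical(dim(fit$r2_map), dim(pre$mask))
})
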