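#' Build an event-kernel design matrix
#'
#' Expands each binary event variable into time-lagged indicator columns on
#' the neural clock. Behavior and stage-translation variables contribute one
#' column per sample from the event onset up to 2 s after it
#' (`ceiling(2*fs)` columns); mouse-approach events cover the 5 s before the
#' approach (lags `-ceiling(5*fs)..0`) and mouse-leave events the 5 s after
#' (lags `0..ceiling(5*fs)`). Kernels never cross trial boundaries: lags
#' falling outside an event's own trial are dropped.
#'
#' @param onsets named list, one entry per variable, of event-onset sample
#'   indices (1-based, on the concatenated neural clock).
#' @param fs neural sampling rate (frames/s).
#' @param n_time number of rows (concatenated samples).
#' @param trial_breaks integer vector of trial start samples (first trial
#'   starts at 1).
#' @param kinds named character vector assigning each variable a kernel
#'   kind: `"kernel"` (post-event, default), `"pre"` (approach-style) or
#'   `"post"` (leave-style). Unlisted variables default to `"kernel"`, except
#'   variables named `"approach"` / `"leave"`.
#' @param windows named numeric vector of kernel lengths in seconds
#'   (default 2 for `"kernel"`, 5 for `"pre"`/`"post"`).
#' @return object of class `design_matrix`: list with `X` (time x columns),
#'   `column_groups`, `lags` (per variable), `onsets`, `fs`, `n_time`,
#'   `trial_breaks`, and `empty` (variables with no events, flagged for
#'   exclusion).
#' @export
build_design_matrix <- function(onsets, fs, n_time, trial_breaks = 1L,
                                kinds = NULL, windows = NULL) {
  vars <- names(onsets)
  if (is.null(vars) || any(vars == ""))
    stopf("'onsets' must be a fully named list")
  kind_of <- function(v) {
    if (!is.null(kinds) && v %in% names(kinds)) return(kinds[[v]])
    if (v == "approach") "pre" else if (v == "leave") "post" else "kernel"
  }
  win_of <- function(v, kind) {
    if (!is.null(windows) && v %in% names(windows)) return(windows[[v]])
    if (kind == "kernel") 2 else 5
  }
  trial_breaks <- sort(unique(as.integer(trial_breaks)))
  trial_of <- function(i) findInterval(i, trial_breaks)
  trial_end <- c(trial_breaks[-1L] - 1L, n_time)

  cols <- list(); groups <- list(); lag_list <- list()
  kinds_used <- character(0); windows_used <- numeric(0)
  empty <- character(0)
  nc <- 0L
  for (v in vars) {
    kind <- kind_of(v)
    w <- win_of(v, kind)
    kinds_used[v] <- kind; windows_used[v] <- w
    lags <- switch(kind,
      kernel = 0L:(as.integer(ceiling(w * fs)) - 1L),
      pre = (-as.integer(ceiling(w * fs))):0L,
      post = 0L:as.integer(ceiling(w * fs)),
      stopf("unknown kernel kind '%s'", kind))
    on <- as.integer(onsets[[v]])
    if (any(on < 1L | on > n_time))
      stopf("variable '%s': events outside the clock", v)
    M <- matrix(0, n_time, length(lags))
    if (length(on)) {
      tr <- trial_of(on)
      for (li in seq_along(lags)) {
        t <- on + lags[li]
        ok <- t >= trial_breaks[tr] & t <= trial_end[tr]
        M[t[ok], li] <- 1
      }
    } else {
      empty <- c(empty, v)
    }
    groups[[v]] <- nc + seq_along(lags)
    lag_list[[v]] <- lags
    nc <- nc + length(lags)
    cols[[v]] <- M
  }
  dm <- list(X = do.call(cbind, cols), column_groups = groups,
             lags = lag_list, onsets = lapply(onsets, as.integer), fs = fs,
             n_time = as.integer(n_time), trial_breaks = trial_breaks,
             kinds = kinds_used, windows = windows_used, empty = empty)
  class(dm) <- "design_matrix"
  dm
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d samples x %d columns, %d variables at %.1f fps\n",
              nrow(x$X), ncol(x$X), length(x$column_groups), x$fs))
  for (v in names(x$column_groups))
    cat(sprintf("  %-24s %3d lags, %3d events%s\n", v,
                length(x$column_groups[[v]]), length(x$onsets[[v]]),
                if (v %in% x$empty) " [empty]" else ""))
  invisible(x)
}

#' Reduce masked pixel data to its leading principal components
#'
#' Mean-centers each pixel and keeps the top `k` singular triplets (default
#' 200) of the time x pixels matrix, via the eigendecomposition of the
#' smaller Gram matrix. The reconstruction `temporal %*% spatial + center`
#' is the rank-k approximation; its error equals the tail singular energy.
#'
#' @param Y time x pixels matrix of masked dF/F0 values.
#' @param k number of components to keep.
#' @param mask optional H x W logical mask used later to project maps.
#' @return object of class `reduced_neural`: `temporal` (time x k, columns
#'   orthogonal), `spatial` (k x pixels), `center` (pixel means), `sv`
#'   (singular values), `mask`.
#' @export
svd_reduce <- function(Y, k = 200, mask = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (k > min(n, p)) {
    warnf("k = %d exceeds min(dim) = %d; truncating", k, min(n, p))
    k <- min(n, p)
  }
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr, "-")
  if (p <= n) {
    eg <- eigen(crossprod(Yc), symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    V <- eg$vectors[, seq_len(k), drop = FALSE]
    temporal <- Yc %*% V
    spatial <- t(V)
  } else {
    eg <- eigen(tcrossprod(Yc), symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    temporal <- U * rep(sqrt(d2[seq_len(k)]), each = n)
    sv_inv <- ifelse(d2[seq_len(k)] > 0, 1 / sqrt(d2[seq_len(k)]), 0)
    spatial <- (t(U) * sv_inv) %*% Yc
  }
  rn <- list(temporal = temporal, spatial = spatial, center = ctr,
             sv = sqrt(d2), k = k, mask = mask)
  class(rn) <- "reduced_neural"
  rn
}

#' Closed-form ridge regression
#'
#' `B = (X'X + lambda I)^(-1) X'Y`, fitted jointly for every response
#' column. With `lambda = 0` this is ordinary least squares.
#'
#' @param X design matrix (rows = samples).
#' @param Y response matrix (rows = samples), e.g. reduced temporal
#'   components.
#' @param lambda ridge penalty, >= 0.
#' @param penalize optional logical vector marking which columns are
#'   penalized (default all); used to leave an intercept unpenalized.
#' @return coefficient matrix, columns x responses.
#' @export
ridge_fit <- function(X, Y, lambda, penalize = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stopf("'lambda' must be a single number >= 0")
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y row counts differ")
  pen <- if (is.null(penalize)) rep(1, ncol(X)) else as.numeric(penalize)
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda * pen
  solve(A, crossprod(X, Y))
}

# contiguous-block fold assignment
fold_blocks <- function(n, folds) {
  if (folds < 2L) stopf("need at least 2 folds")
  sizes <- rep(n %/% folds, folds)
  sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1L
  rep(seq_len(folds), sizes)
}

# Cross-validated prediction errors in component space. Returns k x k
# error and total Gram matrices so per-pixel sums of squares can be formed
# through the spatial components without materializing pixel predictions.
cv_component_errors <- function(temporal, X, folds, lambda) {
  n <- nrow(temporal)
  fb <- fold_blocks(n, folds)
  Xi <- cbind(1, X)
  pen <- c(0, rep(1, ncol(X)))
  Eg <- matrix(0, ncol(temporal), ncol(temporal))
  Eg_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- fb == f
    B <- ridge_fit(Xi[!te, , drop = FALSE], temporal[!te, , drop = FALSE],
                   lambda, penalize = pen)
    err <- temporal[te, , drop = FALSE] - Xi[te, , drop = FALSE] %*% B
    G <- crossprod(err)
    Eg <- Eg + G
    Eg_fold[[f]] <- G
  }
  list(pooled = Eg, per_fold = Eg_fold)
}

# per-pixel quadratic form q_p = sum_ij spatial[i,p] G[i,j] spatial[j,p]
pixel_quadform <- function(G, spatial) {
  colSums(spatial * (G %*% spatial))
}

#' Cross-validated explained variance of a design matrix
#'
#' Contiguous-block k-fold cross-validation (default 10 folds): the model is
#' fitted on the training blocks, held-out temporal components are
#' predicted, pixel-level prediction errors are obtained through the spatial
#' components, and per-pixel R^2 = 1 - SSE/SStot is pooled over folds
#' (per-fold R^2 maps are also returned).
#'
#' @param reduced a [svd_reduce()] result.
#' @param X design matrix or `design_matrix` object.
#' @param folds number of folds.
#' @param lambda ridge penalty.
#' @return list with `r2` (per-pixel, pooled SSE), `r2_map` (H x W if a mask
#'   is attached, else NULL), `r2_per_fold_mean` (mean over per-fold R^2),
#'   `sstot` (per-pixel total sum of squares).
#' @export
cv_explained_variance <- function(reduced, X, folds = 10, lambda = 1) {
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (nrow(Xm) != nrow(reduced$temporal))
    stopf("design matrix rows (%d) must match temporal rows (%d)", nrow(Xm),
          nrow(reduced$temporal))
  ce <- cv_component_errors(reduced$temporal, Xm, folds, lambda)
  sstot <- pixel_quadform(crossprod(reduced$temporal), reduced$spatial)
  sse <- pixel_quadform(ce$pooled, reduced$spatial)
  r2 <- ifelse(sstot > 0, 1 - sse / sstot, NA_real_)
  fb <- fold_blocks(nrow(reduced$temporal), folds)
  per_fold <- vapply(seq_len(folds), function(f) {
    Tc <- reduced$temporal[fb == f, , drop = FALSE]
    Tc <- sweep(Tc, 2L, colMeans(Tc), "-")
    sst_f <- pixel_quadform(crossprod(Tc), reduced$spatial)
    sse_f <- pixel_quadform(ce$per_fold[[f]], reduced$spatial)
    mean(ifelse(sst_f > 0, 1 - sse_f / sst_f, NA_real_), na.rm = TRUE)
  }, numeric(1))
  list(r2 = r2, r2_map = project_map(r2, reduced$mask),
       r2_per_fold_mean = mean(per_fold), sstot = sstot)
}

project_map <- function(values, mask) {
  if (is.null(mask)) return(NULL)
  m <- matrix(NA_real_, nrow(mask), ncol(mask))
  m[mask] <- values
  m
}

# re-expand a design matrix with one variable's onsets circularly shifted
permute_variable <- function(dm, variable, seed) {
  if (!variable %in% names(dm$column_groups))
    stopf("unknown variable '%s'", variable)
  set.seed(seed)
  shift <- sample.int(dm$n_time - 1L, 1L)
  src <- numeric(dm$n_time)
  src[dm$onsets[[variable]]] <- 1
  src <- src[1L + (seq_len(dm$n_time) - 1L + shift) %% dm$n_time]
  new_onsets <- dm$onsets
  new_onsets[[variable]] <- which(src > 0)
  build_design_matrix(new_onsets, dm$fs, dm$n_time, dm$trial_breaks,
                      kinds = dm$kinds, windows = dm$windows)
}

#' Unique contribution of one model variable
#'
#' The variable's event train is circularly shifted in time by a seeded
#' random offset and its lag columns re-expanded (keeping the kernel
#' structure intact), the cross-validated explained variance is recomputed,
#' and the per-pixel difference full - reduced is the variable's unique
#' contribution (delta R^2) map.
#'
#' @param reduced a [svd_reduce()] result.
#' @param dm the full `design_matrix`.
#' @param variable variable name to permute.
#' @param folds,lambda as in [cv_explained_variance()].
#' @param seed integer seed for the permutation (reproducible bit-exactly).
#' @param full optional precomputed [cv_explained_variance()] result for the
#'   full model.
#' @return list with `dr2` (per-pixel), `dr2_map`, and the reduced-model
#'   `r2`.
#' @export
unique_contribution <- function(reduced, dm, variable, folds = 10,
                                lambda = 1, seed = 1L, full = NULL) {
  full <- full %||% cv_explained_variance(reduced, dm, folds, lambda)
  dmp <- permute_variable(dm, variable, seed)
  red <- cv_explained_variance(reduced, dmp, folds, lambda)
  dr2 <- full$r2 - red$r2
  list(dr2 = dr2, dr2_map = project_map(dr2, reduced$mask),
       reduced_r2 = red$r2)
}
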