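#' Event onsets for the standard encoding-model variables
#'
#' Assembles the eight binary event variables of the interaction encoding
#' model from a session's behavior events and phase schedule, on the neural
#' clock: the stationary mouse's whisker movements split by context
#' (`stat_whisk_alone` vs `stat_whisk_together`, by the phase at bout
#' onset), its forelimb movements, the partner's whisker and forelimb
#' movements during the together phase, stage-translation onsets, the
#' approach moment (translation-in ends) and the leave moment
#' (translation-out begins).
#'
#' @param events nested list `[mouse][channel]` of [event_series()] (see
#'   [session_behavior_events()]).
#' @param phase_schedule the trial's phase schedule.
#' @param fs neural sampling rate (frames/s).
#' @param n_time number of neural samples in the trial.
#' @return named list of onset sample vectors, ready for
#'   [build_design_matrix()].
#' @export
encoding_variables <- function(events, phase_schedule, fs, n_time) {
  tog <- phase_window(phase_schedule, "together")
  to_samples <- function(t_s) {
    s <- floor(t_s * fs) + 1L
    s[s >= 1L & s <= n_time]
  }
  sw <- events$stationary$whisker$events$onset_s
  in_tog <- sw >= tog[1L] & sw < tog[2L]
  mw <- events$moving$whisker$events$onset_s
  mf <- events$moving$forelimb$events$onset_s
  list(
    stat_whisk_alone = to_samples(sw[!in_tog]),
    stat_whisk_together = to_samples(sw[in_tog]),
    stat_forelimb = to_samples(events$stationary$forelimb$events$onset_s),
    partner_whisk_together = to_samples(mw[mw >= tog[1L] & mw < tog[2L]]),
    partner_forelimb_together = to_samples(mf[mf >= tog[1L] & mf < tog[2L]]),
    translation = to_samples(c(phase_window(phase_schedule, "translate_in")[1L],
                               phase_window(phase_schedule, "translate_out")[1L])),
    approach = to_samples(phase_window(phase_schedule, "translate_in")[2L]),
    leave = to_samples(phase_window(phase_schedule, "translate_out")[1L])
  )
}

#' Fit the ridge-regression encoding model
#'
#' Fits the full pipeline of the encoding analysis for one mouse: the
#' masked, concatenated dF/F0 data are reduced to their leading principal
#' components ([svd_reduce()]), the event-kernel design matrix is regressed
#' against the components with ridge regression, explained variance is
#' estimated by contiguous-block 10-fold cross-validation and projected back
#' onto the cortical map, and each variable's unique contribution (delta
#' R^2) is measured by permuting that variable and refitting. The ridge
#' penalty is chosen by grid search on a held-out contiguous validation
#' split unless fixed.
#'
#' @param trials a `preprocessed_session`, or a list of them (concatenated
#'   as separate trials); the stationary mouse's corrected stack is modeled.
#' @param events behavior events per trial as from
#'   [session_behavior_events()] (a single nested list, or a list of them
#'   matching `trials`).
#' @param k number of principal components.
#' @param folds cross-validation folds.
#' @param lambda ridge penalty; `NULL` selects from `lambda_grid` on a
#'   validation split (final 10% of samples).
#' @param lambda_grid candidate penalties.
#' @param variables which variables to compute delta R^2 maps for
#'   (`"all"` or a character vector); empty variables are skipped.
#' @param mouse which mouse's cortex to model.
#' @param seed seed for the permutation tests.
#' @return object of class `encoding_model` with fields `betas` (full-data
#'   ridge fit), `lambda`, `r2`, `r2_map`, `dr2`, `dr2_maps`, `design`,
#'   `reduced`, `folds`, `mask`.
#' @export
encoding_model <- function(trials, events, k = 200, folds = 10,
                           lambda = NULL,
                           lambda_grid = c(0.1, 1, 10, 100, 1000),
                           variables = "all", mouse = "stationary",
                           seed = 1L) {
  if (inherits(trials, "preprocessed_session")) {
    trials <- list(trials)
    events <- list(events)
  }
  stopifnot(length(trials) == length(events))
  mask <- trials[[1L]]$mask
  fs <- trials[[1L]]$mice[[mouse]]$corrected$fs
  Ys <- list(); ons <- NULL; breaks <- integer(0); n_time <- 0L
  for (i in seq_along(trials)) {
    dff <- trials[[i]]$mice[[mouse]]$corrected
    Y <- as_tp(dff$values)[, as.vector(mask), drop = FALSE]
    breaks <- c(breaks, n_time + 1L)
    vars_i <- encoding_variables(events[[i]], trials[[i]]$phase_schedule,
                                 fs, nrow(Y))
    vars_i <- lapply(vars_i, function(s) s + n_time)
    ons <- if (is.null(ons)) vars_i else
      Map(function(a, b) c(a, b), ons, vars_i)
    n_time <- n_time + nrow(Y)
    Ys[[i]] <- Y
  }
  Y <- do.call(rbind, Ys)
  dm <- build_design_matrix(ons, fs, n_time, trial_breaks = breaks)
  reduced <- svd_reduce(Y, k = k, mask = mask)

  if (is.null(lambda)) {
    nv <- max(folds, round(0.1 * n_time))
    tr_idx <- seq_len(n_time - nv)
    va_idx <- (n_time - nv + 1L):n_time
    Xi <- cbind(1, dm$X)
    pen <- c(0, rep(1, ncol(dm$X)))
    val_sse <- vapply(lambda_grid, function(l) {
      B <- ridge_fit(Xi[tr_idx, , drop = FALSE],
                     reduced$temporal[tr_idx, , drop = FALSE], l,
                     penalize = pen)
      sum((reduced$temporal[va_idx, , drop = FALSE] -
             Xi[va_idx, , drop = FALSE] %*% B)^2)
    }, numeric(1))
    lambda <- lambda_grid[which.min(val_sse)]
  }

  full <- cv_explained_variance(reduced, dm, folds = folds, lambda = lambda)
  use_vars <- if (identical(variables, "all"))
    setdiff(names(dm$column_groups), dm$empty) else variables
  dr2 <- list()
  for (v in use_vars) {
    dr2[[v]] <- unique_contribution(reduced, dm, v, folds = folds,
                                    lambda = lambda,
                                    seed = derive_seed(seed, match(v, use_vars)),
                                    full = full)
  }
  betas <- ridge_fit(cbind(1, dm$X), reduced$temporal, lambda,
                     penalize = c(0, rep(1, ncol(dm$X))))
  obj <- list(betas = betas, lambda = lambda, r2 = full$r2,
              r2_map = full$r2_map,
              r2_per_fold_mean = full$r2_per_fold_mean,
              dr2 = lapply(dr2, `[[`, "dr2"),
              dr2_maps = lapply(dr2, `[[`, "dr2_map"),
              design = dm, reduced = reduced, folds = folds, mask = mask,
              call = match.call())
  class(obj) <- "encoding_model"
  obj
}

#' @export
print.encoding_model <- function(x, ...) {
  cat("Ridge-regression encoding model\n")
  cat(sprintf("  %d samples, %d design columns (%d variables), %d components, lambda = %g\n",
              nrow(x$design$X), ncol(x$design$X),
              length(x$design$column_groups), x$reduced$k, x$lambda))
  cat(sprintf("  cross-validated R^2 (%d folds): mean %.3f, max %.3f\n",
              x$folds, mean(x$r2, na.rm = TRUE), max(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.encoding_model <- function(object, ...) {
  tab <- data.frame(
    variable = names(object$dr2),
    n_events = vapply(names(object$dr2),
                      function(v) length(object$design$onsets[[v]]), 1L),
    mean_dr2 = vapply(object$dr2, mean, numeric(1), na.rm = TRUE),
    max_dr2 = vapply(object$dr2, max, numeric(1), na.rm = TRUE),
    row.names = NULL
  )
  out <- list(r2_mean = mean(object$r2, na.rm = TRUE),
              r2_max = max(object$r2, na.rm = TRUE),
              lambda = object$lambda, variables = tab)
  class(out) <- "summary.encoding_model"
  out
}

#' @export
print.summary.encoding_model <- function(x, ...) {
  cat(sprintf("Full model: mean R^2 %.3f, max R^2 %.3f (lambda = %g)\n",
              x$r2_mean, x$r2_max, x$lambda))
  cat("Unique contributions (delta R^2):\n")
  print(x$variables, digits = 3)
  invisible(x)
}

#' @export
coef.encoding_model <- function(object, variable = NULL, ...) {
  B <- object$betas[-1L, , drop = FALSE]  # drop intercept row
  if (is.null(variable)) return(B)
  B[object$design$column_groups[[variable]], , drop = FALSE]
}

#' Predicted dF/F0 (or temporal components) from the fitted model
#'
#' @param object an `encoding_model`.
#' @param newdesign optional design matrix (defaults to the training one).
#' @param space `"components"` (time x k) or `"pixels"` (time x pixels,
#'   reconstructed through the spatial components and center).
#' @param ... unused.
#' @export
predict.encoding_model <- function(object, newdesign = NULL,
                                   space = c("components", "pixels"), ...) {
  space <- match.arg(space)
  X <- if (is.null(newdesign)) object$design$X else
    if (inherits(newdesign, "design_matrix")) newdesign$X else
      as.matrix(newdesign)
  pred <- cbind(1, X) %*% object$betas
  if (space == "components") return(pred)
  sweep(pred %*% object$reduced$spatial, 2L, object$reduced$center, "+")
}

#' @export
residuals.encoding_model <- function(object, ...) {
  object$reduced$temporal - predict(object)
}

#' Map plots for an encoding model
#'
#' Images the cross-validated R^2 map, or one variable's unique-contribution
#' (delta R^2) map.
#'
#' @param x an `encoding_model`.
#' @param variable `NULL` for the full-model map, or a variable name.
#' @param ... passed to [graphics::image()].
#' @export
plot.encoding_model <- function(x, variable = NULL, ...) {
  m <- if (is.null(variable)) x$r2_map else x$dr2_maps[[variable]]
  if (is.null(m)) stopf("no map available for '%s'", variable %||% "full")
  graphics::image(t(m)[, nrow(m):1], axes = FALSE, asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = if (is.null(variable)) "cross-validated R^2"
                         else sprintf("delta R^2: %s", variable), ...)
  invisible(x)
}
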