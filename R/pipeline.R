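#' Interbrain analysis of one preprocessed session
#'
#' Computes the session-level synchrony statistics: global signals per mouse
#' (corrected and uncorrected), per-phase interbrain Pearson correlations
#' with Fisher z, region time series and inter/intrabrain correlation
#' matrices (before vs together, with change matrices), and the
#' time-varying multitaper coherence of the corrected global signals.
#'
#' @param pre a `preprocessed_session`.
#' @param analysis_window_s phase analysis window (s).
#' @param coherence logical; compute the multitaper coherence map.
#' @param regions logical or `"auto"`; compute region matrices (requires
#'   all region 5x5 blocks inside the mask — at very coarse image sizes some
#'   peripheral regions fall outside, and `"auto"` then skips the matrices
#'   with a message).
#' @return object of class `interbrain_result`: `pcc` (data.frame of phase x
#'   signal-type correlations and Fisher z), `global` (signals), `matrices`
#'   (a [correlation_matrices()] result or NULL), `coherence`
#'   (a `coherence_map` or NULL), `phases` (the windows used).
#' @export
interbrain_analysis <- function(pre, analysis_window_s = 60,
                                coherence = TRUE, regions = "auto") {
  stopifnot(inherits(pre, "preprocessed_session"))
  sched <- pre$phase_schedule
  phases <- list(separate1 = phase_window(sched, "separate1"),
                 together = phase_window(sched, "together"),
                 separate2 = phase_window(sched, "separate2"))
  gl <- list()
  for (m in names(pre$mice)) {
    gl[[m]] <- list(
      corrected = global_signal(pre$mice[[m]]$corrected),
      uncorrected = global_signal(pre$mice[[m]]$uncorrected_green)
    )
  }
  rows <- list()
  for (ph in names(phases)) {
    for (sig in c("corrected", "uncorrected")) {
      r <- phase_pcc(gl$stationary[[sig]], gl$moving[[sig]], phases[[ph]],
                     analysis_window_s)
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, signal = sig, pcc = r,
        fisher_z = if (is.na(r)) NA_real_ else fisher_z(r))
    }
  }
  mats <- NULL
  if (!identical(regions, FALSE)) {
    rs <- pre$regions
    rs <- rs[rs$ML_mm > 0, , drop = FALSE]  # one hemisphere: 10 regions
    mats <- tryCatch({
      tsA <- region_timeseries(pre$mice$stationary$corrected, rs)
      tsB <- region_timeseries(pre$mice$moving$corrected, rs)
      correlation_matrices(tsA, tsB,
                           pre$mice$stationary$corrected$fs,
                           phases = list(before = phases$separate1,
                                         together = phases$together),
                           analysis_window_s = analysis_window_s)
    }, error = function(e) {
      if (identical(regions, "auto")) {
        message("skipping region matrices: ", conditionMessage(e))
        NULL
      } else stop(e)
    })
  }
  cm <- NULL
  if (coherence) {
    cm <- mt_coherence(gl$stationary$corrected, gl$moving$corrected)
  }
  res <- list(pcc = do.call(rbind, rows), global = gl, matrices = mats,
              coherence = cm, phases = phases)
  class(res) <- "interbrain_result"
  res
}

#' @export
print.interbrain_result <- function(x, ...) {
  cat("Interbrain synchrony results\n")
  print(x$pcc, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline on a session
#'
#' Executes the stage graph `simulate -> preprocess -> behavior ->
#' interbrain -> encode` and (optionally) writes each stage's outputs under
#' `out_dir` with a provenance stamp (configuration hash + seed). Re-running
#' with the same configuration skips stages whose stamped outputs already
#' exist, unless `force = TRUE`.
#'
#' @param manifest a [session_params()] object (synthetic sessions), a
#'   manifest YAML path, or a `raw_session`.
#' @param out_dir optional output directory for CSV/TIFF/JSON artifacts.
#' @param encode logical; fit the encoding model (the slowest stage).
#' @param k,folds passed to [encoding_model()].
#' @param force rerun stages even if stamped outputs exist.
#' @return list with `session`, `pre`, `events`, `interbrain`, `encoding`
#'   (NULL unless `encode`), `provenance`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, encode = FALSE,
                         k = 200, folds = 10, force = FALSE) {
  if (inherits(manifest, "session_params")) {
    seed <- manifest$seed
    cfg_hash <- object_hash(unclass(manifest))
    sim <- simulate_session(manifest)
    session <- sim$session
  } else if (inherits(manifest, "raw_session")) {
    session <- manifest
    seed <- session$params$seed %||% NA_integer_
    cfg_hash <- object_hash(session$phase_schedule)
  } else {
    session <- read_session(manifest)
    man <- read_manifest(manifest)
    seed <- man$seed %||% NA_integer_
    cfg_hash <- object_hash(man)
  }
  prov <- list(config_hash = cfg_hash, seed = seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  stamp_path <- function(stage) file.path(out_dir, paste0(stage, ".done.json"))
  stage_done <- function(stage) {
    !force && !is.null(out_dir) && file.exists(stamp_path(stage)) && {
      st <- jsonlite::read_json(stamp_path(stage))
      identical(st$config_hash, cfg_hash)
    }
  }
  stamp <- function(stage) {
    if (!is.null(out_dir))
      jsonlite::write_json(c(prov, stage = stage), stamp_path(stage),
                           auto_unbox = TRUE)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- proc.time()[3L]
  pre <- preprocess_session(session)
  message(sprintf("[preprocess] done in %.1f s", proc.time()[3L] - t0))

  events <- session_behavior_events(pre)
  ib <- interbrain_analysis(pre)
  enc <- NULL
  if (encode) {
    t0 <- proc.time()[3L]
    enc <- encoding_model(pre, events, k = k, folds = folds, seed = seed)
    message(sprintf("[encode] done in %.1f s", proc.time()[3L] - t0))
  }

  if (!is.null(out_dir)) {
    if (!stage_done("behavior")) {
      write_events_csv(events, file.path(out_dir, "behavior_events.csv"))
      stamp("behavior")
    }
    if (!stage_done("interbrain")) {
      utils::write.csv(cbind(trial = prov$seed, ib$pcc),
                       file.path(out_dir, "interbrain_pcc.csv"),
                       row.names = FALSE)
      if (!is.null(ib$matrices)) {
        utils::write.csv(ib$matrices$together$inter,
                         file.path(out_dir, "inter_matrix_together.csv"))
        utils::write.csv(ib$matrices$before$inter,
                         file.path(out_dir, "inter_matrix_before.csv"))
      }
      if (!is.null(ib$coherence)) {
        utils::write.csv(
          data.frame(time_s = rep(ib$coherence$times,
                                  ncol(ib$coherence$coherence)),
                     freq_hz = rep(ib$coherence$freqs,
                                   each = nrow(ib$coherence$coherence)),
                     coherence = as.vector(ib$coherence$coherence)),
          file.path(out_dir, "coherence.csv"), row.names = FALSE)
      }
      stamp("interbrain")
    }
    if (encode && !stage_done("encode")) {
      write_map_tiff(enc$r2_map, file.path(out_dir, "r2_full.tif"))
      for (v in names(enc$dr2_maps))
        write_map_tiff(enc$dr2_maps[[v]],
                       file.path(out_dir, sprintf("dr2_%s.tif", v)))
      utils::write.csv(summary(enc)$variables,
                       file.path(out_dir, "encoding_variables.csv"),
                       row.names = FALSE)
      stamp("encode")
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  invisible(list(session = session, pre = pre, events = events,
                 interbrain = ib, encoding = enc, provenance = prov))
}
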