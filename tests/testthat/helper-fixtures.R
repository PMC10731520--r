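# Shared fixtures. Simulated sessions are cached in-process so several test
# files (and several acceptance properties) can reuse the same runs.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# short schedule for fast structural tests (not used for synchrony
# statistics, which need the full-length phases)
short_schedule <- function() default_phase_schedule(separate_s = 20,
                                                    translate_s = 5,
                                                    together_s = 20)

tiny_params <- function(seed = 1L, ...) {
  session_params(image_size = 8L, phase_schedule = short_schedule(),
                 seed = seed, ...)
}

# full-length session at reduced resolution; phase PCC / coherence fixtures
sync_run <- function(seed, coupling, gfp_mode = FALSE, image_size = 16L) {
  key <- sprintf("sync_%d_%g_%d_%d", seed, coupling, gfp_mode, image_size)
  cache_get(key, function() {
    p <- session_params(image_size = image_size, seed = seed,
                        coupling = coupling, gfp_mode = gfp_mode)
    pre <- preprocess_session(simulate_session(p)$session)
    gl <- list(
      corr_a = global_signal(pre$mice$stationary$corrected),
      corr_b = global_signal(pre$mice$moving$corrected),
      raw_a = global_signal(pre$mice$stationary$uncorrected_green),
      raw_b = global_signal(pre$mice$moving$uncorrected_green)
    )
    sched <- pre$phase_schedule
    list(global = gl, fs = gl$corr_a$fs,
         phases = list(separate1 = phase_window(sched, "separate1"),
                       together = phase_window(sched, "together"),
                       separate2 = phase_window(sched, "separate2")))
  })
}

sync_pcc <- function(run, which = "corr", phase = "together") {
  phase_pcc(run$global[[paste0(which, "_a")]],
            run$global[[paste0(which, "_b")]],
            run$phases[[phase]])
}

# window of a global signal restricted to the centered 60-s phase window
phase_values <- function(gs, phase, analysis_window_s = 60) {
  idx <- duobrain:::analysis_window_idx(length(gs$values), gs$fs, phase,
                                        analysis_window_s)
  gs$values[idx]
}

coupling_levels <- c(0, 0.3, 0.6, 1.0)
coupling_seeds <- 1:10
gfp_seeds <- 201:240

# every simulated trial must be an independent draw: seeds are distinct
# across coupling levels so trial-shuffled pairings never match sessions
# that share bout trains or hemodynamics
coupling_seed <- function(level_idx, s) s + 40L * (level_idx - 1L)

coupling_run <- function(level_idx, s) {
  sync_run(coupling_seed(level_idx, s), coupling_levels[level_idx])
}

# a dff_stack built directly from a T x H x W array
make_dff <- function(values, fs = 28.9, mask = NULL) {
  d <- dim(values)
  mask <- mask %||% matrix(TRUE, d[2], d[3])
  dff_stack(values, mask, fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
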