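# Multi-page TIFF helpers. Stacks are stored as 32-bit TIFF pages scaled to
# [0, 1] by a per-file scale factor recorded in the session manifest, so
# intensities round-trip at ~1e-8 relative precision.

write_stack_tiff <- function(frames, path) {
  mx <- max(frames, 1e-12)
  pages <- lapply(seq_len(dim(frames)[1L]),
                  function(i) frames[i, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  mx
}

read_stack_tiff <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  out <- array(0, c(length(pages), h, w))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]] * scale
  out
}

#' Write a map (H x W matrix) as a single-page TIFF
#'
#' NA values (outside the mask) are written as the minimum; the value range
#' is returned so maps can be rescaled on read.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @return named list with the `lo`/`hi` scaling range, invisibly.
#' @export
write_map_tiff <- function(m, path) {
  lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
  rng <- max(hi - lo, 1e-12)
  m[is.na(m)] <- lo
  tiff::writeTIFF((m - lo) / rng, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  invisible(list(lo = lo, hi = hi))
}

#' Write a raw session to disk
#'
#' One multi-page TIFF per channel per mouse, the behavior ROI traces and
#' ground-truth events as CSV, the mask as TIFF, and a YAML manifest tying
#' everything together (timestamps, phase schedule, key-points, scale
#' factors, parameters).
#'
#' @param sim a [simulate_session()] result (list with `session`, `truth`).
#' @param dir output directory (created).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sess <- sim$session
  stacks <- list()
  for (m in names(sess$brain)) {
    for (ch in names(sess$brain[[m]])) {
      s <- sess$brain[[m]][[ch]]
      f <- sprintf("%s_%s.tif", m, ch)
      sc <- write_stack_tiff(s$frames, file.path(dir, f))
      stacks[[paste(m, ch, sep = "_")]] <- list(
        file = f, scale = sc, channel_label = s$channel_label,
        timestamps = s$timestamps)
    }
  }
  tiff::writeTIFF(sess$mask * 1, file.path(dir, "mask.tif"),
                  bits.per.sample = 8L)
  tr <- sess$behavior$traces
  beh <- data.frame(timestamp_s = sess$behavior$timestamps)
  for (m in names(tr)) for (ch in names(tr[[m]]))
    beh[[paste(m, ch, sep = "_")]] <- tr[[m]][[ch]]
  utils::write.csv(beh, file.path(dir, "behavior_traces.csv"),
                   row.names = FALSE)
  write_events_csv(sim$truth$events, file.path(dir, "truth_events.csv"))
  p <- sess$params
  manifest <- list(
    trial_id = sprintf("synthetic-%d", p$seed),
    condition = "open",
    fs_brain = p$fs_brain, fs_behavior = p$fs_behavior,
    image_size = p$image_size, seed = p$seed,
    phase_schedule = as.list(sess$phase_schedule),
    key_points = lapply(unclass(sess$key_points), as.numeric),
    stacks = stacks,
    behavior_traces = "behavior_traces.csv",
    truth_events = "truth_events.csv",
    mask = "mask.tif"
  )
  path <- file.path(dir, "session.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param manifest_path path to the `session.yaml` manifest.
#' @return a `raw_session` (without ground truth).
#' @export
read_session <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  brain <- list()
  for (key in names(man$stacks)) {
    info <- man$stacks[[key]]
    parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
    frames <- read_stack_tiff(file.path(dir, info$file), info$scale)
    brain[[parts[1L]]][[parts[2L]]] <-
      raw_stack(frames, unlist(info$timestamps), info$channel_label)
  }
  mask <- tiff::readTIFF(file.path(dir, man$mask)) > 0.5
  beh <- utils::read.csv(file.path(dir, man$behavior_traces))
  traces <- list()
  for (nm in setdiff(names(beh), "timestamp_s")) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    traces[[parts[1L]]][[parts[2L]]] <- beh[[nm]]
  }
  sched <- as.data.frame(man$phase_schedule)
  kp <- do.call(key_points, man$key_points)
  trf <- fit_transform(kp)
  regions <- rbind(place_regions(trf, default_regions("right"), mask),
                   place_regions(trf, default_regions("left"), mask))
  sess <- list(
    params = list(fs_brain = man$fs_brain, fs_behavior = man$fs_behavior,
                  seed = man$seed, image_size = man$image_size),
    brain = brain,
    behavior = list(timestamps = beh$timestamp_s, fs = man$fs_behavior,
                    traces = traces),
    mask = mask, key_points = kp, regions = regions,
    phase_schedule = sched
  )
  class(sess) <- "raw_session"
  sess
}

#' Read and validate a session manifest
#'
#' @param path YAML manifest path.
#' @return the manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- yaml::read_yaml(path)
  validate_manifest(man, dirname(path))
}

validate_manifest <- function(man, dir) {
  for (field in c("condition", "fs_brain", "fs_behavior")) {
    if (is.null(man[[field]])) stopf("manifest missing field '%s'", field)
  }
  if (!man$condition %in% c("open", "mesh", "opaque"))
    stopf("condition must be one of open/mesh/opaque, got '%s'",
          man$condition)
  for (field in c("mask", "behavior_traces")) {
    if (is.null(man[[field]]))
      stopf("manifest missing field '%s'", field)
    if (!file.exists(file.path(dir, man[[field]])))
      stopf("manifest field '%s': file not found (%s)", field, man[[field]])
  }
  for (key in names(man$stacks)) {
    if (!file.exists(file.path(dir, man$stacks[[key]]$file)))
      stopf("manifest stack '%s': file not found", key)
  }
  man
}
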