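# Run configuration and the end-to-end pipeline: frames -> preprocess ->
# detect -> classify -> gait summary, with CSV/JSON outputs. The pipeline
# consumes no randomness, so reruns on the same input are byte-identical.

#' Full run configuration
#'
#' Bundles the per-stage configurations. Defaults are the package's standard
#' operating point: detection thresholds (205, 2, 65, 510) at 60 fps.
#'
#' @param preprocess A [preprocess_config()].
#' @param detect A [detection_thresholds()].
#' @param classify A [classification_config()].
#' @param fps Frame rate.
#' @param gap_tolerance Step-segmentation gap bridge (frames).
#' @param px_per_mm Optional length calibration.
#' @param band Optional analysis band `c(top, bottom)` within the
#'   preprocessed frame.
#' @return A `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       detect = detection_thresholds(),
                       classify = classification_config(),
                       fps = 60, gap_tolerance = 2L, px_per_mm = NULL,
                       band = NULL) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(detect, "detection_thresholds"),
            inherits(classify, "classification_config"))
  if (fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  structure(list(preprocess = preprocess, detect = detect,
                 classify = classify, fps = fps,
                 gap_tolerance = as.integer(gap_tolerance),
                 px_per_mm = px_per_mm, band = band),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `preprocess`, `detect`, `classify`, `gait` mirror the
#' constructor arguments; missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, ctor) do.call(ctor, as.list(block %||% list()))
  gait <- y$gait %||% list()
  run_config(
    preprocess = take(y$preprocess, preprocess_config),
    detect = take(y$detect, detection_thresholds),
    classify = take(y$classify, classification_config),
    fps = gait$fps %||% 60,
    gap_tolerance = gait$gap_tolerance %||% 2L,
    px_per_mm = gait$px_per_mm,
    band = if (!is.null(y$band)) as.integer(unlist(y$band))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Preprocess, detect, classify and summarize a frame sequence, optionally
#' writing `detections.csv`, `classified.csv`, `gait_summary.json`,
#' `gait_summary.csv` and `traces.csv` to `out_dir`. Per-stage counts are
#' reported via `message()`.
#'
#' @param frames List of `gait_frame` objects, or a directory path for
#'   [read_frames()].
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `detections`, `classified`, `summary`,
#'   and `traces`.
#' @export
run_pipeline <- function(frames, cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.character(frames)) frames <- read_frames(frames)
  message(sprintf("pipeline: %d frames", length(frames)))
  pp <- preprocess_frames(frames, cfg$preprocess)
  det <- detect_run(pp, thresholds = cfg$detect, band = cfg$band)
  message(sprintf("pipeline: %d clusters detected", nrow(det)))
  cls <- classify_paws(det, cfg$classify)
  message(sprintf("pipeline: %d classified, %d unclassified",
                  sum(!cls$excluded), sum(cls$excluded)))
  summ <- summarize_gait(cls, fps = cfg$fps,
                         gap_tolerance = cfg$gap_tolerance,
                         px_per_mm = cfg$px_per_mm)
  message(sprintf("pipeline: %d steps across paws", summ$run$total_steps))
  traces <- footfall_traces(cls, fps = cfg$fps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(det, file.path(out_dir, "detections.csv"), row.names = FALSE)
    write.csv(cls, file.path(out_dir, "classified.csv"), row.names = FALSE)
    write.csv(summ$paws, file.path(out_dir, "gait_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(run = summ$run, paws = summ$paws,
                              supports = summ$supports),
                         file.path(out_dir, "gait_summary.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
    write.csv(traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
  }
  invisible(list(detections = det, classified = cls, summary = summ,
                 traces = traces))
}

#' Preview the preprocessing transform
#'
#' Writes before/after PNGs for one frame so the distortion, rotation and
#' crop parameters can be tuned by eye — the configuration-driven
#' replacement for an interactive calibration step.
#'
#' @param frame A `gait_frame`.
#' @param cfg A [preprocess_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
calibrate_preview <- function(frame, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  before <- file.path(out_dir, "calibrate_before.png")
  after <- file.path(out_dir, "calibrate_after.png")
  png::writePNG(unclass(frame) / 255, before)
  png::writePNG(unclass(preprocess_frame(frame, cfg)) / 255, after)
  invisible(c(before, after))
}
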