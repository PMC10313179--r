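#' Run the full analysis pipeline on a detection stream
#'
#' Convenience wrapper: links body detections into tracks, assigns heads
#' for headings, produces chase events (from detector-labeled boxes when
#' present and requested, otherwise kinematically), aggregates chaining
#' records, and computes the metrics report.
#'
#' @param detections A detections tibble ([read_detections()]).
#' @param config An [arena_config()].
#' @param tracker A [tracker_params()].
#' @param chase A [chase_params()].
#' @param metrics A [metric_params()].
#' @param use_detector_events If `TRUE` and the stream contains event
#'   boxes (`chase`/`wing_ext`/`mount`), attribute those instead of
#'   running the kinematic classifier.
#' @param corrections Optional corrections tibble
#'   ([read_corrections()]) applied to the tracks before event analysis.
#' @return A list with `tracks`, `events`, `chains`, and `metrics`
#'   (a `fly_metrics`).
#' @examples
#' fx <- make_worked_examples(duration = 120)
#' sim <- simulate_arena(fx$A$script, fx$A$config)
#' res <- run_pipeline(sim$detections, fx$A$config)
#' glance(res$metrics)
#' @export
run_pipeline <- function(detections, config,
                         tracker = tracker_params(),
                         chase = chase_params(),
                         metrics = metric_params(),
                         use_detector_events = FALSE,
                         corrections = NULL) {
  tracks <- link_detections(detections, config, tracker)
  tracks <- assign_heads(tracks, detections, tracker)
  if (!is.null(corrections)) tracks <- apply_corrections(tracks, corrections)
  has_boxes <- any(detections$label %in% c("chase", "wing_ext", "mount"))
  events <- if (use_detector_events && has_boxes) {
    attribute_detector_events(detections, tracks, config, chase)
  } else {
    classify_kinematic_chases(tracks, config, chase)
  }
  frames <- seq(min(tracks$frame), max(tracks$frame))
  chains <- detect_chaining(events, frames, config$n_flies)
  report <- compute_metrics(tracks, events, chains, config, metrics)
  list(tracks = tracks, events = events, chains = chains, metrics = report)
}
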