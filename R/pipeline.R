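#' Run the full SMAM quantification pipeline on a series
#'
#' Convenience wrapper chaining [normalize_series()], [detect_voids()],
#' [filter_large_dropouts()] (when a label map is available) and
#' [link_events()], then deriving the summary quantities.
#'
#' @param series A `dwi_series`, or a 4D array with `label_map` supplied.
#' @param drop_threshold,min_size Passed to [detect_voids()].
#' @param label_map Optional label map overriding the scene's.
#' @param max_muscle_fraction,max_muscle_count Passed to
#'   [filter_large_dropouts()]; set `max_muscle_fraction = NULL` to skip
#'   the filter.
#' @param trf Frame interval, ms; defaults to the schedule's `trf` when
#'   the input is a `dwi_series`.
#' @param reference Passed to [normalize_series()].
#' @return List with `smams` (`smam_set`), `events` (event table), `pecm`
#'   (overall map), `pecm_per_cycle`, `activity_rate_pct` and `discarded`.
#' @export
analyze_series <- function(series, drop_threshold = 0.3, min_size = 2,
                           label_map = NULL, max_muscle_fraction = 0.5,
                           max_muscle_count = 2, trf = NULL,
                           reference = "auto") {
  if (inherits(series, "dwi_series")) {
    if (is.null(trf)) trf <- attr(series$schedule, "params")$trf
    if (is.null(label_map)) label_map <- series$scene$label_map
  }
  norm <- normalize_series(series, reference = reference)
  if (!is.null(label_map)) norm$label_map <- label_map
  roi <- if (!is.null(label_map)) label_map > 0 else NULL
  masks <- detect_voids(norm, drop_threshold, min_size, roi = roi)
  if (!is.null(label_map) && !is.null(max_muscle_fraction))
    masks <- filter_large_dropouts(masks, label_map,
                                   max_muscle_fraction, max_muscle_count)
  set <- link_events(masks, trf = trf)
  list(smams = set,
       events = smam_table(set),
       pecm = compute_pecm(set, "overall"),
       pecm_per_cycle = compute_pecm(set, "per_cycle"),
       activity_rate_pct = repetition_activity_rate(set),
       discarded = attr(masks, "discarded"))
}
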