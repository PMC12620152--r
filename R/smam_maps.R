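#' Percentage event count map
#'
#' Per-voxel SMAM occurrence frequency across repetitions, in percent. In
#' `"overall"` mode a voxel counts once per repetition when it belongs to
#' any frame of any SMAM of that repetition (union over cycles); in
#' `"per_cycle"` mode the same count is restricted to each cycle,
#' producing one map per cycle that is voxel-wise bounded by the overall
#' map. `"sum"` mode counts voxel-frames (may exceed 100).
#'
#' @param x A `smam_set` from [link_events()].
#' @param mode `"overall"`, `"per_cycle"` or `"sum"`.
#' @return For `"overall"`/`"sum"`: a matrix of percentages. For
#'   `"per_cycle"`: a 3D array `rows x cols x cycles`.
#' @export
compute_pecm <- function(x, mode = c("overall", "per_cycle", "sum")) {
  stopifnot(inherits(x, "smam_set"))
  mode <- match.arg(mode)
  R <- x$n_repetitions
  if (is.null(R) || R < 1L) .stopf("repetition count must be >= 1")
  dm <- x$dim
  if (mode == "per_cycle") {
    out <- array(0, dim = c(dm, x$n_cycles))
    for (n in seq_len(x$n_cycles)) {
      cnt <- matrix(0, dm[1], dm[2])
      for (r in seq_len(R)) {
        hit <- unique(unlist(lapply(x$smams, function(s)
          if (s$repetition == r) s$masks[[as.character(n)]])))
        cnt[hit] <- cnt[hit] + 1
      }
      out[, , n] <- 100 * cnt / R
    }
    return(out)
  }
  cnt <- matrix(0, dm[1], dm[2])
  for (r in seq_len(R)) {
    vox <- lapply(x$smams, function(s)
      if (s$repetition == r) unlist(s$masks, use.names = FALSE))
    if (mode == "overall") {
      hit <- unique(unlist(vox))
      cnt[hit] <- cnt[hit] + 1
    } else {
      for (v in unlist(vox)) cnt[v] <- cnt[v] + 1
    }
  }
  100 * cnt / R
}

#' Share of repetitions showing at least one SMAM
#'
#' @param x A `smam_set`.
#' @return Percentage of repetitions with one or more surviving SMAMs.
#' @export
repetition_activity_rate <- function(x) {
  stopifnot(inherits(x, "smam_set"))
  active <- unique(vapply(x$smams, function(s) s$repetition, integer(1)))
  100 * length(active) / x$n_repetitions
}

#' Per-muscle summary of SMAM dynamics
#'
#' For each muscle (dominant label at the peak frame) reports the event
#' count, and median with distribution-free 95% CI of the contraction time
#' (evaluable events only) and duration, in frames and ms.
#'
#' @param x A `smam_set`.
#' @param label_names Named integer vector mapping muscle names to labels
#'   (e.g. `scene$label_names`).
#' @param level CI level for [median_ci()].
#' @return Data frame with one row per muscle, including muscles without
#'   events (`n = 0`, NA summaries).
#' @export
per_muscle_summary <- function(x, label_names, level = 0.95) {
  stopifnot(inherits(x, "smam_set"))
  tab <- smam_table(x)
  rows <- lapply(names(label_names), function(m) {
    sub <- tab[!is.na(tab$dominant_muscle) &
               tab$dominant_muscle == as.character(label_names[[m]]), ]
    tc <- sub$smam_tc_frames[sub$tc_evaluable]
    dur <- sub$duration_frames
    ci_or_na <- function(v) {
      if (!length(v)) return(list(median = NA_real_, lower = NA_real_,
                                  upper = NA_real_))
      median_ci(v, level)
    }
    tci <- ci_or_na(tc); dci <- ci_or_na(dur)
    data.frame(
      muscle = m, n_events = nrow(sub), n_tc_evaluable = length(tc),
      tc_median_frames = tci$median, tc_ci_lower = tci$lower,
      tc_ci_upper = tci$upper, tc_median_ms = tci$median * x$trf,
      duration_median_frames = dci$median, duration_ci_lower = dci$lower,
      duration_ci_upper = dci$upper, duration_median_ms = dci$median * x$trf)
  })
  do.call(rbind, rows)
}

#' Onset-by-duration distribution of SMAMs
#'
#' Tabulates events by first visible frame (onset) and duration in frames,
#' normalized by the total number of SMAM-indicating images (the sum of all
#' event durations), in percent.
#'
#' @param x A `smam_set`.
#' @return Matrix `onset x duration` (1..n_cycles each) of percentages.
#' @export
onset_duration_histogram <- function(x) {
  stopifnot(inherits(x, "smam_set"))
  tab <- smam_table(x)
  h <- matrix(0, x$n_cycles, x$n_cycles,
              dimnames = list(onset = seq_len(x$n_cycles),
                              duration = seq_len(x$n_cycles)))
  for (i in seq_len(nrow(tab)))
    h[tab$first_frame[i], tab$duration_frames[i]] <-
      h[tab$first_frame[i], tab$duration_frames[i]] + tab$duration_frames[i]
  if (sum(h) > 0) h <- 100 * h / sum(h)
  h
}
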