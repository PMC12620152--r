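#' Link per-frame voids into SMAM events
#'
#' Within each repetition, void components in consecutive cycles are joined
#' into one event when their masks share at least one voxel. A component
#' overlapping no active chain starts a new event; a chain with no
#' overlapping component in the next frame ends there (no gap bridging: a
#' one-frame disappearance splits the event). A component overlapping
#' several chains joins the one with the largest overlap (ties: the
#' earlier-started chain). Linking is deterministic and independent across
#' repetitions.
#'
#' @param masks A [detect_voids()] (optionally
#'   [filter_large_dropouts()]-ed) result.
#' @param trf Inter-pulse interval, ms, for frame-to-ms conversion (taken
#'   as 40 when not supplied and no schedule is known).
#' @return An object of class `smam_set`: list with `smams` (list of
#'   `detected_smam` objects), `n_repetitions`, `n_cycles`, `dim`, `trf`,
#'   `label_map`.
#' @export
link_events <- function(masks, trf = NULL) {
  stopifnot(inherits(masks, "void_masks"))
  if (is.null(trf)) trf <- 40
  ncyc <- attr(masks, "n_cycles")
  dm <- attr(masks, "grid_dim")
  label_map <- attr(masks, "label_map")
  smams <- list()
  for (r in seq_along(masks)) {
    open <- list()  # each: list(frames = named list cycle -> voxel idx)
    closed <- list()
    for (n in seq_len(ncyc)) {
      lab <- masks[[r]][[n]]
      comps <- setdiff(unique(as.integer(lab)), 0L)
      comp_vox <- lapply(comps, function(k) which(lab == k))
      extended <- rep(FALSE, length(open))
      assign_to <- integer(length(comps))
      for (i in seq_along(comps)) {
        ov <- vapply(open, function(ch)
          length(intersect(ch$last_vox, comp_vox[[i]])), integer(1))
        assign_to[i] <- if (length(ov) && max(ov) > 0L) which.max(ov) else 0L
      }
      new_open <- open
      for (i in seq_along(comps)) {
        j <- assign_to[i]
        if (j > 0L) {
          key <- as.character(n)
          prev <- new_open[[j]]$frames[[key]]
          new_open[[j]]$frames[[key]] <- union(prev, comp_vox[[i]])
          extended[j] <- TRUE
        }
      }
      for (j in seq_along(open)) {
        if (!extended[j]) closed[[length(closed) + 1L]] <- open[[j]]
      }
      open <- new_open[extended]
      for (i in seq_along(comps)) {
        if (assign_to[i] == 0L) {
          open[[length(open) + 1L]] <-
            list(frames = stats::setNames(list(comp_vox[[i]]),
                                          as.character(n)))
        }
      }
      open <- lapply(open, function(ch) {
        ch$last_vox <- ch$frames[[as.character(n)]]
        ch
      })
    }
    closed <- c(closed, open)
    for (ch in closed)
      smams[[length(smams) + 1L]] <-
        .make_smam(ch$frames, r, ncyc, trf, dm, label_map)
  }
  structure(list(smams = smams,
                 n_repetitions = attr(masks, "n_repetitions"),
                 n_cycles = ncyc, dim = dm, trf = trf,
                 label_map = label_map),
            class = "smam_set")
}

.make_smam <- function(frames, repetition, ncyc, trf, dm, label_map) {
  cycles <- sort(as.integer(names(frames)))
  first <- min(cycles); last <- max(cycles)
  csa <- integer(ncyc)
  for (n in cycles) csa[n] <- length(frames[[as.character(n)]])
  peak <- which.max(csa)  # first frame of maximum CSA
  dominant <- NA_character_
  if (!is.null(label_map)) {
    hit <- label_map[frames[[as.character(peak)]]]
    hit <- hit[hit > 0]
    if (length(hit)) {
      tab <- sort(table(hit), decreasing = TRUE)
      dominant <- names(tab)[1]  # majority label; ties -> smallest label
    }
  }
  s <- list(repetition = repetition,
            masks = frames[as.character(cycles)],
            first_frame = first, last_frame = last, peak_frame = peak,
            csa_course = csa,
            duration_frames = last - first + 1L,
            duration_ms = (last - first + 1L) * trf,
            dominant_muscle = dominant,
            tc_evaluable = first > 1L)
  tc <- contraction_time(s, trf)
  s$smam_tc_frames <- tc$frames
  s$smam_tc_ms <- tc$ms
  s$category <- categorize_observed(first, last, ncyc)
  s$two_frame <- s$duration_frames == 2L
  class(s) <- "detected_smam"
  s
}

#' Contraction time of a linked SMAM
#'
#' The contraction time is the span from the first visible void to the
#' maximum cross-sectional area, counted inclusively in frames and
#' converted to ms with the frame interval: an event peaking in the frame
#' after its first appearance has a contraction time of 2 frames = 80 ms at
#' `trf = 40`; peaking in its first visible frame gives the smallest
#' possible value, 1 frame = 40 ms. Events already visible in the first
#' image are not evaluable, because their true start is unobserved.
#'
#' @param smam A `detected_smam` (or a list with `first_frame`,
#'   `peak_frame`, `tc_evaluable`).
#' @param trf Frame interval, ms.
#' @return List with `frames`, `ms` (both `NA` when not evaluable) and
#'   `evaluable`.
#' @export
contraction_time <- function(smam, trf) {
  if (!isTRUE(smam$tc_evaluable))
    return(list(frames = NA_integer_, ms = NA_real_, evaluable = FALSE))
  frames <- smam$peak_frame - smam$first_frame + 1L
  list(frames = frames, ms = frames * trf, evaluable = TRUE)
}

#' Cross-sectional-area course of a SMAM
#'
#' @param smam A `detected_smam`.
#' @return Data frame with columns `cycle`, `csa_voxels` and `csa_pct`
#'   (percent of the peak CSA; the peak is 100). CSA is zero outside
#'   `[first_frame, last_frame]`.
#' @export
csa_course <- function(smam) {
  csa <- smam$csa_course
  data.frame(cycle = seq_along(csa), csa_voxels = csa,
             csa_pct = 100 * csa / max(csa))
}

#' Observed start/end category of a SMAM
#'
#' Maps the first and last visible frame onto the reporting categories used
#' for event tallies: present from the first to the last image, starting at
#' the first image but ending early, starting late but lasting to the end,
#' or fully contained within the series. Whether an event spans exactly two
#' frames is tracked separately (`two_frame` flag on the event).
#'
#' @param first_frame,last_frame 1-based cycle indices.
#' @param nrf Number of cycles in the series.
#' @return One of `"start1_end_last"`, `"start1_end_early"`,
#'   `"late_start_end_last"`, `"contained"`.
#' @export
categorize_observed <- function(first_frame, last_frame, nrf) {
  if (first_frame == 1L && last_frame == nrf) "start1_end_last"
  else if (first_frame == 1L) "start1_end_early"
  else if (last_frame == nrf) "late_start_end_last"
  else "contained"
}

#' Event table of a linked SMAM set
#'
#' @param x A `smam_set` from [link_events()].
#' @return Data frame with one row per SMAM: repetition, frames, peak,
#'   CSA at peak, contraction time, duration, dominant muscle label,
#'   category and flags.
#' @export
smam_table <- function(x) {
  stopifnot(inherits(x, "smam_set"))
  if (!length(x$smams))
    return(data.frame(repetition = integer(0), first_frame = integer(0),
                      last_frame = integer(0), peak_frame = integer(0),
                      peak_csa_voxels = integer(0), smam_tc_frames = integer(0),
                      smam_tc_ms = numeric(0), duration_frames = integer(0),
                      duration_ms = numeric(0), dominant_muscle = character(0),
                      category = character(0), two_frame = logical(0),
                      tc_evaluable = logical(0)))
  do.call(rbind, lapply(x$smams, function(s) data.frame(
    repetition = s$repetition, first_frame = s$first_frame,
    last_frame = s$last_frame, peak_frame = s$peak_frame,
    peak_csa_voxels = max(s$csa_course),
    smam_tc_frames = s$smam_tc_frames, smam_tc_ms = s$smam_tc_ms,
    duration_frames = s$duration_frames, duration_ms = s$duration_ms,
    dominant_muscle = s$dominant_muscle, category = s$category,
    two_frame = s$two_frame, tc_evaluable = s$tc_evaluable)))
}
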