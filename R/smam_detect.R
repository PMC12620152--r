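#' Normalize a DWI series to relative signal
#'
#' Divides every voxel value by a cycle-matched reference so that b-value
#' growth and T1-related drifts cancel and undisturbed voxels sit near 1.
#' The reference is the per-voxel, per-cycle median across repetitions,
#' which is robust to events present in fewer than half of the repetitions.
#' With a single repetition the model-predicted event-free signal is used
#' instead (requires the series to carry its scene and schedule).
#'
#' @param series A `dwi_series`, or a plain array
#'   `rows x cols x cycles x repetitions`.
#' @param reference `"auto"` (median across repetitions when there are at
#'   least two, model prediction otherwise), `"median"`, or `"model"` (the
#'   event-free rendered signal; useful when an event recurs at the same
#'   place in most repetitions, where the median itself is contaminated).
#' @return An object of class `normalized_series`: list with `rel` (array of
#'   relative signal, same shape) and `label_map` (from the scene, or
#'   `NULL`).
#' @export
normalize_series <- function(series, reference = c("auto", "median", "model")) {
  reference <- match.arg(reference)
  if (inherits(series, "dwi_series")) {
    data <- series$data
    label_map <- series$scene$label_map
  } else {
    data <- series
    label_map <- NULL
  }
  d <- dim(data)
  if (length(d) != 4L) .stopf("expected a 4D rows x cols x cycles x reps array")
  if (reference == "auto")
    reference <- if (d[4] >= 2L) "median" else "model"
  if (reference == "median") {
    if (d[4] < 2L)
      .stopf("single repetition and no scene/schedule to predict a reference")
    ref <- apply(data, c(1, 2, 3), stats::median)
  } else {
    if (!inherits(series, "dwi_series") || is.null(series$scene))
      .stopf(if (d[4] >= 2L) "model reference needs a dwi_series with a scene"
             else "single repetition and no scene/schedule to predict a reference")
    ref <- render_dwi_series(series$scene, series$schedule)$noiseless[, , , 1]
  }
  ref[ref <= 0] <- NA_real_
  rel <- data / as.vector(ref)  # ref recycles over repetitions
  rel[is.na(rel)] <- 1
  structure(list(rel = rel, label_map = label_map),
            class = "normalized_series")
}

# 8-connectivity connected-component labelling of a logical matrix.
# Iterative flood fill; grids here are small (64 x 64).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 1L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((v - 1L) %% nr) + 1L
      c <- ((v - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        w <- rr + (cc - 1L) * nr
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          stack <- c(stack, w)
        }
      }
    }
    nxt <- nxt + 1L
  }
  lab
}

#' Detect signal voids in a normalized series
#'
#' Thresholds the relative signal at `1 - drop_threshold` and keeps
#' 8-connected components of at least `min_size` voxels, per repetition and
#' cycle.
#'
#' @param normalized A [normalize_series()] result.
#' @param drop_threshold Minimum relative signal drop, fraction in (0, 1).
#' @param min_size Minimum component size, voxels.
#' @param roi Optional logical matrix restricting detection to tissue of
#'   interest (e.g. `label_map > 0`); outside voxels carry no meaningful
#'   relative signal (air is pure noise) and are ignored.
#' @return An object of class `void_masks`: list of repetitions, each a
#'   list of labelled integer matrices (one per cycle, 0 = background),
#'   with attributes `drop_threshold`, `min_size`, `grid_dim`, `n_cycles`,
#'   `n_repetitions` and `label_map`.
#' @export
detect_voids <- function(normalized, drop_threshold = 0.3, min_size = 2,
                         roi = NULL) {
  stopifnot(inherits(normalized, "normalized_series"))
  if (drop_threshold <= 0 || drop_threshold >= 1)
    .stopf("drop_threshold must be in (0, 1)")
  d <- dim(normalized$rel)
  if (!is.null(roi) && !identical(dim(roi), d[1:2]))
    .stopf("roi grid does not match the series")
  masks <- lapply(seq_len(d[4]), function(r) {
    lapply(seq_len(d[3]), function(n) {
      hit <- normalized$rel[, , n, r] <= 1 - drop_threshold
      if (!is.null(roi)) hit <- hit & roi
      lab <- label_components(hit)
      if (min_size > 1L && any(lab > 0L)) {
        sizes <- tabulate(lab)
        lab[lab > 0L & sizes[pmax(lab, 1L)] < min_size] <- 0L
      }
      lab
    })
  })
  structure(masks, class = "void_masks",
            drop_threshold = drop_threshold, min_size = min_size,
            grid_dim = d[1:2], n_cycles = d[3], n_repetitions = d[4],
            label_map = normalized$label_map)
}

#' Discard large signal dropouts spanning muscles
#'
#' Voids covering most of a muscle, or straddling many muscles, are taken
#' to reflect intended limb movement rather than a spontaneous twitch and
#' are removed before linking.
#'
#' @param masks A [detect_voids()] result.
#' @param label_map Integer muscle label map (defaults to the one carried
#'   by `masks`).
#' @param max_muscle_fraction Discard a component covering more than this
#'   fraction of any single muscle.
#' @param max_muscle_count Discard a component intersecting more than this
#'   many muscles.
#' @return `masks` with offending components zeroed; the discard log (data
#'   frame `repetition`, `cycle`, `component`, `reason`) is attached as
#'   attribute `discarded`.
#' @export
filter_large_dropouts <- function(masks, label_map = NULL,
                                  max_muscle_fraction = 0.5,
                                  max_muscle_count = 2) {
  stopifnot(inherits(masks, "void_masks"))
  if (is.null(label_map)) label_map <- attr(masks, "label_map")
  if (is.null(label_map)) .stopf("no label map available")
  muscle_sizes <- table(label_map[label_map > 0])
  log <- list()
  for (r in seq_along(masks)) {
    for (n in seq_along(masks[[r]])) {
      lab <- masks[[r]][[n]]
      for (comp in setdiff(unique(as.integer(lab)), 0L)) {
        vox <- lab == comp
        hit <- label_map[vox]
        hit <- hit[hit > 0]
        reason <- NULL
        if (length(unique(hit)) > max_muscle_count) {
          reason <- sprintf("intersects %d muscles", length(unique(hit)))
        } else if (length(hit)) {
          frac <- table(hit) / muscle_sizes[names(table(hit))]
          if (any(frac > max_muscle_fraction))
            reason <- sprintf("covers %.0f%% of muscle %s",
                              100 * max(frac), names(which.max(frac)))
        }
        if (!is.null(reason)) {
          lab[vox] <- 0L
          log[[length(log) + 1L]] <- data.frame(
            repetition = r, cycle = n, component = comp, reason = reason)
        }
      }
      masks[[r]][[n]] <- lab
    }
  }
  attr(masks, "discarded") <- if (length(log)) do.call(rbind, log) else
    data.frame(repetition = integer(0), cycle = integer(0),
               component = integer(0), reason = character(0))
  masks
}
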