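# Minimal hand-built inputs: arrays are rows x cols x cycles x repetitions.

flat_series <- function(nr = 8, nc = 8, ncyc = 5, reps = 6, value = 2) {
  array(value, dim = c(nr, nc, ncyc, reps))
}

# detect/link on a hand-built normalized stack
masks_from_rel <- function(rel, threshold = 0.3, min_size = 1) {
  detect_voids(structure(list(rel = rel, label_map = NULL),
                         class = "normalized_series"),
               drop_threshold = threshold, min_size = min_size)
}

test_that("median normalization removes trends and isolates drops", {
  x <- flat_series()
  trend <- exp(-(1:5) / 4)
  x <- sweep(x, 3, trend, "*")  # same b/T1 trend in every repetition
  norm <- normalize_series(x)
  expect_equal(norm$rel, array(1, dim = dim(x)), tolerance = 1e-12)
  # a 50% drop in one repetition reads 0.5 and leaves the reference intact
  x[3, 4, 2, 1] <- x[3, 4, 2, 1] * 0.5
  norm <- normalize_series(x)
  expect_equal(norm$rel[3, 4, 2, 1], 0.5, tolerance = 1e-12)
  expect_equal(norm$rel[3, 4, 2, 2], 1, tolerance = 1e-12)
  # median reference unaffected by events in < 50% of repetitions
  x2 <- flat_series(reps = 7)
  x2[5, 5, 3, 1:3] <- 0.1  # 3 of 7 repetitions
  norm2 <- normalize_series(x2)
  expect_equal(norm2$rel[5, 5, 3, 4], 1, tolerance = 1e-12)
  expect_error(normalize_series(array(1, dim = c(4, 4, 3, 1))),
               "single repetition")
})

test_that("void detection thresholds, sizes and 8-connectivity", {
  rel <- array(1, dim = c(8, 8, 3, 1))
  m <- masks_from_rel(rel)
  expect_true(all(vapply(m[[1]], function(x) all(x == 0L), logical(1))))
  # diagonal pair is one 8-connected component
  rel[3, 3, 2, 1] <- 0.4
  rel[4, 4, 2, 1] <- 0.4
  m <- masks_from_rel(rel, min_size = 2)
  expect_equal(sort(unique(as.integer(m[[1]][[2]]))), c(0L, 1L))
  # single-voxel drop rejected at min_size 2
  rel2 <- array(1, dim = c(8, 8, 3, 1))
  rel2[6, 6, 1, 1] <- 0.2
  m2 <- masks_from_rel(rel2, min_size = 2)
  expect_true(all(m2[[1]][[1]] == 0L))
  # exactly at the threshold boundary: 0.7 counts for drop_threshold 0.3
  rel3 <- array(1, dim = c(8, 8, 1, 1))
  rel3[2, 2, 1, 1] <- 0.7
  expect_equal(sum(masks_from_rel(rel3)[[1]][[1]] > 0), 1)
  expect_error(masks_from_rel(rel, threshold = 1.2), "0, 1")
})

test_that("large dropouts across muscles are discarded with reasons", {
  label_map <- matrix(0L, 8, 8)
  label_map[2:4, 2:4] <- 1L  # muscle 1
  label_map[2:4, 6:8] <- 2L  # muscle 2
  label_map[6:8, 2:4] <- 3L  # muscle 3
  rel <- array(1, dim = c(8, 8, 2, 1))
  rel[2:4, 2:4, 1, 1] <- 0.1          # whole muscle 1
  rel[2, 2:8, 2, 1] <- 0.1            # straddles muscles 1 and 2
  rel[6, 2, 2, 1] <- 0.1              # small, inside muscle 3
  masks <- masks_from_rel(rel)
  filtered <- filter_large_dropouts(masks, label_map,
                                    max_muscle_fraction = 0.5,
                                    max_muscle_count = 1)
  log <- attr(filtered, "discarded")
  expect_equal(nrow(log), 2)
  expect_match(log$reason[log$cycle == 1], "covers")
  expect_match(log$reason[log$cycle == 2], "muscles")
  expect_equal(sum(filtered[[1]][[2]] > 0), 1)  # the small one survives
  # with permissive limits everything is kept
  keep <- filter_large_dropouts(masks, label_map,
                                max_muscle_fraction = 1.1,
                                max_muscle_count = 99)
  expect_equal(nrow(attr(keep, "discarded")), 0)
})

test_that("linking joins overlapping voids and splits on gaps", {
  rel <- array(1, dim = c(8, 8, 10, 1))
  rel[3:4, 3:4, 5:8, 1] <- 0.2       # frames 5-8, one location
  set <- link_events(masks_from_rel(rel), trf = 40)
  expect_length(set$smams, 1)
  expect_equal(set$smams[[1]]$first_frame, 5)
  expect_equal(set$smams[[1]]$last_frame, 8)
  expect_equal(set$smams[[1]]$duration_frames, 4)
  expect_equal(set$smams[[1]]$duration_ms, 160)
  # two disjoint simultaneous voids -> two events
  rel2 <- array(1, dim = c(8, 8, 10, 1))
  rel2[2, 2, 3, 1] <- 0.2
  rel2[7, 7, 3, 1] <- 0.2
  expect_length(link_events(masks_from_rel(rel2), 40)$smams, 2)
  # same location in frames 2 and 4 with nothing in frame 3 -> two events
  rel3 <- array(1, dim = c(8, 8, 10, 1))
  rel3[5, 5, 2, 1] <- 0.2
  rel3[5, 5, 4, 1] <- 0.2
  set3 <- link_events(masks_from_rel(rel3), 40)
  expect_length(set3$smams, 2)
  expect_equal(sort(vapply(set3$smams, function(s) s$first_frame,
                           integer(1))), c(2L, 4L))
  # non-overlapping drift in consecutive frames also splits
  rel4 <- array(1, dim = c(8, 8, 10, 1))
  rel4[2, 2, 2, 1] <- 0.2
  rel4[6, 6, 3, 1] <- 0.2
  expect_length(link_events(masks_from_rel(rel4), 40)$smams, 2)
})

test_that("contraction time follows the inclusive-frame convention", {
  mk <- function(first, peak) list(first_frame = first, peak_frame = peak,
                                   tc_evaluable = first > 1L)
  expect_equal(contraction_time(mk(5L, 6L), 40),
               list(frames = 2L, ms = 80, evaluable = TRUE))
  expect_equal(contraction_time(mk(3L, 3L), 40),
               list(frames = 1L, ms = 40, evaluable = TRUE))
  tc <- contraction_time(mk(1L, 4L), 40)
  expect_false(tc$evaluable)
  expect_true(is.na(tc$frames))
})

test_that("CSA course normalizes to its peak", {
  rel <- array(1, dim = c(10, 10, 5, 1))
  sizes <- c(25, 42, 30, 14)  # frames 1-4
  for (i in seq_along(sizes)) {
    vox <- arrayInd(1:63, c(10, 10))  # a fixed connected block
    pick <- vox[seq_len(sizes[i]), ]
    rel[cbind(pick, i, 1)] <- 0.2
  }
  set <- link_events(masks_from_rel(rel), 40)
  expect_length(set$smams, 1)
  course <- csa_course(set$smams[[1]])
  expect_equal(course$csa_voxels[1:4], sizes)
  expect_equal(round(course$csa_pct[1:4], 1), c(59.5, 100, 71.4, 33.3))
  expect_equal(course$csa_voxels[5], 0)
  # single-frame event
  rel1 <- array(1, dim = c(8, 8, 3, 1))
  rel1[4:5, 4, 2, 1] <- 0.2
  one <- link_events(masks_from_rel(rel1), 40)$smams[[1]]
  expect_equal(csa_course(one)$csa_pct[2], 100)
})

test_that("observed categories map first/last frames as reported", {
  expect_identical(categorize_observed(1L, 10L, 10L), "start1_end_last")
  expect_identical(categorize_observed(1L, 6L, 10L), "start1_end_early")
  expect_identical(categorize_observed(3L, 10L, 10L), "late_start_end_last")
  expect_identical(categorize_observed(3L, 7L, 10L), "contained")
  # two-frame flag is independent of the category
  rel <- array(1, dim = c(8, 8, 10, 1))
  rel[4:5, 4:5, 4:5, 1] <- 0.2
  s <- link_events(masks_from_rel(rel), 40)$smams[[1]]
  expect_identical(s$category, "contained")
  expect_true(s$two_frame)
})

test_that("pECM normalization and per-cycle bound", {
  rel <- array(1, dim = c(8, 8, 10, 300))
  rel[3:4, 3, 5:6, 10] <- 0.2  # one event in 1 of 300 repetitions
  set <- link_events(masks_from_rel(rel), 40)
  pecm <- compute_pecm(set, "overall")
  expect_equal(pecm[3, 3], 100 / 300)
  expect_equal(sum(pecm > 0), 2)
  per <- compute_pecm(set, "per_cycle")
  expect_true(all(per <= replicate(10, pecm) + 1e-12))
  expect_equal(per[3, 3, 5], 100 / 300)
  expect_equal(per[3, 3, 1], 0)
  # no detections -> all-zero map
  empty <- link_events(masks_from_rel(array(1, dim = c(8, 8, 10, 4))), 40)
  expect_true(all(compute_pecm(empty, "overall") == 0))
  # an event in every repetition at one location -> 100%
  rel2 <- array(1, dim = c(8, 8, 10, 20))
  rel2[5:6, 5, 3:4, ] <- 0.2
  expect_equal(max(compute_pecm(link_events(masks_from_rel(rel2), 40),
                                "overall")), 100)
})

test_that("repetition activity rate counts repetitions, not events", {
  rel <- array(1, dim = c(8, 8, 10, 300))
  for (r in 1:42) rel[2:3, 2, 3, r] <- 0.2
  set <- link_events(masks_from_rel(rel), 40)
  expect_equal(repetition_activity_rate(set), 14)
  # duplicates within a repetition do not change the rate
  rel[6:7, 6, 3, 1:42] <- 0.2
  set2 <- link_events(masks_from_rel(rel), 40)
  expect_equal(repetition_activity_rate(set2), 14)
  expect_equal(repetition_activity_rate(
    link_events(masks_from_rel(array(1, dim = c(8, 8, 10, 5))), 40)), 0)
})

test_that("per-muscle summary recovers known medians and assigns majorities", {
  label_map <- matrix(0L, 8, 8)
  label_map[2:5, 2:5] <- 1L
  label_map[2:5, 7:8] <- 2L
  rel <- array(1, dim = c(8, 8, 10, 9))
  # nine events in muscle 1 with durations 3,3,3,3,5,5,2,3,3 -> median 3
  durs <- c(3, 3, 3, 3, 5, 5, 2, 3, 3)
  for (r in seq_along(durs)) rel[3:4, 3, 2:(1 + durs[r]), r] <- 0.2
  norm <- structure(list(rel = rel, label_map = label_map),
                    class = "normalized_series")
  set <- link_events(detect_voids(norm, 0.3, 1), trf = 40)
  summ <- per_muscle_summary(set, c(m1 = 1L, m2 = 2L))
  expect_equal(summ$n_events, c(9L, 0L))
  expect_equal(summ$duration_median_frames[1], 3)
  expect_equal(summ$duration_median_ms[1], 120)
  expect_true(is.na(summ$duration_median_frames[2]))
  # all events start after frame 1 -> TC evaluable for all
  expect_equal(summ$n_tc_evaluable[1], 9L)
  # an event with most voxels in muscle 1 is assigned to muscle 1
  rel2 <- array(1, dim = c(8, 8, 10, 2))
  rel2[2:5, 4:7, 3, 1] <- 0.2  # 16 voxels: 8 in m1, 4 in m2, 4 unlabelled
  norm2 <- structure(list(rel = rel2, label_map = label_map),
                     class = "normalized_series")
  set2 <- link_events(detect_voids(norm2, 0.3, 1), trf = 40)
  expect_identical(set2$smams[[1]]$dominant_muscle, "1")
  # onset x duration histogram sums to 100 and sits at the right cell
  h <- onset_duration_histogram(set)
  expect_equal(sum(h), 100)
  expect_gt(h["2", "3"], 0)
})

test_that("end-to-end: rendered M-class events are recovered exactly", {
  scene <- build_leg_scene()
  sch <- setting_schedule("II")
  fp <- muscle_footprint(scene, "soleus", n_vox = 12, amplitude_um = 150)
  m3 <- displacement_event(onset = 200, t_contract = 100, t_relax = 150, fp)
  m1 <- displacement_event(onset = -50, t_contract = 40, t_relax = 100,
                           muscle_footprint(scene, "gastrocnemius_medialis",
                                            n_vox = 10, amplitude_um = 150))
  mv <- displacement_event(onset = 10, t_contract = 50, t_relax = 60,
                           muscle_footprint(scene, "tibialis_anterior",
                                            n_vox = 10, amplitude_um = 150))
  # events recur in 2 of 6 repetitions so the median reference stays clean
  reps <- lapply(1:2, function(r) {
    lapply(list(m3, m1, mv), function(e) { e$repetition <- r; e })
  })
  evs_all <- manual_events(do.call(c, reps), scene, 6)
  ser <- render_dwi_series(scene, sch, evs_all)
  res <- analyze_series(ser)
  tab <- res$events
  # M_V: never detected
  expect_false(any(tab$dominant_muscle ==
                     scene$label_names[["tibialis_anterior"]]))
  # M_I: all 10 frames, category start1_end_last, not TC-evaluable
  mi_rows <- tab[tab$dominant_muscle ==
                   as.character(scene$label_names[["gastrocnemius_medialis"]]), ]
  expect_equal(nrow(mi_rows), 2)
  expect_true(all(mi_rows$category == "start1_end_last"))
  expect_true(all(mi_rows$duration_frames == 10))
  expect_true(all(!mi_rows$tc_evaluable))
  # M_III: detected frames match the analytic envelope prediction exactly
  pred <- predict_visibility(m3, sch, 0.3, 2)
  m3_rows <- tab[tab$dominant_muscle ==
                   as.character(scene$label_names[["soleus"]]), ]
  expect_equal(nrow(m3_rows), 2)
  expect_true(all(m3_rows$first_frame == pred$first))
  expect_true(all(m3_rows$last_frame == pred$last))
  expect_true(all(m3_rows$peak_frame == pred$peak))
  expect_true(all(m3_rows$category == "contained"))
})
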