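test_that("phantom scene has the published tube layout", {
  scene <- build_phantom_scene()
  expect_length(unique(as.integer(scene$label_map)), 7)  # bg + 2 intra + 4 inter
  inter <- grep("^inter", names(scene$label_names), value = TRUE)
  t1s <- sort(vapply(inter, function(nm) {
    unique(scene$t1[scene$label_map == scene$label_names[[nm]]])
  }, numeric(1)))
  expect_equal(unname(t1s), c(800, 1000, 1300, 1600))
  # empty config: background only
  empty <- build_phantom_scene(list())
  expect_true(all(empty$label_map == 0L))
  # overlapping tubes rejected
  cfg <- phantom_config()
  cfg$inter_tubes[[2]]$center <- cfg$inter_tubes[[1]]$center
  expect_error(build_phantom_scene(cfg), "overlap")
})

test_that("leg scene geometry matches the acquisition settings", {
  scene <- build_leg_scene()
  expect_equal(scene$dim, c(64L, 64L))
  expect_equal(scene$pixel_mm, 3)
  expect_gte(length(scene$label_names), 4)
  areas <- vapply(scene$label_names, function(l) sum(scene$label_map == l),
                  integer(1))
  expect_true(all(areas > 0))
  expect_true(all(c("soleus", "gastrocnemius_medialis") %in%
                    names(scene$label_names)))
  # deterministic
  expect_identical(build_leg_scene()$label_map, scene$label_map)
})

test_that("bead trajectory arithmetic and triggers", {
  pos <- bead_trajectory(20, 0, duration = 200, trigger_delay = 0)
  expect_equal(pos(200), 4)  # 20 mm/s over 200 ms
  expect_equal(pos(0), 0)
  still <- bead_trajectory(0, 5, duration = 500, trigger_delay = 0)
  expect_equal(still(c(0, 250, 500)), rep(5, 3))
  late <- bead_trajectory(20, 0, duration = 200, trigger_delay = 300)
  expect_equal(late(1000), 0)
})

test_that("turbulence void area is zero before the trigger and grows with the sweep", {
  scene <- build_phantom_scene()
  sch <- setting_schedule("phantom")  # Delta = 156, 356, ..., 956
  traj <- bead_trajectory(20, 0, duration = sch$delta_ms[5],
                          trigger_delay = sch$delta_ms[1] + 1)
  evs <- turbulence_events_from_trajectory(traj, scene)
  expect_gt(length(evs$events), 0)
  ser <- render_dwi_series(scene, sch, evs)
  plain <- render_dwi_series(scene, sch)
  area <- vapply(1:5, function(n)
    sum(ser$noiseless[, , n, 1] < 0.5 * plain$noiseless[, , n, 1]), integer(1))
  expect_identical(area[1], 0L)            # synchronized start after cycle 1
  expect_true(all(diff(area) >= 0))        # void grows with the sweep
  expect_gt(area[5], area[2])
  # oracle: swept segment geometry, one tube column per pixel crossed.
  # A column counts once its 150 ms rise has reached the 50% drop level:
  # exp(-phi^2/2) < 0.5 at phi = gamma G delta (150 um) e(t).
  onsets <- vapply(evs$events, function(e) e$onset, numeric(1))
  f_thr <- sqrt(2 * log(2)) /
    phase_for_displacement(attr(sch, "g_d_mt_m"), 5, 150)
  expected_area <- vapply(sch$delta_ms, function(d) {
    5L * sum(onsets <= d - 150 * f_thr)  # tube cross-section is 5 voxels high
  }, integer(1))
  expect_equal(area, expected_area)
  # stationary bead: no events
  expect_length(turbulence_events_from_trajectory(
    bead_trajectory(0, 0, 500, 0), scene)$events, 0)
  # trajectory past the tube end is clipped with a warning
  fast <- bead_trajectory(500, 0, duration = 1000, trigger_delay = 0)
  expect_warning(turbulence_events_from_trajectory(fast, scene), "clip")
})

test_that("event sampling is seeded, rate-driven and produces valid events", {
  scene <- build_leg_scene()
  sch <- setting_schedule("II")
  none <- sample_events(scene, c(soleus = 0), 10, seed = 1, schedule = sch)
  expect_length(none$events, 0)
  expect_equal(nrow(events_table(none)), 0)
  a <- sample_events(scene, c(soleus = 1, tibialis_anterior = 0.5), 20,
                     seed = 9, schedule = sch)
  b <- sample_events(scene, c(soleus = 1, tibialis_anterior = 0.5), 20,
                     seed = 9, schedule = sch)
  expect_identical(events_table(a, sch), events_table(b, sch))
  tab <- events_table(a, sch)
  expect_true(all(tab$t_contract_ms >= 40 & tab$t_contract_ms <= 160))
  expect_true(all(tab$t_relax_ms >= 80 & tab$t_relax_ms <= 300))
  expect_true(all(tab$latent_class %in% paste0("M_", c("I", "II", "III",
                                                       "IV", "V"))))
  expect_error(sample_events(scene, c(biceps = 1), 5, schedule = sch),
               "unknown")
  expect_error(sample_events(scene, c(soleus = 1), 5, schedule = sch,
                             t_contract_range = c(-5, 10)), "range")
})

test_that("motion classes partition onset/end space and match definitions", {
  sch <- setting_schedule("II")  # Delta_1 = 156, Delta_10 = 516
  fp <- data.frame(row = 1, col = 1, amplitude_um = 100)
  cls <- function(onset, len) {
    classify_motion_class(
      displacement_event(onset, len / 2, len / 2, fp), sch)
  }
  expect_identical(cls(-50, 150), "M_I")    # ends at 100 < Delta_1
  expect_identical(cls(10, 110), "M_V")     # ends at 120, inside mixing
  expect_identical(cls(200, 200), "M_III")  # 200..400 inside the cycles
  expect_identical(cls(100, 200), "M_II")   # spans Delta_1
  expect_identical(cls(300, 400), "M_IV")   # outlasts Delta_10
  expect_identical(cls(600, 100), "M_V")    # after the last image
  # grid sweep: every combination receives exactly one class
  for (onset in seq(-300, 600, by = 30))
    for (len in c(20, 100, 250, 500, 900))
      expect_length(cls(onset, len), 1)
  # half-open tie-break: onset exactly 0 counts as after dephasing
  expect_identical(cls(0, 150), "M_V")
  expect_identical(cls(0, 156), "M_V")
})

test_that("sampled class frequencies match interval-geometry probabilities", {
  scene <- build_leg_scene()
  sch <- setting_schedule("II")
  d1 <- 156; dN <- 516
  len <- 120 + 180  # degenerate duration: t_contract = 120, t_relax = 180
  w <- c(-500, 900)
  evs <- sample_events(scene, c(soleus = 1), repetitions = 10000, seed = 13,
                       schedule = sch, window = w,
                       t_contract_range = c(120, 120),
                       t_relax_range = c(180, 180))
  tab <- events_table(evs, sch)
  # closed-form interval geometry for fixed event length
  width <- diff(w)
  p <- c(M_I = (min(0, d1 - len) - max(w[1], -len)) / width,
         M_II = (min(d1, dN - len) - (d1 - len)) / width,
         M_III = (dN - len - d1) / width,
         M_IV = (min(w[2], dN) - (dN - len)) / width)
  p["M_V"] <- 1 - sum(p)
  n <- nrow(tab)
  for (k in names(p)) {
    phat <- mean(tab$latent_class == k)
    se <- sqrt(p[[k]] * (1 - p[[k]]) / n)
    expect_lt(abs(phat - p[[k]]), 3 * se + 1e-9)
  }
})
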