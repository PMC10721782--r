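# Generator contracts: determinism, truth sidecars, and parameter recovery.

test_that("all generators are pure functions of (parameters, seed)", {
  v1 <- gen_vessel_image(80, 7, 20, 100, 10, 0.8, seed = 5)
  v2 <- gen_vessel_image(80, 7, 20, 100, 10, 0.8, seed = 5)
  expect_identical(v1$image$pixels, v2$image$pixels)

  labs <- gen_label_volume(c(24L, 24L, 24L),
                           list(list(label = 1L, acronym = "ROI", type = "box",
                                     min = c(2, 2, 2), max = c(21, 21, 21))))
  p1 <- gen_plaque_volume(labs, 0.02, seed = 8)
  p2 <- gen_plaque_volume(labs, 0.02, seed = 8)
  expect_identical(p1$volume$voxels, p2$volume$voxels)

  t1 <- gen_trajectory(seed = 3); t2 <- gen_trajectory(seed = 3)
  expect_identical(t1$trajectory$samples, t2$trajectory$samples)

  e1 <- gen_exploration(0.7, seed = 4); e2 <- gen_exploration(0.7, seed = 4)
  expect_identical(e1$record$t_novel_s, e2$record$t_novel_s)

  th1 <- gen_temperature_trace(rise_C = 1, seed = 6)
  th2 <- gen_temperature_trace(rise_C = 1, seed = 6)
  expect_identical(th1$trace$samples, th2$trace$samples)

  s1 <- gen_group_study(n_control = 2, n_treated = 2, seed = 9)
  s2 <- gen_group_study(n_control = 2, n_treated = 2, seed = 9)
  expect_identical(s1$animals[[1]]$volume$voxels,
                   s2$animals[[1]]$volume$voxels)
  expect_identical(s1$truth$params$drawn_fractions,
                   s2$truth$params$drawn_fractions)
})

test_that("noiseless vessel rasterization binarizes to the ideal mask", {
  g <- gen_vessel_image(100, 7, 0, 100, 0, 0, seed = 1)
  mask <- binarize(g$image, 50)
  # exactly 7 rows wide wherever the tube crosses a column
  widths <- colSums(mask$mask)
  expect_true(all(widths[widths > 0] == 7))
  expect_error(gen_vessel_image(100, 2.5), "3 px")
})

test_that("truth sidecars serialize and record generating parameters", {
  g <- gen_vessel_image(60, 7, 0, seed = 2)
  expect_s3_class(g$truth, "synthetic_truth")
  expect_equal(g$truth$params$mean_diameter_px, 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$params$mean_diameter_px, 7)
  expect_equal(back$seed, 2)
})

test_that("label volume generator enforces disjoint regions", {
  lv <- gen_label_volume(c(10L, 10L, 10L), list(
    list(label = 1L, acronym = "A", type = "box",
         min = c(0, 0, 0), max = c(4, 9, 9)),
    list(label = 2L, acronym = "B", type = "sphere",
         center = c(7, 5, 5), radius = 2)))
  expect_identical(sum(lv$labels == 1L), 5L * 10L * 10L)
  expect_gt(sum(lv$labels == 2L), 0L)
  expect_error(gen_label_volume(c(10L, 10L, 10L), list(
    list(label = 1L, acronym = "A", type = "box",
         min = c(0, 0, 0), max = c(5, 5, 5)),
    list(label = 2L, acronym = "B", type = "box",
         min = c(3, 3, 3), max = c(7, 7, 7)))), "overlap")
  empty <- gen_label_volume(c(4L, 4L, 4L))
  expect_true(all(empty$labels == 0L))
})

test_that("plaque placement hits the target fraction within one sphere", {
  labs <- gen_label_volume(c(32L, 36L, 36L),
                           list(list(label = 1L, acronym = "ROI", type = "box",
                                     min = c(2, 2, 2), max = c(29, 33, 33))))
  max_sphere <- sum(rowSums(expand.grid(-4:4, -4:4, -4:4)^2) <= 16)
  for (target in c(0.005, 0.02, 0.05)) {
    gp <- gen_plaque_volume(labs, target, plaque_radius_vox_range = c(2, 4),
                            seed = round(1000 * target))
    realized <- gp$truth$params$regions$ROI$realized_fraction
    nvox <- sum(labs$labels == 1L)
    expect_lt(abs(realized - target) * nvox, max_sphere)
  }
  # target 0: pure noise, nothing detectable above the robust background
  gp0 <- gen_plaque_volume(labs, 0, seed = 3)
  expect_equal(gp0$truth$params$regions$ROI$realized_fraction, 0)
  ps <- detect_plaques(gp0$volume, "background", min_voxels = 2)
  expect_identical(nrow(ps), 0L)
})

test_that("null-effect studies recover a reduction near zero", {
  reds <- vapply(1:12, function(r) {
    st <- gen_group_study(effect_fraction = 0, between_animal_cv = 0.15,
                          n_control = 4, n_treated = 4, seed = 400 + r)
    quantify_study(st)$reduction$reduction_pct
  }, 0)
  # bias well under cv/sqrt(n) in percentage points
  expect_lt(abs(mean(reds)), 100 * 0.15 / sqrt(4))
  expect_error(gen_group_study(effect_fraction = 1.2), "effect_fraction")
})

test_that("goal-directed swims reach the platform in about the direct time", {
  g <- gen_trajectory(goal_bias = 1, heading_persistence = 0.95, seed = 21)
  expect_false(g$truth$params$capped)
  start <- g$truth$params$start
  direct <- (sqrt(sum((g$trajectory$platform$center - start)^2)) -
             g$trajectory$platform$radius) / 18
  el <- escape_latency(g$trajectory)$latency_s
  expect_lt(abs(el - direct) / direct, 0.2)
  expect_equal(el, g$truth$params$entry_time_s)
})

test_that("undirected swims mostly run into the trial cap", {
  lat <- vapply(1:20, function(s) {
    g <- gen_trajectory(goal_bias = 0, heading_persistence = 0.5,
                        platform = list(center = c(30, 0), radius = 3),
                        trial_cap_s = 60, seed = s)
    escape_latency(g$trajectory, 60)$latency_s
  }, 0)
  expect_gte(stats::median(lat), 60)
})

test_that("exploration draws center on the preference", {
  ris <- vapply(1:300, function(s)
    recognition_index(gen_exploration(0.5, seed = s)$record), 0)
  expect_lt(abs(mean(ris) - 0.5), 0.02)
  expect_equal(recognition_index(gen_exploration(1, seed = 1)$record), 1)
  # recovery within the Beta SD
  pref <- 0.7; conc <- 20
  beta_sd <- sqrt(pref * (1 - pref) / (conc + 1))
  ris7 <- vapply(1:200, function(s)
    recognition_index(gen_exploration(pref, seed = 1000 + s)$record), 0)
  expect_lt(abs(mean(ris7) - pref), beta_sd)
})

test_that("temperature plateau reaches the programmed rise", {
  g <- gen_temperature_trace(rise_C = 1.52, time_constant_s = 30,
                             noise_sd = 0, seed = 1)
  expect_equal(max_temperature_rise(g$trace)$rise_C, 1.52, tolerance = 0.01)
  # null rise: the mean over irradiation is ~0 within sampling error; the
  # max over thousands of noisy samples stays within a few noise SDs
  g0 <- gen_temperature_trace(rise_C = 0, noise_sd = 0.02, seed = 2)
  expect_lt(abs(mean_temperature_rise(g0$trace)$rise_C), 3 * 0.02 / sqrt(120))
  expect_lt(abs(max_temperature_rise(g0$trace)$rise_C), 5 * 0.02)
})
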