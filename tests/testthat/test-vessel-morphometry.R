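# Otsu thresholding, mask cleanup, centerline extraction, tangents and
# perpendicular-chord diameters.

test_that("Otsu threshold matches the exhaustive raw-value oracle", {
  withr::local_seed(41)
  for (i in 1:25) {
    img <- random_8bit(24, p_fg = runif(1, 0.1, 0.9),
                       mu = sort(runif(2, 10, 245)), sd = runif(1, 5, 60))
    expect_equal(compute_otsu_threshold(img), oracle_otsu_integer(img),
                 info = paste("random image", i))
  }
})

test_that("Otsu plateau tie-break returns the midpoint", {
  img <- matrix(c(rep(0, 50), rep(255, 50)), 10)
  expect_equal(compute_otsu_threshold(img), 127)
  expect_error(compute_otsu_threshold(matrix(5, 4, 4)), "no threshold")
})

test_that("binarization takes strictly-greater as foreground", {
  img <- vessel_image(matrix(c(1, 2, 3, 4), 2), 1)
  mk <- binarize(img, 2)
  expect_identical(as.vector(mk$mask), c(0L, 0L, 1L, 1L))
})

test_that("mask cleanup removes speckles, fills holes, keeps clean shapes", {
  # 3-px speckle below the size threshold disappears
  m <- matrix(0L, 20, 20); m[5, 5:7] <- 1L
  expect_equal(sum(clean_mask(binary_mask(m), min_object_px = 10,
                              closing_radius_px = 0)$mask), 0)

  # a solid rectangle is untouched (idempotence on clean input)
  m <- matrix(0L, 20, 60); m[7:13, 5:54] <- 1L
  cleaned <- clean_mask(binary_mask(m), min_object_px = 10,
                        closing_radius_px = 1)
  expect_identical(cleaned$mask, m)

  # a 1-px interior hole is filled
  mh <- m; mh[10, 30] <- 0L
  expect_identical(clean_mask(binary_mask(mh), 10, 1)$mask, m)
})

test_that("rectangle skeleton is one branch retracted about width/2 per end", {
  m <- matrix(0L, 30, 120); m[11:19, 11:110] <- 1L   # 100 x 9 rectangle
  cl <- extract_centerline(binary_mask(m), prune_px = 5)
  expect_length(cl$branches, 1L)
  # thinning retracts ~width/2 from each end (~91 px); the end-point
  # smoothing of the chain shaves about another pixel
  len <- max(cl$branches[[1]]$arclength)
  expect_gte(len, 88); expect_lte(len, 94)
  # path runs along the row center
  expect_true(all(abs(cl$branches[[1]]$points[, 1] - 14) <= 1))
})

test_that("Y-shaped mask decomposes into three branches at one junction", {
  m2 <- matrix(0L, 100, 100)
  m2[48:54, 10:50] <- 1L                     # horizontal arm into center
  for (i in 0:40) {                          # two diagonal arms
    m2[51 - i + (-3:3), 50 + i] <- 1L
    m2[51 + i + (-3:3), 50 + i] <- 1L
  }
  cl <- extract_centerline(binary_mask(m2), prune_px = 6)
  expect_length(cl$branches, 3L)
  expect_false(is.null(cl$junctions))
})

test_that("degenerate masks are rejected", {
  expect_error(extract_centerline(binary_mask(matrix(0L, 5, 5))), "empty")
  tiny <- matrix(0L, 5, 5); tiny[3, 3] <- 1L
  expect_error(extract_centerline(binary_mask(tiny)), "too small")
})

test_that("tangents are exact on straight branches and circles", {
  # horizontal
  pts <- cbind(rep(10, 50), seq(0, 49))
  cl <- estimate_tangents(centerline(list(pts)), window_px = 5)
  tg <- cl$branches[[1]]$tangents
  expect_true(all(abs(tg[, 1]) < 1e-6))
  expect_true(all(abs(abs(tg[, 2]) - 1) < 1e-6))

  # 45 degrees
  pts45 <- cbind(seq(0, 49), seq(0, 49))
  tg45 <- estimate_tangents(centerline(list(pts45)), 5)$branches[[1]]$tangents
  ang <- atan2(tg45[, 1], tg45[, 2]) * 180 / pi
  expect_true(all(abs(ang - 45) < 1))

  # quarter circle radius 50: tangent perpendicular to the radius
  th <- seq(0, pi / 2, length.out = 80)
  ptsc <- cbind(50 * sin(th), 50 * cos(th))
  clc <- estimate_tangents(centerline(list(ptsc)), 5)
  tgc <- clc$branches[[1]]$tangents
  for (i in seq(5, 75, by = 10)) {
    radial <- ptsc[i, ] / sqrt(sum(ptsc[i, ]^2))
    # |tangent . radial| = sin(angular error); must stay within 2 degrees
    expect_lt(abs(sum(tgc[i, ] * radial)), sin(2 * pi / 180))
  }
})

test_that("chord measurement recovers an ideal rectangle's height", {
  m <- matrix(0L, 21, 60); m[8:14, 6:55] <- 1L   # height 7
  res <- measure_diameter_at(binary_mask(m), point = c(10, 30),
                             normal = c(1, 0), max_len_px = 30)
  expect_equal(res$diameter_px, 7, tolerance = 0.2 / 7)
  expect_error(measure_diameter_at(binary_mask(m), c(2, 2), c(1, 0), 30),
               "off-vessel")
})

test_that("chord measurement is stable under rotation of the rectangle", {
  g <- gen_vessel_image(length_px = 60, diameter_profile_px = 7,
                        orientation_deg = 30, contrast = 1, noise_sigma = 0,
                        psf_sigma_px = 0, seed = 1)
  m <- binarize(g$image, 0.5)
  c0 <- floor((nrow(m$mask) - 1) / 2)
  th <- 30 * pi / 180
  u <- c(sin(th), cos(th))
  # single chords carry raster phase noise; the mean over axial positions
  # must sit on the true width
  ds <- vapply(seq(-10, 10, by = 2), function(a) {
    measure_diameter_at(m, c(c0, c0) + a * u,
                        normal = c(cos(th), -sin(th)),
                        max_len_px = 30)$diameter_px
  }, 0)
  expect_equal(mean(ds), 7, tolerance = 0.5 / 7)
  expect_true(all(abs(ds - 7) < 1))
})

test_that("diameter profile recovers constant and tapering widths", {
  cfg <- default_config()
  g <- gen_vessel_image(150, 7, 0, 100, 0, 0, spacing_um = 2, seed = 1)
  res <- measure_vessels(g$image, cfg)
  expect_true(all(abs(res$profile$diameter_um - 14) <= 0.4))

  # tapering tube at an oblique angle (axis-aligned tubes quantize the
  # mask-based chord to odd pixel counts); linearity is asserted on 10-px
  # arclength bin means, which average out raster phase noise
  taper <- function(s) 4 + (10 - 4) * s / 200
  gt <- gen_vessel_image(200, taper, 25, 100, 0, 0.8, spacing_um = 1, seed = 1)
  prof <- as.data.frame(measure_vessels(gt$image, cfg)$profile)
  bin <- floor(prof$arclength_um / 10)
  bm <- stats::aggregate(cbind(arclength_um, diameter_um) ~ bin, prof, mean)
  fit <- stats::lm(diameter_um ~ arclength_um, data = bm)
  expect_lt(max(abs(stats::residuals(fit))), 0.5)
  expect_equal(unname(stats::coef(fit)[2]), 6 / 200, tolerance = 0.05)
})

test_that("tubes shorter than twice the exclusion zone are unmeasurable", {
  m <- matrix(0L, 15, 15); m[6:9, 4:11] <- 1L
  cl <- extract_centerline(binary_mask(m), prune_px = 2)
  expect_error(
    diameter_profile(binary_mask(m), cl, junction_exclusion_px = 10),
    "no measurable")
})

test_that("diameter summary reports pooled and per-branch statistics", {
  prof <- structure(
    data.frame(branch_id = c(1, 1, 2), arclength_um = c(0, 1, 0),
               diameter_um = c(8, 12, 10), x0 = 0, y0 = 0, x1 = 0, y1 = 0),
    class = c("diameter_profile", "data.frame"))
  s <- summarize_diameters(prof)
  expect_equal(s$mean_um, 10)
  expect_equal(s$median_um, 10)
  expect_equal(s$n, sum(s$hist_counts))
  expect_equal(s$per_branch$mean_diameter_um, c(10, 10))
  expect_error(summarize_diameters(prof[0, ]), "empty")
})

test_that("doubling the pixel spacing doubles micron diameters exactly", {
  g <- gen_vessel_image(100, 9, 15, 100, 0, 0.8, seed = 5)
  mask <- clean_mask(binarize(g$image, compute_otsu_threshold(g$image)),
                     64, 2)
  cl <- estimate_tangents(extract_centerline(mask, 5), 5)
  p1 <- diameter_profile(mask, cl, spacing_um = 1)
  p2 <- diameter_profile(mask, cl, spacing_um = 2)
  expect_equal(p2$diameter_um, 2 * p1$diameter_um, tolerance = 1e-12)
})

test_that("dilating the mask never decreases a measured diameter", {
  g <- gen_vessel_image(100, 8, 20, 100, 0, 0.8, seed = 6)
  mask <- clean_mask(binarize(g$image, compute_otsu_threshold(g$image)), 64, 2)
  cl <- estimate_tangents(extract_centerline(mask, 5), 5)
  p1 <- diameter_profile(mask, cl, spacing_um = 1)
  dil <- EBImage::dilate(mask$mask, EBImage::makeBrush(3, "box"))
  dil <- binary_mask(matrix(as.integer(dil != 0), nrow(dil)), 1)
  p2 <- diameter_profile(dil, cl, spacing_um = 1)
  shared <- intersect(
    paste(p1$branch_id, round(p1$arclength_um, 6)),
    paste(p2$branch_id, round(p2$arclength_um, 6)))
  k1 <- match(shared, paste(p1$branch_id, round(p1$arclength_um, 6)))
  k2 <- match(shared, paste(p2$branch_id, round(p2$arclength_um, 6)))
  expect_true(all(p2$diameter_um[k2] >= p1$diameter_um[k1] - 1e-9))
})

test_that("pipeline recovers true tube diameters under noise and rotation", {
  # spot checks at desk scale; the full recovery grid runs in the
  # acceptance suite
  for (case in list(c(5, 0), c(10, 30), c(20, 45))) {
    g <- gen_vessel_image(length_px = 120, diameter_profile_px = case[1],
                          orientation_deg = case[2], contrast = 100,
                          noise_sigma = 10, psf_sigma_px = 0.8,
                          seed = 100 + case[1] + case[2])
    res <- measure_vessels(g$image)
    expect_lt(abs(res$summary$mean_um - case[1]) / case[1], 0.05,
              label = sprintf("width %g at %g deg rel err", case[1], case[2]))
  }
})
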