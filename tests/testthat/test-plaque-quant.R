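# 3D plaque detection, region assignment, densities and reduction rates.

make_blob_volume <- function() {
  vox <- array(0, c(12, 16, 16))
  vox[5:6, 5:6, 5] <- 100; vox[5, 5, 6] <- 100   # one 5-voxel blob
  brain_volume(vox + 0.01, c(1, 1, 1))           # avoid constant-image Otsu
}

test_that("detection finds a bright blob and honors the size filter", {
  vol <- make_blob_volume()
  ps <- detect_plaques(vol, "fixed", fixed_threshold = 50, min_voxels = 2)
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$voxel_count, 5L)
  expect_equal(ps$volume_um3, 5)
  ps6 <- detect_plaques(vol, "fixed", fixed_threshold = 50, min_voxels = 6)
  expect_identical(nrow(ps6), 0L)
  expect_error(detect_plaques(brain_volume(array(1, c(4, 4, 4)), c(1, 1, 1)),
                              "otsu"), "no threshold")
})

test_that("detection equals the brute-force flood-fill oracle", {
  withr::local_seed(7)
  for (i in 1:6) {
    vox <- array(rnorm(24^3, 0, 1), c(24, 24, 24))
    nb <- sample(3:8, 1)
    for (b in seq_len(nb)) {
      c0 <- sample(3:21, 3)
      vox[c0[1] + (-1:1), c0[2] + (-1:1), c0[3] + (-1:1)] <- 12
    }
    vol <- brain_volume(vox, c(1, 1, 1))
    ps <- detect_plaques(vol, "fixed", fixed_threshold = 6, min_voxels = 1)
    oracle <- oracle_flood_fill(vox > 6)
    expect_identical(nrow(ps), oracle$count)
    expect_identical(sort(ps$voxel_count, decreasing = TRUE), oracle$sizes)
  }
})

test_that("2D components also match the flood-fill oracle", {
  withr::local_seed(11)
  for (i in 1:5) {
    m <- matrix(as.integer(runif(40 * 40) < 0.35), 40)
    lab <- label_components(m)
    oracle <- oracle_flood_fill(m)
    expect_identical(max(lab), oracle$count)
    expect_identical(sort(component_sizes(lab), decreasing = TRUE),
                     oracle$sizes)
  }
})

test_that("synthetic sphere fields are detected with centroid accuracy", {
  labs <- gen_label_volume(c(48L, 48L, 48L),
                           list(list(label = 1L, acronym = "ROI", type = "box",
                                     min = c(2, 2, 2), max = c(45, 45, 45))))
  gp <- gen_plaque_volume(labs, c(ROI = 0.02), plaque_radius_vox_range = c(3, 3),
                          snr = 10, seed = 21)
  truth <- gp$truth$params$regions$ROI
  ps <- detect_plaques(gp$volume, "background", min_voxels = 5)
  expect_identical(nrow(ps), truth$n_spheres)
  # each true center has a detected centroid within 1 voxel
  for (i in seq_len(truth$n_spheres)) {
    d <- sqrt((ps$z - truth$centers[i, 1])^2 +
              (ps$y - truth$centers[i, 2])^2 +
              (ps$x - truth$centers[i, 3])^2)
    expect_lt(min(d), 1)
  }
})

test_that("region assignment uses the rounded-centroid voxel", {
  labs <- gen_label_volume(c(12L, 16L, 16L),
                           list(list(label = 3L, acronym = "CA1", type = "box",
                                     min = c(4, 8, 2), max = c(8, 14, 8))))
  vol <- make_blob_volume()
  ps <- detect_plaques(vol, "fixed", 50, min_voxels = 2)
  # blob centroid is near (5.2, 5.2, 5.2): outside CA1 -> background
  ps1 <- assign_regions(ps, labs)
  expect_identical(ps1$region, 0L)
  # move the region to cover the blob
  labs2 <- gen_label_volume(c(12L, 16L, 16L),
                            list(list(label = 3L, acronym = "CA1", type = "box",
                                      min = c(4, 4, 4), max = c(8, 8, 8))))
  expect_identical(assign_regions(ps, labs2)$region, 3L)
  # shape mismatch
  labs3 <- gen_label_volume(c(10L, 16L, 16L), list())
  expect_error(assign_regions(ps, labs3), "shape")
})

test_that("region density arithmetic and zero-plaque regions", {
  labs <- gen_label_volume(c(20L, 20L, 20L), list(
    list(label = 1L, acronym = "A", type = "box",
         min = c(0, 0, 0), max = c(9, 19, 19)),
    list(label = 2L, acronym = "B", type = "box",
         min = c(10, 0, 0), max = c(19, 19, 19))))
  vox <- array(0, c(20, 20, 20)); vox[5, 5, 5] <- 50; vox[5, 5, 6] <- 50
  vox[1, 1, 1] <- 0.01
  vol <- brain_volume(vox, c(5, 5, 5))   # voxel volume 125 um3
  ps <- assign_regions(detect_plaques(vol, "fixed", 10, min_voxels = 1), labs)
  rd <- region_density(ps, labs)
  expect_equal(rd$plaque_count, c(1L, 0L))
  expect_equal(rd$region_volume_um3, rep(4000 * 125, 2))
  expect_equal(rd$volume_fraction, c(250 / 5e5, 0))
  expect_equal(rd$count_density_per_mm3, c(1 / 5e-4, 0))
})

test_that("volume fraction recovery on a generated region", {
  labs <- gen_label_volume(c(40L, 44L, 44L),
                           list(list(label = 1L, acronym = "ROI", type = "box",
                                     min = c(3, 3, 3), max = c(36, 40, 40))))
  gp <- gen_plaque_volume(labs, c(ROI = 0.02), plaque_radius_vox_range = c(2, 4),
                          snr = 10, seed = 33)
  realized <- gp$truth$params$regions$ROI$realized_fraction
  ps <- assign_regions(detect_plaques(gp$volume, "background", min_voxels = 5),
                       labs)
  rd <- region_density(ps, labs)
  expect_equal(rd$volume_fraction, realized, tolerance = 0.1)
})

test_that("merging regions pools counts and volumes, not densities", {
  tab <- structure(data.frame(
    label = c(1L, 2L), acronym = c("A", "B"), plaque_count = c(2L, 3L),
    total_plaque_volume_um3 = c(100, 300),
    region_volume_um3 = c(1e9, 1e9),          # 1 mm3 each
    count_density_per_mm3 = c(2, 3), volume_fraction = c(1e-7, 3e-7)),
    class = c("region_density_table", "data.frame"))
  mg <- merge_region_groups(tab, list(AB = c("A", "B")))
  expect_equal(mg$plaque_count, 5L)
  expect_equal(mg$count_density_per_mm3, 2.5)
  expect_equal(mg$volume_fraction, 2e-7)
  # identity on a single member
  one <- merge_region_groups(tab, list(A = "A"))
  expect_equal(one$count_density_per_mm3, tab$count_density_per_mm3[1])
  expect_error(merge_region_groups(tab, list(X = c("A", "Z"))), "unknown")
})

test_that("merged-region density equals pooling directly from member voxels", {
  labs <- gen_label_volume(c(24L, 24L, 24L), list(
    list(label = 1L, acronym = "A", type = "box",
         min = c(2, 2, 2), max = c(11, 21, 21)),
    list(label = 2L, acronym = "B", type = "box",
         min = c(12, 2, 2), max = c(21, 21, 21))))
  gp <- gen_plaque_volume(labs, c(A = 0.03, B = 0.01),
                          plaque_radius_vox_range = c(2, 3), snr = 10, seed = 5)
  ps <- assign_regions(detect_plaques(gp$volume, "background", min_voxels = 5),
                       labs)
  merged <- merge_region_groups(region_density(ps, labs), list(AB = c("A", "B")))
  # pooled computation from a label volume where A and B share one label
  pooled_labels <- label_volume(
    array(ifelse(labs$labels > 0L, 9L, 0L), dim(labs$labels)), c(AB = 9))
  ps2 <- assign_regions(ps, pooled_labels)
  direct <- region_density(ps2, pooled_labels)
  expect_equal(merged$volume_fraction, direct$volume_fraction)
  expect_equal(merged$count_density_per_mm3, direct$count_density_per_mm3)
})

test_that("raising a fixed threshold never increases count or volume", {
  withr::local_seed(9)
  vox <- array(rnorm(20^3, 5, 3), c(20, 20, 20))
  vol <- brain_volume(vox - min(vox) + 0.1, c(1, 1, 1))
  prev_n <- Inf; prev_v <- Inf
  for (thr in c(6, 8, 10, 12)) {
    ps <- detect_plaques(vol, "fixed", fixed_threshold = thr, min_voxels = 1)
    expect_lte(nrow(ps), prev_n)
    expect_lte(sum(ps$volume_um3), prev_v)
    prev_n <- nrow(ps); prev_v <- sum(ps$volume_um3)
  }
})

test_that("reduction rate follows the group-means formula", {
  r <- reduction_rate(1.0, 0.61)
  expect_equal(r$reduction_pct, 39)
  expect_true(is.na(r$p))                       # n = 1: no test possible
  expect_equal(reduction_rate(c(2, 2), c(2, 2))$reduction_pct, 0)
  expect_equal(reduction_rate(c(1, 2), c(0, 0))$reduction_pct, 100)
  expect_error(reduction_rate(c(0, 0), c(1, 1)), "undefined")
  rr <- reduction_rate(c(10, 11, 9, 10.5, 9.5), c(6, 6.5, 5.5, 6.2, 5.8))
  expect_equal(rr$reduction_pct,
               100 * (1 - mean(c(6, 6.5, 5.5, 6.2, 5.8)) / mean(c(10, 11, 9, 10.5, 9.5))))
  expect_false(is.na(rr$p))
  expect_identical(rr$stars, star_flags(rr$p))
})
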