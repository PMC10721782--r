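# Synthetic microscopy generators with known ground truth: tubular vessel
# images, atlas label volumes, spherical plaque fields, and two-group plaque
# studies with a specified reduction effect. Every generator is a pure
# function of (parameters, seed) and ships a synthetic_truth sidecar.

#' Ground-truth sidecar of a synthetic dataset
#'
#' @param generator Generator name.
#' @param seed RNG seed the dataset was generated from.
#' @param params Named list of generating parameters (including realized
#'   quantities where they differ from targets).
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(generator, seed, params) {
  structure(list(generator = generator, seed = seed, params = params),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s (seed %s)\n", x$generator, x$seed))
  utils::str(x$params, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Write a truth sidecar as JSON
#'
#' @param truth A [synthetic_truth()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(generator = truth$generator, seed = truth$seed,
                            params = truth$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a fluorescence image of a tubular vessel
#'
#' Rasterizes a straight tube of given width profile along a midline through
#' the image center at `orientation_deg`, convolves with a Gaussian PSF
#' (realized as the exact Gaussian-blurred edge profile), and adds Gaussian
#' noise. With `psf_sigma_px = 0` and `noise_sigma = 0` the image is the
#' ideal binary tube scaled by `contrast`.
#'
#' @param length_px Tube length along its axis.
#' @param diameter_profile_px Constant width in px, or a function of
#'   arclength (px) returning the local width; all widths >= 3 px (below
#'   that the tube is not measurable at pixel resolution).
#' @param orientation_deg Axis orientation, degrees counter-clockwise from
#'   the +x direction.
#' @param contrast Foreground intensity above the zero background.
#' @param noise_sigma Gaussian noise SD in intensity units.
#' @param psf_sigma_px Gaussian point-spread SD in pixels.
#' @param spacing_um Micrometres per pixel recorded on the image.
#' @param seed RNG seed; the same seed gives a bit-identical image.
#' @return List with `image` ([vessel_image()]) and `truth`
#'   ([synthetic_truth()]; `params$diameter_px` holds the width sampled at
#'   1-px arclength steps).
#' @export
gen_vessel_image <- function(length_px = 200, diameter_profile_px = 7,
                             orientation_deg = 0, contrast = 100,
                             noise_sigma = 0, psf_sigma_px = 0.8,
                             spacing_um = 1, seed = 1) {
  wfun <- if (is.function(diameter_profile_px)) {
    diameter_profile_px
  } else {
    force(diameter_profile_px)
    function(s) rep(diameter_profile_px, length(s))
  }
  s_grid <- seq(0, length_px, by = 1)
  w_grid <- wfun(s_grid)
  if (any(w_grid < 3))
    stop("diameter below 3 px is not measurable", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)

  margin <- ceiling(max(w_grid) / 2 + 4 * psf_sigma_px + 6)
  side <- as.integer(ceiling(length_px + 2 * margin))
  c0 <- floor((side - 1) / 2)          # integer center => exact rasters at 0 deg
  th <- orientation_deg * pi / 180
  u <- c(sin(th), cos(th))             # (dy, dx) along the axis
  nvec <- c(cos(th), -sin(th))         # perpendicular

  ys <- matrix(rep(0:(side - 1L), side), side, side)        # row = y
  xs <- t(ys)
  dy <- ys - c0; dx <- xs - c0
  a <- dy * u[1L] + dx * u[2L] + length_px / 2              # axial coord
  r <- abs(dy * nvec[1L] + dx * nvec[2L])                   # radial distance
  w_here <- matrix(wfun(pmin(pmax(a, 0), length_px)), side, side)

  if (psf_sigma_px > 0) {
    body <- stats::pnorm((w_here / 2 - r) / psf_sigma_px)
    ends <- stats::pnorm(a / psf_sigma_px) *
            stats::pnorm((length_px - a) / psf_sigma_px)
    img <- contrast * body * ends
  } else {
    img <- contrast * as.numeric(r <= w_here / 2 & a >= 0 & a <= length_px)
    img <- matrix(img, side, side)
  }
  if (noise_sigma > 0) {
    img <- img + withr::with_seed(seed, matrix(rnorm(side * side, 0, noise_sigma),
                                               side, side))
  }
  truth <- synthetic_truth("gen_vessel_image", seed, list(
    length_px = length_px, arclength_px = s_grid, diameter_px = w_grid,
    mean_diameter_px = mean(w_grid), mean_diameter_um = mean(w_grid) * spacing_um,
    orientation_deg = orientation_deg, contrast = contrast,
    noise_sigma = noise_sigma, psf_sigma_px = psf_sigma_px,
    spacing_um = spacing_um))
  list(image = vessel_image(img, spacing_um, name = "synthetic vessel"),
       truth = truth)
}

#' Build a synthetic atlas label volume
#'
#' Disjoint boxes and/or spheres of integer labels on a zero background,
#' standing in for registration-deformed atlas labels.
#'
#' @param shape Volume shape (z, y, x).
#' @param region_spec List of regions; each is a list with `label`,
#'   `acronym`, and either `type = "box"` with 0-based inclusive `min`/`max`
#'   corners (z, y, x) or `type = "sphere"` with `center` (z, y, x) and
#'   `radius` in voxels. Overlapping regions are an error.
#' @return A [label_volume()] (all background for an empty spec).
#' @export
gen_label_volume <- function(shape, region_spec = list()) {
  arr <- array(0L, as.integer(shape))
  nm <- data.frame(label = integer(), acronym = character())
  for (rs in region_spec) {
    stopifnot(!is.null(rs$label), !is.null(rs$acronym), !is.null(rs$type))
    if (rs$type == "box") {
      lo <- as.integer(rs$min) + 1L; hi <- as.integer(rs$max) + 1L
      stopifnot(all(lo >= 1L), all(hi <= dim(arr)), all(lo <= hi))
      sub <- arr[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
      if (any(sub != 0L))
        stop("overlapping regions: ", rs$acronym, call. = FALSE)
      arr[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- as.integer(rs$label)
    } else if (rs$type == "sphere") {
      ctr <- as.numeric(rs$center); rad <- as.numeric(rs$radius)
      bb_lo <- pmax(floor(ctr - rad), 0); bb_hi <- pmin(ceiling(ctr + rad), shape - 1)
      gz <- bb_lo[1L]:bb_hi[1L]; gy <- bb_lo[2L]:bb_hi[2L]; gx <- bb_lo[3L]:bb_hi[3L]
      co <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
      inside <- rowSums(sweep(co, 2L, ctr)^2) <= rad^2
      idx <- co[inside, , drop = FALSE] + 1L
      lin <- (idx[, 3L] - 1L) * shape[1L] * shape[2L] +
             (idx[, 2L] - 1L) * shape[1L] + idx[, 1L]
      if (any(arr[lin] != 0L))
        stop("overlapping regions: ", rs$acronym, call. = FALSE)
      arr[lin] <- as.integer(rs$label)
    } else {
      stop("unknown region type: ", rs$type, call. = FALSE)
    }
    nm <- rbind(nm, data.frame(label = as.integer(rs$label),
                               acronym = as.character(rs$acronym)))
  }
  label_volume(arr, nm)
}

# voxel offsets of a sphere of radius r centred on a voxel
sphere_offsets <- function(r) {
  g <- -ceiling(r):ceiling(r)
  co <- as.matrix(expand.grid(z = g, y = g, x = g))
  co[rowSums(co^2) <= r^2, , drop = FALSE]
}

#' Simulate a plaque-bearing brain volume over an atlas
#'
#' Places non-overlapping bright spheres with centers uniform over each
#' region's voxels until the target plaque volume fraction is met: a
#' proposed sphere is accepted only while it moves the realized fraction
#' closer to the target, so the realized fraction ends within one sphere's
#' volume of the target with no systematic overshoot. Gaussian background
#' noise of unit SD is added; the foreground amplitude equals `snr`.
#'
#' @param labels A [label_volume()].
#' @param per_region_volume_fraction Named numeric vector (by acronym) or
#'   single value recycled to all regions; targets in \[0, 0.2\].
#' @param plaque_radius_vox_range Uniform radius range in voxels.
#' @param snr Foreground amplitude over the unit background noise SD.
#' @param spacing_um Voxel spacing (z, y, x) recorded on the volume.
#' @param seed RNG seed.
#' @param max_failures Consecutive rejected proposals per region before the
#'   target is declared unreachable.
#' @return List with `volume` ([brain_volume()]) and `truth`; the truth
#'   records the realized (not target) fraction, sphere count, centers and
#'   radii per region.
#' @export
gen_plaque_volume <- function(labels, per_region_volume_fraction,
                              plaque_radius_vox_range = c(2, 5), snr = 10,
                              spacing_um = c(1, 1, 1), seed = 1,
                              max_failures = 500L) {
  stopifnot(inherits(labels, "label_volume"))
  nm <- labels$region_names
  frac <- per_region_volume_fraction
  if (is.null(names(frac))) frac <- stats::setNames(rep(frac, nrow(nm))[seq_len(nrow(nm))], nm$acronym)
  if (any(frac < 0 | frac > 0.2))
    stop("volume fractions must be in [0, 0.2]", call. = FALSE)
  missing_r <- setdiff(names(frac), nm$acronym)
  if (length(missing_r))
    stop("unknown region(s): ", paste(missing_r, collapse = ", "), call. = FALSE)

  dims <- dim(labels$labels)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  lab_vec <- as.integer(labels$labels)

  withr::with_seed(seed, {
    occupied <- logical(prod(dims))
    signal <- logical(prod(dims))
    region_truth <- list()
    for (acr in names(frac)) {
      lb <- nm$label[match(acr, nm$acronym)]
      region_idx <- which(lab_vec == lb)
      nvox <- length(region_idx)
      target_vox <- frac[[acr]] * nvox
      placed_vox <- 0
      centers <- list(); radii <- numeric(0)
      failures <- 0L
      while (failures < max_failures) {
        r <- runif(1, plaque_radius_vox_range[1L], plaque_radius_vox_range[2L])
        off <- sphere_offsets(r)
        ci <- region_idx[sample.int(nvox, 1L)]
        cc <- arrayInd(ci, dims)            # 1-based (z, y, x)
        vz <- cc[1L] + off[, 1L]; vy <- cc[2L] + off[, 2L]; vx <- cc[3L] + off[, 3L]
        if (any(vz < 1L | vz > dims[1L] | vy < 1L | vy > dims[2L] |
                vx < 1L | vx > dims[3L])) {
          failures <- failures + 1L; next
        }
        lin <- (vx - 1L) * strides[3L] + (vy - 1L) * strides[2L] + vz
        if (any(lab_vec[lin] != lb) || any(occupied[lin])) {
          failures <- failures + 1L; next
        }
        v <- length(lin)
        if (abs(placed_vox + v - target_vox) >= abs(placed_vox - target_vox))
          break                              # adding would not improve: done
        occupied[lin] <- TRUE
        signal[lin] <- TRUE
        placed_vox <- placed_vox + v
        centers[[length(centers) + 1L]] <- cc - 1L
        radii <- c(radii, r)
        failures <- 0L
      }
      max_sphere_vox <- nrow(sphere_offsets(plaque_radius_vox_range[2L]))
      if (failures >= max_failures &&
          abs(placed_vox - target_vox) > max_sphere_vox)
        stop("target fraction unreachable without overlap in region ", acr,
             call. = FALSE)
      region_truth[[acr]] <- list(
        label = lb, target_fraction = unname(frac[[acr]]),
        realized_fraction = placed_vox / nvox,
        n_spheres = length(radii),
        centers = if (length(centers)) do.call(rbind, centers) else NULL,
        radii = radii)
    }
    vox <- array(rnorm(prod(dims), 0, 1), dims)
    vox[signal] <- vox[signal] + snr
  })

  truth <- synthetic_truth("gen_plaque_volume", seed, list(
    snr = snr, plaque_radius_vox_range = plaque_radius_vox_range,
    spacing_um = spacing_um, regions = region_truth))
  list(volume = brain_volume(vox, spacing_um, channel = "Abeta",
                             name = "synthetic plaques"),
       truth = truth)
}

# default study geometry: one cuboid region inside a small volume, sized so
# that a full two-group Monte-Carlo study runs in minutes on one CPU
default_study_labels <- function() {
  gen_label_volume(c(40L, 48L, 48L), list(
    list(label = 1L, acronym = "ROI", type = "box",
         min = c(4L, 4L, 4L), max = c(35L, 43L, 43L))))
}

#' Simulate a two-group plaque study with a known reduction effect
#'
#' Control animals draw their per-animal plaque volume fraction from a
#' lognormal distribution with mean `base_fraction` and coefficient of
#' variation `between_animal_cv`; treated animals from the same family with
#' mean `base_fraction * (1 - effect_fraction)`. One plaque volume is
#' generated per animal.
#'
#' @param labels A [label_volume()]; `NULL` uses the default single-region
#'   study geometry (40 x 48 x 48 voxels, one 32 x 40 x 40 region).
#' @param base_fraction Control-group mean plaque volume fraction: a scalar
#'   applied to every region, or a named vector by region acronym.
#' @param effect_fraction Treatment effect in \[0, 1): fractional reduction
#'   of the mean; scalar or named vector by region acronym.
#' @param n_control,n_treated Animals per group.
#' @param between_animal_cv Between-animal coefficient of variation (>= 0).
#' @param snr Detection signal-to-noise ratio of each volume.
#' @param plaque_radius_vox_range Sphere radius range in voxels.
#' @param spacing_um Voxel spacing (z, y, x).
#' @param seed RNG seed; fixed seed reproduces the whole study.
#' @return List of class `plaque_study` with `animals` (list of lists:
#'   `volume`, `group`, `truth`), `labels`, and study-level `truth`
#'   (drawn per-animal fractions and all parameters).
#' @export
gen_group_study <- function(labels = NULL, base_fraction = 0.02,
                            effect_fraction = 0.39, n_control = 5,
                            n_treated = 5, between_animal_cv = 0.15,
                            snr = 10, plaque_radius_vox_range = c(2, 4),
                            spacing_um = c(1, 1, 1), seed = 1) {
  if (any(effect_fraction < 0) || any(effect_fraction >= 1))
    stop("effect_fraction must be in [0, 1)", call. = FALSE)
  if (between_animal_cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (is.null(labels)) labels <- default_study_labels()
  acr <- labels$region_names$acronym
  expand_by_region <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) != 1L)
        stop(what, " must be a scalar or named by region", call. = FALSE)
      stats::setNames(rep(x, length(acr)), acr)
    } else {
      if (!all(acr %in% names(x)))
        stop(what, " missing regions: ",
             paste(setdiff(acr, names(x)), collapse = ", "), call. = FALSE)
      x[acr]
    }
  }
  base_fraction <- expand_by_region(base_fraction, "base_fraction")
  effect_fraction <- expand_by_region(effect_fraction, "effect_fraction")
  groups <- c(rep("control", n_control), rep("treated", n_treated))
  # animals x regions matrix of target means
  means <- matrix(base_fraction, nrow = length(groups), ncol = length(acr),
                  byrow = TRUE, dimnames = list(NULL, acr))
  tr <- groups == "treated"
  means[tr, ] <- sweep(means[tr, , drop = FALSE], 2L,
                       1 - effect_fraction, `*`)
  drawn <- withr::with_seed(seed, {
    sig2 <- log(1 + between_animal_cv^2)
    fr <- if (between_animal_cv > 0) {
      matrix(stats::rlnorm(length(means), meanlog = log(means) - sig2 / 2,
                           sdlog = sqrt(sig2)), nrow(means))
    } else {
      means
    }
    dimnames(fr) <- dimnames(means)
    list(fractions = pmin(fr, 0.2),
         subseeds = sample.int(.Machine$integer.max - 1L, length(groups)))
  })
  animals <- lapply(seq_along(groups), function(i) {
    gp <- gen_plaque_volume(labels, drawn$fractions[i, ],
                            plaque_radius_vox_range = plaque_radius_vox_range,
                            snr = snr, spacing_um = spacing_um,
                            seed = drawn$subseeds[i])
    list(volume = gp$volume, group = groups[i], truth = gp$truth)
  })
  truth <- synthetic_truth("gen_group_study", seed, list(
    base_fraction = base_fraction, effect_fraction = effect_fraction,
    n_control = n_control, n_treated = n_treated,
    between_animal_cv = between_animal_cv, snr = snr,
    drawn_fractions = drawn$fractions, groups = groups))
  structure(list(animals = animals, labels = labels, truth = truth),
            class = "plaque_study")
}

#' Quantify a (simulated or real) two-group plaque study
#'
#' Runs the full measurement chain per animal — [detect_plaques()],
#' [assign_regions()], [region_density()] — then scores the between-group
#' reduction per region with [reduction_rate()].
#'
#' @param study A `plaque_study` (or a list with `animals` and `labels` in
#'   the same layout).
#' @param metric `"volume_fraction"` (default headline: plaque burden is
#'   conventionally a volume fraction) or `"count_density_per_mm3"`.
#' @param min_voxels Detection size filter.
#' @param threshold_method,fixed_threshold Passed to [detect_plaques()];
#'   the default is the robust-background threshold because treated-group
#'   volumes carry very sparse foreground, where global Otsu collapses.
#' @return List with `per_animal` (data frame: animal, group, region,
#'   metric value) and `reduction` (one `reduction_result` row per region).
#' @export
quantify_study <- function(study, metric = c("volume_fraction",
                                             "count_density_per_mm3"),
                           min_voxels = 5L,
                           threshold_method = "background",
                           fixed_threshold = NULL) {
  metric <- match.arg(metric)
  rows <- list()
  for (i in seq_along(study$animals)) {
    an <- study$animals[[i]]
    ps <- detect_plaques(an$volume, threshold_method = threshold_method,
                         fixed_threshold = fixed_threshold,
                         min_voxels = min_voxels)
    ps <- assign_regions(ps, study$labels)
    rd <- region_density(ps, study$labels)
    rows[[i]] <- data.frame(animal = i, group = an$group,
                            region = rd$acronym, value = rd[[metric]])
  }
  per_animal <- do.call(rbind, rows)
  red <- lapply(split(per_animal, per_animal$region), function(d) {
    reduction_rate(d$value[d$group == "control"],
                   d$value[d$group == "treated"],
                   region = d$region[1L])
  })
  red <- do.call(rbind, red)
  rownames(red) <- NULL
  list(per_animal = per_animal, reduction = red, metric = metric)
}
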