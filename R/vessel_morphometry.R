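# Meningeal-lymphatic-vessel diameter pipeline: Otsu binarization ->
# morphological cleanup -> centerline -> tangents -> perpendicular-chord
# diameters -> diameter distribution and averages.

#' Otsu intensity threshold
#'
#' Histograms the intensity range into 256 equally spaced levels (or one
#' level per integer when the data are integer-valued with a range of at
#' most 256 levels, making the result exact for 8-bit images) and returns
#' the cut maximizing inter-class variance. Foreground is defined as
#' strictly greater than the returned threshold. When several cuts tie (a
#' plateau of maximizers) the plateau midpoint is returned, which makes the
#' result symmetric and deterministic.
#'
#' @param image `vessel_image`, `brain_volume` or numeric array with at
#'   least two distinct values.
#' @return Threshold on the intensity scale of the input.
#' @export
compute_otsu_threshold <- function(image) {
  v <- if (inherits(image, "vessel_image")) image$pixels
       else if (inherits(image, "brain_volume")) image$voxels
       else image
  v <- as.numeric(v)
  mn <- min(v); mx <- max(v)
  if (mx == mn) stop("no threshold exists (constant image)", call. = FALSE)
  if (all(v == round(v)) && mx - mn <= 255) {
    nlev <- as.integer(mx - mn + 1)       # exact integer histogram
    step <- 1
  } else {
    nlev <- 256L
    step <- (mx - mn) / 255
  }
  lev <- as.integer(round((v - mn) / step))
  counts <- tabulate(lev + 1L, nbins = nlev)
  reps <- mn + (seq_len(nlev) - 1) * step
  cw <- cumsum(counts)
  cm <- cumsum(counts * reps)
  total <- cw[nlev]; msum <- cm[nlev]
  k <- seq_len(nlev - 1L)          # cut k: background = levels 0..k-1
  w0 <- cw[k]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  var_b <- rep(-Inf, nlev - 1L)
  m0 <- cm[k][valid] / w0[valid]
  m1 <- (msum - cm[k][valid]) / w1[valid]
  var_b[valid] <- w0[valid] * w1[valid] * (m0 - m1)^2
  vmax <- max(var_b)
  tol <- max(abs(vmax), 1) * 1e-10
  plateau <- which(var_b >= vmax - tol)
  k_mid <- (min(plateau) + max(plateau)) / 2
  # cut k puts levels >= k in the foreground; threshold is the value of
  # level k-1 (the brightest background level)
  mn + (k_mid - 1) * step
}

#' Binarize an image at a threshold
#'
#' @param image `vessel_image` or matrix.
#' @param threshold Intensity cut; foreground is strictly greater.
#' @return A [binary_mask()].
#' @export
binarize <- function(image, threshold) {
  if (inherits(image, "vessel_image")) {
    binary_mask(image$pixels > threshold, image$spacing_um)
  } else {
    binary_mask(image > threshold)
  }
}

#' Morphological cleanup of a binary vessel mask
#'
#' Closing with a disk of `closing_radius_px`, removal of 8-connected
#' components smaller than `min_object_px`, then hole filling. Standard
#' denoising for immunofluorescence masks; all three steps are idempotent.
#'
#' @param mask `binary_mask` or 0/1 matrix.
#' @param min_object_px Smallest component kept, in pixels.
#' @param closing_radius_px Disk radius for closing (0 skips closing).
#' @return Cleaned [binary_mask()].
#' @export
clean_mask <- function(mask, min_object_px = 64, closing_radius_px = 2) {
  spacing <- if (inherits(mask, "binary_mask")) mask$spacing_um else 1
  m <- as_mask_array(mask)
  if (sum(m) > 0L && closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
    m <- EBImage::closing(m, brush)
    storage.mode(m) <- "integer"
    m <- matrix(as.integer(m != 0L), nrow(m), ncol(m))
  }
  if (sum(m) > 0L && min_object_px > 0) {
    lab <- label_components(m)
    sizes <- component_sizes(lab)
    keep <- which(sizes >= min_object_px)
    m <- matrix(as.integer(lab %in% keep), nrow(m), ncol(m))
  }
  if (sum(m) > 0L) {
    m <- EBImage::fillHull(m)
    m <- matrix(as.integer(m != 0L), nrow(m), ncol(m))
  }
  binary_mask(m, spacing)
}

# bilinear interpolation of a 0/1 mask as a continuous field; coordinates
# are 0-based with pixel centers at integers; outside the grid -> 0
bilinear_mask <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  val <- function(r, c) {
    ok <- r >= 0 & r < nr & c >= 0 & c < nc
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok] + 1, c[ok] + 1)]
    out
  }
  v00 <- val(y0, x0); v01 <- val(y0, x0 + 1)
  v10 <- val(y0 + 1, x0); v11 <- val(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# cast a ray from `point` along `dir`, return distance where the bilinearly
# interpolated mask first drops below 0.5 (NA if still inside at max_len)
ray_to_boundary <- function(m, point, dir, max_len_px, step = 0.1) {
  d <- seq(0, max_len_px, by = step)
  ys <- point[1L] + d * dir[1L]
  xs <- point[2L] + d * dir[2L]
  vals <- bilinear_mask(m, ys, xs)
  below <- which(vals < 0.5)
  if (!length(below) || below[1L] == 1L) {
    return(if (length(below) && below[1L] == 1L) 0 else NA_real_)
  }
  j <- below[1L]
  v0 <- vals[j - 1L]; v1 <- vals[j]
  d[j - 1L] + step * (v0 - 0.5) / (v0 - v1)
}

#' Measure the vessel diameter at one centerline point
#'
#' Casts rays from `point` in the `+normal` and `-normal` directions,
#' sampling the mask by bilinear interpolation at 0.1-px steps; each
#' boundary is localized where the interpolated value first drops below 0.5,
#' and the diameter is the sum of the two ray lengths. The subpixel 0.5
#' crossing makes diameters continuous under rotation of the vessel.
#'
#' @param mask `binary_mask` or 0/1 matrix.
#' @param point Subpixel (y, x), 0-based; must lie inside the foreground.
#' @param normal Unit vector (dy, dx) perpendicular to the vessel axis.
#' @param max_len_px Ray-length cap; if either ray fails to exit within it,
#'   no sample is returned.
#' @return List with `diameter_px` and the two chord `endpoints` (2x2
#'   matrix, rows (y, x)); `diameter_px` is `NA` when a ray hit the cap.
#' @export
measure_diameter_at <- function(mask, point, normal, max_len_px = 100) {
  m <- as_mask_array(mask)
  nrm <- sqrt(sum(normal^2))
  if (abs(nrm - 1) > 1e-6) normal <- normal / nrm
  if (bilinear_mask(m, point[1L], point[2L]) < 0.5)
    stop("off-vessel sample (point outside foreground)", call. = FALSE)
  d_plus <- ray_to_boundary(m, point, normal, max_len_px)
  d_minus <- ray_to_boundary(m, point, -normal, max_len_px)
  if (is.na(d_plus) || is.na(d_minus)) {
    return(list(diameter_px = NA_real_, endpoints = NULL))
  }
  ends <- rbind(point + d_plus * normal, point - d_minus * normal)
  list(diameter_px = d_plus + d_minus, endpoints = ends)
}

# linear interpolation of a polyline at arclength s; also returns the index
# of the nearest original point (for tangent lookup)
interp_polyline <- function(points, arclength, s) {
  j <- findInterval(s, arclength, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), nrow(points) - 1L)
  seg <- arclength[j + 1L] - arclength[j]
  t <- ifelse(seg > 0, (s - arclength[j]) / seg, 0)
  pt <- points[j, , drop = FALSE] * (1 - t) +
        points[j + 1L, , drop = FALSE] * t
  nearest <- ifelse(t < 0.5, j, j + 1L)
  list(point = pt, nearest = nearest)
}

#' Diameter profile along a vessel centerline
#'
#' Samples every `step_px` of arclength along each branch, excluding points
#' within `junction_exclusion_px` of branch ends (junctions and endpoints,
#' where tangents are ill-defined), and measures the perpendicular-chord
#' diameter at each sample. A sample is also discarded afterwards when its
#' distance to the branch end is less than half its own measured diameter:
#' that close to an end the perpendicular chord cuts the vessel end cap (or
#' a joining branch) and underestimates the width. Samples where a ray
#' fails to exit within `max_len_px` are dropped and counted.
#'
#' @param mask `binary_mask` the centerline was derived from.
#' @param cl [centerline()] (tangents are estimated if absent).
#' @param spacing_um Micrometres per pixel.
#' @param step_px Arclength sampling interval.
#' @param junction_exclusion_px Exclusion zone at branch ends.
#' @param max_len_px Ray cap passed to [measure_diameter_at()].
#' @param tangent_window_px Window for tangent estimation when needed.
#' @return Object of class `diameter_profile`: a data frame with columns
#'   `branch_id`, `arclength_um`, `diameter_um`, `x0`, `y0`, `x1`, `y1`
#'   (chord endpoints, pixel coordinates), with attributes `spacing_um` and
#'   `n_failed`.
#' @export
diameter_profile <- function(mask, cl, spacing_um = 1, step_px = 1,
                             junction_exclusion_px = 3, max_len_px = 100,
                             tangent_window_px = 5) {
  stopifnot(inherits(cl, "centerline"))
  if (is.null(cl$branches[[1L]]$tangents))
    cl <- estimate_tangents(cl, tangent_window_px)
  m <- as_mask_array(mask)
  rows <- list()
  n_failed <- 0L
  for (bi in seq_along(cl$branches)) {
    b <- cl$branches[[bi]]
    L <- max(b$arclength)
    if (L <= 2 * junction_exclusion_px) next
    s <- seq(0, L, by = step_px)
    s <- s[s >= junction_exclusion_px & s <= L - junction_exclusion_px]
    if (!length(s)) next
    ip <- interp_polyline(b$points, b$arclength, s)
    for (i in seq_along(s)) {
      tang <- b$tangents[ip$nearest[i], ]
      normal <- c(tang[2L], -tang[1L])
      pt <- ip$point[i, ]
      if (bilinear_mask(m, pt[1L], pt[2L]) < 0.5) {
        n_failed <- n_failed + 1L
        next
      }
      res <- measure_diameter_at(m, pt, normal, max_len_px)
      if (is.na(res$diameter_px)) {
        n_failed <- n_failed + 1L
        next
      }
      if (min(s[i], L - s[i]) < res$diameter_px / 2) next  # end-cap zone
      rows[[length(rows) + 1L]] <- data.frame(
        branch_id = bi,
        arclength_um = s[i] * spacing_um,
        diameter_um = res$diameter_px * spacing_um,
        x0 = res$endpoints[1L, 2L], y0 = res$endpoints[1L, 1L],
        x1 = res$endpoints[2L, 2L], y1 = res$endpoints[2L, 1L])
    }
  }
  if (!length(rows)) stop("no measurable vessel", call. = FALSE)
  out <- do.call(rbind, rows)
  structure(out, spacing_um = spacing_um, n_failed = n_failed,
            class = c("diameter_profile", "data.frame"))
}

#' Summarize a diameter profile
#'
#' Pooled mean/median/SD over all samples, a fixed 1-um-bin histogram from 0
#' to the ceiling of the largest diameter, and per-branch means. Whether the
#' scientific average should pool samples or average per-vessel means is a
#' reporting choice; both are returned (`mean_um` pools, `per_branch` holds
#' the branch means and `mean_of_branch_means_um` their average).
#'
#' @param profile A [diameter_profile()].
#' @return List of class `diameter_summary`.
#' @export
summarize_diameters <- function(profile) {
  d <- profile$diameter_um
  if (is.null(d) || !length(d)) stop("empty profile", call. = FALSE)
  breaks <- seq(0, max(1, ceiling(max(d))), by = 1)
  counts <- as.integer(table(cut(d, breaks, right = TRUE, include.lowest = TRUE)))
  per_branch <- stats::aggregate(diameter_um ~ branch_id,
                                 data = as.data.frame(profile), FUN = mean)
  names(per_branch) <- c("branch_id", "mean_diameter_um")
  structure(list(
    mean_um = mean(d),
    median_um = stats::median(d),
    sd_um = if (length(d) > 1L) stats::sd(d) else NA_real_,
    n = length(d),
    hist_breaks_um = breaks,
    hist_counts = counts,
    per_branch = per_branch,
    mean_of_branch_means_um = mean(per_branch$mean_diameter_um)
  ), class = "diameter_summary")
}

#' @export
print.diameter_summary <- function(x, ...) {
  cat(sprintf(
    "<diameter_summary> n=%d  mean=%.2f um  median=%.2f um  sd=%.2f um\n",
    x$n, x$mean_um, x$median_um, x$sd_um))
  invisible(x)
}

#' Full vessel-diameter pipeline on one image
#'
#' Otsu binarization and morphological cleanup give the topology mask from
#' which the centerline and tangents are extracted. Chord diameters are then
#' measured on a half-height mask: the image binarized at the midpoint of
#' the foreground and background class medians. Otsu's threshold satisfies
#' `t = (mu0 + mu1)/2` over class *means*, which the partial-intensity
#' pixels of the blurred vessel edge drag below half contrast, dilating the
#' mask by a fraction of a pixel; class medians are insensitive to the edge
#' ramp, so the half-height boundary sits at the true half-maximum of the
#' edge profile.
#'
#' @param image A [vessel_image()].
#' @param config Parameter list from [load_config()] / [default_config()].
#' @return List with `threshold` (Otsu), `measure_threshold` (half-height),
#'   `mask` (topology mask), `centerline`, `profile`, `summary`.
#' @export
measure_vessels <- function(image, config = default_config()) {
  thr <- compute_otsu_threshold(image)
  mask <- binarize(image, thr)
  mask <- clean_mask(mask, config$min_object_px, config$closing_radius_px)
  cl <- extract_centerline(mask, config$prune_px)
  cl <- estimate_tangents(cl, config$tangent_window_px)
  # foreground level from the centerline points (interior by construction;
  # a thin vessel's mask is mostly partial edge pixels, which drag a
  # mask-wide median down), background level from off-mask pixels
  fg <- mask$mask == 1L
  pts <- do.call(rbind, lapply(cl$branches, function(b) b$points))
  level_fg <- stats::median(bilinear_mask(image$pixels, pts[, 1L], pts[, 2L]))
  thr_half <- (level_fg + stats::median(image$pixels[!fg])) / 2
  meas_mask <- binarize(image, thr_half)
  prof <- diameter_profile(meas_mask, cl,
                           spacing_um = image$spacing_um,
                           step_px = config$step_px,
                           junction_exclusion_px = config$junction_exclusion_px,
                           max_len_px = config$max_chord_px,
                           tangent_window_px = config$tangent_window_px)
  list(threshold = thr, measure_threshold = thr_half, mask = mask,
       centerline = cl, profile = prof,
       summary = summarize_diameters(prof))
}
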