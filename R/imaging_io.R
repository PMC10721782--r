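# ---- domain containers -------------------------------------------------

#' Single-channel 2D fluorescence image with physical pixel spacing
#'
#' The raw measurement substrate for vessel morphometry: a 2D scalar grid of
#' fluorescence intensities (arbitrary units) plus an isotropic pixel size in
#' micrometres. Coordinates follow the package convention: 0-based (y, x)
#' indices with pixel centers at integer coordinates.
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#' @param spacing_um Micrometres per pixel; finite, > 0.
#' @param name Free-text identifier carried through outputs.
#' @return An object of class `vessel_image`.
#' @export
vessel_image <- function(pixels, spacing_um, name = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    stop("intensities must be finite", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 1L || !is.finite(spacing_um) || spacing_um <= 0)
    stop("spacing_um must be a single finite positive number", call. = FALSE)
  structure(list(pixels = pixels, spacing_um = spacing_um,
                 name = as.character(name)[1L]),
            class = "vessel_image")
}

#' @export
print.vessel_image <- function(x, ...) {
  cat(sprintf("<vessel_image> %dx%d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_um,
              if (nzchar(x$name)) paste0(" [", x$name, "]") else ""))
  invisible(x)
}

#' Single-channel 3D image stack with anisotropic voxel spacing
#'
#' Container for light-sheet volumes of cleared brain. Axis order is
#' (z, y, x); `spacing_um` gives the voxel size along each axis in the same
#' order, all in micrometres.
#'
#' @param voxels 3D numeric array (z, y, x).
#' @param spacing_um Numeric length-3 vector (um_z, um_y, um_x), all > 0.
#' @param channel Channel label, e.g. `"Abeta"` or `"autofluorescence"`.
#' @param name Free-text identifier.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(voxels, spacing_um, channel = "Abeta", name = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("voxels must be a non-empty 3D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("intensities must be finite", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || !all(is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("spacing_um must be three finite positive numbers (z, y, x)", call. = FALSE)
  structure(list(voxels = voxels, spacing_um = spacing_um,
                 channel = as.character(channel)[1L],
                 name = as.character(name)[1L]),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<brain_volume> %dx%dx%d vox (z,y,x), spacing %s um, channel %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing_um, 4), collapse = "x"),
              x$channel))
  invisible(x)
}

#' Atlas label volume aligned to a brain volume
#'
#' Integer region labels on the same grid as an associated [brain_volume()]:
#' the "wrapped labels" produced by atlas registration, consumed here as
#' input. Background is label 0 and is excluded from all region statistics.
#'
#' @param labels 3D integer array (z, y, x); non-negative.
#' @param region_names Named integer vector or two-column data frame mapping
#'   label -> acronym (e.g. `c(CA1 = 1, DG = 2)` or columns `label`,
#'   `acronym`). Every nonzero label present in `labels` must be named.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, region_names) {
  if (!is.array(labels) || length(dim(labels)) != 3L || length(labels) == 0L)
    stop("labels must be a non-empty 3D array", call. = FALSE)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  if (any(labels != round(labels))) stop("labels must be integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  names_df <- normalize_region_names(region_names)
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  orphans <- setdiff(present, names_df$label)
  if (length(orphans))
    stop("labels present in volume but absent from names map: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, region_names = names_df),
            class = "label_volume")
}

normalize_region_names <- function(region_names) {
  if (is.data.frame(region_names)) {
    if (nrow(region_names) == 0L)
      return(data.frame(label = integer(), acronym = character()))
    stopifnot(all(c("label", "acronym") %in% names(region_names)))
    df <- data.frame(label = as.integer(region_names$label),
                     acronym = as.character(region_names$acronym))
  } else if (length(region_names) == 0L) {
    df <- data.frame(label = integer(), acronym = character())
  } else {
    df <- data.frame(label = as.integer(region_names),
                     acronym = names(region_names))
  }
  if (anyDuplicated(df$label)) stop("duplicate labels in names map", call. = FALSE)
  if (any(df$label <= 0)) stop("region labels must be positive", call. = FALSE)
  df[order(df$label), , drop = FALSE]
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %dx%dx%d vox, %d named regions\n",
              d[1], d[2], d[3], nrow(x$region_names)))
  invisible(x)
}

#' Binary mask on the grid of a source image or volume
#'
#' @param mask Matrix or 3D array with values in {0, 1} (logical accepted).
#' @param spacing_um Physical spacing inherited from the source grid.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, spacing_um = 1) {
  if (is.logical(mask)) {
    m <- mask
    storage.mode(m) <- "integer"
    mask <- m
  }
  if (!all(mask %in% c(0L, 1L)))
    stop("mask values must be 0/1", call. = FALSE)
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, spacing_um = as.numeric(spacing_um)),
            class = "binary_mask")
}

as_mask_array <- function(x) {
  if (inherits(x, "binary_mask")) x$mask else x
}

# ---- TIFF I/O ----------------------------------------------------------

#' Read a single-channel TIFF image or stack
#'
#' Reads 8/16-bit unsigned or 32-bit float TIFF. A one-page file becomes a
#' [vessel_image()]; a multi-page file becomes a [brain_volume()] with page
#' order mapping to ascending z. Pixel spacing is always supplied by the
#' caller (from configuration), never inferred from TIFF resolution tags,
#' which are unreliable across microscope exporters.
#'
#' @param path TIFF file path.
#' @param spacing_um Scalar (2D) or length-3 (z, y, x) spacing in um.
#' @param channel Channel label for volumes.
#' @param name Identifier; defaults to the file name.
#' @return A `vessel_image` or `brain_volume`.
#' @export
read_image <- function(path, spacing_um, channel = "Abeta", name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      stop("single-channel required (RGB/multi-sample TIFF given)", call. = FALSE)
  }
  if (length(pages) == 1L) {
    if (length(spacing_um) != 1L)
      stop("a 2D image needs one scalar spacing_um", call. = FALSE)
    vessel_image(pages[[1L]] * 1.0, spacing_um, name = name)
  } else {
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("pages differ in shape", call. = FALSE)
    vox <- aperm(simplify2array(pages), c(3L, 1L, 2L)) * 1.0
    brain_volume(vox, spacing_um, channel = channel, name = name)
  }
}

#' Write an image, volume or mask to TIFF
#'
#' Integer-valued data are written at 8 or 16 bits (bit-exact round trip);
#' other data at 32-bit float. Volumes are written as multi-page TIFF with z
#' ascending.
#'
#' @param x A `vessel_image`, `brain_volume`, `binary_mask`, matrix or 3D
#'   array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  a <- if (inherits(x, "vessel_image")) x$pixels
       else if (inherits(x, "brain_volume")) x$voxels
       else if (inherits(x, "label_volume")) x$labels
       else as_mask_array(x)
  intish <- all(a == round(a)) && min(a) >= 0
  if (intish && max(a) <= 255) {
    scale <- 255; bits <- 8L
  } else if (intish && max(a) <= 65535) {
    scale <- 65535; bits <- 16L
  } else {
    scale <- 1; bits <- 32L
  }
  pages <- if (length(dim(a)) == 3L) {
    lapply(seq_len(dim(a)[1L]), function(z) a[z, , ] / scale)
  } else {
    list(a / scale)
  }
  invisible(tiff::writeTIFF(pages, path, bits.per.sample = bits))
  invisible(path)
}

#' Read an atlas label volume plus its region-name table
#'
#' @param path Integer-valued TIFF (single- or multi-page).
#' @param names_path Two-column CSV `label,acronym`.
#' @return A [label_volume()]. Errors if any nonzero label in the volume is
#'   missing from the names map.
#' @export
read_label_volume <- function(path, names_path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- if (length(pages) == 1L) {
    array(pages[[1L]], dim = c(1L, dim(pages[[1L]])))
  } else {
    aperm(simplify2array(pages), c(3L, 1L, 2L))
  }
  if (any(arr != round(arr))) stop("label volume must be integer-valued", call. = FALSE)
  nm <- utils::read.csv(names_path, stringsAsFactors = FALSE)
  if (nrow(nm) && !all(c("label", "acronym") %in% names(nm)))
    names(nm) <- c("label", "acronym")[seq_len(ncol(nm))]
  label_volume(arr, nm)
}

# ---- tables ------------------------------------------------------------

#' Write / read a rectangular table as CSV
#'
#' UTF-8 CSV with a header row and '.' decimal separator. Missing values are
#' written as empty fields and read back as `NA`. Round trips preserve
#' numeric values to better than 1e-9 relative.
#'
#' @param table A data frame with unique column names.
#' @param path CSV path.
#' @return `write_table` returns `path` invisibly; `read_table` returns a
#'   data frame.
#' @export
write_table <- function(table, path) {
  table <- as.data.frame(table)
  if (anyDuplicated(names(table)))
    stop("duplicate column names", call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8")
  if (anyDuplicated(names(df)))
    stop("duplicate column names", call. = FALSE)
  df
}

# ---- configuration -----------------------------------------------------

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults. Lengths are
#' in pixels/voxels unless suffixed `_um` or `_s`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    spacing_um            = 1.0,    # 2D pixel size
    voxel_spacing_um      = c(1.0, 1.0, 1.0),  # (z, y, x)
    closing_radius_px     = 2L,     # mask cleanup: disk radius for closing
    min_object_px         = 64L,    # mask cleanup: smallest kept component
    prune_px              = 5,      # skeleton spur pruning length
    tangent_window_px     = 5,      # +/- arclength window for tangent PCA
    step_px               = 1,      # arclength sampling interval
    junction_exclusion_px = 3,      # skip samples this close to branch ends
    max_chord_px          = 100,    # ray-cast length cap
    min_plaque_voxels     = 5L,     # smallest kept 3D component
    threshold_method      = "otsu", # "otsu" or "fixed"
    fixed_threshold       = NA_real_,
    baseline_window_s     = 60,     # thermometry baseline before 1st irradiation
    trial_cap_s           = 60      # water-maze trial duration cap
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads JSON or YAML (by file extension), rejects unknown keys, applies
#' defaults for absent keys, validates types and positivity, and echoes the
#' full effective configuration to the message log.
#'
#' @param path JSON or YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (same validation).
#' @param quiet Suppress the echo of the effective configuration.
#' @return Validated named list.
#' @export
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    v <- user[[k]]
    if (!is.numeric(v) && !is.character(v))
      stop("config key '", k, "' has unsupported type", call. = FALSE)
    if (is.character(cfg[[k]]) != is.character(v))
      stop("config key '", k, "' has wrong type", call. = FALSE)
    cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(v) else v
  }
  if (cfg$spacing_um <= 0 || any(cfg$voxel_spacing_um <= 0))
    stop("spacing must be > 0", call. = FALSE)
  if (length(cfg$voxel_spacing_um) != 3L)
    stop("voxel_spacing_um must have 3 entries (z, y, x)", call. = FALSE)
  if (!cfg$threshold_method %in% c("otsu", "fixed"))
    stop("threshold_method must be 'otsu' or 'fixed'", call. = FALSE)
  if (cfg$min_plaque_voxels < 1L || cfg$min_object_px < 0L)
    stop("size thresholds must be positive", call. = FALSE)
  if (!quiet)
    message("effective config: ",
            paste(names(cfg), vapply(cfg, function(v) paste(v, collapse = ","),
                                     ""), sep = "=", collapse = " "))
  cfg
}
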