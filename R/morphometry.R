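#' Gaussian smoothing of a disc volume
#'
#' Separable 3D Gaussian filter with an odd window of `kernel` voxels per
#' axis (sigma = kernel / 4, so the window spans roughly +/- 2 sigma),
#' normalized weights and edge-replicated borders. Constant volumes pass
#' through unchanged; `kernel = 1` is the identity.
#'
#' @param vol A [disc_volume()].
#' @param kernel Odd window width in voxels (default 3).
#'
#' @return A smoothed `disc_volume` of identical shape.
#' @export
smooth_volume <- function(vol, kernel = 3) {
  stopifnot(inherits(vol, "disc_volume"))
  if (kernel < 1 || kernel %% 2 == 0) {
    stop_ivd("`kernel` must be an odd integer >= 1.", "bad_kernel")
  }
  if (kernel == 1) return(vol)
  h <- (kernel - 1) / 2
  w <- dnorm(seq(-h, h), sd = kernel / 4)
  w <- w / sum(w)
  disc_volume(convolve_separable(vol$data, w), vol$voxel_size)
}

#' Define a sparse contour set for whole-disc mask construction
#'
#' Closed planar polygons drawn on a subset of transverse slices
#' (conventionally every 10 slices); intermediate slices are filled in by
#' [build_disc_mask()] via linear interpolation of the polygons' signed
#' distance fields.
#'
#' @param contours Named list: transverse slice index (as name) -> numeric
#'   matrix of (row, col) polygon vertices (>= 3, implicitly closed).
#'
#' @return A `contour_set`.
#' @export
contour_set <- function(contours) {
  if (!is.list(contours) || length(contours) < 2 || is.null(names(contours))) {
    stop_ivd("Need a named list of polygons on at least 2 slices.", "bad_contours")
  }
  slices <- as.integer(names(contours))
  if (any(is.na(slices)) || anyDuplicated(slices) > 0) {
    stop_ivd("Contour names must be unique integer slice indices.", "bad_contours")
  }
  for (p in contours) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop_ivd("Each contour must be a (row, col) matrix with >= 3 vertices.",
               "bad_contours")
    }
  }
  ord <- order(slices)
  structure(list(slices = slices[ord], polygons = unname(contours)[ord]),
            class = "contour_set")
}

#' Contours of a phantom's disc envelope
#'
#' Generates the elliptical perimeter polygon of a [disc_phantom_spec()]'s
#' disc envelope on every `every`-th transverse slice (plus the last slice
#' of the disc span), emulating the manual contouring workflow.
#'
#' @param spec A `disc_phantom_spec`.
#' @param every Contour spacing in slices (default 10).
#' @param n_vertices Polygon resolution (default 72).
#'
#' @return A `contour_set`.
#' @export
phantom_contours <- function(spec, every = 10, n_vertices = 72) {
  stopifnot(inherits(spec, "disc_phantom_spec"))
  dg <- spec$disc_geometry
  z_all <- seq_len(spec$grid_shape[1])
  zin <- z_all[abs(z_all - dg$center[1]) <= dg$half_height]
  sl <- unique(c(seq(min(zin), max(zin), by = every), max(zin)))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  poly <- cbind(dg$center[2] + dg$radius[1] * cos(theta),
                dg$center[3] + dg$radius[2] * sin(theta))
  contours <- stats::setNames(rep(list(poly), length(sl)), sl)
  contour_set(contours)
}

#' Build the whole-disc mask from sparse contours
#'
#' Contoured slices are rasterized by filling the polygon (a voxel belongs
#' to the disc when its centre is inside). Slices between two contoured
#' slices are obtained by linearly interpolating the two polygons' signed
#' distance fields and thresholding at zero — a definition of
#' "morphing by linear interpolation" that is exact for concentric circles
#' (the radius interpolates linearly). Slices outside the contoured span
#' are empty.
#'
#' @param contours A [contour_set()].
#' @param shape Volume shape, 3 integers (slices, rows, cols).
#'
#' @return A `mask_set` whose NP mask is empty (disc mask only).
#' @export
build_disc_mask <- function(contours, shape) {
  stopifnot(inherits(contours, "contour_set"), length(shape) == 3)
  shape <- as.integer(shape)
  sl <- contours$slices
  if (min(sl) < 1 || max(sl) > shape[1]) {
    stop_ivd("Contoured slices fall outside the volume extent.", "bad_contours")
  }
  sdfs <- lapply(contours$polygons, polygon_sdf, nr = shape[2], nc = shape[3])
  disc <- array(FALSE, shape)
  for (i in seq_along(sl)) disc[sl[i], , ] <- sdfs[[i]] <= 0
  for (i in seq_len(length(sl) - 1)) {
    z0 <- sl[i]; z1 <- sl[i + 1]
    if (z1 - z0 > 1) {
      for (z in (z0 + 1):(z1 - 1)) {
        t <- (z - z0) / (z1 - z0)
        disc[z, , ] <- ((1 - t) * sdfs[[i]] + t * sdfs[[i + 1]]) <= 0
      }
    }
  }
  mask_set(disc = disc, np = array(FALSE, shape))
}

#' Segment the nucleus pulposus within the whole-disc mask
#'
#' Thresholds the (typically smoothed) volume inside the disc mask — Otsu's
#' method by default, or a fixed value — then applies a 3D morphological
#' close followed by open (3x3x3 cube, one iteration each) to fill
#' interior holes and smooth the NP boundary, keeps the largest connected
#' component, and intersects with the disc mask.
#'
#' @param vol A `disc_volume` (smooth first with [smooth_volume()] for
#'   noisy data).
#' @param disc_mask Logical array (or a `mask_set`, whose `disc` is used).
#' @param threshold `"otsu"` (default) or a fixed numeric intensity; a
#'   fixed value must lie within the intensity range inside the disc.
#'
#' @return A `mask_set` with both `disc` and the segmented `np`.
#' @export
segment_np <- function(vol, disc_mask, threshold = "otsu") {
  stopifnot(inherits(vol, "disc_volume"))
  if (inherits(disc_mask, "mask_set")) disc_mask <- disc_mask$disc
  stopifnot(is.logical(disc_mask), identical(dim(disc_mask), dim(vol$data)))
  if (!any(disc_mask)) stop_ivd("Disc mask is empty.", "empty_mask")
  inside <- vol$data[disc_mask]
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(inside)
  } else {
    check_scalar_number(threshold, "threshold")
    if (threshold < min(inside) || threshold > max(inside)) {
      stop_ivd("Fixed threshold lies outside the intensity range in the disc.",
               "bad_threshold")
    }
    threshold
  }
  cand <- vol$data >= thr & disc_mask
  if (!any(cand)) stop_ivd("Threshold selects no voxels.", "bad_threshold")
  np <- binary_open(binary_close(cand, 3L), 3L)
  if (any(np)) np <- largest_component(np)
  np <- np & disc_mask
  if (!any(np)) stop_ivd("NP segmentation is empty after morphology.", "empty_mask")
  mask_set(disc = disc_mask, np = np)
}

#' Disc morphometry: NPVF, NI/DI and DHI
#'
#' From a volume and its masks computes the NP volume fraction
#' `NPVF = |NP| / |disc|`, the intensity ratio `NIDI = mean NP intensity /
#' mean whole-disc intensity` (the disc mean includes the NP voxels), and
#' the disc height index `DHI`: the height-to-width ratio of the disc mask
#' (height along the transverse stack axis, width in-plane) averaged over
#' the five sagittal slices centred on the disc-mask centroid.
#'
#' @param vol A `disc_volume` (intensities are read from this volume,
#'   conventionally the unsmoothed one).
#' @param masks A `mask_set` with non-empty disc and NP masks.
#'
#' @return A one-row tibble: `npvf`, `nidi`, `dhi`, voxel counts, volumes
#'   in cubic micrometres, and region mean intensities.
#' @export
morphometry_metrics <- function(vol, masks) {
  stopifnot(inherits(vol, "disc_volume"), inherits(masks, "mask_set"))
  disc <- masks$disc; np <- masks$np
  if (!any(disc) || !any(np)) stop_ivd("Masks must be non-empty.", "empty_mask")
  n_disc <- sum(disc); n_np <- sum(np)
  mean_disc <- mean(vol$data[disc]); mean_np <- mean(vol$data[np])

  # DHI over the 5 sagittal (fixed-column) slices centred on the centroid.
  idx <- which(disc, arr.ind = TRUE)
  mid <- round(mean(idx[, 3]))
  cols <- (mid - 2):(mid + 2)
  present <- vapply(cols, function(cc)
    cc >= 1 && cc <= dim(disc)[3] && any(disc[, , cc]), logical(1))
  if (!all(present)) {
    stop_ivd("Fewer than 5 central sagittal slices intersect the disc.",
             "too_thin")
  }
  ratios <- vapply(cols, function(cc) {
    sl <- disc[, , cc]
    ij <- which(sl, arr.ind = TRUE)
    height <- diff(range(ij[, 1])) + 1
    width <- diff(range(ij[, 2])) + 1
    height / width
  }, numeric(1))

  vs3 <- vol$voxel_size^3
  tibble(
    npvf = n_np / n_disc,
    nidi = mean_np / mean_disc,
    dhi = mean(ratios),
    np_voxels = n_np, disc_voxels = n_disc,
    np_volume_um3 = n_np * vs3, disc_volume_um3 = n_disc * vs3,
    mean_np_intensity = mean_np, mean_disc_intensity = mean_disc
  )
}

#' Run the full morphometry pipeline on a volume
#'
#' Convenience wrapper: Gaussian smoothing, disc mask from contours, NP
#' segmentation on the smoothed volume, metrics on the original volume.
#'
#' @inheritParams smooth_volume
#' @inheritParams segment_np
#' @param contours A [contour_set()].
#' @return A list: `masks` and one-row `metrics` tibble.
#' @export
morphometry_pipeline <- function(vol, contours, kernel = 3, threshold = "otsu") {
  sm <- smooth_volume(vol, kernel)
  disc <- build_disc_mask(contours, dim(vol$data))
  masks <- segment_np(sm, disc$disc, threshold)
  list(masks = masks, metrics = morphometry_metrics(vol, masks))
}
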