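#' Parametric specification of a contrast-enhanced disc phantom
#'
#' The phantom emulates a contrast-enhanced micro-CT scan of a functional
#' spine unit: a disc envelope (axis-aligned elliptic cylinder along the
#' transverse stack axis) containing a strictly interior ellipsoidal nucleus
#' pulposus (NP). Because the contrast agent partitions into the
#' proteoglycan-rich NP, the NP is the brightest region:
#' `np_intensity > disc_intensity > background_intensity`.
#'
#' @param grid_shape Integer vector of 3 (slices, rows, cols).
#' @param voxel_size Voxel edge length in micrometres (default 10).
#' @param disc_geometry List: `center` (3-vector, voxel units), `radius`
#'   (in-plane semi-axes, length 1 or 2) and `half_height` (along axis 1).
#' @param np_geometry List: `center` and `semiaxes` (length 3) of the NP
#'   ellipsoid, in voxel units; must be strictly inside the disc.
#' @param disc_intensity,np_intensity,background_intensity Grayscale levels.
#' @param noise_sd Additive Gaussian noise SD (0 for a noise-free phantom).
#'
#' @return A `disc_phantom_spec` list.
#' @export
disc_phantom_spec <- function(grid_shape = c(72, 72, 72),
                              voxel_size = 10,
                              disc_geometry = list(center = (grid_shape + 1) / 2,
                                                   radius = min(grid_shape[2:3]) * 0.38,
                                                   half_height = grid_shape[1] * 0.33),
                              np_geometry = list(center = (grid_shape + 1) / 2,
                                                 semiaxes = c(grid_shape[1] * 0.18,
                                                              min(grid_shape[2:3]) * 0.20,
                                                              min(grid_shape[2:3]) * 0.20)),
                              disc_intensity = 100,
                              np_intensity = 200,
                              background_intensity = 10,
                              noise_sd = 0) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8))
  check_scalar_number(voxel_size, "voxel_size", 0, strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", 0)
  if (length(disc_geometry$radius) == 1) {
    disc_geometry$radius <- rep(disc_geometry$radius, 2)
  }
  if (!(np_intensity > disc_intensity && disc_intensity > background_intensity)) {
    stop_ivd("Intensities must satisfy np > disc > background.", "bad_phantom")
  }
  # NP strictly inside the disc envelope: bounding extents with a 1-voxel margin.
  np_lo <- np_geometry$center - np_geometry$semiaxes
  np_hi <- np_geometry$center + np_geometry$semiaxes
  disc_lo <- c(disc_geometry$center[1] - disc_geometry$half_height,
               disc_geometry$center[2:3] - disc_geometry$radius)
  disc_hi <- c(disc_geometry$center[1] + disc_geometry$half_height,
               disc_geometry$center[2:3] + disc_geometry$radius)
  if (any(np_lo <= disc_lo + 1) || any(np_hi >= disc_hi - 1)) {
    stop_ivd("NP geometry must lie strictly inside the disc envelope.", "bad_phantom")
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         disc_geometry = disc_geometry, np_geometry = np_geometry,
         disc_intensity = disc_intensity, np_intensity = np_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd),
    class = "disc_phantom_spec"
  )
}

#' Generate a disc phantom volume with ground-truth masks
#'
#' Rasterizes the phantom geometry onto the voxel grid (a voxel belongs to a
#' region when its centre lies inside the parametric solid), assigns the
#' three intensity levels, and adds seeded Gaussian noise. The exact masks
#' used for rasterization are returned so that planted NPVF and NI/DI are
#' computable without segmentation.
#'
#' @param spec A [disc_phantom_spec()].
#' @param seed Integer seed for the noise (irrelevant when `noise_sd = 0`
#'   but still required, for uniform call signatures).
#'
#' @return A list with `volume` (a `disc_volume`: 3D array + voxel size) and
#'   `masks` (a `mask_set`: logical `disc` and `np` arrays).
#' @export
#' @examples
#' ph <- generate_disc_volume(disc_phantom_spec(grid_shape = c(24, 24, 24),
#'   disc_geometry = list(center = c(12.5, 12.5, 12.5), radius = 9, half_height = 8),
#'   np_geometry = list(center = c(12.5, 12.5, 12.5), semiaxes = c(4, 5, 5))), seed = 1)
#' mean(ph$masks$np) / mean(ph$masks$disc) # planted NPVF
generate_disc_volume <- function(spec, seed) {
  stopifnot(inherits(spec, "disc_phantom_spec"))
  dims <- spec$grid_shape
  z <- seq_len(dims[1]); y <- seq_len(dims[2]); x <- seq_len(dims[3])

  dg <- spec$disc_geometry
  ng <- spec$np_geometry

  # Elliptic cylinder: in-plane ellipse and |z - cz| <= half_height.
  inplane <- outer((y - dg$center[2])^2 / dg$radius[1]^2,
                   (x - dg$center[3])^2 / dg$radius[2]^2, "+") <= 1
  zin <- abs(z - dg$center[1]) <= dg$half_height
  disc <- array(FALSE, dims)
  for (k in which(zin)) disc[k, , ] <- inplane

  # NP ellipsoid.
  zq <- (z - ng$center[1])^2 / ng$semiaxes[1]^2
  yq <- (y - ng$center[2])^2 / ng$semiaxes[2]^2
  xq <- (x - ng$center[3])^2 / ng$semiaxes[3]^2
  np <- outer(zq, outer(yq, xq, "+"), "+") <= 1
  np <- np & disc  # guaranteed by spec validation; intersection is a safeguard

  vol <- array(spec$background_intensity, dims)
  vol[disc] <- spec$disc_intensity
  vol[np] <- spec$np_intensity
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(seed, array(rnorm(prod(dims), sd = spec$noise_sd), dims))
  }
  list(
    volume = disc_volume(vol, spec$voxel_size),
    masks = mask_set(disc = disc, np = np)
  )
}

#' Construct a disc volume object
#'
#' @param data 3D numeric array (slices, rows, cols); axis 1 is the
#'   transverse stack direction.
#' @param voxel_size Voxel edge length in micrometres.
#' @return A `disc_volume`.
#' @export
disc_volume <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  check_scalar_number(voxel_size, "voxel_size", 0, strict_lower = TRUE)
  structure(list(data = data, voxel_size = voxel_size), class = "disc_volume")
}

#' Construct a mask set (whole-disc and NP binary masks)
#'
#' @param disc,np Logical arrays of identical shape; `np` must be a subset
#'   of `disc`.
#' @return A `mask_set`.
#' @export
mask_set <- function(disc, np) {
  stopifnot(is.logical(disc), is.logical(np), identical(dim(disc), dim(np)))
  if (any(np & !disc)) {
    stop_ivd("NP mask must be a subset of the disc mask.", "bad_mask")
  }
  structure(list(disc = disc, np = np), class = "mask_set")
}

#' @export
print.disc_volume <- function(x, ...) {
  cat(sprintf("<disc_volume> %s voxels @ %g um, intensity [%g, %g]\n",
              paste(dim(x$data), collapse = " x "), x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}
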