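# Synthetic tomogram-like volumes: particle placement, membrane slabs,
# Gaussian noise, and Fourier missing-wedge degradation.

#' Tomogram-like volume container
#'
#' @param density 3D numeric array.
#' @param voxel_size Angstrom per voxel.
#' @param truth Truth table (see [generate_tomogram()]).
#' @param membranes Optional list of two `membrane_plane` objects.
#' @param wedge_applied Logical; has a missing wedge been applied?
#' @param tilt_range Tilt range of the applied wedge, or NULL.
#' @return An object of class `tomo_volume`.
#' @export
tomo_volume <- function(density, voxel_size, truth = NULL, membranes = NULL,
                        wedge_applied = FALSE, tilt_range = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (any(!is.finite(density))) stop("densities must be finite")
  structure(list(density = density, voxel_size = voxel_size,
                 truth = truth, membranes = membranes,
                 wedge_applied = wedge_applied, tilt_range = tilt_range),
            class = "tomo_volume")
}

# Add a soft-edged homogeneous ball to a volume in place-ish fashion.
# Edge antialiasing: the voxel value ramps linearly over one voxel width.
add_ball <- function(density, center, radius, contrast, voxel) {
  d <- dim(density)
  idx <- lapply(1:3, function(a) {
    lo <- max(1L, floor(center[a] / voxel - radius / voxel) )
    hi <- min(d[a], ceiling(center[a] / voxel + radius / voxel) + 2L)
    lo:hi
  })
  if (any(vapply(idx, length, integer(1)) == 0)) return(density)
  xs <- (idx[[1]] - 1) * voxel - center[1]
  ys <- (idx[[2]] - 1) * voxel - center[2]
  zs <- (idx[[3]] - 1) * voxel - center[3]
  dist <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  patch <- contrast * pmin(1, pmax(0, (radius - dist) / voxel + 0.5))
  density[idx[[1]], idx[[2]], idx[[3]]] <-
    density[idx[[1]], idx[[2]], idx[[3]]] + patch
  density
}

#' Generate a synthetic tomogram with ground truth
#'
#' Places monomers and dimers at uniform-random positions and (for
#' dimers) uniform-random 3D orientations inside the volume, honouring a
#' minimum center-to-center distance by rejection sampling. Optional
#' membrane slabs are two parallel high-density sheets perpendicular to
#' z whose mid-planes are `cleft_width` apart; particle placement is
#' restricted to the cleft between them when requested. Additive
#' Gaussian noise brings the peak particle density to the spec's SNR.
#' Truth is recorded before any degradation; if a tilt range is present
#' in the spec the missing wedge is applied afterwards.
#'
#' @param spec A `scene_spec` with a length-3 `shape`.
#' @param retry_cap Placement retries per particle before giving up
#'   (default 1000).
#' @return A `tomo_volume`; its `truth` is a data frame with columns
#'   id, class, x, y, z, axis_x, axis_y, axis_z, separation (Angstrom).
#' @export
generate_tomogram <- function(spec, retry_cap = 1000L) {
  stopifnot(inherits(spec, "scene_spec"), length(spec$shape) == 3)
  set.seed(spec$seed)
  d <- spec$shape
  voxel <- spec$pixel_size
  extent <- (d - 1) * voxel
  density <- array(0, dim = d)

  membranes <- NULL
  zlim <- c(0, extent[3])
  if (!is.null(spec$membrane_pair)) {
    cleft <- spec$membrane_pair$cleft_width %||% 280
    thick <- spec$membrane_pair$thickness %||% 50
    mcontrast <- spec$membrane_pair$contrast %||% (spec$contrast / 2)
    zmid <- extent[3] / 2
    zplanes <- c(zmid - cleft / 2, zmid + cleft / 2)
    zs <- (seq_len(d[3]) - 1) * voxel
    for (zp in zplanes) {
      sel <- abs(zs - zp) <= thick / 2
      density[, , sel] <- density[, , sel] + mcontrast
    }
    membranes <- list(
      presynaptic = membrane_plane(c(0, 0, zplanes[2]), c(0, 0, 1)),
      postsynaptic = membrane_plane(c(0, 0, zplanes[1]), c(0, 0, 1))
    )
    if (isTRUE(spec$membrane_pair$restrict_to_cleft)) {
      zlim <- c(zplanes[1] + thick / 2, zplanes[2] - thick / 2)
    }
  }

  n <- spec$n_particles
  classes <- ifelse(stats::runif(n) < spec$dimer_fraction, "dimer", "monomer")
  truths <- list()
  centers <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    sep <- if (classes[i] == "dimer") draw_separation(spec) else 0
    margin <- spec$monomer_radius + sep / 2
    placed <- FALSE
    for (try in seq_len(retry_cap)) {
      cand <- c(stats::runif(1, margin, extent[1] - margin),
                stats::runif(1, margin, extent[2] - margin),
                stats::runif(1, max(margin, zlim[1] + margin),
                             min(extent[3] - margin, zlim[2] - margin)))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= spec$min_center_distance) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place particle %d of %d under min_center_distance = %g (placed %d)",
                   i, n, spec$min_center_distance, nrow(centers)))
    }
    centers <- rbind(centers, cand)
    truths[[i]] <- if (classes[i] == "dimer") {
      particle_truth(i, "dimer", cand, axis = drop(random_unit_vectors(1)),
                     separation = sep)
    } else {
      particle_truth(i, "monomer", cand)
    }
  }

  render_scene(spec, truths, density = density, membranes = membranes)
}

#' Render a volume from an explicit list of truth records
#'
#' Draws every particle in `truths` into a fresh (or supplied) density
#' array, adds Gaussian noise at the spec's SNR, and applies the spec's
#' missing wedge if present. Used by [generate_tomogram()] after
#' placement and directly by evaluation harnesses that need controlled
#' geometries.
#'
#' @param spec A `scene_spec` with a length-3 `shape`.
#' @param truths List of `particle_truth` records.
#' @param density Optional pre-filled density array (e.g. membranes).
#' @param membranes Optional membrane list to attach.
#' @return A `tomo_volume`.
#' @export
render_scene <- function(spec, truths, density = NULL, membranes = NULL) {
  stopifnot(inherits(spec, "scene_spec"), length(spec$shape) == 3)
  d <- spec$shape
  voxel <- spec$pixel_size
  if (is.null(density)) density <- array(0, dim = d)
  for (t in truths) {
    if (t$class == "dimer") {
      density <- add_ball(density, t$center + t$separation / 2 * t$axis,
                          spec$monomer_radius, spec$contrast, voxel)
      density <- add_ball(density, t$center - t$separation / 2 * t$axis,
                          spec$monomer_radius, spec$contrast, voxel)
    } else {
      density <- add_ball(density, t$center, spec$monomer_radius,
                          spec$contrast, voxel)
    }
  }
  if (is.finite(spec$snr)) {
    density <- density + array(stats::rnorm(length(density),
                                            sd = spec$contrast / spec$snr), dim = d)
  }
  vol <- tomo_volume(density, voxel, truth = truth_table(truths),
                     membranes = membranes)
  if (!is.null(spec$tilt_range)) {
    vol <- apply_missing_wedge(vol, spec$tilt_range[1], spec$tilt_range[2])
  }
  vol
}

# Binary missing-wedge mask over the (kx, kz) frequency plane for a tilt
# series about the y axis: a frequency direction is sampled iff its angle
# in the xz plane (folded to (-90, 90]) lies within the tilt range.
wedge_mask_xz <- function(nx, nz, tilt_min, tilt_max) {
  kx <- fft_freq(nx)
  kz <- fft_freq(nz)
  ang <- atan2(rep(kz, each = nx), rep(kx, times = nz)) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  keep <- (ang >= tilt_min - 1e-9) & (ang <= tilt_max + 1e-9)
  keep[rep(kx == 0, times = nz) & rep(kz == 0, each = nx)] <- TRUE
  matrix(keep, nx, nz)
}

#' Apply a Fourier missing-wedge mask to a volume
#'
#' Limited tilt ranges leave a double wedge of Fourier space unsampled
#' (rotation about the tilt axis, here y). Coefficients outside the
#' sampled wedge are set to zero; the mask is Hermitian-symmetric so the
#' output is real. The result shows the familiar anisotropy: point
#' responses elongate along z and density features normal to the xy
#' plane blur.
#'
#' @param volume A `tomo_volume` (or bare 3D array).
#' @param tilt_min,tilt_max Tilt range in degrees, -90 <= min < max <= 90.
#' @return Same type as `volume`, with `wedge_applied`/`tilt_range` set.
#' @export
apply_missing_wedge <- function(volume, tilt_min, tilt_max) {
  if (!(tilt_min < tilt_max)) stop("tilt_min must be strictly below tilt_max")
  if (tilt_min < -90 || tilt_max > 90) stop("tilt range must lie within [-90, 90]")
  arr <- if (inherits(volume, "tomo_volume")) volume$density else volume
  d <- dim(arr)
  mask2d <- wedge_mask_xz(d[1], d[3], tilt_min, tilt_max)
  mask <- aperm(array(rep(mask2d, d[2]), dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  out <- Re(fft(fft(arr) * mask, inverse = TRUE)) / length(arr)
  if (inherits(volume, "tomo_volume")) {
    volume$density <- out
    volume$wedge_applied <- TRUE
    volume$tilt_range <- c(tilt_min, tilt_max)
    volume
  } else {
    out
  }
}
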