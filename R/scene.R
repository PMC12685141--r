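# Scene specification and ground-truth containers for synthetic data.

#' Scene specification for synthetic 2D/3D label data
#'
#' Collects every generative parameter used by the synthetic projection,
#' class-average and tomogram generators. Lengths are in Angstrom
#' throughout; array indices are 0-based in physical conversions
#' (coordinate = index * pixel/voxel size).
#'
#' @param pixel_size Angstrom per pixel/voxel (> 0).
#' @param shape Integer extents: length 2 (images) or 3 (volumes).
#' @param n_particles Number of particles to place in a scene.
#' @param monomer_fraction,dimer_fraction Mixture fractions (sum to 1).
#'   The default 1:2 monomer:dimer molar mixture mirrors the benchmark
#'   discrimination experiment.
#' @param monomer_radius Sphere radius, Angstrom (default 13.2, the 20%
#'   intensity-cutoff radius adopted as the monomer radius).
#' @param dimer_separation_mean,dimer_separation_sd Center-to-center
#'   separation distribution of dimers, Angstrom (default 34.8 +/- 3.6).
#' @param dimer_separation_range Truncation bounds for drawn separations
#'   (default c(26, 46), the support of the measured histogram).
#' @param snr Signal-to-noise ratio: peak noiseless particle intensity
#'   divided by the noise standard deviation. `Inf` disables noise.
#' @param contrast Peak density of a particle (arbitrary units).
#' @param tilt_range Optional length-2 tilt range in degrees for
#'   missing-wedge degradation (e.g. c(-48, 48)), or NULL.
#' @param membrane_pair Optional list with `cleft_width` (Angstrom) and
#'   logical `restrict_to_cleft`; generates two parallel membrane slabs
#'   perpendicular to z separated by `cleft_width` (default ~280 Angstrom,
#'   the synaptic cleft scale, when enabled).
#' @param min_center_distance Minimum distance between particle centers
#'   during placement, Angstrom.
#' @param seed Integer seed threaded through all randomness.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(pixel_size = 10, shape = c(64L, 64L, 64L),
                       n_particles = 20L,
                       monomer_fraction = 1 / 3, dimer_fraction = 2 / 3,
                       monomer_radius = 13.2,
                       dimer_separation_mean = 34.8,
                       dimer_separation_sd = 3.6,
                       dimer_separation_range = c(26, 46),
                       snr = 5, contrast = 1,
                       tilt_range = NULL, membrane_pair = NULL,
                       min_center_distance = 60, seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (monomer_fraction < 0 || dimer_fraction < 0 ||
      abs(monomer_fraction + dimer_fraction - 1) > 1e-9) {
    stop("mixture fractions must be non-negative and sum to 1")
  }
  if (dimer_separation_mean <= 0) stop("dimer_separation_mean must be positive")
  if (!is.null(tilt_range)) {
    if (length(tilt_range) != 2 || tilt_range[1] >= tilt_range[2]) {
      stop("tilt_range must be c(min, max) with min < max")
    }
  }
  if (snr <= 0) stop("snr must be positive")
  if (min_center_distance < 0) stop("min_center_distance must be >= 0")
  structure(
    list(
      pixel_size = pixel_size, shape = as.integer(shape),
      n_particles = as.integer(n_particles),
      monomer_fraction = monomer_fraction, dimer_fraction = dimer_fraction,
      monomer_radius = monomer_radius,
      dimer_separation_mean = dimer_separation_mean,
      dimer_separation_sd = dimer_separation_sd,
      dimer_separation_range = dimer_separation_range,
      snr = snr, contrast = contrast,
      tilt_range = tilt_range, membrane_pair = membrane_pair,
      min_center_distance = min_center_distance, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Ground-truth record for one particle
#'
#' @param id Integer identifier.
#' @param class `"monomer"` or `"dimer"`.
#' @param center Numeric coordinates in Angstrom (length 2 or 3).
#' @param axis Unit vector of the dumbbell axis (dimers; length matches
#'   `center`, normalized internally).
#' @param separation Center-to-center separation in Angstrom (dimers).
#' @return An object of class `particle_truth`.
#' @export
particle_truth <- function(id, class = c("monomer", "dimer"), center,
                           axis = NULL, separation = NA_real_) {
  class <- match.arg(class)
  if (class == "dimer") {
    # separation 0 (coincident spheres) is a valid degenerate case
    if (is.null(axis) || !is.finite(separation) || separation < 0) {
      stop("dimers need an axis and a non-negative separation")
    }
    axis <- axis / sqrt(sum(axis^2))
  }
  structure(list(id = id, class = class, center = center,
                 axis = axis, separation = separation),
            class = "particle_truth")
}

# Flatten a list of particle_truth records into the canonical truth table
# (columns id, class, x, y, z, axis_x, axis_y, axis_z, separation).
truth_table <- function(truths) {
  if (!length(truths)) {
    return(data.frame(id = integer(), class = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
                      separation = numeric()))
  }
  do.call(rbind, lapply(truths, function(t) {
    cen <- c(t$center, rep(NA_real_, 3 - length(t$center)))
    ax <- if (is.null(t$axis)) rep(NA_real_, 3) else
      c(t$axis, rep(NA_real_, 3 - length(t$axis)))
    data.frame(id = t$id, class = t$class,
               x = cen[1], y = cen[2], z = cen[3],
               axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
               separation = t$separation)
  }))
}

#' Write/read a scene specification as YAML
#'
#' @param spec A `scene_spec`.
#' @param path File path.
#' @return `read_scene_spec` returns a `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 15L)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scene_spec))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown scene_spec fields: ", paste(unknown, collapse = ", "))
  }
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!is.null(vals$tilt_range)) vals$tilt_range <- unlist(vals$tilt_range)
  if (!is.null(vals$dimer_separation_range)) {
    vals$dimer_separation_range <- unlist(vals$dimer_separation_range)
  }
  do.call(scene_spec, vals)
}
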