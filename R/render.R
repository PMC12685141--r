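# Noiseless 2D projections of spheres/dumbbells and noisy class averages.

# Draw one separation from the truncated normal distribution of the spec.
draw_separation <- function(spec) {
  lo <- spec$dimer_separation_range[1]
  hi <- spec$dimer_separation_range[2]
  repeat {
    s <- stats::rnorm(1, spec$dimer_separation_mean, spec$dimer_separation_sd)
    if (s >= lo && s <= hi) return(s)
  }
}

#' Render a noiseless projection of a monomer or dimer
#'
#' A homogeneous sphere of radius R projects to a disc whose intensity at
#' in-plane distance rho from the center is the chord length
#' 2 sqrt(R^2 - rho^2) (times the density contrast); a dimer is the sum
#' of two such discs displaced by +/- separation/2 along the in-plane
#' projection of the dumbbell axis. The integrated image intensity of a
#' monomer therefore equals the analytic ball volume (4/3) pi R^3 times
#' contrast, up to pixel discretization.
#'
#' @param truth A `particle_truth`; its `center` is in Angstrom with the
#'   convention coordinate = (index - 1) * pixel_size.
#' @param spec A `scene_spec` (uses `pixel_size`, `shape` (first two
#'   extents), `monomer_radius`, `contrast`).
#' @return Numeric H x W matrix.
#' @export
render_projection <- function(truth, spec) {
  stopifnot(inherits(truth, "particle_truth"), inherits(spec, "scene_spec"))
  R <- spec$monomer_radius
  if (R <= 0) stop("monomer_radius must be positive")
  h <- spec$shape[1]; w <- spec$shape[2]
  px <- spec$pixel_size
  xs <- (seq_len(h) - 1) * px
  ys <- (seq_len(w) - 1) * px
  img <- matrix(0, h, w)
  add_disc <- function(cx, cy) {
    dx2 <- (xs - cx)^2
    dy2 <- (ys - cy)^2
    rho2 <- outer(dx2, dy2, "+")
    img <<- img + spec$contrast * 2 * sqrt(pmax(0, R^2 - rho2))
  }
  if (truth$class == "monomer") {
    add_disc(truth$center[1], truth$center[2])
  } else {
    ax <- truth$axis
    # in-plane projection of the 3D dumbbell axis
    off <- truth$separation / 2 * ax[1:2]
    add_disc(truth$center[1] + off[1], truth$center[2] + off[2])
    add_disc(truth$center[1] - off[1], truth$center[2] - off[2])
  }
  img
}

#' Class-average container
#'
#' @param image H x W intensity matrix.
#' @param pixel_size Angstrom per pixel.
#' @param n_particles Number of particle images behind the average (>= 1).
#' @param truth Optional `particle_truth` shared by the averaged images.
#' @return An object of class `class_average`.
#' @export
class_average <- function(image, pixel_size, n_particles = 1L, truth = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (any(!is.finite(image))) stop("intensities must be finite")
  structure(list(image = image, pixel_size = pixel_size,
                 n_particles = as.integer(n_particles), truth = truth),
            class = "class_average")
}

#' Generate a synthetic 2D class average with known truth
#'
#' Averages `n_particles` noisy renders that share a single truth
#' geometry (the alignment step of real 2D classification is assumed
#' perfect, so averaging n independent Gaussian noise fields is carried
#' out as one field scaled by 1/sqrt(n), which is identical in
#' distribution). The per-image noise SD is peak noiseless intensity
#' divided by `spec$snr`. The particle is centered on the image midpoint
#' and, for dimers, the dumbbell axis lies in-plane at a random angle
#' with separation drawn from the spec's truncated normal.
#'
#' @param spec A `scene_spec`.
#' @param n_particles Number of contributing particle images (>= 1).
#' @param class `"monomer"` or `"dimer"` (default follows a draw from the
#'   spec's mixture fractions).
#' @param truth Optional `particle_truth` to use instead of drawing one.
#' @return A `class_average` with the generating truth attached.
#' @export
generate_class_average <- function(spec, n_particles,
                                   class = NULL, truth = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (is.null(truth)) {
    if (is.null(class)) {
      class <- if (stats::runif(1) < spec$dimer_fraction) "dimer" else "monomer"
    }
    center <- (spec$shape[1:2] - 1) / 2 * spec$pixel_size
    truth <- if (class == "dimer") {
      theta <- stats::runif(1, 0, 2 * pi)
      particle_truth(1L, "dimer", center,
                     axis = c(cos(theta), sin(theta), 0),
                     separation = draw_separation(spec))
    } else {
      particle_truth(1L, "monomer", center)
    }
  }
  img <- render_projection(truth, spec)
  if (is.finite(spec$snr)) {
    noise_sd <- max(img) / spec$snr / sqrt(n_particles)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img))
  }
  class_average(img, spec$pixel_size, n_particles, truth)
}

#' Generate a set of class averages from one scene specification
#'
#' Seeds the generator from `spec$seed` and draws `n_classes` class
#' averages, each backed by `particles_per_class` particle images.
#'
#' @param spec A `scene_spec`.
#' @param n_classes Number of classes (default 20, the classification
#'   depth used for the separation histogram).
#' @param particles_per_class Particle count per class.
#' @param class Optional fixed class for all averages.
#' @return List of `class_average` objects.
#' @export
generate_class_set <- function(spec, n_classes = 20L,
                               particles_per_class = 1000L, class = NULL) {
  set.seed(spec$seed)
  lapply(seq_len(n_classes), function(i) {
    generate_class_average(spec, particles_per_class, class = class)
  })
}
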