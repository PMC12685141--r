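# Class-average metrology: recentering, radial profiles, cutoff radii.

# Median of a 2-pixel border frame; the background estimate subtracted
# before any intensity-weighted computation.
border_median <- function(img, width = 2L) {
  d <- dim(img)
  sel <- matrix(FALSE, d[1], d[2])
  sel[c(seq_len(width), d[1] - seq_len(width) + 1L), ] <- TRUE
  sel[, c(seq_len(width), d[2] - seq_len(width) + 1L)] <- TRUE
  stats::median(img[sel])
}

# Background-subtracted, floored-at-zero copy of a class-average image.
prepare_image <- function(img) {
  pmax(img - border_median(img), 0)
}

# Intensity-weighted centroid in pixel units (1-based indices).
centroid_px <- function(img) {
  tot <- sum(img)
  if (tot <= 0) stop("image has no positive intensity after background removal")
  c(sum(row(img) * img), sum(col(img) * img)) / tot
}

#' Recenter a class average on its intensity centroid
#'
#' Shifts the image (subpixel, via Fourier phase) so that the
#' intensity-weighted centroid of the background-subtracted,
#' floored-at-zero image coincides with the geometric image center
#' within `tol` pixels. Errors when the image carries no reliable
#' centroid (all-zero, or indistinguishable from border noise).
#'
#' @param ca A `class_average`.
#' @param tol Convergence tolerance in pixels (default 0.01).
#' @param max_iter Iteration cap (default 20).
#' @return The recentered `class_average`.
#' @export
recenter <- function(ca, tol = 0.01, max_iter = 20L) {
  stopifnot(inherits(ca, "class_average"))
  img <- ca$image
  if (any(!is.finite(img))) stop("image must be finite")
  work <- prepare_image(img)
  if (sum(work) <= 0) stop("image has no positive intensity after background removal")
  noise <- stats::mad(img[row(img) <= 2 | row(img) >= nrow(img) - 1])
  if (max(work) <= 5 * noise) {
    stop("no reliable centroid: signal does not rise above border noise")
  }
  target <- (dim(img) + 1) / 2
  for (i in seq_len(max_iter)) {
    cen <- centroid_px(prepare_image(img))
    shift <- target - cen
    if (max(abs(shift)) < tol) break
    img <- fourier_shift2d(img, shift[1], shift[2])
  }
  ca$image <- img
  ca
}

#' Radial intensity profile of (weighted) class averages
#'
#' Computes annular mean intensities (annulus width one pixel) about the
#' geometric image center for each class average, averages them weighted
#' by the per-class particle counts, and normalizes the profile to a
#' maximum of 1. The profile is reported as measured; no monotonicity is
#' imposed.
#'
#' @param class_averages A `class_average` or list of them, already
#'   recentered and sharing one pixel size.
#' @param weights Optional particle-count weights (default: each class's
#'   `n_particles`).
#' @return An object of class `radial_profile`: list with `radii`
#'   (Angstrom, annulus centers starting at 0), `mean_intensity`
#'   (max-normalized), `n_particles`.
#' @export
radial_profile <- function(class_averages, weights = NULL) {
  if (inherits(class_averages, "class_average")) {
    class_averages <- list(class_averages)
  }
  stopifnot(all(vapply(class_averages, inherits, logical(1), "class_average")))
  px <- vapply(class_averages, `[[`, numeric(1), "pixel_size")
  if (diff(range(px)) > 1e-9) stop("class averages must share one pixel size")
  px <- px[1]
  if (is.null(weights)) {
    weights <- vapply(class_averages, `[[`, integer(1), "n_particles")
  }
  stopifnot(length(weights) == length(class_averages))

  profiles <- lapply(class_averages, function(ca) {
    img <- prepare_image(ca$image)
    ctr <- (dim(img) + 1) / 2
    dist <- sqrt((row(img) - ctr[1])^2 + (col(img) - ctr[2])^2)
    ann <- floor(dist + 0.5)
    means <- tapply(img, ann, mean)
    # index annuli by their radius so an empty central annulus (center
    # between pixels) cannot shift the radial axis
    out <- rep(NA_real_, max(ann) + 1L)
    out[as.integer(names(means)) + 1L] <- means
    out
  })
  n_ann <- min(vapply(profiles, length, integer(1)))
  mat <- vapply(profiles, function(p) p[seq_len(n_ann)], numeric(n_ann))
  mat <- matrix(mat, nrow = n_ann)
  if (anyNA(mat[1, ])) mat[1, ] <- mat[2, ]  # empty r = 0 annulus
  prof <- drop(mat %*% weights) / sum(weights)
  prof <- prof / max(prof)
  structure(
    list(radii = (seq_len(n_ann) - 1) * px, mean_intensity = prof,
         n_particles = sum(weights)),
    class = "radial_profile"
  )
}

#' Cutoff radii and diameters from a radial profile
#'
#' For each intensity fraction f, finds the outermost radius where the
#' (max-normalized) profile crosses f on its descending outer branch, by
#' linear interpolation between bracketing annuli; the corresponding
#' operational diameter is 2 r_f.
#'
#' @param profile A `radial_profile`.
#' @param fractions Intensity fractions (default c(0.5, 0.2, 0.1)).
#' @return An object of class `cutoff_diameters`: list with `r` and `d`
#'   (named numeric vectors, Angstrom).
#' @examples
#' # a noiseless projected sphere of radius R crosses fraction f at
#' # r = R * sqrt(1 - f^2)
#' @export
cutoff_radii <- function(profile, fractions = c(0.5, 0.2, 0.1)) {
  stopifnot(inherits(profile, "radial_profile"))
  p <- profile$mean_intensity
  r <- profile$radii
  rf <- vapply(fractions, function(f) {
    above <- which(p >= f)
    if (!length(above)) stop(sprintf("profile never reaches fraction %g", f))
    i <- max(above)
    if (i == length(p)) stop(sprintf("profile never falls below fraction %g", f))
    # linear interpolation between annulus i (>= f) and i+1 (< f)
    r[i] + (p[i] - f) / (p[i] - p[i + 1]) * (r[i + 1] - r[i])
  }, numeric(1))
  names(rf) <- paste0("r", round(100 * fractions))
  d <- 2 * rf
  names(d) <- paste0("d", round(100 * fractions))
  structure(list(r = rf, d = d, fractions = fractions),
            class = "cutoff_diameters")
}

#' @export
print.cutoff_diameters <- function(x, ...) {
  cat("Cutoff radii (Angstrom):\n")
  for (i in seq_along(x$r)) {
    cat(sprintf("  %d%%: r = %.2f, diameter = %.2f\n",
                round(100 * x$fractions[i]), x$r[i], x$d[i]))
  }
  invisible(x)
}
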