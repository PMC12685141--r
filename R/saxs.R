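# SAXS forward models: homogeneous sphere and two-sphere dimer.

#' SAXS profile container
#'
#' @param q Scattering vector grid, 1/Angstrom, strictly increasing, > 0
#'   (q = 0 is tolerated and handled by analytic limits in the models).
#' @param intensity Intensities, arbitrary units.
#' @param sigma Optional per-point uncertainties.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(q < 0)) stop("q must be non-negative")
  if (length(intensity) != length(q)) stop("q and intensity lengths differ")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (!is.null(sigma) && (length(sigma) != length(q) || any(sigma <= 0))) {
    stop("sigma must be positive and match q in length")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "saxs_profile")
}

#' Homogeneous (optionally core-shell) sphere model
#'
#' @param radius Core radius, Angstrom.
#' @param contrast Core electron-density contrast, arbitrary units.
#' @param shell_thickness Optional concentric shell thickness, Angstrom
#'   (0 disables the shell).
#' @param shell_contrast Shell contrast (used only if shell_thickness > 0).
#' @return An object of class `sphere_model`.
#' @export
sphere_model <- function(radius, contrast = 1, shell_thickness = 0,
                         shell_contrast = 0) {
  if (radius <= 0) stop("radius must be positive")
  if (shell_thickness < 0) stop("shell thickness must be >= 0")
  structure(
    list(radius = radius, contrast = contrast,
         shell_thickness = shell_thickness, shell_contrast = shell_contrast),
    class = "sphere_model"
  )
}

#' Two identical spheres at fixed center-to-center separation
#'
#' @param sphere A `sphere_model`.
#' @param separation Center-to-center distance, Angstrom (>= 0).
#' @return An object of class `dimer_model`.
#' @export
dimer_model <- function(sphere, separation) {
  stopifnot(inherits(sphere, "sphere_model"))
  if (separation < 0) stop("separation must be >= 0")
  structure(list(sphere = sphere, separation = separation),
            class = "dimer_model")
}

# Normalized sphere form-factor kernel Phi(x) = 3(sin x - x cos x)/x^3,
# with Phi(0) = 1. First zero at x ~ 4.493.
sphere_phi <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- 3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3
  out
}

# Scattering amplitude of a (core-shell) sphere: contrast-weighted sum of
# ball amplitudes, A(q) -> contrast * V as q -> 0.
sphere_amplitude <- function(model, q) {
  R <- model$radius
  V <- (4 / 3) * pi * R^3
  amp <- model$contrast * V * sphere_phi(q * R)
  if (model$shell_thickness > 0) {
    Ro <- R + model$shell_thickness
    Vo <- (4 / 3) * pi * Ro^3
    amp <- amp + model$shell_contrast * (Vo * sphere_phi(q * Ro) - V * sphere_phi(q * R))
  }
  amp
}

#' Sphere scattering intensity
#'
#' I(q) = A(q)^2 with A the sphere (or core-shell) amplitude; the forward
#' limit is I(0) = (contrast * V)^2 for a bare sphere.
#'
#' @param model A `sphere_model`.
#' @param q Scattering vector grid, 1/Angstrom.
#' @return A `saxs_profile`.
#' @examples
#' p <- sphere_intensity(sphere_model(12.5), seq(0.01, 0.5, by = 0.002))
#' @export
sphere_intensity <- function(model, q) {
  stopifnot(inherits(model, "sphere_model"))
  saxs_profile(q, sphere_amplitude(model, q)^2)
}

#' Orientation-averaged dimer scattering intensity
#'
#' For two identical spheres at center-to-center distance d, the
#' orientation average of the interference term gives
#' I(q) = 2 I_sphere(q) [1 + sin(qd)/(qd)]; at q -> 0 this is
#' 4 I_sphere(0), i.e. elevated forward scattering relative to the
#' monomer (per particle pair).
#'
#' @param model A `dimer_model`.
#' @param q Scattering vector grid, 1/Angstrom.
#' @return A `saxs_profile`.
#' @export
dimer_intensity <- function(model, q) {
  stopifnot(inherits(model, "dimer_model"))
  isph <- sphere_amplitude(model$sphere, q)^2
  d <- model$separation
  interference <- rep(1, length(q))
  if (d > 0) {
    nz <- q * d > 1e-8
    interference[nz] <- sin(q[nz] * d) / (q[nz] * d)
  }
  saxs_profile(q, 2 * isph * (1 + interference))
}

#' Guinier analysis of the low-q region
#'
#' Linear fit of ln I against q^2 over a q window; the slope gives
#' R_g = sqrt(-3 * slope) and the intercept I_0 = exp(intercept). Valid
#' only while q * R_g is small; a warning is emitted when the fitted R_g
#' implies max(q) * R_g > `qrg_limit` in the chosen window.
#'
#' @param profile A `saxs_profile`.
#' @param q_window Numeric length-2: q range to fit over.
#' @param qrg_limit Validity bound on q * R_g (default 1.3).
#' @return List with `rg`, `i0`, `qrg_max`, `n_points`.
#' @export
guinier_fit <- function(profile, q_window, qrg_limit = 1.3) {
  stopifnot(inherits(profile, "saxs_profile"), length(q_window) == 2)
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2]
  if (sum(sel) < 3) stop("q window contains fewer than 3 points")
  I <- profile$intensity[sel]
  if (any(I <= 0)) stop("non-positive intensities in the Guinier window")
  q2 <- profile$q[sel]^2
  fit <- stats::lm(log(I) ~ q2)
  slope <- unname(stats::coef(fit)[2])
  rg <- if (slope < 0) sqrt(-3 * slope) else 0
  if (slope >= 0) warning("non-negative Guinier slope; R_g reported as 0")
  qrg_max <- max(profile$q[sel]) * rg
  if (rg > 0 && qrg_max > qrg_limit) {
    warning(sprintf("Guinier validity bound exceeded: max(q)*Rg = %.2f > %.2f",
                    qrg_max, qrg_limit))
  }
  list(rg = rg, i0 = exp(unname(stats::coef(fit)[1])),
       qrg_max = qrg_max, n_points = sum(sel))
}

#' Read a SAXS profile from a whitespace- or comma-delimited table
#'
#' Columns: q, intensity and optionally sigma; lines starting with `#`
#' are skipped.
#'
#' @param path File path.
#' @return A `saxs_profile`.
#' @export
read_saxs <- function(path) {
  first <- grep("^\\s*#", readLines(path, n = 20), value = TRUE, invert = TRUE)[1]
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "[,\\s]+")[[1]][1])))
  tab <- utils::read.table(path, sep = sep, comment.char = "#",
                           header = has_header, fill = TRUE)
  sigma <- if (ncol(tab) >= 3 && !all(is.na(tab[[3]]))) tab[[3]] else NULL
  saxs_profile(tab[[1]], tab[[2]], sigma)
}

#' Write a SAXS profile as a 3-column CSV
#'
#' @param profile A `saxs_profile`.
#' @param path Output path.
#' @export
write_saxs <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  df <- data.frame(q = profile$q, intensity = profile$intensity,
                   sigma = profile$sigma %||% NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
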