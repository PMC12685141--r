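#' Volume of a spherical nanoparticle
#'
#' Computes V = (4/3) pi r^3 in cubic nanometres. Used to compare the
#' steric footprint of label designs: two linked 1.3 nm-radius particles
#' occupy far less volume than a single 2.5 nm or 5 nm-radius particle.
#'
#' @param radius Particle radius.
#' @param units Units of `radius`: `"nm"` (default) or `"angstrom"`.
#' @return Volume in nm^3.
#' @examples
#' sphere_volume(1.3)   # ~9.2 nm^3
#' sphere_volume(2.5)   # ~65.4 nm^3
#' @export
sphere_volume <- function(radius, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("radius must be positive and finite")
  }
  r_nm <- if (units == "angstrom") radius / 10 else radius
  (4 / 3) * pi * r_nm^3
}

#' Combined volume footprint of a multi-particle label
#'
#' @param n_particles Number of spheres in the label (>= 1).
#' @inheritParams sphere_volume
#' @return Total volume in nm^3.
#' @export
label_footprint <- function(n_particles, radius, units = c("nm", "angstrom")) {
  if (n_particles < 1) stop("n_particles must be >= 1")
  n_particles * sphere_volume(radius, units)
}

#' Dimer gap and end-to-end geometry
#'
#' From a center-to-center separation d and a monomer diameter D, derives
#' the surface-to-surface gap (d - D) that the dithiol linkers must bridge
#' and the end-to-end extent (d + D) of the dumbbell.
#'
#' @param separation Center-to-center separation d, in Angstrom.
#' @param monomer_diameter Monomer diameter D, in Angstrom.
#' @return An object of class `dimer_geometry`: list with `separation`,
#'   `monomer_diameter`, `gap`, `end_to_end` (all Angstrom).
#' @examples
#' dimer_geometry(40, 26.4)  # gap 13.6 A, end-to-end 66.4 A
#' @export
dimer_geometry <- function(separation, monomer_diameter) {
  stopifnot(separation >= 0, monomer_diameter > 0)
  structure(
    list(
      separation = separation,
      monomer_diameter = monomer_diameter,
      gap = separation - monomer_diameter,
      end_to_end = separation + monomer_diameter
    ),
    class = "dimer_geometry"
  )
}

#' Interparticle gap of a dimer
#'
#' @param geometry A `dimer_geometry` object.
#' @return Gap in Angstrom (surface-to-surface, assuming hard spheres).
#' @export
interparticle_gap <- function(geometry) {
  stopifnot(inherits(geometry, "dimer_geometry"))
  geometry$gap
}

#' Dithiol linker model
#'
#' A biphenyl dithiol's S-S span depends on the biphenyl torsion angle phi:
#' maximal at phi = 0 (coplanar rings) and minimal at phi = 90.
#'
#' @param length_at_phi0 S-S span at phi = 0 deg, Angstrom (default 10.6).
#' @param length_at_phi90 S-S span at phi = 90 deg, Angstrom (default 7.5).
#' @param n_linkers Number of linkers joined in series.
#' @param joint_flexible Whether inter-linker joints rotate freely.
#' @return An object of class `linker_model`.
#' @export
linker_model <- function(length_at_phi0 = 10.6, length_at_phi90 = 7.5,
                         n_linkers = 1L, joint_flexible = TRUE) {
  if (length_at_phi90 > length_at_phi0) {
    stop("length_at_phi90 must not exceed length_at_phi0")
  }
  if (n_linkers < 1) stop("n_linkers must be >= 1")
  structure(
    list(
      length_at_phi0 = length_at_phi0,
      length_at_phi90 = length_at_phi90,
      n_linkers = as.integer(n_linkers),
      joint_flexible = isTRUE(joint_flexible)
    ),
    class = "linker_model"
  )
}

#' Single-linker span at a torsion angle
#'
#' Smooth interpolation L(phi) = sqrt(L90^2 + (L0^2 - L90^2) cos^2 phi),
#' exact at both endpoints and monotone non-increasing on [0, 90] deg.
#' The functional form is a modelling choice; only the endpoints are
#' experimentally constrained.
#'
#' @param model A `linker_model`.
#' @param phi Torsion angle in degrees, in [0, 90].
#' @return Span in Angstrom.
#' @export
linker_span <- function(model, phi) {
  stopifnot(inherits(model, "linker_model"))
  if (any(phi < 0 | phi > 90)) stop("phi must lie in [0, 90] degrees")
  L0 <- model$length_at_phi0
  L90 <- model$length_at_phi90
  sqrt(L90^2 + (L0^2 - L90^2) * cos(phi * pi / 180)^2)
}

#' Can n linkers in series bridge a gap?
#'
#' Treats each linker as a rigid segment of adjustable length in
#' [L90, L0]; with freely rotating joints, n >= 2 segments can fold back
#' and reach any span from 0 up to n * L0, while a single segment is
#' confined to [L90, L0].
#'
#' @param gap Gap to bridge, Angstrom (>= 0).
#' @param model A `linker_model` (its `n_linkers` is used).
#' @return List with `feasible` (logical) and `reachable_interval`
#'   (numeric length-2, Angstrom).
#' @examples
#' bridge_feasible(13.6, linker_model(n_linkers = 1))$feasible  # FALSE
#' bridge_feasible(13.6, linker_model(n_linkers = 2))$feasible  # TRUE
#' @export
bridge_feasible <- function(gap, model) {
  stopifnot(inherits(model, "linker_model"), gap >= 0)
  n <- model$n_linkers
  lo <- if (n >= 2L && model$joint_flexible) 0 else model$length_at_phi90
  hi <- n * model$length_at_phi0
  list(
    feasible = gap >= lo && gap <= hi,
    reachable_interval = c(lo, hi)
  )
}

#' Label-to-membrane reach model
#'
#' One-dimensional normal-to-membrane model of how far the center of a
#' dimeric label can sit from the postsynaptic membrane when its Fab is
#' bound to an epitope at a fixed height. The shipping defaults are
#' calibrated so that the predicted interval is [110, 190] Angstrom; the
#' individual lengths are package calibrations, not measured quantities.
#'
#' @param epitope_height Height of the epitope above the membrane, Angstrom.
#' @param fab_reach_min,fab_reach_max Signed normal displacement the Fab
#'   linkage adds between epitope and label attachment point, Angstrom.
#' @param label_offset Distance from Fab attachment point to the dimer
#'   midpoint, Angstrom.
#' @param expected_pair_spacing Expected spacing between the two labels on
#'   a doubly labeled receptor, Angstrom.
#' @return An object of class `reach_model`.
#' @export
reach_model <- function(epitope_height = 135, fab_reach_min = -10,
                        fab_reach_max = 40, label_offset = 15,
                        expected_pair_spacing = 200) {
  if (fab_reach_min > fab_reach_max) stop("fab_reach_min must be <= fab_reach_max")
  if (epitope_height < 0 || label_offset < 0) stop("heights/offsets must be >= 0")
  structure(
    list(
      epitope_height = epitope_height,
      fab_reach_min = fab_reach_min,
      fab_reach_max = fab_reach_max,
      label_offset = label_offset,
      expected_pair_spacing = expected_pair_spacing
    ),
    class = "reach_model"
  )
}

#' Predicted distance range of a label center from the membrane
#'
#' Minimum: Fab folded toward the membrane with the label offset pointing
#' inward; maximum: extended away with the offset pointing outward. Both
#' clamped at zero.
#'
#' @param model A `reach_model`.
#' @return Numeric length-2: `c(min, max)` in Angstrom.
#' @export
reach_range <- function(model) {
  stopifnot(inherits(model, "reach_model"))
  lo <- model$epitope_height + model$fab_reach_min - model$label_offset
  hi <- model$epitope_height + model$fab_reach_max + model$label_offset
  c(max(0, lo), max(0, hi))
}

#' Is a measured distance within a reach interval?
#'
#' @param distance Distance in Angstrom.
#' @param range Numeric length-2 interval (closed).
#' @return Logical.
#' @export
in_reach <- function(distance, range) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  distance >= range[1] & distance <= range[2]
}
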