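#' Phantom specification for the cylindrical thorax model
#'
#' Describes the simulated thorax used throughout the package: a cylinder of
#' diameter 2 and height 0.8 (model units) carrying 16 circular electrodes
#' (diameter 0.1) centred at z = 0.4, two full-height lung cylinders
#' (diameter 0.8) and a full-height blood-target cylinder (default diameter
#' 0.1) placed at a radial offset along the direction of electrode 9. In the
#' \code{"internal"} arrangement an axial channel (diameter 0.1, the
#' oesophagus) replaces the location of electrode 16, whose patch then sits
#' on the channel wall.
#'
#' Electrode \eqn{\ell} is centred at angle \eqn{\theta_\ell = \pi/2 -
#' 2\pi(\ell-1)/16} in the (x, y) plane, so electrode 1 sits on the +y axis
#' and electrode 9 on the -y axis; the target moves along -y, between the two
#' lungs whose axes are at (\eqn{\pm}0.55, 0).
#'
#' @param arrangement `"external"` (all 16 electrodes on the outer wall) or
#'   `"internal"` (electrode 16 on the oesophageal channel wall).
#' @param boundary_diameter,boundary_height Boundary cylinder size, model units.
#' @param electrode_diameter Electrode disc diameter.
#' @param electrode_center_z Height of the electrode plane.
#' @param n_electrodes Number of electrodes (16).
#' @param internal_channel_diameter Diameter of the axial channel
#'   (internal arrangement only).
#' @param lung_diameter Diameter of each lung cylinder.
#' @param lung_center_offset Distance of each lung axis from the centre.
#' @param target_diameter Diameter of the blood-target cylinder.
#' @param target_offset Default radial offset of the target centre.
#' @param target_direction_electrode Electrode index towards which the target
#'   moves (9, i.e. the -y direction).
#' @param conductivities Named vector of tissue conductivities in S/m:
#'   `blood`, `lung`, `background`.
#' @param contact_impedance Electrode contact impedance z_c in Ohm m^2,
#'   applied to every electrode.
#' @param include_lungs Include the two lung cylinders? (`FALSE` gives a
#'   lung-free background, used by the voltage-profile experiment whose
#'   oversized perturbation would otherwise overlap the lungs.)
#'
#' @return An object of class `eit_phantom_spec`.
#' @export
phantom_spec <- function(arrangement = c("external", "internal"),
                         boundary_diameter = 2.0,
                         boundary_height = 0.8,
                         electrode_diameter = 0.1,
                         electrode_center_z = 0.4,
                         n_electrodes = 16L,
                         internal_channel_diameter = 0.1,
                         lung_diameter = 0.8,
                         lung_center_offset = 0.55,
                         target_diameter = 0.1,
                         target_offset = 0.5,
                         target_direction_electrode = 9L,
                         conductivities = c(blood = 0.7, lung = 0.13,
                                            background = 0.48),
                         contact_impedance = 1e-3,
                         include_lungs = TRUE) {
  arrangement <- match.arg(arrangement)
  stopifnot(boundary_diameter > 0, boundary_height > 0,
            electrode_diameter > 0, n_electrodes >= 4L,
            internal_channel_diameter > 0, lung_diameter > 0,
            target_diameter > 0, contact_impedance > 0,
            all(c("blood", "lung", "background") %in% names(conductivities)),
            all(conductivities > 0))
  spec <- structure(list(
    arrangement = arrangement,
    boundary_diameter = boundary_diameter,
    boundary_height = boundary_height,
    electrode_diameter = electrode_diameter,
    electrode_center_z = electrode_center_z,
    n_electrodes = as.integer(n_electrodes),
    internal_channel_diameter = internal_channel_diameter,
    lung_diameter = lung_diameter,
    lung_center_offset = lung_center_offset,
    target_diameter = target_diameter,
    target_offset = target_offset,
    target_direction_electrode = as.integer(target_direction_electrode),
    conductivities = conductivities,
    contact_impedance = contact_impedance,
    include_lungs = isTRUE(include_lungs)
  ), class = "eit_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @export
print.eit_phantom_spec <- function(x, ...) {
  cat("EIT phantom spec:", x$arrangement, "arrangement,",
      x$n_electrodes, "electrodes\n")
  cat("  boundary D =", x$boundary_diameter, " H =", x$boundary_height,
      "; target D =", x$target_diameter, "at offset", x$target_offset, "\n")
  cat("  sigma [S/m]: blood", x$conductivities[["blood"]],
      " lung", x$conductivities[["lung"]],
      " background", x$conductivities[["background"]], "\n")
  invisible(x)
}

#' Angular position of an electrode centre
#'
#' @param spec An `eit_phantom_spec`.
#' @param l Electrode index (1-based).
#' @return Angle in radians in the (x, y) plane.
#' @keywords internal
electrode_angle <- function(spec, l) {
  pi / 2 - 2 * pi * (l - 1) / spec$n_electrodes
}

# Centre of the target cylinder at a given radial offset, in the direction of
# spec$target_direction_electrode (default -y).
target_center <- function(spec, offset = spec$target_offset) {
  a <- electrode_angle(spec, spec$target_direction_electrode)
  c(offset * cos(a), offset * sin(a))
}

lung_centers <- function(spec) {
  rbind(c(spec$lung_center_offset, 0), c(-spec$lung_center_offset, 0))
}

#' Validate a phantom specification
#'
#' Checks the geometric invariants: interior cylinders (lungs, target,
#' oesophageal channel) must be pairwise disjoint and lie strictly inside the
#' boundary cylinder.
#'
#' @param spec An `eit_phantom_spec`.
#' @param target_offset Radial target offset to validate (defaults to the
#'   spec's own).
#' @return The spec, invisibly. Errors on violation.
#' @export
validate_phantom_spec <- function(spec, target_offset = spec$target_offset) {
  R <- spec$boundary_diameter / 2
  r_t <- spec$target_diameter / 2
  r_l <- spec$lung_diameter / 2
  r_c <- spec$internal_channel_diameter / 2
  tc <- target_center(spec, target_offset)
  lc <- lung_centers(spec)
  if (target_offset < 0 || target_offset + r_t >= R)
    stop("target cylinder extends outside the boundary cylinder")
  if (spec$include_lungs) {
    if (spec$lung_center_offset + r_l >= R)
      stop("lung cylinders extend outside the boundary cylinder")
    d_tl <- sqrt(rowSums(sweep(lc, 2, tc)^2))
    if (any(d_tl <= r_t + r_l))
      stop("target cylinder intersects a lung cylinder")
  }
  if (spec$arrangement == "internal") {
    if (target_offset - r_t <= r_c)
      stop("target cylinder intersects the internal electrode channel")
    if (spec$include_lungs && spec$lung_center_offset - r_l <= r_c)
      stop("lung cylinders intersect the internal electrode channel")
  }
  invisible(spec)
}

#' Radial target positions of the position-sweep experiment
#'
#' The blood target is moved from 0.2 units from the cylinder centre in 0.1
#' unit increments out to 0.8 units, towards electrode 9.
#'
#' @param spec An `eit_phantom_spec` (unused beyond its class; the sweep is a
#'   fixed study design).
#' @return Numeric vector `c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)`.
#' @export
sweep_positions <- function(spec = phantom_spec()) {
  seq(0.2, 0.8, by = 0.1)
}
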