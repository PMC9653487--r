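# Per-state geometry of the transmembrane domain and the closed->open deltas
# that parameterise the gating-energetics model.
#
# The midplane bending angle is measured from TM-helix representative points:
# atoms inside the slab are split per chain into contiguous residue runs (one
# run per membrane crossing), each run is represented by its centroid, and z is
# regressed on radial distance r pooled over subunits. The angle is
# arctan|dz/dr| - the cone-like deflection the curved TMD imposes on the
# membrane midplane. Use a slab that covers the full TMD z-extent.

check_aligned <- function(s) {
  if (!isTRUE(attr(s, "frame_aligned"))) {
    abort("Structure must be frame-aligned (see align_to_axis())",
          class = "mechgate_frame_error")
  }
}

# TM-helix representative points: one centroid per contiguous residue run per
# chain among atoms inside the slab.
helix_midpoints <- function(s, slab, min_atoms = 5, max_resno_gap = 2) {
  check_aligned(s)
  inslab <- s[s$z >= slab$z_min & s$z <= slab$z_max, , drop = FALSE]
  if (nrow(inslab) == 0) {
    abort("No atoms inside the membrane slab", class = "mechgate_insufficient_data")
  }
  inslab |>
    arrange(.data$chain_id, .data$residue_number) |>
    group_by(.data$chain_id) |>
    mutate(segment = cumsum(c(1, pmax(0, diff(.data$residue_number)) > max_resno_gap))) |>
    group_by(.data$chain_id, .data$segment) |>
    summarise(n_atoms = n(),
              x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop") |>
    filter(.data$n_atoms >= min_atoms) |>
    mutate(r = sqrt(.data$x^2 + .data$y^2))
}

#' Midplane bending angle of the transmembrane domain
#'
#' Least-squares fit of z versus radial distance r over TM-helix midpoint
#' representative points pooled over subunits; the angle is `atan(|dz/dr|)`.
#' A curved (cone-shaped) TMD gives a positive angle; a flat TMD gives ~0.
#'
#' @param s A frame-aligned `channel_structure`.
#' @param slab A `membrane_slab` covering the TMD z-extent.
#' @return Angle in degrees.
#' @export
midplane_bending_angle <- function(s, slab) {
  pts <- helix_midpoints(s, slab)
  if (nrow(pts) < 4) {
    abort(paste0("Only ", nrow(pts), " TM-helix representative points; need >= 4"),
          class = "mechgate_insufficient_data")
  }
  slope <- coef(lm(z ~ r, data = pts))[["r"]]
  atan(abs(slope)) * 180 / pi
}

# shoelace polygon area
polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' In-plane radius and cross-sectional area at the membrane midplane
#'
#' Projects the atoms in a thin band around the slab midplane onto the x,y
#' plane and takes the area of their 2D convex hull; the effective in-plane
#' radius is `sqrt(A/pi)`.
#'
#' @param s A frame-aligned `channel_structure`.
#' @param slab A `membrane_slab`.
#' @param band Full width (A) of the midplane band (default 6).
#' @return A list with `R_nm` (effective radius, nm) and `area_nm2` (nm^2).
#' @export
inplane_radius_area <- function(s, slab, band = 6) {
  check_aligned(s)
  m <- abs(s$z - slab$z_mid) <= band / 2
  if (sum(m) < 3) {
    abort("Fewer than 3 atoms in the midplane band", class = "mechgate_insufficient_data")
  }
  x <- s$x[m]; y <- s$y[m]
  h <- grDevices::chull(x, y)
  area_A2 <- polygon_area(x[h], y[h])
  area_nm2 <- area_A2 / 100
  list(R_nm = sqrt(area_nm2 / pi), area_nm2 = area_nm2)
}

#' Height of the transmembrane domain
#'
#' Robust z-extent (2.5th-97.5th percentile span) of atoms inside the slab,
#' resistant to single-atom outliers.
#'
#' @inheritParams inplane_radius_area
#' @param probs Percentile pair defining the span.
#' @return Height in Angstrom.
#' @export
tmd_height <- function(s, slab, probs = c(0.025, 0.975)) {
  check_aligned(s)
  z <- s$z[s$z >= slab$z_min & s$z <= slab$z_max]
  if (length(z) == 0) {
    abort("No atoms inside the membrane slab", class = "mechgate_insufficient_data")
  }
  unname(diff(quantile(z, probs)))
}

#' Outer diameter of a residue-selection ring
#'
#' Twice the maximum radial distance of the selected atom centers from the
#' pore axis (outer diameter), e.g. of the periplasmic gating ring.
#'
#' @param s A frame-aligned `channel_structure`.
#' @param residues Residue numbers to select.
#' @param chains Optional chain filter.
#' @return Diameter in Angstrom.
#' @export
ring_diameter <- function(s, residues, chains = NULL) {
  check_aligned(s)
  m <- s$residue_number %in% residues
  if (!is.null(chains)) m <- m & s$chain_id %in% chains
  if (!any(m)) abort("Ring selection matches no atoms", class = "mechgate_selection_error")
  2 * max(sqrt(s$x[m]^2 + s$y[m]^2))
}

#' Measure the per-state geometry profile
#'
#' @param s A frame-aligned `channel_structure`.
#' @param slab A `membrane_slab`.
#' @param ring_residues Optional residue numbers of the periplasmic ring; if
#'   given, the ring outer diameter is reported.
#' @param band Midplane band width (A) for the in-plane area.
#' @return A one-row `geometry_profile` tibble: `theta_deg`, `R_nm`,
#'   `area_nm2`, `height_A`, `ring_diameter_A`.
#' @export
measure_geometry <- function(s, slab, ring_residues = NULL, band = 6) {
  ra <- inplane_radius_area(s, slab, band = band)
  out <- tibble(
    theta_deg = midplane_bending_angle(s, slab),
    R_nm = ra$R_nm,
    area_nm2 = ra$area_nm2,
    height_A = tmd_height(s, slab),
    ring_diameter_A = if (is.null(ring_residues)) NA_real_ else
      ring_diameter(s, ring_residues))
  structure(out, class = c("geometry_profile", class(out)),
            slab = c(slab$z_min, slab$z_max))
}

#' Closed->open geometry deltas
#'
#' Converts two per-state geometry profiles into the state delta that
#' parameterises the gating-energetics model: bending angles in radians,
#' radii in nm, the in-plane area change in nm^2, and the height change in A.
#' Both profiles must come from the same slab convention.
#'
#' @param closed,open One-row `geometry_profile` tibbles from
#'   [measure_geometry()].
#' @return A one-row `state_delta` tibble: `theta_c_rad`, `theta_o_rad`,
#'   `R_c_nm`, `R_o_nm`, `delta_R_nm`, `delta_A_nm2`, `delta_height_A`,
#'   `ring_dilation_A`.
#' @export
compare_states <- function(closed, open) {
  sc <- attr(closed, "slab"); so <- attr(open, "slab")
  if (!is.null(sc) && !is.null(so) && !isTRUE(all.equal(sc, so, tolerance = 1e-6))) {
    abort("Closed and open profiles use different slab conventions",
          class = "mechgate_convention_error")
  }
  out <- tibble(
    theta_c_rad = closed$theta_deg * pi / 180,
    theta_o_rad = open$theta_deg * pi / 180,
    R_c_nm = closed$R_nm,
    R_o_nm = open$R_nm,
    delta_R_nm = open$R_nm - closed$R_nm,
    delta_A_nm2 = open$area_nm2 - closed$area_nm2,
    delta_height_A = closed$height_A - open$height_A,
    ring_dilation_A = open$ring_diameter_A - closed$ring_diameter_A)
  structure(out, class = c("state_delta", class(out)))
}
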