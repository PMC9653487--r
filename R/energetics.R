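# Membrane-tension gating energetics.
#
# Two-state (closed/open) model of a channel whose curved TMD bends the
# membrane midplane. With lateral tension sigma (kBT/nm^2):
#
#   dG(sigma)         = dG0 + dG_bending(sigma) - sigma * dA
#   dG_bending(sigma) = pi * (theta_c^2 R_c - theta_o^2 R_o) * sqrt(sigma * Kb)
#
# Energies are in kBT (dimensionless), tensions in kBT/nm^2, lengths in nm,
# angles in radians. The midpoint tension sigma_1/2 (open probability 0.5,
# dG0 = 0) solves pi*X*sqrt(sigma*Kb) = sigma*dA with X = theta_c^2 R_c -
# theta_o^2 R_o, and has the closed form X^2 Kb / (4 R_c^2 dR^2) when
# dA = 2 pi R_c dR (annular expansion).

#' Gating parameters of the two-state tension model
#'
#' Builds a consistent parameter set from any sufficient subset: given
#' `delta_A` and `delta_R`, the closed in-plane radius is taken as
#' `R_c = delta_A / (2*pi*delta_R)` (annular expansion); given radii, the
#' missing deltas are filled in.
#'
#' @param theta_c,theta_o Closed/open midplane bending angles, radians.
#' @param R_c,R_o Closed/open in-plane radii, nm.
#' @param delta_R In-plane radius change, nm.
#' @param delta_A In-plane area change, nm^2.
#' @param K_b Bilayer bending modulus, kBT (default 20).
#' @param dG0 Intrinsic free-energy difference at zero tension, kBT
#'   (default 0, as in midpoint-tension estimates).
#' @param annular_tol Relative tolerance on `|delta_A - 2*pi*R_c*delta_R|`
#'   beyond which the annular-consistency flag is FALSE (default 0.15).
#' @return A `gating_parameters` object (list) with fields `theta_c`,
#'   `theta_o`, `R_c`, `R_o`, `delta_R`, `delta_A`, `K_b`, `dG0`, `X`
#'   (`theta_c^2*R_c - theta_o^2*R_o`), `well_posed` (X > 0) and
#'   `annular_consistent`.
#' @export
gating_parameters <- function(theta_c, theta_o, R_c = NULL, R_o = NULL,
                              delta_R = NULL, delta_A = NULL,
                              K_b = 20, dG0 = 0, annular_tol = 0.15) {
  if (is.null(R_c)) {
    if (is.null(delta_A) || is.null(delta_R)) {
      abort("Provide either R_c (and R_o or delta_R) or both delta_A and delta_R",
            class = "mechgate_incomplete_parameters")
    }
    R_c <- delta_A / (2 * pi * delta_R)
  }
  if (is.null(delta_R)) {
    if (is.null(R_o)) {
      abort("Provide R_o or delta_R", class = "mechgate_incomplete_parameters")
    }
    delta_R <- R_o - R_c
  }
  if (is.null(R_o)) R_o <- R_c + delta_R
  if (is.null(delta_A)) delta_A <- 2 * pi * R_c * delta_R
  stopifnot(is.finite(theta_c), is.finite(theta_o), is.finite(R_c),
            is.finite(R_o), is.finite(K_b))
  if (theta_c < 0 || theta_o < 0 || theta_c < theta_o) {
    abort("Require theta_c >= theta_o >= 0 (radians)",
          class = "mechgate_parameter_error")
  }
  if (R_c <= 0 || K_b <= 0 || delta_A <= 0) {
    abort("Require R_c > 0, K_b > 0, delta_A > 0",
          class = "mechgate_parameter_error")
  }
  if (abs(R_o - (R_c + delta_R)) > 1e-9 * max(1, R_o)) {
    abort("Inconsistent R_o, R_c, delta_R", class = "mechgate_parameter_error")
  }
  X <- theta_c^2 * R_c - theta_o^2 * R_o
  annular <- abs(delta_A - 2 * pi * R_c * delta_R) / delta_A <= annular_tol
  structure(list(theta_c = theta_c, theta_o = theta_o, R_c = R_c, R_o = R_o,
                 delta_R = delta_R, delta_A = delta_A, K_b = K_b, dG0 = dG0,
                 X = X, well_posed = X > 0, annular_consistent = annular),
            class = "gating_parameters")
}

#' Canonical MscK gating parameters
#'
#' The parameter set deduced from the closed and open MscK structures:
#' theta_c = pi/6, theta_o = pi/12 (30 -> 15 degrees), delta_A = 54 nm^2,
#' delta_R = 1.1 nm (half of the 22 A in-plane diameter expansion, so
#' R_c = delta_A/(2*pi*delta_R) ~ 7.81 nm), K_b = 20 kBT. Yields a midpoint
#' tension of ~0.16 kBT/nm^2.
#'
#' @param K_b Bilayer bending modulus, kBT.
#' @param dG0 Intrinsic free-energy difference, kBT.
#' @return A `gating_parameters` object.
#' @export
msck_parameters <- function(K_b = 20, dG0 = 0) {
  gating_parameters(theta_c = pi / 6, theta_o = pi / 12,
                    delta_A = 54, delta_R = 1.1, K_b = K_b, dG0 = dG0)
}

#' @export
print.gating_parameters <- function(x, ...) {
  cat(sprintf(paste0("<gating_parameters> theta_c %.4g rad, theta_o %.4g rad, ",
                     "R_c %.4g nm, R_o %.4g nm, dA %.4g nm^2, Kb %.4g kBT\n"),
              x$theta_c, x$theta_o, x$R_c, x$R_o, x$delta_A, x$K_b))
  if (!x$well_posed) cat("  (X <= 0: no positive midpoint tension)\n")
  invisible(x)
}

check_sigma <- function(sigma) {
  if (any(sigma < 0)) {
    abort("Membrane tension must be >= 0", class = "mechgate_domain_error")
  }
}

#' Midplane bending free-energy difference
#'
#' `dG_bending(sigma) = pi * (theta_c^2 R_c - theta_o^2 R_o) * sqrt(sigma*Kb)`,
#' the cost difference of the membrane deformation footprints of the curved
#' (closed) and flattened (open) conformations under tension.
#'
#' @param gp A `gating_parameters` object.
#' @param sigma Membrane tension(s), kBT/nm^2 (>= 0).
#' @return Energy in kBT (vectorised over `sigma`).
#' @export
bending_energy <- function(gp, sigma) {
  check_sigma(sigma)
  pi * gp$X * sqrt(sigma * gp$K_b)
}

#' Total gating free-energy difference
#'
#' `dG(sigma) = dG0 + dG_bending(sigma) - sigma * delta_A`. Positive values
#' favour the closed state.
#'
#' @inheritParams bending_energy
#' @param dG0 Intrinsic free-energy difference at zero tension, kBT
#'   (default: the value stored in `gp`).
#' @return Energy in kBT (vectorised over `sigma`).
#' @export
gating_energy <- function(gp, sigma, dG0 = gp$dG0) {
  check_sigma(sigma)
  dG0 + bending_energy(gp, sigma) - sigma * gp$delta_A
}

check_well_posed <- function(gp) {
  if (!isTRUE(gp$well_posed)) {
    abort("theta_c^2*R_c - theta_o^2*R_o <= 0: no positive midpoint tension",
          class = "mechgate_midpoint_error")
  }
}

#' Midpoint tension, closed form
#'
#' `sigma_1/2 = (theta_c^2 R_c - theta_o^2 R_o)^2 * K_b / (4 R_c^2 delta_R^2)`,
#' the tension at which the open probability is 0.5 (intrinsic dG0 not
#' considered). Exact when `delta_A = 2*pi*R_c*delta_R`.
#'
#' @param gp A `gating_parameters` object.
#' @return Midpoint tension in kBT/nm^2.
#' @export
midpoint_tension <- function(gp) {
  check_well_posed(gp)
  if (gp$delta_R <= 0) {
    abort("delta_R must be positive for the closed form",
          class = "mechgate_midpoint_error")
  }
  gp$X^2 * gp$K_b / (4 * gp$R_c^2 * gp$delta_R^2)
}

#' Midpoint tension by root finding
#'
#' Solves `pi*X*sqrt(sigma*Kb) - sigma*delta_A = 0` for the unique positive
#' root by bracketing bisection (relative tolerance 1e-10). Agrees with the
#' closed form to ~1e-8 relative whenever `delta_A = 2*pi*R_c*delta_R`.
#'
#' @param gp A `gating_parameters` object.
#' @return Midpoint tension in kBT/nm^2.
#' @export
midpoint_tension_root <- function(gp) {
  check_well_posed(gp)
  f <- function(sigma) pi * gp$X * sqrt(sigma * gp$K_b) - sigma * gp$delta_A
  # f > 0 for small sigma, < 0 for large; expand the bracket until it flips
  upper <- 1
  while (f(upper) > 0) upper <- upper * 2
  scale <- upper
  lower <- .Machine$double.eps * scale
  root <- uniroot(f, lower = lower, upper = upper, tol = 1e-12 * scale)$root
  # Newton polish to machine precision
  for (i in 1:4) {
    fp <- pi * gp$X * sqrt(gp$K_b) / (2 * sqrt(root)) - gp$delta_A
    root <- root - f(root) / fp
  }
  root
}

#' Channel open probability under tension
#'
#' Two-state Boltzmann: `P_open = 1 / (1 + exp(dG(sigma)))` with energies in
#' kBT. With `dG0 = 0`, `P_open = 0.5` exactly at the midpoint tension.
#'
#' @inheritParams gating_energy
#' @return Open probability in `[0, 1]` (vectorised over `sigma`).
#' @export
open_probability <- function(gp, sigma, dG0 = gp$dG0) {
  1 / (1 + exp(gating_energy(gp, sigma, dG0 = dG0)))
}

#' Gating parameters from measured state deltas
#'
#' Converts a `state_delta` (from [compare_states()]) into model parameters,
#' warning when the measured area change is inconsistent with the annular
#' approximation `delta_A = 2*pi*R_c*delta_R` underlying the closed-form
#' midpoint.
#'
#' @param delta A one-row `state_delta` tibble.
#' @param K_b Bilayer bending modulus, kBT.
#' @param dG0 Intrinsic free-energy difference, kBT.
#' @param annular_tol Relative tolerance for the consistency flag.
#' @return A `gating_parameters` object.
#' @export
params_from_states <- function(delta, K_b = 20, dG0 = 0, annular_tol = 0.15) {
  needed <- c("theta_c_rad", "theta_o_rad", "R_c_nm", "R_o_nm", "delta_A_nm2")
  if (!all(needed %in% names(delta)) || anyNA(delta[needed])) {
    abort("State delta lacks required fields", class = "mechgate_incomplete_delta")
  }
  gp <- gating_parameters(theta_c = delta$theta_c_rad, theta_o = delta$theta_o_rad,
                          R_c = delta$R_c_nm, R_o = delta$R_o_nm,
                          delta_A = delta$delta_A_nm2,
                          K_b = K_b, dG0 = dG0, annular_tol = annular_tol)
  if (!gp$annular_consistent) {
    warn("Measured delta_A deviates from 2*pi*R_c*delta_R by more than the tolerance")
  }
  gp
}

#' Energetics curve over a tension grid
#'
#' @param gp A `gating_parameters` object.
#' @param sigma_max Upper end of the tension grid, kBT/nm^2 (default: 3x the
#'   midpoint tension when well-posed, else 1).
#' @param n Number of grid points.
#' @param dG0 Intrinsic free-energy difference, kBT.
#' @return An `energetics_curve` tibble: `sigma`, `dG_bending`, `dG_total`,
#'   `P_open`, with attribute `sigma_half`.
#' @export
energetics_curve <- function(gp, sigma_max = NULL, n = 201, dG0 = gp$dG0) {
  sigma_half <- if (isTRUE(gp$well_posed)) midpoint_tension_root(gp) else NA_real_
  sigma_max <- sigma_max %||% (if (is.finite(sigma_half)) 3 * sigma_half else 1)
  grid <- seq(0, sigma_max, length.out = n)
  out <- tibble(sigma = grid,
                dG_bending = bending_energy(gp, grid),
                dG_total = gating_energy(gp, grid, dG0 = dG0),
                P_open = open_probability(gp, grid, dG0 = dG0))
  structure(out, class = c("energetics_curve", class(out)),
            sigma_half = sigma_half, parameters = gp)
}

#' Convert tension from kBT/nm^2 to mN/m
#'
#' 1 kBT/nm^2 = kB*298K / 1 nm^2 ~ 4.114 mN/m (reporting convenience only;
#' all model arithmetic stays in kBT units).
#'
#' @param sigma Tension in kBT/nm^2.
#' @param temperature Kelvin (default 298).
#' @return Tension in mN/m.
#' @export
tension_to_mN_per_m <- function(sigma, temperature = 298) {
  kB <- 1.380649e-23                       # J/K
  sigma * kB * temperature / 1e-18 * 1e3   # J/nm^2 -> N/m -> mN/m
}

#' @export
tidy.gating_parameters <- function(x, ...) {
  tibble(term = c("theta_c", "theta_o", "R_c", "R_o", "delta_R", "delta_A",
                  "K_b", "dG0"),
         value = c(x$theta_c, x$theta_o, x$R_c, x$R_o, x$delta_R, x$delta_A,
                   x$K_b, x$dG0),
         unit = c("rad", "rad", "nm", "nm", "nm", "nm^2", "kBT", "kBT"))
}

#' @export
glance.gating_parameters <- function(x, ...) {
  sh <- if (isTRUE(x$well_posed)) midpoint_tension(x) else NA_real_
  tibble(sigma_half_kBT_nm2 = sh,
         sigma_half_mN_m = tension_to_mN_per_m(sh),
         X_nm = x$X,
         well_posed = x$well_posed,
         annular_consistent = x$annular_consistent)
}

#' @export
autoplot.energetics_curve <- function(object, ...) {
  sh <- attr(object, "sigma_half")
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("dG_total", "dG_bending", "P_open"),
                              names_to = "quantity", values_to = "value")
  p <- ggplot(long, aes(x = .data$sigma, y = .data$value)) +
    geom_line(...) +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = expression(sigma ~ "(kBT/nm"^2 * ")"), y = NULL,
         title = "Tension-gating energetics") +
    theme_bw()
  if (is.finite(sh)) p <- p + geom_vline(xintercept = sh, linetype = 2)
  p
}
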