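# Sphere-probe pore-radius profiling.
#
# At each z the probe radius is the largest sphere centered within `wander` of
# the pore axis that touches no atom: max over candidate centers of
# min_atoms(|center - atom| - vdw). The maximisation is a deterministic grid
# search at resolution step/2 (not stochastic annealing), so results are
# reproducible and checkable against a brute-force oracle.

#' Sphere-probe pore-radius profile along the channel axis
#'
#' @param s A frame-aligned `channel_structure`.
#' @param z_range Numeric length-2 (A); default: the atom z-range.
#' @param step Axial sampling step in A (default 0.5). The probe-center grid
#'   resolution is `step/2`.
#' @param wander Maximum probe-center offset from the axis in A (default 5).
#' @param r_max Radius cap in A (default 15): the reported radius saturates at
#'   this value where the pore is wider than `r_max`.
#' @param atoms `"all"` (default, side chains included so bulky gate residues
#'   count) or `"backbone"` (N, CA, C, O only).
#' @return A `pore_profile` tibble: `z_A`, `radius_A`, `x_offset_A`,
#'   `y_offset_A`, with attributes `step` and `wander`.
#' @export
pore_profile <- function(s, z_range = NULL, step = 0.5, wander = 5,
                         r_max = 15, atoms = c("all", "backbone")) {
  check_aligned(s)
  atoms <- match.arg(atoms)
  if (step <= 0) abort("step must be positive", class = "mechgate_range_error")
  if (wander < 0) abort("wander must be >= 0", class = "mechgate_range_error")
  at <- s
  if (atoms == "backbone") {
    at <- at[at$atom_name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  }
  zr <- range(at$z)
  z_range <- z_range %||% zr
  if (z_range[1] > zr[2] || z_range[2] < zr[1]) {
    abort("z_range lies outside the structure", class = "mechgate_range_error")
  }
  z_samples <- seq(z_range[1], z_range[2], by = step)
  # candidate probe-center offsets: grid at step/2 within the wander disk,
  # ordered by |offset| so ties resolve toward the axis
  if (wander > 0) {
    g <- seq(-wander, wander, by = step / 2)
    cand <- expand.grid(ox = g, oy = g)
    cand <- cand[cand$ox^2 + cand$oy^2 <= wander^2 + 1e-9, , drop = FALSE]
    cand <- cand[order(cand$ox^2 + cand$oy^2, cand$ox, cand$oy), , drop = FALSE]
  } else {
    cand <- data.frame(ox = 0, oy = 0)
  }
  ax <- at$x; ay <- at$y; az <- at$z; avdw <- at$vdw_radius
  max_vdw <- max(avdw)
  res <- vapply(z_samples, function(z0) {
    keep <- abs(az - z0) <= r_max + max_vdw
    if (!any(keep)) return(c(r_max, 0, 0))
    dz2 <- (az[keep] - z0)^2
    # centers x atoms distance matrix
    dx <- outer(cand$ox, ax[keep], "-")
    dy <- outer(cand$oy, ay[keep], "-")
    d <- sqrt(dx * dx + dy * dy + rep(dz2, each = nrow(cand))) -
      rep(avdw[keep], each = nrow(cand))
    dmin <- d[, 1]
    for (j in seq_len(ncol(d))[-1]) dmin <- pmin(dmin, d[, j])
    rad <- pmin(pmax(dmin, 0), r_max)
    best <- which.max(rad)   # first max: smallest |offset| wins ties
    c(rad[best], cand$ox[best], cand$oy[best])
  }, numeric(3))
  out <- tibble(z_A = z_samples, radius_A = res[1, ],
                x_offset_A = res[2, ], y_offset_A = res[3, ])
  structure(out, class = c("pore_profile", class(out)),
            step = step, wander = wander, r_max = r_max)
}

# prominence of local minima of y (computed on the inverted signal):
# height one must rise from the minimum before descending below it again,
# capped at the boundary maxima.
local_min_prominence <- function(y) {
  n <- length(y)
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) Inf else y[i - 1]
    right <- if (i == n) Inf else y[i + 1]
    y[i] < left && y[i] <= right
  }, logical(1))
  idx <- which(is_min)
  prom <- vapply(idx, function(i) {
    lmax <- if (i == 1) NA_real_ else {
      m <- -Inf
      for (j in (i - 1):1) {
        m <- max(m, y[j])
        if (y[j] < y[i]) break
      }
      m
    }
    rmax <- if (i == n) NA_real_ else {
      m <- -Inf
      for (j in (i + 1):n) {
        m <- max(m, y[j])
        if (y[j] < y[i]) break
      }
      m
    }
    # boundary minima are judged on their one existing side
    min(c(lmax, rmax), na.rm = TRUE) - y[i]
  }, numeric(1))
  tibble(index = idx, prominence = prom)
}

#' Locate pore constrictions (gates) and attribute lining residues
#'
#' Finds local minima of the smoothed pore-radius profile with radial
#' prominence above a threshold, then attributes each constriction to the
#' residues whose atoms lie within `contact_slack` of touching the probe
#' sphere.
#'
#' @param p A `pore_profile`.
#' @param structure The `channel_structure` the profile was computed from
#'   (optional; needed for residue attribution).
#' @param smoothing_window Moving-average window in A (default 1.5).
#' @param prominence Minimum radial prominence in A (default 0.5).
#' @param contact_slack Contact cutoff beyond touching, in A (default 1.0).
#' @return A tibble of constrictions ordered by z: `z_A`, `diameter_A`
#'   (2 x local minimum probe radius), and a `lining_residues` list-column of
#'   `(chain_id, residue_name, residue_number)` tibbles.
#' @export
find_gates <- function(p, structure = NULL, smoothing_window = 1.5,
                       prominence = 0.5, contact_slack = 1.0) {
  if (nrow(p) == 0) abort("Empty pore profile", class = "mechgate_range_error")
  step <- attr(p, "step") %||% (if (nrow(p) > 1) diff(p$z_A[1:2]) else 1)
  k <- max(1L, as.integer(round(smoothing_window / step)))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(p$radius_A, rep(1 / k, k), sides = 2))
  # moving average is undefined at the edges; keep raw values there
  sm[is.na(sm)] <- p$radius_A[is.na(sm)]
  mins <- local_min_prominence(sm)
  mins <- mins[mins$prominence >= prominence, , drop = FALSE]
  if (nrow(mins) == 0) {
    return(tibble(z_A = numeric(), diameter_A = numeric(),
                  lining_residues = list()))
  }
  half <- max(1L, (k - 1L) %/% 2L)
  rows <- purrr::map(mins$index, function(i) {
    # locate the raw minimum near the smoothed one
    win <- max(1L, i - half):min(nrow(p), i + half)
    j <- win[which.min(p$radius_A[win])]
    lining <- NULL
    if (!is.null(structure)) {
      cx <- p$x_offset_A[j]; cy <- p$y_offset_A[j]; cz <- p$z_A[j]
      d <- sqrt((structure$x - cx)^2 + (structure$y - cy)^2 + (structure$z - cz)^2)
      m <- d <= p$radius_A[j] + structure$vdw_radius + contact_slack
      lining <- dplyr::distinct(
        tibble(chain_id = structure$chain_id[m],
               residue_name = structure$residue_name[m],
               residue_number = structure$residue_number[m]))
      lining <- arrange(lining, .data$residue_number, .data$chain_id)
    }
    tibble(z_A = p$z_A[j], diameter_A = 2 * p$radius_A[j],
           lining_residues = list(lining))
  })
  arrange(list_rbind(rows), .data$z_A)
}

#' Minimal pore diameter of a profile
#'
#' @param p A `pore_profile`.
#' @param z_range Optional z-window (A) to restrict the search.
#' @return Minimal diameter (2 x min probe radius) in A.
#' @export
min_pore_diameter <- function(p, z_range = NULL) {
  if (!is.null(z_range)) p <- p[p$z_A >= z_range[1] & p$z_A <= z_range[2], ]
  2 * min(p$radius_A)
}

#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$radius_A, y = .data$z_A)) +
    geom_line(...) +
    labs(x = "probe radius (Å)", y = "z along pore axis (Å)",
         title = "Sphere-probe pore profile") +
    theme_bw()
}
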