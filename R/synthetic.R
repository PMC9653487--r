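# Ground-truthed synthetic inputs: parametric bent Cn helix bundles
# (closed/open pairs emulating the MscK gating transition) and tension-gated
# patch-clamp recordings. Pseudo-atom bundles trade realism for analytic
# ground truth: helices are CA traces with a small helical wind, pore-lining
# atoms are placed to realise requested constriction radii exactly, and every
# artifact carries its generation ground truth.

#' Specification of a synthetic bent helix bundle
#'
#' @param n_subunits Rotational symmetry order (default 7, a heptamer).
#' @param cone_angle_deg Midplane bending angle of the bundle, degrees: TM
#'   helix midpoints fall on a cone with slope `tan(angle)` in (r, z).
#' @param inplane_radius_A Radial position of the outermost helices, A.
#' @param tm_span_A z-extent of each helix, A.
#' @param helices_per_subunit Helices per protomer, spread radially inward
#'   from `inplane_radius_A`.
#' @param constrictions Tibble of pore-lining rings: `z_A`, `radius_A` (the
#'   probe radius the ring realises on the axis), `residue_name`,
#'   `residue_number`. One atom per subunit per ring, placed at radial
#'   distance `radius_A + pore_atom_radius_A` so a sphere probe on the axis
#'   clears exactly `radius_A`.
#' @param ring_radius_A Radius of the periplasmic marker ring (residues
#'   100-103), A.
#' @param pore_atom_radius_A vdW radius of pore-lining pseudo-atoms (default
#'   1.70, carbon).
#' @param jitter_sd_A Gaussian coordinate jitter SD, A (applied last).
#' @param seed RNG seed (all randomness flows through it).
#' @return A `toy_channel_spec` list.
#' @export
toy_channel_spec <- function(n_subunits = 7, cone_angle_deg = 30,
                             inplane_radius_A = 78, tm_span_A = 34,
                             helices_per_subunit = 3,
                             constrictions = tibble(
                               z_A = c(-8, -6.5, 6),
                               radius_A = c(2.5, 2.7, 4.0),
                               residue_name = c("VAL", "PHE", "TRP"),
                               residue_number = c(921L, 925L, 914L)),
                             ring_radius_A = 77,
                             pore_atom_radius_A = 1.70,
                             jitter_sd_A = 0, seed = 1) {
  if (n_subunits < 3) abort("Need n_subunits >= 3", class = "mechgate_spec_error")
  if (inplane_radius_A <= 0 || tm_span_A <= 0 || ring_radius_A <= 0 ||
      pore_atom_radius_A <= 0) {
    abort("Radii and spans must be positive", class = "mechgate_spec_error")
  }
  if (jitter_sd_A < 0) abort("jitter_sd_A must be >= 0", class = "mechgate_spec_error")
  constrictions <- as_tibble(constrictions)
  if (nrow(constrictions) > 0) {
    if (any(constrictions$radius_A <= 0)) {
      abort("Constriction radii must be positive", class = "mechgate_spec_error")
    }
    if (any(abs(constrictions$z_A) > tm_span_A / 2)) {
      abort("Constriction z outside the TM span", class = "mechgate_spec_error")
    }
  }
  structure(list(n_subunits = as.integer(n_subunits),
                 cone_angle_deg = cone_angle_deg,
                 inplane_radius_A = inplane_radius_A,
                 tm_span_A = tm_span_A,
                 helices_per_subunit = as.integer(helices_per_subunit),
                 constrictions = constrictions,
                 ring_radius_A = ring_radius_A,
                 pore_atom_radius_A = pore_atom_radius_A,
                 jitter_sd_A = jitter_sd_A,
                 seed = as.integer(seed)),
            class = "toy_channel_spec")
}

#' Generate a synthetic Cn helix-bundle channel
#'
#' Builds a pseudo-atom (CA-trace) bundle with known bending angle, in-plane
#' size, height and pore constrictions, already in the canonical frame
#' (symmetry axis = z, periplasmic marker ring at +z). Ground truth is
#' computed from the noiseless coordinates before jitter is applied.
#'
#' @param spec A `toy_channel_spec`.
#' @return A list: `structure` (a frame-aligned `channel_structure`) and
#'   `ground_truth` (true cone angle, hull radius/area, height, constriction
#'   diameters, ring diameter, suggested measurement slab, spec echo).
#' @export
make_toy_channel <- function(spec) {
  stopifnot(inherits(spec, "toy_channel_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_subunits
    h <- spec$helices_per_subunit
    theta <- spec$cone_angle_deg * pi / 180
    radii <- if (h == 1) spec$inplane_radius_A else
      seq(0.55 * spec$inplane_radius_A, spec$inplane_radius_A, length.out = h)
    r_ref <- mean(radii)
    n_at <- max(5L, as.integer(floor(spec$tm_span_A / 1.5)) + 1L)
    zloc <- seq(-spec$tm_span_A / 2, spec$tm_span_A / 2, length.out = n_at)
    wind <- (seq_len(n_at) - 1) * 100 * pi / 180   # helical wind, 100 deg/res
    helix_local_r <- 2.3
    rows <- list()
    for (k in seq_len(n) - 1L) {
      phi0 <- 2 * pi * k / n
      ch <- LETTERS[k + 1L]
      for (j in seq_len(h)) {
        r <- radii[j]
        phi <- phi0 + (j - (h + 1) / 2) * 0.35
        zmid <- tan(theta) * (r_ref - r)
        rows[[length(rows) + 1L]] <- tibble(
          atom_name = "CA", element = "C", residue_name = "ALA",
          residue_number = 600L + (j - 1L) * 50L + seq_len(n_at),
          chain_id = ch,
          x = r * cos(phi) + helix_local_r * cos(wind + phi),
          y = r * sin(phi) + helix_local_r * sin(wind + phi),
          z = zmid + zloc,
          vdw_radius = vdw_radius("C"))
      }
      # pore-lining rings: one atom per subunit per constriction
      if (nrow(spec$constrictions) > 0) {
        cons <- spec$constrictions
        rows[[length(rows) + 1L]] <- tibble(
          atom_name = "CG", element = "C",
          residue_name = cons$residue_name,
          residue_number = as.integer(cons$residue_number),
          chain_id = ch,
          x = (cons$radius_A + spec$pore_atom_radius_A) * cos(phi0 + 0.45),
          y = (cons$radius_A + spec$pore_atom_radius_A) * sin(phi0 + 0.45),
          z = cons$z_A,
          vdw_radius = spec$pore_atom_radius_A)
      }
      # periplasmic marker ring (polar residues, outside the membrane)
      mphi <- phi0 + c(-0.15, -0.05, 0.05, 0.15)
      rows[[length(rows) + 1L]] <- tibble(
        atom_name = "CA", element = "C", residue_name = "ASN",
        residue_number = 100:103, chain_id = ch,
        x = spec$ring_radius_A * cos(mphi),
        y = spec$ring_radius_A * sin(mphi),
        z = NA_real_,   # filled below, above the TM span
        vdw_radius = vdw_radius("C"))
    }
    atoms <- list_rbind(rows)
    tm <- atoms$residue_number >= 600
    z_top <- max(atoms$z[tm])
    atoms$z[is.na(atoms$z)] <- z_top + 8
    # ground truth from noiseless coordinates
    tm_or_pore <- atoms$residue_number >= 600 |
      atoms$residue_number %in% spec$constrictions$residue_number
    band <- abs(atoms$z) <= 3 & tm_or_pore
    hx <- atoms$x[band]; hy <- atoms$y[band]
    hull <- grDevices::chull(hx, hy)
    area_nm2 <- polygon_area(hx[hull], hy[hull]) / 100
    zt <- atoms$z[tm_or_pore]
    gt <- list(
      spec = spec,
      true_cone_angle_deg = spec$cone_angle_deg,
      true_hull_radius_nm = sqrt(area_nm2 / pi),
      true_area_nm2 = area_nm2,
      true_height_A = unname(diff(quantile(zt, c(0.025, 0.975)))),
      true_constrictions = spec$constrictions[, c("z_A", "radius_A",
                                                  "residue_name", "residue_number")],
      true_min_pore_diameter_A = if (nrow(spec$constrictions) > 0)
        2 * min(spec$constrictions$radius_A) else NA_real_,
      true_ring_diameter_A = 2 * spec$ring_radius_A,
      suggested_slab = c(min(zt) - 1, max(zt) + 1),
      seed = spec$seed)
    if (spec$jitter_sd_A > 0) {
      atoms$x <- atoms$x + rnorm(nrow(atoms), 0, spec$jitter_sd_A)
      atoms$y <- atoms$y + rnorm(nrow(atoms), 0, spec$jitter_sd_A)
      atoms$z <- atoms$z + rnorm(nrow(atoms), 0, spec$jitter_sd_A)
    }
    s <- new_channel_structure(atoms,
                               subunit_chains = LETTERS[seq_len(n)],
                               symmetry_order = n,
                               frame_aligned = TRUE)
    list(structure = s, ground_truth = gt)
  })
}

#' Generate a matched closed/open synthetic state pair
#'
#' The defaults emulate the MscK gating transition: closed state with cone
#' angle 30 deg, outer radius 78 A, gate constrictions of probe radius
#' 2.5/2.7 A (VAL921/PHE925, cytoplasmic) and 4 A (TRP914, periplasmic),
#' marker ring radius 77 A; open state with cone angle 15 deg, outer radius
#' +11 A, a single 10 A constriction and marker ring radius 89 A.
#'
#' @param closed_spec,open_spec `toy_channel_spec`s (defaults as above).
#' @param seed Seed used when the default specs are built.
#' @return A list: `closed`, `open` (each as from [make_toy_channel()]) and
#'   `ground_truth` with the true deltas.
#' @export
make_state_pair <- function(closed_spec = NULL, open_spec = NULL, seed = 1) {
  closed_spec <- closed_spec %||% toy_channel_spec(seed = seed)
  open_spec <- open_spec %||% toy_channel_spec(
    cone_angle_deg = 15, inplane_radius_A = 89,
    constrictions = tibble(z_A = 0, radius_A = 10,
                           residue_name = "GLY", residue_number = 924L),
    ring_radius_A = 89, seed = seed + 1L)
  if (closed_spec$n_subunits != open_spec$n_subunits) {
    abort("Closed and open specs must share the symmetry order",
          class = "mechgate_spec_error")
  }
  closed <- make_toy_channel(closed_spec)
  open <- make_toy_channel(open_spec)
  list(closed = closed, open = open,
       ground_truth = list(
         delta_theta_deg = closed_spec$cone_angle_deg - open_spec$cone_angle_deg,
         delta_hull_radius_nm = open$ground_truth$true_hull_radius_nm -
           closed$ground_truth$true_hull_radius_nm,
         delta_area_nm2 = open$ground_truth$true_area_nm2 -
           closed$ground_truth$true_area_nm2,
         ring_dilation_A = open$ground_truth$true_ring_diameter_A -
           closed$ground_truth$true_ring_diameter_A))
}

#' Specification of a simulated pressure-ramp patch recording
#'
#' @param duration_s Recording length, s.
#' @param sample_rate Hz.
#' @param voltage_mV Holding potential, mV (default -30).
#' @param noise_sd_pA Additive Gaussian noise SD, pA.
#' @param ramp_rate_mmHg_s Suction ramp rate, mmHg/s (default 4, a slow ramp).
#' @param channels Tibble of channel populations: `conductance_pS`,
#'   `activation_pressure_mmHg`, `count`, and optional `dwell_open_s` /
#'   `dwell_closed_s` (exponential mean sojourns; if present the channel
#'   flickers after activation instead of latching open).
#' @param seed RNG seed.
#' @return A `recording_spec` list.
#' @export
recording_spec <- function(duration_s = 30, sample_rate = 2000,
                           voltage_mV = -30, noise_sd_pA = 2,
                           ramp_rate_mmHg_s = 4,
                           channels = tibble(conductance_pS = 895,
                                             activation_pressure_mmHg = 40,
                                             count = 1L),
                           seed = 1) {
  if (duration_s <= 0 || sample_rate <= 0) {
    abort("duration and sample rate must be positive", class = "mechgate_spec_error")
  }
  channels <- as_tibble(channels)
  if (!"count" %in% names(channels)) channels$count <- 1L
  if (any(channels$count < 1)) abort("channel counts must be >= 1",
                                     class = "mechgate_spec_error")
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 voltage_mV = voltage_mV, noise_sd_pA = noise_sd_pA,
                 ramp_rate_mmHg_s = ramp_rate_mmHg_s,
                 channels = channels, seed = as.integer(seed)),
            class = "recording_spec")
}

# open/closed state series for one flickering channel copy
flicker_states <- function(n, start_index, fs, dwell_open, dwell_closed) {
  state <- logical(n)
  if (start_index > n) return(state)
  i <- start_index
  open <- TRUE
  while (i <= n) {
    dwell <- rexp(1, 1 / (if (open) dwell_open else dwell_closed))
    len <- max(1L, as.integer(round(dwell * fs)))
    j <- min(n, i + len - 1L)
    if (open) state[i:j] <- TRUE
    i <- j + 1L
    open <- !open
  }
  state
}

#' Simulate a tension-gated patch-clamp recording
#'
#' Suction is ramped linearly (`pressure = -ramp_rate * t`); each channel copy
#' opens when the suction magnitude exceeds its activation pressure, either
#' latching open (sharp threshold) or flickering with exponential dwell times;
#' open copies add `g * V` to the current; seeded Gaussian noise is added
#' last. Generation ground truth travels with the recording.
#'
#' @param spec A `recording_spec`.
#' @return A `patch_recording` tibble (`time_s`, `current_pA`,
#'   `pressure_mmHg`) with `voltage`, `sample_rate` and `ground_truth`
#'   attributes.
#' @export
simulate_patch_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  withr::with_seed(spec$seed, {
    fs <- spec$sample_rate
    n <- as.integer(round(spec$duration_s * fs))
    t <- (seq_len(n) - 1) / fs
    pressure <- -spec$ramp_rate_mmHg_s * t      # suction is negative
    current <- numeric(n)
    ch <- spec$channels
    has_dwell <- all(c("dwell_open_s", "dwell_closed_s") %in% names(ch))
    for (i in seq_len(nrow(ch))) {
      amp <- ch$conductance_pS[i] * spec$voltage_mV / 1000   # pA
      first <- which(abs(pressure) >= ch$activation_pressure_mmHg[i])[1]
      if (is.na(first)) next
      flick <- has_dwell && is.finite(ch$dwell_open_s[i]) &&
        is.finite(ch$dwell_closed_s[i])
      for (copy in seq_len(ch$count[i])) {
        state <- if (flick) {
          flicker_states(n, first, fs, ch$dwell_open_s[i], ch$dwell_closed_s[i])
        } else {
          seq_len(n) >= first
        }
        current <- current + amp * state
      }
    }
    if (spec$noise_sd_pA > 0) current <- current + rnorm(n, 0, spec$noise_sd_pA)
    # flag amplitude classes too close to separate (< 6 noise SD apart)
    amps <- sort(unique(abs(ch$conductance_pS * spec$voltage_mV / 1000)))
    overlap <- length(amps) > 1 &&
      any(diff(amps) <= 6 * spec$noise_sd_pA)
    if (overlap) warn("Channel amplitude classes closer than 6 noise SD")
    gt <- list(channels = ch, voltage_mV = spec$voltage_mV,
               sample_rate = fs, noise_sd_pA = spec$noise_sd_pA,
               ramp_rate_mmHg_s = spec$ramp_rate_mmHg_s,
               unitary_current_pA = ch$conductance_pS * spec$voltage_mV / 1000,
               class_overlap = overlap, seed = spec$seed)
    new_recording(t, current, pressure, sample_rate = fs,
                  voltage = spec$voltage_mV, ground_truth = gt)
  })
}
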