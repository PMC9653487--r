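# Fixture builders and independent oracles shared across the suite.

# structure already in the canonical frame, from a plain coordinate table
aligned_structure <- function(df, subunit_chains = NULL) {
  s <- as_channel_structure(df, subunit_chains = subunit_chains)
  attr(s, "frame_aligned") <- TRUE
  s
}

# dense cylinder of pseudo-atoms: points on circles of the given radius
cylinder_structure <- function(radius_A, z_range = c(-18, 18), n_azimuth = 100,
                               z_step = 2, vdw = 1.7) {
  phi <- seq(0, 2 * pi, length.out = n_azimuth + 1)[-1]
  zz <- seq(z_range[1], z_range[2], by = z_step)
  grid <- expand.grid(phi = phi, z = zz)
  aligned_structure(tibble::tibble(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_number = seq_len(nrow(grid)), chain_id = "A",
    x = radius_A * cos(grid$phi), y = radius_A * sin(grid$phi),
    z = grid$z, vdw_radius = vdw))
}

# ring of n spheres in the z = z0 plane at axial distance `dist` from the axis
ring_structure_rows <- function(n, dist, z0, vdw = 1.7, residue_name = "ALA",
                                residue_number = 1L) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(
    atom_name = "CG", element = "C", residue_name = residue_name,
    residue_number = as.integer(residue_number),
    chain_id = LETTERS[seq_len(n)],
    x = dist * cos(phi), y = dist * sin(phi), z = z0, vdw_radius = vdw)
}

# independent brute-force sphere-probe evaluation: dense center grid at
# `fine` resolution, plain min-over-atoms arithmetic
brute_force_pore_radius <- function(s, z0, wander, fine = 0.1, r_max = 15) {
  g <- seq(-wander, wander, by = fine)
  cand <- expand.grid(ox = g, oy = g)
  cand <- cand[cand$ox^2 + cand$oy^2 <= wander^2 + 1e-9, , drop = FALSE]
  if (nrow(cand) == 0) cand <- data.frame(ox = 0, oy = 0)
  best <- 0
  for (i in seq_len(nrow(cand))) {
    d <- sqrt((s$x - cand$ox[i])^2 + (s$y - cand$oy[i])^2 + (s$z - z0)^2) -
      s$vdw_radius
    best <- max(best, min(c(d, r_max)))
  }
  min(max(best, 0), r_max)
}

# brute-force first activation: scan the noiseless staircase implied by the
# generator ground truth for the first step whose amplitude is in the band
oracle_first_activation <- function(rec, band) {
  gt <- attr(rec, "ground_truth")
  amps <- abs(gt$unitary_current_pA)
  ok <- amps >= band[1] & amps <= band[2]
  if (!any(ok)) return(NA_real_)
  min(gt$channels$activation_pressure_mmHg[ok])
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

random_rigid_transform <- function(df, seed) {
  withr::with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0.3, 3)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    shift <- rnorm(3, 0, 20)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  })
}

flicker_channels <- function(conductance_pS = 895, activation = 40, count = 1L,
                             dwell = 0.03) {
  tibble::tibble(conductance_pS = conductance_pS,
                 activation_pressure_mmHg = activation,
                 count = as.integer(count),
                 dwell_open_s = dwell, dwell_closed_s = dwell)
}
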