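# Structure input/output and canonical-frame placement.
#
# A channel structure is a tibble of atom records (one row per atom) carrying
# three attributes: `subunit_chains` (chains taken to be the symmetry-related
# protomers), `symmetry_order` (NA until detected) and `frame_aligned`
# (TRUE once the pore axis is the z-axis, periplasm at +z).

# Bondi van der Waals radii (Angstrom) for the elements that occur in
# deposited protein models; unknown elements fall back to carbon.
.bondi <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
            SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Van der Waals radius lookup (Bondi set)
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom. Unrecognised elements get the
#'   carbon radius (1.70 A) with a warning.
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  r <- unname(.bondi[key])
  if (anyNA(r)) {
    warn(paste0("Unknown element(s) ", paste(unique(key[is.na(r)]), collapse = ", "),
                "; using carbon vdW radius 1.70 A"))
    r[is.na(r)] <- .bondi[["C"]]
  }
  r
}

new_channel_structure <- function(atoms, subunit_chains = NULL,
                                  symmetry_order = NA_integer_,
                                  frame_aligned = FALSE) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_name", "element", "residue_name", "residue_number",
              "chain_id", "x", "y", "z", "vdw_radius")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste("Atom table lacks column(s):", paste(missing, collapse = ", ")),
          class = "mechgate_structure_error")
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("Non-finite atom coordinates", class = "mechgate_structure_error")
  }
  if (any(atoms$vdw_radius <= 0)) {
    abort("vdW radii must be positive", class = "mechgate_structure_error")
  }
  structure(atoms,
            class = c("channel_structure", class(tibble())),
            subunit_chains = subunit_chains %||% sort(unique(atoms$chain_id)),
            symmetry_order = symmetry_order,
            frame_aligned = frame_aligned)
}

#' Build a channel structure from an atom table
#'
#' @param atoms Data frame with columns `atom_name`, `element`, `residue_name`,
#'   `residue_number`, `chain_id`, `x`, `y`, `z` (Angstrom). A `vdw_radius`
#'   column is added from the Bondi table if absent.
#' @param subunit_chains Chains treated as the symmetry-related protomers
#'   (default: all chains).
#' @return A `channel_structure` tibble.
#' @export
as_channel_structure <- function(atoms, subunit_chains = NULL) {
  atoms <- as_tibble(atoms)
  if (!"vdw_radius" %in% names(atoms)) {
    atoms$vdw_radius <- vdw_radius(atoms$element)
  }
  new_channel_structure(atoms, subunit_chains = subunit_chains)
}

#' @export
print.channel_structure <- function(x, ...) {
  cat(sprintf("<channel_structure> %d atoms, %d chains (%d subunit chains), %s\n",
              nrow(x), length(unique(x$chain_id)),
              length(attr(x, "subunit_chains")),
              if (isTRUE(attr(x, "frame_aligned"))) "frame-aligned" else "not aligned"))
  NextMethod()
}

# carry structure attributes through a coordinate edit
restamp <- function(atoms, template, frame_aligned = attr(template, "frame_aligned")) {
  new_channel_structure(atoms,
                        subunit_chains = attr(template, "subunit_chains"),
                        symmetry_order = attr(template, "symmetry_order"),
                        frame_aligned = frame_aligned)
}

coords <- function(s) cbind(s$x, s$y, s$z)

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps protein (ATOM) records, drops hydrogens
#' and water/heteroatoms by default, and assigns Bondi vdW radii.
#' Subunit chains are taken as the largest group of chains sharing the same
#' residue count (the symmetry-related protomers of a homo-oligomer).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keep_het Keep HETATM records (default FALSE).
#' @param keep_hydrogens Keep hydrogens (default FALSE; deposited models of
#'   this kind rarely include them).
#' @return A `channel_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_het = FALSE, keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste("No such file:", path), class = "mechgate_format_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) abort(paste0("Cannot parse ", path, " as ", format, ": ",
                                     conditionMessage(e)),
                              class = "mechgate_format_error"))
  at <- as_tibble(parsed$atom)
  if (!keep_het) at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  no_elem <- is.na(elem) | elem == ""
  if (any(no_elem)) {
    # fall back on the first letter of the atom name
    elem[no_elem] <- substr(gsub("[^A-Za-z].*$", "", toupper(trimws(at$elety[no_elem]))), 1, 1)
  }
  if (!keep_hydrogens) {
    keep <- elem != "H"
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  if (nrow(at) == 0) {
    abort(paste("No protein atoms in", path), class = "mechgate_empty_error")
  }
  atoms <- tibble(
    atom_name = trimws(at$elety),
    element = elem,
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = as.character(at$chain),
    x = at$x, y = at$y, z = at$z,
    vdw_radius = suppressWarnings(vdw_radius(elem)))
  # protomers: the largest set of chains with equal residue counts
  res_per_chain <- vapply(split(atoms$residue_number, atoms$chain_id),
                          function(v) length(unique(v)), integer(1))
  counts <- table(res_per_chain)
  modal <- as.integer(names(counts)[which.max(counts)])
  protomers <- names(res_per_chain)[res_per_chain == modal]
  new_channel_structure(atoms, subunit_chains = sort(protomers))
}

#' Write a channel structure to a PDB file
#'
#' @param s A `channel_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(coords(s))),
                   type = rep("ATOM", nrow(s)),
                   resno = s$residue_number,
                   resid = s$residue_name,
                   eleno = seq_len(nrow(s)),
                   elety = s$atom_name,
                   chain = s$chain_id,
                   elesy = s$element,
                   o = rep(1, nrow(s)), b = rep(0, nrow(s)))
  invisible(path)
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

rotz <- function(phi) {
  matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# rmsd between two equal-length coordinate matrices
rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

chain_centroids <- function(s, chains) {
  t(vapply(chains, function(ch) {
    m <- s$chain_id == ch
    c(mean(s$x[m]), mean(s$y[m]), mean(s$z[m]))
  }, numeric(3)))
}

# RMSD of the structure against itself rotated by 2*pi/order about axis
# through center, with chains mapped by azimuth. Inf if no consistent mapping.
symmetry_rmsd <- function(s, chains, order, axis, center) {
  cen <- chain_centroids(s, chains)
  R <- rotation_between(axis, c(0, 0, 1))
  loc <- sweep(cen, 2, center) %*% t(R)
  phi <- atan2(loc[, 2], loc[, 1])
  delta <- 2 * pi / order
  nchain <- length(chains)
  wrap <- function(a) atan2(sin(a), cos(a))
  target <- phi + delta
  mapping <- integer(nchain)
  for (i in seq_len(nchain)) {
    d <- abs(wrap(phi - target[i]))
    j <- which.min(d)
    if (d[j] > delta / 3) return(list(rmsd = Inf, mapping = NULL))
    mapping[i] <- j
  }
  if (any(duplicated(mapping))) return(list(rmsd = Inf, mapping = NULL))
  # equal atom counts between mapped chains required for atomwise comparison
  idx <- split(seq_len(nrow(s)), factor(s$chain_id, levels = chains))
  sq <- 0; natoms <- 0
  xyz <- coords(s)
  Rrot <- t(R) %*% rotz(delta) %*% R   # rotation by delta about `axis`
  for (i in seq_len(nchain)) {
    a <- idx[[i]]; b <- idx[[mapping[i]]]
    if (length(a) != length(b)) return(list(rmsd = Inf, mapping = NULL))
    rot <- sweep(sweep(xyz[a, , drop = FALSE], 2, center) %*% t(Rrot), 2, center, "+")
    sq <- sq + sum((rot - xyz[b, , drop = FALSE])^2)
    natoms <- natoms + length(a)
  }
  list(rmsd = sqrt(sq / natoms), mapping = mapping)
}

#' Detect the rotational (Cn) symmetry of a channel structure
#'
#' Scans candidate orders 2..`max_order` over candidate axes (the normal of
#' the subunit-centroid plane plus the principal axes of the atom cloud),
#' scoring each by the RMSD of the structure against itself rotated by
#' 2*pi/order with subunits mapped by azimuth. Among orders whose RMSD is
#' indistinguishable from the best, the highest order wins, so a C7 channel
#' is reported as C7 rather than a lower divisor.
#'
#' @param s A `channel_structure`.
#' @param max_order Highest order to consider (default 12).
#' @param rmsd_threshold RMSD (A) above which symmetry is ambiguous
#'   (default 5).
#' @return A `symmetry_info` list: `order`, `axis` (unit 3-vector), `center`
#'   (A), `rmsd` (A, self-agreement under rotation by 2*pi/order).
#' @export
detect_symmetry <- function(s, max_order = 12, rmsd_threshold = 5) {
  chains <- attr(s, "subunit_chains")
  natoms_per <- vapply(chains, function(ch) sum(s$chain_id == ch), integer(1))
  if (length(chains) < 2 || length(unique(natoms_per)) != 1) {
    warn("Fewer than 2 comparable subunit chains; assuming symmetry order from chain count")
    ord <- max(1L, length(chains))
    if (length(chains) < 2) ord <- 1L
    return(structure(list(order = ord, axis = c(0, 0, 1),
                          center = colMeans(coords(s)), rmsd = NA_real_),
                     class = "symmetry_info"))
  }
  cen <- chain_centroids(s, chains)
  center <- colMeans(cen)
  cands <- list()
  if (length(chains) >= 3) {
    ev <- eigen(stats::cov(cen), symmetric = TRUE)
    cands <- c(cands, list(ev$vectors[, 3]))   # normal of the centroid plane
  }
  ev_all <- eigen(stats::cov(coords(s)), symmetric = TRUE)
  cands <- c(cands, lapply(1:3, function(i) ev_all$vectors[, i]))
  orders <- 2:max_order
  best <- NULL
  score <- matrix(Inf, length(cands), length(orders))
  for (ai in seq_along(cands)) {
    for (oi in seq_along(orders)) {
      score[ai, oi] <- symmetry_rmsd(s, chains, orders[oi], cands[[ai]], center)$rmsd
    }
  }
  if (!any(is.finite(score))) {
    abort("No rotational symmetry mapping found for any candidate axis",
          class = "mechgate_symmetry_error")
  }
  best_rmsd <- min(score)
  # accept orders close to the best fit; prefer the highest such order
  tol <- max(best_rmsd * 1.5, best_rmsd + 0.5)
  ok <- which(score <= tol, arr.ind = TRUE)
  maxord <- max(orders[ok[, 2]])
  sel <- ok[orders[ok[, 2]] == maxord, , drop = FALSE]
  pick <- sel[which.min(score[sel]), ]
  ord <- orders[pick[2]]
  axis <- cands[[pick[1]]]
  rmsd <- score[pick[1], pick[2]]
  if (axis[3] < 0) axis <- -axis
  out <- structure(list(order = as.integer(ord), axis = axis,
                        center = center, rmsd = rmsd),
                   class = "symmetry_info")
  if (rmsd > rmsd_threshold) {
    abort(paste0("Best symmetry candidate C", ord, " has RMSD ",
                 signif(rmsd, 3), " A above threshold ", rmsd_threshold),
          class = "mechgate_symmetry_error", candidate = out)
  }
  out
}

#' @export
print.symmetry_info <- function(x, ...) {
  cat(sprintf("<symmetry_info> C%d, rmsd %.4g A, axis (%.3f, %.3f, %.3f)\n",
              x$order, x$rmsd, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Place a structure in the canonical analysis frame
#'
#' Rigidly transforms the structure so the symmetry axis is the z-axis through
#' the origin, the periplasmic side has positive z (decided by the marker
#' residue selection), and the centroid of the first subunit chain lies at
#' azimuth zero (+x half-plane). Pairwise distances are preserved exactly.
#'
#' @param s A `channel_structure`.
#' @param sym A `symmetry_info`; detected from `s` if NULL.
#' @param periplasmic_marker Residue numbers marking the periplasmic side
#'   (default `1:500`, the N-terminal periplasmic domain in author numbering
#'   for MscK-family channels).
#' @return The aligned `channel_structure` (`frame_aligned = TRUE`).
#' @export
align_to_axis <- function(s, sym = NULL, periplasmic_marker = 1:500) {
  sym <- sym %||% detect_symmetry(s)
  if (is.na(sym$rmsd) && sym$order < 2) {
    warn("Aligning a structure without detected symmetry; using given axis")
  }
  marker <- s$residue_number %in% periplasmic_marker
  if (!any(marker)) {
    abort("Periplasmic marker selection matches no residues",
          class = "mechgate_orientation_error")
  }
  R <- rotation_between(sym$axis, c(0, 0, 1))
  xyz <- sweep(coords(s), 2, sym$center) %*% t(R)
  if (mean(xyz[marker, 3]) < 0) {
    xyz <- xyz %*% diag(c(1, -1, -1))   # flip about x: keeps handedness
  }
  # fix the azimuth: first subunit chain centroid to +x
  ref <- attr(s, "subunit_chains")[1]
  m <- s$chain_id == ref
  phi <- atan2(mean(xyz[m, 2]), mean(xyz[m, 1]))
  xyz <- xyz %*% t(rotz(-phi))
  atoms <- s
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  out <- restamp(atoms, s, frame_aligned = TRUE)
  attr(out, "symmetry_order") <- sym$order
  out
}

#' @export
#' @rdname assign_membrane_slab
membrane_slab <- function(z_min, z_max) {
  if (!(z_min < z_max)) abort("z_min must be < z_max", class = "mechgate_slab_error")
  if (z_max - z_min < 10) {
    abort("Membrane slab thinner than 10 A", class = "mechgate_slab_error")
  }
  structure(list(z_min = z_min, z_max = z_max, z_mid = (z_min + z_max) / 2),
            class = "membrane_slab")
}

#' @export
print.membrane_slab <- function(x, ...) {
  cat(sprintf("<membrane_slab> z in [%.1f, %.1f] A, midplane %.1f A\n",
              x$z_min, x$z_max, x$z_mid))
  invisible(x)
}

.hydrophobic <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP", "PRO", "GLY")

#' Assign the membrane slab
#'
#' The membrane z-window used for all geometry measurements. Explicit mode
#' returns user bounds; hydrophobic-belt mode slides a window of the given
#' width along z and returns the position maximising the fraction of atoms in
#' hydrophobic residues (ties broken toward the window containing the most
#' hydrophobic atoms).
#'
#' @param s A frame-aligned `channel_structure`.
#' @param mode `"explicit"` or `"hydrophobic-belt"`.
#' @param z_bounds Numeric length-2, explicit slab bounds in A
#'   (default `c(-16, 16)`, a 32 A hydrophobic thickness).
#' @param width Belt width in A for `"hydrophobic-belt"` mode (default 32).
#' @return A `membrane_slab` (`z_min`, `z_max`, `z_mid`).
#' @export
assign_membrane_slab <- function(s, mode = c("explicit", "hydrophobic-belt"),
                                 z_bounds = c(-16, 16), width = 32) {
  mode <- match.arg(mode)
  if (!isTRUE(attr(s, "frame_aligned"))) {
    abort("Structure must be frame-aligned before slab assignment",
          class = "mechgate_slab_error")
  }
  zr <- range(s$z)
  if (mode == "explicit") {
    if (z_bounds[1] > zr[2] || z_bounds[2] < zr[1]) {
      abort("Explicit slab lies outside the atom z-range", class = "mechgate_slab_error")
    }
    return(membrane_slab(z_bounds[1], z_bounds[2]))
  }
  if (width < 10) abort("Belt thinner than 10 A", class = "mechgate_slab_error")
  if (diff(zr) < width) {
    abort("Structure z-extent smaller than belt width", class = "mechgate_slab_error")
  }
  centers <- seq(zr[1] + width / 2, zr[2] - width / 2, by = 0.5)
  hyd <- s$residue_name %in% .hydrophobic
  frac <- numeric(length(centers)); cnt <- numeric(length(centers))
  for (i in seq_along(centers)) {
    inw <- s$z >= centers[i] - width / 2 & s$z <= centers[i] + width / 2
    cnt[i] <- sum(hyd & inw)
    frac[i] <- if (any(inw)) cnt[i] / sum(inw) else 0
  }
  if (max(cnt) == 0) {
    abort("No hydrophobic atoms: cannot place a hydrophobic belt",
          class = "mechgate_slab_error")
  }
  top <- which(frac >= max(frac) - 1e-9)
  best <- top[which.max(cnt[top])]
  membrane_slab(centers[best] - width / 2, centers[best] + width / 2)
}
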