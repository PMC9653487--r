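test_that("a hand-written PDB file reads back with identical coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "ATOM  %5d  %-3s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, 1, "N", "GLY", "A", 1, 1.234, -2.5, 3.75, 1, 0, "N"),
    sprintf(fmt, 2, "CA", "GLY", "A", 1, 2.0, 0.125, -4.5, 1, 0, "C"),
    sprintf(fmt, 3, "O", "GLY", "A", 1, -3.25, 1.0, 0.001, 1, 0, "O"),
    "END"), path)
  s <- read_structure(path)
  expect_s3_class(s, "channel_structure")
  expect_equal(nrow(s), 3)
  expect_equal(s$x, c(1.234, 2.0, -3.25))
  expect_equal(s$y, c(-2.5, 0.125, 1.0))
  expect_equal(s$z, c(3.75, -4.5, 0.001))
  expect_equal(s$element, c("N", "C", "O"))
  expect_equal(s$vdw_radius, c(1.55, 1.70, 1.52))
})

test_that("generated heptamer survives a PDB write/read round trip", {
  tc <- make_toy_channel(toy_channel_spec(seed = 11))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc$structure, path)
  back <- read_structure(path)
  expect_equal(nrow(back), nrow(tc$structure))
  expect_equal(length(attr(back, "subunit_chains")), 7)
  ord <- order(back$chain_id, back$residue_number, back$atom_name)
  ord0 <- order(tc$structure$chain_id, tc$structure$residue_number,
                tc$structure$atom_name)
  expect_equal(back$x[ord], tc$structure$x[ord0], tolerance = 1e-3)
  expect_equal(back$z[ord], tc$structure$z[ord0], tolerance = 1e-3)
  expect_equal(back$residue_name[ord], tc$structure$residue_name[ord0])
})

test_that("read_structure rejects garbage and empty inputs", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure file", bad)
  expect_error(read_structure(bad), class = "mechgate_empty_error")
  expect_error(read_structure("/nonexistent/file.pdb"),
               class = "mechgate_format_error")
})

test_that("exact Cn bundles are detected at the generated order", {
  for (n in c(3, 5, 7, 8)) {
    tc <- make_toy_channel(toy_channel_spec(n_subunits = n, seed = n))
    sym <- detect_symmetry(tc$structure)
    expect_identical(sym$order, as.integer(n))
    expect_lt(sym$rmsd, 1e-6)
    expect_equal(abs(sym$axis[3]), 1, tolerance = 1e-9)
  }
})

test_that("symmetry detection tolerates coordinate jitter", {
  for (n in c(4, 6, 7)) {
    tc <- make_toy_channel(toy_channel_spec(n_subunits = n, jitter_sd_A = 0.3,
                                            seed = 20 + n))
    sym <- detect_symmetry(tc$structure)
    expect_identical(sym$order, as.integer(n))
    # self-agreement rmsd should be on the jitter scale (~sqrt(2)*0.3 A)
    expect_gt(sym$rmsd, 0.1)
    expect_lt(sym$rmsd, 1.0)
  }
})

test_that("single-chain structures fall back to order 1 with a warning", {
  df <- tibble::tibble(atom_name = "CA", element = "C", residue_name = "ALA",
                       residue_number = 1:10, chain_id = "A",
                       x = rnorm(10), y = rnorm(10), z = 1:10,
                       vdw_radius = 1.7)
  s <- as_channel_structure(df)
  expect_warning(sym <- detect_symmetry(s), "chain count")
  expect_identical(sym$order, 1L)
})

test_that("alignment is rigid, idempotent, and recovers a scrambled frame", {
  tc <- make_toy_channel(toy_channel_spec(seed = 5))
  s0 <- align_to_axis(tc$structure)
  # rigid-transform contract: pairwise distances preserved
  idx <- seq(1, nrow(s0), by = 37)
  d0 <- dist(cbind(tc$structure$x, tc$structure$y, tc$structure$z)[idx, ])
  d1 <- dist(cbind(s0$x, s0$y, s0$z)[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-6)
  # idempotence
  s1 <- align_to_axis(s0)
  expect_lt(rmsd_points(cbind(s0$x, s0$y, s0$z), cbind(s1$x, s1$y, s1$z)), 1e-6)
  # scrambled frame comes back to the canonical one
  df <- random_rigid_transform(tibble::as_tibble(tc$structure), seed = 42)
  s2 <- align_to_axis(as_channel_structure(df))
  expect_lt(rmsd_points(cbind(s0$x, s0$y, s0$z), cbind(s2$x, s2$y, s2$z)), 1e-3)
  # periplasmic marker ends up on +z
  expect_gt(mean(s2$z[s2$residue_number %in% 100:103]), 0)
  expect_error(align_to_axis(tc$structure, periplasmic_marker = 9999),
               class = "mechgate_orientation_error")
})

test_that("explicit membrane slab is the identity on its bounds", {
  tc <- make_toy_channel(toy_channel_spec(seed = 2))
  slab <- assign_membrane_slab(tc$structure, "explicit", z_bounds = c(-18, 18))
  expect_equal(slab$z_min, -18)
  expect_equal(slab$z_max, 18)
  expect_equal(slab$z_mid, 0)
  expect_error(membrane_slab(-3, 3), class = "mechgate_slab_error")
  expect_error(assign_membrane_slab(tc$structure, "explicit",
                                    z_bounds = c(500, 600)),
               class = "mechgate_slab_error")
})

test_that("hydrophobic belt recovers the generated TM span", {
  tc <- make_toy_channel(toy_channel_spec(cone_angle_deg = 0, tm_span_A = 32,
                                          seed = 3))
  slab <- assign_membrane_slab(tc$structure, "hydrophobic-belt", width = 32)
  expect_lt(abs(slab$z_min - (-16)), 3)
  expect_lt(abs(slab$z_max - 16), 3)
})

test_that("all-polar structures cannot host a hydrophobic belt", {
  df <- tibble::tibble(atom_name = "CA", element = "C", residue_name = "ASN",
                       residue_number = 1:200, chain_id = "A",
                       x = rnorm(200), y = rnorm(200),
                       z = seq(-20, 20, length.out = 200), vdw_radius = 1.52)
  s <- aligned_structure(df)
  expect_error(assign_membrane_slab(s, "hydrophobic-belt", width = 32),
               class = "mechgate_slab_error")
})
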