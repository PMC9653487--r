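# End-to-end orchestration: structure pair -> geometry -> pore -> energetics
# -> report, and recording -> ephys report. Reports are plain lists with a
# stable config hash and full provenance; numeric content is deterministic
# for a given config + seed.

pipeline_config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

report_provenance <- function(cfg) {
  list(package = "mechgate",
       version = as.character(utils::packageVersion("mechgate")),
       config_hash = pipeline_config_hash(cfg),
       seed = cfg$seed %||% NA_integer_,
       timestamp = format(Sys.time(), tz = "UTC"))
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

load_state <- function(path, format = "auto", periplasmic_marker = 1:500) {
  s <- read_structure(path, format = format)
  align_to_axis(s, periplasmic_marker = periplasmic_marker)
}

#' Run the closed/open state comparison pipeline
#'
#' Executes structure input -> canonical frame -> geometry -> pore profiling
#' -> gating energetics and collects everything in a report. Input is either
#' the synthetic MscK-mimic preset, a pair of structure files, or the
#' canonical parameter profile alone (no structures; geometry and pore stages
#' are skipped).
#'
#' @param config A list:
#'   * `preset`: `"msck-mimic"` (synthetic closed/open pair) or
#'     `"canonical"` (canonical MscK gating parameters, no structures), or
#'     NULL when `closed_path`/`open_path` are given;
#'   * `closed_path`, `open_path`: structure files (PDB/mmCIF);
#'   * `slab`: explicit slab bounds `c(z_min, z_max)` in A (default: the
#'     generator-suggested slab for the preset, `c(-16, 16)` for files);
#'   * `ring_residues`: periplasmic ring selection (default 100:103 for the
#'     preset);
#'   * `pore`: list(step, wander, r_max) for the pore profiler;
#'   * `energetics`: list(K_b, dG0);
#'   * `out_dir`: optional output directory for report.json + CSV tables;
#'   * `seed`: RNG seed for the synthetic preset.
#' @return A `mechgate_report` list: `geometry` (per-state tibble), `delta`,
#'   `pore` (per-state constriction tables and minimal diameters),
#'   `parameters`, `sigma_half_kBT_nm2`, `curve`, `provenance`.
#' @export
run_state_comparison <- function(config = list()) {
  cfg <- config
  cfg$seed <- cfg$seed %||% 1L
  cfg$pore <- cfg$pore %||% list()
  step <- cfg$pore$step %||% 0.5
  wander <- cfg$pore$wander %||% 5
  r_max <- cfg$pore$r_max %||% 15
  en <- cfg$energetics %||% list()
  K_b <- en$K_b %||% 20
  dG0 <- en$dG0 %||% 0
  preset <- cfg$preset %||% NULL

  geometry <- NULL; delta <- NULL; pore <- NULL
  if (identical(preset, "canonical")) {
    gp <- msck_parameters(K_b = K_b, dG0 = dG0)
  } else {
    if (identical(preset, "msck-mimic")) {
      pair <- make_state_pair(seed = cfg$seed)
      closed <- pair$closed$structure
      open <- pair$open$structure
      slab_b <- cfg$slab %||% c(
        min(pair$closed$ground_truth$suggested_slab[1],
            pair$open$ground_truth$suggested_slab[1]),
        max(pair$closed$ground_truth$suggested_slab[2],
            pair$open$ground_truth$suggested_slab[2]))
      ring_res <- cfg$ring_residues %||% 100:103
    } else {
      if (is.null(cfg$closed_path) || is.null(cfg$open_path)) {
        abort("Provide a preset or both closed_path and open_path",
              class = "mechgate_config_error")
      }
      closed <- load_state(cfg$closed_path, cfg$format %||% "auto")
      open <- load_state(cfg$open_path, cfg$format %||% "auto")
      slab_b <- cfg$slab %||% c(-16, 16)
      ring_res <- cfg$ring_residues
    }
    slab <- membrane_slab(slab_b[1], slab_b[2])
    prof_c <- measure_geometry(closed, slab, ring_residues = ring_res)
    prof_o <- measure_geometry(open, slab, ring_residues = ring_res)
    geometry <- bind_rows(closed = prof_c, open = prof_o, .id = "state")
    delta <- compare_states(prof_c, prof_o)
    pp_c <- pore_profile(closed, z_range = slab_b, step = step,
                         wander = wander, r_max = r_max)
    pp_o <- pore_profile(open, z_range = slab_b, step = step,
                         wander = wander, r_max = r_max)
    pore <- list(
      closed = list(profile = pp_c, gates = find_gates(pp_c, closed),
                    min_diameter_A = min_pore_diameter(pp_c)),
      open = list(profile = pp_o, gates = find_gates(pp_o, open),
                  min_diameter_A = min_pore_diameter(pp_o)))
    gp <- params_from_states(delta, K_b = K_b, dG0 = dG0)
  }
  sigma_half <- if (isTRUE(gp$well_posed)) midpoint_tension_root(gp) else NA_real_
  curve <- energetics_curve(gp, dG0 = dG0)
  report <- structure(list(
    geometry = geometry,
    delta = delta,
    pore = pore,
    parameters = tidy(gp),
    sigma_half_kBT_nm2 = sigma_half,
    sigma_half_mN_m = tension_to_mN_per_m(sigma_half),
    curve = curve,
    provenance = report_provenance(cfg)),
    class = "mechgate_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(geometry)) {
      readr::write_csv(geometry, file.path(cfg$out_dir, "geometry_deg_nm_A.csv"))
      readr::write_csv(as_tibble(pore$closed$profile),
                       file.path(cfg$out_dir, "pore_closed_A.csv"))
      readr::write_csv(as_tibble(pore$open$profile),
                       file.path(cfg$out_dir, "pore_open_A.csv"))
    }
    readr::write_csv(as_tibble(curve),
                     file.path(cfg$out_dir, "energetics_kBT_kBTnm2.csv"))
    json <- report
    json$curve <- NULL
    if (!is.null(json$pore)) {
      json$pore$closed$profile <- NULL
      json$pore$open$profile <- NULL
      json$pore$closed$gates$lining_residues <-
        purrr::map(json$pore$closed$gates$lining_residues, identity)
      json$pore$open$gates$lining_residues <-
        purrr::map(json$pore$open$gates$lining_residues, identity)
    }
    write_report_json(json, file.path(cfg$out_dir, "report.json"))
  }
  report
}

#' @export
print.mechgate_report <- function(x, ...) {
  cat("<mechgate_report>\n")
  if (!is.null(x$delta)) {
    cat(sprintf("  bending angle %.1f -> %.1f deg, delta_A %.1f nm^2\n",
                x$delta$theta_c_rad * 180 / pi, x$delta$theta_o_rad * 180 / pi,
                x$delta$delta_A_nm2))
  }
  if (!is.null(x$sigma_half_kBT_nm2)) {
    cat(sprintf("  sigma_half = %.4g kBT/nm^2 (%.3g mN/m)\n",
                x$sigma_half_kBT_nm2, x$sigma_half_mN_m))
  }
  if (!is.null(x$conductance)) {
    cat(sprintf("  unitary conductance %.0f pS (%d events)\n",
                x$conductance$g_pS, x$conductance$n_events))
  }
  invisible(x)
}

#' Run the electrophysiology pipeline
#'
#' Simulates (or loads) a pressure-ramp recording, estimates the unitary
#' conductance of the test channel, and, when a calibrator class is present,
#' the tension-sensitivity ratio.
#'
#' @param config A list:
#'   * `preset`: `"wildtype-mimic"` (one 895 pS channel flickering above
#'     40 mmHg) or `"two-population"` (test 895 pS at 40 mmHg + calibrator
#'     3650 pS at 100 mmHg), or NULL with `recording_path` set;
#'   * `recording_path`: CSV written by [write_recording()];
#'   * `test_conductance_pS`, `calibrator_conductance_pS`: amplitude-class
#'     definitions (defaults 895 and 3650);
#'   * `out_dir`: optional output directory;
#'   * `seed`: RNG seed for presets.
#' @return A `mechgate_report` list with `conductance`, `sensitivity` (or
#'   NULL) and `provenance`.
#' @export
run_ephys <- function(config = list()) {
  cfg <- config
  cfg$seed <- cfg$seed %||% 1L
  preset <- cfg$preset %||% NULL
  if (!is.null(preset)) {
    channels <- switch(
      preset,
      "wildtype-mimic" = tibble(conductance_pS = 895,
                                activation_pressure_mmHg = 40, count = 1L,
                                dwell_open_s = 0.03, dwell_closed_s = 0.03),
      "two-population" = tibble(conductance_pS = c(895, 3650),
                                activation_pressure_mmHg = c(40, 100),
                                count = c(1L, 1L)),
      abort(paste("Unknown preset:", preset), class = "mechgate_config_error"))
    rec <- simulate_patch_recording(recording_spec(channels = channels,
                                                   seed = cfg$seed))
  } else if (!is.null(cfg$recording_path)) {
    rec <- read_recording(cfg$recording_path)
  } else {
    abort("Provide a preset or recording_path", class = "mechgate_config_error")
  }
  g_test <- cfg$test_conductance_pS %||% 895
  g_cal <- cfg$calibrator_conductance_pS %||% 3650
  noise <- mad(diff(rec$current_pA)) / sqrt(2)
  cls_test <- amplitude_class(g_test, attr(rec, "voltage"), noise_sd = max(noise, 0.5))
  cls_cal <- amplitude_class(g_cal, attr(rec, "voltage"), noise_sd = max(noise, 0.5))
  conductance <- estimate_unitary_conductance(rec)
  sensitivity <- tryCatch(
    tension_sensitivity_ratio(rec, cls_test, cls_cal),
    mechgate_no_activation_error = function(e) NULL)
  report <- structure(list(conductance = conductance,
                           sensitivity = sensitivity,
                           provenance = report_provenance(cfg)),
                      class = "mechgate_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(conductance, file.path(cfg$out_dir, "conductance_pS.csv"))
    if (!is.null(sensitivity)) {
      readr::write_csv(sensitivity, file.path(cfg$out_dir, "sensitivity_mmHg.csv"))
    }
    json <- report
    write_report_json(json, file.path(cfg$out_dir, "ephys_report.json"))
  }
  report
}
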