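test_that("a noiseless two-level trace gives the exact unitary conductance", {
  rec <- simulate_patch_recording(recording_spec(
    noise_sd_pA = 0, channels = flicker_channels(895, 40), seed = 3))
  est <- estimate_unitary_conductance(rec)
  expect_equal(est$g_pS, 895, tolerance = 1e-6)
  expect_equal(abs(est$open_level_pA - est$baseline_pA), 26.85,
               tolerance = 1e-4)
  expect_gt(est$n_events, 20)
})

test_that("noisy seeded traces stay inside the 895 +/- 25 pS band", {
  for (seed in c(1, 17, 42)) {
    rec <- simulate_patch_recording(recording_spec(
      channels = flicker_channels(895, 40), seed = seed))
    est <- estimate_unitary_conductance(rec)
    expect_gt(est$g_pS, 870)
    expect_lt(est$g_pS, 920)
    expect_gt(est$n_events, 20)
  }
})

test_that("stacked openings of two copies still yield the unitary step", {
  rec <- simulate_patch_recording(recording_spec(
    channels = flicker_channels(895, 40, count = 2L), seed = 6))
  est <- estimate_unitary_conductance(rec)
  expect_equal(est$g_pS, 895, tolerance = 0.02 * 895)
})

test_that("conductance is invariant to baseline offset and voltage sign", {
  rec <- simulate_patch_recording(recording_spec(
    channels = flicker_channels(895, 40), seed = 9))
  g0 <- estimate_unitary_conductance(rec)$g_pS
  shifted <- rec
  shifted$current_pA <- shifted$current_pA + 10
  expect_equal(estimate_unitary_conductance(shifted)$g_pS, g0, tolerance = 1e-4)
  pos <- simulate_patch_recording(recording_spec(
    voltage_mV = 30, channels = flicker_channels(895, 40), seed = 9))
  expect_equal(estimate_unitary_conductance(pos)$g_pS, g0, tolerance = 0.01 * g0)
})

test_that("flat traces raise a structured no-events error", {
  rec <- simulate_patch_recording(recording_spec(
    channels = flicker_channels(895, 1e6), seed = 2))
  expect_error(estimate_unitary_conductance(rec),
               class = "mechgate_no_events_error")
})

test_that("the standard error shrinks with the number of events", {
  short <- simulate_patch_recording(recording_spec(
    duration_s = 12, channels = flicker_channels(895, 40), seed = 21))
  long <- simulate_patch_recording(recording_spec(
    duration_s = 40, channels = flicker_channels(895, 40), seed = 21))
  es <- estimate_unitary_conductance(short)
  el <- estimate_unitary_conductance(long)
  expect_gt(el$n_events, es$n_events)
  expect_lt(el$se_pS, es$se_pS)
})

test_that("mean recovery over seeded simulations is within 2 percent", {
  for (g_true in c(895, 3650)) {
    g <- vapply(1:25, function(seed) {
      rec <- simulate_patch_recording(recording_spec(
        channels = flicker_channels(g_true, 40), seed = seed))
      estimate_unitary_conductance(rec)$g_pS
    }, numeric(1))
    expect_lt(abs(mean(g) - g_true) / g_true, 0.02)
  }
})

test_that("first activation pressure matches the generator threshold", {
  rec <- simulate_patch_recording(recording_spec(
    channels = flicker_channels(895, 40), seed = 5))
  band <- amplitude_class(895, -30)
  expect_equal(first_activation_pressure(rec, band), 40, tolerance = 0.5)
})

test_that("a channel conducting from the first sample activates at its pressure", {
  rec <- simulate_patch_recording(recording_spec(
    channels = flicker_channels(895, 0), seed = 5))
  band <- amplitude_class(895, -30)
  expect_equal(first_activation_pressure(rec, band),
               abs(rec$pressure_mmHg[1]))
})

test_that("interleaved amplitude classes are separated correctly", {
  channels <- tibble::tibble(
    conductance_pS = c(895, 3650),
    activation_pressure_mmHg = c(40, 100),
    count = c(1L, 1L))
  rec <- simulate_patch_recording(recording_spec(
    duration_s = 30, channels = channels, seed = 13))
  band_k <- amplitude_class(895, -30)
  band_l <- amplitude_class(3650, -30)
  p_k <- first_activation_pressure(rec, band_k)
  p_l <- first_activation_pressure(rec, band_l)
  expect_equal(p_k, oracle_first_activation(rec, band_k), tolerance = 0.5)
  expect_equal(p_l, oracle_first_activation(rec, band_l), tolerance = 0.5)
  expect_error(first_activation_pressure(rec, c(300, 400)),
               class = "mechgate_no_activation_error")
})

test_that("the tension-sensitivity ratio reflects the generator thresholds", {
  channels <- tibble::tibble(
    conductance_pS = c(895, 3650),
    activation_pressure_mmHg = c(40, 100),
    count = c(1L, 1L))
  rec <- simulate_patch_recording(recording_spec(channels = channels, seed = 8))
  res <- tension_sensitivity_ratio(rec, amplitude_class(895, -30),
                                   amplitude_class(3650, -30))
  expect_equal(res$ratio, 2.5, tolerance = 0.02)
  # identical classes give a ratio of exactly 1
  same <- tension_sensitivity_ratio(rec, amplitude_class(895, -30),
                                    amplitude_class(895, -30))
  expect_identical(same$ratio, 1)
  # a lower activation threshold (W914A-like) raises the ratio
  gof <- tibble::tibble(
    conductance_pS = c(895, 3650),
    activation_pressure_mmHg = c(30, 100),
    count = c(1L, 1L))
  rec2 <- simulate_patch_recording(recording_spec(channels = gof, seed = 8))
  res2 <- tension_sensitivity_ratio(rec2, amplitude_class(895, -30),
                                    amplitude_class(3650, -30))
  expect_gt(res2$ratio, res$ratio)
})

test_that("recordings round-trip through CSV plus JSON sidecar", {
  rec <- simulate_patch_recording(recording_spec(
    duration_s = 2, channels = flicker_channels(895, 2), seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$current_pA, rec$current_pA)
  expect_equal(attr(back, "voltage"), -30)
  expect_equal(attr(back, "sample_rate"), 2000)
  expect_equal(attr(back, "ground_truth")$channels$conductance_pS, 895)
})
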