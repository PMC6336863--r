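test_that("background spike counts follow the Poisson expectation", {
  # 8 electrodes x 600 s x 1 Hz, no bursts: E[total] = 4800
  counts <- vapply(1:20, function(s) {
    nrow(simulate_spike_trains(
      sim_profile(n_electrodes = 8, duration_s = 600, base_rate_hz = 1,
                  burst_rate_per_min = 0, seed = s))$spikes)
  }, double(1))
  se_mean <- sqrt(4800 / 20)
  expect_lt(abs(mean(counts) - 4800), 3 * se_mean)
})

test_that("burst onsets follow the Poisson onset process", {
  nb <- vapply(1:20, function(s) {
    nrow(simulate_spike_trains(
      sim_profile(duration_s = 600, burst_rate_per_min = 6,
                  burst_participation = 1, seed = s))$bursts)
  }, double(1))
  expect_lt(abs(mean(nb) - 60), 3 * sqrt(60 / 20))
})

test_that("silent profiles generate no spikes and invalid profiles are rejected", {
  sim <- simulate_spike_trains(
    sim_profile(duration_s = 60, base_rate_hz = 0, burst_rate_per_min = 0))
  expect_equal(nrow(sim$spikes), 0L)
  expect_equal(nrow(sim$bursts), 0L)
  expect_error(sim_profile(base_rate_hz = -1), "base_rate_hz")
  expect_error(sim_profile(burst_participation = 1.4), "burst_participation")
  expect_error(sim_profile(duration_s = 0), "duration_s")
  expect_error(sim_profile(base_rate_hz = NaN), "base_rate_hz")
})

test_that("spike simulation is deterministic and internally consistent", {
  p <- sim_profile(duration_s = 120, seed = 42)
  a <- simulate_spike_trains(p)
  b <- simulate_spike_trains(p)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$bursts, b$bursts)
  # sorted within electrode, in range
  expect_true(all(a$spikes$time_s >= 0 & a$spikes$time_s < 120))
  by_el <- split(a$spikes$time_s, a$spikes$electrode_id)
  expect_true(all(vapply(by_el, function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
  # every ground-truth burst has spikes on every recruited electrode
  ok <- vapply(seq_len(nrow(a$bursts)), function(i) {
    b <- a$bursts[i, ]
    all(vapply(b$electrode_ids[[1]], function(el) {
      any(a$spikes$electrode_id == el &
            a$spikes$time_s >= b$onset_s &
            a$spikes$time_s <= b$onset_s + b$duration_s)
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("synthesized raw voltage has the requested spectral content", {
  empty <- spike_trains(data.frame(electrode_id = integer(), time_s = double()),
                        duration_s = 20, n_electrodes = 1)
  raw <- synthesize_raw(empty, fs_hz = 1000, noise_sd_uV = 0,
                        oscillations = data.frame(freq_hz = 5, amp_uV = 10),
                        seed = 1)
  psd <- compute_psd(raw$voltage_uV[1, ], fs_hz = 1000)
  expect_equal(psd$freq_hz[which.max(psd$psd_uV2_per_hz)], 5)

  # estimator consistency on pure noise of known SD
  raw_n <- synthesize_raw(empty, fs_hz = 5000, noise_sd_uV = 10, seed = 2,
                          duration_s = 20)
  expect_lt(abs(estimate_noise_sigma(raw_n$voltage_uV[1, ]) - 10) / 10, 0.05)

  # 1/f noise is still scaled to the requested SD
  raw_p <- synthesize_raw(empty, fs_hz = 5000, noise_sd_uV = 10,
                          one_over_f_exponent = 1, seed = 3)
  expect_equal(sd(raw_p$voltage_uV[1, ]), 10, tolerance = 0.01)

  expect_error(
    synthesize_raw(empty, fs_hz = 100,
                   oscillations = data.frame(freq_hz = 60, amp_uV = 1)),
    "alias")
})

test_that("zero-amplitude spikes leave nothing to detect (TTX emulation)", {
  sim <- simulate_spike_trains(sim_profile(duration_s = 30, seed = 5))
  raw <- synthesize_raw(sim$spikes, fs_hz = 5000, spike_amp_sigma = 0,
                        noise_sd_uV = 10, seed = 6)
  expect_equal(nrow(detect_spikes(raw)), 0L)
})

test_that("calcium simulation honors coupling structure", {
  # full coupling, no noise: all traces identical, pairwise correlation 1
  sim <- simulate_calcium(
    calcium_profile(n_cells = 5, coupling_per_cell = 1, noise_sd = 0, seed = 1),
    drive_event_rate_per_min = 6, duration_s = 200)
  cc <- cor(t(sim$F))
  expect_true(all(abs(cc - 1) < 1e-12))

  # zero coupling, private events only: near-zero pairwise correlation
  sim0 <- simulate_calcium(
    calcium_profile(n_cells = 6, fs_hz = 10, coupling_per_cell = 0,
                    noise_sd = 0.02, seed = 2),
    drive_event_rate_per_min = 6, duration_s = 1500,
    private_event_rate_per_min = 4)
  expect_gte(ncol(sim0$F), 5000)
  cc0 <- cor(t(sim0$F))
  expect_lt(max(abs(cc0[upper.tri(cc0)])), 0.1)

  # zero event rates: flat baseline
  simf <- simulate_calcium(
    calcium_profile(n_cells = 3, noise_sd = 0, seed = 3),
    drive_event_rate_per_min = 0, duration_s = 60)
  expect_true(all(simf$F == simf$F[1, 1]))

  expect_error(
    simulate_calcium(calcium_profile(n_cells = 2, fs_hz = 1, tau_rise_s = 0.2,
                                     tau_decay_s = 1.5), duration_s = 60),
    "fs_hz too low")
})

test_that("generated morphologies hit the length target and are valid", {
  p <- morphology_params(target_total_length_um = 848, seed = 9)
  m <- generate_morphology(p)
  out <- morpho_summary(m)
  expect_gte(out$total_outgrowth_um, 763)
  expect_lte(out$total_outgrowth_um, 933)
  expect_equal(out$n_primary_neurites, 3L)
  expect_silent(new_neuron_morphology(m))  # re-runs the structural checks

  # same seed => byte-identical SWC
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(generate_morphology(p), f1)
  write_swc(generate_morphology(p), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(morphology_params(target_total_length_um = 5,
                                 mean_segment_um = 20), "target_total_length")
})

test_that("puncta fields realize the requested colocalization structure", {
  # fraction 1, zero jitter: every pre punctum has an exactly coincident post
  f1 <- generate_puncta(puncta_params(colocalization_fraction = 1,
                                      jitter_um = 0, post_density_per_um = 0.4,
                                      seed = 1))
  expect_gt(nrow(f1$pre), 0)
  d <- sqrt(outer(f1$pre$x, f1$post$x, "-")^2 +
              outer(f1$pre$y, f1$post$y, "-")^2)
  expect_true(all(apply(d, 1, min) < 1e-9))

  # fraction 0 at low density: only chance-level pairs, bounded by a
  # Poisson tail on the analytic expectation of uniform matches
  f0 <- generate_puncta(puncta_params(neurite_length_um = 100,
                                      pre_density_per_um = 0.05,
                                      post_density_per_um = 0.05,
                                      colocalization_fraction = 0,
                                      image_shape = c(96, 1100), seed = 2))
  res <- colocalize_and_density(f0$pre, f0$post, 100)
  # x displacements uniform over ~100 um: P(|dx| < 0.5) ~ 2*0.5/100 per pair
  lam <- nrow(f0$pre) * nrow(f0$post) * (2 * 0.5) / 100
  expect_lte(res$n_pairs, qpois(0.999, lam))

  # zero density: empty field
  fe <- generate_puncta(puncta_params(pre_density_per_um = 0,
                                      post_density_per_um = 0, seed = 3))
  expect_equal(nrow(fe$pre), 0L)
  expect_equal(nrow(fe$post), 0L)

  expect_error(
    generate_puncta(puncta_params(neurite_length_um = 100,
                                  image_shape = c(64, 64))),
    "image too small")
})

test_that("all generators are seed-reproducible", {
  expect_identical(
    simulate_calcium(calcium_profile(n_cells = 4, seed = 7), duration_s = 60),
    simulate_calcium(calcium_profile(n_cells = 4, seed = 7), duration_s = 60))
  expect_identical(generate_puncta(puncta_params(seed = 7)),
                   generate_puncta(puncta_params(seed = 7)))
  expect_identical(generate_morphology(morphology_params(seed = 7)),
                   generate_morphology(morphology_params(seed = 7)))
})
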