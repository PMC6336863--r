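test_that("robust noise estimate is consistent and spike-resistant", {
  withr::with_seed(1, {
    x <- rnorm(1e5, sd = 10)
    expect_lt(abs(estimate_noise_sigma(x) - 10) / 10, 0.05)
    expect_equal(estimate_noise_sigma(rep(3.2, 200)), 0)
    # contaminate 1% of samples with 100 uV spikes: MAD stays near 10 while
    # the plain SD inflates
    idx <- sample.int(1e5, 1e3)
    x[idx] <- x[idx] + 100
    expect_lt(abs(estimate_noise_sigma(x) - 10) / 10, 0.10)
    expect_gt(sd(x), 1.2 * estimate_noise_sigma(x))
  })
  expect_error(estimate_noise_sigma(rnorm(50)), "too short")
  expect_error(estimate_noise_sigma(c(rnorm(200), NA)), "non-finite")
})

test_that("threshold detection recovers injected spikes and nothing else", {
  fs <- 5000
  truth <- spike_trains(
    data.frame(electrode_id = 1L, time_s = sort(runif(50, 1, 59)) |>
                 (\(x) x[c(TRUE, diff(x) > 0.02)])()),
    duration_s = 60, n_electrodes = 1)
  raw <- synthesize_raw(truth, fs_hz = fs, spike_amp_sigma = 10,
                        noise_sd_uV = 10, seed = 4)
  det <- detect_spikes(raw, threshold_sigma = 6)
  # match detections to truth within 2 ms
  hits <- vapply(truth$time_s,
                 function(t) any(abs(det$time_s - t) <= 0.002), logical(1))
  matched <- vapply(det$time_s,
                    function(t) any(abs(truth$time_s - t) <= 0.002), logical(1))
  expect_gte(mean(hits), 0.95)     # recall
  expect_gte(mean(matched), 0.95)  # precision
})

test_that("false positives on pure noise stay near the Gaussian tail bound", {
  empty <- spike_trains(data.frame(electrode_id = integer(), time_s = double()),
                        duration_s = 60, n_electrodes = 1)
  raw <- synthesize_raw(empty, fs_hz = 12500, noise_sd_uV = 10, seed = 8)
  det <- detect_spikes(raw, threshold_sigma = 6)
  # analytic expectation 2 * pnorm(-6) * n_samples is well below 1
  expect_lt(2 * pnorm(-6) * 60 * 12500, 0.01)
  expect_lte(nrow(det), 3)
})

test_that("spike counts match a brute-force suprathreshold scan", {
  withr::with_seed(9, {
    v <- rnorm(5000)
    spikes_at <- c(1000, 1003, 2500, 4000)   # two nearby, two isolated
    v[spikes_at] <- 12
    raw <- structure(list(voltage_uV = matrix(v, nrow = 1), fs_hz = 1000,
                          div_day = NA_integer_, well_id = "w"),
                     class = "raw_recording")
    det <- detect_spikes(raw, threshold_sigma = 6, refractory_ms = 5)
    # brute force: crossings of 6*sigma merged within 5 samples
    sigma <- mad(v)
    idx <- which(abs(v) >= 6 * sigma)
    n_groups <- sum(diff(c(-100, idx)) > 5)
    expect_equal(nrow(det), n_groups)
    expect_equal(nrow(det), 3L)   # the 3-sample pair merges
  })
})

test_that("activity criterion is an inclusive 5 spikes/min threshold", {
  mk <- function(n) spike_trains(
    data.frame(electrode_id = rep(1L, n), time_s = seq(0, 1799, length.out = n)),
    duration_s = 1800, n_electrodes = 2)
  expect_equal(active_electrodes(mk(150)), 1L)      # exactly 5/min: active
  expect_equal(length(active_electrodes(mk(149))), 0L)
  empty <- spike_trains(data.frame(electrode_id = integer(), time_s = double()),
                        duration_s = 1800, n_electrodes = 2)
  expect_equal(length(active_electrodes(empty)), 0L)
})

test_that("weighted mean firing rate averages active electrodes only", {
  dur <- 600
  df <- rbind(
    data.frame(electrode_id = 1L, time_s = seq(0, dur - 1, length.out = 2 * dur)),
    data.frame(electrode_id = 2L, time_s = seq(0, dur - 1, length.out = 4 * dur)))
  st <- spike_trains(df, dur, n_electrodes = 8)   # six silent electrodes
  expect_equal(weighted_mean_firing_rate(st), 3)
  # adding more silent electrodes changes nothing
  st2 <- spike_trains(df, dur, n_electrodes = 16)
  expect_equal(weighted_mean_firing_rate(st2), 3)

  one <- spike_trains(data.frame(electrode_id = 1L,
                                 time_s = seq(0, 59.9, length.out = 300)),
                      60, 1)
  expect_equal(weighted_mean_firing_rate(one), 5)
  silent <- spike_trains(data.frame(electrode_id = 1L, time_s = 1), 600, 8)
  expect_equal(weighted_mean_firing_rate(silent), 0)
})

test_that("network-burst detection recovers generator ground truth", {
  sim <- simulate_spike_trains(
    sim_profile(duration_s = 600, burst_participation = 1, seed = 11))
  b <- detect_network_bursts(sim$spikes)
  expect_lt(abs(nrow(b) - nrow(sim$bursts)) / nrow(sim$bursts), 0.10)
  expect_lt(abs(attr(b, "mean_breadth") - 8), 1)
  expect_equal(attr(b, "burst_freq_per_min"), nrow(b) / 10)
})

test_that("bursts below the electrode criterion are not reported", {
  sim <- simulate_spike_trains(
    sim_profile(duration_s = 300, burst_participation = 0.5,
                base_rate_hz = 0, seed = 12))
  # bursts recruit 4 of 8 electrodes; criterion needs 5
  b <- detect_network_bursts(sim$spikes, min_active_electrodes = 5)
  expect_equal(nrow(b), 0L)
  expect_error(detect_network_bursts(sim$spikes, bin_ms = 400e3), "bin_ms")
})

test_that("independent firing yields chance-level burst rates", {
  st <- poisson_trains(8, 0.5, 600, seed = 13)
  observed <- nrow(detect_network_bursts(st, min_rate_per_min = 5))
  # shuffling oracle: spike times redrawn uniformly preserve rates only
  shuffled <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      df <- data.frame(electrode_id = st$electrode_id,
                       time_s = runif(nrow(st), 0, 600))
      nrow(detect_network_bursts(spike_trains(df, 600, 8)))
    })
  }, double(1))
  expect_lte(observed, max(max(shuffled), 2))
})

test_that("burst detection commutes with time reversal", {
  sim <- simulate_spike_trains(sim_profile(duration_s = 300, seed = 14))
  b_fwd <- detect_network_bursts(sim$spikes)
  dur <- 300
  rev <- spike_trains(data.frame(electrode_id = sim$spikes$electrode_id,
                                 time_s = dur - sim$spikes$time_s - 1e-9),
                      dur, attr(sim$spikes, "n_electrodes"))
  b_rev <- detect_network_bursts(rev)
  expect_equal(nrow(b_rev), nrow(b_fwd))
  mid_fwd <- sort((b_fwd$start_s + b_fwd$end_s) / 2)
  mid_rev <- sort(dur - (b_rev$start_s + b_rev$end_s) / 2)
  expect_true(all(abs(mid_fwd - mid_rev) < 0.08))
})

test_that("synchrony index is 1 for duplicates, ~0 for independence", {
  withr::with_seed(15, {
    train <- sort(runif(1200, 0, 600))
    dup <- duplicated_trains(train, 8, 600)
    expect_equal(synchrony_index(dup), 1)
  })
  ind <- poisson_trains(8, 2, 600, seed = 16)
  expect_lt(abs(synchrony_index(ind)), 0.05)
  # fewer than two active electrodes: defined as 0
  one <- spike_trains(data.frame(electrode_id = 1L,
                                 time_s = seq(0, 599, by = 0.5)), 600, 8)
  expect_equal(synchrony_index(one), 0)
})

test_that("synchrony decreases with jitter and ignores global time shifts", {
  withr::with_seed(17, {
    base <- sort(runif(1200, 1, 549))
    si <- vapply(c(8, 16, 32, 64) / 1000, function(j) {
      df <- do.call(rbind, lapply(1:8, function(e) {
        data.frame(electrode_id = e,
                   time_s = pmin(599.9, pmax(0, base + rnorm(1200, 0, j))))
      }))
      synchrony_index(spike_trains(df, 600, 8))
    }, double(1))
    expect_true(all(diff(si) < 0))
  })
  st <- poisson_trains(4, 2, 500, seed = 18)
  shifted <- spike_trains(data.frame(electrode_id = st$electrode_id,
                                     time_s = st$time_s + 50),
                          600, 4)
  orig <- spike_trains(as.data.frame(st), 600, 4)
  expect_equal(synchrony_index(shifted), synchrony_index(orig))
})

test_that("activity summary collects the per-recording metrics", {
  sim <- simulate_spike_trains(sim_profile(duration_s = 300, seed = 19))
  s <- activity_summary(sim$spikes)
  expect_named(s, c("wmfr_hz", "n_active", "burst_freq_per_min",
                    "burst_freq_normalized", "mean_burst_breadth",
                    "synchrony_index"))
  expect_gt(s$wmfr_hz, 0)
  expect_equal(s$n_active, 8L)
  sn <- activity_summary(sim$spikes, normalize_burst_freq = TRUE)
  expect_equal(sn$burst_freq_per_min, s$burst_freq_per_min / s$n_active)
})
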