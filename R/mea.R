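#' Robust noise estimate of an extracellular trace
#'
#' Median-absolute-deviation estimate of the noise standard deviation,
#' `MAD / 0.6745`, which is insensitive to sparse large-amplitude spikes that
#' would inflate a plain SD.
#'
#' @param trace Numeric voltage series (uV).
#' @return Estimated noise SD (uV).
#' @export
estimate_noise_sigma <- function(trace) {
  if (any(!is.finite(trace))) abort("trace contains non-finite samples.")
  if (length(trace) < 100) abort("trace too short (< 100 samples) for a noise estimate.")
  stats::mad(trace)
}

#' Detect spikes by amplitude threshold crossing
#'
#' Flags samples whose absolute voltage reaches `threshold_sigma` times the
#' per-electrode robust noise SD (both polarities, since extracellular field
#' potentials are biphasic). Crossings closer together than `refractory_ms`
#' are collapsed to the sample of largest absolute amplitude.
#'
#' @param raw A `raw_recording` (see [synthesize_raw()]).
#' @param threshold_sigma Detection threshold in noise SDs (default 6).
#' @param refractory_ms Merge window (ms, default 1).
#' @return A [spike_trains] tibble.
#' @export
detect_spikes <- function(raw, threshold_sigma = 6, refractory_ms = 1) {
  stopifnot(inherits(raw, "raw_recording"))
  check_scalar(threshold_sigma, "threshold_sigma", min = 0)
  check_scalar(refractory_ms, "refractory_ms", min = 0)
  if (any(!is.finite(raw$voltage_uV))) abort("recording contains non-finite voltage.")
  fs <- raw$fs_hz
  refr <- max(1L, round(refractory_ms / 1000 * fs))
  n_el <- nrow(raw$voltage_uV)
  out <- vector("list", n_el)
  for (el in seq_len(n_el)) {
    v <- raw$voltage_uV[el, ]
    sigma <- estimate_noise_sigma(v)
    if (sigma <= 0) { out[[el]] <- NULL; next }
    idx <- which(abs(v) >= threshold_sigma * sigma)
    if (!length(idx)) next
    grp <- cumsum(c(1L, diff(idx) > refr))
    peak <- vapply(split(idx, grp), function(ii) ii[which.max(abs(v[ii]))],
                   integer(1))
    out[[el]] <- tibble::tibble(electrode_id = el,
                                time_s = (peak - 1) / fs)
  }
  spike_trains(dplyr::bind_rows(out), duration_s = ncol(raw$voltage_uV) / fs,
               n_electrodes = n_el)
}

#' Active electrodes under the spikes-per-minute criterion
#'
#' An electrode is active when its mean firing rate over the whole recording
#' reaches `min_rate_per_min` spikes per minute (inclusive).
#'
#' @param spikes A [spike_trains] tibble.
#' @param min_rate_per_min Activity criterion (default 5 spikes/min).
#' @param duration_s Override recording duration (s).
#' @return Integer vector of active electrode ids.
#' @export
active_electrodes <- function(spikes, min_rate_per_min = 5, duration_s = NULL) {
  dur <- st_duration(spikes, duration_s)
  counts <- dplyr::count(tibble::as_tibble(spikes), .data$electrode_id)
  sort(counts$electrode_id[counts$n / (dur / 60) >= min_rate_per_min])
}

#' Weighted mean firing rate
#'
#' Total spike count on active electrodes divided by (number of active
#' electrodes x duration): the per-electrode firing rate averaged over
#' electrodes meeting the activity criterion only. Returns 0 when no
#' electrode is active; silent electrodes never enter the denominator.
#'
#' @inheritParams active_electrodes
#' @return Firing rate (Hz).
#' @export
weighted_mean_firing_rate <- function(spikes, min_rate_per_min = 5,
                                      duration_s = NULL) {
  dur <- st_duration(spikes, duration_s)
  act <- active_electrodes(spikes, min_rate_per_min, dur)
  if (!length(act)) return(0)
  n_sp <- sum(spikes$electrode_id %in% act)
  n_sp / (length(act) * dur)
}

#' Detect network bursts
#'
#' Spikes from active electrodes are binned at `bin_ms`; bins in which at
#' least `min_active_electrodes` distinct active electrodes fire are burst
#' bins. Runs of burst bins separated by gaps shorter than `min_gap_ms` are
#' merged into one network burst; breadth is the number of distinct
#' electrodes firing within the burst interval.
#'
#' @inheritParams active_electrodes
#' @param bin_ms Bin width (ms, default 25).
#' @param min_active_electrodes Electrode criterion per bin (default 5).
#' @param min_gap_ms Gaps shorter than this are joined (ms, default 100).
#' @return Tibble of class `network_bursts` (`start_s`, `end_s`,
#'   `n_electrodes`, `n_spikes`) with attributes `burst_freq_per_min` and
#'   `mean_breadth`.
#' @export
detect_network_bursts <- function(spikes, bin_ms = 25,
                                  min_active_electrodes = 5,
                                  min_gap_ms = 100, min_rate_per_min = 5,
                                  duration_s = NULL) {
  dur <- st_duration(spikes, duration_s)
  check_scalar(bin_ms, "bin_ms", min = .Machine$double.eps)
  if (bin_ms / 1000 > dur) abort("bin_ms exceeds the recording duration.")
  act <- active_electrodes(spikes, min_rate_per_min, dur)
  empty <- tibble::tibble(start_s = double(), end_s = double(),
                          n_electrodes = integer(), n_spikes = integer())
  finish <- function(df) {
    structure(df,
              burst_freq_per_min = nrow(df) / (dur / 60),
              mean_breadth = if (nrow(df)) mean(df$n_electrodes) else NA_real_,
              class = c("network_bursts", class(df)))
  }
  sp <- spikes[spikes$electrode_id %in% act, ]
  if (!nrow(sp)) return(finish(empty))
  bw <- bin_ms / 1000
  bin <- pmin(floor(sp$time_s / bw), ceiling(dur / bw) - 1)
  per_bin <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, el = sp$electrode_id), .data$bin),
    n_el = dplyr::n_distinct(.data$el), .groups = "drop")
  hot <- sort(per_bin$bin[per_bin$n_el >= min_active_electrodes])
  if (!length(hot)) return(finish(empty))
  gap_bins <- ceiling(min_gap_ms / bin_ms)
  run <- cumsum(c(1L, diff(hot) > gap_bins))
  bursts <- purrr::map_dfr(split(hot, run), function(bb) {
    t0 <- min(bb) * bw; t1 <- (max(bb) + 1) * bw
    inb <- spikes$time_s >= t0 & spikes$time_s < t1
    tibble::tibble(start_s = t0, end_s = t1,
                   n_electrodes = dplyr::n_distinct(spikes$electrode_id[inb]),
                   n_spikes = sum(inb))
  })
  finish(bursts)
}

#' Chance-corrected synchrony index
#'
#' For each pair of active electrodes, coincidences are spike pairs within
#' `window_ms`; the count is corrected by the chance expectation for
#' independent trains of the same rates (`n_i * n_j * 2w / T`) and normalized
#' by `sqrt(n_i * n_j)` minus the same chance term, so identical trains score
#' 1 and independent trains score about 0. Pair scores are clipped to
#' \[0, 1\] and averaged.
#'
#' @inheritParams active_electrodes
#' @param window_ms Coincidence half-window (ms, default 20).
#' @return Synchrony index in \[0, 1\]; 0 when fewer than two electrodes are
#'   active.
#' @export
synchrony_index <- function(spikes, window_ms = 20, min_rate_per_min = 5,
                            duration_s = NULL) {
  dur <- st_duration(spikes, duration_s)
  w <- window_ms / 1000
  act <- active_electrodes(spikes, min_rate_per_min, dur)
  if (length(act) < 2) return(0)
  trains <- purrr::map(act, ~ sort(spikes$time_s[spikes$electrode_id == .x]))
  pair_scores <- c()
  for (i in seq_along(trains)) for (j in seq_along(trains)) {
    if (j <= i) next
    ti <- trains[[i]]; tj <- trains[[j]]
    cc <- sum(findInterval(ti + w, tj) - findInterval(ti - w, tj, left.open = TRUE))
    chance <- length(ti) * length(tj) * 2 * w / dur
    den <- sqrt(length(ti) * length(tj)) - chance
    s <- if (den > 0) (cc - chance) / den else 0
    pair_scores <- c(pair_scores, min(1, max(0, s)))
  }
  mean(pair_scores)
}

#' Per-recording network activity summary
#'
#' One row of the standard network-development metrics: weighted mean firing rate,
#' active-electrode count, network-burst frequency (per minute; optionally
#' normalized per active electrode), mean burst breadth and synchrony index.
#'
#' @inheritParams detect_network_bursts
#' @param window_ms Synchrony coincidence window (ms).
#' @param normalize_burst_freq Divide burst frequency by the active-electrode
#'   count (flagged in the `burst_freq_normalized` column).
#' @return One-row tibble.
#' @export
activity_summary <- function(spikes, min_rate_per_min = 5, bin_ms = 25,
                             min_active_electrodes = 5, min_gap_ms = 100,
                             window_ms = 20, normalize_burst_freq = FALSE,
                             duration_s = NULL) {
  dur <- st_duration(spikes, duration_s)
  act <- active_electrodes(spikes, min_rate_per_min, dur)
  bursts <- detect_network_bursts(spikes, bin_ms, min_active_electrodes,
                                  min_gap_ms, min_rate_per_min, dur)
  bf <- attr(bursts, "burst_freq_per_min")
  if (normalize_burst_freq) bf <- if (length(act)) bf / length(act) else 0
  tibble::tibble(
    wmfr_hz = weighted_mean_firing_rate(spikes, min_rate_per_min, dur),
    n_active = length(act),
    burst_freq_per_min = bf,
    burst_freq_normalized = normalize_burst_freq,
    mean_burst_breadth = attr(bursts, "mean_breadth"),
    synchrony_index = synchrony_index(spikes, window_ms, min_rate_per_min, dur))
}
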