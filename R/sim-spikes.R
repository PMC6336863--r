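#' Construct a spike-train table
#'
#' The package's spike-train container is an ordinary tibble with columns
#' `electrode_id` (integer) and `time_s` (seconds, sorted within electrode),
#' carrying the recording duration and electrode count as attributes so that
#' downstream rate-based metrics know the denominator even for silent
#' electrodes.
#'
#' @param df Data frame with columns `electrode_id`, `time_s`.
#' @param duration_s Recording duration (s); all times must fall in
#'   \[0, duration_s).
#' @param n_electrodes Total electrodes in the well (including silent ones);
#'   defaults to the largest id seen.
#' @return A tibble of class `spike_trains`.
#' @export
spike_trains <- function(df, duration_s, n_electrodes = NULL) {
  check_scalar(duration_s, "duration_s", min = .Machine$double.eps)
  df <- tibble::as_tibble(df)
  if (!nrow(df)) {
    df <- tibble::tibble(electrode_id = integer(), time_s = double())
  }
  df <- df[c("electrode_id", "time_s")]
  if (nrow(df) > 0) {
    if (any(!is.finite(df$time_s)) || any(df$time_s < 0) ||
        any(df$time_s >= duration_s)) {
      abort("spike times must be finite and in [0, duration_s).")
    }
    df <- dplyr::arrange(df, .data$electrode_id, .data$time_s)
  }
  n_electrodes <- n_electrodes %||%
    if (nrow(df)) max(df$electrode_id) else 0L
  df$electrode_id <- as.integer(df$electrode_id)
  structure(df, duration_s = duration_s,
            n_electrodes = as.integer(n_electrodes),
            class = c("spike_trains", class(df)))
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains: %d spikes, %d electrodes, %.1f s>\n",
              nrow(x), attr(x, "n_electrodes"), attr(x, "duration_s")))
  NextMethod()
}

st_duration <- function(spikes, duration_s = NULL) {
  d <- duration_s %||% attr(spikes, "duration_s")
  if (is.null(d)) abort("supply `duration_s` or a `spike_trains` object.")
  d
}

st_n_electrodes <- function(spikes, n_electrodes = NULL) {
  n <- n_electrodes %||% attr(spikes, "n_electrodes") %||%
    (if (nrow(spikes)) max(spikes$electrode_id) else 0L)
  as.integer(n)
}

#' Simulate multielectrode spike trains with network bursts
#'
#' Generates per-electrode spike times as the superposition of background
#' Poisson firing and network bursts. Burst onsets follow a homogeneous
#' Poisson process at `burst_rate_per_min`; each burst recruits
#' `round(burst_participation * n_electrodes)` electrodes chosen uniformly
#' without replacement. Within a burst, a shared "mother" Poisson train at
#' `within_burst_rate_hz` is thinned per recruited electrode with probability
#' `synchrony_coupling`; each electrode additionally receives an independent
#' in-burst Poisson train at the complementary rate, so expected in-burst
#' firing is the same at any coupling. A recruited electrode that drew no
#' in-burst spike is given one uniform spike inside the burst window so the
#' returned ground truth is always consistent with the emitted data.
#'
#' @param profile A [sim_profile()].
#' @return A list of class `mea_simulation` with elements `spikes`
#'   (a [spike_trains] tibble), `bursts` (ground-truth tibble: `burst_id`,
#'   `onset_s`, `duration_s`, `electrode_ids` list-column), and `profile`.
#' @export
#' @examples
#' sim <- simulate_spike_trains(sim_profile(duration_s = 60, seed = 7))
#' nrow(sim$spikes); nrow(sim$bursts)
simulate_spike_trains <- function(profile) {
  stopifnot(inherits(profile, "sim_profile"))
  p <- profile
  withr::with_seed(p$seed, {
    # background firing
    n_bg <- rpois(p$n_electrodes, p$base_rate_hz * p$duration_s)
    bg <- purrr::map2(seq_len(p$n_electrodes), n_bg,
                      ~ tibble::tibble(electrode_id = .x,
                                       time_s = runif(.y, 0, p$duration_s)))

    # burst onsets: homogeneous Poisson process
    n_bursts <- rpois(1, p$burst_rate_per_min / 60 * p$duration_s)
    onsets <- sort(runif(n_bursts, 0, max(p$duration_s - p$burst_duration_s, 0)))
    n_recruit <- round(p$burst_participation * p$n_electrodes)
    burst_rows <- vector("list", n_bursts)
    burst_spikes <- vector("list", n_bursts)
    for (b in seq_len(n_bursts)) {
      recruited <- sort(sample.int(p$n_electrodes, n_recruit))
      t0 <- onsets[b]
      n_mother <- rpois(1, p$within_burst_rate_hz * p$burst_duration_s)
      mother <- runif(n_mother, t0, t0 + p$burst_duration_s)
      per_el <- purrr::map(recruited, function(el) {
        kept <- mother[runif(length(mother)) < p$synchrony_coupling]
        n_own <- rpois(1, (1 - p$synchrony_coupling) *
                         p$within_burst_rate_hz * p$burst_duration_s)
        own <- runif(n_own, t0, t0 + p$burst_duration_s)
        ts <- c(kept, own)
        if (!length(ts)) ts <- runif(1, t0, t0 + p$burst_duration_s)
        tibble::tibble(electrode_id = el, time_s = ts)
      })
      burst_spikes[[b]] <- dplyr::bind_rows(per_el)
      burst_rows[[b]] <- tibble::tibble(
        burst_id = b, onset_s = t0, duration_s = p$burst_duration_s,
        electrode_ids = list(recruited))
    }

    spikes <- dplyr::bind_rows(dplyr::bind_rows(bg), dplyr::bind_rows(burst_spikes))
    spikes <- spikes[spikes$time_s >= 0 & spikes$time_s < p$duration_s, ]
    spikes <- dplyr::distinct(dplyr::arrange(spikes, .data$electrode_id,
                                             .data$time_s))
    bursts <- if (n_bursts) dplyr::bind_rows(burst_rows) else
      tibble::tibble(burst_id = integer(), onset_s = double(),
                     duration_s = double(), electrode_ids = list())
    structure(
      list(spikes = spike_trains(spikes, p$duration_s, p$n_electrodes),
           bursts = bursts, profile = p),
      class = "mea_simulation")
  })
}

# 2 ms biphasic spike template (negative-leading), peak amplitude 1
spike_template <- function(fs_hz, width_ms = 2) {
  n <- max(3L, round(width_ms / 1000 * fs_hz))
  tt <- seq(0, 1, length.out = n)
  w <- -sin(2 * pi * tt) * sin(pi * tt)  # tapered biphasic
  w / max(abs(w))
}

# noise with power spectral density proportional to 1/f^chi, unit variance
shaped_noise <- function(n, chi) {
  if (chi == 0) return(rnorm(n))
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f ^ (-chi / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))  # Nyquist bin real
    if (nf > 1) full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  as.numeric(x / sd(x))
}

#' Synthesize a raw extracellular voltage recording from spike trains
#'
#' Renders each spike as a brief biphasic waveform whose peak is
#' `spike_amp_sigma` times the noise SD, adds the requested sinusoidal
#' oscillations, and adds noise with spectral exponent `one_over_f_exponent`
#' (0 = white Gaussian, 1 = pink) scaled to `noise_sd_uV`.
#'
#' @param spikes A [spike_trains] tibble (or data frame with `electrode_id`,
#'   `time_s`).
#' @param fs_hz Sampling rate (Hz); must exceed twice the highest oscillation
#'   frequency.
#' @param spike_amp_sigma Spike peak amplitude as a multiple of `noise_sd_uV`.
#' @param oscillations Data frame (or NULL) with columns `freq_hz`, `amp_uV`:
#'   sinusoids added to every electrode.
#' @param noise_sd_uV Noise standard deviation (uV).
#' @param one_over_f_exponent Spectral exponent chi of the noise
#'   (PSD proportional to 1/f^chi).
#' @param duration_s,n_electrodes Overrides when `spikes` is a plain data
#'   frame.
#' @param div_day,well_id Metadata carried on the recording.
#' @param seed Integer seed.
#' @return A list of class `raw_recording`: `voltage_uV` (electrodes x
#'   samples matrix), `fs_hz`, `div_day`, `well_id`.
#' @export
synthesize_raw <- function(spikes, fs_hz = 12500, spike_amp_sigma = 10,
                           oscillations = NULL, noise_sd_uV = 10,
                           one_over_f_exponent = 0, duration_s = NULL,
                           n_electrodes = NULL, div_day = NA_integer_,
                           well_id = "sim", seed = 1) {
  duration_s <- st_duration(spikes, duration_s)
  n_el <- st_n_electrodes(spikes, n_electrodes)
  check_scalar(fs_hz, "fs_hz", min = 1)
  check_scalar(spike_amp_sigma, "spike_amp_sigma", min = 0)
  check_scalar(noise_sd_uV, "noise_sd_uV", min = 0)
  check_scalar(one_over_f_exponent, "one_over_f_exponent", min = 0)
  if (!is.null(oscillations) && nrow(as.data.frame(oscillations))) {
    oscillations <- as.data.frame(oscillations)
    if (any(oscillations$freq_hz >= fs_hz / 2)) {
      abort("oscillation frequency at or above Nyquist would alias; lower it or raise fs_hz.")
    }
  }
  n_samp <- round(duration_s * fs_hz)
  tmpl <- spike_template(fs_hz)
  withr::with_seed(seed, {
    v <- matrix(0, nrow = n_el, ncol = n_samp)
    for (el in seq_len(n_el)) {
      x <- if (noise_sd_uV > 0) {
        noise_sd_uV * shaped_noise(n_samp, one_over_f_exponent)
      } else numeric(n_samp)
      if (!is.null(oscillations) && nrow(oscillations)) {
        tt <- seq_len(n_samp) / fs_hz
        for (k in seq_len(nrow(oscillations))) {
          x <- x + oscillations$amp_uV[k] *
            sin(2 * pi * oscillations$freq_hz[k] * tt)
        }
      }
      ts <- spikes$time_s[spikes$electrode_id == el]
      if (length(ts) && spike_amp_sigma > 0) {
        amp <- spike_amp_sigma * noise_sd_uV
        idx0 <- round(ts * fs_hz)
        for (i0 in idx0) {
          j <- i0 + seq_along(tmpl)
          ok <- j >= 1 & j <= n_samp
          x[j[ok]] <- x[j[ok]] + amp * tmpl[ok]
        }
      }
      v[el, ] <- x
    }
    structure(list(voltage_uV = v, fs_hz = fs_hz,
                   div_day = as.integer(div_day), well_id = well_id),
              class = "raw_recording")
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording: %d electrodes x %d samples @ %g Hz, DIV %s, well %s>\n",
              nrow(x$voltage_uV), ncol(x$voltage_uV), x$fs_hz,
              x$div_day, x$well_id))
  invisible(x)
}
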