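#' Extract the local field potential from a raw recording
#'
#' Zero-phase low-pass filtering (forward-backward 4th-order Butterworth at
#' `cutoff_hz`) of each electrode, optionally followed by anti-aliased integer
#' decimation to `downsample_to_hz`.
#'
#' @param raw A `raw_recording`, or a numeric vector with `fs_hz` supplied.
#' @param cutoff_hz Low-pass cutoff (Hz, default 500).
#' @param downsample_to_hz Optional target rate; must divide `fs_hz`.
#' @param fs_hz Sampling rate when `raw` is a plain vector.
#' @param electrode Electrode row to extract when `raw` is a recording
#'   (default 1); use `electrode = NULL` for the electrode average.
#' @return A list of class `lfp_series`: `samples_uV`, `fs_hz`, `div_day`.
#' @export
extract_lfp <- function(raw, cutoff_hz = 500, downsample_to_hz = NULL,
                        fs_hz = NULL, electrode = 1) {
  if (inherits(raw, "raw_recording")) {
    x <- if (is.null(electrode)) colMeans(raw$voltage_uV) else
      raw$voltage_uV[electrode, ]
    fs <- raw$fs_hz
    div <- raw$div_day
  } else {
    x <- as.numeric(raw)
    fs <- fs_hz %||% abort("supply `fs_hz` for a plain numeric series.")
    div <- NA_integer_
  }
  if (any(!is.finite(x))) abort("non-finite samples in input.")
  check_scalar(cutoff_hz, "cutoff_hz", min = .Machine$double.eps)
  if (cutoff_hz >= fs / 2) abort("cutoff at or above Nyquist; raise fs or lower cutoff.")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  if (!is.null(downsample_to_hz)) {
    check_scalar(downsample_to_hz, "downsample_to_hz", min = .Machine$double.eps)
    fac <- fs / downsample_to_hz
    if (abs(fac - round(fac)) > 1e-9) {
      abort("`downsample_to_hz` must divide fs_hz (integer decimation).")
    }
    fac <- round(fac)
    if (fac > 1) {
      # extra anti-alias guard below the new Nyquist
      aa <- signal::butter(4, 0.8 * (downsample_to_hz / 2) / (fs / 2), type = "low")
      if (0.8 * downsample_to_hz / 2 < cutoff_hz) y <- signal::filtfilt(aa, y)
      y <- y[seq(1, length(y), by = fac)]
      fs <- downsample_to_hz
    }
  }
  structure(list(samples_uV = as.numeric(y), fs_hz = fs, div_day = div),
            class = "lfp_series")
}

#' Welch power spectral density
#'
#' Averaged modified periodograms over Hann-tapered segments of `segment_s`
#' seconds with fractional `overlap`, each segment demeaned. Density
#' normalization is such that the integral of the PSD over frequency
#' approximates the signal variance (one-sided spectrum).
#'
#' @param lfp An `lfp_series`, or numeric vector with `fs_hz`.
#' @param segment_s Segment length (s, default 2).
#' @param overlap Fractional overlap in \[0, 1) (default 0.5).
#' @param fs_hz Sampling rate when `lfp` is a plain vector.
#' @return A tibble of class `spectral_summary` (`freq_hz`, `psd_uV2_per_hz`)
#'   with method metadata in attributes.
#' @export
compute_psd <- function(lfp, segment_s = 2, overlap = 0.5, fs_hz = NULL) {
  if (inherits(lfp, "lfp_series")) {
    x <- lfp$samples_uV; fs <- lfp$fs_hz
  } else {
    x <- as.numeric(lfp)
    fs <- fs_hz %||% abort("supply `fs_hz` for a plain numeric series.")
  }
  check_scalar(segment_s, "segment_s", min = .Machine$double.eps)
  check_scalar(overlap, "overlap", min = 0, max = 1 - 1e-9)
  nseg <- round(segment_s * fs)
  if (nseg > length(x)) abort("segment longer than the series.")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann taper
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything but DC (and Nyquist when nseg even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  out <- tibble::tibble(freq_hz = seq(0, by = fs / nseg, length.out = nf),
                        psd_uV2_per_hz = psd)
  structure(out, fs_hz = fs, segment_s = segment_s, overlap = overlap,
            taper = "hann", n_segments = length(starts),
            class = c("spectral_summary", class(out)))
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the power spectral density over
#' \[`f_lo_hz`, `f_hi_hz`\], with linear interpolation at the band edges.
#'
#' @param psd A `spectral_summary` from [compute_psd()].
#' @param f_lo_hz,f_hi_hz Band edges (Hz), `f_lo_hz < f_hi_hz <= ` Nyquist.
#' @return Band power (uV^2).
#' @export
band_power <- function(psd, f_lo_hz, f_hi_hz) {
  stopifnot(inherits(psd, "spectral_summary"))
  if (!(f_lo_hz < f_hi_hz)) abort("empty band: need f_lo_hz < f_hi_hz.")
  if (f_hi_hz > max(psd$freq_hz) + 1e-9) abort("band extends beyond Nyquist.")
  f <- psd$freq_hz; p <- psd$psd_uV2_per_hz
  grid <- sort(unique(c(f[f > f_lo_hz & f < f_hi_hz], f_lo_hz, f_hi_hz)))
  pv <- approx(f, p, xout = grid, rule = 2)$y
  sum(diff(grid) * (head(pv, -1) + tail(pv, -1)) / 2)
}

#' Log10 band-power ratio timecourse baselined to the first recording day
#'
#' For per-day LFP series, computes the band power of each day and the ratio
#' `log10(P_day / P_first)`; the first recorded day is exactly 0 by
#' construction.
#'
#' @param recordings List of `lfp_series` (each carrying `div_day`), or a
#'   tibble with columns `div_day` and `power_uV2` already computed.
#' @param band Numeric length-2: band edges (Hz), e.g. `c(1, 10)` or
#'   `c(100, 150)`.
#' @param segment_s,overlap Welch parameters passed to [compute_psd()].
#' @return A tibble of class `band_timecourse`: `div_day`, `band_lo_hz`,
#'   `band_hi_hz`, `power_uV2`, `log10_ratio`, sorted by day.
#' @export
log_power_ratio_timecourse <- function(recordings, band, segment_s = 2,
                                       overlap = 0.5) {
  if (length(band) != 2 || band[1] >= band[2]) {
    abort("`band` must be c(f_lo, f_hi) with f_lo < f_hi.")
  }
  tab <- if (is.data.frame(recordings)) {
    tibble::as_tibble(recordings)[c("div_day", "power_uV2")]
  } else {
    purrr::map_dfr(recordings, function(l) {
      stopifnot(inherits(l, "lfp_series"))
      tibble::tibble(div_day = l$div_day,
                     power_uV2 = band_power(compute_psd(l, segment_s, overlap),
                                            band[1], band[2]))
    })
  }
  if (!nrow(tab)) abort("need at least one recording day.")
  tab <- dplyr::arrange(tab, .data$div_day)
  p0 <- tab$power_uV2[1]
  if (!is.finite(p0) || p0 <= 0) {
    abort("baseline (first-day) band power must be positive.")
  }
  out <- dplyr::mutate(tab, band_lo_hz = band[1], band_hi_hz = band[2],
                       log10_ratio = log10(.data$power_uV2 / p0),
                       .after = "div_day")
  out$log10_ratio[1] <- 0   # exact baseline identity
  structure(out, class = c("band_timecourse", class(out)))
}
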