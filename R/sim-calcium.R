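#' Simulate calcium fluorescence traces driven by a shared network process
#'
#' Each cell's raw fluorescence is `F0 * (1 + s(t)) + noise`, where `s(t)` is
#' the cell's event train convolved with a difference-of-exponentials
#' indicator kernel normalized to unit peak. Events come from two sources: a
#' shared network drive (Poisson at `drive_event_rate_per_min`) that each cell
#' accepts independently with probability `coupling_per_cell`, and per-cell
#' private events at `private_event_rate_per_min`.
#'
#' @param profile A [calcium_profile()].
#' @param drive_event_rate_per_min Shared network event rate (per minute).
#' @param duration_s Recording length (s).
#' @param private_event_rate_per_min Per-cell private event rate (per minute).
#' @param event_amplitude Transient peak amplitude in dF/F units.
#' @param baseline_f Baseline fluorescence level F0 (arbitrary units).
#' @return A list of class `calcium_simulation`: `F` (cells x samples raw
#'   fluorescence), `fs_hz`, `events` (ground-truth tibble `cell_id`,
#'   `time_s`, `source` = "shared"/"private"), `coupled` (logical, coupling
#'   weight > 0), and `profile`.
#' @export
simulate_calcium <- function(profile, drive_event_rate_per_min = 6,
                             duration_s = 600,
                             private_event_rate_per_min = 0,
                             event_amplitude = 1, baseline_f = 100) {
  stopifnot(inherits(profile, "calcium_profile"))
  p <- profile
  check_scalar(drive_event_rate_per_min, "drive_event_rate_per_min", min = 0)
  check_scalar(private_event_rate_per_min, "private_event_rate_per_min", min = 0)
  check_scalar(duration_s, "duration_s", min = .Machine$double.eps)
  if (p$fs_hz < 2 / p$tau_rise_s) {
    abort("fs_hz too low to resolve tau_rise_s (need fs_hz >= 2 / tau_rise_s).")
  }
  n_samp <- round(duration_s * p$fs_hz)
  # unit-peak difference-of-exponentials kernel
  tk <- seq(0, p$tau_decay_s * 6, by = 1 / p$fs_hz)
  kern <- exp(-tk / p$tau_decay_s) - exp(-tk / p$tau_rise_s)
  kern <- kern / max(kern)

  withr::with_seed(p$seed, {
    n_drive <- rpois(1, drive_event_rate_per_min / 60 * duration_s)
    drive_t <- sort(runif(n_drive, 0, duration_s))
    Fmat <- matrix(0, nrow = p$n_cells, ncol = n_samp)
    ev <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
      acc <- drive_t[runif(n_drive) < p$coupling_per_cell[i]]
      n_priv <- rpois(1, private_event_rate_per_min / 60 * duration_s)
      priv <- runif(n_priv, 0, duration_s)
      ev[[i]] <- tibble::tibble(
        cell_id = i, time_s = c(acc, priv),
        source = rep(c("shared", "private"), c(length(acc), n_priv)))
      imp <- numeric(n_samp)
      idx <- pmin(n_samp, pmax(1L, round(c(acc, priv) * p$fs_hz) + 1L))
      for (j in idx) imp[j] <- imp[j] + event_amplitude
      s <- if (any(imp != 0)) {
        head(convolve_open(imp, kern), n_samp)
      } else numeric(n_samp)
      Fmat[i, ] <- baseline_f * (1 + s) +
        if (p$noise_sd > 0) baseline_f * p$noise_sd * rnorm(n_samp) else 0
    }
    events <- dplyr::arrange(dplyr::bind_rows(ev), .data$cell_id, .data$time_s)
    structure(list(F = Fmat, fs_hz = p$fs_hz, events = events,
                   coupled = p$coupling_per_cell > 0, profile = p),
              class = "calcium_simulation")
  })
}

# open (full) linear convolution via FFT
convolve_open <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, 2)
  Re(fft(fft(c(x, numeric(nf - length(x)))) *
           fft(c(y, numeric(nf - length(y)))), inverse = TRUE))[seq_len(n)] / nf
}
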