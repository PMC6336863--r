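#' Baseline-normalized fluorescence (dF/F)
#'
#' `(F - F0) / F0` per cell, with `F0` a running low-percentile baseline
#' (centered rolling window), which tracks slow drift while ignoring
#' transients. `F0` is clamped away from zero.
#'
#' @param F Cells x samples numeric matrix of raw fluorescence (a single
#'   trace may be given as a vector).
#' @param fs_hz Sampling rate (Hz).
#' @param baseline_percentile Percentile used for the running baseline
#'   (default 10).
#' @param window_s Baseline window length (s, default 30); must be shorter
#'   than the recording.
#' @return Matrix of the same shape with dF/F values.
#' @export
delta_f_over_f <- function(F, fs_hz, baseline_percentile = 10, window_s = 30) {
  if (is.vector(F)) F <- matrix(F, nrow = 1)
  check_scalar(fs_hz, "fs_hz", min = .Machine$double.eps)
  check_scalar(baseline_percentile, "baseline_percentile", min = 0, max = 100)
  win <- round(window_s * fs_hz)
  if (win >= ncol(F)) abort("baseline window must be shorter than the recording.")
  win <- max(3L, win)
  if (any(F <= 0)) {
    warn("nonpositive raw fluorescence values present; baseline is clamped.")
  }
  # running percentile evaluated on a stride of win/4 and linearly
  # interpolated between evaluation points (cost win/4 below a dense scan,
  # indistinguishable for baselines varying on the window timescale)
  n <- ncol(F)
  stride <- max(1L, win %/% 4L)
  centers <- unique(c(seq(1L, n, by = stride), n))
  t(apply(F, 1, function(x) {
    q <- vapply(centers, function(c0) {
      lo <- max(1L, c0 - win %/% 2L)
      hi <- min(n, c0 + win %/% 2L)
      quantile(x[lo:hi], probs = baseline_percentile / 100, names = FALSE)
    }, double(1))
    f0 <- pmax(approx(centers, q, xout = seq_len(n))$y, 1e-9)
    (x - f0) / f0
  }))
}

#' Detect calcium transients
#'
#' Events are maximal runs where dF/F exceeds `k_sigma` times the per-cell
#' robust noise SD (MAD-based) for at least `min_duration_s`. Cells with at
#' least one event are marked active.
#'
#' @param dff Cells x samples dF/F matrix (see [delta_f_over_f()]).
#' @param fs_hz Sampling rate (Hz).
#' @param k_sigma Threshold in noise SDs (default 3).
#' @param min_duration_s Minimum suprathreshold duration (s, default 0.5).
#' @return A list: `events` (tibble `cell_id`, `onset_s`, `end_s`, `peak_dff`)
#'   and `active_cells` (integer ids with >= 1 event).
#' @export
detect_transients <- function(dff, fs_hz, k_sigma = 3, min_duration_s = 0.5) {
  if (is.vector(dff)) dff <- matrix(dff, nrow = 1)
  check_scalar(fs_hz, "fs_hz", min = .Machine$double.eps)
  min_len <- max(1L, round(min_duration_s * fs_hz))
  ev <- vector("list", nrow(dff))
  for (i in seq_len(nrow(dff))) {
    x <- dff[i, ]
    sigma <- stats::mad(x)
    if (sigma == 0) sigma <- 1e-9   # noiseless traces: any positive excursion
    above <- x > k_sigma * sigma
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) next
    ev[[i]] <- tibble::tibble(
      cell_id = i,
      onset_s = (starts[keep] - 1) / fs_hz,
      end_s = ends[keep] / fs_hz,
      peak_dff = purrr::map2_dbl(starts[keep], ends[keep],
                                 ~ max(x[.x:.y])))
  }
  events <- dplyr::bind_rows(ev)
  if (!nrow(events)) {
    events <- tibble::tibble(cell_id = integer(), onset_s = double(),
                             end_s = double(), peak_dff = double())
  }
  list(events = events, active_cells = sort(unique(events$cell_id)))
}

#' Correlated firing response ratio
#'
#' Fraction of active cells whose activity is significantly correlated with
#' the network. Per active cell, the statistic is the zero-lag Pearson
#' correlation between its dF/F trace and the mean trace of all other active
#' cells; significance is assessed against circular time-shift surrogates of
#' that cell (random rotations, which preserve autocorrelation but destroy
#' alignment). A cell is correlated when its statistic exceeds the
#' `(1 - alpha)` empirical quantile of its surrogate statistics.
#'
#' @param dff Cells x samples dF/F matrix.
#' @param fs_hz Sampling rate (Hz).
#' @param n_surrogates Circular-shift surrogates per cell (default 200).
#' @param alpha Per-cell significance level (default 0.05).
#' @param seed Integer seed for surrogate shifts.
#' @param k_sigma,min_duration_s Passed to [detect_transients()] to define
#'   active cells; constant (degenerate) traces are excluded.
#' @return A list of class `correlation_result`: `per_cell` tibble
#'   (`cell_id`, `statistic`, `threshold`, `correlated`),
#'   `active_cell_ids`, `correlated_firing_ratio` (NA with a flag when fewer
#'   than two cells are active), and `n_active`.
#' @export
correlated_firing_ratio <- function(dff, fs_hz, n_surrogates = 200,
                                    alpha = 0.05, seed = 1, k_sigma = 3,
                                    min_duration_s = 0.5) {
  if (is.vector(dff)) dff <- matrix(dff, nrow = 1)
  check_scalar(n_surrogates, "n_surrogates", min = 1, integer = TRUE)
  check_scalar(alpha, "alpha", min = 1e-9, max = 1 - 1e-9)
  act <- detect_transients(dff, fs_hz, k_sigma, min_duration_s)$active_cells
  act <- act[apply(dff[act, , drop = FALSE], 1, sd) > 0]
  n <- ncol(dff)
  empty <- tibble::tibble(cell_id = integer(), statistic = double(),
                          threshold = double(), correlated = logical())
  if (length(act) < 2) {
    return(structure(list(per_cell = empty, active_cell_ids = act,
                          correlated_firing_ratio = NA_real_,
                          n_active = length(act), undefined = TRUE),
                     class = "correlation_result"))
  }
  A <- dff[act, , drop = FALSE]
  tot <- colSums(A)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_along(act), function(k) {
      x <- A[k, ]
      ref <- (tot - x) / (length(act) - 1)   # mean of the other active cells
      # correlations of every circular rotation of x with ref in one FFT
      # cross-correlation (identical to cor() on the rotated series)
      xc <- x - mean(x); rc <- ref - mean(ref)
      denom <- sqrt(sum(xc^2) * sum(rc^2))
      all_r <- if (denom > 0) {
        Re(fft(Conj(fft(xc)) * fft(rc), inverse = TRUE)) / n / denom
      } else rep(0, n)
      stat <- all_r[1]
      shifts <- sample.int(n - 1, n_surrogates, replace = TRUE)
      surr <- all_r[shifts + 1L]
      thr <- sort(surr)[ceiling((1 - alpha) * n_surrogates)]
      tibble::tibble(cell_id = act[k], statistic = stat, threshold = thr,
                     correlated = stat > thr)
    })
  })
  structure(list(per_cell = rows, active_cell_ids = act,
                 correlated_firing_ratio = mean(rows$correlated),
                 n_active = length(act), undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<correlation_result: ratio undefined (<2 active cells)>\n")
  } else {
    cat(sprintf(
      "<correlation_result: %d/%d active cells correlated, ratio %.3f>\n",
      sum(x$per_cell$correlated), x$n_active, x$correlated_firing_ratio))
  }
  invisible(x)
}
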