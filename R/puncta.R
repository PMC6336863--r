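#' Detect fluorescent puncta in a single-channel image
#'
#' Scale-matched blob detection: the image is convolved with a Gaussian of the
#' expected punctum width, a scale-normalized Laplacian-of-Gaussian response
#' is computed (`-sigma^2 * Laplacian`), and 3x3 local maxima above
#' `threshold` are reported with sub-pixel centers from a one-dimensional
#' quadratic fit along each axis.
#'
#' @param image Numeric matrix (rows = y, cols = x).
#' @param pixel_size_um Pixel size in um; required.
#' @param psf_sigma_um Expected punctum Gaussian sigma (um).
#' @param threshold Minimum LoG response at a maximum. With unit-amplitude
#'   Gaussian spots the response at a spot center is about 0.5, so the default
#'   0.1 keeps clear spots and rejects shot noise.
#' @return Tibble with columns `x`, `y` (um) and `response`.
#' @export
detect_puncta <- function(image, pixel_size_um, psf_sigma_um = 0.15,
                          threshold = 0.1) {
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  if (missing(pixel_size_um) || is.null(pixel_size_um)) {
    abort("`pixel_size_um` metadata is required.")
  }
  check_scalar(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  check_scalar(threshold, "threshold", min = 0)
  s_px <- psf_sigma_um / pixel_size_um
  sm <- gauss_blur(image, s_px)
  lap <- discrete_laplacian(sm)
  resp <- -s_px^2 * lap
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(tibble::tibble(x = double(), y = double(),
                                              response = double()))
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- resp[2:(nr - 1) + di, 2:(nc - 1) + dj]
    # plateau tie-break: strict inequality against scan-order-later neighbors
    is_max <- is_max & if (dj > 0 || (dj == 0 && di > 0)) ctr > nb else ctr >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(tibble::tibble(x = double(), y = double(),
                                        response = double()))
  iy <- idx[, 1] + 1L; ix <- idx[, 2] + 1L
  # sub-pixel quadratic interpolation per axis
  off1 <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    ifelse(abs(den) > .Machine$double.eps, 0.5 * (vm - vp) / den, 0)
  }
  dy <- off1(resp[cbind(iy - 1L, ix)], resp[cbind(iy, ix)], resp[cbind(iy + 1L, ix)])
  dx <- off1(resp[cbind(iy, ix - 1L)], resp[cbind(iy, ix)], resp[cbind(iy, ix + 1L)])
  tibble::tibble(
    x = (ix + pmax(-0.5, pmin(0.5, dx)) - 0.5) * pixel_size_um,
    y = (iy + pmax(-0.5, pmin(0.5, dy)) - 0.5) * pixel_size_um,
    response = resp[cbind(iy, ix)])
}

# separable Gaussian blur with replicate padding
gauss_blur <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  img <- t(apply(img, 1, conv_reflect, k = k, half = half))
  apply(img, 2, conv_reflect, k = k, half = half)
}

conv_reflect <- function(x, k, half) {
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

discrete_laplacian <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), ]
  dn <- img[c(seq_len(nr - 1) + 1, nr), ]
  lf <- img[, c(1, seq_len(nc - 1))]
  rt <- img[, c(seq_len(nc - 1) + 1, nc)]
  up + dn + lf + rt - 4 * img
}

#' Colocalize pre/post puncta and compute synapse density
#'
#' One-to-one matching of pre- and post-synaptic puncta: all pre/post pairs
#' closer than `max_dist_um` are sorted by ascending distance (ties broken by
#' point index) and matched greedily so each punctum is used at most once.
#' Density is expressed per 50 um of neurite, the field's customary unit.
#'
#' @param pre,post Data frames with `x`, `y` positions (um).
#' @param neurite_length_um Length of the analysed neurite stretch (um).
#' @param max_dist_um Maximum center distance for a colocalized pair (um);
#'   default 0.5 um, a typical synapse-scale tolerance.
#' @return One-row tibble: `n_pairs`, `density_per_50um`, `n_pre`, `n_post`.
#' @export
colocalize_and_density <- function(pre, post, neurite_length_um,
                                   max_dist_um = 0.5) {
  check_scalar(neurite_length_um, "neurite_length_um", min = .Machine$double.eps)
  check_scalar(max_dist_um, "max_dist_um", min = 0)
  n1 <- nrow(pre); n2 <- nrow(post)
  pairs <- 0L
  if (n1 > 0 && n2 > 0) {
    d <- sqrt(outer(pre$x, post$x, "-")^2 + outer(pre$y, post$y, "-")^2)
    cand <- which(d <= max_dist_um, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_pre <- logical(n1); used_post <- logical(n2)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_pre[i] && !used_post[j]) {
          used_pre[i] <- TRUE; used_post[j] <- TRUE
          pairs <- pairs + 1L
        }
      }
    }
  }
  tibble::tibble(n_pairs = pairs,
                 density_per_50um = pairs * 50 / neurite_length_um,
                 n_pre = n1, n_post = n2)
}

#' Read or write a two-channel puncta TIFF
#'
#' Channels are stored as two pages of a 32-bit float TIFF; pixel size is not
#' stored in the file and must be tracked by the caller.
#'
#' @param channels List of two numeric matrices.
#' @param path File path.
#' @return `read_puncta_tiff` returns a list of matrices.
#' @export
write_puncta_tiff <- function(channels, path) {
  rlang::check_installed("tiff")
  mx <- max(1e-12, max(vapply(channels, max, double(1))))
  tiff::writeTIFF(lapply(channels, function(m) m / mx), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_puncta_tiff
#' @export
read_puncta_tiff <- function(path) {
  rlang::check_installed("tiff")
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}
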