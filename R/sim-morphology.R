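#' Generate a synthetic neuron morphology
#'
#' Grows a branching neurite tree from a soma in the 2-D plane of a tracing.
#' `n_primary_neurites` trunks leave the soma at evenly spaced angles with
#' random rotation; tips elongate by gamma-distributed segments whose
#' direction drifts by Gaussian angular noise, and bifurcate with probability
#' `branch_prob` after each segment. Growth cycles over active tips and stops
#' when total neurite length reaches `target_total_length_um`, truncating the
#' final segment so the target is met exactly.
#'
#' @param params A [morphology_params()].
#' @return A `neuron_morphology`: tibble of SWC-style nodes (`id`, `type`,
#'   `x`, `y`, `z`, `radius`, `parent`), soma as root (type 1, parent -1).
#' @export
#' @examples
#' m <- generate_morphology(morphology_params(seed = 3))
#' morpho_summary(m)
generate_morphology <- function(params) {
  stopifnot(inherits(params, "morphology_params"))
  p <- params
  withr::with_seed(p$seed, {
    nodes <- tibble::tibble(
      id = 1L, type = 1L, x = 0, y = 0, z = 0,
      radius = p$soma_radius_um, parent = -1L)
    rot <- runif(1, 0, 2 * pi)
    angles <- rot + 2 * pi * (seq_len(p$n_primary_neurites) - 1) /
      p$n_primary_neurites
    # each tip: list(node_id, angle); trunks start at the soma centroid so
    # summed node-to-node distances equal accumulated length exactly
    tips <- purrr::map(angles, function(a) list(node = 1L, angle = a))
    total <- 0
    next_id <- 2L
    while (total < p$target_total_length_um && length(tips)) {
      new_tips <- list()
      for (tp in sample(tips)) {     # random growth order
        if (total >= p$target_total_length_um) { new_tips <- c(new_tips, list(tp)); next }
        len <- rgamma_seg(p$mean_segment_um)
        if (total + len > p$target_total_length_um) {
          len <- p$target_total_length_um - total
        }
        a <- tp$angle + rnorm(1, 0, 0.35)
        x1 <- nodes$x[tp$node] + len * cos(a)
        y1 <- nodes$y[tp$node] + len * sin(a)
        total <- total + len
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          id = next_id, type = 3L, x = x1, y = y1, z = 0,
          radius = 0.5, parent = tp$node))
        child <- list(node = next_id, angle = a, start = FALSE)
        next_id <- next_id + 1L
        if (runif(1) < p$branch_prob && total < p$target_total_length_um) {
          da <- runif(1, 0.3, 0.8)
          new_tips <- c(new_tips,
                        list(modifyList(child, list(angle = a - da)),
                             modifyList(child, list(angle = a + da))))
        } else {
          new_tips <- c(new_tips, list(child))
        }
      }
      tips <- new_tips
    }
    new_neuron_morphology(nodes)
  })
}

rgamma_seg <- function(mean_um, shape = 4) {
  stats::rgamma(1, shape = shape, rate = shape / mean_um)
}

#' Generate a synthetic pre/post synaptic-puncta field
#'
#' Places pre-synaptic puncta as a Poisson process along a straight horizontal
#' neurite path centered in the field, gives a `colocalization_fraction` of
#' them a post-synaptic partner offset uniformly within a disc of radius
#' `jitter_um`, and adds unpaired post puncta so the total post density is
#' close to `post_density_per_um`. Optionally renders both channels as sums of
#' unit-amplitude Gaussian spots of width `psf_sigma_um`.
#'
#' @param params A [puncta_params()].
#' @param render Render two image channels (matrices) as well?
#' @return A list of class `puncta_field`: `pre`, `post` (tibbles with `x`,
#'   `y` in um), `path` (two-point polyline tibble), `neurite_length_um`,
#'   `truth` (list: `n_colocalized`, `pair_indices`), and if `render`,
#'   `channels` (list of two matrices) with `pixel_size_um`.
#' @export
generate_puncta <- function(params, render = FALSE) {
  stopifnot(inherits(params, "puncta_params"))
  p <- params
  field_w <- p$image_shape[2] * p$pixel_size_um
  field_h <- p$image_shape[1] * p$pixel_size_um
  if (p$neurite_length_um > field_w - 2) {
    abort("image too small for neurite length; enlarge `image_shape` or shrink the neurite.")
  }
  withr::with_seed(p$seed, {
    x0 <- (field_w - p$neurite_length_um) / 2
    y0 <- field_h / 2
    n_pre <- rpois(1, p$pre_density_per_um * p$neurite_length_um)
    pre <- tibble::tibble(
      x = x0 + runif(n_pre, 0, p$neurite_length_um),
      y = y0 + rnorm(n_pre, 0, 0.3))
    n_pair <- round(p$colocalization_fraction * n_pre)
    pair_idx <- if (n_pair) sort(sample.int(n_pre, n_pair)) else integer()
    # partner offset uniform in a disc of radius jitter_um
    r <- p$jitter_um * sqrt(runif(n_pair))
    th <- runif(n_pair, 0, 2 * pi)
    partners <- tibble::tibble(x = pre$x[pair_idx] + r * cos(th),
                               y = pre$y[pair_idx] + r * sin(th))
    n_post_total <- rpois(1, p$post_density_per_um * p$neurite_length_um)
    n_extra <- max(0L, n_post_total - n_pair)
    extra <- tibble::tibble(
      x = x0 + runif(n_extra, 0, p$neurite_length_um),
      y = y0 + rnorm(n_extra, 0, 0.3))
    post <- dplyr::bind_rows(partners, extra)
    out <- list(
      pre = pre, post = post,
      path = tibble::tibble(x = c(x0, x0 + p$neurite_length_um), y = c(y0, y0)),
      neurite_length_um = p$neurite_length_um,
      truth = list(n_colocalized = n_pair, pair_indices = pair_idx),
      params = p)
    if (render) {
      out$channels <- list(
        pre = render_spots(pre, p$image_shape, p$pixel_size_um, p$psf_sigma_um),
        post = render_spots(post, p$image_shape, p$pixel_size_um, p$psf_sigma_um))
      out$pixel_size_um <- p$pixel_size_um
    }
    structure(out, class = "puncta_field")
  })
}

# render points (um) as unit-amplitude Gaussian spots on a pixel grid
render_spots <- function(pts, image_shape, pixel_size_um, psf_sigma_um) {
  img <- matrix(0, nrow = image_shape[1], ncol = image_shape[2])
  if (!nrow(pts)) return(img)
  s_px <- psf_sigma_um / pixel_size_um
  half <- ceiling(4 * s_px)
  for (k in seq_len(nrow(pts))) {
    cx <- pts$x[k] / pixel_size_um + 0.5   # pixel centers at (i - 0.5)
    cy <- pts$y[k] / pixel_size_um + 0.5
    ix <- max(1, floor(cx - half)):min(ncol(img), ceiling(cx + half))
    iy <- max(1, floor(cy - half)):min(nrow(img), ceiling(cy + half))
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ix - cx)^2) / (2 * s_px^2))
    gy <- exp(-((iy - cy)^2) / (2 * s_px^2))
    img[iy, ix] <- img[iy, ix] + outer(gy, gx)
  }
  img
}
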