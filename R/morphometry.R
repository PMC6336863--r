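#' Neuron morphology node tables and SWC input/output
#'
#' A `neuron_morphology` is a tibble of SWC nodes (`id`, `type`, `x`, `y`,
#' `z`, `radius`, `parent`) validated to have exactly one root of soma type
#' (parent -1, type 1), every parent defined before its child (which also
#' guarantees acyclicity), and finite coordinates.
#'
#' @param nodes Data frame of SWC columns.
#' @return A tibble of class `neuron_morphology`.
#' @export
new_neuron_morphology <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)[c("id", "type", "x", "y", "z",
                                      "radius", "parent")]
  validate_morphology(nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  structure(nodes, class = c("neuron_morphology", class(nodes)))
}

validate_morphology <- function(nodes) {
  if (!nrow(nodes)) abort("morphology has no nodes.")
  if (anyDuplicated(nodes$id)) abort("duplicate node ids.")
  num_cols <- c("x", "y", "z", "radius")
  if (any(!is.finite(as.matrix(nodes[num_cols])))) {
    abort("non-finite coordinates or radii.")
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) {
    abort(sprintf("expected exactly one root (parent -1), found %d.",
                  length(roots)))
  }
  if (nodes$type[roots] != 1L) abort("root node must be soma type (1).")
  seen <- new.env(hash = TRUE, size = nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (p != -1 && is.null(seen[[as.character(p)]])) {
      abort(sprintf(
        "line %d: node %d references parent %d before it is defined (orphan or cycle).",
        i, nodes$id[i], p))
    }
    seen[[as.character(nodes$id[i])]] <- i
  }
  invisible(nodes)
}

#' @rdname new_neuron_morphology
#' @param path File path of a whitespace-delimited SWC file (`#` comments).
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort("no SWC records in file.")
  m <- utils::read.table(text = lines[keep],
                         col.names = c("id", "type", "x", "y", "z",
                                       "radius", "parent"))
  new_neuron_morphology(m)
}

#' @rdname new_neuron_morphology
#' @param morph A `neuron_morphology`.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "neuron_morphology"))
  header <- "# SWC generated by neurocultr"
  rows <- sprintf("%d %d %.6f %.6f %.6f %.6f %d", morph$id, morph$type,
                  morph$x, morph$y, morph$z, morph$radius, morph$parent)
  writeLines(c(header, rows), path)
  invisible(path)
}

soma_centroid <- function(morph) {
  s <- morph[morph$type == 1L, ]
  c(x = mean(s$x), y = mean(s$y), z = mean(s$z))
}

# non-soma segments as (parent, child) coordinate pairs
neurite_segments <- function(morph) {
  child <- morph[morph$parent != -1 & morph$type != 1L, ]
  pidx <- match(child$parent, morph$id)
  tibble::tibble(
    x0 = morph$x[pidx], y0 = morph$y[pidx], z0 = morph$z[pidx],
    x1 = child$x, y1 = child$y, z1 = child$z)
}

#' Sholl intersection profile
#'
#' Counts, for concentric circles of radius `step_um`, `2*step_um`, ...
#' centered at the soma centroid, how many neurite segments cross each circle.
#' A segment whose endpoint distances from the centroid straddle a radius
#' (lower end exclusive, upper end inclusive, so a crossing exactly at the
#' radius counts once) contributes one intersection at that radius. Distances
#' are taken in the tracing's x-y plane by default, matching 2-D
#' reconstructions; set `use_3d = TRUE` for spheres.
#'
#' @param morph A `neuron_morphology`.
#' @param step_um Radius increment (um), default 10.
#' @param use_3d Measure 3-D Euclidean distances instead of in-plane.
#' @return A tibble of class `sholl_profile`: `radius_um`, `intersections`.
#' @export
sholl_profile <- function(morph, step_um = 10, use_3d = FALSE) {
  stopifnot(inherits(morph, "neuron_morphology"))
  check_scalar(step_um, "step_um", min = .Machine$double.eps)
  ctr <- soma_centroid(morph)
  seg <- neurite_segments(morph)
  dist_fun <- function(x, y, z) {
    if (use_3d) sqrt((x - ctr["x"])^2 + (y - ctr["y"])^2 + (z - ctr["z"])^2)
    else sqrt((x - ctr["x"])^2 + (y - ctr["y"])^2)
  }
  if (!nrow(seg)) {
    out <- tibble::tibble(radius_um = step_um, intersections = 0L)
    return(structure(out, class = c("sholl_profile", class(out))))
  }
  d0 <- dist_fun(seg$x0, seg$y0, seg$z0)
  d1 <- dist_fun(seg$x1, seg$y1, seg$z1)
  lo <- pmin(d0, d1); hi <- pmax(d0, d1)
  max_r <- max(hi)
  radii <- seq(step_um, by = step_um,
               length.out = max(1L, ceiling(max_r / step_um)))
  counts <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  out <- tibble::tibble(radius_um = radii, intersections = counts)
  structure(out, class = c("sholl_profile", class(out)))
}

#' Morphometric summary of a reconstruction
#'
#' Total neuritic outgrowth (sum of neurite segment lengths; segments joining
#' soma nodes are excluded), number of primary neurites (non-soma children of
#' the root) and soma area (`pi * r^2` from the root radius).
#'
#' @param morph A `neuron_morphology`.
#' @return One-row tibble: `total_outgrowth_um`, `n_primary_neurites`,
#'   `soma_area_um2`.
#' @export
morpho_summary <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  seg <- neurite_segments(morph)
  outgrowth <- if (nrow(seg)) {
    sum(sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2))
  } else 0
  root_id <- morph$id[morph$parent == -1]
  n_primary <- sum(morph$parent == root_id & morph$type != 1L)
  r <- morph$radius[morph$parent == -1]
  tibble::tibble(total_outgrowth_um = outgrowth,
                 n_primary_neurites = as.integer(n_primary),
                 soma_area_um2 = pi * r^2)
}
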