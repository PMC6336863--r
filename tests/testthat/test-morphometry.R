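test_that("SWC round trip preserves topology and coordinates", {
  m <- generate_morphology(morphology_params(seed = 21))
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(as.data.frame(m2), as.data.frame(m), tolerance = 1e-6)

  # minimal two-node file
  f2 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 5 -1", "2 3 10 0 0 0.5 1"), f2)
  small <- read_swc(f2)
  expect_equal(nrow(small), 2L)

  # child before parent is a parse error with a line reference
  f3 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 0.5 3", "3 3 5 0 0 0.5 1"), f3)
  expect_error(read_swc(f3), "before it is defined")
  # two roots rejected
  f4 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 1 0 0 5 -1"), f4)
  expect_error(read_swc(f4), "exactly one root")
})

test_that("Sholl counts match hand-derived toy geometries", {
  s <- sholl_profile(straight_neurite(len = 95, step = 5))
  expect_equal(s$radius_um, seq(10, 100, by = 10))
  expect_equal(s$intersections, c(rep(1L, 9), 0L))

  y <- sholl_profile(y_neurite())
  expect_equal(s$radius_um[1:4], c(10, 20, 30, 40))
  expect_equal(y$intersections[y$radius_um %in% c(10, 20)], c(1L, 1L))
  expect_equal(y$intersections[y$radius_um %in% c(30, 40)], c(2L, 2L))
  expect_true(all(y$intersections[y$radius_um >= 50] == 0L))

  soma_only <- new_neuron_morphology(
    data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0, radius = 5,
               parent = -1L))
  expect_true(all(sholl_profile(soma_only)$intersections == 0L))
})

test_that("a crossing exactly at a circle radius counts once", {
  # tip exactly at 20 um: segment (10,20] crosses r = 20 inclusively
  m <- new_neuron_morphology(data.frame(
    id = 1:3, type = c(1L, 3L, 3L), x = c(0, 10, 20), y = 0, z = 0,
    radius = c(5, 0.5, 0.5), parent = c(-1L, 1L, 2L)))
  s <- sholl_profile(m)
  expect_equal(s$intersections[s$radius_um == 20], 1L)
})

test_that("morphometry is invariant under rigid motions", {
  m <- generate_morphology(morphology_params(seed = 22))
  th <- 0.7; dx <- 12; dy <- -30
  rot <- m
  rot$x <- cos(th) * m$x - sin(th) * m$y + dx
  rot$y <- sin(th) * m$x + cos(th) * m$y + dy
  rot <- new_neuron_morphology(rot)
  expect_equal(sholl_profile(rot)$intersections, sholl_profile(m)$intersections)
  expect_equal(morpho_summary(rot), morpho_summary(m), tolerance = 1e-9)
})

test_that("summary metrics follow their definitions", {
  one <- straight_neurite(len = 100, step = 10, soma_r = 10)
  s <- morpho_summary(one)
  expect_equal(s$total_outgrowth_um, 100)
  expect_equal(s$n_primary_neurites, 1L)
  expect_equal(s$soma_area_um2, pi * 100)

  gen <- morpho_summary(generate_morphology(
    morphology_params(target_total_length_um = 600, seed = 23)))
  expect_lt(abs(gen$total_outgrowth_um - 600) / 600, 0.10)
})

test_that("intersections accumulate at least one crossing set per far tip", {
  m <- generate_morphology(morphology_params(seed = 24))
  ctr <- c(0, 0)
  is_parent <- m$id %in% m$parent
  tips <- m[!is_parent & m$type != 1L, ]
  tip_d <- sqrt(tips$x^2 + tips$y^2)
  s <- sholl_profile(m, step_um = 10)
  expect_gte(sum(s$intersections), sum(tip_d > 10))
})

test_that("LoG puncta detection localizes rendered spots to a pixel", {
  fld <- generate_puncta(puncta_params(neurite_length_um = 50,
                                       pre_density_per_um = 0.3,
                                       colocalization_fraction = 0,
                                       post_density_per_um = 0, seed = 25),
                         render = TRUE)
  det <- detect_puncta(fld$channels$pre, pixel_size_um = fld$pixel_size_um,
                       psf_sigma_um = 0.15, threshold = 0.1)
  # each true punctum recovered within one pixel (0.1 um grid)
  truth <- fld$pre
  dmin <- vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2))
  }, double(1))
  expect_true(all(dmin <= 0.15))
  expect_lte(abs(nrow(det) - nrow(truth)), ceiling(0.1 * nrow(truth)))

  expect_equal(nrow(detect_puncta(matrix(0, 64, 64), pixel_size_um = 0.1)), 0L)
  expect_error(detect_puncta(matrix(0, 64, 64)), "pixel_size_um")
})

test_that("two spots separated by 4 sigma are resolved", {
  pts <- tibble::tibble(x = c(2.0, 2.0 + 4 * 0.15), y = c(2, 2))
  img <- neurocultr:::render_spots(pts, c(40, 40), 0.1, 0.15)
  det <- detect_puncta(img, pixel_size_um = 0.1, psf_sigma_um = 0.15,
                       threshold = 0.05)
  expect_equal(nrow(det), 2L)
})

test_that("colocalization density follows its definition and is symmetric", {
  xs <- seq(2, 47, length.out = 10)
  pre <- tibble::tibble(x = xs, y = 1)
  post <- tibble::tibble(x = xs, y = 1)
  expect_equal(colocalize_and_density(pre, post, 50)$density_per_50um, 10)
  expect_equal(colocalize_and_density(pre, post, 100)$density_per_50um, 5)
  # symmetry under swapping channels
  withr::with_seed(26, {
    p1 <- tibble::tibble(x = runif(30, 0, 50), y = runif(30, 0, 2))
    p2 <- tibble::tibble(x = runif(25, 0, 50), y = runif(25, 0, 2))
  })
  expect_equal(colocalize_and_density(p1, p2, 50)$n_pairs,
               colocalize_and_density(p2, p1, 50)$n_pairs)
})

test_that("generator colocalization fraction is recovered from the field", {
  fracs <- vapply(1:6, function(s) {
    fld <- generate_puncta(puncta_params(neurite_length_um = 200,
                                         colocalization_fraction = 0.6,
                                         image_shape = c(96, 2100), seed = s))
    res <- colocalize_and_density(fld$pre, fld$post, fld$neurite_length_um)
    res$n_pairs / nrow(fld$pre)
  }, double(1))
  expect_lt(abs(mean(fracs) - 0.6), 0.1)
})

test_that("two-channel TIFF round trip preserves the rendered field", {
  fld <- generate_puncta(puncta_params(seed = 27), render = TRUE)
  f <- withr::local_tempfile(fileext = ".tif")
  write_puncta_tiff(fld$channels, f)
  back <- read_puncta_tiff(f)
  expect_equal(length(back), 2L)
  sc <- max(fld$channels$pre, fld$channels$post)
  expect_equal(back[[1]] * sc, fld$channels$pre, tolerance = 1e-5)
})
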