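test_that("analytic ground truth matches closed forms", {
  sp <- c(150, 120, 120)
  shape <- c(40, 80, 120)
  spec <- phantom_spec(shape, sp, nuclei = list(list(
    center = shape * sp / 2000, radii = c(6, 4, 2),
    angles = c(0, pi / 2, 0), intensity = 0.6)),
    texture_amp = 0, psf_sigma = c(0, 0, 0), noise_sd = 0, background = 0)
  ph <- generate_nucleus(spec)
  expect_equal(ph$truth$volume_um3, 4 / 3 * pi * 48, tolerance = 1e-10)
  expect_equal(ph$truth$elongation, 1.5)
  # sphere: E = 1, V = 4/3 pi 27
  shp <- c(50, 60, 60)
  spec2 <- phantom_spec(shp, sp, nuclei = list(list(
    center = shp * sp / 2000, radii = c(3, 3, 3), intensity = 0.5)),
    texture_amp = 0, psf_sigma = c(0, 0, 0), noise_sd = 0)
  ph2 <- generate_nucleus(spec2)
  expect_equal(ph2$truth$elongation, 1)
  expect_equal(ph2$truth$volume_um3, 4 / 3 * pi * 27, tolerance = 1e-10)
  expect_equal(ph2$truth$surface_um2, 4 * pi * 9, tolerance = 1e-8)
})

test_that("ellipsoid surface quadrature matches known closed forms", {
  expect_equal(ellipsoid_surface_area(3, 3, 3), 4 * pi * 9,
               tolerance = 1e-10)
  # prolate spheroid a > b = c: S = 2 pi b^2 (1 + a/(b e) asin(e))
  a <- 6; b <- 2
  e <- sqrt(1 - b^2 / a^2)
  S_prolate <- 2 * pi * b^2 * (1 + a / (b * e) * asin(e))
  expect_equal(ellipsoid_surface_area(a, b, b), S_prolate, tolerance = 1e-8)
})

test_that("generation is deterministic given a seed", {
  sp <- c(150, 120, 120)
  shp <- c(30, 40, 40)
  mk <- function() generate_nucleus(phantom_spec(
    shp, sp, nuclei = list(list(center = shp * sp / 2000,
                                radii = c(1.5, 1.2, 1.0))),
    seed = 11))
  a <- mk(); b <- mk()
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$labels, b$labels$labels)
})

test_that("out-of-bounds ellipsoids are rejected", {
  sp <- c(150, 120, 120)
  expect_error(phantom_spec(c(20, 20, 20), sp, nuclei = list(list(
    center = c(1, 1, 1), radii = c(3, 2, 1)))), "out of bounds")
})

test_that("touching pairs have the stated geometry", {
  # separation 0: one connected blob, two coincident ground-truth labels
  p0 <- generate_touching_pair(0, radius_vox = 8)
  d <- dim(p0$labels$labels)
  comp <- nucleomorph:::.cpp_label_components(
    as.logical(p0$labels$labels > 0), as.integer(d))
  expect_equal(max(comp), 1L)
  # two ground-truth nuclei coincide in one blob: both centers are reported
  # even though the instance mask can only carry one label for them
  expect_equal(nrow(p0$centers), 2L)
  expect_equal(p0$centers[1, ], p0$centers[2, ])
  # separation 30, radius 10: two disjoint components
  p30 <- generate_touching_pair(30, radius_vox = 10)
  d <- dim(p30$labels$labels)
  comp <- nucleomorph:::.cpp_label_components(
    as.logical(p30$labels$labels > 0), as.integer(d))
  expect_equal(max(comp), 2L)
  # determinism with noise
  a <- generate_touching_pair(5, noise_sd = 0.05, seed = 2)
  b <- generate_touching_pair(5, noise_sd = 0.05, seed = 2)
  expect_identical(a$image$data, b$image$data)
})

test_that("voxelized ground-truth volume converges to the analytic value", {
  # at acquisition spacing and r >= 2 um the discrepancy is < 2%
  sp <- c(150, 120, 120)
  shp <- c(40, 50, 50)
  spec <- phantom_spec(shp, sp, nuclei = list(list(
    center = shp * sp / 2000, radii = c(2, 2, 2))),
    texture_amp = 0, psf_sigma = c(0, 0, 0), noise_sd = 0)
  ph <- generate_nucleus(spec)
  vox_V <- sum(ph$labels$labels == 1) * prod(sp) / 1e9
  expect_lt(abs(vox_V / ph$truth$volume_um3 - 1), 0.02)
  # doubled resolution is closer
  spec2 <- phantom_spec(shp * 2L, sp / 2, nuclei = list(list(
    center = shp * sp / 2000, radii = c(2, 2, 2))),
    texture_amp = 0, psf_sigma = c(0, 0, 0), noise_sd = 0)
  ph2 <- generate_nucleus(spec2)
  vox_V2 <- sum(ph2$labels$labels == 1) * prod(sp / 2) / 1e9
  expect_lt(abs(vox_V2 / ph2$truth$volume_um3 - 1),
            abs(vox_V / ph$truth$volume_um3 - 1))
})

test_that("population sampling honors the stated distributions", {
  pop <- population_spec(n_per_group = 20, seed = 9)
  res <- generate_population(pop, render = FALSE)
  expect_equal(nrow(res$truth), 40L)
  for (gn in c("A", "B")) {
    g <- pop$groups[[gn]]
    tr <- res$truth[res$truth$group == gn, ]
    # Monte-Carlo check of the generator against its own distribution
    expect_lt(abs(mean(tr$volume_um3) - g$volume_mean),
              3 * g$volume_sd / sqrt(20))
    expect_lt(abs(mean(tr$elongation) - g$elongation_mean),
              3.2 * g$elongation_sd / sqrt(20))
    expect_true(all(tr$elongation >= 1))
    expect_true(all(tr$volume_um3 > 0 & tr$chromatin_density > 0))
    expect_true(all(tr$r1 >= tr$r2 & tr$r2 >= tr$r3))
  }
  # n = 1 per group emits 2 records; SD 0 collapses each group
  degen <- population_spec(
    n_per_group = 2,
    groups = list(A = list(volume_mean = 30, volume_sd = 0,
                           elongation_mean = 1.3, elongation_sd = 0,
                           density_mean = 0.5, density_sd = 0)),
    seed = 1)
  dres <- generate_population(degen, render = FALSE)
  expect_equal(nrow(dres$truth), 2L)
  expect_equal(dres$truth$volume_um3[1], dres$truth$volume_um3[2])
  expect_equal(dres$truth$r1[1], dres$truth$r1[2])
  one <- population_spec(n_per_group = 1,
                         groups = degen$groups["A"], seed = 2)
  ores <- generate_population(one, render = TRUE)
  expect_equal(length(ores$samples), 1L)
})
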