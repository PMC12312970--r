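test_that("volume is voxel count times physical voxel volume", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_equal(measure_volume(m, c(150, 120, 120)), 0.00216)
  sph <- voxel_sphere(30)  # r = 3 um at 100 nm voxels
  expect_lt(abs(measure_volume(sph$mask, sph$spacing) / (4 / 3 * pi * 27) - 1),
            0.02)
  expect_error(measure_volume(array(FALSE, c(3, 3, 3))), "empty label")
})

test_that("surface area matches closed forms for sphere, ellipsoid and box", {
  sph <- voxel_sphere(30)
  S <- measure_surface(sph$mask, sph$spacing)
  expect_lt(abs(S / (4 * pi * 9) - 1), 0.03)
  ell <- voxel_ellipsoid(c(6, 4, 2))
  S_exact <- ellipsoid_surface_area(6, 4, 2)
  expect_lt(abs(measure_surface(ell$mask, ell$spacing) / S_exact - 1), 0.03)
  # axis-aligned box: 25 x 34 x 50 voxels at 120 nm
  b <- array(FALSE, c(45, 54, 70)); b[10:34, 10:43, 10:59] <- TRUE
  du <- c(25, 34, 50) * 0.12
  S_box <- 2 * (du[1] * du[2] + du[2] * du[3] + du[1] * du[3])
  expect_lt(abs(measure_surface(b, rep(120, 3)) / S_box - 1), 0.03)
  expect_error(measure_surface(array(FALSE, c(5, 5, 5))), "empty")
  thin <- array(FALSE, c(5, 5, 5)); thin[3, , ] <- TRUE
  expect_error(measure_surface(thin), "too small to mesh")
})

test_that("surface estimate converges with resolution", {
  e1 <- abs(measure_surface(voxel_sphere(15)$mask, rep(200, 3)) /
              (4 * pi * 9) - 1)
  e2 <- abs(measure_surface(voxel_sphere(30)$mask, rep(100, 3)) /
              (4 * pi * 9) - 1)
  expect_lt(e2, e1)
})

test_that("compactness follows V^2/S^3 with the 36 pi normalization", {
  Vs <- 4 / 3 * pi * 27; Ss <- 4 * pi * 9
  C <- compactness(Vs, Ss)
  expect_equal(C$compactness, 1 / (36 * pi), tolerance = 1e-12)
  expect_equal(C$compactness_norm, 1, tolerance = 1e-12)
  # isotropic x2 rescale leaves compactness unchanged (dimensional analysis)
  C2 <- compactness(8 * Vs, 4 * Ss)
  expect_lt(abs(C2$compactness / C$compactness - 1), 1e-12)
  # elongated ellipsoid: normalized compactness below 1 (quadrature oracle)
  Ve <- 4 / 3 * pi * 6 * 2 * 2
  Se <- ellipsoid_surface_area(6, 2, 2)
  expect_lt(compactness(Ve, Se)$compactness_norm, 1)
  expect_error(compactness(0, 1))
})

test_that("ellipsoid fitting recovers radii and is rotation invariant", {
  ell <- voxel_ellipsoid(c(6, 4, 2))
  fit <- fit_ellipsoid(ell$mask, ell$spacing)
  expect_true(all(abs(fit$radii / c(6, 4, 2) - 1) < 0.03))
  rot <- voxel_ellipsoid(c(6, 4, 2), angles = c(0.4, 1.1, 0.7))
  fit2 <- fit_ellipsoid(rot$mask, rot$spacing)
  expect_true(all(abs(fit2$radii / c(6, 4, 2) - 1) < 0.03))
  sph <- voxel_sphere(30)
  fs <- fit_ellipsoid(sph$mask, sph$spacing)
  expect_true(all(abs(fs$radii - 3) < 0.03))
  # degenerate labels
  flat <- array(FALSE, c(9, 9, 9)); flat[5, , ] <- TRUE
  expect_error(fit_ellipsoid(flat), "degenerate")
  tiny <- array(FALSE, c(9, 9, 9)); tiny[5, 5, 5] <- TRUE
  expect_error(fit_ellipsoid(tiny), "fewer than 4")
})

test_that("elongation is the ratio of the two main radii", {
  expect_equal(elongation(6, 4), 1.5)
  expect_equal(elongation(6, 6), 1)
  expect_error(elongation(6, 0), "r2")
  expect_error(elongation(4, 6), "r1")
  sph <- voxel_sphere(20)
  fit <- fit_ellipsoid(sph$mask, sph$spacing)
  expect_equal(elongation(fit$radii[1], fit$radii[2]), 1, tolerance = 0.03)
})

test_that("chromatin density is the normalized mean intensity over the label", {
  sph <- voxel_sphere(10)
  img <- voxel_grid(array(0.5, dim(sph$mask)), spacing = sph$spacing)
  V <- measure_volume(sph$mask, sph$spacing)
  expect_equal(chromatin_density(img, sph$mask, V), 0.5, tolerance = 1e-12)
  img0 <- voxel_grid(array(0, dim(sph$mask)), spacing = sph$spacing)
  expect_equal(chromatin_density(img0, sph$mask, V), 0)
  # doubling intensities doubles D; bit-depth normalization applies
  set.seed(2)
  a <- array(runif(length(sph$mask), 0, 0.5), dim(sph$mask))
  g1 <- voxel_grid(a, spacing = sph$spacing)
  g2 <- voxel_grid(2 * a, spacing = sph$spacing)
  expect_equal(chromatin_density(g2, sph$mask, V),
               2 * chromatin_density(g1, sph$mask, V), tolerance = 1e-12)
  g16 <- voxel_grid(round(a * 65535), spacing = sph$spacing, bit_max = 65535)
  expect_equal(chromatin_density(g16, sph$mask, V),
               chromatin_density(g1, sph$mask, V), tolerance = 1e-3)
})

test_that("G1 gating thresholds the mean marker intensity with >=", {
  sph <- voxel_sphere(8)
  zero <- voxel_grid(array(0, dim(sph$mask)), spacing = sph$spacing)
  one <- voxel_grid(array(1, dim(sph$mask)), spacing = sph$spacing)
  expect_false(gate_g1(zero, sph$mask, threshold = 0.1))
  expect_true(gate_g1(one, sph$mask, threshold = 0.1))
  half <- voxel_grid(array(0.31, dim(sph$mask)), spacing = sph$spacing)
  expect_true(gate_g1(half, sph$mask, threshold = 0.31))  # boundary: >=
  bad <- voxel_grid(array(1, c(4, 4, 4)))
  expect_error(gate_g1(bad, sph$mask), "differ")
})

test_that("measure_nuclei produces one consistent record per label", {
  ph <- grid_population_phantom(n_nuclei = 2, noise_sd = 0.01, seed = 5)
  marker <- voxel_grid(array(0.5, dim(ph$image$data)),
                       spacing = ph$image$spacing)
  rec <- measure_nuclei(ph$image, ph$labels, marker = marker)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$volume_um3 > 0 & rec$surface_um2 > 0))
  expect_true(all(rec$elongation >= 1))
  expect_true(all(rec$r1 >= rec$r2 & rec$r2 >= rec$r3))
  expect_true(all(rec$g1_positive))
  expect_true(all(abs(rec$volume_um3 / ph$truth$volume_um3 - 1) < 0.05))
  expect_true(all(abs(rec$elongation / ph$truth$elongation - 1) < 0.05))
})
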