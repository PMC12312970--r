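# Shared fixture builders: all fixtures are generated in code at test time.

# voxelized solid sphere, isotropic spacing, radius in voxels
voxel_sphere <- function(radius_vox, spacing_nm = 100, margin = 5L) {
  n <- as.integer(2 * radius_vox + 2 * margin + 1)
  c0 <- (n + 1) / 2
  ax <- seq_len(n) - c0
  Z <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  X <- array(rep(ax, each = n * n), c(n, n, n))
  list(mask = Z^2 + Y^2 + X^2 <= radius_vox^2,
       spacing = rep(spacing_nm, 3))
}

# axis-aligned voxelized ellipsoid phantom at the default acquisition spacing
voxel_ellipsoid <- function(radii_um, spacing = c(150, 120, 120),
                            angles = c(0, pi / 2, 0)) {
  # default angles put r1 along x so the default spacing box stays compact
  half <- sqrt((rotation_angles_extent(angles, radii_um)))
  shape <- ceiling((2 * half + 1.5) * 1000 / spacing)
  spec <- phantom_spec(shape, spacing, nuclei = list(list(
    center = shape * spacing / 2000, radii = radii_um, angles = angles,
    intensity = 0.6)),
    texture_amp = 0, psf_sigma = c(0, 0, 0), noise_sd = 0, background = 0)
  ph <- generate_nucleus(spec)
  list(mask = ph$labels$labels == 1L, spacing = spacing, phantom = ph)
}

rotation_angles_extent <- function(angles, radii) {
  R <- nucleomorph:::rotation_matrix(angles)
  ((R^2) %*% radii^2)[, 1]
}

# minimum over ground-truth nuclei of the best Jaccard achieved by any
# predicted label
min_best_jaccard <- function(pred_labels, truth_labels, K) {
  min(vapply(seq_len(K), function(g) {
    b <- truth_labels == g
    max(vapply(seq_len(max(pred_labels)), function(k) {
      a <- pred_labels == k
      sum(a & b) / sum(a | b)
    }, 0))
  }, 0))
}

# multi-nucleus single-stack phantom: K nuclei on a grid, well separated
grid_population_phantom <- function(n_nuclei = 10, noise_sd = 0,
                                    texture_amp = 0.15, seed = 7) {
  set.seed(seed)
  ny_grid <- 5
  centers <- expand.grid(y = seq(2.2, by = 3.2, length.out = ny_grid),
                         x = c(2.6, 7.0))
  nuclei <- lapply(seq_len(n_nuclei), function(i) {
    r1 <- stats::runif(1, 1.3, 1.6)
    e <- stats::runif(1, 1.1, 1.5)
    list(center = c(1.9, centers$y[i], centers$x[i]),
         radii = c(r1, r1 / e, r1 / e * 0.8),
         angles = stats::runif(3, 0, pi), intensity = 0.6)
  })
  spec <- phantom_spec(shape = c(26, 144, 81), spacing = c(150, 120, 120),
                       nuclei = nuclei, texture_amp = texture_amp,
                       noise_sd = noise_sd, seed = seed)
  generate_nucleus(spec)
}

# structured 2D image for FRC tests: smoothed white noise
structured_image <- function(n = 256, pixel_nm = 35, seed = 3,
                             smooth = 3) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  if (smooth > 0) m <- gaussian_smooth(array(m, c(1, n, n)), c(0, smooth, smooth))[1, , ]
  voxel_grid(m - min(m) + 0.01, spacing = c(pixel_nm, pixel_nm),
             channel_name = "sted")
}

# band-limited shared-signal pair with independent noise, for the FRC
# threshold-crossing oracle
bandlimited_pair <- function(n = 256, pixel_nm = 35, f0_frac = 0.5,
                             noise_sd = 0.05, seed = 3) {
  set.seed(seed)
  f0 <- f0_frac * 0.5 / pixel_nm
  fy <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * pixel_nm)
  fr <- sqrt(outer(fy^2, fy^2, `+`))
  sigF <- matrix(stats::rnorm(n * n) + 1i * stats::rnorm(n * n), n, n) *
    (fr <= f0)
  sig <- Re(stats::fft(sigF, inverse = TRUE)) / n
  sig <- sig / stats::sd(sig)
  mk <- function(m) voxel_grid(m - min(m) + 0.01,
                               spacing = c(pixel_nm, pixel_nm))
  list(A = mk(sig + noise_sd * matrix(stats::rnorm(n * n), n, n)),
       B = mk(sig + noise_sd * matrix(stats::rnorm(n * n), n, n)),
       f0 = f0)
}

# worked comparative-Cq table: target 2 cycles lower in treated, refs equal
example_cq_table <- function() {
  data.frame(sample = rep(c("m1", "s1"), each = 2),
             group = rep(c("Mock", "S1.1"), each = 2),
             gene = rep(c("NDM29", "GAPDH"), 2),
             cq = c(24, 20, 22, 20))
}
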