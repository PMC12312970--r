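# Synthetic Hoechst-like nucleus phantoms with analytic ground truth.
# The generator emulates the acquisition geometry of the confocal stacks the
# pipeline targets (120 nm lateral / 150 nm axial voxels), with ellipsoidal
# nuclei, a smoothed-random-field chromatin texture, anisotropic Gaussian
# PSF blur and additive/shot noise.

#' Specification of a synthetic nucleus phantom
#'
#' @param shape image shape in voxels, `(z, y, x)`.
#' @param spacing voxel size in nm, `(z, y, x)`; default the target
#'   acquisition geometry (150, 120, 120).
#' @param nuclei list of per-nucleus parameter lists with fields `center`
#'   (µm, `(z, y, x)`), `radii` (µm, `r1 >= r2 >= r3 > 0`), `angles`
#'   (radians, intrinsic rotations about z, y, x; default none) and
#'   `intensity` (interior mean intensity on the unit scale, default 0.6).
#' @param texture_amp chromatin texture amplitude `a`: the interior is
#'   multiplied by a smoothed Gaussian random field rescaled to
#'   `[1 - a, 1 + a]`. 0 disables texture.
#' @param texture_corr_nm correlation length of the texture field (nm).
#' @param psf_sigma Gaussian PSF sigma per axis in nm, `(z, y, x)`.
#'   `c(0, 0, 0)` disables blur.
#' @param noise_sd additive Gaussian noise standard deviation (unit scale).
#' @param poisson if `TRUE`, apply Poisson (shot) noise before the Gaussian
#'   read noise.
#' @param poisson_photons photon count corresponding to unit intensity when
#'   `poisson = TRUE`.
#' @param background background intensity level (unit scale).
#' @param seed random seed; `NULL` leaves the RNG state alone.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(150, 120, 120),
                         nuclei = list(),
                         texture_amp = 0.2, texture_corr_nm = 400,
                         psf_sigma = c(300, 130, 130),
                         noise_sd = 0.02, poisson = FALSE,
                         poisson_photons = 500,
                         background = 0.01, seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 1), length(spacing) == 3,
            all(spacing > 0), texture_amp >= 0, noise_sd >= 0,
            background >= 0)
  extent_um <- shape * spacing / 1000  # physical image extent per axis
  nuclei <- lapply(nuclei, function(nu) {
    if (is.null(nu$angles)) nu$angles <- c(0, 0, 0)
    if (is.null(nu$intensity)) nu$intensity <- 0.6
    r <- nu$radii
    if (length(r) != 3 || any(r <= 0) || r[1] < r[2] || r[2] < r[3])
      stop("nucleus radii must satisfy r1 >= r2 >= r3 > 0")
    # exact per-axis half-extent of the rotated ellipsoid (support function)
    R <- rotation_matrix(nu$angles)
    half <- sqrt((R^2) %*% r^2)[, 1]
    if (any(nu$center - half < 0) || any(nu$center + half > extent_um))
      stop("ellipsoid out of bounds (center ", paste(nu$center, collapse = ","),
           " µm, extent ", paste(round(half, 2), collapse = ","), " µm)")
    nu
  })
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 nuclei = nuclei, texture_amp = texture_amp,
                 texture_corr_nm = texture_corr_nm,
                 psf_sigma = as.numeric(psf_sigma), noise_sd = noise_sd,
                 poisson = poisson, poisson_photons = poisson_photons,
                 background = background, seed = seed),
            class = "phantom_spec")
}

rotation_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  # rotations about the z, y, x axes of the (z, y, x) coordinate frame
  Rz <- rbind(c(1, 0, 0), c(0, cz, -sz), c(0, sz, cz))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(cx, -sx, 0), c(sx, cx, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# squared normalized ellipsoid coordinate for every voxel: <= 1 is interior
ellipsoid_q <- function(shape, spacing_um, center_um, radii_um, angles) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zc <- (seq_len(nz) - 0.5) * spacing_um[1] - center_um[1]
  yc <- (seq_len(ny) - 0.5) * spacing_um[2] - center_um[2]
  xc <- (seq_len(nx) - 0.5) * spacing_um[3] - center_um[3]
  R <- rotation_matrix(angles)
  # M = R diag(1/r^2) R^T on (z, y, x) displacement
  M <- R %*% diag(1 / radii_um^2) %*% t(R)
  Z <- array(rep(zc, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yc, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(xc, each = nz * ny), c(nz, ny, nx))
  M[1, 1] * Z^2 + M[2, 2] * Y^2 + M[3, 3] * X^2 +
    2 * (M[1, 2] * Z * Y + M[1, 3] * Z * X + M[2, 3] * Y * X)
}

gaussian_random_field <- function(shape, sigma_vox, amp) {
  g <- array(stats::rnorm(prod(shape)), shape)
  g <- gaussian_smooth(g, sigma_vox)
  g <- g - mean(g)
  mx <- max(abs(g))
  if (mx == 0) return(array(1, shape))
  1 + amp * g / mx
}

#' Exact surface area of an ellipsoid by numerical quadrature
#'
#' Gauss-Legendre quadrature of the parametric surface element; accurate to
#' well below 1e-8 relative for the radii ratios encountered here.
#'
#' @param r1,r2,r3 semi-axes (any order), in consistent units.
#' @param n quadrature nodes per dimension.
#' @return surface area in squared input units.
#' @export
ellipsoid_surface_area <- function(r1, r2, r3, n = 96) {
  # Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  # theta in [0, pi], phi in [0, 2 pi]
  th <- (nodes + 1) * pi / 2; wth <- weights * pi / 2
  ph <- (nodes + 1) * pi;     wph <- weights * pi
  a <- r1; b <- r2; cc <- r3
  st <- sin(th); ct <- cos(th)
  integrand <- outer(st, ph, function(s, p) s) # placeholder shape
  for (i in seq_len(n)) {
    integrand[i, ] <- st[i] * sqrt(
      (b * cc * st[i] * cos(ph))^2 + (a * cc * st[i] * sin(ph))^2 +
        (a * b * ct[i])^2)
  }
  sum((wth %*% integrand) * wph)
}

#' Generate a synthetic nucleus stack with analytic ground truth
#'
#' Renders the ellipsoids of `spec` into an intensity stack (background
#' outside, textured interior, PSF blur, noise), the matching ground-truth
#' label mask, and a morphometry table computed analytically from the
#' ellipsoid parameters: `V = 4/3 pi r1 r2 r3`, surface area by exact
#' quadrature, `E = r1 / r2`, chromatin density equal to the interior mean
#' intensity.
#'
#' @param spec a [phantom_spec()] with at least one nucleus.
#' @return list with elements `image` ([voxel_grid()]), `labels`
#'   ([label_mask()]) and `truth` (data frame, one row per nucleus).
#' @export
generate_nucleus <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!length(spec$nuclei)) stop("spec contains no nuclei")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shape <- spec$shape
  sp_um <- spec$spacing / 1000
  img <- array(spec$background, shape)
  lab <- array(0L, shape)
  best_q <- array(Inf, shape)

  texture <- if (spec$texture_amp > 0) {
    gaussian_random_field(shape, spec$texture_corr_nm / spec$spacing,
                          spec$texture_amp)
  } else array(1, shape)

  truth <- list()
  for (i in seq_along(spec$nuclei)) {
    nu <- spec$nuclei[[i]]
    q <- ellipsoid_q(shape, sp_um, nu$center, nu$radii, nu$angles)
    inside <- q <= 1
    img[inside] <- spec$background + nu$intensity * texture[inside]
    take <- inside & q < best_q
    lab[take] <- i
    best_q[take] <- q[take]
    V <- 4 / 3 * pi * prod(nu$radii)
    S <- ellipsoid_surface_area(nu$radii[1], nu$radii[2], nu$radii[3])
    truth[[i]] <- data.frame(
      label = i, volume_um3 = V, surface_um2 = S,
      compactness = V^2 / S^3, compactness_norm = 36 * pi * V^2 / S^3,
      r1 = nu$radii[1], r2 = nu$radii[2], r3 = nu$radii[3],
      elongation = nu$radii[1] / nu$radii[2],
      chromatin_density = nu$intensity, g1_positive = TRUE)
  }

  if (any(spec$psf_sigma > 0))
    img <- gaussian_smooth(img, spec$psf_sigma / spec$spacing)
  if (spec$poisson) {
    ph <- spec$poisson_photons
    img <- array(stats::rpois(length(img), pmax(img, 0) * ph) / ph, shape)
  }
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), shape)
  img[img < 0] <- 0

  list(image = voxel_grid(img, spacing = spec$spacing,
                          channel_name = "Hoechst", bit_max = 1),
       labels = label_mask(lab, spacing = spec$spacing),
       truth = do.call(rbind, truth))
}

#' Generate a touching-pair phantom with controlled seed separation
#'
#' Two equal spheres whose centers — and hence the interior maxima of the
#' mask's Euclidean distance transform, the watershed seed candidates — lie
#' exactly `separation` voxels apart along the y axis. Used to probe the
#' "nuclei closer than 10 voxels are not separated" merge rule.
#'
#' @param separation center-to-center distance in voxels (>= 0).
#' @param radius_vox sphere radius in voxels.
#' @param spacing isotropic voxel size in nm (a scalar).
#' @param intensity interior intensity.
#' @param noise_sd additive Gaussian noise sd (default 0: deterministic).
#' @param seed random seed used when `noise_sd > 0`.
#' @return list with `image`, `labels` (2 ground-truth labels) and `centers`
#'   (voxel coordinates of the two sphere centers).
#' @export
generate_touching_pair <- function(separation, radius_vox = 12,
                                   spacing = 120, intensity = 0.6,
                                   noise_sd = 0, seed = NULL) {
  if (separation < 0) stop("`separation` must be >= 0")
  margin <- 4L
  r <- radius_vox
  ny <- as.integer(2 * r + separation + 2 * margin + 1)
  nz <- nx <- as.integer(2 * r + 2 * margin + 1)
  if (separation > ny) stop("separation larger than image")
  cz <- (nz + 1) / 2; cx <- (nx + 1) / 2
  cy1 <- margin + r + 1
  cy2 <- cy1 + separation
  zc <- seq_len(nz) - cz
  yc <- seq_len(ny)
  xc <- seq_len(nx) - cx
  Z <- array(rep(zc, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yc, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(xc, each = nz * ny), c(nz, ny, nx))
  d1 <- Z^2 + (Y - cy1)^2 + X^2
  d2 <- Z^2 + (Y - cy2)^2 + X^2
  r2 <- r^2
  inside <- d1 <= r2 | d2 <= r2
  lab <- array(0L, dim(inside))
  lab[inside & (d1 <= d2)] <- 1L
  lab[inside & (d1 > d2)] <- 2L
  img <- array(0, dim(inside))
  img[inside] <- intensity
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmax(img + array(stats::rnorm(length(img), 0, noise_sd), dim(img)), 0)
  }
  list(image = voxel_grid(img, spacing = rep(spacing, 3),
                          channel_name = "Hoechst", bit_max = 1),
       labels = label_mask(lab, spacing = rep(spacing, 3)),
       centers = rbind(c(cz, cy1, cx), c(cz, cy2, cx)))
}

#' Specification of a two-group phantom population
#'
#' States the group structure used for parameter-recovery and group-contrast
#' validation: per-group sample size and normal distributions (truncated at
#' physical bounds `V > 0`, `E >= 1`, `D > 0`) for nuclear volume,
#' elongation and chromatin density. Defaults mirror the contrast the
#' pipeline is meant to resolve: group B smaller in volume, more elongated
#' and denser than group A (means 486 vs 638 µm³, 1.86 vs 1.34, 0.319 vs
#' 0.254).
#'
#' @param n_per_group nuclei per group.
#' @param groups named list of per-group parameter lists with fields
#'   `volume_mean`, `volume_sd` (µm³), `elongation_mean`, `elongation_sd`,
#'   `density_mean`, `density_sd`.
#' @param flatness fixed ratio `r3 / r2` used to convert (V, E) into
#'   ellipsoid semi-axes.
#' @param touching_fraction fraction of nuclei emitted as touching pairs.
#' @param g1_fraction fraction of G1-positive nuclei per group.
#' @param spacing voxel size in nm.
#' @param noise_sd,texture_amp,psf_sigma rendering options passed to
#'   [phantom_spec()].
#' @param seed random seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_per_group = 20,
                            groups = list(
                              A = list(volume_mean = 638, volume_sd = 50,
                                       elongation_mean = 1.34,
                                       elongation_sd = 0.15,
                                       density_mean = 0.254,
                                       density_sd = 0.03),
                              B = list(volume_mean = 486, volume_sd = 50,
                                       elongation_mean = 1.86,
                                       elongation_sd = 0.15,
                                       density_mean = 0.319,
                                       density_sd = 0.03)),
                            flatness = 0.65,
                            touching_fraction = 0,
                            g1_fraction = 1,
                            spacing = c(150, 120, 120),
                            noise_sd = 0.02, texture_amp = 0.15,
                            psf_sigma = c(300, 130, 130),
                            seed = 1L) {
  stopifnot(n_per_group >= 1, touching_fraction >= 0, touching_fraction <= 1,
            g1_fraction >= 0, g1_fraction <= 1, flatness > 0, flatness <= 1)
  for (g in groups)
    stopifnot(g$volume_sd >= 0, g$elongation_sd >= 0, g$density_sd >= 0)
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 flatness = flatness, touching_fraction = touching_fraction,
                 g1_fraction = g1_fraction, spacing = spacing,
                 noise_sd = noise_sd, texture_amp = texture_amp,
                 psf_sigma = psf_sigma, seed = seed),
            class = "population_spec")
}

rtruncnorm1 <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v > lower) return(v)
  }
}

#' Generate a two-group phantom population with ground truth
#'
#' Draws per-nucleus (volume, elongation, density) from the group
#' distributions of `pop`, converts them to ellipsoid semi-axes using the
#' fixed flatness ratio, renders each nucleus in its own minimal stack, and
#' returns the rendered samples together with the generator's ground truth.
#'
#' @param pop a [population_spec()].
#' @param out_dir optional directory; when given, each stack is written as
#'   TIFF along with `ground_truth.csv`.
#' @param render if `FALSE`, only the ground-truth table is produced (fast
#'   path for statistics-only work).
#' @return list with `samples` (list of per-nucleus lists: `image`, `labels`,
#'   `group`, `truth`) and `truth` (data frame with generator parameters).
#' @export
generate_population <- function(pop, out_dir = NULL, render = TRUE) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(pop$seed)
  samples <- list()
  rows <- list()
  id <- 0L
  for (gname in names(pop$groups)) {
    g <- pop$groups[[gname]]
    for (i in seq_len(pop$n_per_group)) {
      id <- id + 1L
      V <- rtruncnorm1(g$volume_mean, g$volume_sd, 0)
      E <- max(rtruncnorm1(g$elongation_mean, g$elongation_sd, 1), 1)
      D <- rtruncnorm1(g$density_mean, g$density_sd, 0)
      k <- pop$flatness
      r2 <- (3 * V / (4 * pi * E * k))^(1 / 3)
      radii <- c(E * r2, r2, k * r2)
      angles <- stats::runif(3, 0, pi)
      g1 <- stats::runif(1) < pop$g1_fraction
      rows[[id]] <- data.frame(id = id, group = gname, volume_um3 = V,
                               elongation = E, chromatin_density = D,
                               r1 = radii[1], r2 = radii[2], r3 = radii[3],
                               g1_positive = g1)
      if (render) {
        margin_um <- 1.2
        extent <- 2 * radii[1] + 2 * margin_um
        shape <- ceiling(extent * 1000 / pop$spacing)
        spec <- phantom_spec(
          shape = shape, spacing = pop$spacing,
          nuclei = list(list(center = shape * pop$spacing / 2000,
                             radii = radii, angles = angles, intensity = D)),
          texture_amp = pop$texture_amp, noise_sd = pop$noise_sd,
          psf_sigma = pop$psf_sigma, seed = NULL)
        ph <- generate_nucleus(spec)
        samples[[id]] <- list(image = ph$image, labels = ph$labels,
                              group = gname, truth = rows[[id]])
        if (!is.null(out_dir)) {
          if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
          write_stack(list(Hoechst = ph$image),
                      file.path(out_dir, sprintf("nucleus_%03d.tif", id)))
          write_labels(ph$labels,
                       file.path(out_dir, sprintf("labels_%03d.tif", id)))
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, truth = truth)
}
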