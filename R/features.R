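# Per-voxel feature bank for the voxel classifier: Gaussian blur,
# derivatives (gradient magnitude), Hessian eigenvalue, Laplacian of
# Gaussian, structure-tensor eigenvalue, edge strength (gradient magnitude
# with non-maximum suppression, the 3D stand-in for Canny), Difference of
# Gaussians, local mean and local variance — at each requested scale, plus
# the raw intensity once. Scales are given in x/y-voxel units and corrected
# per axis so physical smoothing is isotropic on anisotropic grids.

feature_basenames <- c("gauss", "grad", "hess", "log", "stensor", "edge",
                       "dog", "mean", "var")

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_deriv_kernel <- function(sigma, order) {
  r <- max(order, ceiling(3 * sigma + order))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 1L) {
    k <- -x / sigma^2 * g
    k <- k - mean(k)          # exact zero response to constants
    k / sum(k * x)            # unit response to a unit ramp
  } else {
    k <- (x^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k)
    k / sum(k * x^2 / 2)      # unit response to x^2/2
  }
}

conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  out <- .cpp_conv1d_axis(as.double(arr), as.integer(d), as.double(kernel),
                          as.integer(axis - 1L))
  dim(out) <- d
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr numeric array, dim `(z, y, x)`.
#' @param sigma_vox per-axis sigma in voxels (length 3 or scalar); axes with
#'   sigma below 0.01 are skipped.
#' @return smoothed array, same dim.
#' @export
gaussian_smooth <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  for (ax in 1:3)
    if (sigma_vox[ax] >= 0.01)
      arr <- conv_axis(arr, gaussian_kernel(sigma_vox[ax]), ax)
  arr
}

# separable Gaussian-derivative filter: derivative of given order along
# `orders` (per-axis vector of 0/1/2), smoothing elsewhere
gauss_deriv <- function(arr, sigma_vox, orders) {
  for (ax in 1:3) {
    k <- if (orders[ax] == 0) gaussian_kernel(sigma_vox[ax])
         else gaussian_deriv_kernel(sigma_vox[ax], orders[ax])
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

box_mean <- function(arr, radius_vox) {
  for (ax in 1:3) {
    r <- radius_vox[ax]
    if (r >= 1) arr <- conv_axis(arr, rep(1 / (2 * r + 1), 2 * r + 1), ax)
  }
  arr
}

# eigenvalues of a field of symmetric 3x3 matrices (vectorized trigonometric
# method); returns list(largest, smallest) by signed value
sym3_eigen_range <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-30
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e1[!ok] <- q[!ok]
  e3[!ok] <- q[!ok]
  list(largest = e1, smallest = e3)
}

#' Compute the per-voxel feature bank
#'
#' @param img a [voxel_grid()] (3D; single-plane grids are lifted to a
#'   1-slice stack).
#' @param scales smoothing scales in x/y-voxel units, all positive.
#' @return an object of class `feature_stack`: list with `features` (array of
#'   dim `(n_features, z, y, x)`), `names`, `scales`, `spacing`.
#' @export
compute_features <- function(img, scales = c(1, 2, 4, 8)) {
  stopifnot(inherits(img, "voxel_grid"))
  if (!length(scales) || any(scales <= 0))
    stop("`scales` must be non-empty and positive")
  data <- unclass(img$data)
  sp <- img$spacing
  if (length(dim(data)) == 2L) {
    dim(data) <- c(1L, dim(data))
    sp <- c(sp[["x"]], sp)  # dummy axial spacing for a single plane
  }
  d <- dim(data)
  arr <- data / img$bit_max
  nf <- 1L + length(scales) * length(feature_basenames)
  feats <- array(0, c(nf, d))
  fnames <- character(nf)
  feats[1, , , ] <- arr
  fnames[1] <- "raw"
  fi <- 1L
  sp_ratio <- sp[["x"]] / sp  # per-axis voxel-unit correction factors

  for (s in scales) {
    sig <- s * sp_ratio  # per-axis sigma in voxels
    g <- gaussian_smooth(arr, sig)
    # first derivatives in x-voxel units
    gz <- gauss_deriv(arr, sig, c(1, 0, 0)) * sp_ratio[1]
    gy <- gauss_deriv(arr, sig, c(0, 1, 0)) * sp_ratio[2]
    gx <- gauss_deriv(arr, sig, c(0, 0, 1)) * sp_ratio[3]
    gm <- sqrt(gz^2 + gy^2 + gx^2)
    # Hessian
    hzz <- gauss_deriv(arr, sig, c(2, 0, 0)) * sp_ratio[1]^2
    hyy <- gauss_deriv(arr, sig, c(0, 2, 0)) * sp_ratio[2]^2
    hxx <- gauss_deriv(arr, sig, c(0, 0, 2)) * sp_ratio[3]^2
    hzy <- gauss_deriv(arr, sig, c(1, 1, 0)) * sp_ratio[1] * sp_ratio[2]
    hzx <- gauss_deriv(arr, sig, c(1, 0, 1)) * sp_ratio[1] * sp_ratio[3]
    hyx <- gauss_deriv(arr, sig, c(0, 1, 1)) * sp_ratio[2] * sp_ratio[3]
    he <- sym3_eigen_range(hzz, hyy, hxx, hzy, hzx, hyx)
    hmax <- ifelse(abs(he$largest) >= abs(he$smallest), he$largest,
                   he$smallest)
    lap <- hzz + hyy + hxx
    # structure tensor (integration scale = sigma)
    s11 <- gaussian_smooth(gz * gz, sig)
    s22 <- gaussian_smooth(gy * gy, sig)
    s33 <- gaussian_smooth(gx * gx, sig)
    s12 <- gaussian_smooth(gz * gy, sig)
    s13 <- gaussian_smooth(gz * gx, sig)
    s23 <- gaussian_smooth(gy * gx, sig)
    st <- sym3_eigen_range(s11, s22, s33, s12, s13, s23)$largest
    edge <- .cpp_nms(as.double(gm), as.double(gz), as.double(gy),
                     as.double(gx), as.integer(d))
    dim(edge) <- d
    dog <- g - gaussian_smooth(arr, 1.6 * sig)
    rad <- pmax(1L, as.integer(round(sig)))
    bm <- box_mean(arr, rad)
    bv <- pmax(box_mean(arr^2, rad) - bm^2, 0)
    per_scale <- list(gauss = g, grad = gm, hess = hmax, log = lap,
                      stensor = st, edge = edge, dog = dog, mean = bm,
                      var = bv)
    for (bn in feature_basenames) {
      fi <- fi + 1L
      feats[fi, , , ] <- per_scale[[bn]]
      fnames[fi] <- sprintf("%s_s%g", bn, s)
    }
  }
  if (any(!is.finite(feats))) stop("non-finite feature values produced")
  structure(list(features = feats, names = fnames, scales = scales,
                 spacing = sp, dim = d),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d features at scales {%s}  dim: %s\n",
              length(x$names), paste(x$scales, collapse = ", "),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# features as an (n_voxels x n_features) design matrix
feature_matrix <- function(fs) {
  nf <- length(fs$names)
  m <- t(matrix(fs$features, nrow = nf))
  colnames(m) <- fs$names
  m
}
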