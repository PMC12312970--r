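# Fourier ring correlation (FRC) resolution estimation for 2D
# super-resolution micrographs. When only a single image is available it is
# split into two half-images from complementary checkerboard pixel sets; the
# FRC curve is the per-frequency-ring normalized cross-spectrum of the two
# images and the resolution is the inverse of the first frequency where the
# curve drops below the threshold (fixed 1/7 by default).

#' Split a single image into complementary checkerboard half-images
#'
#' Pixels of the two checkerboard colors are reassembled row-wise onto
#' half-resolution grids of `n_y` by `n_x / 2` pixels (half the pixel count
#' each) with the x spacing doubled, which keeps the frequency sampling of
#' the two axes identical.
#'
#' @param img a 2D [voxel_grid()] with even width, at least 64 x 64.
#' @return list of two 2D voxel grids `A` and `B`.
#' @export
checkerboard_split <- function(img) {
  stopifnot(inherits(img, "voxel_grid"))
  d <- dim(img$data)
  if (length(d) != 2L) stop("checkerboard_split needs a 2D image")
  if (any(d < 64)) stop("image too small (need >= 64x64)")
  if (d[2] %% 2L) stop("image width must be even")
  ny <- d[1]; nx <- d[2]
  A <- matrix(0, ny, nx / 2)
  B <- matrix(0, ny, nx / 2)
  for (y in seq_len(ny)) {
    off <- (y - 1L) %% 2L            # checkerboard phase of this row
    a_cols <- seq(1L + off, nx, 2L)
    b_cols <- seq(2L - off, nx, 2L)
    A[y, ] <- img$data[y, a_cols]
    B[y, ] <- img$data[y, b_cols]
  }
  sp <- c(img$spacing[["y"]], 2 * img$spacing[["x"]])
  list(A = voxel_grid(A, spacing = sp, channel_name = img$channel_name,
                      bit_max = img$bit_max),
       B = voxel_grid(B, spacing = sp, channel_name = img$channel_name,
                      bit_max = img$bit_max))
}

hann2d <- function(ny, nx) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  outer(wy, wx)
}

fft_freq <- function(n, spacing_nm) {
  half <- floor((n - 1) / 2)
  k <- c(0:half, -(n - half - 1):-1)
  k / (n * spacing_nm)
}

#' Fourier ring correlation curve of two images
#'
#' Both images are mean-subtracted and Hann-apodized; per frequency ring
#' `FRC(r) = Re(sum F_A conj(F_B)) / sqrt(sum |F_A|^2 sum |F_B|^2)`.
#'
#' @param imgA,imgB 2D [voxel_grid()]s of equal shape and spacing.
#' @param ring_width ring width in frequency bins (>= 1).
#' @return object of class `frc_curve`: list with `freq` (1/nm, strictly
#'   increasing ring centers), `frc`, `n_pixels` per ring.
#' @export
frc_curve <- function(imgA, imgB, ring_width = 1) {
  stopifnot(inherits(imgA, "voxel_grid"), inherits(imgB, "voxel_grid"))
  if (!identical(dim(imgA$data), dim(imgB$data))) stop("shape mismatch")
  if (ring_width < 1) stop("`ring_width` must be >= 1")
  d <- dim(imgA$data)
  ny <- d[1]; nx <- d[2]
  w <- hann2d(ny, nx)
  A <- (imgA$data - mean(imgA$data)) * w
  B <- (imgB$data - mean(imgB$data)) * w
  FA <- stats::fft(A)
  FB <- stats::fft(B)
  fy <- fft_freq(ny, imgA$spacing[["y"]])
  fx <- fft_freq(nx, imgA$spacing[["x"]])
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  df <- 1 / (ny * imgA$spacing[["y"]])  # radial bin width
  nyq <- 0.5 / max(imgA$spacing)
  ring <- floor(fr / (df * ring_width))
  keep <- fr > 0 & fr <= nyq
  rid <- ring[keep]
  num <- Re(FA[keep] * Conj(FB[keep]))
  pa <- Mod(FA[keep])^2
  pb <- Mod(FB[keep])^2
  agg <- rowsum(cbind(num, pa, pb, 1), rid)
  rids <- as.numeric(rownames(agg))
  ord <- order(rids)
  agg <- agg[ord, , drop = FALSE]
  rids <- rids[ord]
  denom <- sqrt(agg[, 2] * agg[, 3])
  ok <- denom > 0
  structure(list(freq = (rids[ok] + 0.5) * df * ring_width,
                 frc = pmin(pmax(agg[ok, 1] / denom[ok], -1), 1),
                 n_pixels = agg[ok, 4]),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d rings, freq %.4g-%.4g 1/nm\n",
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Resolution from an FRC curve
#'
#' The first downward crossing of the threshold is located by linear
#' interpolation between adjacent rings; resolution is the inverse of the
#' crossing frequency. A curve that never falls below the threshold yields
#' `NA` ("not determined"), which is a valid outcome.
#'
#' @param curve an [frc_curve()].
#' @param threshold fixed numeric threshold (default 1/7), or `"3sigma"` /
#'   `"halfbit"` for the per-ring statistical criteria.
#' @return list with `resolution_nm` (`NA` if not determined),
#'   `crossing_freq` (1/nm) and the threshold used.
#' @export
frc_resolution <- function(curve, threshold = 1 / 7) {
  stopifnot(inherits(curve, "frc_curve"))
  if (!length(curve$freq)) stop("empty FRC curve")
  thr <- if (is.character(threshold)) {
    switch(match.arg(threshold, c("3sigma", "halfbit")),
           "3sigma" = 3 / sqrt(curve$n_pixels / 2),
           "halfbit" = (0.2071 + 1.9102 / sqrt(curve$n_pixels)) /
                       (1.2071 + 0.9102 / sqrt(curve$n_pixels)))
  } else rep(threshold, length(curve$freq))
  below <- which(curve$frc < thr)
  if (!length(below))
    return(list(resolution_nm = NA_real_, crossing_freq = NA_real_,
                threshold = threshold))
  i <- below[1]
  if (i == 1) {
    f <- curve$freq[1]
  } else {
    g1 <- curve$frc[i - 1] - thr[i - 1]
    g2 <- curve$frc[i] - thr[i]
    t <- g1 / (g1 - g2)
    f <- curve$freq[i - 1] + t * (curve$freq[i] - curve$freq[i - 1])
  }
  list(resolution_nm = 1 / f, crossing_freq = f, threshold = threshold)
}

#' Single-image FRC resolution
#'
#' Convenience wrapper: checkerboard split, FRC curve, threshold crossing.
#'
#' @param img a 2D [voxel_grid()].
#' @param threshold see [frc_resolution()].
#' @param ring_width see [frc_curve()].
#' @return list as in [frc_resolution()] with the curve attached.
#' @export
frc_single_image <- function(img, threshold = 1 / 7, ring_width = 1) {
  halves <- checkerboard_split(img)
  curve <- frc_curve(halves$A, halves$B, ring_width = ring_width)
  res <- frc_resolution(curve, threshold = threshold)
  res$curve <- curve
  res
}
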