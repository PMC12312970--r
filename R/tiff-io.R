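# Minimal baseline-TIFF I/O (uncompressed grayscale, little-endian writer,
# either byte order on read, ImageJ-style hyperstack metadata). Written
# in-package because no TIFF reader is available in the target library set.
# Supports exactly what the pipeline needs: 8/16-bit unsigned and 32-bit
# float samples, one sample per pixel, strip storage.

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write voxel grids to a multi-page TIFF stack
#'
#' Channels are interleaved channel-fastest (ImageJ hyperstack order) and the
#' voxel spacing is recorded in the ImageDescription (`spacing=`, axial, in
#' micron) plus X/YResolution tags (lateral). Data with `bit_max > 1` are
#' stored as 16-bit unsigned integers (bit-exact round trip); unit-scale data
#' are stored as 32-bit float.
#'
#' @param x a [voxel_grid()] or a named list of voxel grids (one per channel,
#'   identical shape and spacing).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    nm <- if (nzchar(x$channel_name)) x$channel_name else "channel1"
    x <- stats::setNames(list(x), nm)
  }
  if (!length(x) || !all(vapply(x, inherits, TRUE, "voxel_grid")))
    stop("`x` must be a voxel_grid or a list of voxel_grids")
  d0 <- dim(x[[1]]$data)
  for (g in x) {
    if (!identical(dim(g$data), d0)) stop("all channels must share one shape")
    if (!identical(g$spacing, x[[1]]$spacing))
      stop("all channels must share one spacing")
  }
  is3d <- length(d0) == 3L
  nz <- if (is3d) d0[1] else 1L
  ny <- if (is3d) d0[2] else d0[1]
  nx <- if (is3d) d0[3] else d0[2]
  nC <- length(x)
  sp <- x[[1]]$spacing  # nm
  sp_z_um <- if (is3d) sp[["z"]] / 1000 else 0
  sp_y_um <- sp[["y"]] / 1000
  sp_x_um <- sp[["x"]] / 1000
  bit_max <- x[[1]]$bit_max
  as_float <- bit_max <= 1

  bytes_per <- if (as_float) 4L else 2L
  bits <- if (as_float) 32L else 16L
  fmt <- if (as_float) 3L else 1L
  npage <- nz * nC
  page_bytes <- as.integer(nx) * as.integer(ny) * bytes_per

  ch_names <- names(x)
  if (is.null(ch_names)) ch_names <- paste0("channel", seq_len(nC))
  desc <- paste0("ImageJ=1.54f\nimages=", npage, "\nchannels=", nC,
                 "\nslices=", nz, "\nhyperstack=true\nmode=grayscale\n",
                 "unit=micron\nspacing=", format(sp_z_um, digits = 10),
                 "\nchannel_names=", paste(ch_names, collapse = ","),
                 "\nloop=false\n")
  desc_len <- nchar(desc, type = "bytes") + 1L  # trailing NUL
  desc_pad <- desc_len %% 2L

  data_off <- 8L + (seq_len(npage) - 1L) * page_bytes
  desc_off <- 8L + npage * page_bytes
  xres_off <- desc_off + desc_len + desc_pad
  yres_off <- xres_off + 8L
  n_tags <- c(14L, rep(13L, npage - 1L))
  ifd_sizes <- 2L + 12L * n_tags + 4L
  ifd_off <- yres_off + 8L + c(0L, cumsum(ifd_sizes))[seq_len(npage)]

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")

  writeChar("II", con, eos = NULL)
  w2(42L)
  w4(ifd_off[1])

  for (ci in seq_len(nC)) x[[ci]]$data <- unclass(x[[ci]]$data)
  for (p in seq_len(npage)) {
    z <- (p - 1L) %/% nC + 1L
    ci <- (p - 1L) %% nC + 1L
    m <- if (is3d) x[[ci]]$data[z, , ] else x[[ci]]$data
    dim(m) <- c(ny, nx)
    v <- as.vector(t(m))  # x fastest within each row
    if (as_float) {
      writeBin(as.double(v), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(v))
      if (any(v < 0L | v > 65535L)) stop("16-bit data out of range [0, 65535]")
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  writeChar(desc, con, eos = NULL)
  writeBin(as.raw(rep(0L, 1L + desc_pad)), con)
  w4(c(10000000L, as.integer(round(sp_x_um * 1e7))))  # pixels per micron
  w4(c(10000000L, as.integer(round(sp_y_um * 1e7))))

  entry <- function(tag, type, count, value, short_val = FALSE) {
    w2(tag); w2(type); w4(count)
    if (short_val) { w2(value); w2(0L) } else w4(value)
  }
  for (p in seq_len(npage)) {
    w2(n_tags[p])
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    entry(258L, 3L, 1L, bits, short_val = TRUE)
    entry(259L, 3L, 1L, 1L, short_val = TRUE)
    entry(262L, 3L, 1L, 1L, short_val = TRUE)
    if (p == 1L) entry(270L, 2L, desc_len, desc_off)
    entry(273L, 4L, 1L, data_off[p])
    entry(277L, 3L, 1L, 1L, short_val = TRUE)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, page_bytes)
    entry(282L, 5L, 1L, xres_off)
    entry(283L, 5L, 1L, yres_off)
    entry(296L, 3L, 1L, 1L, short_val = TRUE)
    entry(339L, 3L, 1L, fmt, short_val = TRUE)
    w4(if (p < npage) ifd_off[p + 1] else 0L)
  }
  invisible(path)
}

read_tiff_raw <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("unreadable TIFF: file too short")
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("unreadable TIFF: bad byte-order mark")
  rd_int <- function(off, n, size, signed = FALSE) {
    # readBin only honors signed for sizes 1 and 2
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            signed = if (size >= 4) TRUE else signed, endian = endian)
  }
  rd_dbl <- function(off, n, size) {
    readBin(raw[(off + 1):(off + n * size)], "double", n = n, size = size,
            endian = endian)
  }
  if (rd_int(2, 1, 2) != 42L) stop("unreadable TIFF: bad magic number")

  read_entry_values <- function(off) {
    type <- rd_int(off + 2, 1, 2)
    count <- rd_int(off + 4, 1, 4)
    size <- tiff_type_size[[as.character(type)]]
    total <- size * count
    voff <- if (total <= 4) off + 8 else rd_int(off + 8, 1, 4)
    vals <- switch(as.character(type),
      `1` = rd_int(voff, count, 1),
      `2` = rawToChar(raw[(voff + 1):(voff + count)] |>
                        (\(r) r[r != as.raw(0)])()),
      `3` = rd_int(voff, count, 2),
      `4` = rd_int(voff, count, 4),
      `5` = {
        v <- rd_int(voff, 2 * count, 4)
        v <- ifelse(v < 0, v + 2^32, v)
        v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
      },
      stop("unsupported TIFF tag type: ", type))
    vals
  }

  pages <- list()
  ifd_off <- rd_int(4, 1, 4)
  while (ifd_off != 0L) {
    n <- rd_int(ifd_off, 1, 2)
    tags <- list()
    for (i in seq_len(n)) {
      eoff <- ifd_off + 2 + (i - 1) * 12
      tag <- rd_int(eoff, 1, 2)
      tag <- if (tag < 0) tag + 65536 else tag
      tags[[as.character(tag)]] <- read_entry_values(eoff)
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- rd_int(ifd_off + 2 + n * 12, 1, 4)
  }

  get_tag <- function(tags, id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  mats <- lapply(pages, function(tags) {
    w <- get_tag(tags, 256); h <- get_tag(tags, 257)
    if (is.null(w) || is.null(h)) stop("unreadable TIFF: missing dimensions")
    if (get_tag(tags, 259, 1L) != 1L) stop("compressed TIFF not supported")
    bits <- get_tag(tags, 258, 1L)
    fmt <- get_tag(tags, 339, 1L)
    offs <- get_tag(tags, 273); cnts <- get_tag(tags, 279)
    if (is.null(offs) || is.null(cnts)) stop("unreadable TIFF: missing strips")
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nval <- cnts[s] %/% (bits %/% 8L)
      v <- if (bits == 32L && fmt == 3L) rd_dbl(offs[s], nval, 4)
           else if (bits == 32L) rd_int(offs[s], nval, 4)
           else if (bits == 16L) rd_int(offs[s], nval, 2, signed = FALSE)
           else if (bits == 8L) rd_int(offs[s], nval, 1, signed = FALSE)
           else stop("unsupported bit depth: ", bits)
      vals <- c(vals, v)
    }
    m <- matrix(vals, nrow = w, ncol = h)  # x fastest
    list(data = t(m), bits = bits, fmt = fmt)
  })

  tags1 <- pages[[1]]
  desc <- get_tag(tags1, 270, "")
  parse_desc <- function(key) {
    m <- regmatches(desc, regexec(paste0(key, "=([^\n]+)"), desc))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  xres <- get_tag(tags1, 282)
  yres <- get_tag(tags1, 283)
  list(mats = mats,
       n_channels = suppressWarnings(as.integer(parse_desc("channels"))),
       n_slices = suppressWarnings(as.integer(parse_desc("slices"))),
       spacing_z_um = suppressWarnings(as.numeric(parse_desc("spacing"))),
       channel_names = {
         cn <- parse_desc("channel_names")
         if (is.na(cn)) NULL else strsplit(cn, ",")[[1]]
       },
       pixel_x_um = if (!is.null(xres) && xres > 0) 1 / xres else NA_real_,
       pixel_y_um = if (!is.null(yres) && yres > 0) 1 / yres else NA_real_)
}

#' Read one channel of a TIFF / OME-TIFF stack as a voxel grid
#'
#' Voxel spacing is taken from the file metadata (ImageJ `spacing=` plus
#' X/YResolution); if the file carries none and no `spacing` override is
#' given, this is an error. Single-plane files yield a 2D grid (for use with
#' the Fourier-ring-correlation stage).
#'
#' @param path TIFF file path.
#' @param channel channel name or 1-based index; may be omitted for
#'   single-channel files.
#' @param spacing optional `(z, y, x)` spacing override in nm (also accepted
#'   for files without metadata).
#' @return a [voxel_grid()].
#' @export
read_stack <- function(path, channel = NULL, spacing = NULL) {
  tf <- read_tiff_raw(path)
  npage <- length(tf$mats)
  nC <- if (is.na(tf$n_channels)) 1L else tf$n_channels
  nz <- if (is.na(tf$n_slices)) npage %/% nC else tf$n_slices
  if (nC * nz != npage)
    stop("ambiguous axes: page count does not match channels x slices")

  ci <- 1L
  ch_name <- if (!is.null(tf$channel_names)) tf$channel_names[1] else ""
  if (!is.null(channel)) {
    if (is.character(channel)) {
      if (is.null(tf$channel_names) || !channel %in% tf$channel_names)
        stop("channel '", channel, "' not found; available: ",
             paste(tf$channel_names, collapse = ", "))
      ci <- match(channel, tf$channel_names)
    } else ci <- as.integer(channel)
    if (ci < 1 || ci > nC) stop("channel index out of range")
    ch_name <- if (!is.null(tf$channel_names)) tf$channel_names[ci]
               else as.character(ci)
  } else if (nC > 1) {
    stop("multi-channel stack: specify `channel` (available: ",
         paste(tf$channel_names, collapse = ", "), ")")
  }

  sp_xy <- c(tf$pixel_y_um, tf$pixel_x_um) * 1000
  sp_z <- tf$spacing_z_um * 1000
  bits <- tf$mats[[1]]$bits
  fmt <- tf$mats[[1]]$fmt
  bit_max <- if (bits == 32L && fmt == 3L) 1 else 2^bits - 1

  page_idx <- (seq_len(nz) - 1L) * nC + ci
  d1 <- dim(tf$mats[[1]]$data)
  if (nz == 1L) {
    sp <- if (!is.null(spacing)) {
      if (length(spacing) == 3) spacing[2:3] else spacing
    } else sp_xy
    if (any(is.na(sp))) stop("missing spacing metadata and no override given")
    return(voxel_grid(tf$mats[[page_idx]]$data, spacing = sp,
                      channel_name = ch_name, bit_max = bit_max))
  }
  sp <- if (!is.null(spacing)) spacing else c(sp_z, sp_xy)
  if (length(sp) != 3 || any(is.na(sp)))
    stop("missing spacing metadata and no override given")
  arr <- array(0, c(nz, d1[1], d1[2]))
  for (z in seq_len(nz)) arr[z, , ] <- tf$mats[[page_idx[z]]]$data
  voxel_grid(arr, spacing = sp, channel_name = ch_name, bit_max = bit_max)
}

#' Write a label mask as a 16-bit TIFF stack
#' @param mask a [label_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(mask, path) {
  g <- voxel_grid(mask$labels, spacing = mask$spacing,
                  channel_name = "labels", bit_max = 65535)
  write_stack(list(labels = g), path)
}

#' Read a label mask written by [write_labels()]
#' @param path TIFF file path.
#' @param spacing optional spacing override in nm.
#' @return a [label_mask()].
#' @export
read_labels <- function(path, spacing = NULL) {
  g <- read_stack(path, spacing = spacing)
  label_mask(g$data, spacing = g$spacing)
}
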