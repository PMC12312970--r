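#' Voxel grid: an intensity array with physical voxel spacing
#'
#' The raw-image contract for every pipeline stage: a scalar intensity array
#' indexed `(z, y, x)` (or `(y, x)` for single-plane images) together with the
#' physical voxel size per axis in nanometres. The default acquisition
#' geometry is a 120 nm lateral pixel and a 150 nm axial step.
#'
#' @param data numeric array, dim `(z, y, x)` or `(y, x)`; finite,
#'   non-negative intensities.
#' @param spacing numeric vector of per-axis voxel size in nm, same length as
#'   `dim(data)`, ordered `(z, y, x)` (or `(y, x)`).
#' @param channel_name free-text channel label (e.g. `"Hoechst"`).
#' @param bit_max intensity full-scale used to normalize to `[0, 1]` (e.g.
#'   65535 for 16-bit data); `1` for data already on a unit scale.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(150, 120, 120), channel_name = "",
                       bit_max = 1) {
  if (is.null(dim(data))) stop("`data` must be a 2D or 3D array")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("`data` must be a 2D or 3D array")
  if (length(spacing) != nd)
    stop("`spacing` must have one entry per array dimension")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing values must be positive and finite")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  names(spacing) <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
  structure(list(data = data, spacing = as.numeric(spacing) |>
                   stats::setNames(names(spacing)),
                 channel_name = channel_name, bit_max = bit_max),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s  dim: %s  spacing(nm): %s\n",
              if (nzchar(x$channel_name)) x$channel_name else "(unnamed)",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "/")))
  invisible(x)
}

#' Integer instance-label mask paired with a voxel grid
#'
#' Labels are non-negative integers with 0 reserved for background; instance
#' ids are contiguous `1..K`.
#'
#' @param labels integer array of instance labels.
#' @param spacing per-axis voxel size in nm (see [voxel_grid()]).
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing = c(150, 120, 120)) {
  if (is.null(dim(labels))) stop("`labels` must be an array")
  if (any(labels < 0)) stop("labels must be non-negative")
  u <- sort(unique(as.integer(labels[labels > 0])))
  if (length(u) && !identical(u, seq_along(u)))
    stop("label ids must be contiguous 1..K")
  names(spacing) <- if (length(dim(labels)) == 3L) c("z", "y", "x") else c("y", "x")
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 spacing = as.numeric(spacing) |> stats::setNames(names(spacing)),
                 n_labels = length(u)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d instance(s)  dim: %s\n", x$n_labels,
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

check_same_shape <- function(img, mask) {
  di <- dim(if (inherits(img, "voxel_grid")) img$data else img)
  dm <- dim(if (inherits(mask, "label_mask")) mask$labels else mask)
  if (!identical(di, dm))
    stop("image and mask shapes differ: ", paste(di, collapse = "x"),
         " vs ", paste(dm, collapse = "x"))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Central knob set for the segmentation/morphometry pipeline. Defaults follow
#' the acquisition and segmentation settings the pipeline was designed for:
#' a 200-tree voxel classifier and a 10-voxel minimum seed separation for
#' watershed splitting of touching nuclei.
#'
#' @param feature_scales smoothing scales of the feature bank, in x/y voxel
#'   units (anisotropy-corrected internally).
#' @param n_trees number of trees of the random-forest voxel classifier.
#' @param p_threshold probability threshold turning the class-"nucleus"
#'   probability map into a binary mask.
#' @param seed_threshold minimum distance-transform height (voxels) for a
#'   local maximum to seed the watershed.
#' @param min_separation seeds closer than this Euclidean distance (voxels)
#'   are merged, so the nuclei they mark are not separated.
#' @param g1_threshold mean CDT1-marker intensity (normalized) at or above
#'   which a nucleus is gated as G1-positive.
#' @param min_size minimum object size in voxels; smaller components are
#'   dropped as debris (set 0 to keep everything).
#' @param elongation_mode `"intermediate"` (r1/r2, the two main radii) or
#'   `"smallest"` (r1/r3).
#' @param spacing default voxel spacing (nm) used when image metadata is
#'   absent.
#' @param seed random seed for classifier training.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_scales = c(1, 2, 4, 8),
                            n_trees = 200,
                            p_threshold = 0.5,
                            seed_threshold = 2,
                            min_separation = 10,
                            g1_threshold = 0.2,
                            min_size = 500,
                            elongation_mode = c("intermediate", "smallest"),
                            spacing = c(150, 120, 120),
                            seed = 1L) {
  elongation_mode <- match.arg(elongation_mode)
  if (n_trees < 1) stop("`n_trees` must be >= 1")
  if (min_separation < 0) stop("`min_separation` must be >= 0")
  if (!length(feature_scales) || any(feature_scales <= 0))
    stop("`feature_scales` must be positive")
  structure(list(feature_scales = feature_scales, n_trees = as.integer(n_trees),
                 p_threshold = p_threshold, seed_threshold = seed_threshold,
                 min_separation = min_separation, g1_threshold = g1_threshold,
                 min_size = min_size, elongation_mode = elongation_mode,
                 spacing = spacing, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config()] may appear in the file; missing fields
#' keep their defaults, and `...` overrides (e.g. from command-line flags)
#' take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param ... overrides applied after the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(pipeline_config)))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}
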