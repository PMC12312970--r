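# Random-forest voxel classification: background vs nucleus. The ensemble
# (bagged CART trees with Gini splits and per-split feature subsampling) is
# implemented in compiled code because no random-forest package is available
# in the target library set; training uses R's RNG so results are
# reproducible under a seed.

#' Train the random-forest voxel classifier
#'
#' @param features a `feature_stack` from [compute_features()].
#' @param labels sparse voxel annotations: integer array (same spatial shape)
#'   with 0 = unlabeled, 1 = background, 2 = nucleus. A logical array is
#'   accepted as a dense annotation (FALSE = background, TRUE = nucleus).
#' @param n_trees number of trees (default 200).
#' @param seed RNG seed for bootstrap/feature subsampling and annotation
#'   subsampling.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param min_node minimum samples per leaf.
#' @param max_depth maximum tree depth.
#' @param max_samples annotated voxels are subsampled (per class,
#'   proportionally) to at most this many training rows.
#' @return an object of class `voxel_classifier`.
#' @export
train_classifier <- function(features, labels, n_trees = 200, seed = 1L,
                             mtry = NULL, min_node = 5L, max_depth = 25L,
                             max_samples = 5000L) {
  stopifnot(inherits(features, "feature_stack"))
  if (is.logical(labels)) labels <- array(as.integer(labels) + 1L, dim(labels))
  lab <- as.integer(labels)
  ann <- which(lab > 0L)
  cls <- lab[ann]
  if (length(unique(cls)) < 2)
    stop("annotations must contain both classes (background and nucleus)")
  set.seed(seed)
  if (length(ann) > max_samples) {
    keep <- sort(sample.int(length(ann), max_samples))
    ann <- ann[keep]
    cls <- cls[keep]
    if (length(unique(cls)) < 2)
      stop("annotation subsample lost a class; increase `max_samples`")
  }
  X <- feature_matrix(features)[ann, , drop = FALSE]
  y <- as.integer(cls == 2L)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  forest <- .cpp_rf_train(X, y, as.integer(n_trees), as.integer(mtry),
                          as.integer(min_node), as.integer(max_depth))
  structure(list(forest = forest, feature_names = features$names,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 classes = c("background", "nucleus"), seed = seed,
                 version = "nucleomorph-rf-1"),
            class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat(sprintf("<voxel_classifier> %d trees, %d features (%s)\n", x$n_trees,
              length(x$feature_names), x$version))
  invisible(x)
}

#' Per-voxel probability of class "nucleus"
#'
#' @param clf a [train_classifier()] model.
#' @param features a `feature_stack` with the same feature names as used in
#'   training.
#' @return numeric array of probabilities in `[0, 1]`, spatial shape of
#'   `features`.
#' @export
predict_nucleus_prob <- function(clf, features) {
  stopifnot(inherits(clf, "voxel_classifier"),
            inherits(features, "feature_stack"))
  if (!identical(clf$feature_names, features$names))
    stop("feature names do not match the classifier's training features")
  X <- feature_matrix(features)
  prob <- .cpp_rf_predict(clf$forest, X)
  dim(prob) <- features$dim
  prob
}

#' Binary nucleus mask from the classifier
#'
#' Thresholds the class-"nucleus" probability map at `p_threshold` and fills
#' interior cavities in 3D (any background pocket not connected to the image
#' border becomes foreground), yielding the hole-filled binary mask that
#' defines the regions of interest.
#'
#' @inheritParams predict_nucleus_prob
#' @param p_threshold probability threshold (mask = probability >=
#'   `p_threshold`).
#' @return logical array.
#' @export
predict_mask <- function(clf, features, p_threshold = 0.5) {
  prob <- predict_nucleus_prob(clf, features)
  fill_mask_holes(prob >= p_threshold)
}

#' Fill interior cavities of a binary mask in 3D
#'
#' Background pockets with no 6-connected path to the image border become
#' foreground (turns a hollow shell into a solid object).
#'
#' @param mask logical 3D array.
#' @return logical array with holes filled.
#' @export
fill_mask_holes <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("`mask` must be a 3D logical array")
  out <- .cpp_fill_holes(as.logical(mask), as.integer(d))
  dim(out) <- d
  out
}

#' Save / load a fitted voxel classifier
#'
#' Plain base-R serialization with a version tag check on load.
#'
#' @param clf a `voxel_classifier`.
#' @param path file path.
#' @return `path` (save) or the classifier (load).
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "voxel_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "voxel_classifier") ||
      !identical(clf$version, "nucleomorph-rf-1"))
    stop("not a compatible voxel classifier file")
  clf
}
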