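# Shape-based splitting of touching nuclei and the full two-step
# segmentation: (1) voxel classification separating nuclei from background,
# (2) marker-controlled watershed on the distance transform, with seeds from
# local maxima and the rule that nuclei closer than `min_separation` voxels
# (default 10) are not separated.

#' Split touching nuclei by marker-controlled watershed
#'
#' Seeds are the local maxima of the Euclidean distance transform of the
#' mask (computed in isotropic voxel units) with height above
#' `seed_threshold`. Any two seeds closer than `min_separation` voxels
#' (Euclidean, single-linkage over the seed set) are merged into one marker,
#' so the objects they mark are not separated; the merge rule is strict
#' (`< min_separation` merges, `>= min_separation` may split). A watershed
#' flood on the inverted distance transform then partitions the mask, so
#' every mask voxel receives a label and labels are contiguous `1..K`.
#'
#' @param mask logical array (3D), non-empty.
#' @param spacing voxel spacing in nm (kept on the returned mask; seed
#'   distances are measured in voxels regardless).
#' @param seed_threshold minimum distance-transform height (voxels) for a
#'   maximum to seed a basin.
#' @param min_separation merge radius in voxels (default 10).
#' @return a [label_mask()].
#' @export
split_touching <- function(mask, spacing = c(150, 120, 120),
                           seed_threshold = 2, min_separation = 10) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("`mask` must be a 3D logical array")
  if (!any(mask)) stop("empty mask")
  dist <- .cpp_edt(as.logical(mask), as.integer(d), c(1, 1, 1))
  maxima <- .cpp_local_maxima(dist, as.logical(mask), as.integer(d),
                              seed_threshold)
  idx <- which(maxima)
  markers <- integer(length(mask))
  if (length(idx)) {
    co <- arrayInd(idx, d)  # (z, y, x) voxel coordinates
    cluster <- merge_seeds(co, min_separation)
    markers[idx] <- cluster
  }
  lab <- .cpp_watershed(-dist, markers, as.logical(mask), as.integer(d))
  # components whose distance peak never exceeded seed_threshold have no
  # seed; keep them as their own labels rather than dropping foreground
  orphan <- mask & lab == 0L
  if (any(orphan)) {
    extra <- .cpp_label_components(as.logical(orphan), as.integer(d))
    lab[orphan] <- max(lab) + extra[orphan]
  }
  lab <- relabel_contiguous(lab)
  dim(lab) <- d
  label_mask(lab, spacing = spacing)
}

# single-linkage clustering of seed coordinates: seeds at Euclidean distance
# < min_separation end up in one cluster (union-find)
merge_seeds <- function(coords, min_separation) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (min_separation > 0 && n > 1) {
    lim2 <- min_separation^2
    for (i in seq_len(n - 1)) {
      d2 <- (coords[(i + 1):n, 1] - coords[i, 1])^2 +
            (coords[(i + 1):n, 2] - coords[i, 2])^2 +
            (coords[(i + 1):n, 3] - coords[i, 3])^2
      for (j in which(d2 < lim2)) {
        ri <- find(i); rj <- find(i + j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

relabel_contiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(as.integer(lab))
  out <- match(lab, u, nomatch = 0L)
  as.integer(out)
}

#' Drop small objects from a binary mask
#' @param mask logical 3D array.
#' @param min_size minimum connected-component size in voxels.
#' @return logical array with small components removed.
#' @export
filter_small_objects <- function(mask, min_size) {
  if (min_size <= 0) return(mask)
  d <- dim(mask)
  comp <- .cpp_label_components(as.logical(mask), as.integer(d))
  if (!max(comp)) return(mask)
  sizes <- tabulate(comp)
  keep <- comp > 0L & sizes[pmax(comp, 1L)] >= min_size
  dim(keep) <- d
  mask & keep
}

#' Full two-step instance segmentation
#'
#' Composition of [compute_features()], [predict_mask()] (voxel
#' classification + hole filling + debris removal) and [split_touching()]
#' (watershed splitting of touching nuclei). Voxel counts per stage are
#' reported via `message()` when `verbose = TRUE`.
#'
#' @param img a [voxel_grid()].
#' @param clf a fitted [train_classifier()] model.
#' @param config a [pipeline_config()].
#' @param verbose log per-stage voxel counts.
#' @return a [label_mask()].
#' @export
segment <- function(img, clf, config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(img, "voxel_grid"), inherits(config, "pipeline_config"))
  features <- compute_features(img, config$feature_scales)
  mask <- predict_mask(clf, features, config$p_threshold)
  n_mask <- sum(mask)
  mask <- filter_small_objects(mask, config$min_size)
  n_kept <- sum(mask)
  if (verbose)
    message(sprintf("segment: %d mask voxels (%d after size filter >= %d)",
                    n_mask, n_kept, config$min_size))
  if (!n_kept)
    return(label_mask(array(0L, dim(img$data)), spacing = img$spacing))
  lab <- split_touching(mask, spacing = img$spacing,
                        seed_threshold = config$seed_threshold,
                        min_separation = config$min_separation)
  if (verbose)
    message(sprintf("segment: %d nucleus label(s)", lab$n_labels))
  lab
}
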