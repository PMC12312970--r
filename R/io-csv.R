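morpho_columns <- c("label", "volume_um3", "surface_um2", "compactness",
                    "compactness_norm", "r1", "r2", "r3", "elongation",
                    "chromatin_density", "g1_positive")

#' Write per-nucleus morphometry records to CSV
#'
#' One row per nucleus with columns `label`, `volume_um3`, `surface_um2`,
#' `compactness` (raw V^2/S^3), `compactness_norm` (36*pi*V^2/S^3, 1 for a
#' sphere), `r1`..`r3`, `elongation`, `chromatin_density`, `g1_positive`.
#' Values round-trip at 6 significant digits via [read_morphometry_csv()].
#'
#' @param records data frame of morphometry records (see [measure_nuclei()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("`records` must be a non-empty data frame")
  missing_cols <- setdiff(morpho_columns, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  out <- records[morpho_columns]
  num <- setdiff(morpho_columns, c("label", "g1_positive"))
  for (cn in num) out[[cn]] <- signif(out[[cn]], 7)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a morphometry CSV written by [write_morphometry_csv()]
#' @param path CSV path.
#' @return data frame of morphometry records.
#' @export
read_morphometry_csv <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(morpho_columns, names(df))
  if (length(missing_cols))
    stop("not a morphometry CSV; missing: ",
         paste(missing_cols, collapse = ", "))
  df$g1_positive <- as.logical(df$g1_positive)
  df
}
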