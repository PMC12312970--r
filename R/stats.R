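# Group statistics for morphometrics and expression readouts: comparative-Cq
# fold induction normalized to GAPDH, plate-array percent-of-control with
# blank correction, and two-sample Student t-tests with the significance-star
# convention * p <= 0.05, ** p <= 0.01, *** p <= 0.001.

#' Significance stars from a p-value
#'
#' Thresholds use `<=`: `***` for p <= 0.001, `**` for p <= 0.01, `*` for
#' p <= 0.05, empty otherwise.
#'
#' @param p p-value in `[0, 1]`.
#' @return character string of stars.
#' @export
significance_stars <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else ""
}

#' Fold induction by the comparative-Cq method
#'
#' Per sample, replicate Cq values are averaged and `dCq = Cq_target -
#' Cq_ref`; per treated group `ddCq = mean(dCq_group) - mean(dCq_control)`
#' and `fold = 2^-ddCq`. The control group's fold is 1 by construction.
#' Normalization to the reference gene makes the result invariant to adding
#' a constant to every Cq.
#'
#' @param cq data frame with columns `sample`, `group`, `gene`, `cq`
#'   (replicate rows allowed).
#' @param target_gene gene whose induction is computed.
#' @param ref_gene reference gene (e.g. `"GAPDH"`), present in every sample.
#' @param control_group name of the control group.
#' @return data frame with columns `group`, `ddcq`, `fold`.
#' @export
fold_induction <- function(cq, target_gene, ref_gene,
                           control_group = "control") {
  need <- c("sample", "group", "gene", "cq")
  if (!all(need %in% names(cq)))
    stop("`cq` must have columns: ", paste(need, collapse = ", "))
  if (!control_group %in% cq$group)
    stop("control group '", control_group, "' not present")
  for (g in c(target_gene, ref_gene))
    if (!g %in% cq$gene) stop("gene '", g, "' not present")
  # replicate Cq averaged per (sample, gene)
  avg <- stats::aggregate(cq ~ sample + group + gene, data = cq, FUN = mean)
  dcq_of <- function(df) {
    tg <- df$cq[df$gene == target_gene]
    rf <- df$cq[df$gene == ref_gene]
    if (!length(tg) || !length(rf))
      stop("sample '", df$sample[1], "' lacks target or reference Cq")
    tg - rf
  }
  samples <- unique(avg[c("sample", "group")])
  samples$dcq <- vapply(seq_len(nrow(samples)), function(i) {
    dcq_of(avg[avg$sample == samples$sample[i] &
               avg$group == samples$group[i], ])
  }, 0)
  ctrl_mean <- mean(samples$dcq[samples$group == control_group])
  groups <- unique(samples$group)
  out <- data.frame(group = groups,
                    ddcq = vapply(groups, function(g)
                      mean(samples$dcq[samples$group == g]) - ctrl_mean, 0))
  out$fold <- 2^(-out$ddcq)
  rownames(out) <- NULL
  out
}

#' Plate-array normalization: percent of control per gene
#'
#' Luminescence is blank-corrected and divided by the blank-corrected
#' reference-gene (GAPDH) signal of the same group; each gene is then
#' expressed as percent of the control group's normalized value (control =
#' 100%). Invariant to rescaling all luminescence values of a group.
#'
#' @param plate data frame with columns `gene`, `group`, `lum` (relative
#'   light units).
#' @param blank blank-well luminescence used for background correction.
#' @param ref_gene reference gene, present in every group.
#' @param control_group name of the control group.
#' @return data frame with columns `gene`, `group`, `normalized`,
#'   `percent_of_control`, `percent_change`.
#' @export
plate_normalize <- function(plate, blank, ref_gene = "GAPDH",
                            control_group = "control") {
  need <- c("gene", "group", "lum")
  if (!all(need %in% names(plate)))
    stop("`plate` must have columns: ", paste(need, collapse = ", "))
  if (any(plate$lum < 0)) stop("luminescence must be >= 0")
  if (!control_group %in% plate$group)
    stop("control group '", control_group, "' not present")
  groups <- unique(plate$group)
  ref <- vapply(groups, function(g) {
    v <- plate$lum[plate$group == g & plate$gene == ref_gene]
    if (!length(v)) stop("reference gene '", ref_gene,
                         "' missing in group '", g, "'")
    mean(v)
  }, 0)
  if (any(ref <= blank))
    stop("reference-gene signal must exceed the blank in every group")
  out <- plate[plate$gene != ref_gene, need]
  out$normalized <- (out$lum - blank) / ref[out$group]
  ctrl <- out[out$group == control_group, c("gene", "normalized")]
  out$percent_of_control <- 100 * out$normalized /
    ctrl$normalized[match(out$gene, ctrl$gene)]
  out$percent_change <- out$percent_of_control - 100
  out$lum <- NULL
  rownames(out) <- NULL
  out
}

#' Two-sample Student t-test with significance stars
#'
#' Classic pooled-variance two-sided Student t-test (Welch available via
#' `welch = TRUE`), with group summaries and the star mapping of
#' [significance_stars()].
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form instead of the pooled
#'   form.
#' @return object of class `group_comparison`: list with `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `t`, `df`, `p`, `stars`.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs n >= 2")
  tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  structure(list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
                 mean_b = mean(values_b), sd_b = stats::sd(values_b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stars = significance_stars(tt$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("A: %.4g +/- %.4g   B: %.4g +/- %.4g\n", x$mean_a, x$sd_a,
              x$mean_b, x$sd_b))
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g %s\n", x$t, x$df, x$p,
              x$stars))
  invisible(x)
}

#' Group contrasts over a morphometry table
#'
#' Runs [compare_groups()] for each morphometric column between two groups
#' of a combined morphometry table.
#'
#' @param morpho data frame of morphometry records plus a group column.
#' @param group_col name of the group column.
#' @param columns morphometric columns to compare.
#' @param welch see [compare_groups()].
#' @return data frame with one row per column: group means/SDs, t, p, stars.
#' @export
morphometry_contrasts <- function(morpho, group_col = "group",
                                  columns = c("volume_um3", "elongation",
                                              "compactness",
                                              "chromatin_density"),
                                  welch = FALSE) {
  g <- unique(morpho[[group_col]])
  if (length(g) != 2) stop("need exactly 2 groups, found ", length(g))
  rows <- lapply(columns, function(cn) {
    cmp <- compare_groups(morpho[[cn]][morpho[[group_col]] == g[1]],
                          morpho[[cn]][morpho[[group_col]] == g[2]],
                          welch = welch)
    data.frame(parameter = cn, group_a = g[1], mean_a = cmp$mean_a,
               sd_a = cmp$sd_a, group_b = g[2], mean_b = cmp$mean_b,
               sd_b = cmp$sd_b, t = cmp$t, p = cmp$p, stars = cmp$stars)
  })
  do.call(rbind, rows)
}
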