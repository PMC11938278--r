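# Post-processing of raw weighted predictions into final hydration sites:
# certainty filter, Ward agglomerative clustering at a fixed linkage
# threshold, weighted centroids, and a cluster-weight gate.

#' Filter predictions by certainty weight
#'
#' Keeps exactly the predictions with `w >= w_c` (default cutoff 0.035).
#'
#' @param preds prediction tibble with a `w` column.
#' @param w_c certainty cutoff.
#' @return The filtered tibble (possibly empty).
#' @export
filter_low_certainty <- function(preds, w_c = 0.035) {
  dplyr::filter(preds, .data$w >= w_c)
}

#' Ward agglomerative clustering of predictions
#'
#' Clusters prediction coordinates with Ward linkage, merging while the
#' Ward merge distance is strictly below `distance_threshold`. Linkage
#' operates on unweighted coordinates; certainty weights only enter the
#' centroid and aggregate-weight computation downstream. Assignment is
#' deterministic: ties are broken by lexicographic coordinate order.
#'
#' @param preds tibble with `x`, `y`, `z` and optionally `w`.
#' @param distance_threshold Ward linkage distance threshold in A.
#' @return The input tibble with a `cluster` integer column; cluster ids are
#'   ordered by their first (lexicographically smallest) member.
#' @export
cluster_predictions <- function(preds, distance_threshold = 2) {
  n <- nrow(preds)
  if (n == 0) abort("cluster_predictions() needs at least one prediction.")
  ord <- order(preds$x, preds$y, preds$z)
  sorted <- preds[ord, ]
  if (n == 1) {
    assign_sorted <- 1L
  } else {
    hc <- stats::hclust(stats::dist(coord_matrix(sorted)), method = "ward.D2")
    # strict "< threshold" merging: every merge at height >= threshold is undone
    k <- sum(hc$height >= distance_threshold) + 1L
    raw <- stats::cutree(hc, k = k)
    # relabel clusters by first occurrence so ids are order-independent
    assign_sorted <- match(raw, unique(raw))
  }
  preds$cluster <- NA_integer_
  preds$cluster[ord] <- assign_sorted
  preds
}

#' Aggregate clusters into final hydration sites
#'
#' Per cluster, the site center is the certainty-weighted mean of member
#' coordinates and the cluster weight aggregates the member certainty
#' weights (sum by default; `"mean"` available as an alternative reading).
#' Clusters whose aggregate weight does not exceed `min_cluster_weight` are
#' dropped.
#'
#' @param clustered tibble from [cluster_predictions()] (columns `x`, `y`,
#'   `z`, `w`, `cluster`).
#' @param min_cluster_weight gate on the aggregate cluster weight
#'   (strictly-greater comparison).
#' @param weight_mode `"sum"` or `"mean"` aggregation of member weights.
#' @return Tibble of sites: `x`, `y`, `z`, `weight`, `n_members`.
#' @export
finalize_sites <- function(clustered, min_cluster_weight = 0.1,
                           weight_mode = c("sum", "mean")) {
  weight_mode <- match.arg(weight_mode)
  if (!"w" %in% names(clustered)) clustered$w <- 1
  sites <- clustered |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      x = sum(.data$w * .data$x) / sum(.data$w),
      y = sum(.data$w * .data$y) / sum(.data$w),
      z = sum(.data$w * .data$z) / sum(.data$w),
      weight = if (weight_mode == "sum") sum(.data$w) else mean(.data$w),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$weight > min_cluster_weight) |>
    dplyr::arrange(.data$x, .data$y, .data$z) |>
    dplyr::select(-"cluster")
  sites
}

#' Write sites as a PDB of water oxygens
#'
#' Emits each site as a HETATM oxygen of residue HOH for visualization.
#'
#' @param sites site tibble (`x`, `y`, `z`).
#' @param path output path; `NULL` returns the lines invisibly.
#' @return PDB lines, invisibly.
#' @export
write_sites_pdb <- function(sites, path = NULL) {
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
            i, i, sites$x[i], sites$y[i], sites$z[i], 1, 0)
  }, character(1))
  out <- c(lines, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
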