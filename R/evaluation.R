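# Recovery metrics for hydration-site prediction: ground-truth recovery
# rate (GTRR), prediction hit rate (PHR), hydration-layer classification,
# occupancy-stratified tables, and regression metrics.

min_cross_dist <- function(a, b) {
  apply(cross_distances(a, b), 1, min)
}

#' Ground Truth Recovery Rate
#'
#' Fraction of reference sites having at least one prediction within
#' distance `r` (many-to-one matching allowed). With
#' `matching = "hungarian"` a one-to-one greedy assignment variant is used
#' for sensitivity checks.
#'
#' @param refs reference site tibble (`x`, `y`, `z`).
#' @param preds predicted site tibble.
#' @param r distance cutoff in A (`> 0`).
#' @param matching `"any"` (default) or `"one_to_one"`.
#' @return Fraction in \[0, 1\].
#' @export
gtrr <- function(refs, preds, r, matching = c("any", "one_to_one")) {
  matching <- match.arg(matching)
  if (nrow(refs) == 0) abort("GTRR undefined for empty reference set.")
  if (r <= 0) abort("Cutoff r must be positive.")
  if (nrow(preds) == 0) return(0)
  if (matching == "any") {
    return(mean(min_cross_dist(coord_matrix(refs), coord_matrix(preds)) <= r))
  }
  sum(one_to_one_matches(coord_matrix(refs), coord_matrix(preds), r)) /
    nrow(refs)
}

#' Prediction Hit Rate
#'
#' Fraction of predictions lying within distance `r` of at least one
#' reference site.
#'
#' @inheritParams gtrr
#' @return Fraction in \[0, 1\].
#' @export
phr <- function(refs, preds, r, matching = c("any", "one_to_one")) {
  matching <- match.arg(matching)
  if (nrow(preds) == 0) abort("PHR undefined for empty prediction set.")
  if (r <= 0) abort("Cutoff r must be positive.")
  if (nrow(refs) == 0) return(0)
  if (matching == "any") {
    return(mean(min_cross_dist(coord_matrix(preds), coord_matrix(refs)) <= r))
  }
  sum(one_to_one_matches(coord_matrix(preds), coord_matrix(refs), r)) /
    nrow(preds)
}

# Greedy one-to-one matching by increasing pair distance; returns a logical
# per row of `a` indicating whether it received a partner within r.
one_to_one_matches <- function(a, b, r) {
  d <- cross_distances(a, b)
  matched_a <- rep(FALSE, nrow(a))
  used_b <- rep(FALSE, nrow(b))
  cand <- which(d <= r, arr.ind = TRUE)
  if (!nrow(cand)) return(matched_a)
  cand <- cand[order(d[cand]), , drop = FALSE]
  for (row in seq_len(nrow(cand))) {
    i <- cand[row, 1]; j <- cand[row, 2]
    if (!matched_a[i] && !used_b[j]) {
      matched_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  matched_a
}

#' Classify a site into first or second hydration layer
#'
#' A site belongs to the first layer if it is no further than `boundary`
#' (inclusive, default 3.5 A) from any protein heavy atom.
#'
#' @param sites site tibble.
#' @param structure atom tibble.
#' @param boundary layer boundary in A.
#' @return Character vector `"first"`/`"second"` per site.
#' @export
classify_layer <- function(sites, structure, boundary = 3.5) {
  if (nrow(structure) == 0) abort("classify_layer() needs a non-empty structure.")
  dmin <- min_cross_dist(coord_matrix(sites), coord_matrix(structure))
  ifelse(dmin <= boundary, "first", "second")
}

#' Occupancy-stratified GTRR table
#'
#' GTRR computed independently per occupancy bin and distance cutoff. The
#' default bins are \[0.5,0.6), ..., \[0.8,0.9), \[0.9,1.0\]. Empty bins are
#' reported as `NA`, not zero.
#'
#' @param refs reference sites with an `occupancy` column.
#' @param preds predicted sites.
#' @param bins numeric vector of bin edges.
#' @param cutoffs distance cutoffs in A.
#' @return A tibble with columns `cutoff`, `bin`, `n_refs`, `gtrr`.
#' @export
binned_gtrr <- function(refs, preds, bins = seq(0.5, 1, by = 0.1),
                        cutoffs = c(0.5, 1, 1.5, 2)) {
  stopifnot("occupancy" %in% names(refs))
  labels <- paste0("[", head(bins, -1), ",", tail(bins, -1), ")")
  labels[length(labels)] <- sub("\\)$", "]", labels[length(labels)])
  bin_of <- cut(refs$occupancy, breaks = bins, right = FALSE,
                include.lowest = TRUE, labels = labels)
  tidyr::expand_grid(cutoff = cutoffs, bin = labels) |>
    dplyr::mutate(
      n_refs = purrr::map_int(.data$bin, ~ sum(bin_of == .x, na.rm = TRUE)),
      gtrr = purrr::map2_dbl(.data$cutoff, .data$bin, function(r, b) {
        sub <- refs[which(bin_of == b), , drop = FALSE]
        if (nrow(sub) == 0) return(NA_real_)
        gtrr(sub, preds, r)
      })
    )
}

#' Regression metrics
#'
#' Coefficient of determination `R2 = 1 - SSres/SStot`, mean squared error,
#' and root mean squared error between predictions and targets.
#'
#' @param pred numeric vector of predictions.
#' @param target numeric vector of targets (same length, variance `> 0`).
#' @return A tibble with `r2`, `mse`, `rmse`.
#' @export
regression_metrics <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 2) {
    abort("regression_metrics() needs two equal-length vectors (n >= 2).")
  }
  sstot <- sum((target - mean(target))^2)
  if (sstot == 0) abort("Target is constant: R2 undefined.")
  ssres <- sum((target - pred)^2)
  tibble::tibble(
    r2 = 1 - ssres / sstot,
    mse = mean((target - pred)^2),
    rmse = sqrt(mean((target - pred)^2))
  )
}

#' Full site-prediction evaluation report
#'
#' GTRR and PHR across cutoffs, plus per-layer and occupancy-binned GTRR
#' when a structure / occupancies are available.
#'
#' @param refs reference sites.
#' @param preds predicted sites.
#' @param structure optional atom tibble for layer classification.
#' @param cutoffs distance cutoffs in A.
#' @return An object of class `hydrasite_eval` (a list of tibbles:
#'   `rates`, optional `layers`, optional `binned`).
#' @export
evaluate_sites <- function(refs, preds, structure = NULL,
                           cutoffs = c(0.5, 1, 1.5, 2)) {
  rates <- tibble::tibble(
    cutoff = cutoffs,
    gtrr = purrr::map_dbl(cutoffs, ~ gtrr(refs, preds, .x)),
    phr = purrr::map_dbl(cutoffs, ~ phr(refs, preds, .x))
  )
  out <- list(rates = rates)
  if (!is.null(structure)) {
    site_layer <- classify_layer(refs, structure)
    out$layers <- tidyr::expand_grid(cutoff = cutoffs,
                                     layer = c("first", "second")) |>
      dplyr::mutate(
        n_refs = purrr::map_int(.data$layer, ~ sum(site_layer == .x)),
        gtrr = purrr::map2_dbl(.data$cutoff, .data$layer, function(r, l) {
          sub <- refs[site_layer == l, , drop = FALSE]
          if (nrow(sub) == 0) return(NA_real_)
          gtrr(sub, preds, r)
        })
      )
  }
  if ("occupancy" %in% names(refs)) {
    out$binned <- binned_gtrr(refs, preds, cutoffs = cutoffs)
  }
  class(out) <- "hydrasite_eval"
  out
}

#' @export
print.hydrasite_eval <- function(x, ...) {
  cat("<hydrasite_eval>\n")
  print(x$rates)
  invisible(x)
}
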