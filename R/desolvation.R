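# Ligand desolvation scoring by hydration-site displacement: a bound ligand
# displaces the hydration sites whose centers fall within a distance
# tolerance of any ligand heavy atom; releasing those waters back to bulk
# contributes -dG per displaced site, so displacing unfavorable (dG > 0)
# water yields a favorable (negative) desolvation free energy.

#' Hydration sites displaced by a ligand pose
#'
#' @param sites site tibble (`x`, `y`, `z`, typically with `dG`).
#' @param ligand ligand heavy-atom tibble (`x`, `y`, `z`).
#' @param tolerance displacement tolerance in A (default 2.4): a site is
#'   displaced when its center is within the tolerance (inclusive) of any
#'   ligand heavy atom.
#' @return The displaced subset of `sites`.
#' @export
displaced_sites <- function(sites, ligand, tolerance = 2.4) {
  if (tolerance <= 0) abort("tolerance must be positive.")
  if (nrow(sites) == 0 || nrow(ligand) == 0) return(sites[0, , drop = FALSE])
  dmin <- min_cross_dist(coord_matrix(sites), coord_matrix(ligand))
  sites[dmin <= tolerance, , drop = FALSE]
}

#' Desolvation free energy of displaced sites
#'
#' Signed sum over displaced sites: `-sum(dG)`. Displacing water that is
#' unfavorable in the site (dG > 0 for bulk-to-site transfer) gives a
#' negative, favorable desolvation term; an empty displaced set scores 0.
#' Additive over disjoint subsets.
#'
#' @param displaced displaced site tibble carrying a `dG` column.
#' @return Desolvation free energy (same units as `dG`).
#' @export
desolvation_energy <- function(displaced) {
  if (nrow(displaced) == 0) return(0)
  stopifnot("dG" %in% names(displaced))
  -sum(displaced$dG)
}

#' Slope-one calibration
#'
#' Fits the experimental values on the predictions with a linear regression
#' of slope one, i.e. shifts the predictions by
#' `b = mean(exp) - mean(pred)` so the residuals sum to exactly zero.
#'
#' @param pred numeric predictions.
#' @param exp numeric experimental values (same length).
#' @return The calibrated prediction vector.
#' @export
slope_one_calibrate <- function(pred, exp) {
  if (length(pred) != length(exp) || length(pred) < 2) {
    abort("slope_one_calibrate() needs two equal-length vectors (n >= 2).")
  }
  pred + (mean(exp) - mean(pred))
}

#' Benchmark several prediction sets against experiment
#'
#' Applies slope-one calibration per method, then [regression_metrics()]
#' (R2 as 1 - SSres/SStot on the calibrated predictions).
#'
#' @param pred_sets named list of numeric prediction vectors.
#' @param exp experimental values.
#' @return A tibble with `method`, `r2`, `mse`, `rmse`.
#' @export
benchmark_table <- function(pred_sets, exp) {
  purrr::imap(pred_sets, function(p, nm) {
    cal <- slope_one_calibrate(p, exp)
    dplyr::bind_cols(tibble::tibble(method = nm), regression_metrics(cal, exp))
  }) |>
    dplyr::bind_rows()
}

#' Packaged MUP desolvation benchmark
#'
#' Loads the bundled benchmark of hydration-site-displacement desolvation
#' free energies for 12 ligands co-crystallized with major urinary protein
#' (MUP): slope-one-transformed model predictions, an explicit-trajectory
#' reference method, experimental binding free energies, and MM-GB/SA
#' estimates, all in kJ/mol.
#'
#' @param path optional CSV path; defaults to the packaged fixture.
#' @return A tibble with one row per ligand.
#' @export
load_mup_benchmark <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mup_desolvation.csv", package = "hydrasite")
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run the MUP desolvation benchmark
#'
#' Benchmarks each method column of the MUP table against the experimental
#' binding free energies.
#'
#' @param table benchmark tibble as from [load_mup_benchmark()].
#' @return A tibble with `method`, `r2`, `mse`, `rmse` (energies kJ/mol).
#' @export
run_mup_benchmark <- function(table = load_mup_benchmark()) {
  methods <- setdiff(names(table), c("pdb_id", "ligand", "experimental"))
  benchmark_table(as.list(table[methods]), table$experimental)
}
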