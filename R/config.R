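# Physical constants and the frozen featurization vocabularies.

#' Thermodynamic and model constants
#'
#' Constants used throughout the package. Temperatures are in Kelvin,
#' energies in kcal/mol (the internal unit system; kJ/mol only at reporting
#' boundaries), lengths in Angstrom.
#'
#' @format A list with elements:
#' \describe{
#'   \item{temperature}{simulation/analysis temperature, 300 K}
#'   \item{gas_constant}{R in kcal/(mol K)}
#'   \item{bulk_concentration}{pure-water concentration C0, 1 molecule / 29.9 A^3}
#'   \item{sigma}{Gaussian mixture standard deviation, 0.5 A}
#'   \item{kcal_to_kj}{unit conversion factor, 4.184}
#' }
#' @export
thermo_constants <- list(
  temperature        = 300,
  gas_constant       = 1.987204258640832e-3,
  bulk_concentration = 1 / 29.9,
  sigma              = 0.5,
  kcal_to_kj         = 4.184
)

# Fixed atom-type vocabulary: 37 protein heavy-atom PDB names + "other" = 38.
# Frozen so that feature layouts (and hence checkpoints) are reproducible.
.atom_type_vocab <- c(
  "N", "CA", "C", "O", "OXT",
  "CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE", "CE1", "CE2", "CE3",
  "CZ", "CZ2", "CZ3", "CH2",
  "ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2", "NZ",
  "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
  "SD", "SG",
  "other"
)

# 20 standard amino acids + "other" = 21.
.residue_type_vocab <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "other"
)

# Bondi van der Waals radii (A) for elements expected in heavy-atom PDB input.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

#' Default run configuration
#'
#' All tunable thresholds of the pipeline with their defaults: SASA gate for
#' water-node seeding (0.1, fractional), graph cutoffs (6 A location / 8 A
#' thermo), mixture standard deviation sigma = 0.5 A, certainty cutoff
#' w_c = 0.035, Ward linkage threshold 2 A, cluster-weight gate 0.1,
#' occupancy gates 0.3 (thermo graph nodes) and 0.5 (loss terms), first-layer
#' boundary 3.5 A, ligand displacement tolerance 2.4 A, T = 300 K, and the
#' loss mixing weight alpha.
#'
#' @param ... named overrides of any default entry. Unknown keys raise an
#'   error so configuration typos fail loudly.
#' @return A named list of configuration values with class
#'   `hydrasite_config`.
#' @examples
#' cfg <- hydrasite_config(alpha = 0.2)
#' cfg$cluster_linkage_threshold
#' @export
hydrasite_config <- function(...) {
  cfg <- list(
    sasa_threshold            = 0.1,    # fractional SASA gate for seeding
    sasa_probe_radius         = 1.4,
    sasa_n_sphere_points      = 960,
    location_cutoff           = 6,
    thermo_cutoff             = 8,
    n_rbf_edge                = 32,
    sigma                     = 0.5,
    alpha                     = 0.1,
    certainty_cutoff          = 0.035,  # w_c
    cluster_linkage_threshold = 2,
    min_cluster_weight        = 0.1,
    cluster_weight_mode       = "sum",  # Eq-9 aggregation; "mean" kept as alternative
    thermo_occupancy_min      = 0.3,    # node gate in the thermo graph
    loss_occupancy_min        = 0.5,    # reference gate in both losses
    layer_boundary            = 3.5,
    displacement_tolerance    = 2.4,
    temperature               = 300,
    grid_spacing              = 0.25,
    site_radius               = 1,
    units                     = "kcal/mol",
    seed                      = 1
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = c("hydrasite_config", "list"))
}

# Stable polynomial string hash of a configuration, used to stamp
# outputs/checkpoints so results are traceable to their settings.
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
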