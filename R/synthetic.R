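# Synthetic fixtures: toy protein-like structures, planted hydration sites
# with occupancy and thermodynamic labels, and pseudo-trajectories. The
# structures are geometric (a coarse helix with sidechain dummy atoms), not
# physically folded -- every contract exercised on them is geometric or
# statistical. All randomness flows through one seeded generator so fixtures
# are bit-reproducible.

POLAR_RESIDUES <- c(SER = "OG", THR = "OG1", ASN = "OD1", ASP = "OD1", LYS = "NZ")
APOLAR_RESIDUES <- c(ALA = "CB", VAL = "CG1", LEU = "CD1", PHE = "CZ", ILE = "CD1")

#' Specification for synthetic fixtures
#'
#' Collects the generator's knobs: structure size, site-planting geometry
#' (anchor offsets 2.8--3.0 A from exposed polar atoms, pairwise site
#' separation > 2 A), the occupancy distribution, per-site positional
#' spread, label rules, and the frame count.
#'
#' @param n_residues residues in the toy structure.
#' @param seed RNG seed; seeded runs are bit-reproducible.
#' @param n_frames pseudo-trajectory frames (the reference analysis
#'   emulates 1000-frame simulations).
#' @param occupancy_range uniform sampling range of planted occupancies.
#' @param anchor_distance_range planted site distance from its polar anchor.
#' @param min_site_separation minimum pairwise distance between planted
#'   sites.
#' @param bulk_energy bulk-water interaction energy reference (kcal/mol).
#' @param orientation_kappa orientational order: 0 = uniform orientations;
#'   larger values concentrate orientations (used with positional spread).
#' @return A list of class `hydrasite_spec`.
#' @export
synthetic_spec <- function(n_residues = 8, seed = 1, n_frames = 1000,
                           occupancy_range = c(0.35, 0.95),
                           anchor_distance_range = c(2.8, 3.0),
                           min_site_separation = 2,
                           bulk_energy = -9.5,
                           orientation_kappa = 0) {
  structure(
    list(n_residues = n_residues, seed = seed, n_frames = n_frames,
         occupancy_range = occupancy_range,
         anchor_distance_range = anchor_distance_range,
         min_site_separation = min_site_separation,
         bulk_energy = bulk_energy,
         orientation_kappa = orientation_kappa),
    class = "hydrasite_spec"
  )
}

#' Generate a toy protein-like structure
#'
#' Places residues along a coarse helix (rise 1.5 A, 100 degrees per
#' residue) with backbone N/CA/C/O and one outward sidechain dummy atom per
#' non-GLY residue (a polar tip for polar residues). A small seeded jitter
#' is applied and the structure is rebuilt until no two heavy atoms are
#' closer than 2 A.
#'
#' @param spec a [synthetic_spec()].
#' @param path optional path to also write the structure as a PDB fixture.
#' @return An atom tibble (as from [read_pdb()]).
#' @export
make_structure <- function(spec, path = NULL) {
  set.seed(spec$seed)
  res_pool <- c(names(POLAR_RESIDUES), names(APOLAR_RESIDUES))
  resnames <- sample(res_pool, spec$n_residues, replace = TRUE)
  for (attempt in 1:25) {
    atoms <- build_helix_atoms(resnames, jitter_sd = 0.08)
    dmat <- cross_distances(coord_matrix(atoms), coord_matrix(atoms))
    diag(dmat) <- Inf
    if (min(dmat) >= 2) {
      if (!is.null(path)) {
        write_pdb(atoms, path, header = sprintf("synthetic fixture seed=%d", spec$seed))
      }
      return(atoms)
    }
  }
  abort("Could not generate a clash-free synthetic structure (25 attempts).")
}

build_helix_atoms <- function(resnames, jitter_sd = 0.08) {
  # coarse-grained helix: all heavy-atom pairs stay >= 2.3 A before jitter
  rows <- purrr::imap(resnames, function(rn, i) {
    theta <- (i - 1) * 100 * pi / 180
    zc <- (i - 1) * 3.0
    radial <- c(cos(theta), sin(theta), 0)
    tangent <- c(-sin(theta), cos(theta), 0)
    ca <- 4.0 * radial + c(0, 0, zc)
    n <- ca - 1.2 * radial - 1.6 * tangent + c(0, 0, -1.5)
    cc <- ca - 1.0 * radial + 1.6 * tangent + c(0, 0, 1.5)
    o <- ca + 0.4 * radial + 3.0 * tangent + c(0, 0, 3.2)
    coords <- rbind(n, ca, cc, o)
    names_ <- c("N", "CA", "C", "O")
    elements <- c("N", "C", "C", "O")
    if (rn != "GLY") {
      cb <- ca + 2.4 * radial + c(0, 0, 0.9)
      tip_name <- c(POLAR_RESIDUES, APOLAR_RESIDUES)[[rn]]
      tip <- ca + 4.8 * radial + c(0, 0, 1.6)
      coords <- rbind(coords, cb, tip)
      names_ <- c(names_, "CB", tip_name)
      elements <- c(elements, "C", substr(tip_name, 1, 1))
    }
    tibble::tibble(
      element = elements, atom_name = names_, residue_name = rn,
      residue_index = i, chain_id = "A",
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    )
  })
  atoms <- dplyr::bind_rows(rows)
  jitter <- matrix(rnorm(3 * nrow(atoms), sd = jitter_sd), ncol = 3)
  set_coords(atoms, coord_matrix(atoms) + jitter)
}

#' Plant reference hydration sites on a structure
#'
#' Sites are placed at hydrogen-bond-like geometry: 2.8--3.0 A from exposed
#' polar sidechain atoms, in the direction least crowded by other heavy
#' atoms (hydrophobic/steric exclusion), with pairwise separation > 2 A.
#' Occupancy is sampled from the spec's distribution; the positional spread
#' sigma and the thermodynamic labels follow smooth deterministic rules of
#' the local environment, with higher-sigma (more mobile) sites receiving
#' higher entropy labels.
#'
#' @param structure atom tibble (SASA computed when absent).
#' @param spec a [synthetic_spec()].
#' @return Site tibble: `x`, `y`, `z`, `anchor` (atom row), `occupancy`,
#'   `sigma`, `dH`, `dS`, `mTdS`, `dG` (energies kcal/mol, dS kcal/(mol K)).
#' @export
plant_sites <- function(structure, spec) {
  if (!"sasa" %in% names(structure)) structure <- compute_sasa(structure)
  set.seed(spec$seed + 1)
  coords <- coord_matrix(structure)
  polar <- which(structure$element %in% c("N", "O") &
                   !(structure$atom_name %in% c("N", "CA", "C")) &
                   structure$sasa > 0.2)
  if (!length(polar)) {
    inform("No exposed polar atoms; zero sites planted.")
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
  }
  placed <- matrix(numeric(0), 0, 3)
  anchors <- integer(0)
  for (a in polar) {
    r <- runif(1, spec$anchor_distance_range[1], spec$anchor_distance_range[2])
    dirs <- matrix(rnorm(3 * 64), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cand <- sweep(dirs * r, 2, coords[a, ], "+")
    # crowding score: distance to the nearest non-anchor heavy atom
    dmin <- apply(cross_distances(cand, coords[-a, , drop = FALSE]), 1, min)
    ord <- order(-dmin)
    for (ci in ord) {
      pos <- cand[ci, ]
      if (dmin[ci] < 2.5) break
      if (nrow(placed) &&
          min(sqrt(colSums((t(placed) - pos)^2))) <= spec$min_site_separation) {
        next
      }
      placed <- rbind(placed, pos)
      anchors <- c(anchors, a)
      break
    }
  }
  if (!nrow(placed)) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
  }
  n <- nrow(placed)
  occ <- runif(n, spec$occupancy_range[1], spec$occupancy_range[2])
  # local-environment descriptors (7 A shell) drive sigma and the labels
  d_all <- cross_distances(placed, coords)
  is_polar_atom <- structure$element %in% c("N", "O")
  n_heavy <- rowSums(d_all < 7)
  n_polar <- rowSums(d_all[, is_polar_atom, drop = FALSE] < 7)
  n_apolar <- n_heavy - n_polar
  sigma <- pmin(0.35, pmax(0.1, 0.1 + 0.04 * pmax(0, 8 - n_heavy)))
  dH <- 0.4 - 0.35 * n_polar - 0.06 * n_apolar
  mTdS <- 1.8 - 4 * sigma              # mobile (high sigma) -> higher entropy
  dS <- -mTdS / thermo_constants$temperature
  tibble::tibble(
    x = placed[, 1], y = placed[, 2], z = placed[, 3],
    anchor = anchors, occupancy = occ, sigma = sigma,
    dH = dH, dS = dS, mTdS = mTdS, dG = dH + mTdS
  )
}

#' Toy water--protein interaction energy
#'
#' A Lennard-Jones plus Coulomb-like evaluator used only to give synthetic
#' trajectories self-consistent per-observation energies (the reference
#' analysis treats energies as inputs).
#'
#' @param positions n x 3 water oxygen coordinates.
#' @param structure atom tibble.
#' @param bulk_energy baseline bulk energy added to every observation.
#' @return Numeric vector of interaction energies (kcal/mol).
#' @export
toy_water_energy <- function(positions, structure, bulk_energy = -9.5) {
  coords <- coord_matrix(structure)
  d <- cross_distances(positions, coords)
  d <- pmax(d, 2.2)                     # clamp core to keep energies sane
  lj <- 4 * 0.15 * ((3.2 / d)^12 - (3.2 / d)^6)
  qa <- ifelse(structure$element %in% c("N", "O"), 0.35, 0.05)
  coul <- -sweep(1 / d, 2, qa, "*") * 332 * 0.4 / 80
  inter <- rowSums((lj + coul) * (d < 8))
  bulk_energy + inter
}

#' Sample a pseudo-trajectory from planted sites
#'
#' Per frame each site emits a water with probability equal to its
#' occupancy, at a Gaussian displacement (the site's sigma) from its
#' center; orientations are uniform unit quaternions (or concentrated when
#' the spec's `orientation_kappa > 0`), and toy interaction energies are
#' attached when a structure is supplied.
#'
#' @param sites planted site tibble from [plant_sites()].
#' @param spec a [synthetic_spec()].
#' @param structure optional atom tibble for toy energies.
#' @param path optional frames CSV fixture path.
#' @return Trajectory tibble: `frame`, `water_id`, `x`, `y`, `z`, `qw`,
#'   `qx`, `qy`, `qz` and `energy` when a structure is given.
#' @export
make_trajectory <- function(sites, spec, structure = NULL, path = NULL) {
  if (nrow(sites) == 0) abort("make_trajectory() needs at least one site.")
  set.seed(spec$seed + 2)
  nf <- spec$n_frames
  ns <- nrow(sites)
  present <- matrix(rbinom(nf * ns, 1, rep(sites$occupancy, each = nf)) == 1,
                    nrow = nf)
  total <- sum(present)
  disp <- matrix(rnorm(3 * total), ncol = 3)
  qs <- random_quaternions(total)
  if (spec$orientation_kappa > 0) {
    # shrink rotations toward the identity: mix the sampled quaternion with
    # (1,0,0,0) and renormalize
    lam <- spec$orientation_kappa / (1 + spec$orientation_kappa)
    qs[, 1] <- lam + (1 - lam) * abs(qs[, 1])
    qs[, 2:4] <- (1 - lam) * qs[, 2:4]
    qs <- qs / sqrt(rowSums(qs^2))
  }
  idx <- which(present, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  s <- idx[, 2]
  pos <- cbind(sites$x[s], sites$y[s], sites$z[s]) + disp * sites$sigma[s]
  traj <- tibble::tibble(
    frame = idx[, 1], water_id = s,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4]
  )
  if (!is.null(structure)) {
    traj$energy <- toy_water_energy(pos, structure, spec$bulk_energy)
  }
  if (!is.null(path)) write_frames_csv(traj, path)
  traj
}

#' Write a complete fixture set
#'
#' Generates a structure, planted sites and a pseudo-trajectory and writes
#' them as `structure.pdb`, `sites.csv` and `frames.csv` under `dir`.
#'
#' @param dir output directory (created if missing).
#' @param spec a [synthetic_spec()].
#' @return Invisibly, a list with the generated `structure`, `sites`,
#'   `trajectory` and file paths.
#' @export
make_fixtures <- function(dir, spec = synthetic_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  structure <- make_structure(spec, path = file.path(dir, "structure.pdb"))
  structure <- compute_sasa(structure)
  sites <- plant_sites(structure, spec)
  traj <- NULL
  if (nrow(sites)) {
    traj <- make_trajectory(sites, spec, structure,
                            path = file.path(dir, "frames.csv"))
    readr::write_csv(sites, file.path(dir, "sites.csv"))
  }
  invisible(list(structure = structure, sites = sites, trajectory = traj,
                 paths = file.path(dir, c("structure.pdb", "sites.csv",
                                          "frames.csv"))))
}
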