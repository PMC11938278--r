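# Explicit-trajectory hydration-site analysis: water density grids,
# site extraction, occupancy, and inhomogeneous-solvation-theory
# thermodynamics (dH from interaction energies, dS from the discretized
# external-mode probability density of translations and rotations,
# dG = dH - T dS).

#' Accumulate a water density grid
#'
#' Bins every (frame, water) oxygen observation onto a regular grid.
#' Observations outside the bounds are ignored; the total count equals the
#' number of in-bounds observations exactly.
#'
#' @param traj trajectory tibble with columns `frame`, `x`, `y`, `z`
#'   (optionally `energy`, `qw`, `qx`, `qy`, `qz`).
#' @param spacing grid resolution in A (default 0.25).
#' @param bounds optional list with `lo` and `hi` (3-vectors); defaults to
#'   the data range padded by one voxel.
#' @return A list of class `hydrasite_grid`: `origin`, `spacing`, `dims`,
#'   `counts` (3d array), `n_frames`.
#' @export
accumulate_density <- function(traj, spacing = 0.25, bounds = NULL) {
  if (nrow(traj) == 0 || length(unique(traj$frame)) == 0) {
    abort("Trajectory has zero frames.")
  }
  coords <- coord_matrix(traj)
  if (is.null(bounds)) {
    lo <- apply(coords, 2, min) - spacing
    hi <- apply(coords, 2, max) + spacing
  } else {
    lo <- bounds$lo; hi <- bounds$hi
  }
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  idx <- floor(sweep(coords, 2, lo) / spacing) + 1L
  inb <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= dims[3]
  counts <- array(0L, dims)
  if (any(inb)) {
    flat <- idx[inb, 1] + dims[1] * (idx[inb, 2] - 1L) +
      dims[1] * dims[2] * (idx[inb, 3] - 1L)
    tab <- table(flat)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  structure(
    list(origin = lo, spacing = spacing, dims = dims, counts = counts,
         n_frames = length(unique(traj$frame))),
    class = "hydrasite_grid"
  )
}

# Voxel centers for flat indices into the counts array.
voxel_centers <- function(grid, flat) {
  d <- grid$dims
  i <- (flat - 1L) %% d[1] + 1L
  j <- ((flat - 1L) %/% d[1]) %% d[2] + 1L
  k <- (flat - 1L) %/% (d[1] * d[2]) + 1L
  cbind(grid$origin[1] + (i - 0.5) * grid$spacing,
        grid$origin[2] + (j - 0.5) * grid$spacing,
        grid$origin[3] + (k - 0.5) * grid$spacing)
}

#' Extract hydration sites from a density grid
#'
#' Greedy density-peak clustering: repeatedly take the highest-count voxel,
#' absorb all density within `site_radius` of it into a site whose center is
#' the density-weighted centroid of the absorbed voxels, and continue until
#' no voxel reaches `min_peak` counts. A candidate peak closer than
#' `2 * site_radius` to an existing site is merged into it instead of
#' founding a new one. Sites whose total density is below
#' `min_site_fraction` of the frame count are dropped. Ties are broken by
#' voxel storage order, so extraction is deterministic.
#'
#' @param grid a `hydrasite_grid`.
#' @param site_radius site radius in A (default 1).
#' @param min_peak minimum voxel count to found a site.
#' @param min_site_fraction minimum total site density as a fraction of the
#'   frame count.
#' @return Tibble of site centers `x`, `y`, `z` with `density` (absorbed
#'   counts), ordered by decreasing density.
#' @export
extract_sites <- function(grid, site_radius = 1, min_peak = 3,
                          min_site_fraction = 0.1) {
  counts <- as.numeric(grid$counts)
  occupied <- which(counts > 0)
  if (!length(occupied)) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          density = numeric()))
  }
  centers_all <- voxel_centers(grid, occupied)
  vals <- counts[occupied]
  sites <- list()
  repeat {
    peak <- which.max(vals)
    if (vals[peak] < min_peak) break
    pc <- centers_all[peak, ]
    merged <- FALSE
    if (length(sites)) {
      sc <- do.call(rbind, purrr::map(sites, "center"))
      ds <- sqrt(colSums((t(sc) - pc)^2))
      near <- which(ds < 2 * site_radius)
      if (length(near)) {
        target <- near[which.min(ds[near])]
        absorb <- which(sqrt(colSums((t(centers_all) - pc)^2)) <= site_radius &
                          vals > 0)
        s <- sites[[target]]
        wsum <- s$density + sum(vals[absorb])
        s$center <- (s$center * s$density +
                       colSums(centers_all[absorb, , drop = FALSE] *
                                 vals[absorb])) / wsum
        s$density <- wsum
        sites[[target]] <- s
        vals[absorb] <- 0
        merged <- TRUE
      }
    }
    if (!merged) {
      absorb <- which(sqrt(colSums((t(centers_all) - pc)^2)) <= site_radius &
                        vals > 0)
      dsum <- sum(vals[absorb])
      center <- colSums(centers_all[absorb, , drop = FALSE] * vals[absorb]) / dsum
      sites[[length(sites) + 1]] <- list(center = center, density = dsum)
      vals[absorb] <- 0
    }
    if (!any(vals > 0)) break
  }
  if (!length(sites)) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          density = numeric()))
  }
  out <- tibble::tibble(
    x = purrr::map_dbl(sites, ~ .x$center[1]),
    y = purrr::map_dbl(sites, ~ .x$center[2]),
    z = purrr::map_dbl(sites, ~ .x$center[3]),
    density = purrr::map_dbl(sites, "density")
  )
  out <- dplyr::filter(out, .data$density >= min_site_fraction * grid$n_frames)
  dplyr::arrange(out, dplyr::desc(.data$density))
}

#' Site occupancy from a trajectory
#'
#' Fraction of frames in which at least one water oxygen lies within
#' `radius` of the site center.
#'
#' @param site_center 3-vector (A).
#' @param traj trajectory tibble.
#' @param radius site radius in A.
#' @return Occupancy in \[0, 1\].
#' @export
occupancy <- function(site_center, traj, radius = 1) {
  d2 <- (traj$x - site_center[1])^2 + (traj$y - site_center[2])^2 +
    (traj$z - site_center[3])^2
  frames_in <- unique(traj$frame[d2 <= radius^2])
  length(frames_in) / length(unique(traj$frame))
}

# Observations (rows of traj) belonging to a site.
site_observations <- function(site_center, traj, radius = 1) {
  d2 <- (traj$x - site_center[1])^2 + (traj$y - site_center[2])^2 +
    (traj$z - site_center[3])^2
  traj[d2 <= radius^2, , drop = FALSE]
}

#' Hydration-site enthalpy change
#'
#' Mean water interaction energy (van der Waals + electrostatic, with
#' protein and other waters) of the site observations, minus the bulk-water
#' reference energy: `dH = mean(E_site) - E_bulk`.
#'
#' @param energies per-observation interaction energies (kcal/mol).
#' @param bulk_energy bulk-water reference interaction energy (kcal/mol).
#' @return dH in kcal/mol.
#' @export
site_enthalpy <- function(energies, bulk_energy) {
  if (!length(energies)) abort("site_enthalpy() received zero observations.")
  mean(energies) - bulk_energy
}

#' Hydration-site entropy change
#'
#' Estimates the entropy change by discretized integration of the
#' external-mode probability density of the water's translational and
#' rotational motions:
#' `dS = -R * sum p ln(p / C0)` over translational voxels plus
#' `-R * sum f ln(f / u)` over orientation bins (with `u` the uniform
#' orientation measure of each bin), minus a configurable bulk reference.
#' For observations uniform over a volume V with uniform orientations this
#' reduces to `R * ln(V * C0)`.
#'
#' Two refinements control the discretization bias: when the site support
#' (center + radius) is supplied, voxel volumes are clipped to the site
#' sphere (observations belong to a known 1 A-radius ball, and unclipped
#' boundary voxels would dilute the density); and the Miller--Madow
#' correction compensates the plug-in undersampling bias of sparsely
#' occupied bins. With both, halving the bin width changes the uniform-case
#' estimate by well under 2 percent.
#'
#' @param obs site observation tibble with `x`, `y`, `z` and, when
#'   rotational entropy is wanted, unit quaternions `qw`, `qx`, `qy`, `qz`.
#' @param center optional site center (3-vector) defining the spherical
#'   support for voxel clipping.
#' @param radius site radius in A (support clipping; used with `center`).
#' @param trans_bin translational bin width in A.
#' @param rot_bin_deg orientational bin width in degrees (z-y-z Euler).
#' @param c0 bulk water concentration (molecules per A^3).
#' @param bulk_entropy bulk reference entropy, kcal/(mol K).
#' @param min_obs minimum number of observations required.
#' @return dS in kcal/(mol K), with attributes `S_trans` and `S_rot`.
#' @export
site_entropy <- function(obs, center = NULL, radius = 1,
                         trans_bin = 0.25, rot_bin_deg = 30,
                         c0 = thermo_constants$bulk_concentration,
                         bulk_entropy = 0, min_obs = 50) {
  n <- nrow(obs)
  if (n < min_obs) {
    abort(sprintf("site_entropy() needs >= %d observations, got %d.",
                  min_obs, n))
  }
  Rgas <- thermo_constants$gas_constant
  coords <- coord_matrix(obs)
  lo <- apply(coords, 2, min)
  idx <- floor(sweep(coords, 2, lo) / trans_bin)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  cnt <- table(key)
  f <- as.numeric(cnt) / n
  k_occ <- length(f)
  veff <- rep(trans_bin^3, k_occ)
  if (!is.null(center)) {
    # clip voxel volumes to the site sphere with a deterministic subgrid
    km <- t(vapply(strsplit(names(cnt), " "), as.numeric, numeric(3)))
    corners <- sweep(km * trans_bin, 2, lo, "+")
    nsub <- 8
    sub <- (seq_len(nsub) - 0.5) / nsub * trans_bin
    grid <- as.matrix(expand.grid(sub, sub, sub))
    veff <- vapply(seq_len(k_occ), function(v) {
      pts <- sweep(grid, 2, corners[v, ], "+")
      inside <- mean((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
                       (pts[, 3] - center[3])^2 <= radius^2)
      max(inside, 1 / (2 * nsub^3)) * trans_bin^3
    }, numeric(1))
  }
  # -R * sum_v p_v ln(p_v / C0) dV with p_v = f_v / V_v, plus Miller-Madow
  s_trans <- -Rgas * sum(f * log((f / veff) / c0)) +
    Rgas * (k_occ - 1) / (2 * n)

  s_rot <- 0
  if (all(c("qw", "qx", "qy", "qz") %in% names(obs))) {
    eul <- quaternion_to_euler_zyz(cbind(obs$qw, obs$qx, obs$qy, obs$qz))
    nphi <- max(1L, round(360 / rot_bin_deg))
    ntheta <- max(1L, round(180 / rot_bin_deg))
    bphi <- pmin(floor(eul[, 1] / (2 * pi) * nphi), nphi - 1)
    btheta <- pmin(floor(eul[, 2] / pi * ntheta), ntheta - 1)
    bpsi <- pmin(floor(eul[, 3] / (2 * pi) * nphi), nphi - 1)
    key_r <- paste(bphi, btheta, bpsi)
    cnt_r <- table(key_r)
    fr <- as.numeric(cnt_r) / n
    # uniform measure of each occupied bin: dphi dpsi (cos(th_lo)-cos(th_hi)) / 8 pi^2
    th_idx <- as.numeric(vapply(strsplit(names(cnt_r), " "), `[`, "", 2))
    th_lo <- th_idx * pi / ntheta
    th_hi <- (th_idx + 1) * pi / ntheta
    u <- (2 * pi / nphi)^2 * (cos(th_lo) - cos(th_hi)) / (8 * pi^2)
    s_rot <- -Rgas * sum(fr * log(fr / u)) + Rgas * (length(fr) - 1) / (2 * n)
  }
  out <- s_trans + s_rot - bulk_entropy
  attr(out, "S_trans") <- s_trans
  attr(out, "S_rot") <- s_rot
  out
}

#' Gibbs free energy of hydration-site transfer
#'
#' `dG = dH - T * dS`, exactly.
#'
#' @param dH enthalpy change (kcal/mol).
#' @param dS entropy change (kcal/(mol K)).
#' @param temperature T in Kelvin.
#' @return dG in kcal/mol.
#' @export
free_energy <- function(dH, dS, temperature = 300) {
  dH - temperature * dS
}

#' Full trajectory hydration-site analysis
#'
#' Density grid, site extraction, and per-site occupancy and thermodynamics
#' (dH when energies are present, dS when orientations are present).
#'
#' @param traj trajectory tibble.
#' @param config a [hydrasite_config()].
#' @param bulk_energy bulk-water interaction energy reference (kcal/mol).
#' @param bulk_entropy bulk entropy reference (kcal/(mol K)).
#' @param min_site_fraction density gate for [extract_sites()].
#' @return Site tibble `x`, `y`, `z`, `occupancy`, and where computable
#'   `dH`, `mTdS`, `dG` (kcal/mol).
#' @export
analyze_trajectory <- function(traj, config = hydrasite_config(),
                               bulk_energy = -9.5, bulk_entropy = 0,
                               min_site_fraction = 0.1) {
  grid <- accumulate_density(traj, spacing = config$grid_spacing)
  sites <- extract_sites(grid, site_radius = config$site_radius,
                         min_site_fraction = min_site_fraction)
  if (nrow(sites) == 0) return(sites)
  temperature <- config$temperature
  res <- purrr::map(seq_len(nrow(sites)), function(i) {
    ctr <- c(sites$x[i], sites$y[i], sites$z[i])
    obs <- site_observations(ctr, traj, radius = config$site_radius)
    occ <- occupancy(ctr, traj, radius = config$site_radius)
    dH <- if ("energy" %in% names(obs) && nrow(obs) > 0) {
      site_enthalpy(obs$energy, bulk_energy)
    } else {
      NA_real_
    }
    dS <- tryCatch(
      as.numeric(site_entropy(obs, center = ctr, radius = config$site_radius,
                              bulk_entropy = bulk_entropy)),
      error = function(e) NA_real_
    )
    tibble::tibble(x = ctr[1], y = ctr[2], z = ctr[3], occupancy = occ,
                   dH = dH, mTdS = -temperature * dS,
                   dG = dH - temperature * dS)
  })
  dplyr::bind_rows(res)
}

#' Read / write trajectory frames CSV
#'
#' Frames CSV columns: `frame`, `water_id`, `x`, `y`, `z` and optionally
#' `energy`, `qw`, `qx`, `qy`, `qz`.
#'
#' @param path CSV path.
#' @return A trajectory tibble.
#' @export
read_frames_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_frames_csv
#' @param traj trajectory tibble to write.
#' @export
write_frames_csv <- function(traj, path) {
  readr::write_csv(traj, path)
}

#' Write a density grid in OpenDX format
#'
#' @param grid a `hydrasite_grid`.
#' @param path output `.dx` path.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  # OpenDX expects z fastest
  vals <- as.numeric(aperm(grid$counts, c(3, 2, 1)))
  writeLines(
    vapply(split(vals, ceiling(seq_along(vals) / 3)),
           function(v) paste(sprintf("%.1f", v), collapse = " "),
           character(1)),
    con
  )
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
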