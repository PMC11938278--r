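# Protein structure input, solvent accessibility, and node featurization.
#
# Structures are plain tibbles (one row per heavy atom) so they compose with
# dplyr verbs; the parser enforces the heavy-atom convention used by the
# location model (hydrogens dropped, HETATM waters/ions excluded).

#' Parse a PDB structure into an atom tibble
#'
#' Reads ATOM records from PDB-format text. Hydrogens are removed unless
#' `keep_hydrogens = TRUE`; HETATM records (waters, ions, ligands) are
#' excluded. When a residue carries alternate locations, only the
#' highest-occupancy altloc is kept. Multi-chain structures are returned as
#' one atom set in file order.
#'
#' @param input path to a PDB file, or a character scalar/vector of PDB text.
#' @param keep_hydrogens keep hydrogen atoms? Default `FALSE` (the models use
#'   heavy atoms only).
#' @return A tibble with columns `element`, `atom_name`, `residue_name`,
#'   `residue_index`, `chain_id`, `x`, `y`, `z` (Angstrom).
#' @examples
#' pdb <- c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C"
#' )
#' read_pdb(paste(pdb, collapse = "\n"))
#' @export
read_pdb <- function(input, keep_hydrogens = FALSE) {
  lines <- pdb_lines(input)
  atom_lines <- grepl("^ATOM  ", lines)
  if (!any(atom_lines)) {
    abort("No ATOM records found: input is empty or not PDB-format text.")
  }
  idx <- which(atom_lines)
  parse_field <- function(line, from, to) trimws(substr(line, from, to))
  num_field <- function(line, from, to, lineno, what) {
    raw <- parse_field(line, from, to)
    val <- suppressWarnings(as.numeric(raw))
    if (is.na(val)) {
      abort(sprintf("Malformed %s field '%s' on line %d.", what, raw, lineno))
    }
    val
  }
  rows <- purrr::map(idx, function(i) {
    ln <- lines[[i]]
    name <- parse_field(ln, 13, 16)
    element <- toupper(parse_field(ln, 77, 78))
    if (!nzchar(element)) element <- guess_element(name)
    tibble::tibble(
      element = element,
      atom_name = name,
      altloc = substr(ln, 17, 17),
      residue_name = parse_field(ln, 18, 20),
      chain_id = substr(ln, 22, 22),
      residue_index = as.integer(num_field(ln, 23, 26, i, "residue number")),
      x = num_field(ln, 31, 38, i, "x coordinate"),
      y = num_field(ln, 39, 46, i, "y coordinate"),
      z = num_field(ln, 47, 54, i, "z coordinate"),
      occupancy = {
        occ <- suppressWarnings(as.numeric(parse_field(ln, 55, 60)))
        if (is.na(occ)) 1 else occ
      }
    )
  })
  atoms <- dplyr::bind_rows(rows)
  if (!all(is.finite(coord_matrix(atoms)))) {
    abort("Non-finite coordinates in PDB input.")
  }
  # Highest-occupancy altloc per (chain, residue, atom name); ties keep the
  # first in file order so parsing stays deterministic.
  atoms$.file_order <- seq_len(nrow(atoms))
  atoms <- atoms |>
    dplyr::group_by(.data$chain_id, .data$residue_index, .data$atom_name) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order)
  if (!keep_hydrogens) {
    atoms <- dplyr::filter(atoms, !(.data$element %in% c("H", "D")))
  }
  if (nrow(atoms) == 0) {
    abort("No atoms left after hydrogen filtering.")
  }
  dplyr::select(atoms, "element", "atom_name", "residue_name",
                "residue_index", "chain_id", "x", "y", "z")
}

# Accept a file path or in-memory PDB text (scalar with newlines or a
# character vector of lines).
pdb_lines <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}

# PDB element inference from the atom-name column for files without an
# element field: two-letter elements are not expected in protein ATOM input.
guess_element <- function(atom_name) {
  first <- substr(gsub("[0-9']", "", atom_name), 1, 1)
  toupper(first)
}

#' Parse ligand heavy-atom coordinates
#'
#' Reads both ATOM and HETATM records (excluding waters) and drops
#' hydrogens, giving the heavy-atom pose used for desolvation scoring.
#'
#' @inheritParams read_pdb
#' @return A tibble with `element`, `atom_name`, `x`, `y`, `z`.
#' @export
read_ligand <- function(input) {
  lines <- pdb_lines(input)
  keep <- grepl("^(ATOM  |HETATM)", lines) & substr(lines, 18, 20) != "HOH"
  if (!any(keep)) abort("No ATOM/HETATM records found in ligand input.")
  lines[keep] <- sub("^HETATM", "ATOM  ", lines[keep])
  atoms <- read_pdb(paste(lines[keep], collapse = "\n"))
  dplyr::select(atoms, "element", "atom_name", "x", "y", "z")
}

#' Write an atom tibble as PDB text
#'
#' @param structure atom tibble as returned by [read_pdb()].
#' @param path output file path; when `NULL` the PDB text is returned
#'   invisibly as a character vector.
#' @param header optional REMARK lines to prepend.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(structure, path = NULL, header = NULL) {
  n <- nrow(structure)
  lines <- vapply(seq_len(n), function(i) {
    a <- structure[i, ]
    name <- a$atom_name
    # PDB alignment: 1-3 character names start in column 14
    name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
    sprintf("ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_fmt, "", a$residue_name, a$chain_id, a$residue_index,
            a$x, a$y, a$z, 1, 0, a$element)
  }, character(1))
  out <- c(if (!is.null(header)) paste("REMARK    ", header), lines, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

# Deterministic Fibonacci sphere: n approximately uniform unit vectors.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Per-atom fractional solvent accessibility (Shrake--Rupley)
#'
#' Computes fractional SASA per atom with the Shrake--Rupley algorithm:
#' a fixed deterministic sphere of test points is placed on each atom's
#' solvent-accessible sphere (Bondi radius + probe) and the accessible
#' fraction is the share of points not buried inside any neighbor's
#' accessible sphere. The fraction is exposed area over the atom's full
#' accessible sphere area, in [0, 1].
#'
#' @param structure atom tibble.
#' @param probe_radius solvent probe radius in A (water: 1.4).
#' @param n_sphere_points number of test points per atom.
#' @param sphere_rotation optional 3 x 3 rotation applied to the test-point
#'   set; rotating it together with a rigidly moved structure reproduces
#'   SASA values exactly.
#' @return The structure tibble with a `sasa` column appended.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960,
                         sphere_rotation = NULL) {
  elements <- toupper(structure$element)
  unknown <- setdiff(unique(elements), names(.vdw_radii))
  if (length(unknown)) {
    abort(paste0("No van der Waals radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  radii <- .vdw_radii[elements] + probe_radius
  coords <- coord_matrix(structure)
  n <- nrow(coords)
  pts <- fibonacci_sphere(n_sphere_points)
  if (!is.null(sphere_rotation)) pts <- pts %*% t(sphere_rotation)
  sasa <- numeric(n)
  # neighbor prefilter: only atoms whose accessible spheres can intersect
  d <- cross_distances(coords, coords)
  for (i in seq_len(n)) {
    nbr <- which(d[i, ] < radii[i] + radii & seq_len(n) != i)
    if (!length(nbr)) {
      sasa[i] <- 1
      next
    }
    surf <- sweep(pts * radii[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nbr) {
      dj2 <- (surf[, 1] - coords[j, 1])^2 + (surf[, 2] - coords[j, 2])^2 +
        (surf[, 3] - coords[j, 3])^2
      free <- free & dj2 > radii[j]^2
      if (!any(free)) break
    }
    sasa[i] <- sum(free) / n_sphere_points
  }
  structure$sasa <- sasa
  structure
}

#' Write per-atom SASA as CSV
#'
#' @param structure atom tibble carrying a `sasa` column.
#' @param path output CSV path.
#' @export
write_sasa_csv <- function(structure, path) {
  stopifnot("sasa" %in% names(structure))
  readr::write_csv(
    dplyr::select(structure, chain = "chain_id", resi = "residue_index",
                  atom = "atom_name", "sasa"),
    path
  )
}

#' 92-dimensional node feature vectors
#'
#' Builds the feature matrix used by both graph models: a 38-slot one-hot of
#' the PDB atom-type vocabulary, a 21-slot one-hot of the residue type
#' (20 standard amino acids + other), a 32-center Gaussian RBF expansion of
#' the fractional SASA on [0, 1], and a node-type flag (0 = protein atom,
#' 1 = water/site node). Unknown atom or residue names map to the reserved
#' "other" slots so every one-hot block still sums to one.
#'
#' @param nodes tibble of nodes; protein atoms need `atom_name`,
#'   `residue_name` and `sasa`, water/site nodes only coordinates.
#' @param node_type `"atom"` or `"water"`.
#' @return A numeric matrix with `nrow(nodes)` rows and 92 columns.
#' @export
featurize <- function(nodes, node_type = c("atom", "water")) {
  node_type <- match.arg(node_type)
  n <- nrow(nodes)
  if (node_type == "atom" && !"sasa" %in% names(nodes)) {
    abort("Protein atoms must carry a `sasa` column; run compute_sasa() first.")
  }
  atom_slot <- function(name) {
    i <- match(name, .atom_type_vocab)
    ifelse(is.na(i), length(.atom_type_vocab), i)
  }
  res_slot <- function(name) {
    i <- match(name, .residue_type_vocab)
    ifelse(is.na(i), length(.residue_type_vocab), i)
  }
  atom_oh <- matrix(0, n, length(.atom_type_vocab))
  res_oh <- matrix(0, n, length(.residue_type_vocab))
  if (node_type == "atom") {
    atom_oh[cbind(seq_len(n), atom_slot(nodes$atom_name))] <- 1
    res_oh[cbind(seq_len(n), res_slot(nodes$residue_name))] <- 1
    sasa <- nodes$sasa
    flag <- rep(0, n)
  } else {
    atom_oh[, length(.atom_type_vocab)] <- 1
    res_oh[, length(.residue_type_vocab)] <- 1
    sasa <- rep(0, n)
    flag <- rep(1, n)
  }
  sasa_rbf <- rbf_expand(pmin(sasa, 1), n_centers = 32, lo = 0, hi = 1)
  unname(cbind(atom_oh, res_oh, sasa_rbf, flag))
}
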