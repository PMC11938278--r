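# Distance-cutoff spatial graphs with RBF edge features.

#' Gaussian radial basis expansion
#'
#' Expands scalar values into `n_centers` Gaussian activations with centers
#' evenly spaced on `[lo, hi]` and width equal to the center spacing. A value
#' sitting exactly on center k activates component k at its maximum of 1.
#'
#' @param value numeric vector of values to expand.
#' @param n_centers number of Gaussian centers.
#' @param lo,hi range over which centers are placed (`lo < hi`).
#' @return A matrix with `length(value)` rows and `n_centers` columns,
#'   entries in (0, 1].
#' @examples
#' rbf_expand(c(0, 3), n_centers = 8, lo = 0, hi = 6)
#' @export
rbf_expand <- function(value, n_centers = 32, lo = 0, hi = NULL) {
  if (is.null(hi)) abort("rbf_expand() needs an explicit upper range `hi`.")
  if (!(lo < hi)) abort("rbf_expand() requires lo < hi.")
  if (any(!is.finite(value))) abort("rbf_expand() received non-finite values.")
  centers <- seq(lo, hi, length.out = n_centers)
  width <- centers[2] - centers[1]
  exp(-(outer(value, centers, "-"))^2 / (2 * width^2))
}

# Derivative of rbf_expand with respect to the value, same shape.
rbf_expand_deriv <- function(value, n_centers = 32, lo = 0, hi = 6) {
  centers <- seq(lo, hi, length.out = n_centers)
  width <- centers[2] - centers[1]
  diffs <- outer(value, centers, "-")
  -diffs / width^2 * exp(-diffs^2 / (2 * width^2))
}

#' Build a distance-cutoff spatial graph
#'
#' Connects every pair of nodes strictly closer than `cutoff` (Euclidean),
#' using a cell-list spatial index. Self-edges are never created; each edge
#' is stored once with `i < j`. Optionally a node-kind pair class can be
#' excluded, e.g. `exclude_pairs = "atom-atom"` for the thermodynamic graph
#' that ignores intra-protein edges.
#'
#' @param coords n x 3 coordinate matrix (or tibble with x/y/z columns).
#' @param cutoff distance cutoff in A (edges require distance `< cutoff`).
#' @param node_kind optional character vector (`"atom"`/`"water"`) per node.
#' @param exclude_pairs optional pair class to drop: one of `"atom-atom"`,
#'   `"water-water"`, `"atom-water"`.
#' @param n_rbf number of RBF centers for the edge-length featurization
#'   (range `[0, cutoff]`).
#' @return A list of class `hydrasite_graph` with elements `coords`,
#'   `node_kind`, `edges` (tibble `i`, `j`, `dist`), `edge_features`
#'   (matrix, one row per edge) and `cutoff`.
#' @export
build_graph <- function(coords, cutoff, node_kind = NULL, exclude_pairs = NULL,
                        n_rbf = 32) {
  if (is.data.frame(coords)) coords <- coord_matrix(coords)
  if (cutoff <= 0) abort("cutoff must be positive.")
  n <- nrow(coords)
  if (n < 1) abort("Need at least one node.")
  if (is.null(node_kind)) node_kind <- rep("atom", n)
  pairs <- cell_list_pairs(coords, cutoff)
  if (!is.null(exclude_pairs) && nrow(pairs)) {
    cls <- paste(pmin(node_kind[pairs$i], node_kind[pairs$j]),
                 pmax(node_kind[pairs$i], node_kind[pairs$j]), sep = "-")
    pairs <- pairs[cls != exclude_pairs, , drop = FALSE]
  }
  ef <- if (nrow(pairs)) {
    rbf_expand(pairs$dist, n_centers = n_rbf, lo = 0, hi = cutoff)
  } else {
    matrix(numeric(0), 0, n_rbf)
  }
  structure(
    list(coords = coords, node_kind = node_kind, edges = pairs,
         edge_features = ef, cutoff = cutoff),
    class = "hydrasite_graph"
  )
}

# Cell-list neighbor search: all unordered pairs with distance < cutoff.
# Returns a tibble (i, j, dist) with i < j, sorted for determinism.
cell_list_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  lo <- apply(coords, 2, min)
  cell <- floor(sweep(coords, 2, lo) / cutoff)
  dims <- apply(cell, 2, max) + 1L
  key <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  by_cell <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  for (ck in names(by_cell)) {
    members <- by_cell[[ck]]
    base <- cell[members[1], ]
    cand <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      nb <- base + offsets[r, ]
      if (any(nb < 0) || any(nb >= dims)) next
      nk <- as.character(nb[1] + dims[1] * (nb[2] + dims[2] * nb[3]))
      cand <- c(cand, by_cell[[nk]])
    }
    if (!length(cand)) next
    d <- cross_distances(coords[members, , drop = FALSE],
                         coords[cand, , drop = FALSE])
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    ii <- members[hit[, 1]]
    jj <- cand[hit[, 2]]
    keep <- ii < jj
    res_i <- c(res_i, ii[keep])
    res_j <- c(res_j, jj[keep])
    res_d <- c(res_d, d[hit][keep])
  }
  ord <- order(res_i, res_j)
  tibble::tibble(i = res_i[ord], j = res_j[ord], dist = res_d[ord])
}

# Reference O(N^2) enumeration, kept as the check path for the spatial index.
brute_force_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  d <- cross_distances(coords, coords)
  hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  tibble::tibble(i = hit[ord, 1], j = hit[ord, 2], dist = d[hit][ord])
}

# Directed adjacency: for message passing each undirected edge is expanded
# to both directions. Returns tibble (target, source, dist).
directed_edges <- function(edges) {
  tibble::tibble(
    target = c(edges$i, edges$j),
    source = c(edges$j, edges$i),
    dist = c(edges$dist, edges$dist)
  )
}

#' Dump graph edges as CSV (debug aid)
#'
#' @param graph a `hydrasite_graph`.
#' @param path output CSV path.
#' @export
write_edges_csv <- function(graph, path) {
  readr::write_csv(graph$edges, path)
}
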