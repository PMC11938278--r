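# Shared fixture builders. Everything is generated in code (seeded) so the
# suite needs no stored data. Built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small structure with SASA and planted sites.
toy_fixture <- function(seed = 3, n_residues = 8, n_frames = 1000) {
  cached(sprintf("fx_%d_%d_%d", seed, n_residues, n_frames), function() {
    spec <- synthetic_spec(n_residues = n_residues, seed = seed,
                           n_frames = n_frames)
    st <- compute_sasa(make_structure(spec))
    sites <- plant_sites(st, spec)
    list(spec = spec, structure = st, sites = sites)
  })
}

# The five-structure training set used by the overfit-recovery checks.
training_fixtures <- function() {
  cached("train5", function() {
    lapply(1:5, function(s) {
      fx <- toy_fixture(seed = s)
      list(structure = fx$structure, refs = fx$sites)
    })
  })
}

# Ten labelled fixtures for the thermodynamic model (7 train / 3 held out).
thermo_fixtures <- function() {
  cached("thermo10", function() {
    lapply(1:10, function(s) {
      fx <- toy_fixture(seed = s)
      list(structure = fx$structure, sites = fx$sites)
    })
  })
}

# Observations uniform over the unit ball with uniform orientations.
uniform_ball_obs <- function(n = 20000, seed = 1) {
  cached(sprintf("ball_%d_%d", n, seed), function() {
    set.seed(seed)
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(n)^(1 / 3)
    q <- hydrasite:::random_quaternions(n)
    tibble::tibble(x = u[, 1] * r, y = u[, 2] * r, z = u[, 3] * r,
                   qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  })
}

# Pooled GTRR of the final predicted sites over a fixture list.
pooled_training_gtrr <- function(model, fixtures, r = 1) {
  tot <- 0
  hits <- 0
  for (fx in fixtures) {
    refs <- dplyr::filter(fx$refs, .data$occupancy >= 0.5)
    sites <- predict_sites(fx$structure, model)
    if (nrow(sites) == 0) {
      tot <- tot + nrow(refs)
      next
    }
    d <- hydrasite:::cross_distances(hydrasite:::coord_matrix(refs),
                                     hydrasite:::coord_matrix(sites))
    tot <- tot + nrow(refs)
    hits <- hits + sum(apply(d, 1, min) <= r)
  }
  hits / tot
}

# Independent brute-force Ward agglomeration: at every step the merge cost
# of each active cluster pair is recomputed from scratch as
# sqrt(2 * (ESS(A u B) - ESS(A) - ESS(B))) on the raw member coordinates
# (the Ward distance; equals the Euclidean distance for singletons). Merging
# continues while the smallest cost is strictly below the threshold. Used as
# the reference against the hclust-based production path.
naive_ward_labels <- function(coords, threshold) {
  ess <- function(idx) {
    m <- coords[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  active <- as.list(seq_len(nrow(coords)))
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(Inf, 0, 0)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        cost <- sqrt(2 * (ess(c(active[[i]], active[[j]])) -
                            ess(active[[i]]) - ess(active[[j]])))
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    if (best[1] >= threshold) break
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- c(active[-c(best[2], best[3])], list(merged))
  }
  labels <- integer(nrow(coords))
  for (c_idx in seq_along(active)) labels[active[[c_idx]]] <- c_idx
  labels
}

# Are two cluster labelings the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
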