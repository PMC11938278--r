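# The hydration-site location model.
#
# Water nodes are seeded at solvent-exposed heavy atoms and refined by five
# equivariant attention layers on the 6 A distance graph, the topology being
# rebuilt before each layer. Each layer moves a water node by an
# attention-weighted sum of relative-position vectors scaled by invariant
# (distance-based) messages, so the update is E(3)-equivariant by
# construction and protein positions never change. A sigmoid head maps the
# final local protein environment of each water to a certainty weight in
# [0, 1]. Reverse-mode gradients for the whole stack are derived by hand
# (there is no autodiff here) and are validated against finite differences
# in the test suite.

POLAR_ELEMENTS <- c("N", "O", "S")

#' Create an untrained location model
#'
#' @param n_layers number of equivariant attention layers.
#' @param n_rbf number of Gaussian radial basis functions parameterizing the
#'   attention logits and message magnitudes.
#' @param cutoff graph distance cutoff in A.
#' @param sasa_threshold fractional SASA above which an atom seeds a water
#'   node.
#' @param sigma,alpha mixture-loss hyperparameters (see [mixture_loss()]).
#' @param seed RNG seed for parameter initialization.
#' @param init_sd standard deviation of the random initial parameters.
#' @return An object of class `hydrasite_site_model`.
#' @export
new_site_model <- function(n_layers = 5, n_rbf = 16, cutoff = 6,
                           sasa_threshold = 0.1, sigma = 0.5, alpha = 0.1,
                           seed = 1, init_sd = 0.01) {
  set.seed(seed)
  # per-layer radial profiles, one column per neighbor class
  # (backbone polar / sidechain polar / apolar protein atom / water node)
  layers <- purrr::map(seq_len(n_layers), function(l) {
    list(
      a = matrix(rnorm(n_rbf * 4, sd = init_sd), n_rbf, 4), # attention logits
      b = matrix(rnorm(n_rbf * 4, sd = init_sd), n_rbf, 4)  # message magnitudes
    )
  })
  head <- list(c0 = 0, cvec = rnorm(n_rbf, sd = init_sd))
  structure(
    list(
      params = list(layers = layers, head = head),
      config = list(n_layers = n_layers, n_rbf = n_rbf, cutoff = cutoff,
                    sasa_threshold = sasa_threshold, sigma = sigma,
                    alpha = alpha),
      history = tibble::tibble(epoch = integer(), loss = numeric()),
      trained = FALSE
    ),
    class = "hydrasite_site_model"
  )
}

#' Seed initial water nodes on exposed atoms
#'
#' One water node per heavy atom whose fractional SASA strictly exceeds the
#' threshold, placed at that atom's coordinate. An empty result (fully
#' buried structure) is valid.
#'
#' @param structure atom tibble with a `sasa` column.
#' @param sasa_threshold exposure gate (default 0.1, fractional).
#' @return Tibble with `x`, `y`, `z` and `seed_atom` (row index into the
#'   structure).
#' @export
initialize_waters <- function(structure, sasa_threshold = 0.1) {
  if (!"sasa" %in% names(structure)) {
    abort("Structure has no `sasa` column; run compute_sasa() first.")
  }
  keep <- which(structure$sasa > sasa_threshold)
  if (!length(keep)) {
    inform("No atoms exceed the SASA threshold; zero water nodes seeded.")
  }
  tibble::tibble(
    x = structure$x[keep], y = structure$y[keep], z = structure$z[keep],
    seed_atom = keep
  )
}

# Neighbor classes seen by a water node: 1 = backbone polar atom (N/O/OXT),
# 2 = sidechain polar atom (N/O/S), 3 = apolar atom, 4 = water node.
protein_classes <- function(structure) {
  polar <- toupper(structure$element) %in% POLAR_ELEMENTS
  backbone <- structure$atom_name %in% c("N", "O", "OXT")
  ifelse(polar & backbone, 1L, ifelse(polar, 2L, 3L))
}

# Edge list from each water to every node (protein or water) strictly
# within the cutoff, excluding the water itself. Coincident nodes (distance
# 0, e.g. a water still sitting on its seed atom) are legal neighbors.
water_edges <- function(waters, prot, cutoff) {
  nw <- nrow(waters); np <- nrow(prot)
  all_coords <- rbind(prot, waters)
  d <- cross_distances(waters, all_coords)
  d[cbind(seq_len(nw), np + seq_len(nw))] <- Inf # no self edges
  hit <- which(d < cutoff, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  hit <- hit[ord, , drop = FALSE]
  list(j = hit[, 1], k = hit[, 2], d = d[hit], np = np)
}

# One equivariant attention layer: returns updated water coordinates and,
# when cache = TRUE, everything the backward pass needs.
site_layer_forward <- function(waters, prot, prot_class, layer, cutoff, n_rbf,
                               cache = FALSE) {
  nw <- nrow(waters)
  ed <- water_edges(waters, prot, cutoff)
  if (!length(ed$j)) {
    out <- list(coords = waters)
    if (cache) out$cache <- list(empty = TRUE, waters_in = waters)
    return(out)
  }
  np <- ed$np
  kclass <- ifelse(ed$k <= np, prot_class[pmin(ed$k, np)], 4L)
  B <- rbf_expand(ed$d, n_centers = n_rbf, lo = 0, hi = cutoff)
  tlog <- rowSums(B * t(layer$a[, kclass, drop = FALSE]))
  # per-water softmax over neighbors
  tmax <- as.numeric(tapply(tlog, ed$j, max)[as.character(ed$j)])
  ex <- exp(tlog - tmax)
  denom <- rowsum_vec(ex, ed$j, nw)
  alpha <- ex / denom[ed$j]
  m <- rowSums(B * t(layer$b[, kclass, drop = FALSE]))
  all_coords <- rbind(prot, waters)
  u <- waters[ed$j, , drop = FALSE] - all_coords[ed$k, , drop = FALSE]
  s <- alpha * m
  delta <- rowsum_mat(u * s, ed$j, nw)
  out <- list(coords = waters + delta)
  if (cache) {
    out$cache <- list(
      empty = FALSE, waters_in = waters, ed = ed, kclass = kclass,
      B = B, alpha = alpha, m = m, u = u, s = s
    )
  }
  out
}

# rowsum helpers that keep absent groups as zero rows.
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg
  out
}
rowsum_mat <- function(x, g, n) {
  out <- matrix(0, n, ncol(x))
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Apply one equivariant attention layer
#'
#' Updates water-node coordinates on the current distance-graph topology;
#' protein atoms are left bit-identical. With no edges (or no water nodes)
#' the layer is the identity.
#'
#' @param waters tibble of water nodes (`x`, `y`, `z`).
#' @param structure atom tibble.
#' @param model a `hydrasite_site_model` supplying parameters.
#' @param layer_index which layer's parameters to apply.
#' @return The water tibble with updated coordinates.
#' @export
equivariant_layer <- function(waters, structure, model, layer_index = 1) {
  if (nrow(waters) == 0) return(waters)
  cfg <- model$config
  res <- site_layer_forward(
    coord_matrix(waters), coord_matrix(structure),
    protein_classes(structure), model$params$layers[[layer_index]],
    cfg$cutoff, cfg$n_rbf
  )
  set_coords(waters, res$coords)
}

# Certainty-weight head: w_j = sigmoid(c0 + sum_c cvec_c * rho_jc), where
# rho_jc pools the RBF expansion of distances to protein atoms within the
# cutoff. Returns w plus the head cache.
site_head_forward <- function(waters, prot, head, cutoff, n_rbf) {
  nw <- nrow(waters)
  d <- cross_distances(waters, prot)
  hit <- which(d < cutoff, arr.ind = TRUE)
  rho <- matrix(0, nw, n_rbf)
  hcache <- NULL
  if (nrow(hit)) {
    B <- rbf_expand(d[hit], n_centers = n_rbf, lo = 0, hi = cutoff)
    rho <- rowsum_mat(B, hit[, 1], nw)
    hcache <- list(j = hit[, 1], k = hit[, 2], d = d[hit])
  }
  slog <- head$c0 + drop(rho %*% head$cvec)
  list(w = 1 / (1 + exp(-slog)), rho = rho, edges = hcache)
}

# Full forward pass. protein coordinates never change; topology is rebuilt
# from the moved waters before each layer. Returns final coordinates,
# weights, and per-layer caches for the backward pass.
site_forward <- function(structure, model, cache = FALSE) {
  cfg <- model$config
  prot <- coord_matrix(structure)
  pclass <- protein_classes(structure)
  seeds <- initialize_waters(structure, cfg$sasa_threshold)
  waters <- coord_matrix(seeds)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    res <- site_layer_forward(waters, prot, pclass, model$params$layers[[l]],
                              cfg$cutoff, cfg$n_rbf, cache = cache)
    waters <- res$coords
    if (cache) caches[[l]] <- res$cache
  }
  hd <- site_head_forward(waters, prot, model$params$head, cfg$cutoff, cfg$n_rbf)
  list(coords = waters, w = hd$w, seeds = seeds, head = hd,
       caches = caches, prot = prot)
}

#' Raw weighted water predictions
#'
#' Runs the full location model: SASA-gated seeding, five equivariant
#' attention layers with topology refresh, and the certainty head. Inference
#' is deterministic; predictions are equivariant under rigid motions of the
#' input and permutation-invariant in the atom order.
#'
#' @param structure atom tibble (SASA computed on the fly when missing).
#' @param model a `hydrasite_site_model`.
#' @return Tibble of predictions with columns `x`, `y`, `z`, `w`.
#' @export
predict_raw <- function(structure, model) {
  if (!"sasa" %in% names(structure)) structure <- compute_sasa(structure)
  fw <- site_forward(structure, model)
  tibble::tibble(x = fw$coords[, 1], y = fw$coords[, 2], z = fw$coords[, 3],
                 w = fw$w)
}

# ---- reverse-mode gradients -------------------------------------------------

# Backward through the certainty head. Adds the coordinate gradient induced
# by w's dependence on the final water positions.
site_head_backward <- function(hd, waters, prot, head, cutoff, n_rbf, grad_w) {
  gs <- grad_w * hd$w * (1 - hd$w)
  grads <- list(c0 = sum(gs), cvec = drop(t(hd$rho) %*% gs))
  gx <- matrix(0, nrow(waters), 3)
  if (!is.null(hd$edges)) {
    e <- hd$edges
    Bp <- rbf_expand_deriv(e$d, n_centers = n_rbf, lo = 0, hi = cutoff)
    dsdd <- drop(Bp %*% head$cvec)            # d s_j / d d_jk per edge
    u <- waters[e$j, , drop = FALSE] - prot[e$k, , drop = FALSE]
    uh <- safe_unit_rows(u, e$d)
    contrib <- uh * (gs[e$j] * dsdd)
    gx <- rowsum_mat(contrib, e$j, nrow(waters))
  }
  list(param_grads = grads, grad_x = gx)
}

# Backward through one equivariant layer: given dL/d(output coords) G,
# return dL/d(input coords) and the layer parameter gradients.
site_layer_backward <- function(cache, layer, cutoff, n_rbf, G) {
  nw <- nrow(cache$waters_in)
  zero <- list(a = matrix(0, n_rbf, 4), b = matrix(0, n_rbf, 4))
  if (isTRUE(cache$empty)) return(list(grad_in = G, param_grads = zero))
  ed <- cache$ed; np <- ed$np
  kclass <- cache$kclass
  B <- cache$B; alpha <- cache$alpha; m <- cache$m; u <- cache$u; s <- cache$s
  Bp <- rbf_expand_deriv(ed$d, n_centers = n_rbf, lo = 0, hi = cutoff)
  p <- rowSums(G[ed$j, , drop = FALSE] * u)   # G_j . u_e per edge
  q <- p * m * alpha
  S <- rowsum_vec(q, ed$j, nw)                # per-water sum of q
  pa <- p * alpha
  resid <- q - S[ed$j] * alpha                # softmax residual per edge

  grad_a <- matrix(0, n_rbf, 4)
  grad_b <- matrix(0, n_rbf, 4)
  for (cl in 1:4) {
    sel <- kclass == cl
    if (!any(sel)) next
    grad_b[, cl] <- drop(t(B[sel, , drop = FALSE]) %*% pa[sel])
    grad_a[, cl] <- drop(t(B[sel, , drop = FALSE]) %*% resid[sel])
  }

  mprime <- rowSums(Bp * t(layer$b[, kclass, drop = FALSE]))
  tprime <- rowSums(Bp * t(layer$a[, kclass, drop = FALSE]))
  D <- pa * mprime + resid * tprime           # dL/dd per edge
  uh <- safe_unit_rows(u, ed$d)
  contrib <- G[ed$j, , drop = FALSE] * s + uh * D
  grad_in <- G + rowsum_mat(contrib, ed$j, nw)
  wsrc <- ed$k > np
  if (any(wsrc)) {
    grad_in <- grad_in - rowsum_mat(contrib[wsrc, , drop = FALSE],
                                    ed$k[wsrc] - np, nw)
  }
  list(grad_in = grad_in, param_grads = list(a = grad_a, b = grad_b))
}

# Loss and full analytic gradient of the training objective on one fixture.
# refs must already carry only qualifying (occupancy >= 0.5) sites.
site_loss_and_grad <- function(structure, refs, model) {
  cfg <- model$config
  fw <- site_forward(structure, model, cache = TRUE)
  if (nrow(fw$seeds) == 0) abort("Structure seeds zero water nodes; cannot train.")
  preds <- tibble::tibble(x = fw$coords[, 1], y = fw$coords[, 2],
                          z = fw$coords[, 3], w = fw$w)
  ml <- mixture_loss(preds, refs, alpha = cfg$alpha, sigma = cfg$sigma,
                     gradients = TRUE)
  hb <- site_head_backward(fw$head, fw$coords, fw$prot, model$params$head,
                           cfg$cutoff, cfg$n_rbf, ml$grad_w)
  G <- ml$grad_x + hb$grad_x
  layer_grads <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lb <- site_layer_backward(fw$caches[[l]], model$params$layers[[l]],
                              cfg$cutoff, cfg$n_rbf, G)
    layer_grads[[l]] <- lb$param_grads
    G <- lb$grad_in
  }
  list(loss = ml$loss,
       grads = list(layers = layer_grads, head = hb$param_grads))
}

# ---- parameter vector plumbing ---------------------------------------------

flatten_site_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_site_params <- function(flat, template) {
  rel <- utils::relist(flat, template)
  rel
}

# ---- training ---------------------------------------------------------------

#' Train the location model
#'
#' Full-batch Adam on the Gaussian-mixture divergence loss over a set of
#' training fixtures. Reference sites are restricted to occupancy >= 0.5
#' before entering the loss (sites without an occupancy column count as
#' fully occupied).
#'
#' After optimization the certainty head's intercept is calibrated: the loss
#' only constrains the normalized weights (the mixture is scale-free in the
#' raw certainties), so the raw-weight scale is a gauge freedom. It is fixed
#' by choosing the intercept such that the mean total raw certainty per
#' structure equals the mean number of qualifying reference sites, giving
#' raw weights an expected-water-count interpretation that makes the
#' downstream `w_c` filter meaningful.
#'
#' @param model a `hydrasite_site_model`.
#' @param data list of fixtures, each a list with elements `structure` (atom
#'   tibble) and `refs` (reference site tibble with `x`, `y`, `z` and
#'   optionally `occupancy`).
#' Optimization is non-convex; to avoid poor initialization basins the run
#' starts with `n_restarts` short pilot optimizations from different random
#' initializations and continues the best one to the full epoch budget.
#'
#' @param epochs maximum Adam steps.
#' @param lr initial learning rate (decayed exponentially to
#'   `lr * lr_decay` over the run).
#' @param lr_decay final learning-rate fraction.
#' @param min_occupancy reference occupancy gate.
#' @param calibrate fix the raw-weight scale gauge after training?
#' @param n_restarts number of pilot initializations (1 = no restarts).
#' @param pilot_epochs Adam steps per pilot.
#' @param verbose print loss every 50 epochs?
#' @return The trained model, with `history` populated.
#' @export
train_site_model <- function(model, data, epochs = 2000, lr = 0.015,
                             lr_decay = 0.02, min_occupancy = 0.5,
                             calibrate = TRUE, n_restarts = 3,
                             pilot_epochs = 200, verbose = FALSE) {
  data <- purrr::map(data, function(fx) {
    if (!"sasa" %in% names(fx$structure)) {
      fx$structure <- compute_sasa(fx$structure)
    }
    if ("occupancy" %in% names(fx$refs)) {
      fx$refs <- dplyr::filter(fx$refs, .data$occupancy >= min_occupancy)
    }
    if (nrow(fx$refs) == 0) abort("A training fixture has no qualifying reference sites.")
    fx
  })
  if (n_restarts > 1 && epochs > pilot_epochs) {
    cfg <- model$config
    # derive pilot seeds from the incoming initialization so independent
    # training runs explore different pilot sets
    seed_base <- floor(sum(abs(flatten_site_params(model$params))) * 1e6) %%
      100000
    candidates <- c(list(model), purrr::map(seq_len(n_restarts - 1), function(i) {
      new_site_model(n_layers = cfg$n_layers, n_rbf = cfg$n_rbf,
                     cutoff = cfg$cutoff, sasa_threshold = cfg$sasa_threshold,
                     sigma = cfg$sigma, alpha = cfg$alpha,
                     seed = seed_base + 7919 * i)
    }))
    pilots <- purrr::map(candidates, function(cand) {
      train_site_model(cand, data, epochs = pilot_epochs, lr = lr,
                       lr_decay = 1, min_occupancy = min_occupancy,
                       calibrate = FALSE, n_restarts = 1)
    })
    best <- which.min(purrr::map_dbl(pilots, ~ tail(.x$history$loss, 1)))
    model <- pilots[[best]]
    if (verbose) inform(sprintf("pilot %d selected (loss %.3f)", best,
                                tail(model$history$loss, 1)))
  }
  theta <- flatten_site_params(model$params)
  mom <- numeric(length(theta)); vel <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist_epoch <- integer(0); hist_loss <- numeric(0)
  for (ep in seq_len(epochs)) {
    model$params <- unflatten_site_params(theta, model$params)
    total <- 0
    gsum <- numeric(length(theta))
    for (fx in data) {
      lg <- site_loss_and_grad(fx$structure, fx$refs, model)
      total <- total + lg$loss
      gsum <- gsum + flatten_site_params(lg$grads)
    }
    total <- total / length(data)
    gsum <- gsum / length(data)
    mom <- b1 * mom + (1 - b1) * gsum
    vel <- b2 * vel + (1 - b2) * gsum^2
    mhat <- mom / (1 - b1^ep); vhat <- vel / (1 - b2^ep)
    lr_ep <- lr * lr_decay^((ep - 1) / max(1, epochs - 1))
    theta <- theta - lr_ep * mhat / (sqrt(vhat) + eps)
    hist_epoch <- c(hist_epoch, ep); hist_loss <- c(hist_loss, total)
    if (verbose && ep %% 50 == 0) {
      inform(sprintf("epoch %d  loss %.4f", ep, total))
    }
  }
  model$params <- unflatten_site_params(theta, model$params)
  if (calibrate) model <- calibrate_weight_scale(model, data)
  model$history <- tibble::tibble(epoch = hist_epoch, loss = hist_loss)
  model$trained <- TRUE
  model
}

# Fix the raw-weight gauge: choose the head intercept so that the mean sum
# of raw certainties over the training structures equals the mean number of
# qualifying reference sites. Monotone in c0, solved by bisection.
calibrate_weight_scale <- function(model, data) {
  target <- mean(purrr::map_dbl(data, ~ nrow(.x$refs)))
  fws <- purrr::map(data, ~ site_forward(.x$structure, model))
  expected_count <- function(c0) {
    mean(purrr::map_dbl(fws, function(fw) {
      s <- c0 + drop(fw$head$rho %*% model$params$head$cvec)
      sum(1 / (1 + exp(-s)))
    })) - target
  }
  lo <- -40; hi <- 40
  if (expected_count(lo) < 0 && expected_count(hi) > 0) {
    model$params$head$c0 <- stats::uniroot(expected_count, c(lo, hi))$root
  }
  model
}

#' Predict final hydration sites
#'
#' The inference pipeline: raw weighted predictions, certainty filtering at
#' `w_c`, Ward clustering at the linkage threshold, weighted centroids, and
#' the cluster-weight gate.
#'
#' @param structure atom tibble.
#' @param model a trained `hydrasite_site_model`.
#' @param config a [hydrasite_config()] supplying the clustering thresholds.
#' @return Tibble of predicted sites (`x`, `y`, `z`, `weight`, `n_members`).
#' @export
predict_sites <- function(structure, model, config = hydrasite_config()) {
  preds <- predict_raw(structure, model)
  kept <- filter_low_certainty(preds, w_c = config$certainty_cutoff)
  if (nrow(kept) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          weight = numeric(), n_members = integer()))
  }
  clusters <- cluster_predictions(
    kept, distance_threshold = config$cluster_linkage_threshold
  )
  finalize_sites(clusters, min_cluster_weight = config$min_cluster_weight,
                 weight_mode = config$cluster_weight_mode)
}

#' @export
print.hydrasite_site_model <- function(x, ...) {
  cat("<hydrasite_site_model>\n")
  cat(sprintf("  layers: %d  rbf: %d  cutoff: %.1f A  trained: %s\n",
              x$config$n_layers, x$config$n_rbf, x$config$cutoff,
              x$trained))
  if (nrow(x$history)) {
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                tail(x$history$loss, 1), nrow(x$history)))
  }
  invisible(x)
}
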