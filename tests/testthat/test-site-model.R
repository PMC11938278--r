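# Location model: seeding, equivariant layers, prediction, loss, gradients.

test_that("water seeding follows the strict SASA gate", {
  st <- tibble::tibble(
    element = "O", atom_name = "O", residue_name = "HOH",
    residue_index = 1:3, chain_id = "A",
    x = c(0, 10, 20), y = 0, z = 0,
    sasa = c(0.05, 0.10, 0.45)
  )
  seeds <- initialize_waters(st, sasa_threshold = 0.1)
  # 0.05 and the boundary value 0.10 do not qualify ("exceeds 0.1")
  expect_equal(seeds$seed_atom, 3L)
  expect_equal(c(seeds$x, seeds$y, seeds$z), c(20, 0, 0))

  buried <- dplyr::mutate(st, sasa = 0)
  expect_equal(nrow(suppressMessages(initialize_waters(buried))), 0)

  st$sasa <- c(0.2, 0.3, 0.4)
  expect_equal(nrow(initialize_waters(st)), 3)
})

test_that("a layer leaves protein coordinates bit-identical and is identity without edges", {
  fx <- toy_fixture(seed = 3)
  model <- new_site_model(seed = 1, init_sd = 0.3)
  seeds <- initialize_waters(fx$structure)
  before <- hydrasite:::coord_matrix(fx$structure)
  moved <- equivariant_layer(seeds, fx$structure, model, 1)
  expect_identical(hydrasite:::coord_matrix(fx$structure), before)
  expect_gt(max(abs(hydrasite:::coord_matrix(moved) -
                      hydrasite:::coord_matrix(seeds))), 0)

  # water far from everything: no edges, no update
  lone <- tibble::tibble(x = 500, y = 500, z = 500)
  out <- equivariant_layer(lone, fx$structure, model, 1)
  expect_identical(out, lone)
})

test_that("predictions are deterministic, permutation-invariant and equivariant", {
  fx <- toy_fixture(seed = 3)
  model <- new_site_model(seed = 1, init_sd = 0.2)
  p1 <- predict_raw(fx$structure, model)
  p2 <- predict_raw(fx$structure, model)
  expect_identical(p1, p2)

  # permuting atoms permutes the prediction multiset
  set.seed(5)
  perm <- sample(nrow(fx$structure))
  p3 <- predict_raw(fx$structure[perm, ], model)
  m1 <- cbind(hydrasite:::coord_matrix(p1), p1$w)
  m3 <- cbind(hydrasite:::coord_matrix(p3), p3$w)
  ord1 <- do.call(order, as.data.frame(m1))
  ord3 <- do.call(order, as.data.frame(m3))
  expect_equal(m1[ord1, ], m3[ord3, ], tolerance = 1e-5)

  # rigid motion of the input rigidly moves predictions, weights unchanged
  set.seed(21)
  for (rep in 1:3) {
    mv <- random_rigid_motion()
    pm <- predict_raw(mv(fx$structure), model)
    expect_equal(hydrasite:::coord_matrix(pm),
                 hydrasite:::coord_matrix(mv(p1)), tolerance = 1e-5)
    expect_equal(pm$w, p1$w, tolerance = 1e-5)
  }
})

test_that("normalize_weights matches the closed form and guards zero input", {
  expect_equal(normalize_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(normalize_weights(0.7), 1)
  set.seed(8)
  w <- runif(20)
  expect_equal(normalize_weights(w), w / sum(w))
  expect_error(normalize_weights(c(0, 0)), "zero")
  expect_error(normalize_weights(c(-1, 2)), "non-negative")
})

test_that("mixture loss is scale-invariant in raw weights and rigid-motion invariant", {
  fx <- toy_fixture(seed = 3)
  refs <- dplyr::filter(fx$sites, .data$occupancy >= 0.5)
  set.seed(2)
  preds <- tibble::tibble(
    x = refs$x + rnorm(nrow(refs), sd = 0.5),
    y = refs$y + rnorm(nrow(refs), sd = 0.5),
    z = refs$z + rnorm(nrow(refs), sd = 0.5),
    w = runif(nrow(refs), 0.2, 0.9)
  )
  l1 <- mixture_loss(preds, refs)
  expect_equal(mixture_loss(dplyr::mutate(preds, w = w * 2), refs), l1)

  mv <- random_rigid_motion()
  expect_equal(mixture_loss(mv(preds), mv(refs)), l1, tolerance = 1e-6)

  # component order does not matter
  expect_equal(mixture_loss(preds[sample(nrow(preds)), ], refs), l1)
  expect_error(mixture_loss(preds[0, ], refs), "prediction")
  expect_error(mixture_loss(preds, refs[0, ]), "reference")
})

test_that("identical-support predictions minimize the loss over random perturbations", {
  fx <- toy_fixture(seed = 4)
  refs <- dplyr::filter(fx$sites, .data$occupancy >= 0.5)
  ideal <- tibble::tibble(x = refs$x, y = refs$y, z = refs$z,
                          w = refs$occupancy)
  base <- mixture_loss(ideal, refs)
  set.seed(33)
  worse <- vapply(1:100, function(i) {
    pert <- dplyr::mutate(
      ideal,
      x = .data$x + rnorm(dplyr::n(), sd = 0.3),
      y = .data$y + rnorm(dplyr::n(), sd = 0.3),
      z = .data$z + rnorm(dplyr::n(), sd = 0.3),
      w = pmax(.data$w + rnorm(dplyr::n(), sd = 0.1), 0.01)
    )
    mixture_loss(pert, refs)
  }, numeric(1))
  expect_true(all(base <= worse))
})

test_that("analytic mixture-loss gradients match central finite differences", {
  refs <- tibble::tibble(x = c(0, 3), y = c(0, 0), z = c(0, 1),
                         occupancy = c(0.9, 0.6))
  preds <- tibble::tibble(x = c(0.4, 2.5, 1.5), y = c(0.2, -0.3, 0.8),
                          z = c(-0.1, 0.9, 0.4), w = c(0.5, 0.7, 0.2))
  g <- mixture_loss(preds, refs, gradients = TRUE)
  e <- 1e-6
  for (j in seq_len(nrow(preds))) {
    for (col in c("x", "y", "z")) {
      up <- preds; up[[col]][j] <- up[[col]][j] + e
      dn <- preds; dn[[col]][j] <- dn[[col]][j] - e
      fd <- (mixture_loss(up, refs) - mixture_loss(dn, refs)) / (2 * e)
      expect_equal(g$grad_x[j, match(col, c("x", "y", "z"))], fd,
                   tolerance = 1e-4)
    }
    up <- preds; up$w[j] <- up$w[j] + e
    dn <- preds; dn$w[j] <- dn$w[j] - e
    fd <- (mixture_loss(up, refs) - mixture_loss(dn, refs)) / (2 * e)
    expect_equal(g$grad_w[j], fd, tolerance = 1e-4)
  }
})

test_that("end-to-end training gradients match finite differences", {
  fx <- toy_fixture(seed = 6, n_residues = 5)
  refs <- dplyr::filter(fx$sites, .data$occupancy >= 0.5)
  skip_if(nrow(refs) == 0)
  model <- new_site_model(seed = 2)
  lg <- hydrasite:::site_loss_and_grad(fx$structure, refs, model)
  theta <- hydrasite:::flatten_site_params(model$params)
  grad <- hydrasite:::flatten_site_params(lg$grads)
  set.seed(14)
  idx <- sample(length(theta), 30)
  e <- 1e-4
  fd <- vapply(idx, function(i) {
    up <- theta; up[i] <- up[i] + e
    dn <- theta; dn[i] <- dn[i] - e
    mu <- model; mu$params <- hydrasite:::unflatten_site_params(up, model$params)
    md <- model; md$params <- hydrasite:::unflatten_site_params(dn, model$params)
    (hydrasite:::site_loss_and_grad(fx$structure, refs, mu)$loss -
        hydrasite:::site_loss_and_grad(fx$structure, refs, md)$loss) / (2 * e)
  }, numeric(1))
  # relative agreement on components above the FD noise floor
  big <- abs(fd) > 1e-4
  expect_true(any(big))
  expect_lt(max(abs(fd[big] - grad[idx][big]) / abs(fd[big])), 1e-4)
})

test_that("checkpoints round-trip through JSON", {
  model <- new_site_model(seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(back$config, model$config)

  fx <- toy_fixture(seed = 3)
  expect_equal(predict_raw(fx$structure, back), predict_raw(fx$structure, model),
               tolerance = 1e-10)
})
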