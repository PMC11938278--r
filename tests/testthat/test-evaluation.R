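# GTRR / PHR, layer classification, occupancy-binned tables and
# regression metrics.

test_that("gtrr and phr reproduce hand-geometry cases", {
  refs <- tibble::tibble(x = c(0, 5), y = 0, z = 0)
  preds <- tibble::tibble(x = 0.6, y = 0, z = 0)
  expect_equal(gtrr(refs, preds, 0.5), 0)
  expect_equal(gtrr(refs, preds, 1.0), 0.5)

  refs1 <- tibble::tibble(x = 0, y = 0, z = 0)
  preds2 <- tibble::tibble(x = c(0.4, 2), y = 0, z = 0)
  expect_equal(phr(refs1, preds2, 0.5), 0.5)

  expect_equal(gtrr(refs, refs, 0.1), 1)
  expect_equal(phr(refs, refs, 0.1), 1)
  expect_equal(gtrr(refs, preds[0, ], 1), 0)
  expect_error(gtrr(refs[0, ], preds, 1), "empty reference")
  expect_error(phr(refs, preds[0, ], 1), "empty prediction")
  expect_error(gtrr(refs, preds, 0), "positive")
})

test_that("recovery rates are monotone in the cutoff and rigid-motion invariant", {
  set.seed(26)
  refs <- tibble::tibble(x = runif(20, 0, 10), y = runif(20, 0, 10),
                         z = runif(20, 0, 10))
  preds <- tibble::tibble(x = runif(15, 0, 10), y = runif(15, 0, 10),
                          z = runif(15, 0, 10))
  rs <- c(0.25, 0.5, 1, 2, 4, 8)
  g <- vapply(rs, function(r) gtrr(refs, preds, r), numeric(1))
  p <- vapply(rs, function(r) phr(refs, preds, r), numeric(1))
  expect_true(all(diff(g) >= 0))
  expect_true(all(diff(p) >= 0))
  expect_true(all(g >= 0 & g <= 1 & p >= 0 & p <= 1))

  mv <- random_rigid_motion()
  expect_equal(gtrr(mv(refs), mv(preds), 1), gtrr(refs, preds, 1))
  expect_equal(phr(mv(refs), mv(preds), 1), phr(refs, preds, 1))
})

test_that("one-to-one matching variant never exceeds the default", {
  refs <- tibble::tibble(x = c(0, 0.2), y = 0, z = 0)
  preds <- tibble::tibble(x = 0.1, y = 0, z = 0)
  expect_equal(gtrr(refs, preds, 0.5), 1)
  expect_equal(gtrr(refs, preds, 0.5, matching = "one_to_one"), 0.5)
})

test_that("layer classification is inclusive at the 3.5 A boundary", {
  st <- tibble::tibble(element = "C", atom_name = "CA", residue_name = "ALA",
                       residue_index = 1L, chain_id = "A", x = 0, y = 0, z = 0)
  sites <- tibble::tibble(x = c(3.5, 3.6, 0), y = 0, z = 0)
  expect_equal(classify_layer(sites, st), c("first", "second", "first"))
  expect_error(classify_layer(sites, st[0, ]), "non-empty")
})

test_that("binned GTRR decomposes into per-bin global GTRR", {
  set.seed(27)
  refs <- tibble::tibble(x = runif(100, 0, 20), y = runif(100, 0, 20),
                         z = runif(100, 0, 20),
                         occupancy = runif(100, 0.5, 1))
  preds <- tibble::tibble(x = runif(40, 0, 20), y = runif(40, 0, 20),
                          z = runif(40, 0, 20))
  tab <- binned_gtrr(refs, preds)
  bins <- seq(0.5, 1, by = 0.1)
  bin_of <- cut(refs$occupancy, bins, right = FALSE, include.lowest = TRUE)
  for (i in seq_len(nrow(tab))) {
    sub <- refs[as.integer(bin_of) == match(tab$bin[i], unique(tab$bin)), ]
    if (nrow(sub) == 0) {
      expect_true(is.na(tab$gtrr[i]))
    } else {
      expect_equal(tab$gtrr[i], gtrr(sub, preds, tab$cutoff[i]))
    }
  }

  # all refs in one bin -> other bins flagged absent, not zero
  one_bin <- dplyr::mutate(refs, occupancy = 0.55)
  tab1 <- binned_gtrr(one_bin, preds, cutoffs = 1)
  expect_false(is.na(tab1$gtrr[tab1$bin == "[0.5,0.6)"]))
  expect_true(all(is.na(tab1$gtrr[tab1$bin != "[0.5,0.6)"])))
})

test_that("regression metrics match their definitions", {
  t <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(t, t)$r2, 1)
  expect_equal(regression_metrics(t, t)$rmse, 0)
  expect_equal(regression_metrics(rep(mean(t), 4), t)$r2, 0)
  expect_error(regression_metrics(t, rep(1, 4)), "constant")
  expect_error(regression_metrics(1, 2), "equal-length")

  set.seed(28)
  p <- rnorm(30); y <- rnorm(30)
  m <- regression_metrics(p, y)
  expect_equal(m$mse, mean((y - p)^2))
  expect_equal(m$rmse, sqrt(m$mse))
  expect_equal(m$r2, 1 - sum((y - p)^2) / sum((y - mean(y))^2))
})

test_that("evaluation reports assemble rates, layers and bins", {
  fx <- toy_fixture(seed = 3)
  refs <- fx$sites
  preds <- dplyr::mutate(refs, x = .data$x + 0.3)
  rep_ <- evaluate_sites(refs, preds, structure = fx$structure)
  expect_s3_class(rep_, "hydrasite_eval")
  expect_equal(rep_$rates$gtrr[rep_$rates$cutoff == 0.5], 1)
  expect_true(!is.null(rep_$layers))
  expect_true(!is.null(rep_$binned))
  td <- tidy(rep_)
  expect_true(all(c("cutoff", "metric", "value") %in% names(td)))
})
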