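# Trajectory analysis: density grids, site extraction, occupancy,
# enthalpy, entropy and free energy.

test_that("density accumulation conserves in-bounds observations", {
  # one stationary water over 100 frames -> a single voxel with count 100
  traj <- tibble::tibble(frame = 1:100, x = 1.003, y = 2.001, z = -0.499)
  grid <- accumulate_density(traj)
  expect_equal(sum(grid$counts), 100)
  expect_equal(max(grid$counts), 100)

  # uniform random waters match a direct binning oracle exactly
  set.seed(17)
  n <- 3000
  traj2 <- tibble::tibble(frame = rep(1:100, each = 30),
                          x = runif(n, 0, 5), y = runif(n, 0, 5),
                          z = runif(n, 0, 5))
  bounds <- list(lo = c(0, 0, 0), hi = c(5, 5, 5))
  grid2 <- accumulate_density(traj2, bounds = bounds)
  expect_equal(sum(grid2$counts), n)
  idx <- floor(cbind(traj2$x, traj2$y, traj2$z) / 0.25) + 1
  oracle <- array(0L, grid2$dims)
  for (i in seq_len(n)) {
    oracle[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      oracle[idx[i, 1], idx[i, 2], idx[i, 3]] + 1L
  }
  expect_equal(as.integer(grid2$counts), as.integer(oracle))

  # out-of-bounds observations contribute nothing
  out_tr <- tibble::tibble(frame = 1, x = 99, y = 0, z = 0)
  g3 <- accumulate_density(dplyr::bind_rows(traj, out_tr),
                           bounds = list(lo = c(0, 1, -1), hi = c(2, 3, 0)))
  expect_equal(sum(g3$counts), 100)

  expect_error(accumulate_density(traj[0, ]), "zero frames")
})

test_that("site extraction finds blob centers and handles empty grids", {
  set.seed(18)
  n <- 800
  blob <- tibble::tibble(frame = rep(1:400, 2),
                         x = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 6, 0.3)),
                         y = rnorm(n, 1, 0.3), z = rnorm(n, -1, 0.3))
  grid <- accumulate_density(blob)
  sites <- extract_sites(grid, min_site_fraction = 0.2)
  expect_equal(nrow(sites), 2)
  ctrs <- hydrasite:::coord_matrix(sites)[order(sites$x), ]
  expect_lt(sqrt(sum((ctrs[1, ] - c(0, 1, -1))^2)), 0.25)
  expect_lt(sqrt(sum((ctrs[2, ] - c(6, 1, -1))^2)), 0.25)

  empty <- grid
  empty$counts[] <- 0L
  expect_equal(nrow(extract_sites(empty)), 0)
})

test_that("occupancy counts frames with a water inside the site radius", {
  traj <- tibble::tibble(frame = 1:1000,
                         x = c(rep(0, 500), rep(5, 500)), y = 0, z = 0)
  expect_equal(occupancy(c(0, 0, 0), traj), 0.5)
  expect_equal(occupancy(c(0, 0, 0), traj[1:500, ]), 1)

  # planted occupancy recovered within the binomial bound
  fx <- toy_fixture(seed = 5)
  traj2 <- make_trajectory(fx$sites, fx$spec, fx$structure)
  occ_hat <- vapply(seq_len(nrow(fx$sites)), function(i) {
    occupancy(c(fx$sites$x[i], fx$sites$y[i], fx$sites$z[i]), traj2)
  }, numeric(1))
  expect_lt(max(abs(occ_hat - fx$sites$occupancy)), 0.05)
})

test_that("enthalpy is the mean site energy minus the bulk reference", {
  expect_equal(site_enthalpy(c(-19, -19), -19), 0)
  expect_equal(site_enthalpy(c(-20, -22), -19), -2)
  # shifting all energies and the reference together changes nothing
  expect_equal(site_enthalpy(c(-20, -22) + 3.7, -19 + 3.7), -2)
  expect_error(site_enthalpy(numeric(0), -19), "zero observations")
})

test_that("uniform-ball entropy matches the analytic value within discretization error", {
  obs <- uniform_ball_obs()
  analytic <- thermo_constants$gas_constant * log(4 / 3 * pi / 29.9)
  s <- site_entropy(obs, center = c(0, 0, 0), radius = 1)
  s_half <- site_entropy(obs, center = c(0, 0, 0), radius = 1,
                         trans_bin = 0.125)
  disc_tol <- max(2 * abs(attr(s, "S_trans") - attr(s_half, "S_trans")),
                  0.01 * abs(analytic))
  expect_lt(abs(attr(s, "S_trans") - analytic), disc_tol)
  # uniform orientations contribute (near) zero rotational entropy
  expect_lt(abs(attr(s, "S_rot")), 0.02 * abs(analytic))
  # halving the bin width moves the estimate by < 2 %
  expect_lt(abs(attr(s, "S_trans") - attr(s_half, "S_trans")) /
              abs(attr(s, "S_trans")), 0.02)
})

test_that("entropy decreases with tighter spread and ignores duplication", {
  mk <- function(sig, n = 4000, seed = 3) {
    set.seed(seed)
    p <- matrix(rnorm(3 * n, sd = sig), ncol = 3)
    tibble::tibble(x = p[, 1], y = p[, 2], z = p[, 3])
  }
  s_tight <- site_entropy(mk(0.1))
  s_loose <- site_entropy(mk(0.3))
  expect_lt(as.numeric(s_tight), as.numeric(s_loose))

  one <- mk(0.2, n = 500)
  s1 <- site_entropy(one)
  s2 <- site_entropy(dplyr::bind_rows(one, one))
  # duplicating observations changes only the Miller-Madow term (~1/n)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 0.01)

  expect_error(site_entropy(mk(0.2, n = 10)), ">= 50")
})

test_that("free energy obeys dG = dH - T dS exactly", {
  expect_equal(free_energy(-2, -1 / 300), -1)
  expect_equal(free_energy(-3.2, 0), -3.2)
  set.seed(40)
  dH <- rnorm(20); dS <- rnorm(20, sd = 1e-3)
  expect_equal(free_energy(dH, dS) + 300 * dS - dH, rep(0, 20))
})

test_that("planted sites round-trip through the full trajectory analysis", {
  fx <- toy_fixture(seed = 4)
  traj <- make_trajectory(fx$sites, fx$spec, fx$structure)
  res <- analyze_trajectory(traj)
  hi <- dplyr::filter(fx$sites, .data$occupancy >= 0.5)
  d <- hydrasite:::cross_distances(hydrasite:::coord_matrix(hi),
                                   hydrasite:::coord_matrix(res))
  dmin <- apply(d, 1, min)
  nearest <- apply(d, 1, which.min)
  expect_lt(max(dmin), 0.3)
  expect_lt(max(abs(res$occupancy[nearest] - hi$occupancy)), 0.05)
  expect_true(all(is.finite(res$dH)))
  expect_equal(res$dG, res$dH + res$mTdS, tolerance = 1e-12)
})

test_that("grids serialize to OpenDX", {
  traj <- tibble::tibble(frame = 1:10, x = rnorm(10), y = rnorm(10),
                         z = rnorm(10))
  grid <- accumulate_density(traj)
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(grid, path)
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions")
  items <- as.integer(sub(".*items (\\d+) .*", "\\1", lines[7]))
  expect_equal(items, prod(grid$dims))
})
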