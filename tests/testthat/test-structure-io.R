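# Structure parsing, SASA and featurization.

ala_pdb <- paste(
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  HA  ALA A   1       1.800  -0.500   0.900  1.00  0.00           H",
    "END"),
  collapse = "\n"
)

test_that("parser keeps heavy atoms, drops hydrogens and rejects bad input", {
  atoms <- read_pdb(ala_pdb)
  expect_equal(nrow(atoms), 5)
  expect_false(any(atoms$element == "H"))
  expect_equal(atoms$atom_name, c("N", "CA", "C", "O", "CB"))
  expect_equal(nrow(read_pdb(ala_pdb, keep_hydrogens = TRUE)), 6)

  expect_error(read_pdb("REMARK nothing here"), "No ATOM records")
  bad <- sub("1.458", "xx.xx", ala_pdb, fixed = TRUE)
  expect_error(read_pdb(bad), "line 2")
})

test_that("fixture PDBs round-trip through write/parse with identical coordinates", {
  fx <- toy_fixture(seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, path)
  back <- read_pdb(path)
  expect_equal(nrow(back), nrow(fx$structure))
  expect_equal(back$atom_name, fx$structure$atom_name)
  # PDB stores 3 decimals
  expect_equal(hydrasite:::coord_matrix(back),
               hydrasite:::coord_matrix(fx$structure), tolerance = 1e-3)
})

test_that("SASA matches geometry: isolated atom fully exposed, symmetry respected", {
  one <- tibble::tibble(element = "O", atom_name = "O", residue_name = "HOH",
                        residue_index = 1L, chain_id = "A", x = 0, y = 0, z = 0)
  expect_equal(compute_sasa(one)$sasa, 1)

  # two identical atoms placed symmetrically get identical fractions
  two <- tibble::tibble(element = c("C", "C"), atom_name = c("CA", "CA"),
                        residue_name = "ALA", residue_index = 1:2,
                        chain_id = "A", x = c(-1.2, 1.2), y = 0, z = 0)
  s <- compute_sasa(two)$sasa
  expect_equal(s[1], s[2], tolerance = 0.01)
  expect_true(all(s < 1))

  expect_error(compute_sasa(dplyr::mutate(one, element = "XX")), "XX")
})

test_that("SASA agrees with a Monte-Carlo rejection oracle on a random cluster", {
  set.seed(42)
  n <- 10
  cl <- tibble::tibble(
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    atom_name = "X", residue_name = "UNK", residue_index = 1:n,
    chain_id = "A",
    x = runif(n, 0, 6), y = runif(n, 0, 6), z = runif(n, 0, 6)
  )
  got <- compute_sasa(cl)$sasa
  # oracle: random surface points, rejection against all other spheres
  radii <- hydrasite:::.vdw_radii[cl$element] + 1.4
  coords <- hydrasite:::coord_matrix(cl)
  npts <- 1e5
  set.seed(99)
  oracle <- vapply(seq_len(n), function(i) {
    pts <- matrix(rnorm(3 * npts), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * radii[i]
    pts <- sweep(pts, 2, coords[i, ], "+")
    free <- rep(TRUE, npts)
    for (j in setdiff(seq_len(n), i)) {
      dj2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      free <- free & dj2 > radii[j]^2
    }
    mean(free)
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 0.02)
})

test_that("SASA is invariant under rigid motion with the rotated sphere convention", {
  fx <- toy_fixture(seed = 3)
  rot <- hydrasite:::quaternion_to_matrix(hydrasite:::random_quaternions(1)[1, ])
  moved <- hydrasite:::set_coords(
    fx$structure,
    hydrasite:::coord_matrix(fx$structure) %*% t(rot) + 5
  )
  s1 <- compute_sasa(fx$structure)$sasa
  s2 <- compute_sasa(moved, sphere_rotation = rot)$sasa
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("feature vectors are 92-dimensional with unit one-hot blocks", {
  fx <- toy_fixture(seed = 3)
  f <- featurize(fx$structure, "atom")
  expect_equal(ncol(f), 92)
  expect_equal(nrow(f), nrow(fx$structure))
  expect_true(all(rowSums(f[, 1:38]) == 1))
  expect_true(all(rowSums(f[, 39:59]) == 1))
  expect_true(all(f[, 60:91] >= 0))
  expect_true(all(f[, 92] == 0))

  # water nodes: reserved slots, flag = 1, SASA expansion of zero
  w <- featurize(tibble::tibble(x = 0, y = 0, z = 0), "water")
  expect_equal(ncol(w), 92)
  expect_equal(w[1, 38], 1)   # "other" atom slot
  expect_equal(w[1, 38 + 21], 1) # "other" residue slot
  expect_equal(w[1, 92], 1)
  expect_equal(w[1, 60:91], rbf_expand(0, 32, 0, 1)[1, ])

  # 20 standard residues + one nonstandard cover 21 distinct slots
  res21 <- tibble::tibble(
    element = "C", atom_name = "CA",
    residue_name = c(hydrasite:::.residue_type_vocab[1:20], "XYZ"),
    residue_index = 1:21, chain_id = "A", x = 0, y = 0, z = 0, sasa = 0.5
  )
  f21 <- featurize(res21, "atom")
  slots <- apply(f21[, 39:59], 1, which.max)
  expect_equal(sort(unique(slots)), 1:21)
})

test_that("featurization is permutation-equivariant", {
  fx <- toy_fixture(seed = 3)
  f <- featurize(fx$structure, "atom")
  set.seed(7)
  perm <- sample(nrow(fx$structure))
  expect_identical(featurize(fx$structure[perm, ], "atom"), f[perm, ])
})

test_that("atom vocabulary has exactly 38 entries and residues 21", {
  expect_length(hydrasite:::.atom_type_vocab, 38)
  expect_length(hydrasite:::.residue_type_vocab, 21)
})
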