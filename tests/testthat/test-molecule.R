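test_that("molecule constructor enforces its invariants", {
  expect_error(molecule(character(0), matrix(numeric(0), 0, 3)),
               "at least one atom")
  expect_error(molecule(c("O", "H"), matrix(0, 3, 3)), "differ")
  expect_error(molecule("O", matrix(c(Inf, 0, 0), 1)), "finite")
  expect_error(molecule("O", matrix(0, 1, 3), formal_charge = 2L),
               "formal_charge")
  expect_error(molecule("Xx", matrix(0, 1, 3)), "Xx")
  expect_error(molecule(c("O", "H"), matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE),
                        bonds = data.frame(i = 1L, j = 1L, order = 1)),
               "distinct")
})

test_that("bond perception connects covalent neighbours only", {
  lib <- toy_library()
  # water: exactly the two O-H bonds
  expect_equal(lib$water$bonds[, c("i", "j")],
               data.frame(i = c(1L, 1L), j = c(2L, 3L)))
  # pyridine: 6 ring bonds + 5 C-H
  expect_equal(nrow(lib$pyridine$bonds), 11L)
  # bromoaniline carries a C-Br bond
  b <- lib$bromoaniline$bonds
  el <- lib$bromoaniline$elements
  expect_true(any(el[b$i] == "Br" | el[b$j] == "Br"))
})

test_that("XYZ round trip preserves elements and coordinates", {
  lib <- toy_library()
  for (mol in lib) {
    path <- tempfile(fileext = ".xyz")
    write_xyz(mol, path, "round trip")
    back <- read_xyz(path)
    expect_identical(back$elements, mol$elements)
    expect_equal(back$coords, mol$coords, tolerance = 1e-6)
    unlink(path)
  }
})

test_that("XYZ reader reports malformed input with line numbers", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c("5", "water", "O 0 0 0", "H 0.7 0.7 0", "H -0.7 0.7 0"), p)
  expect_error(read_xyz(p), "declares 5 atoms")
  writeLines(c("2", "x", "O 0 0 0", "H aa 0.7 0"), p)
  expect_error(read_xyz(p), "line 4")
  writeLines(c("1", "x", "Qq 0 0 0"), p)
  expect_error(read_xyz(p), "Qq")
  expect_error(read_xyz(tempfile()), "no such file")
  unlink(p)
})

test_that("writer refuses a 0-atom molecule", {
  mol <- toy_library()$water
  mol$elements <- character(0)
  mol$coords <- matrix(numeric(0), 0, 3)
  expect_error(write_xyz(mol, tempfile()), "0-atom")
})

test_that("center of mass matches hand-computed values", {
  h2 <- molecule(c("H", "H"), rbind(c(-0.37, 0, 0), c(0.37, 0, 0)))
  expect_equal(center_of_mass(h2), c(0, 0, 0), tolerance = 1e-12)
  single <- molecule("N", matrix(c(1, 2, 3), 1))
  expect_equal(center_of_mass(single), c(1, 2, 3))
  hf <- molecule(c("H", "F"), rbind(c(0, 0, 0), c(0.92, 0, 0)))
  m <- atomic_mass(c("H", "F"))
  expect_equal(center_of_mass(hf)[1], 0.92 * m[2] / sum(m), tolerance = 1e-12)
})

test_that("center of mass is equivariant under rigid motion", {
  set.seed(31)
  mol <- toy_library()$glycine
  com <- center_of_mass(mol)
  for (k in 1:25) {
    r <- random_rotation()
    t <- rnorm(3, sd = 5)
    moved <- protomeR:::transform_molecule(mol, r, t)
    expect_equal(center_of_mass(moved), as.numeric(r %*% com + t),
                 tolerance = 1e-9)
  }
})

test_that("SMILES builder produces relaxed, seed-reproducible structures", {
  w <- parse_smiles_to_3d("O", seed = 5L)
  expect_identical(sort(w$elements), c("H", "H", "O"))
  expect_identical(w$formal_charge, 0L)

  benz <- parse_smiles_to_3d("c1ccccc1", seed = 5L)
  expect_identical(length(benz$elements), 12L)
  cc <- benz$bonds[benz$elements[benz$bonds$i] == "C" &
                     benz$elements[benz$bonds$j] == "C", ]
  d <- sqrt(rowSums((benz$coords[cc$i, ] - benz$coords[cc$j, ])^2))
  expect_true(all(d > 1.35 & d < 1.45))

  again <- parse_smiles_to_3d("c1ccccc1", seed = 5L)
  expect_identical(benz$coords, again$coords)

  expect_error(parse_smiles_to_3d("C1CC", seed = 1L), "invalid SMILES")
  expect_error(parse_smiles_to_3d("O", steps_per_atom = 0L), "steps_per_atom")
})
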