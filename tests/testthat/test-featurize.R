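test_that("center of electronegativity is the Pauling-weighted mean", {
  # homonuclear: COE equals the unweighted centroid and the COM
  eth <- toy_library()$ethane
  cc <- molecule(eth$elements[1:2], eth$coords[1:2, ])
  expect_equal(compute_coe(cc), colMeans(cc$coords), tolerance = 1e-12)
  expect_equal(compute_coe(cc), center_of_mass(cc), tolerance = 1e-12)

  single <- molecule("O", matrix(c(1, 2, 3), 1))
  expect_equal(compute_coe(single), c(1, 2, 3))

  hf <- molecule(c("H", "F"), rbind(c(0, 0, 0), c(0.92, 0, 0)))
  expect_equal(compute_coe(hf)[1], 0.92 * 3.98 / (2.20 + 3.98),
               tolerance = 1e-12)
})

test_that("COE reduces to COM when weights are swapped for masses", {
  # shared weighted-mean oracle behind both centers
  for (mol in toy_library()[c("glycine", "cysteine", "pyridine")]) {
    expect_equal(center_of_mass(mol),
                 weighted_mean_position(mol$coords, atomic_mass(mol$elements)),
                 tolerance = 1e-12)
    expect_equal(compute_coe(mol),
                 weighted_mean_position(mol$coords,
                                        electronegativity(mol$elements)),
                 tolerance = 1e-12)
  }
})

test_that("interaction angle is measured at the COE vertex", {
  expect_equal(interaction_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(interaction_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180,
               tolerance = 1e-12, ignore_attr = TRUE)
  deg <- interaction_angle(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  expect_equal(as.numeric(deg), 0)
  expect_true(isTRUE(attr(deg, "degenerate")))
})

test_that("surface area matches analytic values and the dot oracle", {
  o <- molecule("O", matrix(0, 1, 3))
  expect_equal(molecular_surface_area(o), 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.005)
  # two atoms far apart: no burial, areas add
  oo <- molecule(c("O", "N"), rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(molecular_surface_area(oo),
               4 * pi * ((1.52 + 1.4)^2 + (1.55 + 1.4)^2),
               tolerance = 0.005)
  # rotation invariance
  set.seed(8)
  gly <- toy_library()$glycine
  a0 <- molecular_surface_area(gly)
  moved <- protomeR:::transform_molecule(gly, random_rotation(), rnorm(3))
  expect_equal(molecular_surface_area(moved), a0, tolerance = 1e-6 * a0)
  # independent brute-force oracle within 1% on five fixtures
  for (mol in toy_library()[c("water", "acetic_acid", "glycine",
                              "imidazole", "cysteine")]) {
    ref <- sasa_bruteforce(mol)
    expect_equal(molecular_surface_area(mol), ref, tolerance = 0.01 * ref)
  }
})

test_that("heteroatom counts follow the halogen/othergen definitions", {
  expect_equal(element_counts(toy_library()$water),
               c(n_oxygen = 1L, n_nitrogen = 0L, n_halogen = 0L,
                 n_othergen = 0L))
  ccl3f <- molecule(c("C", "Cl", "Cl", "Cl", "F"),
                    rbind(c(0, 0, 0), c(1.8, 0, 0), c(-1.8, 0, 0),
                          c(0, 1.8, 0), c(0, -1.4, 0)))
  expect_equal(element_counts(ccl3f)[["n_halogen"]], 4L)
  expect_equal(element_counts(toy_library()$cysteine),
               c(n_oxygen = 2L, n_nitrogen = 1L, n_halogen = 0L,
                 n_othergen = 1L))
})

test_that("polarizability lookups come from the snapshotted table", {
  expect_equal(cba_polarizability("O"), 0.802)
  expect_gt(cba_polarizability("N"), cba_polarizability("O"))
  expect_error(cba_polarizability("Xx"), "Xx")
})

test_that("featurize fills the full schema and stays local to the CBA", {
  models <- enumerate_models(toy_library()$glycine, "[M+H]+")
  fv <- featurize(models[[1L]])
  expect_identical(names(fv), feature_schema())
  expect_true(all(fv[c("dist_cba_com", "dist_cba_coe", "dist_com_coe")] >= 0))
  expect_true(fv[["interaction_angle"]] >= 0 && fv[["interaction_angle"]] <= 180)
  expect_gt(fv[["msa"]], 0)

  # two models sharing a geometry differ only in CBA-dependent fields
  m1 <- models[[1L]]
  m2 <- m1
  other_site <- setdiff(which(m1$geometry$elements %in% c("N", "O")),
                        m1$cba_index)[1L]
  m2$cba_index <- other_site
  f1 <- featurize(m1); f2 <- featurize(m2)
  shared <- c("dist_com_coe", "msa", "n_oxygen", "n_nitrogen", "n_halogen",
              "n_othergen")
  expect_equal(f1[shared], f2[shared], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1[["dist_cba_com"]], f2[["dist_cba_com"]])))
})

test_that("training-table CSV round trips through the declared schema", {
  tab <- synthetic_training_table(synthetic_spec(n_systems = 5L, seed = 2L))
  path <- tempfile(fileext = ".csv")
  write_training_table(tab, path)
  back <- read_training_table(path)
  expect_identical(names(back), c(feature_schema(), "re_label", "system_id"))
  expect_equal(back$re_label, tab$re_label, tolerance = 1e-9)
  bad <- tab
  bad$re_label <- bad$re_label + 1
  expect_error(validate_training_table(bad), "minimum")
  unlink(path)
})
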