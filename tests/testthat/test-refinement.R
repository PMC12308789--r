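test_that("surrogate substitution follows the element rules and reverses", {
  lib <- toy_library()
  sub <- surrogate_substitute(lib$bromoaniline, ANI2X_ELEMENTS)
  expect_identical(sub$map$original_element, "Br")
  expect_identical(sub$map$surrogate_element, "Cl")
  expect_identical(sub$mol$coords, lib$bromoaniline$coords)
  expect_identical(restore_substitutions(sub$mol, sub$map)$elements,
                   lib$bromoaniline$elements)

  # H/C/N/O-only molecule: identity with an empty map
  sub2 <- surrogate_substitute(lib$glycine, ANI2X_ELEMENTS)
  expect_identical(nrow(sub2$map), 0L)
  expect_identical(sub2$mol$elements, lib$glycine$elements)
  expect_identical(restore_substitutions(sub2$mol, sub2$map), sub2$mol)

  # Se -> S on a selenium twin of cysteine
  seleno <- lib$cysteine
  seleno$elements[seleno$elements == "S"] <- "Se"
  sub3 <- surrogate_substitute(seleno, ANI2X_ELEMENTS)
  expect_identical(sub3$map$surrogate_element, "S")

  boron <- molecule(c("B", "H", "H", "H"),
                    rbind(c(0, 0, 0), c(1.2, 0, 0), c(-0.6, 1, 0),
                          c(-0.6, -1, 0)))
  expect_error(surrogate_substitute(boron, ANI2X_ELEMENTS), "B")
})

test_that("restored coordinates are the optimized ones, symbols only change", {
  mol <- toy_library()$bromoaniline
  sub <- surrogate_substitute(mol, ANI2X_ELEMENTS)
  opt <- soft_optimize(sub$mol, toy_backend(), 50L)
  back <- restore_substitutions(opt$mol, sub$map)
  expect_identical(back$coords, opt$mol$coords)
  expect_identical(back$elements, mol$elements)
  bad_map <- sub$map
  bad_map$atom_index <- 99L
  expect_error(restore_substitutions(opt$mol, bad_map), "out of range")
})

test_that("soft optimization relaxes a stretched diatomic toward equilibrium", {
  d0 <- sum(covalent_radius(c("C", "C")))
  stretched <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(2 * d0, 0, 0)),
                        bonds = data.frame(i = 1L, j = 2L, order = 1))
  res <- soft_optimize(stretched, toy_backend(), 50L)
  d <- sqrt(sum((res$mol$coords[1L, ] - res$mol$coords[2L, ])^2))
  expect_equal(d, d0, tolerance = 0.05 * d0)
  expect_lt(res$energy, toy_backend()$energy(stretched))

  # fixed point: re-minimizing barely moves the energy
  res2 <- soft_optimize(res$mol, toy_backend(), 50L)
  expect_lte(abs(res2$energy - res$energy), 1e-6)

  # step cap zero returns the input with its single-point energy
  res0 <- soft_optimize(stretched, toy_backend(), 0L)
  expect_identical(res0$mol$coords, stretched$coords)
  expect_equal(res0$energy, toy_backend()$energy(stretched))
})

test_that("refinement never raises the energy of any fixture model", {
  backend <- toy_backend()
  lib <- toy_library()
  for (nm in c("glycine", "acetic_acid", "imidazole")) {
    for (mode in c("[M+H]+", "[M-H]-")) {
      models <- tryCatch(enumerate_models(lib[[nm]], mode),
                         error = function(e) list())
      for (m in models) {
        e0 <- backend$energy(m$geometry)
        res <- soft_optimize(m$geometry, backend, 50L)
        expect_lte(res$energy, e0 + 1e-9)
      }
    }
  }
  expect_error(soft_optimize(lib$bromoaniline, backend), "Br")
})

test_that("final ranking normalizes REs and breaks ties by initial rank", {
  mk <- function(e, r) list(refined_energy = e, initial_rank_r = r,
                            parent_name = "x", cba_index = r)
  ranked <- final_rank(list(mk(-103.0, 1L), mk(-105.2, 2L)))
  expect_equal(sapply(ranked, function(m) m$refined_re), c(0, 2.2),
               tolerance = 1e-9)
  expect_identical(sapply(ranked, function(m) m$final_rank_R), 1:2)
  expect_identical(ranked[[1L]]$initial_rank_r, 2L)

  one <- final_rank(list(mk(-50, 1L)))
  expect_identical(one[[1L]]$final_rank_R, 1L)
  expect_identical(one[[1L]]$refined_re, 0)

  tie <- final_rank(list(mk(-10, 2L), mk(-10, 1L)))
  expect_identical(tie[[1L]]$initial_rank_r, 1L)

  expect_error(final_rank(list(mk(NA_real_, 1L))), "unset")
})

test_that("mole fractions are Boltzmann populations", {
  expect_equal(mole_fractions(rep(0, 4)), rep(0.25, 4), tolerance = 1e-12)
  rt <- 1.98720425864e-3 * 298.15
  expect_equal(mole_fractions(c(0, rt * log(2))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  set.seed(2)
  re <- sort(c(0, runif(5, 0.1, 8)))
  x <- mole_fractions(re)
  expect_equal(sum(x), 1, tolerance = 1e-12)
  expect_true(all(diff(x) < 0))          # strictly decreasing in RE
  expect_true(all(x > 0))
  # temperature dependence: hotter flattens the distribution
  expect_gt(mole_fractions(c(0, 2), temperature = 1000)[2L],
            mole_fractions(c(0, 2), temperature = 200)[2L])
  expect_error(mole_fractions(numeric(0)), "non-empty")
  expect_error(mole_fractions(c(1, 2)), "minimum 0")
})

test_that("the Open Babel backend yields finite energies and descends", {
  backend <- openbabel_backend("UFF")
  w <- toy_library()$water
  e0 <- backend$energy(w)
  expect_true(is.finite(e0))
  stretched <- w
  stretched$coords[2L, ] <- stretched$coords[2L, ] * 1.6
  res <- soft_optimize(stretched, backend, 50L)
  expect_lte(res$energy, backend$energy(stretched))
})
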