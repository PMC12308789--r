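# Potential backends. The classical harmonic backend is fully
# deterministic and dependency-free; the Open Babel backend wraps the
# obabel/obenergy command-line tools when a classical force field with
# full atom typing is wanted. Both deliberately share the element set of
# the ANI-2x neural potential (H, C, N, O, F, Cl, S) so that surrogate
# substitution is exercised the same way a neural backend would require.

ANI2X_ELEMENTS <- c("H", "C", "N", "O", "F", "Cl", "S")

# Energy of the harmonic toy potential: harmonic springs on the perceived
# bond topology (equilibrium length = covalent-radius sum) plus a steep
# pairwise repulsion between non-bonded atoms. Element-dependent through
# the radii, so swapping an element changes the energy surface.
.toy_terms <- function(mol) {
  n <- n_atoms(mol)
  r <- covalent_radius(mol$elements)
  b <- mol$bonds
  bonded <- matrix(FALSE, n, n)
  if (nrow(b) > 0L) {
    bonded[cbind(b$i, b$j)] <- TRUE
    bonded[cbind(b$j, b$i)] <- TRUE
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(bi = b$i, bj = b$j, d0 = r[b$i] + r[b$j],
       ni = pairs[!bonded[pairs], 1L], nj = pairs[!bonded[pairs], 2L],
       sig = outer(r, r, "+"))
}

.toy_energy_grad <- function(x, terms, k_bond = 300, k_rep = 0.5) {
  n <- length(x) / 3L
  xyz <- matrix(x, n, 3L)
  grad <- matrix(0, n, 3L)
  e <- 0
  if (length(terms$bi) > 0L) {
    dv <- xyz[terms$bi, , drop = FALSE] - xyz[terms$bj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    stretch <- d - terms$d0
    e <- e + sum(k_bond * stretch^2)
    f <- 2 * k_bond * stretch / pmax(d, 1e-12)
    g <- dv * f
    for (k in seq_along(terms$bi)) {
      grad[terms$bi[k], ] <- grad[terms$bi[k], ] + g[k, ]
      grad[terms$bj[k], ] <- grad[terms$bj[k], ] - g[k, ]
    }
  }
  if (length(terms$ni) > 0L) {
    dv <- xyz[terms$ni, , drop = FALSE] - xyz[terms$nj, , drop = FALSE]
    d2 <- rowSums(dv^2)
    s <- terms$sig[cbind(terms$ni, terms$nj)]
    # purely repulsive (s^2/d^2)^6 wall keeping non-bonded atoms apart
    ratio6 <- (s^2 / pmax(d2, 1e-12))^6
    e <- e + sum(k_rep * ratio6)
    f <- -12 * k_rep * ratio6 / pmax(d2, 1e-12)
    g <- dv * f
    for (k in seq_along(terms$ni)) {
      grad[terms$ni[k], ] <- grad[terms$ni[k], ] + g[k, ]
      grad[terms$nj[k], ] <- grad[terms$nj[k], ] - g[k, ]
    }
  }
  list(energy = e, grad = as.numeric(grad))
}

#' Deterministic classical toy backend
#'
#' A harmonic bond-spring potential with a steep non-bonded repulsion,
#' minimized by L-BFGS with a hard iteration cap. It has no physical
#' pretension beyond a well-defined, element-dependent energy surface with
#' a minimum near standard covalent geometry; it exists so the whole
#' refinement stage can run deterministically with no external model
#' weights. Energies are reported in kcal/mol.
#'
#' @param supported_elements element set the backend advertises; defaults
#'   to the ANI-2x set so surrogate substitution is exercised.
#' @param k_bond bond force constant, kcal/mol/A^2.
#' @param k_rep non-bonded repulsion prefactor, kcal/mol.
#' @return a `potential_backend`.
#' @export
toy_backend <- function(supported_elements = ANI2X_ELEMENTS, k_bond = 300,
                        k_rep = 0.5) {
  energy <- function(mol) {
    terms <- .toy_terms(mol)
    .toy_energy_grad(as.numeric(mol$coords), terms, k_bond, k_rep)$energy
  }
  minimize <- function(mol, max_steps) {
    terms <- .toy_terms(mol)
    fn <- function(x) .toy_energy_grad(x, terms, k_bond, k_rep)$energy
    gr <- function(x) .toy_energy_grad(x, terms, k_bond, k_rep)$grad
    res <- stats::optim(as.numeric(mol$coords), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_steps, factr = 1e4))
    out <- mol
    out$coords <- matrix(res$par, n_atoms(mol), 3L)
    list(mol = out, energy = res$value)
  }
  potential_backend("toy-harmonic", supported_elements, energy, minimize)
}

#' Open Babel force-field backend
#'
#' Wraps the `obenergy`/`obabel` command-line tools to provide MMFF94 (or
#' UFF) single-point energies and bounded conjugate-gradient minimization.
#' Deterministic for a fixed input geometry. Requires Open Babel on PATH.
#'
#' @param forcefield `"MMFF94"` or `"UFF"`.
#' @param supported_elements advertised element set; defaults to the
#'   ANI-2x set for parity with the other backends.
#' @return a `potential_backend`.
#' @export
openbabel_backend <- function(forcefield = "MMFF94",
                              supported_elements = ANI2X_ELEMENTS) {
  obabel <- Sys.which("obabel")
  obenergy <- Sys.which("obenergy")
  if (!nzchar(obabel) || !nzchar(obenergy)) {
    stop("Open Babel (obabel/obenergy) not found on PATH", call. = FALSE)
  }
  read_energy <- function(path) {
    out <- suppressWarnings(system2(obenergy, c("-ff", forcefield, path),
                                    stdout = TRUE, stderr = TRUE))
    line <- grep("TOTAL ENERGY", out, value = TRUE)
    if (length(line) == 0L) return(NA_real_)
    val <- as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", line[1L]))
    if (grepl("kJ", line[1L])) val <- val / 4.184
    val
  }
  energy <- function(mol) {
    tmp <- tempfile(fileext = ".xyz")
    on.exit(unlink(tmp))
    write_xyz(mol, tmp, "single point")
    read_energy(tmp)
  }
  minimize <- function(mol, max_steps) {
    tin <- tempfile(fileext = ".xyz"); tout <- tempfile(fileext = ".xyz")
    on.exit(unlink(c(tin, tout)))
    write_xyz(mol, tin, "pre-optimization")
    suppressWarnings(system2(
      obabel, c(tin, "-O", tout, "--minimize", "--ff", forcefield,
                "--steps", max_steps), stdout = FALSE, stderr = FALSE))
    if (!file.exists(tout) || file.size(tout) == 0) {
      return(list(mol = mol, energy = NA_real_))
    }
    relaxed <- read_xyz(tout, mol$name)
    out <- mol
    out$coords <- relaxed$coords
    list(mol = out, energy = read_energy(tout))
  }
  potential_backend(paste0("openbabel-", forcefield), supported_elements,
                    energy, minimize)
}

#' Look up a backend by name
#'
#' @param name `"toy"` or `"openbabel"`.
#' @return a `potential_backend`.
#' @export
get_backend <- function(name = c("toy", "openbabel")) {
  name <- match.arg(name)
  switch(name, toy = toy_backend(), openbabel = openbabel_backend())
}
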