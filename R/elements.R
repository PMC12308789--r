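# Element property tables, snapshotted so results never drift with
# dependency versions. Coverage is the organic/MS-relevant set the
# pipeline supports; anything else raises a configuration error.

# IUPAC 2021 standard atomic weights (abridged), g/mol
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403, Na = 22.98977, Si = 28.085, P = 30.973762, S = 32.06,
  Cl = 35.45, K = 39.0983, Se = 78.971, Br = 79.904, I = 126.90447
)

# Cordero et al. covalent radii, Angstrom (C sp3)
.COVALENT_RADIUS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, Na = 1.66, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, K = 2.03, Se = 1.20, Br = 1.20, I = 1.39
)

# Bondi van der Waals radii (Alvarez values where Bondi is absent), Angstrom
.VDW_RADIUS <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
  F = 1.47, Na = 2.27, Si = 2.10, P = 1.80, S = 1.80,
  Cl = 1.75, K = 2.75, Se = 1.90, Br = 1.85, I = 1.98
)

# Pauling electronegativities
.ELECTRONEGATIVITY <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44,
  F = 3.98, Na = 0.93, Si = 1.90, P = 2.19, S = 2.58,
  Cl = 3.16, K = 0.82, Se = 2.55, Br = 2.96, I = 2.66
)

# Static atomic dipole polarizabilities, Angstrom^3
# (2018 Table of recommended values, converted from atomic units)
.POLARIZABILITY <- c(
  H = 0.6668, B = 3.04, C = 1.760, N = 1.100, O = 0.802,
  F = 0.557, Na = 24.11, Si = 5.53, P = 3.63, S = 2.90,
  Cl = 2.18, K = 42.9, Se = 3.77, Br = 3.05, I = 5.35
)

.HALOGENS <- c("F", "Cl", "Br", "I")
.OTHERGENS <- c("S", "P", "Se")

.element_lookup <- function(table, elements, what) {
  vals <- table[elements]
  if (anyNA(vals)) {
    bad <- unique(elements[is.na(vals)])
    stop(sprintf("no tabulated %s for element(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  unname(vals)
}

#' Standard atomic masses
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in g/mol.
#' @export
atomic_mass <- function(elements) {
  .element_lookup(.ATOMIC_MASS, elements, "atomic mass")
}

#' Covalent radii (Cordero compilation)
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(elements) {
  .element_lookup(.COVALENT_RADIUS, elements, "covalent radius")
}

#' Van der Waals radii
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements) {
  .element_lookup(.VDW_RADIUS, elements, "van der Waals radius")
}

#' Pauling electronegativities
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of electronegativity values (dimensionless).
#' @export
electronegativity <- function(elements) {
  .element_lookup(.ELECTRONEGATIVITY, elements, "electronegativity")
}
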