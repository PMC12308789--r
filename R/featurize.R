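# The ten steric/electronic descriptors that tether a charge-state model's
# 3D identity to its relative-energy label.

#' Feature schema
#'
#' The fixed, ordered names of the ten descriptors used for training and
#' prediction.
#'
#' @return character vector of length 10.
#' @export
feature_schema <- function() {
  c("cba_polarizability", "dist_cba_com", "dist_cba_coe", "dist_com_coe",
    "interaction_angle", "msa", "n_oxygen", "n_nitrogen", "n_halogen",
    "n_othergen")
}

#' Center of electronegativity
#'
#' The electronegativity-weighted mean position: `COE = sum(e_i r_i) / E`
#' with Pauling electronegativities `e_i` and `E` their molecular sum. The
#' COE tracks where electron density concentrates and so correlates with
#' preferred protonation targets.
#'
#' @param mol a `molecule`.
#' @return numeric length-3 vector in Angstrom.
#' @export
compute_coe <- function(mol) {
  e <- electronegativity(mol$elements)
  as.numeric(crossprod(mol$coords, e) / sum(e))
}

#' Interaction angle
#'
#' The angle, in degrees, at the center of electronegativity between the
#' rays COE->COM and COE->CBA. If either ray is shorter than 1e-8 Angstrom
#' the geometry is degenerate and 0 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param com,coe,cba numeric length-3 positions.
#' @return angle in `[0, 180]` degrees.
#' @export
interaction_angle <- function(com, coe, cba) {
  u <- com - coe
  v <- cba - coe
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  if (lu < 1e-8 || lv < 1e-8) {
    return(structure(0, degenerate = TRUE))
  }
  # atan2 form: well-conditioned even for near-collinear rays
  atan2(sqrt(sum(.cross3(u, v)^2)), sum(u * v)) * 180 / pi
}

# Deterministic golden-spiral unit sphere template.
.sphere_dots <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Local orthonormal frame for atom i, built from its neighbours ordered by
# (rounded distance, index): first axis toward the nearest atom, second
# from the first non-collinear one. Equivariant under rigid motion —
# frame_i(R x + t) == R frame_i(x) — so a dot template expressed in these
# frames makes the discretized surface area exactly invariant under rigid
# motion rather than invariant only in the many-dot limit. Atoms whose
# whole environment is collinear fall back to an arbitrary perpendicular,
# where burial is axisymmetric and the choice cannot matter.
.local_frame <- function(coords, i) {
  n <- nrow(coords)
  rel <- coords[-i, , drop = FALSE] -
    matrix(coords[i, ], n - 1L, 3L, byrow = TRUE)
  d <- sqrt(rowSums(rel^2))
  ord <- order(round(d, 6L), seq_len(n - 1L))
  e1 <- rel[ord[1L], ] / d[ord[1L]]
  e2 <- NULL
  for (k in ord[-1L]) {
    perp <- rel[k, ] - sum(rel[k, ] * e1) * e1
    pn <- sqrt(sum(perp^2))
    if (pn > 1e-6) { e2 <- perp / pn; break }
  }
  if (is.null(e2)) {
    ref <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- .cross3(e1, ref)
    e2 <- e2 / sqrt(sum(e2^2))
  }
  cbind(e1, e2, .cross3(e1, e2))
}

#' Molecular surface area (solvent-accessible)
#'
#' Shrake-Rupley numerical SASA: each atom's van der Waals sphere is
#' inflated by the probe radius and sampled with a deterministic
#' golden-spiral dot template; dots falling inside any neighbouring
#' inflated sphere are buried, and each surviving dot contributes its share
#' of that sphere's area. The template is expressed per atom in a local
#' frame anchored to the atom's neighbour geometry, so the discretized
#' area is exactly invariant under rigid motion of the input.
#'
#' @param mol a `molecule`.
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_dots dots per atom (>= 960 for the production descriptor).
#' @return surface area in Angstrom^2.
#' @export
molecular_surface_area <- function(mol, probe = 1.4, n_dots = 960L) {
  n <- n_atoms(mol)
  radii <- vdw_radius(mol$elements) + probe
  if (n == 1L) return(4 * pi * radii[1L]^2)
  template <- .sphere_dots(n_dots)
  total <- 0
  d2 <- as.matrix(stats::dist(mol$coords))^2
  for (i in seq_len(n)) {
    # neighbours whose inflated spheres can bury dots of atom i
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    pts <- template %*% t(.local_frame(mol$coords, i)) * radii[i] +
      matrix(mol$coords[i, ], n_dots, 3L, byrow = TRUE)
    exposed <- rep(TRUE, n_dots)
    for (j in nb) {
      dj <- pts - matrix(mol$coords[j, ], n_dots, 3L, byrow = TRUE)
      exposed <- exposed & (rowSums(dj^2) > radii[j]^2)
      if (!any(exposed)) break
    }
    total <- total + 4 * pi * radii[i]^2 * sum(exposed) / n_dots
  }
  total
}

#' Heteroatom counts
#'
#' @param mol a `molecule`.
#' @return named integer vector: `n_oxygen`, `n_nitrogen`, `n_halogen`
#'   (F, Cl, Br, I), `n_othergen` (S, P, Se).
#' @export
element_counts <- function(mol) {
  el <- mol$elements
  c(n_oxygen = sum(el == "O"), n_nitrogen = sum(el == "N"),
    n_halogen = sum(el %in% .HALOGENS), n_othergen = sum(el %in% .OTHERGENS))
}

#' Static atomic dipole polarizability of an element
#'
#' @param element a single element symbol.
#' @return polarizability in Angstrom^3.
#' @export
cba_polarizability <- function(element) {
  .element_lookup(.POLARIZABILITY, element, "atomic polarizability")
}

#' Featurize a charge-state model
#'
#' Computes the full 10-descriptor vector from the model's charged
#' geometry: CBA polarizability, the CBA-COM, CBA-COE and COM-COE
#' distances, the interaction angle, the molecular surface area, and the
#' four heteroatom counts. All descriptors are invariant under rigid
#' motion.
#'
#' @param model a charge-state model from [enumerate_models()].
#' @param n_dots surface dot density passed to [molecular_surface_area()].
#' @return named numeric vector following [feature_schema()].
#' @export
featurize <- function(model, n_dots = 960L) {
  geom <- model$geometry
  cba <- geom$coords[model$cba_index, ]
  com <- center_of_mass(geom)
  coe <- compute_coe(geom)
  counts <- element_counts(geom)
  out <- c(
    cba_polarizability = cba_polarizability(geom$elements[model$cba_index]),
    dist_cba_com = sqrt(sum((cba - com)^2)),
    dist_cba_coe = sqrt(sum((cba - coe)^2)),
    dist_com_coe = sqrt(sum((com - coe)^2)),
    interaction_angle = as.numeric(interaction_angle(com, coe, cba)),
    msa = molecular_surface_area(geom, n_dots = n_dots),
    counts
  )
  stopifnot(identical(names(out), feature_schema()))
  out
}

# --- training-table serialization ---------------------------------------

#' Write a training table to CSV
#'
#' Schema: the ten feature columns of [feature_schema()], then `re_label`
#' (kcal/mol, per-system minimum zero) and `system_id`.
#'
#' @param table training-table data.frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_training_table <- function(table, path) {
  validate_training_table(table)
  utils::write.csv(table[, c(feature_schema(), "re_label", "system_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a training table from CSV
#'
#' @param path CSV path written by [write_training_table()].
#' @return validated training-table data.frame.
#' @export
read_training_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_training_table(tab)
  tab
}

#' Validate a training table
#'
#' Checks the column schema, that labels are non-negative, and that each
#' system's minimum relative-energy label is zero (RE is defined relative
#' to the per-system minimum).
#'
#' @param table data.frame to check.
#' @param tol tolerance on the per-system minimum.
#' @return `table`, invisibly.
#' @export
validate_training_table <- function(table, tol = 1e-9) {
  need <- c(feature_schema(), "re_label", "system_id")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    stop(sprintf("training table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(table$re_label < -tol)) {
    stop("re_label must be non-negative", call. = FALSE)
  }
  mins <- tapply(table$re_label, table$system_id, min)
  if (any(abs(mins) > tol)) {
    stop("each system's minimum re_label must be 0", call. = FALSE)
  }
  invisible(table)
}
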