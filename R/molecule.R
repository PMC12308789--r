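#' Construct a molecule
#'
#' The unit every pipeline stage consumes and produces: element symbols,
#' Cartesian coordinates in Angstrom, a net formal charge and a bond list.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param formal_charge integer net charge; must be -1, 0 or +1.
#' @param bonds data.frame with integer columns `i`, `j` (1-based atom
#'   indices) and numeric `order`, or NULL to perceive bonds from
#'   interatomic distances (covalent-radius sum times 1.25).
#' @param name text label carried through to output files.
#' @return an object of class `molecule`.
#' @export
molecule <- function(elements, coords, formal_charge = 0L, bonds = NULL,
                     name = "molecule") {
  elements <- as.character(elements)
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (length(elements) == 0L) {
    stop("molecule must contain at least one atom", call. = FALSE)
  }
  if (nrow(coords) != length(elements)) {
    stop(sprintf("element count (%d) and coordinate rows (%d) differ",
                 length(elements), nrow(coords)), call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  formal_charge <- as.integer(formal_charge)
  if (!formal_charge %in% c(-1L, 0L, 1L)) {
    stop("formal_charge must be -1, 0 or +1", call. = FALSE)
  }
  atomic_mass(elements)  # errors early on unknown symbols
  mol <- structure(
    list(name = name, elements = elements, coords = unname(coords),
         formal_charge = formal_charge, bonds = NULL),
    class = "molecule")
  mol$bonds <- if (is.null(bonds)) perceive_bonds(mol) else validate_bonds(bonds, length(elements))
  mol
}

validate_bonds <- function(bonds, n_atoms) {
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$order <- as.numeric(bonds$order)
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n_atoms | bonds$j < 1L | bonds$j > n_atoms)) {
      stop("bond indices out of range", call. = FALSE)
    }
    if (any(bonds$i == bonds$j)) {
      stop("bond endpoints must be distinct", call. = FALSE)
    }
    # canonical i < j ordering, sorted, for determinism
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  bonds[, c("i", "j", "order")]
}

#' Perceive bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below 1.25 times the sum of
#' their covalent radii. All perceived bonds carry order 1.
#'
#' @param mol a `molecule`.
#' @param tol multiplicative tolerance on the covalent-radius sum.
#' @return bond data.frame with columns `i`, `j`, `order`.
#' @export
perceive_bonds <- function(mol, tol = 1.25) {
  n <- length(mol$elements)
  if (n < 2L) {
    return(data.frame(i = integer(), j = integer(), order = numeric()))
  }
  r <- covalent_radius(mol$elements)
  d <- as.matrix(stats::dist(mol$coords))
  cutoff <- outer(r, r, "+") * tol
  hit <- which(d > 1e-6 & d <= cutoff & upper.tri(d), arr.ind = TRUE)
  bonds <- data.frame(i = as.integer(hit[, 1L]), j = as.integer(hit[, 2L]),
                      order = rep(1, nrow(hit)))
  validate_bonds(bonds, n)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%s), charge %+d, %d bonds\n",
              x$name, length(x$elements),
              paste(names(sort(-table(x$elements))), collapse = ","),
              x$formal_charge, nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: first line the atom count, second a comment, then one
#' `element x y z` record per atom. Bonds are perceived from distances.
#'
#' @param path path to an XYZ file.
#' @param name molecule name; defaults to the file stem.
#' @return a `molecule`.
#' @export
read_xyz <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    stop(sprintf("%s: not an XYZ file (fewer than 3 lines)", path), call. = FALSE)
  }
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop(sprintf("%s line 1: atom count expected, got '%s'", path, lines[1L]),
         call. = FALSE)
  }
  records <- lines[-(1:2)]
  records <- records[nzchar(trimws(records))]
  if (length(records) < n) {
    stop(sprintf("%s: header declares %d atoms but only %d records follow",
                 path, n, length(records)), call. = FALSE)
  }
  records <- records[seq_len(n)]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    parts <- strsplit(trimws(records[k]), "[[:space:]]+")[[1L]]
    if (length(parts) < 4L) {
      stop(sprintf("%s line %d: expected 'El x y z'", path, k + 2L), call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("%s line %d: non-numeric coordinate", path, k + 2L), call. = FALSE)
    }
    elements[k] <- parts[1L]
    coords[k, ] <- xyz
  }
  if (anyNA(.ATOMIC_MASS[elements])) {
    bad <- which(is.na(.ATOMIC_MASS[elements]))[1L]
    stop(sprintf("%s line %d: unknown element symbol '%s'",
                 path, bad + 2L, elements[bad]), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  molecule(elements, coords, 0L, NULL, name)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a `molecule` with at least one atom.
#' @param path destination path.
#' @param comment text for the XYZ comment line (rank/energy metadata).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  if (n_atoms(mol) == 0L) {
    stop("refusing to write a 0-atom XYZ file", call. = FALSE)
  }
  comment <- gsub("[\r\n]", " ", comment)
  recs <- sprintf("%-2s %12.6f %12.6f %12.6f",
                  mol$elements, mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L])
  ok <- tryCatch({
    writeLines(c(sprintf("%d", n_atoms(mol)), comment, recs), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write XYZ to %s: %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

#' Mass-weighted center of a molecule
#'
#' @param mol a `molecule` with at least one atom.
#' @return numeric length-3 vector, the center of mass in Angstrom.
#' @export
center_of_mass <- function(mol) {
  m <- atomic_mass(mol$elements)
  as.numeric(crossprod(mol$coords, m) / sum(m))
}

# Apply a rigid transform (used by tests and proton placement geometry).
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  mol$coords <- mol$coords %*% t(rotation) +
    matrix(translation, n_atoms(mol), 3L, byrow = TRUE)
  mol
}

# Indices of atoms bonded to atom `idx`.
bonded_to <- function(mol, idx) {
  b <- mol$bonds
  sort(c(b$j[b$i == idx], b$i[b$j == idx]))
}
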