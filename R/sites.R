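# Titratable-site perception and charge-state model generation.
#
# Only N and O sites are considered: the gas-phase protomers seen in
# routine IM-MS experiments of biomolecules and drug-like molecules
# overwhelmingly carry their charge on nitrogen or oxygen, and carbon
# (de)protonation is out of scope.

# --- topological equivalence --------------------------------------------

# Weisfeiler-Lehman (Morgan) color refinement. Two atoms receive the same
# final color iff they are topologically equivalent on molecular graphs of
# this size. Initial color: element, degree, bond-order sum, hydrogen count.
wl_atom_classes <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  nbrs <- vector("list", n)
  ordsum <- numeric(n)
  nh <- integer(n)
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]; o <- b$order[k]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
    ordsum[i] <- ordsum[i] + o; ordsum[j] <- ordsum[j] + o
    if (mol$elements[j] == "H") nh[i] <- nh[i] + 1L
    if (mol$elements[i] == "H") nh[j] <- nh[j] + 1L
  }
  col <- paste(mol$elements, lengths(nbrs), ordsum, nh, sep = "|")
  col <- match(col, sort(unique(col)))
  for (round in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i) {
      paste(col[i], paste(sort(col[nbrs[[i]]]), collapse = ","), sep = ":")
    }, character(1L))
    new_col <- match(sig, sort(unique(sig)))
    if (identical(new_col, col)) break
    col <- new_col
  }
  col
}

# --- site perception -----------------------------------------------------

#' Find titratable N/O sites
#'
#' In protonation mode every nitrogen or oxygen with an available lone pair
#' is a site: nitrogens already carrying four bonds (quaternary) and
#' nitro-group nitrogens are excluded, as are oxygens with a bond-order sum
#' of three or more. Amide N and O are both kept. In deprotonation mode
#' every N-H or O-H group is a site, with the acidic hydrogen recorded.
#' Sites that are topologically equivalent by graph symmetry (for example
#' the two amine nitrogens of ethylenediamine) are collapsed to the
#' lowest-index representative. Order is ascending atom index.
#'
#' @param mol a neutral `molecule` with perceived bonds.
#' @param mode `"protonation"` or `"deprotonation"`.
#' @param collapse_equivalent collapse graph-symmetric sites (default TRUE).
#' @return data.frame with columns `atom_index`, `element`, `mode`,
#'   `acidic_h_index` (NA in protonation mode).
#' @export
find_titratable_sites <- function(mol, mode = c("protonation", "deprotonation"),
                                  collapse_equivalent = TRUE) {
  mode <- match.arg(mode)
  n <- n_atoms(mol)
  cand <- which(mol$elements %in% c("N", "O"))
  b <- mol$bonds
  ordsum <- numeric(n)
  for (k in seq_len(nrow(b))) {
    ordsum[b$i[k]] <- ordsum[b$i[k]] + b$order[k]
    ordsum[b$j[k]] <- ordsum[b$j[k]] + b$order[k]
  }
  keep <- integer(0)
  acidic_h <- integer(0)
  for (a in cand) {
    nb <- bonded_to(mol, a)
    el <- mol$elements[a]
    if (mode == "protonation") {
      deg <- length(nb)
      if (el == "N") {
        if (deg >= 4L || ordsum[a] >= 4) next   # quaternary / hypervalent
        # nitro N: three heavy neighbours of which >= 2 are terminal oxygens
        term_o <- sum(mol$elements[nb] == "O" &
                        vapply(nb, function(x) length(bonded_to(mol, x)) == 1L,
                               logical(1L)))
        if (term_o >= 2L) next
      } else {  # O
        if (deg >= 3L || ordsum[a] >= 3) next   # oxonium-like
      }
      keep <- c(keep, a)
      acidic_h <- c(acidic_h, NA_integer_)
    } else {
      h <- nb[mol$elements[nb] == "H"]
      if (length(h) == 0L) next
      keep <- c(keep, a)
      acidic_h <- c(acidic_h, min(h))
    }
  }
  sites <- data.frame(atom_index = keep, element = mol$elements[keep],
                      mode = rep(mode, length(keep)),
                      acidic_h_index = acidic_h,
                      stringsAsFactors = FALSE)
  if (collapse_equivalent && nrow(sites) > 1L) {
    cls <- wl_atom_classes(mol)
    sites <- sites[!duplicated(cls[sites$atom_index]), , drop = FALSE]
  }
  sites <- sites[order(sites$atom_index), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# --- proton editing ------------------------------------------------------

# Equilibrium X-H placement distances, Angstrom
.XH_DIST <- c(N = 1.02, O = 0.98)

#' Add a proton at a titratable site
#'
#' The new hydrogen is placed 1.02 A (N) or 0.98 A (O) from the site atom,
#' opposite the normalized sum of the site's existing bond vectors, so it
#' points away from the substituents. A buried site whose bond-vector sum
#' nearly cancels falls back to a perpendicular direction. The proton is
#' appended at the end of the atom list and the net charge becomes +1.
#'
#' @param mol neutral parent `molecule`.
#' @param atom_index index of the N/O site to protonate.
#' @return a `molecule` with one more H and formal charge +1.
#' @export
place_proton <- function(mol, atom_index) {
  el <- mol$elements[atom_index]
  if (!el %in% c("N", "O")) {
    stop("protonation site must be N or O", call. = FALSE)
  }
  nb <- bonded_to(mol, atom_index)
  pos <- mol$coords[atom_index, ]
  if (length(nb) > 0L) {
    vecs <- mol$coords[nb, , drop = FALSE] -
      matrix(pos, length(nb), 3L, byrow = TRUE)
    lens <- sqrt(rowSums(vecs^2))
    dir <- -colSums(vecs / lens)
  } else {
    dir <- c(0, 0, 1)
  }
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-6) {
    # buried site: any perpendicular to the first bond vector
    ref <- if (length(nb) > 0L) {
      v <- mol$coords[nb[1L], ] - pos
      v / sqrt(sum(v^2))
    } else c(1, 0, 0)
    axis <- if (abs(ref[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    dir <- c(ref[2L] * axis[3L] - ref[3L] * axis[2L],
             ref[3L] * axis[1L] - ref[1L] * axis[3L],
             ref[1L] * axis[2L] - ref[2L] * axis[1L])
    nrm <- sqrt(sum(dir^2))
  }
  dir <- dir / nrm
  new_h <- pos + .XH_DIST[[el]] * dir
  n <- n_atoms(mol)
  bonds <- rbind(mol$bonds,
                 data.frame(i = atom_index, j = n + 1L, order = 1))
  molecule(c(mol$elements, "H"), rbind(mol$coords, new_h), +1L, bonds,
           mol$name)
}

#' Remove an acidic proton
#'
#' Deletes the given hydrogen; indices of later atoms shift down by one.
#' The net charge becomes -1.
#'
#' @param mol neutral parent `molecule`.
#' @param atom_index index of the N/O site losing the proton.
#' @param h_index index of the hydrogen to remove; must be bonded to
#'   `atom_index`.
#' @return a `molecule` with one fewer H and formal charge -1.
#' @export
remove_proton <- function(mol, atom_index, h_index) {
  if (mol$elements[h_index] != "H") {
    stop("h_index does not point at a hydrogen", call. = FALSE)
  }
  if (!h_index %in% bonded_to(mol, atom_index)) {
    stop("acidic hydrogen is not bonded to the site atom", call. = FALSE)
  }
  keep <- setdiff(seq_len(n_atoms(mol)), h_index)
  remap <- match(seq_len(n_atoms(mol)), keep)  # old index -> new index
  b <- mol$bonds
  b <- b[b$i != h_index & b$j != h_index, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE], -1L, b,
           mol$name)
}

# --- model enumeration ---------------------------------------------------

#' Enumerate charge-state models
#'
#' Generates exactly one singly protonated (`[M+H]+`) or deprotonated
#' (`[M-H]-`) structure per titratable site. Each model records its
#' charge-bearing atom (CBA) index in the edited structure's numbering.
#'
#' @param mol neutral `molecule`.
#' @param mode `"[M+H]+"` or `"[M-H]-"`.
#' @return list of charge-state models; each is a list with `parent_name`,
#'   `mode`, `cba_index`, `geometry` and unset ranking fields.
#' @export
enumerate_models <- function(mol, mode = c("[M+H]+", "[M-H]-")) {
  mode <- match.arg(mode)
  site_mode <- if (mode == "[M+H]+") "protonation" else "deprotonation"
  sites <- find_titratable_sites(mol, site_mode)
  if (nrow(sites) == 0L) {
    stop(sprintf(paste0("no titratable N/O sites found in '%s' for %s mode; ",
                        "the molecule is outside the supported chemistry"),
                 mol$name, mode), call. = FALSE)
  }
  lapply(seq_len(nrow(sites)), function(k) {
    a <- sites$atom_index[k]
    if (site_mode == "protonation") {
      geom <- place_proton(mol, a)
      cba <- a  # removal-free edit keeps indices stable
    } else {
      h <- sites$acidic_h_index[k]
      geom <- remove_proton(mol, a, h)
      cba <- if (a > h) a - 1L else a
    }
    stopifnot(geom$elements[cba] == sites$element[k])
    list(parent_name = mol$name, mode = mode, cba_index = cba,
         geometry = geom, predicted_re = NA_real_,
         refined_energy = NA_real_, initial_rank_r = NA_integer_,
         final_rank_R = NA_integer_, mole_fraction = NA_real_)
  })
}
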