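# Second-pass screen: a short "soft" geometry optimization of the
# forwarded models under a pluggable potential backend, followed by
# reranking on the refined energies and Boltzmann mole fractions.

R_KCAL <- 1.98720425864e-3  # gas constant, kcal/(mol K)

# Substitution rules for elements a limited-element potential cannot
# handle: the nearest supported neighbour element.
.SURROGATE_RULES <- c(Br = "Cl", I = "Cl", P = "S", Se = "S")

#' Construct a potential backend
#'
#' A backend bundles the element set it supports with a single-point
#' energy function and a bounded-step minimizer, both reporting kcal/mol.
#' Backends must be deterministic and their minimizer must never return an
#' energy above the input geometry's single-point energy.
#'
#' @param name backend label.
#' @param supported_elements character vector of supported element symbols.
#' @param energy function(mol) -> kcal/mol.
#' @param minimize function(mol, max_steps) -> list(mol, energy).
#' @return an object of class `potential_backend`.
#' @export
potential_backend <- function(name, supported_elements, energy, minimize) {
  structure(list(name = name, supported_elements = supported_elements,
                 energy = energy, minimize = minimize),
            class = "potential_backend")
}

#' @export
print.potential_backend <- function(x, ...) {
  cat(sprintf("<potential_backend> %s (elements: %s)\n", x$name,
              paste(x$supported_elements, collapse = " ")))
  invisible(x)
}

#' Substitute unsupported elements with surrogates
#'
#' Swaps each element the backend cannot handle for its closest supported
#' neighbour (Br, I -> Cl; P, Se -> S), recording the edits so they can be
#' reversed after optimization. Geometry is untouched.
#'
#' @param mol a `molecule`.
#' @param supported element symbols the backend supports.
#' @return list with `mol` (substituted) and `map` (data.frame of
#'   `atom_index`, `original_element`, `surrogate_element`).
#' @export
surrogate_substitute <- function(mol, supported) {
  el <- mol$elements
  todo <- which(!el %in% supported)
  bad <- todo[!el[todo] %in% names(.SURROGATE_RULES)]
  if (length(bad) > 0L) {
    stop(sprintf("element(s) %s are neither supported by the backend nor substitutable",
                 paste(unique(el[bad]), collapse = ", ")), call. = FALSE)
  }
  map <- data.frame(atom_index = todo,
                    original_element = el[todo],
                    surrogate_element = unname(.SURROGATE_RULES[el[todo]]),
                    stringsAsFactors = FALSE)
  if (nrow(map) > 0L) {
    sub_not_ok <- !map$surrogate_element %in% supported
    if (any(sub_not_ok)) {
      stop(sprintf("surrogate element(s) %s not supported by the backend",
                   paste(unique(map$surrogate_element[sub_not_ok]),
                         collapse = ", ")), call. = FALSE)
    }
    el[todo] <- map$surrogate_element
  }
  out <- mol
  out$elements <- el
  list(mol = out, map = map)
}

#' Restore substituted elements
#'
#' Reverses [surrogate_substitute()]: original element symbols come back,
#' the (optimized) coordinates are kept.
#'
#' @param mol the optimized, substituted `molecule`.
#' @param map substitution map from [surrogate_substitute()].
#' @return the `molecule` with original element symbols.
#' @export
restore_substitutions <- function(mol, map) {
  if (nrow(map) == 0L) return(mol)
  if (any(map$atom_index < 1L | map$atom_index > n_atoms(mol))) {
    stop("substitution map index out of range", call. = FALSE)
  }
  mol$elements[map$atom_index] <- map$original_element
  mol
}

#' Soft geometry optimization
#'
#' Runs at most `max_steps` minimizer iterations under the backend — a
#' deliberately short relaxation that cleans up the placed proton without
#' letting the structure wander into artifacts. `max_steps = 0` returns
#' the input unchanged with its single-point energy.
#'
#' @param mol a `molecule` whose elements the backend supports.
#' @param backend a `potential_backend`.
#' @param max_steps maximum minimizer iterations (default 50).
#' @return list with `mol` (relaxed) and `energy` (kcal/mol).
#' @export
soft_optimize <- function(mol, backend, max_steps = 50L) {
  stopifnot(inherits(backend, "potential_backend"))
  unsupported <- setdiff(unique(mol$elements), backend$supported_elements)
  if (length(unsupported) > 0L) {
    stop(sprintf("backend '%s' does not support element(s): %s",
                 backend$name, paste(unsupported, collapse = ", ")),
         call. = FALSE)
  }
  e0 <- backend$energy(mol)
  if (!is.finite(e0)) {
    stop(sprintf("backend '%s' returned a non-finite energy for '%s'",
                 backend$name, mol$name), call. = FALSE)
  }
  if (max_steps == 0L) return(list(mol = mol, energy = e0))
  res <- backend$minimize(mol, as.integer(max_steps))
  if (!is.finite(res$energy)) {
    stop(sprintf("optimization failed (non-finite energy) for '%s'",
                 mol$name), call. = FALSE)
  }
  if (res$energy > e0) return(list(mol = mol, energy = e0))
  res
}

#' Final ranking from refined energies
#'
#' Converts refined energies to relative energies `RE = E - min(E)`
#' (kcal/mol) and assigns the final rank R by ascending RE; the rank-1
#' model is the assigned major equilibrium charge state. Ties go to the
#' lower initial rank r.
#'
#' @param models charge-state models with `refined_energy` set.
#' @return the models ordered by `final_rank_R`, each with `refined_re`
#'   and `final_rank_R` set.
#' @export
final_rank <- function(models) {
  e <- vapply(models, function(m) {
    if (is.null(m$refined_energy) || is.na(m$refined_energy)) {
      stop("refined_energy unset; run soft_optimize first", call. = FALSE)
    }
    m$refined_energy
  }, numeric(1L))
  re <- e - min(e)
  r <- vapply(models, function(m) m$initial_rank_r, integer(1L))
  ord <- order(re, r)
  ranks <- integer(length(models))
  ranks[ord] <- seq_along(models)
  models <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    m$refined_re <- re[k]
    m$final_rank_R <- ranks[k]
    m
  })
  models[ord]
}

#' Boltzmann mole fractions
#'
#' Gas-phase equilibrium populations from relative energies:
#' `x_i = exp(-RE_i / RT) / sum_j exp(-RE_j / RT)`.
#'
#' @param relative_energies REs in kcal/mol, minimum exactly 0.
#' @param temperature temperature in kelvin.
#' @return numeric vector of fractions summing to 1.
#' @export
mole_fractions <- function(relative_energies, temperature = 298.15) {
  if (length(relative_energies) == 0L) {
    stop("relative_energies must be non-empty", call. = FALSE)
  }
  if (min(relative_energies) < -1e-9 ||
      abs(min(relative_energies)) > 1e-6) {
    stop("relative energies must be >= 0 with minimum 0", call. = FALSE)
  }
  w <- exp(-relative_energies / (R_KCAL * temperature))
  w / sum(w)
}
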