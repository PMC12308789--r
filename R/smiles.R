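#' Build a 3D structure from a SMILES string
#'
#' Embeds the molecule in 3D with RDKit's ETKDG distance-geometry method
#' (seeded, so runs are reproducible) and relaxes it with the MMFF94 force
#' field. The total number of force-field steps scales with molecular size:
#' `max(200, steps_per_atom * n_atoms)`, so small molecules still get a
#' full relaxation while larger, more flexible ones get proportionally more
#' work.
#'
#' @param smiles a SMILES string describing a neutral molecule.
#' @param seed integer seed for the 3D embedding.
#' @param steps_per_atom force-field steps per atom (>= 1).
#' @param name molecule name; defaults to the SMILES string.
#' @return a neutral `molecule` with RDKit-perceived bonds.
#' @export
parse_smiles_to_3d <- function(smiles, seed = 1L, steps_per_atom = 10L,
                               name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  steps_per_atom <- as.integer(steps_per_atom)
  if (is.na(steps_per_atom) || steps_per_atom < 1L) {
    stop("steps_per_atom must be >= 1", call. = FALSE)
  }
  helper <- system.file("python", "smiles_to_3d.py", package = "protomeR",
                        mustWork = TRUE)
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) stop("no python interpreter on PATH", call. = FALSE)

  # the helper knows the hydrogen-complete atom count, so it applies the
  # max(200, steps_per_atom * n_atoms) scaling itself
  res <- suppressWarnings(system2(
    python, c(shQuote(helper), shQuote(smiles), as.integer(seed),
              steps_per_atom),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L) {
    msg <- paste(res, collapse = " ")
    if (status == 2L) stop(sprintf("invalid SMILES '%s'", smiles), call. = FALSE)
    if (status == 3L) stop(sprintf("3D embedding failed for '%s'", smiles),
                           call. = FALSE)
    stop(sprintf("SMILES builder failed (%s): %s", smiles, msg), call. = FALSE)
  }
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyMatrix = TRUE)
  bonds <- as.data.frame(parsed$bonds)
  names(bonds) <- c("i", "j", "order")
  if (is.null(name)) name <- smiles
  fc <- as.integer(parsed$formal_charge)
  if (fc != 0L) {
    stop(sprintf("input SMILES must be neutral (net charge %+d)", fc),
         call. = FALSE)
  }
  molecule(parsed$elements, parsed$coords, 0L, bonds, name)
}
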