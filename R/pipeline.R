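# End-to-end orchestration: input -> enumerate -> featurize -> GBT rank ->
# capacity pruning -> surrogate substitution -> soft optimization ->
# restore -> final rank -> mole fractions -> report.

#' Pipeline configuration
#'
#' @param mode ion mode, `"[M+H]+"` or `"[M-H]-"`.
#' @param ranker a `ranker_model` or path to a [save_ranker()] bundle.
#' @param backend a `potential_backend` or a name for [get_backend()].
#' @param max_steps soft-optimization step cap (default 50).
#' @param temperature temperature for mole fractions, kelvin.
#' @param seed integer seed (3D embedding for SMILES input).
#' @param output_root directory under which `completed/<name>/` is
#'   created, or NULL to produce the report in memory only.
#' @param zip_output also bundle the output directory into a ZIP archive.
#' @param name molecule name override.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("[M+H]+", "[M-H]-"), ranker,
                            backend = "toy", max_steps = 50L,
                            temperature = 298.15, seed = 1L,
                            output_root = NULL, zip_output = FALSE,
                            name = NULL) {
  mode <- match.arg(mode)
  if (is.character(ranker)) ranker <- load_ranker(ranker)
  stopifnot(inherits(ranker, "ranker_model"))
  if (is.character(backend)) backend <- get_backend(backend)
  stopifnot(inherits(backend, "potential_backend"), max_steps >= 0L)
  structure(list(mode = mode, ranker = ranker, backend = backend,
                 max_steps = as.integer(max_steps),
                 temperature = temperature, seed = as.integer(seed),
                 output_root = output_root, zip_output = isTRUE(zip_output),
                 name = name),
            class = "pipeline_config")
}

.load_input <- function(input, config) {
  if (inherits(input, "molecule")) {
    mol <- input
  } else if (file.exists(input) && grepl("\\.xyz$", input, ignore.case = TRUE)) {
    mol <- read_xyz(input)
  } else {
    mol <- parse_smiles_to_3d(input, seed = config$seed)
  }
  if (!is.null(config$name)) {
    mol$name <- config$name
  } else {
    mol$name <- gsub("[^A-Za-z0-9._-]", "_", mol$name)
  }
  mol
}

#' Run the charge-state prediction pipeline
#'
#' Executes the full two-pass screen on one molecule: titratable-site
#' enumeration, per-model featurization and GBT relative-energy ranking
#' (initial rank r), acceptance-capacity pruning, surrogate substitution
#' and soft geometry optimization of the survivors, restoration, final
#' reranking (Rank R) on refined relative energies, and Boltzmann mole
#' fractions. When `config$output_root` is set, one XYZ per forwarded
#' model plus a human-readable summary and a JSON sidecar are written to
#' `output_root/completed/<name>/`.
#'
#' @param input a SMILES string, a path to an XYZ file, or a `molecule`.
#' @param config a `pipeline_config`.
#' @return a `job_report` (invisibly written to disk when requested).
#' @export
run_pipeline <- function(input, config) {
  stopifnot(inherits(config, "pipeline_config"))
  mol <- .load_input(input, config)

  models <- enumerate_models(mol, config$mode)
  ranked <- predict_and_rank(config$ranker, models)
  stats <- acceptance_capacity(
    config$ranker$training_rmse,
    vapply(ranked, function(m) m$predicted_re, numeric(1L)))
  forwarded <- select_models(ranked, stats)

  forwarded <- lapply(forwarded, function(m) {
    sub <- surrogate_substitute(m$geometry, config$backend$supported_elements)
    opt <- soft_optimize(sub$mol, config$backend, config$max_steps)
    m$geometry <- restore_substitutions(opt$mol, sub$map)
    m$refined_energy <- opt$energy
    m$n_substituted <- nrow(sub$map)
    m
  })
  forwarded <- final_rank(forwarded)
  fracs <- mole_fractions(
    vapply(forwarded, function(m) m$refined_re, numeric(1L)),
    config$temperature)
  forwarded <- lapply(seq_along(forwarded), function(k) {
    m <- forwarded[[k]]
    m$mole_fraction <- fracs[k]
    m
  })

  records <- data.frame(
    model_id = vapply(forwarded, function(m)
      sprintf("%s_cba%d", m$parent_name, m$cba_index), character(1L)),
    cba_element = vapply(forwarded, function(m)
      m$geometry$elements[m$cba_index], character(1L)),
    cba_index = vapply(forwarded, function(m) m$cba_index, integer(1L)),
    initial_rank_r = vapply(forwarded, function(m) m$initial_rank_r, integer(1L)),
    final_rank_R = vapply(forwarded, function(m) m$final_rank_R, integer(1L)),
    predicted_re = round(vapply(forwarded, function(m) m$predicted_re,
                                numeric(1L)), 6),
    refined_re = round(vapply(forwarded, function(m) m$refined_re,
                              numeric(1L)), 6),
    mole_fraction = round(vapply(forwarded, function(m) m$mole_fraction,
                                 numeric(1L)), 6),
    stringsAsFactors = FALSE)

  report <- structure(list(
    molecule_name = mol$name, mode = config$mode,
    n_enumerated = length(models),
    selection = list(rmse = round(stats$rmse, 6),
                     re_min = round(stats$re_min, 6),
                     sigma = round(stats$sigma, 6),
                     variance_s = round(stats$variance_s, 6),
                     capacity = round(stats$capacity, 6),
                     k_forwarded = length(forwarded)),
    models = records,
    provenance = list(seed = config$seed, backend = config$backend$name,
                      max_steps = config$max_steps,
                      temperature = config$temperature,
                      package_version =
                        as.character(utils::packageVersion("protomeR"))),
    geometries = lapply(forwarded, function(m) m$geometry)),
    class = "job_report")

  if (!is.null(config$output_root)) {
    dir <- file.path(config$output_root, "completed", mol$name)
    write_report(report, dir)
    if (config$zip_output) .zip_directory(dir)
  }
  report
}

#' @export
print.job_report <- function(x, ...) {
  cat(sprintf("<job_report> %s %s: %d site(s) enumerated, %d forwarded (capacity %.3f)\n",
              x$molecule_name, x$mode, x$n_enumerated,
              x$selection$k_forwarded, x$selection$capacity))
  print(x$models, row.names = FALSE)
  invisible(x)
}

# Sidecar view of a report: everything except geometries, timestamp-free
# so reruns are byte-identical.
.report_sidecar <- function(report) {
  report[c("molecule_name", "mode", "n_enumerated", "selection", "models",
           "provenance")]
}

#' Write a job report to a directory
#'
#' Produces `report.txt` (aligned human-readable summary), `report.json`
#' (machine-readable sidecar, timestamp-free so seeded reruns are
#' byte-identical) and one XYZ file per forwarded model named
#' `<name>_rank<R>_cba<idx>.xyz`, with rank and energy metadata on the
#' comment line.
#'
#' @param report a `job_report`.
#' @param dir destination directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "job_report"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot create output directory %s", dir), call. = FALSE)
  }
  files <- character(0)

  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(.report_sidecar(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, json_path)

  txt_path <- file.path(dir, "report.txt")
  hdr <- c(sprintf("Charge-state prediction report: %s (%s)",
                   report$molecule_name, report$mode),
           sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("sites enumerated: %d | capacity: %.3f | forwarded: %d",
                   report$n_enumerated, report$selection$capacity,
                   report$selection$k_forwarded),
           sprintf("ranker held-out RMSE: %.3f kcal/mol | backend: %s | T: %.2f K",
                   report$selection$rmse, report$provenance$backend,
                   report$provenance$temperature),
           "")
  tab <- utils::capture.output(print(report$models, row.names = FALSE))
  writeLines(c(hdr, tab), txt_path)
  files <- c(files, txt_path)

  for (k in seq_along(report$geometries)) {
    rec <- report$models[k, ]
    xyz_path <- file.path(dir, sprintf("%s_rank%d_cba%d.xyz",
                                       report$molecule_name,
                                       rec$final_rank_R, rec$cba_index))
    write_xyz(report$geometries[[k]], xyz_path,
              sprintf("%s %s Rank %d | RE %.4f kcal/mol | x %.4f",
                      report$molecule_name, report$mode, rec$final_rank_R,
                      rec$refined_re, rec$mole_fraction))
    files <- c(files, xyz_path)
  }
  invisible(files)
}

.zip_directory <- function(dir) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  zip_path <- paste0(normalizePath(dir), ".zip")
  status <- system2(python, c("-m", "zipfile", "-c", shQuote(zip_path),
                              shQuote(normalizePath(dir))),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) warning("ZIP bundling failed", call. = FALSE)
  invisible(zip_path)
}
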