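#' Pipeline configuration
#'
#' Assembles and validates the structured configuration driving
#' [run_pipeline()]. Either a simulated fixture (`preset = "mis18-core"` /
#' `"mis18-full"`) or explicit input paths (`subunits_dir`, `links`,
#' `chain_map`) must be given; referenced paths are checked at validation
#' time, before any compute.
#'
#' @param out_dir run directory (created; must not be an existing file).
#' @param seed integer seed used for every stochastic stage.
#' @param preset fixture preset name, or NULL when real inputs are given.
#' @param subunits_dir directory of per-subunit PDB files (NULL with preset).
#' @param links cross-link CSV path (NULL with preset).
#' @param chain_map chain-map JSON path (NULL with preset).
#' @param threshold cross-link satisfaction cutoff (Angstrom).
#' @param docking a [docking_params()] list.
#' @param assembly an [assembly_params()] list.
#' @param links_per_interface,decoy_fraction fixture-generation knobs
#'   (preset runs only).
#' @param saxs logical: also simulate a SAXS curve from the top model and
#'   fit the ground-truth profile against it (preset runs only).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, preset = "mis18-core",
                            subunits_dir = NULL, links = NULL,
                            chain_map = NULL, threshold = 22,
                            docking = docking_params(),
                            assembly = assembly_params(docking = docking),
                            links_per_interface = 8L, decoy_fraction = 0.1,
                            saxs = FALSE) {
  if (is.null(preset)) {
    for (p in list(subunits_dir = subunits_dir, links = links,
                   chain_map = chain_map)) {
      if (is.null(p)) stop("pipeline_config: without a preset, subunits_dir, ",
                           "links and chain_map are all required")
    }
    if (!dir.exists(subunits_dir))
      stop("pipeline_config: subunits_dir not found: ", subunits_dir)
    if (!file.exists(links))
      stop("pipeline_config: links file not found: ", links)
    if (!file.exists(chain_map))
      stop("pipeline_config: chain map not found: ", chain_map)
  } else if (!preset %in% c("mis18-core", "mis18-full")) {
    stop("pipeline_config: unknown preset '", preset, "'")
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), preset = preset,
              subunits_dir = subunits_dir, links = links,
              chain_map = chain_map, threshold = threshold,
              docking = docking, assembly = assembly,
              links_per_interface = as.integer(links_per_interface),
              decoy_fraction = decoy_fraction, saxs = isTRUE(saxs))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Scalar keys mirror the [pipeline_config()] arguments; `docking:` and
#' `assembly:` sub-maps override individual parameter defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: file not found: ", path)
  y <- yaml::read_yaml(path)
  dk <- do.call(docking_params, y$docking %||% list())
  as_args <- y$assembly %||% list()
  as_args$docking <- dk
  args <- y[setdiff(names(y), c("docking", "assembly"))]
  args$docking <- dk
  args$assembly <- do.call(assembly_params, as_args)
  do.call(pipeline_config, args)
}

#' Run the full docking / assembly / validation pipeline
#'
#' Executes: fixture simulation (preset runs) or input loading, per-edge
#' pairwise docking and hierarchical assembly via [assemble()], global
#' cross-link rescoring, satisfaction comparison across the ranked models,
#' and an optional SAXS self-consistency fit. Writes ranked model PDBs, a
#' per-link satisfaction CSV and JSON summary, and a machine-readable
#' manifest (input checksums, parameters, seed, package version, output
#' checksums). Deterministic given config and seed.
#'
#' @param config a [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @param max_models ranked models to write (default 5).
#' @return Invisibly, a list with `assemblies`, `reports`, `comparison`,
#'   `manifest`, and (preset runs) the `truth` fixture; all outputs are under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, max_models = 5L) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))
  manifest <- list(seed = config$seed, threshold = config$threshold,
                   package_version = as.character(utils::packageVersion("xlassemble")),
                   parameters = list(
                     docking = unclass(config$docking),
                     assembly = unclass(config$assembly[setdiff(
                       names(config$assembly), "docking")])))
  truth <- NULL
  if (!is.null(config$preset)) {
    log_line("simulate", paste("generating fixture", config$preset,
                               "seed", config$seed))
    truth <- make_mis18_mimic(config$seed,
                              scale = sub("mis18-", "", config$preset))
    sim <- simulate_crosslinks(truth,
                               links_per_interface = config$links_per_interface,
                               decoy_fraction = config$decoy_fraction,
                               seed = config$seed)
    pert <- perturb_subunits(truth, seed = config$seed)
    subunits <- pert$subunits
    links <- sim$links
    chain_map <- truth$chain_map
    fixture_dir <- file.path(config$out_dir, "fixture")
    write_fixture(truth, sim, fixture_dir)
    manifest$fixture <- list(preset = config$preset,
                             n_true = sim$n_true, n_decoy = sim$n_decoy)
    manifest$inputs <- checksum_dir(fixture_dir)
  } else {
    log_line("load", paste("reading inputs from", config$subunits_dir))
    pdbs <- sort(list.files(config$subunits_dir, "\\.pdb$", full.names = TRUE))
    if (!length(pdbs)) stop("run_pipeline: no PDB files in ", config$subunits_dir)
    subunits <- lapply(pdbs, read_structure)
    names(subunits) <- sub("\\.pdb$", "", basename(pdbs))
    links <- load_crosslinks(config$links)
    chain_map <- read_chain_map(config$chain_map)
    manifest$inputs <- as.list(tools::md5sum(c(pdbs, config$links,
                                               config$chain_map)))
  }
  log_line("assemble", sprintf("%d subunits, %d links", length(subunits),
                               nrow(links)))
  assemblies <- assemble(subunits, links, chain_map,
                         params = config$assembly,
                         threshold = config$threshold)
  if (!length(assemblies)) {
    manifest$status <- "no assembly survived"
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    warning("run_pipeline: no assembly produced; manifest written")
    return(invisible(list(assemblies = assemblies, manifest = manifest,
                          truth = truth)))
  }
  log_line("score", sprintf("%d ranked assemblies; top fraction %.3f",
                            length(assemblies),
                            assemblies[[1]]$global_fraction_satisfied))
  model_dir <- file.path(config$out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  n_out <- min(max_models, length(assemblies))
  reports <- list()
  for (i in seq_len(n_out)) {
    placed <- assembly_structure(assemblies[[i]], subunits)
    write_structure(placed, file.path(model_dir, sprintf("model_%02d.pdb", i)))
    reports[[sprintf("model_%02d", i)]] <-
      score_assembly(assemblies[[i]], subunits, links, chain_map,
                     config$threshold)
  }
  write_satisfaction(reports[[1]],
                     csv = file.path(config$out_dir, "satisfaction.csv"),
                     json = file.path(config$out_dir, "satisfaction.json"))
  comparison <- satisfaction_comparison(
    reports, csv = file.path(config$out_dir, "satisfaction_comparison.csv"))
  saxs_fit <- NULL
  if (config$saxs && !is.null(truth)) {
    log_line("saxs", "self-consistency fit of top model vs simulated curve")
    exp_curve <- simulate_saxs_curve(truth$structure, n_points = 300L,
                                     noise_scale = 0.5, seed = config$seed)
    top <- assembly_structure(assemblies[[1]], subunits)
    model_curve <- debye_profile(top, exp_curve$q)
    saxs_fit <- fit_scale_chi2(model_curve, exp_curve)
    jsonlite::write_json(unclass(saxs_fit),
                         file.path(config$out_dir, "saxs_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  # wall time deliberately excluded: summaries must be determinism-stable
  writeLines(c(
    sprintf("subunits: %d, links: %d", length(subunits), nrow(links)),
    sprintf("assemblies: %d; top fraction satisfied %.3f, clashes %d",
            length(assemblies), assemblies[[1]]$global_fraction_satisfied,
            assemblies[[1]]$total_clashes)),
    file.path(config$out_dir, "summary.txt"))
  manifest$status <- "ok"
  manifest$n_assemblies <- length(assemblies)
  manifest$top <- list(
    fraction_satisfied = assemblies[[1]]$global_fraction_satisfied,
    total_clashes = assemblies[[1]]$total_clashes,
    score = assemblies[[1]]$score)
  manifest$outputs <- checksum_dir(config$out_dir,
                                   exclude = "manifest\\.json$")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assemblies = assemblies, reports = reports,
                 comparison = comparison, saxs_fit = saxs_fit,
                 manifest = manifest, truth = truth,
                 subunits = subunits, links = links, chain_map = chain_map))
}

# md5 checksums of every regular file under dir (relative names, sorted)
checksum_dir <- function(dir, exclude = NULL) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  if (!is.null(exclude)) files <- files[!grepl(exclude, files)]
  sums <- tools::md5sum(files)
  names(sums) <- substring(files, nchar(dir) + 2L)
  as.list(sums)
}
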