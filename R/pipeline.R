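# End-to-end pipeline: generate (or ingest) -> redox -> hole -> converge ->
# report, for a set of duplex presets, with full provenance in the output
# directory.

#' Pipeline run configuration
#'
#' @param systems Character vector of duplex presets (or dinucleotides);
#'   default: all six presets.
#' @param generator A [generator_config()]; set to `NULL` when reading
#'   existing snapshot tables via `input_paths`.
#' @param input_paths Optional named list `system -> list(neutral =,
#'   cation =, coords_neutral =, coords_cation =)` of files to ingest
#'   instead of generating.
#' @param electrode A [reference_electrode()].
#' @param k_grid Cluster counts for the convergence scan (default `2:10`).
#' @param tolerances Convergence tolerances, see [convergence_scan()].
#' @param outdir Output directory (created if needed); `NULL` to skip all
#'   file output.
#' @param seed Run seed (defaults to the generator seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(systems = duplex_presets(),
                       generator = generator_config(),
                       input_paths = NULL,
                       electrode = reference_electrode(),
                       k_grid = 2:10,
                       tolerances = c(vie = 0.05, vae = 0.05, e_ox = 0.02,
                                      n_vie = 0.05, n_vae = 0.05),
                       outdir = NULL,
                       seed = NULL) {
  if (is.null(generator) && is.null(input_paths)) {
    stopf("either a generator config or input paths must be given")
  }
  if (is.null(seed)) seed <- if (!is.null(generator)) generator$seed else 1L
  structure(list(systems = systems, generator = generator,
                 input_paths = input_paths, electrode = electrode,
                 k_grid = as.integer(k_grid), tolerances = tolerances,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `generator` holds
#' [generator_config()] fields, `electrode` the SHE value.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator)) do.call(generator_config, y$generator)
    else if (is.null(y$input_paths)) generator_config() else NULL
  el <- if (!is.null(y$electrode)) do.call(reference_electrode, y$electrode)
    else reference_electrode()
  run_config(systems = y$systems %||% duplex_presets(),
             generator = gen, input_paths = y$input_paths,
             electrode = el,
             k_grid = y$k_grid %||% 2:10,
             tolerances = if (!is.null(y$tolerances)) unlist(y$tolerances) else
               c(vie = 0.05, vae = 0.05, e_ox = 0.02, n_vie = 0.05, n_vae = 0.05),
             outdir = y$outdir, seed = y$seed)
}

#' Run the full analysis pipeline
#'
#' For every configured system: obtain the neutral and cation trajectories
#' (synthetic generation or ingestion), compute the Marcus redox summary,
#' the hole-delocalization summaries of both trajectories, and the
#' clustering convergence report; optionally write per-system artifacts
#' (snapshot TSV, multi-model PDB, JSON manifest and results document) plus
#' a cross-system comparison table. Reruns with the same seed produce
#' byte-identical results documents.
#'
#' @param config A [run_config()].
#' @param verbose Emit one progress line per stage (default `TRUE`).
#' @return An object of class `dsredox_run`: per-system results and the
#'   comparison table.
#' @export
run_all <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, sysname, t0) {
    if (verbose) message(sprintf("[%s] %s (%.1fs)", stage, sysname,
                                 as.numeric(Sys.time()) - t0))
  }
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  redox_list <- list()
  for (sysname in config$systems) {
    t0 <- as.numeric(Sys.time())
    system <- tryCatch(dna_duplex(sysname),
                       error = function(e) stopf("stage build_system, %s: %s",
                                                 sysname, conditionMessage(e)))
    trajs <- tryCatch(
      pipeline_trajectories(system, config),
      error = function(e) stopf("stage ingest, %s: %s", system$name,
                                conditionMessage(e)))
    say("ingest", system$name, t0)

    redox <- tryCatch(
      marcus_redox(trajs$neutral, trajs$cation, electrode = config$electrode,
                   system = system),
      error = function(e) stopf("stage redox, %s: %s", system$name,
                                conditionMessage(e)))
    say("redox", system$name, t0)

    holes <- tryCatch(
      list(neutral = hole_summary(trajs$neutral, system),
           cation = hole_summary(trajs$cation, system)),
      error = function(e) stopf("stage hole, %s: %s", system$name,
                                conditionMessage(e)))
    say("hole", system$name, t0)

    conv <- tryCatch(
      convergence_scan(trajs$neutral, trajs$cation, system = system,
                       k_grid = config$k_grid, electrode = config$electrode,
                       tolerances = config$tolerances),
      error = function(e) stopf("stage converge, %s: %s", system$name,
                                conditionMessage(e)))
    say("converge", system$name, t0)

    res <- list(system = system$name, arrangement = system$arrangement,
                seed = config$seed, redox = redox, hole = holes,
                convergence = conv)
    if (!is.null(outdir)) {
      sysdir <- file.path(outdir, gsub("[^A-Za-z0-9-]+", "_", system$name))
      dir.create(sysdir, recursive = TRUE, showWarnings = FALSE)
      if (!is.null(config$generator)) {
        write_snapshot_table(trajs$neutral, file.path(sysdir, "snapshots_neutral.tsv"))
        write_snapshot_table(trajs$cation, file.path(sysdir, "snapshots_cation.tsv"))
        write_coordinates_pdb(trajs$neutral, file.path(sysdir, "coords_neutral.pdb"), system)
        write_coordinates_pdb(trajs$cation, file.path(sysdir, "coords_cation.pdb"), system)
        write_manifest(system, config$generator, file.path(sysdir, "manifest.json"))
      }
      write_results(res, file.path(sysdir, "results.json"))
      say("report", system$name, t0)
    }
    results[[system$name]] <- res
    redox_list[[system$name]] <- redox
  }

  comparison <- compare_systems(redox_list)
  comparison$n_vie <- vapply(comparison$system,
                             function(s) results[[s]]$hole$neutral$n_mean, numeric(1))
  comparison$n_vae <- vapply(comparison$system,
                             function(s) results[[s]]$hole$cation$n_mean, numeric(1))
  comparison$nprime_vie <- vapply(comparison$system,
                                  function(s) results[[s]]$hole$neutral$nprime_mean,
                                  numeric(1))
  if (!is.null(outdir)) {
    utils::write.table(comparison, file.path(outdir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(results = results, comparison = comparison, config = config),
            class = "dsredox_run")
}

pipeline_trajectories <- function(system, config) {
  if (!is.null(config$input_paths)) {
    paths <- config$input_paths[[system$name]]
    if (is.null(paths)) stopf("no input paths configured for %s", system$name)
    neutral <- read_snapshot_table(paths$neutral, system)
    cation <- read_snapshot_table(paths$cation, system)
    if (!is.null(paths$coords_neutral)) {
      neutral <- assemble_trajectory(neutral, paths$coords_neutral)
    }
    if (!is.null(paths$coords_cation)) {
      cation <- assemble_trajectory(cation, paths$coords_cation)
    }
    return(list(neutral = neutral, cation = cation))
  }
  list(neutral = sample_trajectory(system, "neutral", config$generator,
                                   seed = config$seed),
       cation = sample_trajectory(system, "cation", config$generator,
                                  seed = config$seed))
}

#' @export
print.dsredox_run <- function(x, ...) {
  cat(sprintf("dsredox pipeline run: %d system(s), seed %d\n",
              length(x$results), x$config$seed))
  cat("\nOxidation-potential ranking (V vs SHE):\n")
  tab <- x$comparison
  tab[-1] <- lapply(tab[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(tab, row.names = FALSE)
  mr <- vapply(x$results, function(r) max(r$convergence$mrue), numeric(1))
  cat(sprintf("\nmax MRUE over properties, per system (%%): %s\n",
              paste(sprintf("%s %.1f", names(mr), mr), collapse = "; ")))
  invisible(x)
}
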