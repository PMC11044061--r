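#' Pipeline configuration
#'
#' Collects everything one analysis run needs: either a simulation
#' configuration (synthetic cohort) or paths to existing cohort/morphometry
#' tables, the atlas, the density grid, the analysis subnetworks, the ANCOVA
#' covariates, and output options.
#'
#' @param simulation An [sim_config()] object to generate a synthetic cohort,
#'   or \code{NULL} to load data from \code{cohort_path}/\code{morphometry_path}.
#' @param cohort_path,morphometry_path Input tables (ignored when
#'   \code{simulation} is given).
#' @param atlas_path Atlas file, or \code{NULL} for the bundled fixture.
#' @param densities Strictly increasing density thresholds in (0, 1].
#' @param networks Named list of [network_definition()]s.
#' @param covariates ANCOVA covariate columns.
#' @param responses Metric columns to model (one ANCOVA per network x metric).
#' @param output_dir Output directory (created if missing), or \code{NULL} to
#'   skip writing files.
#' @param seed Master seed for simulation and null-model streams.
#' @param small_world Compute small-worldness per subject/network/density.
#' @param n_null Null networks per small-worldness evaluation.
#' @param save_msns Also write each subject's full similarity matrix
#'   (off by default: one 360 x 360 text matrix per subject is bulky).
#' @return List of class \code{msn_pipeline_config}.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            cohort_path = NULL,
                            morphometry_path = NULL,
                            atlas_path = NULL,
                            densities = seq(0.25, 0.45, by = 0.05),
                            networks = builtin_networks(),
                            covariates = c("age", "sex", "tiv", "days_mri_npiq",
                                           "cdr_sb", "scanner", "education"),
                            responses = c("transitivity", "global_efficiency"),
                            output_dir = NULL,
                            seed = 1L,
                            small_world = FALSE,
                            n_null = 10L,
                            save_msns = FALSE) {
  if (any(densities <= 0) || any(densities > 1) || any(diff(densities) <= 0))
    stop("configuration error: densities must be strictly increasing in (0, 1]")
  if (is.null(simulation) &&
      (is.null(cohort_path) || is.null(morphometry_path)))
    stop("configuration error [stage: input]: no simulation config and no ",
         "cohort_path/morphometry_path to load")
  cfg <- list(simulation = simulation, cohort_path = cohort_path,
              morphometry_path = morphometry_path, atlas_path = atlas_path,
              densities = densities, networks = networks,
              covariates = covariates, responses = responses,
              output_dir = output_dir, seed = as.integer(seed),
              small_world = isTRUE(small_world), n_null = as.integer(n_null),
              save_msns = isTRUE(save_msns))
  class(cfg) <- "msn_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the [pipeline_config()] arguments; \code{simulation}
#' holds [sim_config()] overrides (e.g. \code{n_dat}, \code{noise_sd},
#' \code{effect_map}); \code{networks} maps subnetwork names to member
#' functional-network label vectors. Omitted keys keep their defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @param seed Optional seed overriding the file's value.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$simulation)) {
    sim_args <- raw$simulation
    if (!is.null(sim_args$effect_map))
      sim_args$effect_map <- lapply(sim_args$effect_map, as.list)
    args$simulation <- do.call(sim_config, sim_args)
  }
  for (k in c("cohort_path", "morphometry_path", "atlas_path", "densities",
              "covariates", "responses", "output_dir", "seed", "small_world",
              "n_null", "save_msns"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$networks))
    args$networks <- mapply(network_definition, names(raw$networks),
                            raw$networks, SIMPLIFY = FALSE)
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

run_stage <- function(stage, output_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(output_dir)) {
      try(writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                     file.path(output_dir, "FAILED")), silent = TRUE)
    }
    stop("pipeline failed [stage: ", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Short deterministic checksum of the analysis-defining configuration (the
# output location is excluded: it does not change any result).
config_checksum <- function(cfg) {
  cfg$output_dir <- NULL
  s <- paste(deparse(cfg, control = "exact"), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 997)) %% 4294967291)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> build similarity networks -> threshold and measure ->
#' repeated-measures ANCOVAs -> demographics. Writes, when \code{output_dir}
#' is set: \code{cohort.tsv}, \code{metrics.tsv}, \code{ancova_results.json},
#' \code{demographics.tsv} and \code{manifest.json} (seed, configuration
#' checksum, package version, warning tallies). Running the same
#' configuration twice produces byte-identical outputs. Disconnected
#' low-density networks are flagged in the metric table and tallied, not
#' fatal.
#'
#' @param config A [pipeline_config()] object.
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class \code{msn_pipeline}: list with \code{cohort},
#'   \code{metrics}, \code{ancova} (one [rm_ancova()] fit per
#'   network x response), \code{demographics}, \code{manifest}.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulation = sim_config(n_dat = 8, n_bvftd = 8),
#'                        seed = 7)
#' res <- run_pipeline(cfg, quiet = TRUE)
#' res$ancova$CCN_global_efficiency
#' }
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "msn_pipeline_config"))
    stop("'config' must come from pipeline_config()")
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  n_warn <- 0L
  tally <- function(expr) withCallingHandlers(expr, warning = function(w) {
    n_warn <<- n_warn + 1L
    invokeRestart("muffleWarning")
  })

  atlas <- run_stage("atlas", out_dir, load_atlas(config$atlas_path))

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    say("simulate: cohort of ", sim$n_dat + sim$n_bvftd, " subjects")
    cohort <- run_stage("simulate", out_dir, simulate_cohort(sim))
    morph <- run_stage("simulate", out_dir,
                       simulate_morphometry(cohort, atlas, sim))
  } else {
    say("load: ", config$cohort_path)
    cohort <- run_stage("input", out_dir, read_cohort(config$cohort_path))
    morph <- run_stage("input", out_dir,
                       read_morphometry(config$morphometry_path))
  }

  say("build-msn: ", length(morph), " similarity matrices")
  msns <- run_stage("build-msn", out_dir, tally(lapply(morph, build_msn)))

  say("metrics: ", length(config$networks), " networks x ",
      length(config$densities), " densities")
  metrics <- run_stage("metrics", out_dir, tally(
    compute_metrics(msns, atlas, networks = config$networks,
                    densities = config$densities,
                    small_world = config$small_world,
                    n_null = config$n_null,
                    seed = derive_seed(config$seed, 2000000L))))

  say("analyze: ", length(config$networks) * length(config$responses),
      " repeated-measures ANCOVAs")
  ancova <- list()
  for (nw in names(config$networks)) {
    for (resp in config$responses) {
      ancova[[paste(nw, resp, sep = "_")]] <- run_stage("analyze", out_dir,
        rm_ancova(metrics, cohort, response = resp, network = nw,
                  covariates = config$covariates))
    }
  }

  demogr <- run_stage("demographics", out_dir, demographics_table(cohort))

  n_disc <- sum(!metrics$connected)
  manifest <- list(
    seed = config$seed,
    config_checksum = config_checksum(config),
    package_version = as.character(packageVersion("msnet")),
    n_subjects = nrow(cohort),
    densities = config$densities,
    networks = names(config$networks),
    warnings = n_warn,
    disconnected_networks = n_disc
  )

  if (!is.null(out_dir)) {
    run_stage("write", out_dir, {
      write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
      write_metrics(metrics, file.path(out_dir, "metrics.tsv"))
      write_tsv(demogr, file.path(out_dir, "demographics.tsv"))
      ancova_json <- lapply(ancova, function(a) a$effects)
      jsonlite::write_json(ancova_json,
                           file.path(out_dir, "ancova_results.json"),
                           dataframe = "rows", digits = NA, auto_unbox = TRUE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           digits = NA, auto_unbox = TRUE)
      if (config$save_msns) {
        msn_dir <- file.path(out_dir, "msn")
        if (!dir.exists(msn_dir)) dir.create(msn_dir)
        for (sid in names(msns))
          write_msn_matrix(msns[[sid]], file.path(msn_dir, paste0(sid, ".tsv")))
      }
      unlink(file.path(out_dir, "FAILED"))
    })
  }
  if (n_disc > 0)
    say("note: ", n_disc, " thresholded networks were disconnected (flagged)")

  structure(list(cohort = cohort, metrics = metrics, ancova = ancova,
                 demographics = demogr, manifest = manifest,
                 config = config),
            class = "msn_pipeline")
}

#' @export
print.msn_pipeline <- function(x, ...) {
  cat("MSN analysis pipeline run\n")
  cat("  subjects:", x$manifest$n_subjects,
      " densities:", paste(x$manifest$densities, collapse = ", "), "\n")
  cat("  disconnected thresholded networks:",
      x$manifest$disconnected_networks, "\n\n")
  for (nm in names(x$ancova)) print(x$ancova[[nm]])
  invisible(x)
}
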