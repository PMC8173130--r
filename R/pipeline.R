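#' @title Run configuration and pipeline orchestration
#' @name pipeline
#' @description
#' The analysis stages (simulate, fit, hf, calibrate, stratify) can be
#' chained through [run_pipeline()], driven by a plain-text YAML or JSON
#' configuration. Each stage consumes the previous stage's on-disk
#' outputs (NIfTI maps, TSV curves, CSV tables, JSON sweeps) from a run
#' directory and records a manifest with the config hash and seed so
#' deterministic stages reproduce byte-identical outputs.
NULL

.known_config_keys <- c(
  "seed", "aif", "setting", "strategy", "endpoint", "n_tumors",
  "n_patients", "hf_pim_sigma", "baseline_hazard", "beta",
  "censor_horizon", "temporal_resolution", "duration",
  "concentration_sigma", "grid_shape", "tumor_radius", "core_fraction",
  "hypoxic_radius_fraction", "k0trans", "ve0", "grid_k0trans",
  "grid_ve0", "include_unphysiological", "hf_col")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, rejecting unknown keys.
#'
#' @param path Config file path.
#' @return A named list of class \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

.cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

.cfg_aif <- function(cfg) {
  a <- .cfg_get(cfg, "aif", "murine")
  if (is.character(a)) aif_preset(a)
  else aif_parameters(a$amp_fast, a$rate_fast, a$amp_slow, a$rate_slow,
                      label = .cfg_get(a, "label", "custom"))
}

.cfg_rule <- function(cfg) {
  hypoxia_rule(.cfg_get(cfg, "strategy", "ktrans_only"),
               k0trans = .cfg_get(cfg, "k0trans"),
               ve0 = .cfg_get(cfg, "ve0"))
}

.cfg_grid <- function(cfg) {
  gk <- .cfg_get(cfg, "grid_k0trans"); gv <- .cfg_get(cfg, "grid_ve0")
  if (is.null(gk) && is.null(gv)) {
    default_threshold_grid(.cfg_get(cfg, "setting", "preclinical"),
                           .cfg_get(cfg, "strategy", "ktrans_only"))
  } else {
    expand <- function(g) {
      if (is.null(g)) return(NULL)
      if (!is.null(g$from)) seq(g$from, g$to, by = g$by) else unlist(g)
    }
    threshold_grid(expand(gk), expand(gv))
  }
}

.cfg_cohort_spec <- function(cfg, seed) {
  cohort_spec(
    n_tumors = .cfg_get(cfg, "n_tumors", 98L),
    n_patients = .cfg_get(cfg, "n_patients", 80L),
    hf_pim_sigma = .cfg_get(cfg, "hf_pim_sigma", 0.05),
    baseline_hazard = .cfg_get(cfg, "baseline_hazard", 0.015),
    beta = .cfg_get(cfg, "beta", 3),
    censor_horizon = .cfg_get(cfg, "censor_horizon", 80),
    temporal_resolution = .cfg_get(cfg, "temporal_resolution"),
    duration = .cfg_get(cfg, "duration", 600),
    concentration_sigma = .cfg_get(cfg, "concentration_sigma", 0.02),
    seed = seed)
}

.cfg_phantom_spec <- function(cfg) {
  phantom_spec(
    grid_shape = .cfg_get(cfg, "grid_shape", c(64L, 64L)),
    tumor_radius = .cfg_get(cfg, "tumor_radius", 24),
    core_fraction = .cfg_get(cfg, "core_fraction", 0.25),
    hypoxic_radius_fraction = .cfg_get(cfg, "hypoxic_radius_fraction",
                                       0.6))
}

.read_table_checked <- function(path, required) {
  if (!file.exists(path))
    stop("missing upstream output: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("malformed table ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

.write_manifest <- function(outdir, stage, cfg_path, seed) {
  manifest <- list(
    schema = "hypoxiaDCE/manifest/v1",
    stage = stage,
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("hypoxiaDCE")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("manifest-", stage,
                                                ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.log_msg <- function(level, threshold, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[threshold]] && threshold != "quiet")
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run one pipeline stage
#'
#' Executes a stage against a run directory. Stages:
#' \describe{
#'   \item{simulate}{Generate the preclinical and clinical cohorts:
#'     per-tumor NIfTI maps under \code{maps/}, one example DCE curve
#'     file, \code{tumors.csv} and \code{patients.csv}.}
#'   \item{fit}{Fit the Tofts model to the curve file, writing fitted
#'     maps under \code{fitted/}.}
#'   \item{hf}{Apply a configured rule to every tumor's maps, appending
#'     \code{hf_mri} to \code{tumors.csv} and writing coded hypoxia
#'     images.}
#'   \item{calibrate}{Sweep the configured threshold grid against
#'     \code{hf_pim}, writing \code{calibration.json} and the
#'     per-tumor HF table at the optimum.}
#'   \item{stratify}{Split \code{patients.csv} on \code{hf_mri} and
#'     compare survival, writing \code{stratification.json} and
#'     per-group Kaplan-Meier CSVs.}
#' }
#' Logs go to stderr; results never interleave with them.
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @param stage One of \code{"simulate"}, \code{"fit"}, \code{"hf"},
#'   \code{"calibrate"}, \code{"stratify"}.
#' @param outdir Run directory (created if absent).
#' @param seed Integer seed overriding the config's.
#' @param log_level \code{"debug"}, \code{"info"}, \code{"warn"} or
#'   \code{"quiet"}.
#' @return Invisibly, a list of the stage's main outputs.
#' @export
run_pipeline <- function(config, stage = c("simulate", "fit", "hf",
                                           "calibrate", "stratify"),
                         outdir = "hypoxia-run", seed = NULL,
                         log_level = c("info", "debug", "warn",
                                       "quiet")) {
  stage <- match.arg(stage)
  log_level <- match.arg(log_level)
  cfg <- if (is.character(config)) load_config(config)
         else structure(config, class = "run_config")
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(seed)) seed <- .cfg_get(cfg, "seed", 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # normalized config snapshot is the hashed artifact
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(cfg[order(names(cfg))], cfg_path,
                       auto_unbox = TRUE, digits = NA)
  .log_msg("info", log_level, "stage '", stage, "' in ", outdir,
           " (seed ", seed, ")")
  out <- switch(stage,
    simulate = .stage_simulate(cfg, outdir, seed, log_level),
    fit = .stage_fit(cfg, outdir, seed, log_level),
    hf = .stage_hf(cfg, outdir, log_level),
    calibrate = .stage_calibrate(cfg, outdir, log_level),
    stratify = .stage_stratify(cfg, outdir, log_level))
  .write_manifest(outdir, stage, cfg_path, seed)
  invisible(out)
}

.stage_simulate <- function(cfg, outdir, seed, log_level) {
  cs <- .cfg_cohort_spec(cfg, seed)
  ps <- .cfg_phantom_spec(cfg)
  pre <- simulate_preclinical_cohort(cs, ps, seed = seed)
  utils::write.csv(pre$tumors, file.path(outdir, "tumors.csv"),
                   row.names = FALSE)
  mapdir <- file.path(outdir, "maps")
  for (id in names(pre$maps))
    write_parameter_maps(pre$maps[[id]], file.path(mapdir, id))
  aif <- .cfg_aif(cfg)
  acq <- simulate_dce_acquisition(pre$maps[[1L]], aif, cs,
                                  setting = .cfg_get(cfg, "setting",
                                                     "preclinical"),
                                  seed = seed + 1L)
  write_curves(acq, file.path(outdir, "curves.tsv"))
  cli <- simulate_clinical_cohort(cs, seed = seed + 2L)
  utils::write.csv(cli$patients, file.path(outdir, "patients.csv"),
                   row.names = FALSE)
  .log_msg("info", log_level, "wrote ", length(pre$maps),
           " tumor map sets, curves.tsv, tumors.csv, patients.csv")
  list(tumors = pre$tumors, patients = cli$patients)
}

.stage_fit <- function(cfg, outdir, seed, log_level) {
  path <- file.path(outdir, "curves.tsv")
  if (!file.exists(path))
    stop("missing upstream output: ", path,
         " (run the 'simulate' stage first)", call. = FALSE)
  acq <- read_curves(path)
  maps <- fit_tofts_map(acq, .cfg_aif(cfg))
  fitdir <- file.path(outdir, "fitted")
  write_parameter_maps(maps, fitdir)
  .log_msg("info", log_level, "fitted ", length(acq$voxel_index),
           " voxels -> ", fitdir)
  list(maps = maps)
}

.stage_hf <- function(cfg, outdir, log_level) {
  tumors <- .read_table_checked(file.path(outdir, "tumors.csv"),
                                c("tumor_id", "hf_pim"))
  rule <- .cfg_rule(cfg)
  incl <- isTRUE(.cfg_get(cfg, "include_unphysiological", FALSE))
  hf <- numeric(nrow(tumors))
  for (i in seq_len(nrow(tumors))) {
    m <- read_parameter_maps(file.path(outdir, "maps",
                                       tumors$tumor_id[i]))
    img <- classify_voxels(m, rule, incl)
    hf[i] <- img$hf_mri
    write_hypoxia_image(img, file.path(outdir, "maps", tumors$tumor_id[i],
                                       "hypoxia.nii.gz"),
                        voxel_size = m$voxel_size)
  }
  tumors$hf_mri <- hf
  utils::write.csv(tumors, file.path(outdir, "tumors.csv"),
                   row.names = FALSE)
  .log_msg("info", log_level, "hypoxic fractions appended to tumors.csv")
  list(tumors = tumors)
}

.stage_calibrate <- function(cfg, outdir, log_level) {
  tumors <- .read_table_checked(file.path(outdir, "tumors.csv"),
                                c("tumor_id", "hf_pim"))
  maps <- lapply(as.character(tumors$tumor_id), function(id)
    read_parameter_maps(file.path(outdir, "maps", id)))
  names(maps) <- tumors$tumor_id
  strategy <- .cfg_get(cfg, "strategy", "ktrans_only")
  grid <- .cfg_grid(cfg)
  cal <- if (strategy %in% c("ktrans_only", "ve_only"))
    calibrate_1d(tumors, maps, strategy, grid)
  else calibrate_2d(tumors, maps, strategy, grid)
  write_calibration(cal, file.path(outdir, "calibration.json"))
  utils::write.csv(cal$table, file.path(outdir, "calibration_hf.csv"),
                   row.names = FALSE)
  .log_msg("info", log_level, "calibration.json written (optimum ",
           paste(sprintf("%s=%g", names(cal$optimal),
                         unlist(cal$optimal)), collapse = ", "), ")")
  list(calibration = cal)
}

.stage_stratify <- function(cfg, outdir, log_level) {
  patients <- .read_table_checked(
    file.path(outdir, "patients.csv"),
    c("patient_id", .cfg_get(cfg, "hf_col", "hf_mri"),
      "dfs_time", "dfs_event", "os_time", "os_event"))
  res <- stratify_cohort(patients, .cfg_get(cfg, "hf_col", "hf_mri"))
  out <- list(schema = "hypoxiaDCE/stratification/v1",
              n_high = nrow(res$split$high), n_low = nrow(res$split$low),
              boundary_tie = res$split$boundary_tie,
              endpoints = lapply(res$endpoints, function(ep)
                list(endpoint = ep$endpoint,
                     chi_square = ep$logrank$chi_square,
                     p_value = ep$logrank$p_value)))
  jsonlite::write_json(out, file.path(outdir, "stratification.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ep in res$endpoints) {
    for (g in c("high", "low")) {
      km <- ep[[paste0("km_", g)]]
      utils::write.csv(km$table,
                       file.path(outdir, sprintf("km_%s_%s.csv",
                                                 ep$endpoint, g)),
                       row.names = FALSE)
    }
  }
  .log_msg("info", log_level, "stratification.json and KM tables written")
  list(stratification = res)
}
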