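#' @title Synthetic tumors and cohorts
#' @name synthetic
#' @description
#' Generators producing tumor phantoms, preclinical tumor cohorts with
#' pimonidazole-like reference hypoxic fractions, clinical cohorts with
#' survival endpoints, and DCE acquisitions, with the statistical
#' structure the analysis pipeline assumes. All generators are
#' deterministic given a seed.
NULL

# Run code under a temporary RNG state so generators are reproducible
# without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Tumor phantom specification
#'
#' Describes a concentric two-dimensional tumor phantom: a necrotic core
#' (unphysiological \eqn{v_e > 1}, near-zero Ktrans), a surrounding
#' hypoxic annulus of low Ktrans, and a well-perfused periphery — the
#' arrangement in which hypoxia borders necrosis. Parameter values carry
#' multiplicative lognormal spread representing tissue heterogeneity;
#' ground-truth hypoxia labels are obtained by applying the true rule to
#' the generated parameter fields.
#'
#' @param grid_shape Grid dimensions (voxels), default 64 x 64.
#' @param tumor_radius Tumor radius in voxels.
#' @param core_fraction Necrotic core radius as a fraction of the tumor
#'   radius, in \[0, 1).
#' @param hypoxic_radius_fraction Outer radius of the hypoxic annulus as
#'   a fraction of the tumor radius (0 disables the annulus).
#' @param rule The true [hypoxia_rule()] generating the ground truth.
#' @param ktrans_periphery,ktrans_hypoxic,ktrans_necrotic Zone median
#'   Ktrans values (min^-1).
#' @param sigma_log Within-tumor lognormal spread (log-scale SD) of
#'   Ktrans.
#' @param ktrans_tumor_sigma Between-tumor lognormal spread: one shared
#'   multiplier per phantom scales all zone medians, representing
#'   intertumor heterogeneity in blood perfusion.
#' @param ve_mean,ve_sd Mean and SD of viable-tissue ve (truncated to
#'   \[0.01, 0.99\]).
#' @param ve_necrotic_offset Necrotic ve excess over 1 (> 0).
#' @param voxel_size Voxel dimensions in mm; default the preclinical
#'   0.23 x 0.23 x 1.0 mm.
#' @param seed Optional RNG seed.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L), tumor_radius = 24,
                         core_fraction = 0.25,
                         hypoxic_radius_fraction = 0.6,
                         rule = hypoxia_rule("ktrans_only",
                                             k0trans = 0.015),
                         ktrans_periphery = 0.05, ktrans_hypoxic = 0.008,
                         ktrans_necrotic = 0.002, sigma_log = 0.3,
                         ktrans_tumor_sigma = 0.3,
                         ve_mean = 0.25, ve_sd = 0.05,
                         ve_necrotic_offset = 0.3,
                         voxel_size = c(0.23, 0.23, 1.0), seed = NULL) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4L),
            tumor_radius > 0, inherits(rule, "hypoxia_rule"),
            ktrans_periphery > 0, ktrans_hypoxic > 0, ktrans_necrotic > 0,
            sigma_log >= 0, ktrans_tumor_sigma >= 0, ve_mean > 0, ve_sd >= 0,
            ve_necrotic_offset > 0)
  if (core_fraction < 0 || core_fraction >= 1)
    stop("core_fraction must be in [0, 1): the necrotic core must be ",
         "smaller than the tumor", call. = FALSE)
  if (hypoxic_radius_fraction < 0 || hypoxic_radius_fraction > 1)
    stop("hypoxic_radius_fraction must be in [0, 1]", call. = FALSE)
  if (2 * tumor_radius > min(grid_shape))
    stop("tumor does not fit the grid", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Simulate a tumor phantom
#'
#' Draws a [phantom_spec()] realization: parameter maps, ground-truth
#' hypoxia labels (the spec's rule applied to the generated fields), and
#' the true hypoxic fraction over viable voxels.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return Object of class \code{tumor_phantom}: \code{maps}
#'   ([parameter_maps()]), \code{truth} (integer label array, coding as
#'   in [classify_voxels()]), \code{true_hf}, and the spec.
#' @export
simulate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(seed, {
    nx <- spec$grid_shape[1L]; ny <- spec$grid_shape[2L]
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`))
    roi <- r <= spec$tumor_radius
    r_core <- spec$core_fraction * spec$tumor_radius
    r_hyp <- spec$hypoxic_radius_fraction * spec$tumor_radius
    necrotic <- roi & r <= r_core
    hypoxic_zone <- roi & r > r_core & r <= r_hyp
    periphery <- roi & !necrotic & !hypoxic_zone
    ktrans <- array(NA_real_, dim = c(nx, ny))
    ve <- array(NA_real_, dim = c(nx, ny))
    # one perfusion scale per tumor: intertumor heterogeneity
    scale <- exp(stats::rnorm(1L, 0, spec$ktrans_tumor_sigma))
    draw_k <- function(mask, med) {
      n <- sum(mask)
      if (n) ktrans[mask] <<- med * scale *
          exp(stats::rnorm(n, 0, spec$sigma_log))
    }
    draw_k(periphery, spec$ktrans_periphery)
    draw_k(hypoxic_zone, spec$ktrans_hypoxic)
    draw_k(necrotic, spec$ktrans_necrotic)
    n_v <- sum(roi & !necrotic)
    ve[roi & !necrotic] <- pmin(pmax(
      stats::rnorm(n_v, spec$ve_mean, spec$ve_sd), 0.01), 0.99)
    n_n <- sum(necrotic)
    if (n_n)
      ve[necrotic] <- 1 + spec$ve_necrotic_offset +
        abs(stats::rnorm(n_n, 0, spec$ve_sd))
    maps <- parameter_maps(ktrans, ve, roi, voxel_size = spec$voxel_size)
    truth <- array(.LBL_OUTSIDE, dim = c(nx, ny))
    truth[roi] <- .classify_values(ktrans[roi], ve[roi], spec$rule)
    n_hyp <- sum(truth == .LBL_HYPOXIC)
    n_cls <- n_hyp + sum(truth == .LBL_NORMOXIC)
    structure(list(maps = maps, truth = truth,
                   true_hf = if (n_cls) n_hyp / n_cls else NA_real_,
                   spec = spec),
              class = "tumor_phantom")
  })
}

#' @export
print.tumor_phantom <- function(x, ...) {
  cat(sprintf("Tumor phantom %s: %d ROI voxels, true HF = %.4f\n",
              paste(dim(x$truth), collapse = "x"), sum(x$truth > 0),
              x$true_hf))
  invisible(x)
}

#' Cohort simulation specification
#'
#' Parameters of the simulated preclinical (tumor + pimonidazole) and
#' clinical (patient + survival) cohorts. Defaults mirror the emulated
#' study design: 98 tumors, 80 patients, preclinical temporal resolution
#' 14.8 s (29 s clinical), 10-minute acquisitions, and a survival model
#' whose hazard increases with hypoxic fraction (exponential
#' proportional hazards, uniform censoring over an 80-month follow-up).
#'
#' @param n_tumors Number of preclinical tumors.
#' @param n_patients Number of clinical patients.
#' @param hf_pim_sigma SD of the truncated-Gaussian noise added to the
#'   true HF to produce the pimonidazole reference value.
#' @param hf_shape1,hf_shape2 Beta parameters of the clinical HF
#'   distribution when no maps are generated.
#' @param baseline_hazard Baseline event hazard per month.
#' @param beta Log-hazard coefficient on HF (0 = null cohort).
#' @param censor_horizon Uniform censoring horizon in months.
#' @param temporal_resolution DCE sampling interval in seconds; NULL
#'   resolves to 14.8 (preclinical) or 29 (clinical) at simulation time.
#' @param duration Acquisition duration in seconds.
#' @param concentration_sigma Additive Gaussian concentration noise (mM).
#' @param seed Optional RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_tumors = 98L, n_patients = 80L,
                        hf_pim_sigma = 0.05, hf_shape1 = 2,
                        hf_shape2 = 5, baseline_hazard = 0.015, beta = 3,
                        censor_horizon = 80, temporal_resolution = NULL,
                        duration = 600, concentration_sigma = 0.02,
                        seed = NULL) {
  stopifnot(n_tumors >= 1L, n_patients >= 1L, hf_pim_sigma >= 0,
            hf_shape1 > 0, hf_shape2 > 0, baseline_hazard > 0,
            censor_horizon > 0, duration > 0, concentration_sigma >= 0)
  if (!is.null(temporal_resolution) && temporal_resolution <= 0)
    stop("temporal_resolution must be positive", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# Per-subject phantom geometry variation: hypoxic annulus extent drives
# the spread of true HF across the cohort; radius varies modestly.
.vary_phantom <- function(template, hrf, radius_scale) {
  sp <- template
  sp$hypoxic_radius_fraction <- hrf
  sp$tumor_radius <- max(4, template$tumor_radius * radius_scale)
  sp$seed <- NULL
  sp
}

#' Simulate a preclinical tumor cohort
#'
#' Generates \code{n_tumors} phantoms with varied geometry (hypoxic
#' annulus extent uniform on \[0.15, 0.9\] of the tumor radius, radius
#' scale uniform on \[0.6, 1\]), cycling model labels over the four
#' xenograft lines and marking roughly a quarter of tumors as
#' bevacizumab-treated (treatment is only a group label). The
#' pimonidazole reference fraction is the true HF plus truncated
#' Gaussian noise, clipped to \[0, 1\].
#'
#' @param spec A [cohort_spec()].
#' @param template A [phantom_spec()] used as the geometric template.
#' @param models Model labels to cycle over.
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return List with \code{tumors} (data frame: \code{tumor_id},
#'   \code{model}, \code{treatment}, \code{hf_pim}, \code{hf_true}) and
#'   \code{maps} (named list of [parameter_maps()]).
#' @export
simulate_preclinical_cohort <- function(spec = cohort_spec(),
                                        template = phantom_spec(),
                                        models = c("BK-12", "ED-15",
                                                   "HL-16", "LA-19"),
                                        seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(template, "phantom_spec"))
  .with_seed(seed, {
    n <- spec$n_tumors
    hrf <- stats::runif(n, 0.15, 0.9)
    rsc <- stats::runif(n, 0.6, 1)
    ids <- sprintf("T%03d", seq_len(n))
    maps <- vector("list", n); names(maps) <- ids
    hf_true <- numeric(n)
    for (i in seq_len(n)) {
      ph <- simulate_phantom(.vary_phantom(template, hrf[i], rsc[i]),
                             seed = NULL)
      maps[[i]] <- ph$maps
      hf_true[i] <- ph$true_hf
    }
    hf_pim <- pmin(pmax(hf_true + stats::rnorm(n, 0, spec$hf_pim_sigma),
                        0), 1)
    tumors <- data.frame(
      tumor_id = ids,
      model = rep_len(models, n),
      treatment = ifelse(seq_len(n) %% 4L == 0L, "bevacizumab",
                         "untreated"),
      hf_pim = hf_pim, hf_true = hf_true)
    list(tumors = tumors, maps = maps)
  })
}

#' Simulate a clinical cohort with survival endpoints
#'
#' Generates \code{n_patients} records. The hypoxic fraction is drawn
#' from a Beta distribution, or — when a phantom template is supplied —
#' computed from generated parameter maps under the template's rule.
#' Event times follow an exponential proportional-hazards model with
#' hazard \eqn{h_0 \exp(\beta \cdot HF)}; death occurs after relapse by
#' an independent exponential gap, so OS times dominate DFS times and
#' share the HF effect. Censoring is uniform on \[0, horizon\].
#'
#' @param spec A [cohort_spec()].
#' @param template Optional [phantom_spec()]; when given, per-patient
#'   maps are generated (clinical voxel size 0.78 x 0.78 x 5.0 mm is the
#'   template author's choice) and HF is the map-derived truth.
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return List with \code{patients} (data frame: \code{patient_id},
#'   \code{hf_mri}, \code{dfs_time}, \code{dfs_event}, \code{os_time},
#'   \code{os_event}, \code{hf_true}) and \code{maps} (named list, or
#'   NULL without a template).
#' @export
simulate_clinical_cohort <- function(spec = cohort_spec(),
                                     template = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(seed, {
    n <- spec$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    maps <- NULL
    if (is.null(template)) {
      hf <- stats::rbeta(n, spec$hf_shape1, spec$hf_shape2)
    } else {
      stopifnot(inherits(template, "phantom_spec"))
      hrf <- stats::runif(n, 0.15, 0.9)
      rsc <- stats::runif(n, 0.6, 1)
      maps <- vector("list", n); names(maps) <- ids
      hf <- numeric(n)
      for (i in seq_len(n)) {
        ph <- simulate_phantom(.vary_phantom(template, hrf[i], rsc[i]),
                               seed = NULL)
        maps[[i]] <- ph$maps
        hf[i] <- ph$true_hf
      }
    }
    rate <- spec$baseline_hazard * exp(spec$beta * hf)
    t_relapse <- stats::rexp(n, rate)
    t_death <- t_relapse + stats::rexp(n, 0.05)
    cens <- stats::runif(n, 0, spec$censor_horizon)
    patients <- data.frame(
      patient_id = ids, hf_mri = hf,
      dfs_time = pmin(t_relapse, cens),
      dfs_event = as.integer(t_relapse <= cens),
      os_time = pmin(t_death, cens),
      os_event = as.integer(t_death <= cens),
      hf_true = hf)
    list(patients = patients, maps = maps)
  })
}

#' Simulate a DCE acquisition over a tumor
#'
#' Produces per-voxel concentration-time curves for every ROI voxel of a
#' parameter map. Viable voxels follow the closed-form Tofts model at
#' the spec's sampling; necrotic voxels (\eqn{v_e > 1}) get a low,
#' slowly rising saturating curve — the contrast behaviour of necrotic
#' tissue, which drives the Tofts fit to unphysiological \eqn{v_e}.
#' Gaussian noise of SD \code{concentration_sigma} is added.
#'
#' @param maps A [parameter_maps()] object.
#' @param aif An [aif_parameters()] object.
#' @param spec A [cohort_spec()] supplying sampling interval, duration
#'   and noise level.
#' @param setting \code{"preclinical"} or \code{"clinical"}; resolves
#'   the default temporal resolution (14.8 s / 29 s) when the spec
#'   leaves it NULL.
#' @param necrotic_cmax,necrotic_tau Plateau (mM) and time constant (s)
#'   of the necrotic uptake curve.
#' @param seed Optional RNG seed.
#' @return A [dce_acquisition()].
#' @export
simulate_dce_acquisition <- function(maps, aif, spec = cohort_spec(),
                                     setting = c("preclinical",
                                                 "clinical"),
                                     necrotic_cmax = 0.5,
                                     necrotic_tau = 2400, seed = spec$seed) {
  stopifnot(inherits(maps, "parameter_maps"),
            inherits(aif, "aif_parameters"),
            inherits(spec, "cohort_spec"))
  setting <- match.arg(setting)
  dt <- spec$temporal_resolution
  if (is.null(dt)) dt <- if (setting == "preclinical") 14.8 else 29
  if (dt <= 0) stop("temporal resolution must be positive", call. = FALSE)
  .with_seed(seed, {
    times <- seq(0, spec$duration, by = dt)
    idx <- which(maps$roi)
    k <- maps$ktrans[idx]; v <- maps$ve[idx]
    amps <- .aif_amps(aif); rates <- .aif_rates_min(aif)
    t_min <- times / 60
    conc <- matrix(0, length(times), length(idx))
    for (j in seq_along(idx)) {
      conc[, j] <- if (is.finite(v[j]) && v[j] <= 1) {
        .tofts_ct(k[j], v[j], amps, rates, t_min)
      } else {
        necrotic_cmax * (1 - exp(-times / necrotic_tau))
      }
    }
    if (spec$concentration_sigma > 0)
      conc <- conc + stats::rnorm(length(conc), 0,
                                  spec$concentration_sigma)
    dce_acquisition(times, conc, idx, dim(maps$ktrans))
  })
}
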