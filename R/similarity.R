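#' Adapted similarity statistic
#'
#' A slope-sensitive variant of the Pearson correlation used to compare
#' two sets of paired fractions (here MRI-derived and
#' pimonidazole-derived hypoxic fractions):
#' \deqn{S(x, y) = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'   {(N - 1)\,\left[\mathrm{var}(x) + \mathrm{var}(y)\right]/2}
#'   = \frac{2\,\mathrm{cov}(x, y)}{\mathrm{var}(x) + \mathrm{var}(y)}.}
#' \eqn{S = 1} exactly iff \eqn{y = x + c} for a constant \eqn{c}
#' (perfect correlation with slope 1); any slope different from 1 or any
#' scatter lowers it, which distinguishes \eqn{S} from the Pearson
#' coefficient. By the AM-GM inequality \eqn{|S| \le 1}.
#'
#' @param x,y Numeric vectors of equal length \eqn{N \ge 3}.
#' @return The similarity value in \[-1, 1\]; \code{NA} with a warning
#'   when \code{var(x) + var(y) == 0} (undefined).
#' @export
#' @examples
#' similarity(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))      # 1
#' similarity(c(0.1, 0.2, 0.3), 2 * c(0.1, 0.2, 0.3))  # 0.8: slope != 1
similarity <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("similarity needs at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx + syy == 0) {
    warning("similarity undefined: zero total variance")
    return(NA_real_)
  }
  2 * sum(dx * dy) / (sxx + syy)
}

#' Agreement statistics between two fraction vectors
#'
#' Squared Pearson correlation with its two-sided p-value, and the
#' ordinary least-squares line of \code{y} regressed on \code{x}.
#'
#' @param x,y Numeric vectors, \eqn{N \ge 3}.
#' @return List with \code{r2}, \code{p_value}, \code{slope},
#'   \code{intercept}, and \code{degenerate} (TRUE, with all-NA values,
#'   when either input has zero variance).
#' @export
agreement_stats <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L)
    stop("agreement_stats needs at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("agreement statistics undefined: zero variance")
    return(list(r2 = NA_real_, p_value = NA_real_, slope = NA_real_,
                intercept = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r2 = unname(ct$estimate)^2, p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       degenerate = FALSE)
}

#' Candidate threshold grid
#'
#' Ordered candidate thresholds for the Ktrans and/or ve axes of a
#' calibration or survival sweep.
#'
#' @param k0trans_values Strictly increasing positive Ktrans thresholds
#'   (min^-1), or NULL.
#' @param ve0_values Strictly increasing positive ve thresholds, or NULL.
#' @return An object of class \code{threshold_grid}.
#' @export
threshold_grid <- function(k0trans_values = NULL, ve0_values = NULL) {
  chk <- function(v, name) {
    if (is.null(v)) return(NULL)
    v <- as.numeric(v)
    if (any(!is.finite(v)) || any(v <= 0) || any(diff(v) <= 0))
      stop(name, " must be positive and strictly increasing", call. = FALSE)
    v
  }
  structure(list(k0trans_values = chk(k0trans_values, "k0trans_values"),
                 ve0_values = chk(ve0_values, "ve0_values")),
            class = "threshold_grid")
}

#' Default threshold grids
#'
#' Sweep grids bracketing the thresholds of interest in each setting.
#' Preclinical: Ktrans 0.001-0.10 min^-1 step 0.001; ve 0.01-1.0 step
#' 0.01 for \code{conjunction}, 50 logarithmically spaced values in
#' 0.1-16 for \code{weighted_sum}. Clinical: Ktrans 0.005-0.5 min^-1
#' (100 points), same ve axes.
#'
#' @param setting \code{"preclinical"} or \code{"clinical"}.
#' @param strategy Strategy the grid is for.
#' @return A [threshold_grid()].
#' @export
default_threshold_grid <- function(setting = c("preclinical", "clinical"),
                                   strategy = c("ktrans_only", "ve_only",
                                                "conjunction",
                                                "weighted_sum")) {
  setting <- match.arg(setting)
  strategy <- match.arg(strategy)
  k0 <- if (setting == "preclinical") seq(0.001, 0.1, by = 0.001)
        else seq(0.005, 0.5, length.out = 100L)
  ve0 <- switch(strategy,
    ktrans_only = NULL,
    ve_only = seq(0.01, 1, by = 0.01),
    conjunction = seq(0.01, 1, by = 0.01),
    weighted_sum = exp(seq(log(0.1), log(16), length.out = 50L)))
  threshold_grid(if (strategy == "ve_only") NULL else k0, ve0)
}

# Extract per-tumor viable voxel values once; maps may be a named list of
# parameter_maps aligned with tumors$tumor_id.
.cohort_viable <- function(tumors, maps) {
  stopifnot(is.data.frame(tumors), all(c("tumor_id", "hf_pim") %in%
                                         names(tumors)))
  if (is.null(names(maps))) names(maps) <- as.character(tumors$tumor_id)
  miss <- setdiff(as.character(tumors$tumor_id), names(maps))
  if (length(miss))
    stop("no maps supplied for tumor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(as.character(tumors$tumor_id), function(id) {
    m <- maps[[id]]
    stopifnot(inherits(m, "parameter_maps"))
    .viable_values(m)
  })
}

.argbest <- function(values, decreasing = TRUE) {
  # index of max (or min) among non-NA values; ties -> smallest index,
  # i.e. smallest threshold(s) on an ascending grid
  if (all(is.na(values))) return(NA_integer_)
  target <- if (decreasing) max(values, na.rm = TRUE)
            else min(values, na.rm = TRUE)
  which(!is.na(values) & values == target)[1L]
}

#' Calibrate a one-threshold hypoxia rule against pimonidazole
#'
#' Sweeps a single-threshold strategy (\code{ktrans_only} or
#' \code{ve_only}) over a candidate grid: for each threshold the
#' MRI-derived hypoxic fraction of every tumor is computed and compared
#' with the pimonidazole hypoxic fraction via [similarity()]. The
#' optimal threshold maximizes the similarity (ties broken toward the
#' smaller threshold); agreement statistics are computed at the optimum.
#'
#' @param tumors Data frame with at least \code{tumor_id} and
#'   \code{hf_pim}.
#' @param maps Named list of [parameter_maps()], one per tumor, named by
#'   \code{tumor_id} (unnamed lists are matched positionally).
#' @param strategy \code{"ktrans_only"} or \code{"ve_only"}.
#' @param grid A [threshold_grid()] supplying the relevant axis.
#' @return Object of class \code{calibration_result}: per-threshold
#'   similarity values, the optimum, similarity at the optimum,
#'   agreement statistics at the optimum, and the per-tumor HF table.
#'   \code{degenerate = TRUE} when the similarity is undefined on the
#'   whole grid (e.g. identical tumors).
#' @export
calibrate_1d <- function(tumors, maps,
                         strategy = c("ktrans_only", "ve_only"),
                         grid = default_threshold_grid("preclinical",
                                                       strategy)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "threshold_grid"))
  if (nrow(tumors) < 3L)
    stop("calibration needs at least 3 tumors", call. = FALSE)
  thr <- if (strategy == "ktrans_only") grid$k0trans_values
         else grid$ve0_values
  if (is.null(thr))
    stop("grid lacks the threshold axis for strategy ", strategy,
         call. = FALSE)
  viable <- .cohort_viable(tumors, maps)
  hf <- do.call(rbind, lapply(viable, function(vv) {
    vals <- if (strategy == "ktrans_only") vv$ktrans else vv$ve
    .hf_curve(vals, thr)
  }))                                 # tumors x thresholds
  hf_pim <- tumors$hf_pim
  sim <- vapply(seq_along(thr), function(j) {
    x <- hf[, j]
    if (any(is.na(x))) return(NA_real_)
    suppressWarnings(similarity(x, hf_pim))
  }, numeric(1L))
  best <- .argbest(sim)
  degenerate <- is.na(best)
  opt_thr <- if (degenerate) NA_real_ else thr[best]
  stats <- if (degenerate) {
    list(r2 = NA_real_, p_value = NA_real_, slope = NA_real_,
         intercept = NA_real_, degenerate = TRUE)
  } else suppressWarnings(agreement_stats(hf[, best], hf_pim))
  tab <- data.frame(tumor_id = tumors$tumor_id, hf_pim = hf_pim,
                    hf_mri = if (degenerate) NA_real_ else hf[, best])
  structure(list(strategy = strategy, thresholds = thr, similarity = sim,
                 optimal = if (strategy == "ktrans_only")
                   list(k0trans = opt_thr) else list(ve0 = opt_thr),
                 similarity_at_optimum =
                   if (degenerate) NA_real_ else sim[best],
                 stats = stats, table = tab, degenerate = degenerate),
            class = "calibration_result")
}

#' Calibrate a two-threshold hypoxia rule against pimonidazole
#'
#' As [calibrate_1d()] but over the Cartesian product of the Ktrans and
#' ve threshold axes, for the \code{conjunction} or \code{weighted_sum}
#' strategy. Besides the similarity surface, the two profile curves
#' through the optimum are returned (similarity versus Ktrans threshold
#' at the optimal ve threshold, and vice versa). Surface ties are broken
#' toward the smallest Ktrans threshold, then the smallest ve threshold.
#'
#' @inheritParams calibrate_1d
#' @param strategy \code{"conjunction"} or \code{"weighted_sum"}.
#' @return A \code{calibration_result} whose \code{similarity} is a
#'   matrix (Ktrans thresholds x ve thresholds), with \code{profiles}.
#' @export
calibrate_2d <- function(tumors, maps,
                         strategy = c("conjunction", "weighted_sum"),
                         grid = default_threshold_grid("preclinical",
                                                       strategy)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "threshold_grid"))
  if (nrow(tumors) < 3L)
    stop("calibration needs at least 3 tumors", call. = FALSE)
  k0 <- grid$k0trans_values; ve0 <- grid$ve0_values
  if (is.null(k0) || is.null(ve0))
    stop("2D calibration needs both threshold axes", call. = FALSE)
  viable <- .cohort_viable(tumors, maps)
  nk <- length(k0); nv <- length(ve0)
  hf <- array(NA_real_, dim = c(nrow(tumors), nk, nv))
  for (i in seq_len(nrow(tumors))) {
    vv <- viable[[i]]
    hf[i, , ] <- .hf_surface(vv$ktrans, vv$ve, k0, ve0, strategy)
  }
  hf_pim <- tumors$hf_pim
  sim <- matrix(NA_real_, nk, nv)
  for (a in seq_len(nk)) for (b in seq_len(nv)) {
    x <- hf[, a, b]
    if (!any(is.na(x)))
      sim[a, b] <- suppressWarnings(similarity(x, hf_pim))
  }
  degenerate <- all(is.na(sim))
  if (degenerate) {
    best_a <- best_b <- NA_integer_
    opt <- list(k0trans = NA_real_, ve0 = NA_real_)
    stats <- list(r2 = NA_real_, p_value = NA_real_, slope = NA_real_,
                  intercept = NA_real_, degenerate = TRUE)
    profiles <- NULL
    tab <- data.frame(tumor_id = tumors$tumor_id, hf_pim = hf_pim,
                      hf_mri = NA_real_)
  } else {
    m <- max(sim, na.rm = TRUE)
    hits <- which(!is.na(sim) & sim == m, arr.ind = TRUE)
    ord <- order(hits[, 1L], hits[, 2L])
    best_a <- hits[ord[1L], 1L]; best_b <- hits[ord[1L], 2L]
    opt <- list(k0trans = k0[best_a], ve0 = ve0[best_b])
    stats <- suppressWarnings(agreement_stats(hf[, best_a, best_b], hf_pim))
    profiles <- list(
      vs_k0trans = data.frame(k0trans = k0, similarity = sim[, best_b]),
      vs_ve0 = data.frame(ve0 = ve0, similarity = sim[best_a, ]))
    tab <- data.frame(tumor_id = tumors$tumor_id, hf_pim = hf_pim,
                      hf_mri = hf[, best_a, best_b])
  }
  structure(list(strategy = strategy,
                 thresholds = list(k0trans = k0, ve0 = ve0),
                 similarity = sim, optimal = opt,
                 similarity_at_optimum =
                   if (degenerate) NA_real_ else sim[best_a, best_b],
                 stats = stats, profiles = profiles, table = tab,
                 degenerate = degenerate),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Threshold calibration [", x$strategy, "]\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: similarity undefined on the whole grid\n")
  } else {
    opt <- paste(sprintf("%s = %g", names(x$optimal), unlist(x$optimal)),
                 collapse = ", ")
    cat(sprintf("  optimum: %s (similarity %.4f)\n", opt,
                x$similarity_at_optimum))
    cat(sprintf("  agreement at optimum: r2 = %.3f, slope = %.3f\n",
                x$stats$r2, x$stats$slope))
  }
  invisible(x)
}

#' Write a calibration result to JSON
#'
#' Serializes grid, similarity surface, optimum and agreement statistics.
#'
#' @param result A \code{calibration_result}.
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  out <- list(schema = "hypoxiaDCE/calibration/v1",
              strategy = result$strategy,
              thresholds = result$thresholds,
              similarity = result$similarity,
              optimal = result$optimal,
              similarity_at_optimum = result$similarity_at_optimum,
              stats = result$stats[c("r2", "p_value", "slope", "intercept")],
              degenerate = result$degenerate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
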