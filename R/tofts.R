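#' @title Tofts generalized pharmacokinetic model
#' @name tofts
#' @description
#' The tissue concentration predicted by the Tofts generalized model with
#' a bi-exponential AIF has the closed form
#' \deqn{C_t(t) = K^{trans} \sum_i M_i \frac{e^{-m_i t} - e^{-k_{ep} t}}
#'   {k_{ep} - m_i}, \qquad k_{ep} = K^{trans}/v_e,}
#' where \eqn{(M_i, m_i)} are the AIF amplitudes and rates. All rates are
#' converted to a single canonical time unit (minutes) so that
#' \eqn{K^{trans}} carries its conventional unit min^-1. When
#' \eqn{k_{ep}} coincides numerically with an AIF rate the degenerate
#' limit \eqn{K^{trans} M_i\, t\, e^{-m_i t}} is used.
NULL

# Raw closed-form tissue curve. t_min in minutes; amps mM; rates min^-1.
# Returns concentrations in mM. Shared by the public forward model and the
# voxel fitter (which needs a bare numeric vector in its residual loop).
.tofts_ct <- function(ktrans, ve, amps, rates_min, t_min) {
  if (ktrans == 0) return(numeric(length(t_min)))
  kep <- ktrans / ve
  ct <- numeric(length(t_min))
  for (i in seq_along(amps)) {
    m <- rates_min[i]
    if (abs(kep - m) < 1e-8) {
      term <- amps[i] * t_min * exp(-m * t_min)
    } else {
      term <- amps[i] * (exp(-m * t_min) - exp(-kep * t_min)) / (kep - m)
    }
    ct <- ct + term
  }
  pmax(ktrans * ct, 0)
}

.aif_amps <- function(params) c(params$amp_fast, params$amp_slow)
# AIF rates are stored in s^-1 as printed; the model works in minutes.
.aif_rates_min <- function(params) c(params$rate_fast, params$rate_slow) * 60

#' Concentration-time curve container
#'
#' A tissue contrast concentration series sampled at strictly increasing
#' times, with the first sample at contrast arrival (t = 0).
#'
#' @param times Sample times in seconds; strictly increasing, starting at 0.
#' @param concentrations Concentrations in mM, same length as \code{times}.
#' @return An object of class \code{concentration_curve}.
#' @export
concentration_curve <- function(times, concentrations) {
  stopifnot(is.numeric(times), is.numeric(concentrations))
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length", call. = FALSE)
  if (length(times) < 4L)
    stop("a concentration curve needs at least 4 samples", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (times[1L] != 0)
    stop("first sample must be at contrast arrival, t = 0", call. = FALSE)
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations)),
            class = "concentration_curve")
}

#' Forward Tofts model
#'
#' Evaluates the closed-form tissue concentration curve for given
#' \eqn{K^{trans}} and \eqn{v_e} under a population AIF.
#'
#' @param ktrans Volume transfer rate constant, min^-1 (\code{>= 0}).
#' @param ve Fractional distribution volume (dimensionless, \code{> 0}
#'   unless \code{ktrans == 0}).
#' @param params An [aif_parameters()] object.
#' @param times Sample times in seconds, strictly increasing from 0.
#' @return A [concentration_curve()] with \eqn{C_t(0) = 0} and
#'   \eqn{C_t \ge 0} everywhere.
#' @export
#' @examples
#' aif <- aif_preset("murine")
#' tofts_forward(0.1, 0.3, aif, seq(0, 600, by = 14.8))
tofts_forward <- function(ktrans, ve, params, times) {
  stopifnot(inherits(params, "aif_parameters"),
            is.numeric(ktrans), length(ktrans) == 1L,
            is.numeric(ve), length(ve) == 1L, is.numeric(times))
  if (!is.finite(ktrans) || ktrans < 0)
    stop("ktrans must be finite and >= 0", call. = FALSE)
  if (ktrans > 0 && (!is.finite(ve) || ve <= 0))
    stop("ve must be > 0 when ktrans > 0 (k_ep undefined otherwise)",
         call. = FALSE)
  if (any(diff(times) <= 0) || times[1L] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  ct <- .tofts_ct(ktrans, if (ktrans == 0) 1 else ve,
                  .aif_amps(params), .aif_rates_min(params), times / 60)
  concentration_curve(times, ct)
}

#' Fit the Tofts model to one voxel
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt,
#' \code{minpack.lm::nls.lm}) of the forward model against a measured
#' concentration curve. Bounds are \eqn{K^{trans} \in [0, 5]} min^-1 and
#' \eqn{v_e \in [10^{-3}, 3]}; the upper \eqn{v_e} bound deliberately
#' admits unphysiological values \eqn{v_e > 1} so that necrotic-voxel
#' behaviour (model-assumption failure) is representable. Start point is
#' (0.1 min^-1, 0.3).
#'
#' @param curve A [concentration_curve()].
#' @param params An [aif_parameters()] object.
#' @return An object of class \code{voxel_fit}: list with \code{ktrans}
#'   (min^-1), \code{ve}, \code{residual_norm} (RMS residual, mM),
#'   \code{converged}, and \code{informative} (FALSE for all-zero or
#'   non-finite input, in which case \code{ktrans = 0}).
#' @export
fit_tofts_voxel <- function(curve, params) {
  stopifnot(inherits(curve, "concentration_curve"),
            inherits(params, "aif_parameters"))
  y <- curve$concentrations
  if (any(!is.finite(y)) || all(y == 0)) {
    return(structure(
      list(ktrans = 0, ve = NA_real_, residual_norm = 0,
           converged = FALSE, informative = FALSE),
      class = "voxel_fit"))
  }
  amps <- .aif_amps(params)
  rates <- .aif_rates_min(params)
  t_min <- curve$times / 60
  resid_fn <- function(p) .tofts_ct(p[1L], p[2L], amps, rates, t_min) - y
  fit <- minpack.lm::nls.lm(
    par = c(0.1, 0.3), lower = c(0, 1e-3), upper = c(5, 3),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500))
  structure(
    list(ktrans = fit$par[1L], ve = fit$par[2L],
         residual_norm = sqrt(mean(fit$fvec^2)),
         converged = fit$info %in% 1:4,
         informative = TRUE),
    class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("Tofts voxel fit: Ktrans = %.5g min^-1, ve = %.5g (RMS %.3g mM, %s)\n",
              x$ktrans, x$ve, x$residual_norm,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Assemble per-voxel curves into an acquisition
#'
#' Bundles a set of per-voxel concentration curves sharing one time axis
#' with their voxel locations, as produced by a DCE acquisition over a
#' tumor ROI.
#'
#' @param times Shared sample times (s), strictly increasing from 0.
#' @param concentrations Matrix, one column per voxel, \code{length(times)}
#'   rows (mM).
#' @param voxel_index Integer linear indices of the voxels into the map
#'   grid (column-major), one per column.
#' @param dim Grid dimensions of the underlying map.
#' @return An object of class \code{dce_acquisition}.
#' @export
dce_acquisition <- function(times, concentrations, voxel_index, dim) {
  concentrations <- as.matrix(concentrations)
  stopifnot(is.numeric(times), nrow(concentrations) == length(times),
            ncol(concentrations) == length(voxel_index))
  if (any(diff(times) <= 0) || times[1L] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  if (any(voxel_index < 1L) || any(voxel_index > prod(dim)))
    stop("voxel_index out of range for grid dim", call. = FALSE)
  structure(list(times = as.numeric(times), concentrations = concentrations,
                 voxel_index = as.integer(voxel_index), dim = as.integer(dim)),
            class = "dce_acquisition")
}

#' Build an acquisition from a list of curves
#'
#' Validates that every curve shares the same time axis and packs them
#' into a [dce_acquisition()].
#'
#' @param curves List of [concentration_curve()] objects.
#' @param voxel_index Linear voxel indices, one per curve.
#' @param dim Grid dimensions.
#' @return A [dce_acquisition()].
#' @export
as_dce_acquisition <- function(curves, voxel_index, dim) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1L), "concentration_curve")))
  times <- curves[[1L]]$times
  same <- vapply(curves, function(cv) {
    length(cv$times) == length(times) && all(cv$times == times)
  }, logical(1L))
  if (!all(same))
    stop("all curves must share one time axis", call. = FALSE)
  conc <- vapply(curves, function(cv) cv$concentrations,
                 numeric(length(times)))
  dce_acquisition(times, conc, voxel_index, dim)
}

#' Fit the Tofts model over an ROI
#'
#' Applies [fit_tofts_voxel()] to every voxel of an acquisition and
#' assembles the results into [parameter_maps()]. Voxels outside the ROI
#' carry \code{NA}; voxels whose curves are non-finite or all zero are
#' flagged non-informative and left \code{NA} without affecting their
#' neighbours.
#'
#' @param acq A [dce_acquisition()] (use [as_dce_acquisition()] for a
#'   plain list of curves).
#' @param params An [aif_parameters()] object.
#' @param voxel_size Spatial voxel dimensions (mm), metadata.
#' @return A [parameter_maps()] object with an additional logical
#'   \code{converged} array.
#' @export
fit_tofts_map <- function(acq, params, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(acq, "dce_acquisition"),
            inherits(params, "aif_parameters"))
  d <- acq$dim
  ktrans <- array(NA_real_, dim = d)
  ve <- array(NA_real_, dim = d)
  roi <- array(FALSE, dim = d)
  converged <- array(NA, dim = d)
  roi[acq$voxel_index] <- TRUE
  nvox <- length(acq$voxel_index)
  if (nvox > 0L) {
    for (j in seq_len(nvox)) {
      cv <- concentration_curve(acq$times, acq$concentrations[, j])
      f <- fit_tofts_voxel(cv, params)
      idx <- acq$voxel_index[j]
      converged[idx] <- f$converged
      if (f$informative) {
        ktrans[idx] <- f$ktrans
        ve[idx] <- f$ve
      }
    }
  }
  maps <- parameter_maps(ktrans, ve, roi, voxel_size = voxel_size)
  maps$converged <- converged
  maps
}
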