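#' Hypoxic-voxel classification rules
#'
#' A rule for labelling tumor voxels as hypoxic from their Ktrans and ve
#' values. Four strategies are supported, with thresholds
#' \eqn{K^{trans}_0} (min^-1) and \eqn{v_{e0}}:
#' \describe{
#'   \item{\code{ktrans_only}}{hypoxic iff \eqn{K^{trans} < K^{trans}_0}}
#'   \item{\code{ve_only}}{hypoxic iff \eqn{v_e < v_{e0}}}
#'   \item{\code{conjunction}}{hypoxic iff both inequalities hold}
#'   \item{\code{weighted_sum}}{hypoxic iff
#'     \eqn{K^{trans}/K^{trans}_0 + v_e/v_{e0} < 1}}
#' }
#' All inequalities are strict: a voxel exactly at threshold is normoxic.
#' \code{Inf} is a legal threshold (useful for limit arguments: with
#' \eqn{v_{e0} = \infty} both combination strategies reduce exactly to
#' \code{ktrans_only}).
#'
#' @param strategy One of \code{"ktrans_only"}, \code{"ve_only"},
#'   \code{"conjunction"}, \code{"weighted_sum"}.
#' @param k0trans Ktrans threshold in min^-1 (required by all but
#'   \code{ve_only}).
#' @param ve0 ve threshold (required by all but \code{ktrans_only}); may
#'   exceed 1 for \code{weighted_sum} (e.g. 8.0).
#' @return An object of class \code{hypoxia_rule}.
#' @export
#' @examples
#' hypoxia_rule("ktrans_only", k0trans = 0.015)
#' hypoxia_rule("weighted_sum", k0trans = 0.015, ve0 = 8.0)
hypoxia_rule <- function(strategy = c("ktrans_only", "ve_only",
                                      "conjunction", "weighted_sum"),
                         k0trans = NULL, ve0 = NULL) {
  strategy <- match.arg(strategy)
  needs_k <- strategy != "ve_only"
  needs_v <- strategy != "ktrans_only"
  chk <- function(x, name) {
    if (is.null(x)) stop("strategy '", strategy, "' requires threshold ",
                         name, call. = FALSE)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop(name, " must be a single positive number", call. = FALSE)
    as.numeric(x)
  }
  structure(list(strategy = strategy,
                 k0trans = if (needs_k) chk(k0trans, "k0trans") else NULL,
                 ve0 = if (needs_v) chk(ve0, "ve0") else NULL),
            class = "hypoxia_rule")
}

#' @export
print.hypoxia_rule <- function(x, ...) {
  pred <- switch(x$strategy,
    ktrans_only  = sprintf("Ktrans < %g min^-1", x$k0trans),
    ve_only      = sprintf("ve < %g", x$ve0),
    conjunction  = sprintf("Ktrans < %g min^-1 and ve < %g", x$k0trans, x$ve0),
    weighted_sum = sprintf("Ktrans/%g + ve/%g < 1", x$k0trans, x$ve0))
  cat("Hypoxia rule [", x$strategy, "]: hypoxic iff ", pred, "\n", sep = "")
  invisible(x)
}

# Label codes shared across the package and the NIfTI hypoxia images.
.LBL_OUTSIDE <- 0L
.LBL_NORMOXIC <- 1L
.LBL_HYPOXIC <- 2L
.LBL_UNPHYS <- 3L

# Vectorized voxel labelling for in-ROI voxels. Non-finite parameters and
# ve > 1 are unphysiological and never hypoxic; ve == 1 is classifiable.
.classify_values <- function(k, v, rule) {
  unphys <- !is.finite(k) | !is.finite(v) | v > 1
  hyp <- switch(rule$strategy,
    ktrans_only  = k < rule$k0trans,
    ve_only      = v < rule$ve0,
    conjunction  = k < rule$k0trans & v < rule$ve0,
    weighted_sum = k / rule$k0trans + v / rule$ve0 < 1)
  out <- ifelse(hyp, .LBL_HYPOXIC, .LBL_NORMOXIC)
  out[unphys] <- .LBL_UNPHYS
  as.integer(out)
}

#' Classify tumor voxels as hypoxic
#'
#' Applies a [hypoxia_rule()] voxel-by-voxel to parameter maps. Voxels
#' outside the ROI are labelled \code{outside_roi}; ROI voxels with
#' \eqn{v_e > 1} (or non-finite parameters) are labelled
#' \code{unphysiological} and are never hypoxic, reflecting necrotic
#' tissue in which the pharmacokinetic model assumptions fail.
#'
#' @param maps A [parameter_maps()] object.
#' @param rule A [hypoxia_rule()].
#' @param include_unphysiological Logical; if \code{TRUE}, unphysiological
#'   voxels enter the hypoxic-fraction denominator (they still cannot be
#'   hypoxic). Default \code{FALSE}: the fraction is taken over viable
#'   voxels only, by analogy with pimonidazole hypoxic fraction being an
#'   area fraction of viable tissue.
#' @return An object of class \code{hypoxia_image}: integer label array
#'   (0 outside, 1 normoxic, 2 hypoxic, 3 unphysiological), per-label
#'   counts, the rule, and \code{hf_mri} (NA if no classifiable voxel).
#' @export
classify_voxels <- function(maps, rule, include_unphysiological = FALSE) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(rule, "hypoxia_rule"))
  labels <- array(.LBL_OUTSIDE, dim = dim(maps$ktrans))
  if (any(maps$roi)) {
    labels[maps$roi] <- .classify_values(maps$ktrans[maps$roi],
                                         maps$ve[maps$roi], rule)
  }
  n_hyp <- sum(labels == .LBL_HYPOXIC)
  n_norm <- sum(labels == .LBL_NORMOXIC)
  n_unph <- sum(labels == .LBL_UNPHYS)
  denom <- n_hyp + n_norm + if (include_unphysiological) n_unph else 0L
  hf <- if (denom > 0L) n_hyp / denom else NA_real_
  structure(list(labels = labels, rule = rule, hf_mri = hf,
                 counts = c(hypoxic = n_hyp, normoxic = n_norm,
                            unphysiological = n_unph,
                            outside_roi = sum(labels == .LBL_OUTSIDE)),
                 include_unphysiological = include_unphysiological),
            class = "hypoxia_image")
}

#' @export
print.hypoxia_image <- function(x, ...) {
  cat("Hypoxia image (", paste(dim(x$labels), collapse = "x"), "): ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      sprintf("; HF_MRI = %.4f\n", x$hf_mri), sep = "")
  invisible(x)
}

#' DCE-MRI-derived hypoxic fraction
#'
#' The fraction of classifiable tumor voxels labelled hypoxic under a
#' rule: \code{hypoxic / (hypoxic + normoxic)}, excluding unphysiological
#' (\eqn{v_e > 1}) and outside-ROI voxels from both numerator and
#' denominator (switchable via \code{include_unphysiological}).
#'
#' @inheritParams classify_voxels
#' @return A fraction in \[0, 1\]; \code{NA} with a warning when the ROI
#'   has no classifiable voxel (undefined, never silently 0).
#' @export
hypoxic_fraction <- function(maps, rule, include_unphysiological = FALSE) {
  img <- classify_voxels(maps, rule, include_unphysiological)
  if (is.na(img$hf_mri))
    warning("hypoxic fraction undefined: ROI has no classifiable voxel")
  img$hf_mri
}

#' Write a hypoxia image as a coded NIfTI-1 volume
#'
#' Integer coding: 0 outside ROI, 1 normoxic, 2 hypoxic,
#' 3 unphysiological.
#'
#' @param image A \code{hypoxia_image} from [classify_voxels()].
#' @param path Output NIfTI path.
#' @param voxel_size Voxel dimensions (mm).
#' @return Invisibly, \code{path}.
#' @export
write_hypoxia_image <- function(image, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(image, "hypoxia_image"))
  a <- image$labels
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  pix <- c(voxel_size, rep(1, max(0, 3 - length(voxel_size))))[1:3]
  img <- RNifti::asNifti(a, reference = list(pixdim = c(-1, pix, rep(1, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Fast HF sweeps used by calibration and survival threshold sweeps.
# `vals` are viable-voxel parameter values; thresholds sorted ascending.
# Strict inequality: count(vals < thr) via findInterval(left.open).
.hf_curve <- function(vals, thresholds) {
  n <- length(vals)
  if (n == 0L) return(rep(NA_real_, length(thresholds)))
  findInterval(thresholds, sort(vals), left.open = TRUE) / n
}

# HF surface over a (k0trans, ve0) grid for one tumor's viable voxels.
# conjunction: 2D cumulative count; weighted_sum: per-ve0 reduction to a
# 1D strict-threshold count of k / (1 - v/ve0).
.hf_surface <- function(k, v, k0_values, ve0_values, strategy) {
  nk <- length(k0_values); nv <- length(ve0_values); n <- length(k)
  if (n == 0L) return(matrix(NA_real_, nk, nv))
  if (strategy == "conjunction") {
    pk <- findInterval(k, k0_values)       # of thresholds <= k
    pv <- findInterval(v, ve0_values)
    tab <- matrix(0, nk + 1L, nv + 1L)
    for (i in seq_len(n)) {
      tab[pk[i] + 1L, pv[i] + 1L] <- tab[pk[i] + 1L, pv[i] + 1L] + 1
    }
    cum <- apply(apply(tab, 2L, cumsum), 1L, cumsum)  # -> (nv+1) x (nk+1)
    t(cum)[seq_len(nk), seq_len(nv), drop = FALSE] / n
  } else if (strategy == "weighted_sum") {
    out <- matrix(NA_real_, nk, nv)
    for (j in seq_len(nv)) {
      inside <- v < ve0_values[j]
      z <- k[inside] / (1 - v[inside] / ve0_values[j])
      zs <- sort(z)
      out[, j] <- findInterval(k0_values, zs, left.open = TRUE) / n
    }
    out
  } else stop("strategy must be 'conjunction' or 'weighted_sum'")
}
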