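#' Split a cohort into high and low hypoxic-fraction groups
#'
#' One-third/two-thirds stratification: the \code{floor(N/3)} patients
#' with the largest hypoxic fraction form the high-HF group and the rest
#' the low-HF group (for N = 80 this gives 26 versus 54). The split size
#' mirrors the proportion of locally-advanced cervical carcinoma
#' patients in whom first-line treatment fails. Ties at the boundary are
#' broken deterministically by \code{patient_id} order and flagged.
#'
#' @param patients Data frame with \code{patient_id} and the hypoxic
#'   fraction column.
#' @param hf_col Name of the hypoxic-fraction column (default
#'   \code{"hf_mri"}).
#' @return List of class \code{cohort_split} with data frames
#'   \code{high} and \code{low}, plus \code{boundary_tie} (TRUE when
#'   tied HF values straddle the cut) and \code{n_excluded} (patients
#'   dropped for missing HF, with a warning).
#' @export
split_cohort <- function(patients, hf_col = "hf_mri") {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", hf_col) %in% names(patients)))
  hf <- patients[[hf_col]]
  drop <- is.na(hf)
  if (any(drop)) {
    warning(sum(drop), " patient(s) excluded for missing ", hf_col)
    patients <- patients[!drop, , drop = FALSE]
    hf <- hf[!drop]
  }
  n <- nrow(patients)
  if (n < 3L)
    stop("cohort split needs at least 3 patients with ", hf_col,
         call. = FALSE)
  n_high <- n %/% 3L
  ord <- order(-hf, patients$patient_id)
  high <- patients[ord[seq_len(n_high)], , drop = FALSE]
  low <- patients[ord[-seq_len(n_high)], , drop = FALSE]
  boundary_tie <- hf[ord[n_high]] == hf[ord[n_high + 1L]]
  structure(list(high = high, low = low, hf_col = hf_col,
                 boundary_tie = boundary_tie, n_excluded = sum(drop)),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("Cohort split on %s: %d high / %d low%s\n", x$hf_col,
              nrow(x$high), nrow(x$low),
              if (x$boundary_tie) " (tie at boundary)" else ""))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; right-censored
#' observations reduce the risk set without a survival drop.
#'
#' @param times Event or censoring times (months), \code{>= 0}.
#' @param events Event indicators (1/TRUE = event observed).
#' @return Object of class \code{km_curve}: step-function table
#'   (\code{time}, \code{n_risk}, \code{n_event}, \code{survival}) and
#'   the underlying \code{survival::survfit} object.
#' @export
km_estimator <- function(times, events) {
  stopifnot(is.numeric(times), length(times) >= 1L,
            length(times) == length(events))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(table = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event,
                                    survival = fit$surv),
                 fit = fit, n = length(times)),
            class = "km_curve")
}

#' Survival probability at given times
#'
#' Evaluates a [km_estimator()] step function, S(0) = 1.
#'
#' @param km A \code{km_curve}.
#' @param times Times (months) to evaluate at.
#' @return Survival probabilities.
#' @export
km_survival <- function(km, times) {
  stopifnot(inherits(km, "km_curve"))
  s <- summary(km$fit, times = times, extend = TRUE)
  s$surv
}

#' Numbers at risk at given times
#'
#' @param km A \code{km_curve}.
#' @param times Times (months).
#' @return Integer numbers at risk.
#' @export
km_at_risk <- function(km, times) {
  stopifnot(inherits(km, "km_curve"))
  s <- summary(km$fit, times = times, extend = TRUE)
  s$n.risk
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events\n", x$n,
              sum(x$table$n_event)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-square (1 df, hypergeometric
#' variance with simultaneous risk-set tie handling) with its two-sided
#' p-value. With zero events overall the test is degenerate: statistic
#' 0, p = 1, flagged.
#'
#' @param times1,events1 Times and event flags of group 1.
#' @param times2,events2 Times and event flags of group 2.
#' @return List with \code{chi_square}, \code{p_value}, \code{n},
#'   \code{observed}, \code{expected}, \code{degenerate}.
#' @export
logrank_test <- function(times1, events1, times2, events2) {
  stopifnot(length(times1) == length(events1),
            length(times2) == length(events2))
  if (length(times1) == 0L || length(times2) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  e1 <- as.integer(as.logical(events1))
  e2 <- as.integer(as.logical(events2))
  if (sum(e1) + sum(e2) == 0L) {
    return(list(chi_square = 0, p_value = 1, n = c(length(times1),
                length(times2)), observed = c(0, 0), expected = c(0, 0),
                degenerate = TRUE))
  }
  grp <- factor(rep(1:2, c(length(times1), length(times2))))
  sd <- survival::survdiff(
    survival::Surv(c(times1, times2), c(e1, e2)) ~ grp)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       n = unname(sd$n), observed = unname(sd$obs),
       expected = unname(sd$exp), degenerate = FALSE)
}

# Resolve endpoint column names in a patients table.
.endpoint_cols <- function(endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  c(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

# HF per patient per threshold: either from maps (recomputed) or from a
# precomputed hf_table (patients x thresholds).
.sweep_hf_table <- function(patients, maps, hf_table, strategy, thr) {
  if (!is.null(hf_table)) {
    hf_table <- as.matrix(hf_table)
    stopifnot(nrow(hf_table) == nrow(patients),
              ncol(hf_table) == length(thr))
    return(hf_table)
  }
  if (is.null(maps))
    stop("supply either per-patient maps or a precomputed hf_table",
         call. = FALSE)
  if (is.null(names(maps))) names(maps) <- as.character(patients$patient_id)
  do.call(rbind, lapply(as.character(patients$patient_id), function(id) {
    vv <- .viable_values(maps[[id]])
    vals <- if (strategy == "ktrans_only") vv$ktrans else vv$ve
    .hf_curve(vals, thr)
  }))
}

.sweep_one <- function(patients, hf, tcol, ecol) {
  # log-rank p for one threshold's HF vector; NA when the split is
  # degenerate (all HF equal) or HF is missing
  if (any(is.na(hf)) || length(unique(hf)) == 1L)
    return(c(NA_real_, NA_real_))
  tmp <- patients
  tmp$.hf <- hf
  sp <- suppressWarnings(split_cohort(tmp, ".hf"))
  lr <- logrank_test(sp$high[[tcol]], sp$high[[ecol]],
                     sp$low[[tcol]], sp$low[[ecol]])
  c(lr$chi_square, lr$p_value)
}

#' One-dimensional survival threshold sweep
#'
#' For every candidate threshold of a single-threshold strategy, the
#' per-patient hypoxic fraction is computed (from maps, or taken from a
#' precomputed table), the cohort is split one-third/two-thirds on it,
#' and the two groups are compared by the log-rank test on the chosen
#' endpoint. No multiplicity correction is applied across thresholds;
#' the result records how many thresholds were tested.
#'
#' @param patients Data frame with \code{patient_id}, endpoint columns
#'   (\code{dfs_time}, \code{dfs_event}, \code{os_time},
#'   \code{os_event} as applicable).
#' @param strategy \code{"ktrans_only"} or \code{"ve_only"}.
#' @param grid A [threshold_grid()] supplying the relevant axis.
#' @param endpoint \code{"dfs"} or \code{"os"}.
#' @param maps Named list of [parameter_maps()] per patient, or NULL.
#' @param hf_table Optional precomputed HF matrix (patients x
#'   thresholds), bypassing \code{maps}.
#' @return Object of class \code{survival_sweep}: data frame
#'   (\code{threshold}, \code{chi_square}, \code{p_value}), the optimal
#'   threshold (argmin p, ties toward smaller threshold), and the
#'   thresholds significant at p < 0.05.
#' @export
survival_sweep_1d <- function(patients,
                              strategy = c("ktrans_only", "ve_only"),
                              grid = default_threshold_grid("clinical",
                                                            strategy),
                              endpoint = c("dfs", "os"),
                              maps = NULL, hf_table = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "threshold_grid"))
  cols <- .endpoint_cols(endpoint)
  stopifnot(all(cols %in% names(patients)))
  thr <- if (strategy == "ktrans_only") grid$k0trans_values
         else grid$ve0_values
  if (is.null(thr))
    stop("grid lacks the threshold axis for strategy ", strategy,
         call. = FALSE)
  hfm <- .sweep_hf_table(patients, maps, hf_table, strategy, thr)
  res <- vapply(seq_along(thr), function(j)
    .sweep_one(patients, hfm[, j], cols["time"], cols["event"]),
    numeric(2L))
  p <- res[2L, ]
  best <- .argbest(p, decreasing = FALSE)
  structure(list(strategy = strategy, endpoint = match.arg(endpoint),
                 results = data.frame(threshold = thr,
                                      chi_square = res[1L, ], p_value = p),
                 optimal = if (is.na(best)) NA_real_ else thr[best],
                 p_at_optimum = if (is.na(best)) NA_real_ else p[best],
                 significant_thresholds = thr[!is.na(p) & p < 0.05],
                 n_thresholds = length(thr)),
            class = "survival_sweep")
}

#' Two-dimensional survival threshold sweep
#'
#' As [survival_sweep_1d()] over the Cartesian product of Ktrans and ve
#' threshold axes for the \code{conjunction} or \code{weighted_sum}
#' strategy, producing a p-value surface. The optimum is the argmin of
#' p, ties broken toward smaller Ktrans then ve thresholds.
#'
#' @inheritParams survival_sweep_1d
#' @param strategy \code{"conjunction"} or \code{"weighted_sum"}.
#' @param hf_table Optional precomputed HF array (patients x Ktrans
#'   thresholds x ve thresholds).
#' @return A \code{survival_sweep} whose \code{p_value} is a matrix.
#' @export
survival_sweep_2d <- function(patients,
                              strategy = c("conjunction", "weighted_sum"),
                              grid = default_threshold_grid("clinical",
                                                            strategy),
                              endpoint = c("dfs", "os"),
                              maps = NULL, hf_table = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "threshold_grid"))
  cols <- .endpoint_cols(endpoint)
  stopifnot(all(cols %in% names(patients)))
  k0 <- grid$k0trans_values; ve0 <- grid$ve0_values
  if (is.null(k0) || is.null(ve0))
    stop("2D sweep needs both threshold axes", call. = FALSE)
  nk <- length(k0); nv <- length(ve0); np <- nrow(patients)
  if (is.null(hf_table)) {
    if (is.null(maps))
      stop("supply either per-patient maps or a precomputed hf_table",
           call. = FALSE)
    if (is.null(names(maps)))
      names(maps) <- as.character(patients$patient_id)
    hf_table <- array(NA_real_, dim = c(np, nk, nv))
    for (i in seq_len(np)) {
      vv <- .viable_values(maps[[as.character(patients$patient_id[i])]])
      hf_table[i, , ] <- .hf_surface(vv$ktrans, vv$ve, k0, ve0, strategy)
    }
  }
  stopifnot(identical(dim(hf_table), as.integer(c(np, nk, nv))))
  pmat <- matrix(NA_real_, nk, nv)
  cmat <- matrix(NA_real_, nk, nv)
  for (a in seq_len(nk)) for (b in seq_len(nv)) {
    r <- .sweep_one(patients, hf_table[, a, b], cols["time"], cols["event"])
    cmat[a, b] <- r[1L]; pmat[a, b] <- r[2L]
  }
  if (all(is.na(pmat))) {
    opt <- list(k0trans = NA_real_, ve0 = NA_real_); popt <- NA_real_
  } else {
    m <- min(pmat, na.rm = TRUE)
    hits <- which(!is.na(pmat) & pmat == m, arr.ind = TRUE)
    ord <- order(hits[, 1L], hits[, 2L])
    a <- hits[ord[1L], 1L]; b <- hits[ord[1L], 2L]
    opt <- list(k0trans = k0[a], ve0 = ve0[b]); popt <- pmat[a, b]
  }
  structure(list(strategy = strategy, endpoint = match.arg(endpoint),
                 thresholds = list(k0trans = k0, ve0 = ve0),
                 chi_square = cmat, p_value = pmat, optimal = opt,
                 p_at_optimum = popt, n_thresholds = nk * nv),
            class = "survival_sweep")
}

#' @export
print.survival_sweep <- function(x, ...) {
  cat("Survival threshold sweep [", x$strategy, ", ", toupper(x$endpoint),
      "], ", x$n_thresholds, " thresholds\n", sep = "")
  if (is.list(x$optimal)) {
    cat(sprintf("  optimum: k0trans = %g, ve0 = %g (p = %.4g)\n",
                x$optimal$k0trans, x$optimal$ve0, x$p_at_optimum))
  } else {
    cat(sprintf("  optimum: threshold = %g (p = %.4g); %d thresholds with p < 0.05\n",
                x$optimal, x$p_at_optimum,
                length(x$significant_thresholds)))
  }
  invisible(x)
}

#' Stratify a cohort and compare survival at one rule
#'
#' Convenience wrapper: split the cohort one-third/two-thirds on a
#' hypoxic-fraction column, estimate Kaplan-Meier curves per group and
#' compare them by the log-rank test on both endpoints present.
#'
#' @param patients Data frame with \code{patient_id}, HF column and
#'   endpoint columns.
#' @param hf_col Hypoxic-fraction column name.
#' @param at_risk_times Times (months) at which numbers at risk are
#'   tabulated.
#' @return Object of class \code{stratification_result}: the split, and
#'   per endpoint the KM curves, log-rank result, and at-risk table.
#' @export
stratify_cohort <- function(patients, hf_col = "hf_mri",
                            at_risk_times = seq(0, 80, by = 20)) {
  sp <- split_cohort(patients, hf_col)
  endpoints <- intersect(c("dfs", "os"),
                         c(if (all(c("dfs_time", "dfs_event") %in%
                                   names(patients))) "dfs",
                           if (all(c("os_time", "os_event") %in%
                                   names(patients))) "os"))
  if (length(endpoints) == 0L)
    stop("patients table has no complete endpoint columns", call. = FALSE)
  res <- lapply(endpoints, function(ep) {
    cols <- .endpoint_cols(ep)
    km_high <- km_estimator(sp$high[[cols["time"]]],
                            sp$high[[cols["event"]]])
    km_low <- km_estimator(sp$low[[cols["time"]]], sp$low[[cols["event"]]])
    lr <- logrank_test(sp$high[[cols["time"]]], sp$high[[cols["event"]]],
                       sp$low[[cols["time"]]], sp$low[[cols["event"]]])
    list(endpoint = ep, km_high = km_high, km_low = km_low, logrank = lr,
         at_risk = data.frame(time = at_risk_times,
                              high = km_at_risk(km_high, at_risk_times),
                              low = km_at_risk(km_low, at_risk_times)))
  })
  names(res) <- endpoints
  structure(list(split = sp, endpoints = res), class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  print(x$split)
  for (ep in x$endpoints) {
    cat(sprintf("  %s: log-rank chi-square = %.3f, p = %.4g\n",
                toupper(ep$endpoint), ep$logrank$chi_square,
                ep$logrank$p_value))
  }
  invisible(x)
}
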