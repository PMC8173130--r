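# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form / survdiff code paths.

# Fine-step numerical convolution of the Tofts kernel with the AIF:
# Ct(t) = Ktrans int_0^t Ca(u) exp(-kep (t-u)) du, via cumulative
# trapezoidal quadrature on an h-second grid.
conv_oracle <- function(ktrans, ve, params, times, h = 0.01) {
  kep_s <- ktrans / ve / 60
  tg <- seq(0, max(times), by = h)
  ca <- evaluate_aif(params, tg)
  cum <- pracma::cumtrapz(tg, ca * exp(kep_s * tg))[, 1L]
  ct <- (ktrans / 60) * exp(-kep_s * tg) * cum
  stats::approx(tg, ct, xout = times)$y
}

# Hand-coded two-group log-rank chi-square (hypergeometric variance,
# simultaneous risk-set tie handling), independent of survival::survdiff.
logrank_chisq_hand <- function(times, events, in_group1) {
  tu <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (s in tu) {
    at_risk <- times >= s
    n <- sum(at_risk); n1 <- sum(at_risk & in_group1)
    d <- sum(times == s & events == 1)
    d1 <- sum(times == s & events == 1 & in_group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# Exhaustive permutation distribution of a two-group statistic over all
# relabelings that keep group sizes fixed.
perm_pvalue <- function(times, events, n1, stat_fn) {
  n <- length(times)
  combs <- utils::combn(n, n1)
  obs <- stat_fn(times, events, seq_len(n) <= n1)
  stats <- apply(combs, 2L, function(ix) {
    g <- rep(FALSE, n); g[ix] <- TRUE
    stat_fn(times, events, g)
  })
  mean(stats >= obs - 1e-9)
}

# Brute-force voxel classification mirroring the printed rule definitions.
brute_hf <- function(k, v, strategy, k0 = NULL, ve0 = NULL) {
  viable <- is.finite(k) & is.finite(v) & v <= 1
  k <- k[viable]; v <- v[viable]
  hyp <- switch(strategy,
    ktrans_only = k < k0,
    ve_only = v < ve0,
    conjunction = k < k0 & v < ve0,
    weighted_sum = k / k0 + v / ve0 < 1)
  if (length(hyp) == 0L) return(NA_real_)
  mean(hyp)
}

# Small random maps for property tests.
random_maps <- function(n = 10L, p_unphys = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- matrix(stats::runif(n * n, 0, 0.1), n, n)
  v <- matrix(stats::runif(n * n, 0, 1), n, n)
  unphys <- stats::runif(n * n) < p_unphys
  v[unphys] <- stats::runif(sum(unphys), 1.01, 2)
  parameter_maps(k, v, matrix(TRUE, n, n))
}

tiny_cohort_spec <- function(...) {
  cohort_spec(n_tumors = 12L, n_patients = 24L, ...)
}

small_template <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L), tumor_radius = 9, ...)
}
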