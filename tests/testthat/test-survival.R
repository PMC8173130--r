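test_that("one-third/two-thirds split yields the documented group sizes", {
  set.seed(101)
  p80 <- data.frame(patient_id = sprintf("P%02d", 1:80),
                    hf_mri = stats::runif(80))
  sp <- split_cohort(p80)
  expect_equal(nrow(sp$high), 26L)
  expect_equal(nrow(sp$low), 54L)
  expect_true(min(sp$high$hf_mri) >= max(sp$low$hf_mri))

  p3 <- data.frame(patient_id = c("a", "b", "c"), hf_mri = c(0.2, 0.9, 0.4))
  sp3 <- split_cohort(p3)
  expect_equal(nrow(sp3$high), 1L)
  expect_equal(sp3$high$patient_id, "b")

  p9 <- data.frame(patient_id = letters[1:9], hf_mri = seq(0.1, 0.9, 0.1))
  sp9 <- split_cohort(p9)
  expect_equal(sort(sp9$high$hf_mri), c(0.7, 0.8, 0.9))

  for (n in 3:20) {
    sp_n <- split_cohort(data.frame(patient_id = seq_len(n),
                                    hf_mri = stats::runif(n)))
    expect_equal(nrow(sp_n$high), n %/% 3L)
    expect_equal(nrow(sp_n$low), n - n %/% 3L)
  }
})

test_that("split handles missing values and boundary ties deterministically", {
  p <- data.frame(patient_id = letters[1:7],
                  hf_mri = c(0.9, 0.5, 0.5, 0.5, 0.2, 0.1, NA))
  expect_warning(sp <- split_cohort(p), "excluded")
  expect_equal(nrow(sp$high) + nrow(sp$low), 6L)
  expect_true(sp$boundary_tie)
  # ties broken by patient_id order: 0.9 then "b" among the tied 0.5s
  expect_equal(sort(sp$high$patient_id), c("a", "b"))
})

test_that("Kaplan-Meier estimates match hand product-limit results", {
  km0 <- km_estimator(c(3, 8, 12, 20, 25), rep(0, 5))
  expect_true(all(km_survival(km0, c(5, 10, 30)) == 1))

  km1 <- km_estimator(c(10, 12, 15, 20), c(1, 0, 0, 0))
  expect_equal(km_survival(km1, 10), 0.75)

  km2 <- km_estimator(c(6, 7, 10, 15), c(1, 0, 1, 1))
  expect_equal(km_survival(km2, 10), 0.375)  # (3/4) * (1/2)

  # no censoring: product-limit equals the empirical survival function
  set.seed(103)
  t <- stats::rexp(40, 0.1)
  km3 <- km_estimator(t, rep(1, 40))
  at <- c(2, 5, 10, 20)
  expect_equal(km_survival(km3, at),
               vapply(at, function(s) mean(t > s), numeric(1L)))
  expect_equal(km_at_risk(km3, 0), 40)
  expect_error(km_estimator(numeric(0), integer(0)))
})

test_that("log-rank is symmetric and degenerates gracefully", {
  t <- c(5, 10, 15, 20); e <- c(1, 0, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  t2 <- c(3, 6, 9, 30); e2 <- c(1, 1, 0, 1)
  a <- logrank_test(t, e, t2, e2)
  b <- logrank_test(t2, e2, t, e)
  expect_equal(a$chi_square, b$chi_square)
  expect_equal(a$p_value, b$p_value)

  z <- logrank_test(t, rep(0, 4), t2, rep(0, 4))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  expect_error(logrank_test(numeric(0), integer(0), t, e), "non-empty")
})

test_that("log-rank statistic matches a hand-coded hypergeometric oracle", {
  set.seed(107)
  for (i in 1:10) {
    n <- 8L
    t <- round(stats::rexp(n, 0.1), 1)
    e <- stats::rbinom(n, 1L, 0.8)
    if (sum(e) == 0L) e[1L] <- 1L
    ours <- logrank_test(t[1:4], e[1:4], t[5:8], e[5:8])$chi_square
    hand <- logrank_chisq_hand(t, e, seq_len(n) <= 4L)
    expect_equal(ours, hand, tolerance = 1e-9)
  }
})

test_that("log-rank p-values track the exact permutation distribution", {
  # dual route: the permutation distribution of our statistic must equal
  # that of the independently coded statistic exactly; the asymptotic
  # chi-square p may differ from the exact p only by its small-sample
  # approximation error (bounded at 0.15 for n <= 8)
  via_pkg <- function(t, e, g)
    logrank_test(t[g], e[g], t[!g], e[!g])$chi_square
  sep_t <- c(1, 2, 3, 10, 20, 30); sep_e <- rep(1L, 6)
  p_pkg <- perm_pvalue(sep_t, sep_e, 3L, via_pkg)
  p_hand <- perm_pvalue(sep_t, sep_e, 3L, logrank_chisq_hand)
  expect_equal(p_pkg, p_hand, tolerance = 1e-12)
  p_asym <- logrank_test(sep_t[1:3], sep_e[1:3], sep_t[4:6],
                         sep_e[4:6])$p_value
  expect_lt(abs(p_asym - p_pkg), 0.15)
  set.seed(109)
  for (i in 1:5) {
    t <- round(stats::rexp(8, 0.1), 1)
    e <- stats::rbinom(8, 1L, 0.8); if (sum(e) == 0L) e[1L] <- 1L
    expect_equal(perm_pvalue(t, e, 4L, via_pkg),
                 perm_pvalue(t, e, 4L, logrank_chisq_hand),
                 tolerance = 1e-12)
    p_asym <- logrank_test(t[1:4], e[1:4], t[5:8], e[5:8])$p_value
    expect_lt(abs(p_asym - perm_pvalue(t, e, 4L, via_pkg)), 0.15)
  }
})

test_that("a single-threshold sweep equals one log-rank call", {
  cl <- simulate_clinical_cohort(tiny_cohort_spec(seed = 111),
                                 small_template())
  grid <- threshold_grid(k0trans_values = 0.015)
  sw <- survival_sweep_1d(cl$patients, "ktrans_only", grid, "dfs",
                          maps = cl$maps)
  hf <- vapply(cl$maps, function(m)
    hypoxic_fraction(m, hypoxia_rule("ktrans_only", k0trans = 0.015)),
    numeric(1L))
  tmp <- cl$patients; tmp$hf_mri <- hf
  sp <- split_cohort(tmp)
  lr <- logrank_test(sp$high$dfs_time, sp$high$dfs_event,
                     sp$low$dfs_time, sp$low$dfs_event)
  expect_equal(sw$results$p_value, lr$p_value)
  expect_equal(sw$optimal, 0.015)
})

test_that("degenerate thresholds are recorded as missing, not errors", {
  cl <- simulate_clinical_cohort(tiny_cohort_spec(seed = 113),
                                 small_template())
  # below every voxel's ktrans the HF is 0 for all patients
  grid <- threshold_grid(k0trans_values = c(1e-8, 0.015))
  sw <- survival_sweep_1d(cl$patients, "ktrans_only", grid, "dfs",
                          maps = cl$maps)
  expect_true(is.na(sw$results$p_value[1L]))
  expect_false(is.na(sw$results$p_value[2L]))
})

test_that("the 2D sweep at dominating ve0 reduces to the 1D sweep", {
  cl <- simulate_clinical_cohort(tiny_cohort_spec(seed = 115),
                                 small_template())
  k0 <- seq(0.005, 0.03, by = 0.005)
  sw1 <- survival_sweep_1d(cl$patients, "ktrans_only",
                           threshold_grid(k0trans_values = k0), "dfs",
                           maps = cl$maps)
  sw2 <- survival_sweep_2d(cl$patients, "conjunction",
                           threshold_grid(k0, ve0_values = c(0.5, 1.001)),
                           "dfs", maps = cl$maps)
  expect_equal(sw2$p_value[, 2L], sw1$results$p_value)
  # argmin over the superset cannot exceed the shared-axis minimum
  expect_lte(sw2$p_at_optimum, min(sw1$results$p_value, na.rm = TRUE))
  # 1x1 grid is a single log-rank result
  sw11 <- survival_sweep_2d(cl$patients, "conjunction",
                            threshold_grid(0.015, ve0_values = 1.001),
                            "dfs", maps = cl$maps)
  expect_equal(dim(sw11$p_value), c(1L, 1L))
  expect_equal(sw11$p_at_optimum,
               survival_sweep_1d(cl$patients, "ktrans_only",
                                 threshold_grid(k0trans_values = 0.015),
                                 "dfs", maps = cl$maps)$p_at_optimum)
})

test_that("stratification reports per-endpoint log-rank and at-risk tables", {
  cl <- simulate_clinical_cohort(cohort_spec(n_patients = 30L, seed = 117))
  st <- stratify_cohort(cl$patients, at_risk_times = c(0, 20, 40))
  expect_equal(nrow(st$split$high), 10L)
  for (ep in st$endpoints) {
    expect_true(ep$logrank$p_value >= 0 && ep$logrank$p_value <= 1)
    expect_equal(ep$at_risk$time, c(0, 20, 40))
    expect_equal(ep$at_risk$high[1L], 10L)
    expect_true(all(diff(ep$at_risk$high) <= 0))
  }
})
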