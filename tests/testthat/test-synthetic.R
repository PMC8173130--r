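test_that("a phantom with no hypoxic zone and no noise has zero true HF", {
  sp <- phantom_spec(grid_shape = c(24L, 24L), tumor_radius = 9,
                     core_fraction = 0, hypoxic_radius_fraction = 0,
                     sigma_log = 0, ktrans_tumor_sigma = 0, ve_sd = 0,
                     seed = 121)
  ph <- simulate_phantom(sp)
  expect_equal(ph$true_hf, 0)
  expect_equal(sum(ph$maps$ve[ph$maps$roi] > 1), 0L)
})

test_that("the noise-free true HF equals the hypoxic-zone area fraction", {
  sp <- phantom_spec(grid_shape = c(64L, 64L), tumor_radius = 24,
                     core_fraction = 0.25, hypoxic_radius_fraction = 0.6,
                     sigma_log = 0, ktrans_tumor_sigma = 0, ve_sd = 0,
                     seed = 123)
  ph <- simulate_phantom(sp)
  # independent geometric count of the annulus over viable voxels
  cx <- (64 + 1) / 2
  r <- sqrt(outer((1:64 - cx)^2, (1:64 - cx)^2, `+`))
  viable <- r <= 24 & r > 0.25 * 24
  annulus <- viable & r <= 0.6 * 24
  expect_equal(ph$true_hf, sum(annulus) / sum(viable))
  # and it approximates the analytic area ratio
  f_analytic <- (0.6^2 - 0.25^2) / (1 - 0.25^2)
  expect_lt(abs(ph$true_hf - f_analytic), 0.05)
})

test_that("phantom structure is concentric: hypoxia surrounds necrosis", {
  ph <- simulate_phantom(phantom_spec(seed = 125))
  d <- dim(ph$truth)
  cx <- (d[1L] + 1) / 2
  r <- sqrt(outer((seq_len(d[1L]) - cx)^2, (seq_len(d[2L]) - cx)^2, `+`))
  expect_lt(max(r[ph$truth == 3L]), min(r[ph$truth == 1L]))
  expect_gt(mean(r[ph$truth == 2L]), mean(r[ph$truth == 3L]))
})

test_that("generators are deterministic given a seed", {
  a <- simulate_phantom(phantom_spec(seed = 127))
  b <- simulate_phantom(phantom_spec(seed = 127))
  expect_identical(a$maps$ktrans, b$maps$ktrans)
  expect_identical(a$true_hf, b$true_hf)
  c <- simulate_phantom(phantom_spec(seed = 128))
  expect_false(identical(a$maps$ktrans, c$maps$ktrans))

  s <- tiny_cohort_spec(seed = 129)
  p1 <- simulate_preclinical_cohort(s, small_template())
  p2 <- simulate_preclinical_cohort(s, small_template())
  expect_identical(p1$tumors, p2$tumors)

  q1 <- simulate_clinical_cohort(s)
  q2 <- simulate_clinical_cohort(s)
  expect_identical(q1$patients, q2$patients)

  acq1 <- simulate_dce_acquisition(a$maps, aif_preset("murine"),
                                   tiny_cohort_spec(seed = 131))
  acq2 <- simulate_dce_acquisition(a$maps, aif_preset("murine"),
                                   tiny_cohort_spec(seed = 131))
  expect_identical(acq1$concentrations, acq2$concentrations)
})

test_that("pimonidazole fractions track the true HF", {
  exact <- simulate_preclinical_cohort(tiny_cohort_spec(hf_pim_sigma = 0,
                                                        seed = 133),
                                       small_template())
  expect_equal(exact$tumors$hf_pim, exact$tumors$hf_true)
  noisy <- simulate_preclinical_cohort(
    cohort_spec(n_tumors = 20L, hf_pim_sigma = 0.05, seed = 135),
    small_template())
  expect_gt(stats::cor(noisy$tumors$hf_pim, noisy$tumors$hf_true), 0.9)
  expect_true(all(noisy$tumors$hf_pim >= 0 & noisy$tumors$hf_pim <= 1))
  expect_equal(unique(noisy$tumors$model),
               c("BK-12", "ED-15", "HL-16", "LA-19"))
})

test_that("clinical cohorts honour the proportional-hazards construction", {
  cl <- simulate_clinical_cohort(cohort_spec(n_patients = 200L, seed = 137))
  p <- cl$patients
  expect_true(all(p$os_time >= p$dfs_time))
  expect_true(all(p$dfs_event %in% 0:1))
  expect_true(all(p$hf_mri >= 0 & p$hf_mri <= 1))
  # a vanishing censoring horizon censors everything at ~0
  cl0 <- simulate_clinical_cohort(cohort_spec(n_patients = 50L,
                                              censor_horizon = 1e-6,
                                              seed = 139))
  expect_true(all(cl0$patients$dfs_event == 0L))
  expect_true(all(cl0$patients$dfs_time <= 1e-6))
})

test_that("beta = 0 decouples HF from event times", {
  # Kendall association between HF and DFS time among uncensored
  # patients rejects at the nominal rate only
  rej <- vapply(1:200, function(r) {
    cl <- simulate_clinical_cohort(cohort_spec(n_patients = 60L, beta = 0,
                                               censor_horizon = 1e6,
                                               seed = 14000 + r))
    ct <- stats::cor.test(cl$patients$hf_mri, cl$patients$dfs_time,
                          method = "kendall")
    ct$p.value < 0.05
  }, logical(1L))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("a strong HF effect is detected at the median split", {
  sig <- vapply(1:30, function(r) {
    cl <- simulate_clinical_cohort(cohort_spec(n_patients = 80L, beta = 5,
                                               seed = 15000 + r))
    hf <- cl$patients$hf_mri
    hi <- hf > stats::median(hf)
    logrank_test(cl$patients$dfs_time[hi], cl$patients$dfs_event[hi],
                 cl$patients$dfs_time[!hi],
                 cl$patients$dfs_event[!hi])$p_value < 0.05
  }, logical(1L))
  expect_gte(mean(sig), 0.95)
})

test_that("noise-free acquisitions round-trip through the Tofts fit", {
  ph <- simulate_phantom(small_template(seed = 141))
  acq <- simulate_dce_acquisition(ph$maps, aif_preset("murine"),
                                  tiny_cohort_spec(concentration_sigma = 0,
                                                   seed = 141))
  fitted <- fit_tofts_map(acq, aif_preset("murine"))
  nec <- ph$maps$ve[ph$maps$roi] > 1
  k_true <- ph$maps$ktrans[ph$maps$roi][!nec]
  v_true <- ph$maps$ve[ph$maps$roi][!nec]
  k_fit <- fitted$ktrans[fitted$roi][!nec]
  v_fit <- fitted$ve[fitted$roi][!nec]
  expect_lt(max(abs(k_fit - k_true) / k_true), 0.01)
  expect_lt(max(abs(v_fit - v_true) / v_true), 0.01)
  # full round trip reproduces the true HF within one voxel
  hf_fit <- hypoxic_fraction(fitted, ph$spec$rule)
  n_viable <- sum(!nec)
  expect_lte(abs(hf_fit - ph$true_hf), 1 / n_viable + 1e-12)
})

test_that("necrotic voxels fit to unphysiological ve under noise", {
  ph <- simulate_phantom(phantom_spec(seed = 143))
  acq <- simulate_dce_acquisition(ph$maps, aif_preset("murine"),
                                  cohort_spec(seed = 143))
  fitted <- fit_tofts_map(acq, aif_preset("murine"))
  nec <- ph$maps$ve[ph$maps$roi] > 1
  expect_gte(mean(fitted$ve[fitted$roi][nec] > 1), 0.9)
})

test_that("invalid phantom and acquisition specifications are rejected", {
  expect_error(phantom_spec(core_fraction = 1), "core_fraction")
  expect_error(phantom_spec(core_fraction = 1.2), "core_fraction")
  expect_error(phantom_spec(grid_shape = c(16L, 16L), tumor_radius = 12),
               "fit")
  expect_error(cohort_spec(temporal_resolution = -1), "positive")
  ph <- simulate_phantom(small_template(seed = 145))
  sp <- tiny_cohort_spec(seed = 145)
  sp$temporal_resolution <- 0
  expect_error(simulate_dce_acquisition(ph$maps, aif_preset("murine"), sp),
               "positive")
})

test_that("acquisition sampling follows the preclinical and clinical presets", {
  ph <- simulate_phantom(small_template(seed = 147))
  a1 <- simulate_dce_acquisition(ph$maps, aif_preset("murine"),
                                 tiny_cohort_spec(seed = 1), "preclinical")
  expect_equal(diff(a1$times)[1L], 14.8)
  a2 <- simulate_dce_acquisition(ph$maps, aif_preset("human"),
                                 tiny_cohort_spec(seed = 1), "clinical")
  expect_equal(diff(a2$times)[1L], 29)
})
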