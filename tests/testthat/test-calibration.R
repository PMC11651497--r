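test_that("pooled SBE regression recovers an exact collinear fit", {
  obs <- obs_from_sbe(c(40, 50, 60), c(0, -0.25, -0.5))
  fit <- fit_sbe_slope(obs, beta = 16.2)
  expect_equal(fit$slope, -0.025, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  expect_identical(fit$n, 3L)
  expect_identical(fit$dof, 1L)
})

test_that("pooled SBE regression is translation invariant in the response", {
  d <- generate_study(study_design("v", seed = 12L))
  f0 <- fit_sbe_slope(d, beta = 16.2)
  shifted <- d
  shifted$hco3_mmol_l <- shifted$hco3_mmol_l + 3  # SBE + 3 at every beta
  f1 <- fit_sbe_slope(shifted, beta = 16.2)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f0$intercept + 3, tolerance = 1e-10)
  expect_equal(f1$slope_se, f0$slope_se, tolerance = 1e-10)
})

test_that("regression preconditions reject degenerate designs", {
  expect_error(fit_sbe_slope(obs_from_sbe(c(40, 50), c(0, 1))), "at least 3")
  expect_error(fit_sbe_slope(obs_from_sbe(c(50, 50, 50), c(0, 1, 2))),
               "constant")
  expect_error(fit_sbe_slope(tibble::tibble(ph = 7.4)), "pco2_mmhg")
})

test_that("slope decomposition is the exact linear twin of the fit", {
  d <- generate_study(study_design("v", seed = 13L))
  dec <- slope_decomposition(d)
  for (beta in c(5, 7.3, 12.1, 16.2, 20)) {
    expect_equal(fit_sbe_slope(d, beta = beta)$slope, dec$a + dec$b * beta,
                 tolerance = 1e-12)
    expect_equal(oracle_sbe_slope(d, beta), dec$a + dec$b * beta,
                 tolerance = 1e-10)
  }
  # noiseless generation at beta_true = 12.1 puts the zero crossing there
  d0 <- generate_study(noiseless_design(seed = 13L))
  dec0 <- slope_decomposition(d0)
  expect_lt(abs(dec0$a + 12.1 * dec0$b), 1e-9)
  expect_equal(dec0$beta_zero, 12.1, tolerance = 1e-6)
})

test_that("buffer-power sweep finds the noiseless truth and matches -a/b", {
  d0 <- generate_study(noiseless_design(seed = 14L))
  sw <- beta_sweep(d0)
  step <- grid_step()
  expect_lte(abs(sw$beta_star - 12.1), step)
  expect_identical(sw$grid[1], 5)
  expect_identical(sw$grid[length(sw$grid)], 20)
  expect_identical(length(sw$grid), 10000L)

  d <- generate_study(study_design("v", seed = 15L))
  sw <- beta_sweep(d)
  dec <- slope_decomposition(d)
  expect_lte(abs(sw$beta_star - dec$beta_zero), step)
  expect_lt(max(abs(sw$slopes - (dec$a + dec$b * sw$grid))), 1e-10)
  expect_identical(sw$beta_zero_closed_form, dec$beta_zero)
  # test-inversion CI brackets the point estimate
  expect_false(sw$degenerate)
  expect_lte(sw$ci_low, sw$beta_star)
  expect_gte(sw$ci_high, sw$beta_star)
})

test_that("sweep is invariant to the Schlichtig outer rescaling", {
  d <- generate_study(study_design("v", seed = 16L))
  # affine transform multiplying BE(beta) by 0.9287 pointwise at every beta
  scaled <- d
  scaled$hco3_mmol_l <- 24.8 + 0.9287 * (d$hco3_mmol_l - 24.8)
  scaled$ph <- 7.40 + 0.9287 * (d$ph - 7.40)
  sw <- beta_sweep(d)
  sws <- beta_sweep(scaled)
  expect_identical(sws$beta_star, sw$beta_star)
  expect_equal(sws$slopes, 0.9287 * sw$slopes, tolerance = 1e-12)
  expect_equal(sws$ci_low, sw$ci_low, tolerance = 1e-9)
  expect_equal(sws$ci_high, sw$ci_high, tolerance = 1e-9)
})

test_that("sweep CI widens with pH measurement noise and flags pathologies", {
  widths <- vapply(c(0.002, 0.01, 0.03), function(sd) {
    d <- generate_study(study_design("v", ph_noise_sd = sd,
                                     pco2_noise_sd = 0, seed = 17L))
    sw <- beta_sweep(d)
    sw$ci_high - sw$ci_low
  }, 0)
  expect_true(all(diff(widths) > 0))

  # pH carrying no PCO2 trend -> buffer power not identifiable
  set.seed(18)
  flat <- tibble::tibble(study_id = "f", subject_id = "S01",
                         exposure_id = sprintf("E%d", 1:8),
                         pco2_mmhg = seq(40, 82, length.out = 8),
                         ph = 7.40, hco3_mmol_l = rnorm(8, 24.8, 0.3))
  expect_true(beta_sweep(flat)$non_identifiable)

  # strong trend, tiny residuals -> no beta accepted by the slope test
  steep <- obs_from_sbe(seq(40, 75, 5), seq(0, -7, -1) + rnorm(8, 0, 1e-4))
  sw <- beta_sweep(steep)
  expect_true(sw$degenerate)
  expect_true(is.na(sw$ci_low) && is.na(sw$ci_high))
})

test_that("ANCOVA separates intercept and slope heterogeneity", {
  # identical physiology -> identical curves: interaction exactly null
  twin_a <- generate_study(noiseless_design("A", seed = 19L))
  twin_b <- generate_study(noiseless_design("B", seed = 19L))
  same <- rbind(as.data.frame(twin_a), as.data.frame(twin_b))
  same$study_id <- rep(c("A", "B"), each = nrow(twin_a))
  anc <- sbe_ancova(same)
  expect_gt(anc$slope_p, 0.999)
  expect_equal(anc$per_study_fits$A$slope, anc$per_study_fits$B$slope,
               tolerance = 1e-10)

  # translating the response (hco3 + c shifts SBE by c at every beta):
  # intercepts differ, slopes exactly shared
  trans_b <- as.data.frame(twin_a)
  trans_b$study_id <- "B"
  trans_b$hco3_mmol_l <- trans_b$hco3_mmol_l - 3
  anc <- sbe_ancova(rbind(as.data.frame(twin_a), trans_b))
  expect_gt(anc$slope_p, 0.999)
  expect_lt(anc$intercept_p, 1e-6)
  expect_lt(anc$intercept_p_reduced, 1e-6)

  # a physiological baseline offset moves subjects along the buffer curve,
  # so slopes match only approximately: interaction stays quiet while the
  # intercept difference is overwhelming
  shift_b <- generate_study(noiseless_design("B", baseline = -3, seed = 19L))
  anc <- sbe_ancova(rbind(as.data.frame(twin_a), as.data.frame(shift_b)))
  expect_gt(anc$slope_p, 0.05)
  expect_lt(anc$intercept_p, 1e-6)

  # different buffer powers: the study x PCO2 interaction must fire
  d <- generate_multistudy(list(noiseless_design("A", beta_true = 9),
                                noiseless_design("B", beta_true = 15)),
                           shared_seed = 20L)
  expect_lt(sbe_ancova(d)$slope_p, 1e-6)
})

test_that("ANCOVA preconditions give informative errors", {
  d <- generate_study(study_design("only", seed = 21L))
  expect_error(sbe_ancova(d), "at least 2 studies")
  one_pt <- rbind(as.data.frame(d),
                  data.frame(study_id = "tiny", subject_id = "S01",
                             exposure_id = "E1", pco2_mmhg = 50, ph = 7.3,
                             hco3_mmol_l = 24, beta_true = 12,
                             baseline_sbe = 0))
  expect_error(sbe_ancova(one_pt), "tiny")
})

test_that("per-subject SBE excursions behave across buffer powers", {
  d0 <- generate_study(noiseless_design(seed = 22L))
  at_truth <- max_delta_sbe(d0, beta = 12.1)
  expect_lt(max(abs(at_truth$cohort_range)), 1e-6)

  # evaluated at 16.2 > beta_true, base excess drifts negative with PCO2
  at_standard <- max_delta_sbe(d0, beta = 16.2)
  expect_true(all(at_standard$per_subject$extreme_delta < 0))
  expect_true(all(at_standard$per_subject$min_delta < 0))
  # drift grows with PCO2: the extreme sits at the top exposure
  sbe <- base_excess(d0$hco3_mmol_l, d0$ph, 16.2)
  s1 <- d0$subject_id == "S01"
  deltas <- sbe[s1] - sbe[s1][which.min(d0$pco2_mmhg[s1])]
  expect_true(all(diff(deltas[order(d0$pco2_mmhg[s1])]) < 0))

  # duplicating an exposure row leaves per-subject extremes unchanged
  dup <- rbind(as.data.frame(d0), as.data.frame(d0[1, ]))
  expect_equal(max_delta_sbe(dup, beta = 16.2)$per_subject$extreme_delta,
               at_standard$per_subject$extreme_delta, tolerance = 1e-12)

  # single-exposure subjects are dropped with a warning
  lone <- rbind(as.data.frame(d0),
                data.frame(study_id = "z", subject_id = "S99",
                           exposure_id = "E1", pco2_mmhg = 45, ph = 7.35,
                           hco3_mmol_l = 24, beta_true = 12, baseline_sbe = 0))
  expect_warning(res <- max_delta_sbe(lone, beta = 16.2), "S99")
  expect_false("S99" %in% res$per_subject$subject_id)
})

test_that("cluster-robust standard errors are available but off by default", {
  skip_if_not_installed("sandwich")
  d <- generate_study(study_design("v", seed = 23L))
  plain <- fit_sbe_slope(d, beta = 16.2)
  robust <- fit_sbe_slope(d, beta = 16.2, cluster = "subject_id")
  expect_identical(robust$slope, plain$slope)
  expect_false(isTRUE(all.equal(robust$slope_se, plain$slope_se)))
})
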