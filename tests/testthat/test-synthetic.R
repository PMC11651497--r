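test_that("pH inversion agrees with an independent bisection oracle", {
  # frozen from the oracle: root of the joint equation at pco2 40, SBE 0,
  # beta 16.2
  expect_equal(solve_ph_for_target_sbe(40, 0, 16.2), 7.404091,
               tolerance = 1e-3 / 7.4)
  set.seed(41)
  for (i in 1:25) {
    pco2 <- runif(1, 20, 120)
    target <- runif(1, -8, 8)
    beta <- runif(1, 5, 20)
    expect_equal(solve_ph_for_target_sbe(pco2, target, beta),
                 oracle_bisect_ph(pco2, target, beta), tolerance = 1e-8)
  }
})

test_that("pH inversion round-trips through the base-excess equation", {
  set.seed(42)
  pco2 <- runif(20, 20, 120)
  target <- runif(20, -8, 8)
  ph <- solve_ph_for_target_sbe(pco2, target, 12.1)
  back <- base_excess(hco3_from_ph_pco2(ph, pco2), ph, 12.1)
  expect_equal(back, target, tolerance = 1e-8)
})

test_that("pH inversion is monotone in the target and errors off-bracket", {
  expect_lt(solve_ph_for_target_sbe(60, -5, 16.2),
            solve_ph_for_target_sbe(60, 0, 16.2))
  # a target far beyond any attainable base excess in the pH bracket
  expect_error(solve_ph_for_target_sbe(40, 500, 16.2), "bracket")
})

test_that("generated studies are reproducible and correctly sized", {
  des <- study_design("volunteers", n_subjects = 14,
                      pco2_levels = c(40, 60, 80), seed = 7L)
  d1 <- generate_study(des)
  d2 <- generate_study(des)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 42L)
  expect_identical(anyDuplicated(d1[c("study_id", "subject_id",
                                      "exposure_id")]), 0L)
  expect_error(generate_study(study_design("noseed")), "seed")
})

test_that("noise-free cohorts are CO2-invariant at the true buffer power", {
  d <- generate_study(noiseless_design(seed = 3L))
  # pooled regression of SBE(beta_true) on PCO2 has slope ~ 0
  expect_lt(abs(oracle_sbe_slope(d, 12.1)), 1e-6)
  # per-subject SBE at beta_true constant across levels
  sbe <- base_excess(d$hco3_mmol_l, d$ph, 12.1)
  dev <- tapply(sbe, d$subject_id, function(x) diff(range(x)))
  expect_lt(max(dev), 1e-6)
})

test_that("subject heterogeneity keeps each subject on their own curve", {
  des <- study_design("h", beta_true_sd = 2, baseline_sbe_sd = 2,
                      ph_noise_sd = 0, pco2_noise_sd = 0, seed = 5L)
  d <- generate_study(des)
  for (s in unique(d$subject_id)) {
    rows <- d[d$subject_id == s, ]
    sbe <- base_excess(rows$hco3_mmol_l, rows$ph, rows$beta_true[1])
    expect_lt(diff(range(sbe)), 1e-6)
    expect_equal(mean(sbe), rows$baseline_sbe[1], tolerance = 1e-6)
  }
})

test_that("multi-study generation uses stable per-study substreams", {
  a <- study_design("A", beta_true_mean = 10)
  b <- study_design("B", beta_true_mean = 14)
  c3 <- study_design("C", beta_true_mean = 12)
  d_ab <- generate_multistudy(list(a, b), shared_seed = 99L)
  d_ba <- generate_multistudy(list(b, a), shared_seed = 99L)
  d_abc <- generate_multistudy(list(a, b, c3), shared_seed = 99L)

  # compare observation values only; provenance attributes legitimately
  # differ between datasets generated in different batches
  pick <- function(d, id) {
    x <- as.data.frame(d[d$study_id == id, ])
    rownames(x) <- NULL
    attr(x, "designs") <- NULL
    attr(x, "seed") <- NULL
    x
  }
  # permuting design order never changes a study's observations
  expect_identical(pick(d_ab, "A"), pick(d_ba, "A"))
  expect_identical(pick(d_ab, "B"), pick(d_ba, "B"))
  # adding a study never changes existing studies' draws
  expect_identical(pick(d_ab, "A"), pick(d_abc, "A"))
  expect_identical(pick(d_ab, "B"), pick(d_abc, "B"))

  # one design degenerates to generate_study
  one <- generate_multistudy(list(a), shared_seed = 99L)
  a_seeded <- a; a_seeded$seed <- invivobe:::stable_seed(99L, "A")
  expect_identical(pick(one, "A"), pick(generate_study(a_seeded), "A"))

  expect_error(generate_multistudy(list(a, a), shared_seed = 1L),
               "duplicate study_id")
  expect_error(generate_multistudy(list(a), shared_seed = NULL), "seed")
})
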