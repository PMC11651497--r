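# Shared fixtures and independent oracles for the test suite.

# Independent scalar bisection oracle for the pH inversion: written against
# the defining equation only, no package solver code.
oracle_bisect_ph <- function(pco2, target_sbe, beta,
                             hco3_ref = 24.8, ph_ref = 7.40, pk = 6.1,
                             sol = 0.0307, lo = 6.5, hi = 8.0,
                             iter = 60) {
  f <- function(ph) (sol * pco2 * 10^(ph - pk) - hco3_ref) +
    (ph - ph_ref) * beta - target_sbe
  stopifnot(f(lo) <= 0, f(hi) >= 0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force pooled OLS slope of SBE(beta) on PCO2 through stats::lm,
# recomputing SBE by hand from the observation columns.
oracle_sbe_slope <- function(obs, beta, hco3_ref = 24.8, ph_ref = 7.40) {
  sbe <- (obs$hco3_mmol_l - hco3_ref) + (obs$ph - ph_ref) * beta
  unname(coef(lm(sbe ~ obs$pco2_mmhg))[2])
}

# Noise-free single-buffer-power cohort: every subject sits exactly on the
# titration curve of beta_true.
noiseless_design <- function(study_id = "z", beta_true = 12.1,
                             baseline = 0, seed = 1L, ...) {
  study_design(study_id, beta_true_mean = beta_true, beta_true_sd = 0,
               baseline_sbe_mean = baseline, baseline_sbe_sd = 0,
               ph_noise_sd = 0, pco2_noise_sd = 0, seed = seed, ...)
}

# Hand-built observation table with prescribed (pco2, sbe) points: pH pinned
# at the reference so SBE equals hco3 - 24.8 at every buffer power.
obs_from_sbe <- function(pco2, sbe) {
  tibble::tibble(study_id = "manual", subject_id = "S01",
                 exposure_id = sprintf("E%d", seq_along(pco2)),
                 pco2_mmhg = pco2, ph = 7.40, hco3_mmol_l = 24.8 + sbe)
}

grid_step <- function(min = 5, max = 20, n = 10000) (max - min) / (n - 1)
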