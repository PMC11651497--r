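# Statistical engine: pooled SBE-on-PCO2 regression, its exact linear
# decomposition in beta, the 10,000-point buffer-power sweep with
# test-inversion CI, multi-study ANCOVA with interaction, and per-subject
# SBE excursions across the titration range.

# Pull validated numeric columns out of an observation table; fills missing
# bicarbonate from the pH/PCO2 pair.
obs_columns <- function(observations, ct) {
  need <- c("pco2_mmhg", "ph")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop(sprintf("observations lack required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  pco2 <- as.numeric(observations$pco2_mmhg)
  ph <- as.numeric(observations$ph)
  hco3 <- if ("hco3_mmol_l" %in% names(observations))
    as.numeric(observations$hco3_mmol_l) else rep(NA_real_, length(ph))
  fill <- is.na(hco3)
  if (any(fill)) hco3[fill] <- hco3_from_ph_pco2(ph[fill], pco2[fill], ct)
  list(pco2 = pco2, ph = ph, hco3 = hco3)
}

check_regression_design <- function(pco2) {
  if (length(pco2) < 3L)
    stop(sprintf("need at least 3 observations, got %d", length(pco2)),
         call. = FALSE)
  if (stats::var(pco2) == 0)
    stop("degenerate design: pco2 is constant across observations",
         call. = FALSE)
  invisible(TRUE)
}

new_regression_fit <- function(slope, intercept, slope_se, n, dof, level,
                               beta) {
  tcrit <- stats::qt(1 - (1 - level) / 2, dof)
  tstat <- slope / slope_se
  structure(list(slope = slope, intercept = intercept, slope_se = slope_se,
                 ci_low = slope - tcrit * slope_se,
                 ci_high = slope + tcrit * slope_se,
                 p_value = 2 * stats::pt(-abs(tstat), dof),
                 n = n, dof = dof, level = level, beta = beta),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "SBE ~ PCO2 regression (beta = %.4g): slope %.4f mmol/L/mmHg (%.0f%% CI %.4f to %.4f), p = %.3g, n = %d\n",
    x$beta, x$slope, 100 * x$level, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Pooled regression of base excess on PCO2
#'
#' Ordinary least squares of base excess (computed at buffer power
#' \code{beta}) on PCO2, pooled over all supplied observations. The slope
#' quantifies how far base excess drifts per mmHg of acute CO2 change: at the
#' true in vivo buffer power it should be zero. The confidence interval and
#' two-sided p-value come from the t distribution on the residual degrees of
#' freedom. Within-subject correlation is ignored by default (each exposure
#' counts as one observation); pass \code{cluster} for cluster-robust
#' standard errors instead.
#'
#' @param observations A data frame / \code{titration_dataset} with columns
#'   \code{pco2_mmhg}, \code{ph} and optionally \code{hco3_mmol_l} (filled
#'   from pH/PCO2 where missing).
#' @param beta Buffer power at which base excess is evaluated. Defaults to
#'   the standard 16.2.
#' @param constants An \code{\link{acid_base_constants}} object.
#' @param level Confidence level. Default 0.95.
#' @param cluster Optional name of a column (e.g. \code{"subject_id"})
#'   defining clusters for sandwich (CR1) standard errors; requires the
#'   \pkg{sandwich} package.
#'
#' @return A \code{regression_fit}: slope, intercept, slope SE, CI bounds,
#'   p-value, n and residual degrees of freedom.
#' @examples
#' d <- generate_study(study_design("volunteers", seed = 1L))
#' fit_sbe_slope(d)            # at beta = 16.2
#' fit_sbe_slope(d, beta = 12.1)
#' @export
fit_sbe_slope <- function(observations, beta = NULL,
                          constants = acid_base_constants(), level = 0.95,
                          cluster = NULL) {
  ct <- as_constants(constants)
  beta <- beta %||% ct$standard_beta
  cols <- obs_columns(observations, ct)
  check_regression_design(cols$pco2)
  sbe <- base_excess(cols$hco3, cols$ph, beta, ct)
  fit <- stats::lm(sbe ~ pco2, data = data.frame(sbe = sbe, pco2 = cols$pco2))
  if (is.null(cluster)) {
    # classical OLS slope SE computed directly (vcov.lm would warn on an
    # exactly collinear fit)
    sxx <- sum((cols$pco2 - mean(cols$pco2))^2)
    se <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual / sxx)
  } else {
    if (!cluster %in% names(observations))
      stop(sprintf("cluster column '%s' not found", cluster), call. = FALSE)
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("cluster-robust standard errors require the 'sandwich' package",
           call. = FALSE)
    vc <- sandwich::vcovCL(fit, cluster = observations[[cluster]])
    se <- sqrt(diag(vc))[["pco2"]]
  }
  new_regression_fit(slope = unname(stats::coef(fit)["pco2"]),
                     intercept = unname(stats::coef(fit)["(Intercept)"]),
                     slope_se = se, n = length(sbe), dof = fit$df.residual,
                     level = level, beta = beta)
}

#' Exact linear decomposition of the SBE slope in the buffer power
#'
#' Because base excess is linear in the buffer power, the pooled OLS slope of
#' SBE on PCO2 decomposes exactly as \code{slope(beta) = a + b * beta}, where
#' \code{a} is the OLS slope of (HCO3 - hco3_ref) on PCO2 and \code{b} the
#' OLS slope of (pH - ph_ref) on PCO2 over the identical observations. The
#' zero crossing \code{-a/b} is the closed-form twin of the grid sweep in
#' \code{\link{beta_sweep}} and serves as its analytic cross-check; a
#' delta-method standard error for \code{-a/b} (accounting for the sampling
#' covariance of \code{a} and \code{b}) is also returned.
#'
#' @inheritParams fit_sbe_slope
#' @return An object of class \code{slope_decomposition} with elements
#'   \code{a}, \code{b}, their standard errors and covariance,
#'   \code{beta_zero = -a/b}, \code{beta_zero_se} (delta method), and
#'   \code{n}.
#' @examples
#' d <- generate_study(study_design("volunteers", seed = 1L))
#' dec <- slope_decomposition(d)
#' dec$beta_zero  # analytic CO2-invariant buffer power
#' @export
slope_decomposition <- function(observations,
                                constants = acid_base_constants()) {
  ct <- as_constants(constants)
  cols <- obs_columns(observations, ct)
  check_regression_design(cols$pco2)
  x <- cols$pco2
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  n <- length(x)
  dof <- n - 2L

  u <- cols$hco3 - ct$hco3_ref
  v <- cols$ph - ct$ph_ref
  a <- sum(xc * u) / sxx
  b <- sum(xc * v) / sxx
  # residuals of the two component regressions share the design, so the
  # slope estimates are correlated; needed for the delta-method SE of -a/b
  ru <- u - mean(u) - a * xc
  rv <- v - mean(v) - b * xc
  var_a <- sum(ru^2) / dof / sxx
  var_b <- sum(rv^2) / dof / sxx
  cov_ab <- sum(ru * rv) / dof / sxx

  beta_zero <- -a / b
  grad <- c(-1 / b, a / b^2)
  var_bz <- grad[1]^2 * var_a + 2 * grad[1] * grad[2] * cov_ab +
    grad[2]^2 * var_b
  structure(list(a = a, b = b, a_se = sqrt(var_a), b_se = sqrt(var_b),
                 ab_cov = cov_ab, beta_zero = beta_zero,
                 beta_zero_se = sqrt(max(var_bz, 0)), n = n, dof = dof),
            class = "slope_decomposition")
}

#' @export
print.slope_decomposition <- function(x, ...) {
  cat(sprintf("slope(beta) = a + b*beta: a = %.5f, b = %.6f (n = %d)\n",
              x$a, x$b, x$n))
  cat(sprintf("zero crossing -a/b = %.3f (delta-method SE %.3f)\n",
              x$beta_zero, x$beta_zero_se))
  invisible(x)
}

#' Buffer-power sweep locating the CO2-invariant base excess
#'
#' Evaluates the pooled OLS regression of base excess on PCO2 at every buffer
#' power on a uniform inclusive grid (default 10,000 points between 5 and
#' 20), and reports \code{beta_star}, the grid point whose regression
#' coefficient is closest to zero - the buffer power at which base excess is
#' invariant to acute CO2 change. The confidence interval on beta is obtained
#' by test inversion: all grid betas whose slope CI (t-based, at
#' \code{level}) contains zero. A delta-method CI for the closed-form zero
#' crossing \code{-a/b} from \code{\link{slope_decomposition}} is reported
#' alongside as a cross-check.
#'
#' Each grid point is a genuine OLS fit (vectorized over the grid); ties in
#' \code{|slope|} resolve to the smallest beta. When the pH-on-PCO2 slope is
#' numerically zero the zero crossing is undefined and the result is flagged
#' non-identifiable; an empty test-inversion set is reported as degenerate
#' with diagnostics rather than clamped.
#'
#' @inheritParams fit_sbe_slope
#' @param grid_min,grid_max Grid bounds for the buffer power, mmol/L per pH
#'   unit. Defaults 5 and 20.
#' @param grid_n Number of grid points (inclusive endpoints). Default 10000.
#'
#' @return An object of class \code{beta_sweep_result} with the grid, the
#'   slope and slope-SE curves, \code{beta_star}, test-inversion
#'   \code{ci_low}/\code{ci_high}, the delta-method interval
#'   (\code{delta_ci_low}/\code{delta_ci_high}), and diagnostic flags.
#' @examples
#' d <- generate_study(study_design("volunteers", seed = 1L))
#' sw <- beta_sweep(d, grid_n = 1001)
#' sw$beta_star
#' @export
beta_sweep <- function(observations, grid_min = 5, grid_max = 20,
                       grid_n = 10000, level = 0.95,
                       constants = acid_base_constants()) {
  ct <- as_constants(constants)
  if (!is.numeric(grid_min) || !is.numeric(grid_max) || grid_min <= 0 ||
      grid_max <= grid_min)
    stop("grid bounds must satisfy 0 < grid_min < grid_max", call. = FALSE)
  if (!is.numeric(grid_n) || grid_n < 2L)
    stop("'grid_n' must be at least 2", call. = FALSE)
  cols <- obs_columns(observations, ct)
  check_regression_design(cols$pco2)

  x <- cols$pco2
  n <- length(x)
  dof <- n - 2L
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  grid <- seq(grid_min, grid_max, length.out = grid_n)

  # one OLS fit per grid beta, vectorized: columns of M are the SBE response
  # at each candidate beta
  h <- cols$hco3 - ct$hco3_ref
  p <- cols$ph - ct$ph_ref
  M <- outer(h, rep(1, grid_n)) + outer(p, grid)
  slopes <- as.vector(crossprod(xc, M)) / sxx
  Mc <- M - rep(colMeans(M), each = n)
  sse <- pmax(colSums(Mc^2) - slopes^2 * sxx, 0)
  slope_se <- sqrt(sse / dof / sxx)

  i_star <- which.min(abs(slopes))   # first minimum = smallest beta on ties
  beta_star <- grid[i_star]

  tcrit <- stats::qt(1 - (1 - level) / 2, dof)
  covers0 <- abs(slopes) <= tcrit * slope_se
  non_identifiable <- abs(sum(xc * p) / sxx) < 1e-12
  if (any(covers0)) {
    idx <- which(covers0)
    ci_low <- grid[idx[1]]
    ci_high <- grid[idx[length(idx)]]
    degenerate <- FALSE
    contiguous <- all(diff(idx) == 1L)
  } else {
    ci_low <- ci_high <- NA_real_
    degenerate <- TRUE
    contiguous <- NA
  }

  dec <- slope_decomposition(observations, ct)
  delta_half <- tcrit * dec$beta_zero_se
  structure(list(
    grid = grid, slopes = slopes, slope_se = slope_se,
    beta_star = beta_star, ci_low = ci_low, ci_high = ci_high,
    level = level, n = n, dof = dof,
    grid_spec = c(min = grid_min, max = grid_max, n_points = grid_n),
    non_identifiable = non_identifiable, degenerate = degenerate,
    ci_contiguous = contiguous,
    min_abs_slope = abs(slopes[i_star]), min_abs_slope_se = slope_se[i_star],
    beta_zero_closed_form = dec$beta_zero,
    delta_ci_low = dec$beta_zero - delta_half,
    delta_ci_high = dec$beta_zero + delta_half),
    class = "beta_sweep_result")
}

#' @export
print.beta_sweep_result <- function(x, ...) {
  cat(sprintf("Buffer-power sweep: %d betas in [%g, %g], n = %d observations\n",
              x$grid_spec["n_points"], x$grid_spec["min"], x$grid_spec["max"],
              x$n))
  cat(sprintf("  beta_star = %.4g (slope %.2e mmol/L/mmHg)\n",
              x$beta_star, x$min_abs_slope))
  if (x$degenerate) {
    cat(sprintf("  %.0f%% test-inversion CI: empty on grid (min |slope|/se = %.2f)\n",
                100 * x$level, x$min_abs_slope / x$min_abs_slope_se))
  } else {
    cat(sprintf("  %.0f%% test-inversion CI: %.4g to %.4g%s\n", 100 * x$level,
                x$ci_low, x$ci_high,
                if (isTRUE(x$ci_contiguous)) "" else " (non-contiguous set)"))
  }
  cat(sprintf("  closed form -a/b = %.4g (delta-method CI %.4g to %.4g)\n",
              x$beta_zero_closed_form, x$delta_ci_low, x$delta_ci_high))
  if (x$non_identifiable)
    cat("  WARNING: pH shows no trend in PCO2; beta is not identifiable\n")
  invisible(x)
}

#' Analysis of covariance of base excess across studies
#'
#' Fits the full interaction model \code{SBE ~ PCO2 + study + PCO2:study}
#' (treatment-coded) and tests, by nested-model F-tests within the full
#' model, (i) whether the studies share a common intercept and (ii) whether
#' they share a common SBE-versus-PCO2 slope (the study x PCO2 interaction).
#' Rejecting either means the titration curves are not exchangeable across
#' studies. Per-study pooled fits are returned alongside. For reference the
#' intercept test is also computed in the reduced main-effects model
#' (\code{intercept_p_reduced}), since the two formulations differ when
#' slopes are heterogeneous.
#'
#' @inheritParams fit_sbe_slope
#' @param observations Must span at least two studies (column
#'   \code{study_id}), each with >= 3 observations and non-constant PCO2.
#'
#' @return An object of class \code{ancova_result}: \code{intercept_f},
#'   \code{intercept_p}, \code{slope_f}, \code{slope_p}, the reduced-model
#'   intercept test, and \code{per_study_fits} (a named list of
#'   \code{regression_fit}).
#' @examples
#' designs <- list(study_design("A", beta_true_mean = 10),
#'                 study_design("B", beta_true_mean = 14))
#' d <- generate_multistudy(designs, shared_seed = 7L)
#' sbe_ancova(d)
#' @export
sbe_ancova <- function(observations, beta = NULL,
                       constants = acid_base_constants(), level = 0.95) {
  ct <- as_constants(constants)
  beta <- beta %||% ct$standard_beta
  if (!"study_id" %in% names(observations))
    stop("observations lack required column(s): study_id", call. = FALSE)
  study <- factor(observations$study_id)
  if (nlevels(study) < 2L)
    stop("ANCOVA requires observations from at least 2 studies", call. = FALSE)
  cols <- obs_columns(observations, ct)
  for (s in levels(study)) {
    xs <- cols$pco2[study == s]
    ok <- tryCatch({check_regression_design(xs); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop(sprintf("study '%s': %s", s, ok), call. = FALSE)
  }
  sbe <- base_excess(cols$hco3, cols$ph, beta, ct)
  df <- data.frame(sbe = sbe, pco2 = cols$pco2, study = study)

  full <- stats::lm(sbe ~ pco2 * study, data = df)
  if (full$rank < 2L * nlevels(study))
    stop("rank-deficient ANCOVA design: check per-study PCO2 spread",
         call. = FALSE)
  no_slope_het <- stats::lm(sbe ~ pco2 + study, data = df)
  no_intercepts <- stats::lm(sbe ~ pco2 + pco2:study, data = df)
  common <- stats::lm(sbe ~ pco2, data = df)

  slope_test <- stats::anova(no_slope_het, full)
  intercept_test <- stats::anova(no_intercepts, full)
  intercept_test_reduced <- stats::anova(common, no_slope_het)

  fits <- lapply(split(observations, study), fit_sbe_slope, beta = beta,
                 constants = ct, level = level)
  structure(list(
    intercept_f = intercept_test$F[2], intercept_p = intercept_test$`Pr(>F)`[2],
    slope_f = slope_test$F[2], slope_p = slope_test$`Pr(>F)`[2],
    intercept_f_reduced = intercept_test_reduced$F[2],
    intercept_p_reduced = intercept_test_reduced$`Pr(>F)`[2],
    per_study_fits = fits, n = nrow(df), n_studies = nlevels(study),
    beta = beta, level = level),
    class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA of SBE(beta = %.4g) on PCO2 across %d studies (n = %d)\n",
              x$beta, x$n_studies, x$n))
  cat(sprintf("  intercept differences: F = %.2f, p = %.3g\n",
              x$intercept_f, x$intercept_p))
  cat(sprintf("  slope differences (study x PCO2): F = %.2f, p = %.3g\n",
              x$slope_f, x$slope_p))
  for (nm in names(x$per_study_fits)) {
    f <- x$per_study_fits[[nm]]
    cat(sprintf("  %-14s slope %.4f (%.0f%% CI %.4f to %.4f)\n", nm,
                f$slope, 100 * f$level, f$ci_low, f$ci_high))
  }
  invisible(x)
}

#' Per-subject base-excess excursion across the titration range
#'
#' For each subject, takes the lowest-PCO2 exposure as baseline and reports
#' the change in base excess (at buffer power \code{beta}) at every other
#' exposure relative to that baseline. The per-subject extreme deltas and
#' the cohort-wide range quantify how far base excess drifts over the
#' hypercapnic range; at the true in vivo buffer power all deltas vanish up
#' to noise. Subjects with a single exposure are excluded with a warning.
#'
#' @inheritParams fit_sbe_slope
#' @param observations Must carry \code{study_id} and \code{subject_id}.
#'
#' @return An object of class \code{sbe_delta_summary}: \code{per_subject}
#'   (tibble with min/max/extreme delta per subject) and
#'   \code{cohort_range} (length-2 numeric, mmol/L).
#' @examples
#' d <- generate_study(study_design("volunteers", seed = 1L))
#' max_delta_sbe(d)            # drift when SBE uses beta = 16.2
#' max_delta_sbe(d, beta = 12.1)
#' @export
max_delta_sbe <- function(observations, beta = NULL,
                          constants = acid_base_constants()) {
  ct <- as_constants(constants)
  beta <- beta %||% ct$standard_beta
  need <- c("study_id", "subject_id")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop(sprintf("observations lack required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  cols <- obs_columns(observations, ct)
  sbe <- base_excess(cols$hco3, cols$ph, beta, ct)
  key <- paste(observations$study_id, observations$subject_id, sep = "\r")
  groups <- split(seq_along(sbe), key)

  singles <- names(groups)[lengths(groups) < 2L]
  if (length(singles))
    warning(sprintf("%d subject(s) with a single exposure excluded: %s",
                    length(singles),
                    paste(gsub("\r", "/", singles), collapse = ", ")),
            call. = FALSE)
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups))
    stop("no subject has more than one exposure", call. = FALSE)

  per <- lapply(groups, function(idx) {
    base_i <- idx[which.min(cols$pco2[idx])]
    deltas <- sbe[idx] - sbe[base_i]
    extreme <- deltas[which.max(abs(deltas))]
    tibble::tibble(study_id = observations$study_id[base_i],
                   subject_id = observations$subject_id[base_i],
                   n_exposures = length(idx),
                   baseline_pco2 = cols$pco2[base_i],
                   min_delta = min(deltas), max_delta = max(deltas),
                   extreme_delta = extreme)
  })
  per <- do.call(rbind, per[order(names(per))])
  all_deltas <- unlist(lapply(groups, function(idx) {
    base_i <- idx[which.min(cols$pco2[idx])]
    sbe[idx] - sbe[base_i]
  }), use.names = FALSE)
  structure(list(per_subject = per, cohort_range = range(all_deltas),
                 beta = beta),
            class = "sbe_delta_summary")
}

#' @export
print.sbe_delta_summary <- function(x, ...) {
  cat(sprintf(
    "SBE change from lowest-PCO2 baseline at beta = %.4g (%d subjects)\n",
    x$beta, nrow(x$per_subject)))
  cat(sprintf("  cohort range: %.2f to %.2f mmol/L\n",
              x$cohort_range[1], x$cohort_range[2]))
  invisible(x)
}
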