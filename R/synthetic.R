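# Synthetic CO2-titration generator. The generative premise mirrors the
# concept the calibration estimates: each subject has a true in vivo buffer
# power beta_true at which their base excess is invariant to acute PCO2
# change. Noiseless pH at each PCO2 level is obtained by inverting the base
# excess equation jointly with Henderson-Hasselbalch; measurement noise is
# then applied to pH and PCO2 and bicarbonate re-derived from the noisy pair,
# the same chain a blood-gas analyzer follows.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit seed derived from a parent seed and a text label.
# Polynomial rolling hash mod (2^31 - 1); exact in double arithmetic.
# Substreams keyed by study/subject label are therefore stable: adding a
# study or permuting design order never changes another study's draws.
stable_seed <- function(master, label) {
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(paste0("s:", label)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Design of one synthetic CO2-titration study
#'
#' Describes a cohort of subjects exposed to an ascending series of arterial
#' PCO2 levels. Each subject draws a true in vivo buffer power
#' (\code{beta_true_mean}, \code{beta_true_sd}) and a baseline metabolic
#' offset (\code{baseline_sbe_mean}, \code{baseline_sbe_sd}); measurement
#' noise is controlled by \code{ph_noise_sd} and \code{pco2_noise_sd}.
#' Defaults emulate an unanesthetized-volunteer chamber study titrated over
#' the hypercapnic range 40-85 mmHg.
#'
#' @param study_id Text label, unique across a multi-study dataset.
#' @param n_subjects Number of subjects (>= 1). Default 14.
#' @param pco2_levels Strictly increasing PCO2 exposure levels, mmHg.
#'   Default \code{c(40, 55, 70, 85)}.
#' @param beta_true_mean,beta_true_sd Population mean and SD of the subject
#'   true buffer power, mmol/L per pH unit. Defaults 12.1 and 1.5.
#' @param baseline_sbe_mean,baseline_sbe_sd Mean and SD of the subject
#'   baseline base excess (metabolic offset), mmol/L. Defaults 0 and 1.0.
#' @param ph_noise_sd Measurement noise SD on pH. Default 0.005.
#' @param pco2_noise_sd Measurement noise SD on PCO2, mmHg. Default 1.0.
#' @param hco3_noise_sd Optional additional noise applied directly to the
#'   derived bicarbonate, mmol/L. Off (0) by default: the default measurement
#'   chain derives bicarbonate from the noisy pH/PCO2 pair only.
#' @param seed Integer seed for this study's draws, or \code{NULL} to derive
#'   one later from a shared seed (see \code{\link{generate_multistudy}}).
#'
#' @return An object of class \code{study_design}.
#' @examples
#' study_design("volunteers", seed = 1L)
#' @export
study_design <- function(study_id, n_subjects = 14,
                         pco2_levels = c(40, 55, 70, 85),
                         beta_true_mean = 12.1, beta_true_sd = 1.5,
                         baseline_sbe_mean = 0, baseline_sbe_sd = 1.0,
                         ph_noise_sd = 0.005, pco2_noise_sd = 1.0,
                         hco3_noise_sd = 0, seed = NULL) {
  if (!is.character(study_id) || length(study_id) != 1L || !nzchar(study_id))
    stop("'study_id' must be a non-empty string", call. = FALSE)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1 ||
      n_subjects != round(n_subjects))
    stop("'n_subjects' must be a positive integer", call. = FALSE)
  if (!is.numeric(pco2_levels) || length(pco2_levels) < 1L ||
      any(!is.finite(pco2_levels)) || is.unsorted(pco2_levels, strictly = TRUE))
    stop("'pco2_levels' must be strictly increasing and finite", call. = FALSE)
  if (!is.numeric(beta_true_mean) || beta_true_mean <= 0)
    stop("'beta_true_mean' must be positive", call. = FALSE)
  for (nm in c("beta_true_sd", "baseline_sbe_sd", "ph_noise_sd",
               "pco2_noise_sd", "hco3_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(study_id = study_id, n_subjects = as.integer(n_subjects),
                 pco2_levels = as.numeric(pco2_levels),
                 beta_true_mean = beta_true_mean, beta_true_sd = beta_true_sd,
                 baseline_sbe_mean = baseline_sbe_mean,
                 baseline_sbe_sd = baseline_sbe_sd,
                 ph_noise_sd = ph_noise_sd, pco2_noise_sd = pco2_noise_sd,
                 hco3_noise_sd = hco3_noise_sd, seed = seed),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Titration study design '%s'\n", x$study_id))
  cat(sprintf("  %d subjects x PCO2 levels [%s] mmHg\n", x$n_subjects,
              paste(format(x$pco2_levels), collapse = ", ")))
  cat(sprintf("  beta_true ~ N(%.2f, %.2f); baseline SBE ~ N(%.2f, %.2f) mmol/L\n",
              x$beta_true_mean, x$beta_true_sd,
              x$baseline_sbe_mean, x$baseline_sbe_sd))
  cat(sprintf("  noise: pH %.4g, PCO2 %.4g mmHg, HCO3 %.4g mmol/L; seed %s\n",
              x$ph_noise_sd, x$pco2_noise_sd, x$hco3_noise_sd,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

#' Invert the base-excess equation for pH at a target base excess
#'
#' Finds the arterial pH at which a subject with buffer power \code{beta}
#' sitting at partial pressure \code{pco2} has base excess equal to
#' \code{target_sbe}, i.e. solves
#' \code{base_excess(hco3_from_ph_pco2(ph, pco2), ph, beta) = target_sbe}.
#' The left-hand side is strictly increasing in pH (both the bicarbonate term
#' and the buffer term rise with pH), so the root is unique; it is located by
#' bisection on the plausibility bracket, which converges unconditionally on
#' a monotone objective.
#'
#' @param pco2 PCO2, mmHg. Vectorized.
#' @param target_sbe Target base excess, mmol/L. Vectorized; recycled.
#' @param beta Buffer power, mmol/L per pH unit (single positive number).
#' @param constants An \code{\link{acid_base_constants}} object; its
#'   \code{ph_bounds} supply the bisection bracket.
#' @param tol Bisection tolerance on pH. Default 1e-10.
#'
#' @return pH value(s) solving the equation to within \code{tol}.
#' @examples
#' ph <- solve_ph_for_target_sbe(40, 0, 16.2)
#' base_excess(hco3_from_ph_pco2(ph, 40), ph, 16.2) # ~0
#' @export
solve_ph_for_target_sbe <- function(pco2, target_sbe, beta,
                                    constants = acid_base_constants(),
                                    tol = 1e-10) {
  ct <- as_constants(constants)
  check_field_range(pco2, "pco2", ct$pco2_bounds[1], ct$pco2_bounds[2])
  check_field_range(target_sbe, "target_sbe")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive finite buffer power", call. = FALSE)
  n <- max(length(pco2), length(target_sbe))
  pco2 <- rep_len(pco2, n)
  target_sbe <- rep_len(target_sbe, n)

  f <- function(ph) {
    (hh_hco3(ph, pco2, ct) - ct$hco3_ref) + (ph - ct$ph_ref) * beta - target_sbe
  }
  lo <- rep_len(ct$ph_bounds[1], n)
  hi <- rep_len(ct$ph_bounds[2], n)
  flo <- f(lo); fhi <- f(hi)
  bad <- which(flo > 0 | fhi < 0)
  if (length(bad))
    stop(sprintf(
      paste0("no pH root in bracket [%g, %g] for pco2 = %g, target_sbe = %g ",
             "(objective %g at lower, %g at upper bound)"),
      lo[bad[1]], hi[bad[1]], pco2[bad[1]], target_sbe[bad[1]],
      flo[bad[1]], fhi[bad[1]]), call. = FALSE)
  # vectorized bisection: objective increasing in ph
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    below <- f(mid) < 0
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  (lo + hi) / 2
}

# Draw one subject's physiological parameters; resampling guards the
# beta_true > 0 invariant (practically unreachable at realistic designs).
draw_subject <- function(design) {
  beta_true <- stats::rnorm(1, design$beta_true_mean, design$beta_true_sd)
  while (beta_true <= 0)
    beta_true <- stats::rnorm(1, design$beta_true_mean, design$beta_true_sd)
  baseline <- stats::rnorm(1, design$baseline_sbe_mean, design$baseline_sbe_sd)
  list(beta_true = beta_true, baseline_sbe = baseline)
}

new_titration_dataset <- function(df, designs, seed = NULL) {
  out <- tibble::as_tibble(df)
  class(out) <- c("titration_dataset", class(out))
  attr(out, "designs") <- designs
  attr(out, "seed") <- seed
  out
}

#' Generate one synthetic CO2-titration study
#'
#' For each subject, draws a true buffer power and baseline base excess from
#' the design's population distributions, computes the noiseless pH at every
#' PCO2 level by \code{\link{solve_ph_for_target_sbe}} (so that base excess at
#' the subject's own buffer power is exactly constant across the titration),
#' then adds Gaussian measurement noise to pH and PCO2 and re-derives
#' bicarbonate from the noisy pair. Per-subject random substreams are keyed by
#' subject label, so the output is bit-reproducible from the study seed.
#'
#' @param design A \code{\link{study_design}}; its \code{seed} must be set
#'   unless \code{seed} is supplied here.
#' @param constants An \code{\link{acid_base_constants}} object.
#' @param seed Optional integer overriding \code{design$seed}.
#'
#' @return A \code{titration_dataset}: a tibble with columns
#'   \code{study_id}, \code{subject_id}, \code{exposure_id},
#'   \code{pco2_mmhg}, \code{ph}, \code{hco3_mmol_l}, plus per-subject truth
#'   columns \code{beta_true} and \code{baseline_sbe} for parameter-recovery
#'   checks. The generating design(s) are attached as attribute
#'   \code{"designs"}.
#' @examples
#' d <- generate_study(study_design("volunteers", seed = 42L))
#' nrow(d) # 14 subjects x 4 levels = 56
#' @export
generate_study <- function(design, constants = acid_base_constants(),
                           seed = NULL) {
  if (!inherits(design, "study_design"))
    stop("'design' must be a study_design object", call. = FALSE)
  ct <- as_constants(constants)
  seed <- seed %||% design$seed
  if (is.null(seed))
    stop(sprintf("study '%s' has no seed: set design$seed or pass seed =",
                 design$study_id), call. = FALSE)
  design$seed <- as.integer(seed)

  levels <- design$pco2_levels
  n_lev <- length(levels)
  subj_ids <- sprintf("S%02d", seq_len(design$n_subjects))
  rows <- vector("list", design$n_subjects)
  for (i in seq_along(subj_ids)) {
    sid <- subj_ids[i]
    set.seed(stable_seed(design$seed, sid))
    subj <- draw_subject(design)
    eps_ph <- stats::rnorm(n_lev, 0, design$ph_noise_sd)
    eps_pco2 <- stats::rnorm(n_lev, 0, design$pco2_noise_sd)
    eps_hco3 <- stats::rnorm(n_lev, 0, design$hco3_noise_sd)

    ph0 <- tryCatch(
      solve_ph_for_target_sbe(levels, subj$baseline_sbe, subj$beta_true, ct),
      error = function(e) stop(sprintf(
        "study '%s', subject '%s': %s", design$study_id, sid,
        conditionMessage(e)), call. = FALSE))
    ph <- ph0 + eps_ph
    pco2 <- levels + eps_pco2
    hco3 <- hh_hco3(ph, pco2, ct) + eps_hco3
    rows[[i]] <- tibble::tibble(
      study_id = design$study_id, subject_id = sid,
      exposure_id = sprintf("E%d", seq_len(n_lev)),
      pco2_mmhg = pco2, ph = ph, hco3_mmol_l = hco3,
      beta_true = subj$beta_true, baseline_sbe = subj$baseline_sbe)
  }
  new_titration_dataset(do.call(rbind, rows), designs = list(design),
                        seed = design$seed)
}

#' Generate a multi-study CO2-titration dataset
#'
#' Concatenates several synthetic studies. Each study draws from an
#' independent random substream derived deterministically from
#' \code{shared_seed} and its own \code{study_id} (designs carrying an
#' explicit seed keep it), so adding, removing or permuting studies never
#' changes another study's observations. Studies given different
#' \code{beta_true_mean} or \code{baseline_sbe_mean} produce the
#' intercept and slope heterogeneity the ANCOVA is designed to detect.
#'
#' @param designs List of \code{\link{study_design}} objects with distinct
#'   \code{study_id}s.
#' @param shared_seed Integer master seed used to derive per-study seeds for
#'   designs without one.
#' @param constants An \code{\link{acid_base_constants}} object.
#'
#' @return A \code{titration_dataset} covering all studies; see
#'   \code{\link{generate_study}}.
#' @examples
#' designs <- list(study_design("A", beta_true_mean = 10),
#'                 study_design("B", beta_true_mean = 14))
#' d <- generate_multistudy(designs, shared_seed = 7L)
#' table(d$study_id)
#' @export
generate_multistudy <- function(designs, shared_seed = NULL,
                                constants = acid_base_constants()) {
  if (inherits(designs, "study_design")) designs <- list(designs)
  if (!length(designs) || !all(vapply(designs, inherits, TRUE, "study_design")))
    stop("'designs' must be a list of study_design objects", call. = FALSE)
  ids <- vapply(designs, `[[`, "", "study_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate study_id: '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  parts <- lapply(designs, function(d) {
    if (is.null(d$seed)) {
      if (is.null(shared_seed))
        stop(sprintf("study '%s' has no seed and no shared_seed was given",
                     d$study_id), call. = FALSE)
      d$seed <- stable_seed(shared_seed, d$study_id)
    }
    generate_study(d, constants)
  })
  new_titration_dataset(do.call(rbind, lapply(parts, as.data.frame)),
                        designs = unlist(lapply(parts, attr, "designs"),
                                         recursive = FALSE),
                        seed = shared_seed)
}
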