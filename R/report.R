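# One-call calibration pipeline and its JSON / text reporting.

#' Run the full base-excess calibration on an observation set
#'
#' Convenience wrapper chaining the package's analyses on one dataset:
#' per-study (and pooled) SBE-on-PCO2 regression at a fixed buffer power,
#' the multi-study ANCOVA (when two or more studies are present), the
#' buffer-power sweep with test-inversion CI, and per-subject base-excess
#' excursions. The returned report carries a config echo (buffer power, grid
#' specification, confidence level, seed) so that results are reproducible
#' from the report alone.
#'
#' @inheritParams fit_sbe_slope
#' @inheritParams beta_sweep
#' @param seed Optional integer echoed into the report (the seed that
#'   generated \code{observations}, when they are synthetic).
#'
#' @return An object of class \code{calibration_report}.
#' @examples
#' d <- generate_study(study_design("volunteers", seed = 1L))
#' rep <- run_calibration(d, seed = 1L)
#' rep$sweep$beta_star
#' @export
run_calibration <- function(observations, beta = NULL,
                            grid_min = 5, grid_max = 20, grid_n = 10000,
                            level = 0.95, constants = acid_base_constants(),
                            seed = NULL) {
  ct <- as_constants(constants)
  beta <- beta %||% ct$standard_beta
  studies <- if ("study_id" %in% names(observations))
    split(observations, observations$study_id) else
      list(all = observations)
  per_study <- lapply(studies, fit_sbe_slope, beta = beta, constants = ct,
                      level = level)
  pooled <- fit_sbe_slope(observations, beta = beta, constants = ct,
                          level = level)
  anc <- if (length(studies) >= 2L)
    sbe_ancova(observations, beta = beta, constants = ct, level = level)
  sweep <- beta_sweep(observations, grid_min = grid_min, grid_max = grid_max,
                      grid_n = grid_n, level = level, constants = ct)
  deltas <- if (all(c("study_id", "subject_id") %in% names(observations)))
    max_delta_sbe(observations, beta = beta, constants = ct)
  structure(list(per_study_fits = per_study, pooled_fit = pooled,
                 ancova = anc, sweep = sweep, deltas = deltas,
                 config = list(beta = beta,
                               grid_spec = list(min = grid_min,
                                                max = grid_max,
                                                n_points = grid_n),
                               level = level, seed = seed,
                               constants = unclass(ct))),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Base-excess calibration report\n")
  cat("==============================\n")
  for (nm in names(x$per_study_fits)) {
    cat(sprintf("study %s: ", nm)); print(x$per_study_fits[[nm]])
  }
  if (!is.null(x$ancova)) print(x$ancova)
  print(x$sweep)
  if (!is.null(x$deltas)) print(x$deltas)
  invisible(x)
}

fit_as_list <- function(f) {
  f[c("slope", "intercept", "slope_se", "ci_low", "ci_high", "p_value",
      "n", "dof", "level", "beta")]
}

report_as_list <- function(report) {
  sw <- report$sweep
  list(
    schema_version = "1.0",
    config = report$config,
    per_study_fits = lapply(report$per_study_fits, fit_as_list),
    pooled_fit = fit_as_list(report$pooled_fit),
    ancova = if (!is.null(report$ancova)) {
      a <- report$ancova
      list(intercept_f = a$intercept_f, intercept_p = a$intercept_p,
           slope_f = a$slope_f, slope_p = a$slope_p,
           intercept_f_reduced = a$intercept_f_reduced,
           intercept_p_reduced = a$intercept_p_reduced,
           n = a$n, n_studies = a$n_studies, beta = a$beta)
    },
    beta_sweep = list(
      grid_spec = as.list(sw$grid_spec),
      beta_star = sw$beta_star, ci_low = sw$ci_low, ci_high = sw$ci_high,
      level = sw$level, degenerate = sw$degenerate,
      ci_contiguous = sw$ci_contiguous,
      non_identifiable = sw$non_identifiable,
      beta_zero_closed_form = sw$beta_zero_closed_form,
      delta_ci_low = sw$delta_ci_low, delta_ci_high = sw$delta_ci_high,
      grid = sw$grid, slopes = sw$slopes, slope_se = sw$slope_se),
    deltas = if (!is.null(report$deltas)) {
      list(beta = report$deltas$beta,
           cohort_range = report$deltas$cohort_range,
           per_subject = report$deltas$per_subject)
    })
}

#' Write a calibration report to JSON plus a text summary
#'
#' Serializes a \code{\link{run_calibration}} report to a schema-versioned
#' JSON file (full double precision, including the complete slope-versus-
#' buffer-power curve for plotting) and a plain-text summary next to it.
#' Output is byte-stable: identical inputs and configuration produce
#' identical files.
#'
#' @param report A \code{calibration_report}.
#' @param path Output JSON path; the text summary goes to the same path with
#'   extension \code{.txt}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "calibration_report"))
    stop("'report' must come from run_calibration()", call. = FALSE)
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  txt_path <- if (grepl("\\.json$", path))
    sub("\\.json$", ".txt", path) else paste0(path, ".txt")
  writeLines(report_summary_lines(report), txt_path)
  invisible(path)
}

report_summary_lines <- function(report) {
  sw <- report$sweep
  lines <- c("Base-excess calibration summary",
             sprintf("beta for SBE analyses: %.4g; confidence level %.0f%%; seed %s",
                     report$config$beta, 100 * report$config$level,
                     if (is.null(report$config$seed)) "none"
                     else report$config$seed))
  for (nm in names(report$per_study_fits)) {
    f <- report$per_study_fits[[nm]]
    lines <- c(lines, sprintf(
      "study %-14s slope %+.4f mmol/L/mmHg (CI %+.4f to %+.4f), p = %.4g, n = %d",
      nm, f$slope, f$ci_low, f$ci_high, f$p_value, f$n))
  }
  if (!is.null(report$ancova))
    lines <- c(lines, sprintf(
      "ANCOVA: intercept differences p = %.4g; slope differences p = %.4g",
      report$ancova$intercept_p, report$ancova$slope_p))
  lines <- c(lines, sprintf(
    "beta sweep (%d points in [%g, %g]): beta_star = %.4f, test-inversion CI %s",
    sw$grid_spec["n_points"], sw$grid_spec["min"], sw$grid_spec["max"],
    sw$beta_star,
    if (sw$degenerate) "empty"
    else sprintf("%.4f to %.4f", sw$ci_low, sw$ci_high)))
  if (!is.null(report$deltas))
    lines <- c(lines, sprintf(
      "per-subject SBE change from lowest-PCO2 baseline: %.3f to %.3f mmol/L",
      report$deltas$cohort_range[1], report$deltas$cohort_range[2]))
  lines
}
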