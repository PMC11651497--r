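# CSV / JSON input and output. The observation CSV dialect is fixed:
# comma-separated, UTF-8, header required, decimal point, columns
# study_id, subject_id, exposure_id, pco2_mmhg, ph, hco3_mmol_l (optional).

obs_required_cols <- c("study_id", "subject_id", "exposure_id",
                       "pco2_mmhg", "ph")

#' Read blood-gas observations from CSV
#'
#' Loads a CO2-titration observation table, validates it against the
#' plausibility bounds in \code{constants}, and fills in bicarbonate from
#' the pH/PCO2 pair where the \code{hco3_mmol_l} column is missing or empty.
#' Rows violating the bounds (or carrying non-finite values) are rejected
#' with a per-row message and a summary warning; the remaining rows load.
#' When a row carries both a measured bicarbonate and a pH/PCO2 pair, the
#' measured value is kept, and a consistency warning is issued if it differs
#' from the Henderson-Hasselbalch value by more than
#' \code{hco3_consistency_tol}.
#'
#' @param path Path to a CSV file with header; required columns
#'   \code{study_id}, \code{subject_id}, \code{exposure_id},
#'   \code{pco2_mmhg}, \code{ph}; optional \code{hco3_mmol_l}.
#' @param constants An \code{\link{acid_base_constants}} object supplying the
#'   plausibility bounds.
#' @param hco3_consistency_tol Tolerance, mmol/L, for the measured-versus-
#'   derived bicarbonate consistency check. Default 1.0.
#' @param quiet Suppress per-row rejection messages. Default FALSE.
#'
#' @return A \code{titration_dataset} tibble of validated observations.
#' @export
read_observations <- function(path, constants = acid_base_constants(),
                              hco3_consistency_tol = 1.0, quiet = FALSE) {
  ct <- as_constants(constants)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  # parse numerics through strtod (correctly rounded) rather than the
  # fast-path float parser, so written values read back bit-identical
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  miss <- setdiff(obs_required_cols, names(raw))
  if (length(miss))
    stop(sprintf("observation CSV lacks required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!nrow(raw))
    stop(sprintf("observation CSV is empty: %s", path), call. = FALSE)

  pco2 <- as.numeric(raw$pco2_mmhg)
  ph <- as.numeric(raw$ph)
  hco3 <- if ("hco3_mmol_l" %in% names(raw))
    as.numeric(raw$hco3_mmol_l) else rep(NA_real_, nrow(raw))

  reasons <- character(nrow(raw))
  flag <- function(bad, why) ifelse(bad & !nzchar(reasons), why, reasons)
  reasons <- flag(!is.finite(pco2), "pco2_mmhg missing or non-numeric")
  reasons <- flag(is.finite(pco2) &
                    (pco2 < ct$pco2_bounds[1] | pco2 > ct$pco2_bounds[2]),
                  sprintf("pco2_mmhg outside [%g, %g]",
                          ct$pco2_bounds[1], ct$pco2_bounds[2]))
  reasons <- flag(!is.finite(ph), "ph missing or non-numeric")
  reasons <- flag(is.finite(ph) &
                    (ph < ct$ph_bounds[1] | ph > ct$ph_bounds[2]),
                  sprintf("ph outside [%g, %g]",
                          ct$ph_bounds[1], ct$ph_bounds[2]))
  reasons <- flag(!is.na(hco3) & hco3 <= 0, "hco3_mmol_l not positive")

  bad <- nzchar(reasons)
  if (any(bad)) {
    if (!quiet)
      for (i in which(bad))
        message(sprintf("row %d rejected: %s", i, reasons[i]))
    warning(sprintf("%d of %d row(s) rejected by plausibility checks",
                    sum(bad), nrow(raw)), call. = FALSE)
  }
  keep <- which(!bad)
  if (!length(keep))
    stop("all rows rejected by plausibility checks", call. = FALSE)

  pco2 <- pco2[keep]; ph <- ph[keep]; hco3 <- hco3[keep]
  derived <- hh_hco3(ph, pco2, ct)
  inconsistent <- !is.na(hco3) & abs(hco3 - derived) > hco3_consistency_tol
  if (any(inconsistent))
    warning(sprintf(
      "%d row(s) with measured hco3_mmol_l differing from the pH/PCO2-derived value by more than %g mmol/L (measured value kept)",
      sum(inconsistent), hco3_consistency_tol), call. = FALSE)
  hco3[is.na(hco3)] <- derived[is.na(hco3)]

  new_titration_dataset(tibble::tibble(
    study_id = as.character(raw$study_id)[keep],
    subject_id = as.character(raw$subject_id)[keep],
    exposure_id = as.character(raw$exposure_id)[keep],
    pco2_mmhg = pco2, ph = ph, hco3_mmol_l = hco3),
    designs = NULL)
}

#' Write blood-gas observations to CSV
#'
#' Writes a \code{titration_dataset} in the package's observation CSV
#' dialect (full double precision, so a read/write cycle round-trips every
#' value). If the dataset carries its generating designs, they can be saved
#' to a JSON sidecar for provenance.
#'
#' @param observations A \code{titration_dataset} or compatible data frame.
#' @param path Output CSV path.
#' @param designs_path Optional path for a JSON sidecar recording the
#'   generating \code{\link{study_design}}s (requires the dataset to carry
#'   them).
#' @return \code{path}, invisibly.
#' @export
write_observations <- function(observations, path, designs_path = NULL) {
  keep <- intersect(c(obs_required_cols, "hco3_mmol_l"), names(observations))
  out <- as.data.frame(observations)[, keep]
  # 17 significant digits guarantee an exact double round trip
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(designs_path)) {
    designs <- attr(observations, "designs")
    if (is.null(designs))
      stop("dataset carries no generating designs to write", call. = FALSE)
    write_designs(designs, designs_path)
  }
  invisible(path)
}

#' Write study designs to JSON
#'
#' @param designs A \code{\link{study_design}} or list of them.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_designs <- function(designs, path) {
  if (inherits(designs, "study_design")) designs <- list(designs)
  payload <- lapply(designs, function(d) unclass(d))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read study designs from JSON
#'
#' Reads a designs file written by \code{\link{write_designs}} (or hand
#' written to the same schema) and revalidates every entry through
#' \code{\link{study_design}}.
#'
#' @param path Path to a designs JSON file.
#' @return A list of \code{\link{study_design}} objects.
#' @export
read_designs <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!length(raw)) stop("designs file is empty", call. = FALSE)
  lapply(raw, function(d) {
    allowed <- names(formals(study_design))
    unknown <- setdiff(names(d), allowed)
    if (length(unknown))
      stop(sprintf("unknown design field(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    do.call(study_design, d)
  })
}
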