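# Blood-gas arithmetic: bicarbonate from pH/PCO2 via Henderson-Hasselbalch,
# and the base-excess equation family (generalized beta, standard beta = 16.2,
# and the Schlichtig 0.9287 * BE(14.83) variant).

#' Acid-base constants, reference points and plausibility bounds
#'
#' Bundles the fixed constants used throughout the package: the reference
#' bicarbonate and pH that define base excess zero, the Henderson-Hasselbalch
#' constants used to derive bicarbonate from a pH/PCO2 pair, the conventional
#' standard-base-excess buffer power (16.2 mmol/L per pH unit), the Schlichtig
#' variant (outer scale 0.9287, buffer power 14.83), and the plausibility
#' bounds used to reject corrupt blood-gas rows.
#'
#' @param hco3_ref Reference bicarbonate, mmol/L. Default 24.8.
#' @param ph_ref Reference arterial pH. Default 7.40.
#' @param pk_prime Apparent pK of the carbonic acid system at 37 degrees C.
#'   Default 6.1.
#' @param co2_solubility CO2 solubility coefficient, mmol/L per mmHg.
#'   Default 0.0307.
#' @param schlichtig_scale Outer multiplier of the Schlichtig SBE equation.
#'   Default 0.9287.
#' @param schlichtig_beta Buffer power inside the Schlichtig SBE equation,
#'   mmol/L per pH unit. Default 14.83.
#' @param standard_beta Buffer power of the conventional SBE equation,
#'   mmol/L per pH unit. Default 16.2.
#' @param ph_bounds Length-2 numeric, plausibility bounds on arterial pH.
#'   Rows outside are rejected on read. Default c(6.5, 8.0).
#' @param pco2_bounds Length-2 numeric, plausibility bounds on PCO2 in mmHg.
#'   Default c(5, 250).
#'
#' @return An object of class \code{acid_base_constants} (a named list).
#' @examples
#' ct <- acid_base_constants()
#' ct$standard_beta
#' @export
acid_base_constants <- function(hco3_ref = 24.8, ph_ref = 7.40,
                                pk_prime = 6.1, co2_solubility = 0.0307,
                                schlichtig_scale = 0.9287,
                                schlichtig_beta = 14.83,
                                standard_beta = 16.2,
                                ph_bounds = c(6.5, 8.0),
                                pco2_bounds = c(5, 250)) {
  scalars <- list(hco3_ref = hco3_ref, ph_ref = ph_ref, pk_prime = pk_prime,
                  co2_solubility = co2_solubility,
                  schlichtig_scale = schlichtig_scale,
                  schlichtig_beta = schlichtig_beta,
                  standard_beta = standard_beta)
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  for (nm in c("ph_bounds", "pco2_bounds")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || v[1] >= v[2])
      stop(sprintf("'%s' must be an increasing pair of finite numbers", nm),
           call. = FALSE)
  }
  structure(c(scalars, list(ph_bounds = as.numeric(ph_bounds),
                            pco2_bounds = as.numeric(pco2_bounds))),
            class = "acid_base_constants")
}

#' @export
print.acid_base_constants <- function(x, ...) {
  cat("Acid-base constants\n")
  cat(sprintf("  reference point : HCO3 %.1f mmol/L, pH %.2f\n",
              x$hco3_ref, x$ph_ref))
  cat(sprintf("  Henderson-Hasselbalch : pK' %.2f, solubility %.4f mmol/L/mmHg\n",
              x$pk_prime, x$co2_solubility))
  cat(sprintf("  standard beta %.1f; Schlichtig %.4f x BE(beta = %.2f)\n",
              x$standard_beta, x$schlichtig_scale, x$schlichtig_beta))
  cat(sprintf("  plausibility : pH [%g, %g], PCO2 [%g, %g] mmHg\n",
              x$ph_bounds[1], x$ph_bounds[2],
              x$pco2_bounds[1], x$pco2_bounds[2]))
  invisible(x)
}

as_constants <- function(constants) {
  if (!inherits(constants, "acid_base_constants"))
    stop("'constants' must be created by acid_base_constants()", call. = FALSE)
  constants
}

# Domain validation naming the offending field; vectorized.
check_field_range <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x))
    stop(sprintf("'%s' must be numeric", field), call. = FALSE)
  bad <- which(!is.finite(x) | x < lo | x > hi)
  if (length(bad))
    stop(sprintf(
      "'%s' out of range [%g, %g]: value %g at position %d",
      field, lo, hi, x[bad[1]], bad[1]), call. = FALSE)
  invisible(TRUE)
}

# Henderson-Hasselbalch without validation; used in solver/generator hot paths.
hh_hco3 <- function(ph, pco2, ct) {
  ct$co2_solubility * pco2 * 10^(ph - ct$pk_prime)
}

#' Bicarbonate from pH and PCO2 (Henderson-Hasselbalch)
#'
#' Computes plasma bicarbonate as
#' \code{co2_solubility * pco2 * 10^(ph - pk_prime)}, the rearranged
#' Henderson-Hasselbalch relation. Used to fill in bicarbonate when an
#' observation table reports only the measured pH/PCO2 pair.
#'
#' @param ph Arterial pH (unitless). Vectorized.
#' @param pco2 Arterial CO2 partial pressure, mmHg. Vectorized; recycled
#'   against \code{ph}.
#' @param constants An \code{\link{acid_base_constants}} object; also supplies
#'   the plausibility bounds enforced on the inputs.
#'
#' @return Bicarbonate concentration(s), mmol/L. Strictly increasing in both
#'   arguments (linear in \code{pco2}, log-linear in \code{ph}).
#' @examples
#' hco3_from_ph_pco2(7.40, 40) # approximately 24.5 mmol/L
#' @export
hco3_from_ph_pco2 <- function(ph, pco2, constants = acid_base_constants()) {
  ct <- as_constants(constants)
  check_field_range(ph, "ph", ct$ph_bounds[1], ct$ph_bounds[2])
  check_field_range(pco2, "pco2", ct$pco2_bounds[1], ct$pco2_bounds[2])
  hh_hco3(ph, pco2, ct)
}

#' Generalized base excess
#'
#' The whole-body base excess at an arbitrary buffer power:
#' \code{(hco3 - hco3_ref) + (ph - ph_ref) * beta}. The buffer power
#' \code{beta} (mmol/L per pH unit) expresses how strongly non-bicarbonate
#' buffers resist pH change during CO2 titration; the conventional standard
#' base excess fixes it at 16.2, while this package's calibration machinery
#' treats it as the free parameter.
#'
#' @param hco3 Bicarbonate, mmol/L. Vectorized.
#' @param ph Arterial pH. Vectorized; recycled.
#' @param beta Buffer power, mmol/L per pH unit; a single positive number.
#' @param constants An \code{\link{acid_base_constants}} object supplying the
#'   reference point.
#'
#' @return Base excess, mmol/L. Exactly linear in \code{beta}.
#' @examples
#' base_excess(24.8, 7.40, 12.1)  # 0 at the reference point, any beta
#' base_excess(24.8, 7.30, 16.2)  # -1.62
#' @export
base_excess <- function(hco3, ph, beta, constants = acid_base_constants()) {
  ct <- as_constants(constants)
  check_field_range(hco3, "hco3", lo = .Machine$double.xmin)
  check_field_range(ph, "ph")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive finite buffer power", call. = FALSE)
  (hco3 - ct$hco3_ref) + (ph - ct$ph_ref) * beta
}

#' Standard base excess (beta = 16.2)
#'
#' The conventional standard-base-excess equation,
#' \code{(hco3 - 24.8) + (ph - 7.40) * 16.2}, i.e. \code{\link{base_excess}}
#' evaluated at the fixed extracellular-fluid buffer power.
#'
#' @inheritParams base_excess
#' @return Standard base excess, mmol/L.
#' @examples
#' sbe_standard(26.0, 7.35) # 0.39
#' @export
sbe_standard <- function(hco3, ph, constants = acid_base_constants()) {
  ct <- as_constants(constants)
  base_excess(hco3, ph, ct$standard_beta, ct)
}

#' Schlichtig variant of standard base excess
#'
#' The alternative SBE formulation
#' \code{0.9287 * ((hco3 - 24.8) + (ph - 7.40) * 14.83)}: an inner base excess
#' at buffer power 14.83 rescaled by 0.9287. Because the outer factor is a
#' positive constant it preserves the zero crossing of any SBE-versus-PCO2
#' regression, so buffer-power calibration is invariant to this choice.
#'
#' @inheritParams base_excess
#' @return Schlichtig standard base excess, mmol/L.
#' @examples
#' sbe_schlichtig(24.8, 7.30) # 0.9287 * (-0.1 * 14.83) = -1.3773
#' @export
sbe_schlichtig <- function(hco3, ph, constants = acid_base_constants()) {
  ct <- as_constants(constants)
  ct$schlichtig_scale * base_excess(hco3, ph, ct$schlichtig_beta, ct)
}
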