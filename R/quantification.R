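# Target-quantification mathematics and method-validation metrics.

#' Fit a calibration curve
#'
#' Ordinary least-squares regression of peak area on concentration.
#'
#' @param levels Concentrations (µg/kg), at least 3 distinct values.
#' @param responses Peak areas.
#' @param analyte Optional analyte label.
#' @param matrix One of `"solvent"`, `"honey_matrix"`.
#' @param r2_warn Linearity threshold; `low_linearity` is flagged when R²
#'   does not exceed it.
#' @return Object of class `calibration_curve`: slope, intercept,
#'   `r_squared`, `low_linearity` flag, data.
#' @export
fit_calibration <- function(levels, responses, analyte = NA_character_,
                            matrix = c("solvent", "honey_matrix"),
                            r2_warn = 0.99) {
  stopifnot(length(levels) == length(responses), length(levels) >= 3L)
  if (length(unique(levels)) < 2L) {
    stop("calibration levels are constant; fit is singular", call. = FALSE)
  }
  matrix <- match.arg(matrix)
  fit <- stats::lm(responses ~ levels)
  # noise-free synthetic series fit exactly; the lm summary warning about a
  # perfect fit is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    analyte = analyte, matrix = matrix,
    levels = levels, responses = responses,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2, low_linearity = r2 <= r2_warn
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s (%s): area = %.4g x conc %+.4g, R2 = %.5f%s\n",
    x$analyte, x$matrix, x$slope, x$intercept, x$r_squared,
    if (x$low_linearity) " [low linearity]" else ""))
  invisible(x)
}

#' Matrix effect (%)
#'
#' ME% = (slope in matrix / slope in solvent - 1) x 100. Zero means no
#' effect; negative values indicate ionization suppression, positive
#' enhancement.
#'
#' @param matrix_curve,solvent_curve `calibration_curve`s (or bare slopes).
#' @return Percentage.
#' @export
matrix_effect <- function(matrix_curve, solvent_curve) {
  sm <- if (inherits(matrix_curve, "calibration_curve"))
    matrix_curve$slope else matrix_curve
  ss <- if (inherits(solvent_curve, "calibration_curve"))
    solvent_curve$slope else solvent_curve
  if (ss == 0) stop("solvent slope is zero", call. = FALSE)
  (sm / ss - 1) * 100
}

#' Recovery (%)
#'
#' Peak-area ratio of samples spiked before extraction to blank extracts
#' spiked just before injection, times 100.
#'
#' @param area_spiked_before,area_spiked_after Positive peak areas.
#' @return Percentage.
#' @export
recovery <- function(area_spiked_before, area_spiked_after) {
  stopifnot(area_spiked_before > 0)
  if (any(area_spiked_after <= 0)) {
    stop("post-extraction spike area must be positive", call. = FALSE)
  }
  100 * area_spiked_before / area_spiked_after
}

#' Relative standard deviation (%)
#'
#' @param replicate_values At least two replicate measurements.
#' @return 100 x sd / mean.
#' @export
precision_rsd <- function(replicate_values) {
  stopifnot(length(replicate_values) >= 2L)
  100 * stats::sd(replicate_values) / mean(replicate_values)
}

#' LOQ from a calibration series
#'
#' The LOQ is the lowest calibration level whose quantifier-transition S/N
#' reaches 10.
#'
#' @param curve `calibration_curve`.
#' @param sn Signal-to-noise estimates aligned with `curve$levels`.
#' @param min_sn S/N requirement (default 10).
#' @return list(`loq` µg/kg or NA, `defined` logical).
#' @export
loq_from_calibration <- function(curve, sn, min_sn = 10) {
  stopifnot(length(sn) == length(curve$levels))
  ord <- order(curve$levels)
  lv <- curve$levels[ord]; sn <- sn[ord]
  ok <- which(sn >= min_sn)
  if (!length(ok)) return(list(loq = NA_real_, defined = FALSE))
  list(loq = lv[ok[1]], defined = TRUE)
}

#' Quantify a feature and decide positivity
#'
#' Concentration = (area - intercept) / slope. A detection is positive iff
#' S/N >= `min_sn`, the qualifier/quantifier ion ratio matches the standard
#' reference within `ratio_tol` (relative), and the concentration reaches
#' the LOQ. Detections failing only the LOQ test are reported `"<LOQ"`.
#'
#' @param area Quantifier peak area.
#' @param sn Signal-to-noise of the detection ions.
#' @param ion_ratio Observed qualifier/quantifier ratio.
#' @param curve `calibration_curve`.
#' @param ion_ratio_ref Reference ratio from standards.
#' @param loq LOQ (µg/kg).
#' @param min_sn Positivity S/N threshold (default 3).
#' @param ratio_tol Relative ion-ratio tolerance (default 0.30).
#' @return list(`concentration`, `status` in
#'   `"positive"`/`"<LOQ"`/`"not_detected"`, `clipped` flag).
#' @export
quantify_and_flag <- function(area, sn, ion_ratio, curve, ion_ratio_ref,
                              loq, min_sn = 3, ratio_tol = 0.30) {
  conc <- (area - curve$intercept) / curve$slope
  clipped <- conc < 0
  if (clipped) conc <- 0
  ratio_ok <- abs(ion_ratio - ion_ratio_ref) <= ratio_tol * ion_ratio_ref
  detected <- sn >= min_sn && ratio_ok
  status <- if (!detected) "not_detected"
  else if (conc >= loq) "positive" else "<LOQ"
  list(concentration = conc, status = status, clipped = clipped)
}

#' Lower-bound panel sum
#'
#' Regulatory total over the reporting panel: censored ("<LOQ") and absent
#' analytes contribute zero; co-eluting isomers enter once through their
#' group column.
#'
#' @param row Named vector over reporting analytes - numeric (µg/kg, with NA
#'   for censored/absent) or character (numbers, `"<LOQ"`, `""`).
#' @return Sum in µg/kg.
#' @export
lower_bound_sum <- function(row) {
  if (is.character(row)) {
    row <- suppressWarnings(as.numeric(ifelse(trimws(row) %in%
                                                c("<LOQ", ""), 0, row)))
  }
  row[is.na(row)] <- 0
  sum(row)
}

#' Upper-bound panel sum
#'
#' Companion bound with censored analytes counted at the LOQ.
#'
#' @param row As in [lower_bound_sum()] (character form required to locate
#'   censoring marks, or numeric with `censored` logical).
#' @param loq LOQ (µg/kg).
#' @param censored Optional logical mask for numeric input.
#' @return Sum in µg/kg.
#' @export
upper_bound_sum <- function(row, loq, censored = NULL) {
  if (is.character(row)) {
    censored <- trimws(row) == "<LOQ"
    row <- suppressWarnings(as.numeric(ifelse(censored | row == "", 0, row)))
  }
  if (is.null(censored)) censored <- rep(FALSE, length(row))
  row[is.na(row)] <- 0
  sum(row) + loq * sum(censored)
}

#' Semiquantify an annotated suspect
#'
#' Estimates the concentration of a tentatively identified compound
#' (confidence level <= 2) with the calibration curve of its structurally
#' nearest regulated analog: same ester type and N-oxidation state, falling
#' back to same necine class. The estimate is labelled semiquantitative with
#' the analog named; with no analog curve the estimate is withheld.
#'
#' @param area Peak area of the suspect.
#' @param candidate One-row data.frame with `ester_type`, `necine_class`,
#'   `is_n_oxide` (layout of [regulated_panel()]).
#' @param curves Named list of `calibration_curve` keyed by panel compound
#'   name.
#' @param confidence_level Schymanski level of the annotation.
#' @return list(`estimate` µg/kg or NA, `analog`, `semiquantitative`,
#'   `withheld`).
#' @export
semiquantify <- function(area, candidate, curves, confidence_level = 2L) {
  if (confidence_level > 2L) {
    stop("semiquantification requires confidence level <= 2", call. = FALSE)
  }
  panel <- regulated_panel()
  avail <- panel[panel$name %in% names(curves), , drop = FALSE]
  pick <- avail[avail$ester_type == candidate$ester_type &
                  avail$is_n_oxide == candidate$is_n_oxide, , drop = FALSE]
  if (!nrow(pick)) {
    pick <- avail[avail$necine_class == candidate$necine_class, ,
                  drop = FALSE]
  }
  if (!nrow(pick)) {
    return(list(estimate = NA_real_, analog = NA_character_,
                semiquantitative = TRUE, withheld = TRUE))
  }
  analog <- pick$name[1]
  cv <- curves[[analog]]
  list(estimate = (area - cv$intercept) / cv$slope, analog = analog,
       semiquantitative = TRUE, withheld = FALSE)
}

#' Validate a method run
#'
#' Applies the acceptance rules used in LC-MS/MS validation: recoveries
#' acceptable in 75-109%, RSD below 20%, linearity R² above 0.99, |ME|
#' within a stated bound.
#'
#' @param recoveries Recovery percentages.
#' @param rsds RSD percentages.
#' @param r_squared Calibration R².
#' @param me_percent ME values (%).
#' @param recovery_range,max_rsd,min_r2,max_abs_me Acceptance limits.
#' @return list of logical flags plus overall `acceptable`.
#' @export
validate_method <- function(recoveries, rsds, r_squared, me_percent,
                            recovery_range = c(75, 109), max_rsd = 20,
                            min_r2 = 0.99, max_abs_me = 14) {
  flags <- list(
    recovery_ok = all(recoveries >= recovery_range[1] &
                        recoveries <= recovery_range[2]),
    precision_ok = all(rsds < max_rsd),
    linearity_ok = all(r_squared > min_r2),
    matrix_effect_ok = all(abs(me_percent) <= max_abs_me)
  )
  flags$acceptable <- all(unlist(flags))
  flags
}
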