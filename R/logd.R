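#' Fit a chromatographic calibration curve
#'
#' Ordinary least-squares line of detector response on concentration, fitted
#' on the per-level replicate means (replicates collapse to means; per-level
#' %RSD is retained as QC metadata). A QC flag is raised when R2 falls below
#' 0.998, the acceptance limit for shake-flask quantification.
#'
#' @param levels calibration concentrations, uM (strictly positive,
#'   distinct; at least 4 levels, e.g. 10, 5, 2.5, 1.25, 0.63).
#' @param responses list (one numeric vector of replicate signals per level)
#'   or a numeric vector of single responses.
#' @param compound optional compound identifier.
#' @param r2_limit QC limit on R2 (default 0.998).
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r2`, `levels`, `mean_responses`, `replicate_rsd` (percent per level),
#'   `qc_pass`, `qc_flags`.
#' @export
#' @examples
#' fit_calibration(c(10, 5, 2.5, 1.25, 0.63), c(100, 50, 25, 12.5, 6.3))
fit_calibration <- function(levels, responses, compound = NA_character_,
                            r2_limit = 0.998) {
  check_number(levels, "levels", lower = 0, strict = TRUE)
  if (anyDuplicated(levels)) {
    abort_zfpk("calibration levels must be distinct", "zfpk_invalid_design")
  }
  if (length(levels) < 4) {
    abort_zfpk("need at least 4 calibration levels", "zfpk_invalid_design")
  }
  if (!is.list(responses)) responses <- as.list(responses)
  if (length(responses) != length(levels)) {
    abort_zfpk("one response vector per level is required", "zfpk_invalid_design")
  }
  means <- vapply(responses, mean, numeric(1))
  rsd <- vapply(responses, function(x) {
    if (length(x) < 2) return(NA_real_)
    100 * sd(x) / mean(x)
  }, numeric(1))
  fit <- lm(means ~ levels)
  sst <- sum((means - mean(means))^2)
  r2 <- 1 - sum(resid(fit)^2) / sst
  flags <- character(0)
  if (r2 < r2_limit) flags <- c(flags, sprintf("r2 %.5f below %.3f", r2, r2_limit))
  bad_rsd <- which(!is.na(rsd) & rsd >= 10)
  if (length(bad_rsd)) {
    flags <- c(flags, sprintf("replicate %%RSD >= 10%% at level %g uM",
                              levels[bad_rsd]))
  }
  structure(list(compound = compound, levels = levels, mean_responses = means,
                 replicate_rsd = rsd, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r2 = r2,
                 qc_pass = length(flags) == 0, qc_flags = flags),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: response = %.4g + %.4g x conc, R2 %.5f (%s)\n",
              x$compound, x$intercept, x$slope, x$r2,
              if (x$qc_pass) "QC pass" else paste(x$qc_flags, collapse = "; ")))
  invisible(x)
}

#' Relative standard deviation of replicate injections
#'
#' 100 * sample standard deviation / mean. Values at or above 10% fail the
#' repeatability QC gate used for shake-flask quantification.
#'
#' @param replicates numeric vector of replicate signals (>= 2 values).
#' @return Percent RSD, with attribute `qc_pass`.
#' @export
#' @examples
#' rsd_check(c(9, 10, 11))  # 10%
rsd_check <- function(replicates) {
  check_number(replicates, "replicates")
  if (length(replicates) < 2) {
    abort_zfpk("need at least 2 replicates", "zfpk_invalid_input")
  }
  m <- mean(replicates)
  if (m == 0) abort_zfpk("zero mean: RSD undefined", "zfpk_undefined_rsd")
  out <- 100 * sd(replicates) / m
  attr(out, "qc_pass") <- out < 10
  out
}

#' Inverse-predict a concentration from a calibration curve
#'
#' @param curve a [fit_calibration()] result with nonzero slope.
#' @param response detector signal.
#' @return Concentration, uM. Warns when the result lies outside the
#'   calibrated level range (extrapolation).
#' @export
quantify <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    abort_zfpk("calibration slope is zero", "zfpk_invalid_curve")
  }
  conc <- (response - curve$intercept) / curve$slope
  rng <- range(curve$levels)
  tol <- 1e-9 * diff(rng)
  if (any(conc < rng[1] - tol | conc > rng[2] + tol)) {
    warn_zfpk("quantified concentration outside the calibrated range (extrapolation)",
              "zfpk_extrapolation")
  }
  conc
}

#' Distribution coefficient from phase concentrations
#'
#' LogD (octanol/Danieau's) is the log10 ratio of the compound concentration
#' in the octanol phase to that in the aqueous (Danieau's) phase after
#' shake-flask equilibration. The logarithm is essential: hydrophilic
#' compounds partition mostly into the aqueous phase and carry negative
#' LogD.
#'
#' @param conc_octanol concentration in the octanol phase, uM (> 0).
#' @param conc_danieau concentration in the aqueous phase, uM (> 0).
#' @return LogD, dimensionless (log10 scale).
#' @export
#' @examples
#' compute_logd(10, 1)   # 1
#' compute_logd(1, 10)   # -1
compute_logd <- function(conc_octanol, conc_danieau) {
  check_number(conc_octanol, "conc_octanol", lower = 0, strict = TRUE)
  check_number(conc_danieau, "conc_danieau", lower = 0, strict = TRUE)
  # difference of logs keeps the antisymmetry exact in floating point
  log10(conc_octanol) - log10(conc_danieau)
}
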