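#' Relative Exposure: immersion AUC over injection AUC
#'
#' The Relative Exposure of a compound compares the total intrabody exposure
#' achieved by immersion at a given bath concentration to that achieved by a
#' microinjected dose over the same window:
#' \deqn{RE = AUC_{imm}(0, t_1) / AUC_{inj}(0, t_1).}
#' Both AUCs come from the closed-form fitted model; the fluorescence
#' constant cancels, so RE is fluorescence-independent. At 10 uM vs 2 mg/kg
#' an RE of 1 means the two routes deliver equal exposure.
#'
#' @param params a [pk_parameters()] object (only `ke` and `q` matter).
#' @param mw molecular weight, g/mol (converts uM to ng/L).
#' @param conc_um immersion concentration, uM (default 10).
#' @param dose_mg_per_kg injected dose, mg/kg (default 2).
#' @param body_weight_mg body weight, mg (default 0.25).
#' @param t1 end of the exposure window, h.
#' @return Dimensionless AUC ratio.
#' @export
#' @examples
#' p <- pk_parameters(fluor = 1, ke = 0.049, q = 8.37e-9)
#' relative_exposure(p, mw = 530.14, t1 = 48)  # about 2.90
relative_exposure <- function(params, mw, conc_um = 10, dose_mg_per_kg = 2,
                              body_weight_mg = 0.25, t1) {
  stopifnot(inherits(params, "pk_parameters"))
  check_number(t1, "t1", lower = 0, strict = TRUE)
  check_number(dose_mg_per_kg, "dose_mg_per_kg", lower = 0, strict = TRUE)
  dose_ng <- dose_amount(dose_mg_per_kg, body_weight_mg)
  m <- medium_concentration(conc_um, mw)
  auc_inj <- auc_closed_form(0, t1, dose_ng, 0, params$ke, params$q)
  if (auc_inj <= 0) {
    abort_zfpk("injection AUC is zero; RE undefined", "zfpk_division_error")
  }
  auc_closed_form(0, t1, 0, m, params$ke, params$q) / auc_inj
}

#' Relative Contribution of each route under combined administration
#'
#' For a combined immersion + microinjection treatment, the Relative
#' Contribution of a route is its share of the combination AUC:
#' \deqn{RC = 100 \times AUC_{route} / AUC_{combination}.}
#' Because the model is linear, the combination AUC is exactly the sum of
#' the two single-route AUCs, so the two contributions always add to 100.
#'
#' @inheritParams relative_exposure
#' @return Named numeric vector `c(rc_immersion, rc_injection)`, percent.
#' @export
relative_contribution <- function(params, mw, conc_um = 10, dose_mg_per_kg = 2,
                                  body_weight_mg = 0.25, t1) {
  stopifnot(inherits(params, "pk_parameters"))
  check_number(t1, "t1", lower = 0, strict = TRUE)
  dose_ng <- dose_amount(dose_mg_per_kg, body_weight_mg)
  m <- if (conc_um > 0) medium_concentration(conc_um, mw) else 0
  auc_imm <- auc_closed_form(0, t1, 0, m, params$ke, params$q)
  auc_inj <- auc_closed_form(0, t1, dose_ng, 0, params$ke, params$q)
  auc_comb <- auc_closed_form(0, t1, dose_ng, m, params$ke, params$q)
  if (auc_comb <= 0) {
    abort_zfpk("combination AUC is zero; RC undefined", "zfpk_division_error")
  }
  c(rc_immersion = 100 * auc_imm / auc_comb,
    rc_injection = 100 * auc_inj / auc_comb)
}

#' Exposure-metric table across compounds and windows
#'
#' Computes, for each fitted compound and each exposure window, the three
#' single- and combined-route AUCs (amount scale, ng*h), the Relative
#' Exposure and the two Relative Contributions.
#'
#' @param fits named list of [fit_pk()] results (or a list of
#'   [pk_parameters()]), one per compound.
#' @param compounds list of [compound_record()] or a data.frame like
#'   [reference_compounds()] supplying molecular weights.
#' @param windows numeric vector of window ends, h (each window is 0 to w).
#' @param conc_um,dose_mg_per_kg,body_weight_mg design constants.
#' @return A data.frame with one row per compound x window: `compound`,
#'   `window_h`, `auc_imm`, `auc_inj`, `auc_comb`, `re`, `rc_imm_pct`,
#'   `rc_inj_pct`.
#' @export
exposure_table <- function(fits, compounds, windows = c(3, 24, 48),
                           conc_um = 10, dose_mg_per_kg = 2,
                           body_weight_mg = 0.25) {
  if (is.data.frame(compounds)) {
    mw_map <- setNames(compounds$mw, compounds$compound)
  } else {
    mw_map <- setNames(vapply(compounds, function(x) x$mw, numeric(1)),
                       vapply(compounds, function(x) x$name, character(1)))
  }
  rows <- list()
  for (cmp in names(fits)) {
    f <- fits[[cmp]]
    params <- if (inherits(f, "pk_fit")) f$params else f
    if (!cmp %in% names(mw_map)) {
      abort_zfpk(sprintf("no compound record for '%s'", cmp),
                 "zfpk_missing_compound")
    }
    mw <- mw_map[[cmp]]
    dose_ng <- dose_amount(dose_mg_per_kg, body_weight_mg)
    m <- medium_concentration(conc_um, mw)
    for (w in windows) {
      auc_imm <- auc_closed_form(0, w, 0, m, params$ke, params$q)
      auc_inj <- auc_closed_form(0, w, dose_ng, 0, params$ke, params$q)
      auc_comb <- auc_closed_form(0, w, dose_ng, m, params$ke, params$q)
      rows[[paste(cmp, w)]] <- data.frame(
        compound = cmp, window_h = w, auc_imm = auc_imm, auc_inj = auc_inj,
        auc_comb = auc_comb, re = auc_imm / auc_inj,
        rc_imm_pct = 100 * auc_imm / auc_comb,
        rc_inj_pct = 100 * auc_inj / auc_comb, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trapezoidal AUC on raw observations (diagnostic)
#'
#' Composite-trapezoid AUC of per-timepoint mean fluorescence against time,
#' for comparing the model-based AUC with the raw data. Reported on the
#' fluorescence scale (RFU*h).
#'
#' @param dataset a `zfpk_dataset`.
#' @param compound compound identifier.
#' @param route route whose observations to use.
#' @param use_censored include censored observations (default FALSE).
#' @return AUC, RFU*h.
#' @export
trapezoid_auc <- function(dataset, compound, route, use_censored = FALSE) {
  obs <- dataset$observations
  obs <- obs[obs$compound == compound & obs$route == route, ]
  if (!use_censored) obs <- obs[!obs$censored, ]
  if (nrow(obs) < 2) {
    abort_zfpk("need at least two timepoints for a trapezoid AUC",
               "zfpk_invalid_input")
  }
  means <- tapply(obs$rfu, obs$time_h, mean)
  tt <- as.numeric(names(means))
  sum(diff(tt) * (head(means, -1) + tail(means, -1)) / 2)
}
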