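#' Create a set of PK parameters
#'
#' Bundles the three identifiable parameters of the one-compartment
#' fluorescence model: `fluor`, the compound-specific constant mapping
#' intrabody amount to fluorescence (RFU/ng); `ke`, the total elimination
#' rate constant (1/h), the lumped (Q + CL)/V of the underlying mass-balance
#' model; and `q`, the passive bidirectional exchange clearance with the
#' medium (L/h). One-way clearance CL and volume V enter only through `ke`
#' and are not separately identifiable, so they are not represented.
#'
#' @param fluor fluorescence constant, RFU/ng. Must be positive.
#' @param ke total elimination rate constant, 1/h. Must be positive.
#' @param q passive exchange clearance, L/h. Must be nonnegative.
#' @return An object of class `pk_parameters`.
#' @export
#' @examples
#' pk_parameters(fluor = 5000, ke = 0.049, q = 8.37e-9)
pk_parameters <- function(fluor, ke, q) {
  check_number(fluor, "fluor", lower = 0, strict = TRUE)
  check_number(ke, "ke", lower = 0, strict = TRUE)
  check_number(q, "q", lower = 0)
  structure(list(fluor = fluor, ke = ke, q = q), class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> FLUOR %.4g RFU/ng, ke %.4g 1/h (t1/2 %.3g h), Q %.4g L/h\n",
              x$fluor, x$ke, log(2) / x$ke, x$q))
  invisible(x)
}

#' Convert a micromolar medium concentration to ng/L
#'
#' @param conc_um concentration in the immersion medium, micromolar.
#' @param mw molecular weight, g/mol.
#' @return Concentration in ng/L (1 uM of a 1 g/mol compound is 1000 ng/L).
#' @export
#' @examples
#' medium_concentration(10, 530.14)  # 5.3014e6 ng/L
medium_concentration <- function(conc_um, mw) {
  check_number(conc_um, "conc_um", lower = 0)
  check_number(mw, "mw", lower = 0, strict = TRUE)
  conc_um * mw * 1000
}

#' Convert a weight-normalised dose to an absolute amount
#'
#' mg/kg times mg gives ng directly, so a 2 mg/kg microinjection into a
#' 0.25 mg eleuthero-embryo delivers 0.5 ng.
#'
#' @param dose_mg_per_kg dose, mg per kg body weight.
#' @param body_weight_mg body weight, mg.
#' @return Injected amount, ng.
#' @export
#' @examples
#' dose_amount(2, 0.25)  # 0.5 ng
dose_amount <- function(dose_mg_per_kg, body_weight_mg) {
  check_number(dose_mg_per_kg, "dose_mg_per_kg", lower = 0)
  check_number(body_weight_mg, "body_weight_mg", lower = 0)
  dose_mg_per_kg * body_weight_mg
}

#' Intrabody amount at time t (closed form)
#'
#' Evaluates the closed-form solution of the one-compartment model,
#' \deqn{A(t) = Dose \, e^{-k_e t} + \frac{M Q}{k_e}\left(1 - e^{-k_e t}\right),}
#' with Dose the injected amount (ng, zero for pure immersion) and M the
#' medium concentration (ng/L, zero for pure injection). Combination
#' regimens use both terms; the model is linear so the two limbs superpose.
#'
#' @param params a [pk_parameters()] object.
#' @param regimen an [exposure_regimen()] object.
#' @param t time(s) since start of exposure, h (vectorised).
#' @param mw molecular weight of the compound, g/mol; needed whenever the
#'   regimen has a nonzero medium concentration.
#' @return Amount in the body, ng (same length as `t`).
#' @export
#' @examples
#' p <- pk_parameters(fluor = 1, ke = 0.049, q = 8.37e-9)
#' r <- exposure_regimen("immersion", medium_conc_um = 10)
#' amount_at_time(p, r, t = 48, mw = 530.14)
amount_at_time <- function(params, regimen, t, mw = NULL) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(regimen, "exposure_regimen"))
  check_number(t, "t", lower = 0)
  if (params$ke <= 0) abort_zfpk("ke must be positive", "zfpk_invalid_parameter")
  dose_ng <- dose_amount(regimen$dose_mg_per_kg, regimen$body_weight_mg)
  m_ng_l <- 0
  if (regimen$medium_conc_um > 0) {
    if (is.null(mw)) {
      abort_zfpk("`mw` is required for a regimen with medium exposure",
                 "zfpk_invalid_input")
    }
    m_ng_l <- medium_concentration(regimen$medium_conc_um, mw)
  }
  amount_closed_form(t, dose_ng, m_ng_l, params$ke, params$q)
}

# closed form on already-converted inputs (ng, ng/L); vectorised over t
amount_closed_form <- function(t, dose_ng, m_ng_l, ke, q) {
  dose_ng * exp(-ke * t) + (m_ng_l * q / ke) * (1 - exp(-ke * t))
}

#' Intrabody amount trajectory by numerical ODE integration
#'
#' Integrates dA/dt = -ke * A + Q * M with A(0) = Dose using an adaptive
#' stiff-capable solver (lsoda, relative tolerance 1e-9). This is the
#' independent oracle for the closed form implemented in [amount_at_time()]:
#' the two must agree to well below 1e-6 relative.
#'
#' @inheritParams amount_at_time
#' @param times sorted nonnegative evaluation times, h.
#' @return A data.frame of class `amount_trajectory` with columns `time_h`
#'   and `amount_ng`.
#' @export
amount_trajectory_ode <- function(params, regimen, times, mw = NULL) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(regimen, "exposure_regimen"))
  check_number(times, "times", lower = 0)
  if (is.unsorted(times)) abort_zfpk("`times` must be sorted", "zfpk_invalid_input")
  dose_ng <- dose_amount(regimen$dose_mg_per_kg, regimen$body_weight_mg)
  m_ng_l <- if (regimen$medium_conc_um > 0) {
    if (is.null(mw)) {
      abort_zfpk("`mw` is required for a regimen with medium exposure",
                 "zfpk_invalid_input")
    }
    medium_concentration(regimen$medium_conc_um, mw)
  } else 0
  tt <- times
  if (tt[1] > 0) tt <- c(0, tt)
  sol <- deSolve::ode(
    y = c(A = dose_ng), times = tt,
    func = function(t, y, parms) list(-parms$ke * y[1] + parms$q * parms$m),
    parms = list(ke = params$ke, q = params$q, m = m_ng_l),
    method = "lsoda", rtol = 1e-9, atol = 1e-12
  )
  if (attr(sol, "istate")[1] < 0) {
    abort_zfpk("ODE solver failed to converge; see deSolve diagnostics",
               "zfpk_numeric_error")
  }
  out <- as.data.frame(sol)
  out <- out[match(times, out$time), ]
  structure(data.frame(time_h = times, amount_ng = out$A),
            class = c("amount_trajectory", "data.frame"))
}

#' Fluorescence readout for a given intrabody amount
#'
#' The whole-body integrated fluorescence is proportional to the amount of
#' compound in the body: RFU = FLUOR * A.
#'
#' @param params a [pk_parameters()] object.
#' @param amount amount(s) in the body, ng.
#' @return Fluorescence, RFU.
#' @export
fluorescence <- function(params, amount) {
  stopifnot(inherits(params, "pk_parameters"))
  check_number(amount, "amount", lower = 0)
  params$fluor * amount
}

#' Steady-state amount under continuous immersion
#'
#' The equilibrium of the uptake/elimination balance, M * Q / ke (ng). On the
#' fluorescence scale this is the horizontal asymptote of an immersion time
#' course.
#'
#' @inheritParams amount_at_time
#' @return Steady-state amount, ng.
#' @export
steady_state_amount <- function(params, regimen, mw) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(regimen, "exposure_regimen"))
  if (regimen$medium_conc_um <= 0) {
    abort_zfpk("steady state is undefined without medium exposure (M = 0)",
               "zfpk_undefined_equilibrium")
  }
  m_ng_l <- medium_concentration(regimen$medium_conc_um, mw)
  m_ng_l * params$q / params$ke
}

#' Area under the amount-time curve (closed form)
#'
#' Integrates the closed-form amount curve over `[t0, t1]`:
#' \deqn{AUC = \frac{Dose}{k_e}\left(e^{-k_e t_0} - e^{-k_e t_1}\right) +
#'   \frac{M Q}{k_e}\left[(t_1 - t_0) -
#'   \frac{e^{-k_e t_0} - e^{-k_e t_1}}{k_e}\right].}
#' Multiply by `fluor` for the fluorescence-scale AUC.
#'
#' @inheritParams amount_at_time
#' @param t0,t1 integration window, h, with `0 <= t0 < t1`.
#' @return AUC, ng*h.
#' @export
#' @examples
#' p <- pk_parameters(fluor = 1, ke = 0.049, q = 8.37e-9)
#' pk_auc(p, exposure_regimen("PC", dose_mg_per_kg = 2), 0, 48)
pk_auc <- function(params, regimen, t0, t1, mw = NULL) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(regimen, "exposure_regimen"))
  check_number(t0, "t0", lower = 0)
  check_number(t1, "t1", lower = 0)
  if (t1 < t0) abort_zfpk("`t1` must be >= `t0`", "zfpk_invalid_interval")
  dose_ng <- dose_amount(regimen$dose_mg_per_kg, regimen$body_weight_mg)
  m_ng_l <- if (regimen$medium_conc_um > 0) {
    if (is.null(mw)) {
      abort_zfpk("`mw` is required for a regimen with medium exposure",
                 "zfpk_invalid_input")
    }
    medium_concentration(regimen$medium_conc_um, mw)
  } else 0
  auc_closed_form(t0, t1, dose_ng, m_ng_l, params$ke, params$q)
}

auc_closed_form <- function(t0, t1, dose_ng, m_ng_l, ke, q) {
  decay <- (exp(-ke * t0) - exp(-ke * t1)) / ke
  dose_ng * decay + (m_ng_l * q / ke) * ((t1 - t0) - decay)
}
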