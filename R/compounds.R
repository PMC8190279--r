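#' Create a compound record
#'
#' A compound record carries the identity and molecular descriptors of one
#' fluorescent compound: molecular weight, experimental LogD
#' (octanol/Danieau's, log10 scale), topological polar surface area, molar
#' refractivity, H-bond acceptor/donor counts and rotatable-bond count, plus
#' the fluorescence filter set (channel) used to image it.
#'
#' @param name compound identifier.
#' @param mw molecular weight, g/mol. Must be positive.
#' @param logd experimental distribution coefficient, log10 scale.
#' @param tpsa topological polar surface area, squared Angstrom.
#' @param mr molar refractivity (dimensionless).
#' @param hba,hbd,rotor H-bond acceptor, donor and rotatable-bond counts.
#' @param channel fluorescence filter set identifier.
#' @return An object of class `compound_record`.
#' @export
#' @examples
#' compound_record("CY3A", mw = 530.14, logd = 1.73)
compound_record <- function(name, mw, logd, tpsa = NA_real_, mr = NA_real_,
                            hba = NA_integer_, hbd = NA_integer_,
                            rotor = NA_integer_, channel = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_number(mw, "mw", lower = 0, strict = TRUE)
  check_number(logd, "logd")
  for (cnt in list(hba = hba, hbd = hbd, rotor = rotor)) {
    if (!is.na(cnt[[1]])) check_number(as.numeric(cnt), names(cnt), lower = 0)
  }
  structure(list(name = name, mw = mw, logd = logd, tpsa = tpsa, mr = mr,
                 hba = hba, hbd = hbd, rotor = rotor, channel = channel),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s: MW %.2f g/mol, LogD %.2f\n",
              x$name, x$mw, x$logd))
  invisible(x)
}

#' Create an exposure regimen
#'
#' Describes one exposure condition: the administration route, the medium
#' concentration for immersion-bearing routes, the injected dose for
#' injection-bearing routes, the embryo body weight used to convert mg/kg to
#' ng, and the sampling schedule.
#'
#' @param route one of `"immersion"`, `"PC"`, `"IP"`, `"combination"`.
#'   PC and IP are pericardial and intraperitoneal microinjection;
#'   `"combination"` is simultaneous immersion plus PC microinjection.
#' @param medium_conc_um medium concentration, micromolar. 0 for pure
#'   injection routes.
#' @param dose_mg_per_kg injected dose, mg/kg. 0 for pure immersion.
#' @param body_weight_mg embryo body weight, mg (default 0.25, the mean wet
#'   weight of a 3 dpf eleuthero-embryo).
#' @param duration_h exposure duration, h.
#' @param sampling_times_h strictly increasing nonnegative sampling times, h.
#' @return An object of class `exposure_regimen`.
#' @export
#' @examples
#' exposure_regimen("immersion", medium_conc_um = 10)
#' exposure_regimen("PC", dose_mg_per_kg = 2)
exposure_regimen <- function(route = c("immersion", "PC", "IP", "combination"),
                             medium_conc_um = 0, dose_mg_per_kg = 0,
                             body_weight_mg = 0.25, duration_h = 48,
                             sampling_times_h = c(0.25, 1, 3, 6, 24, 48)) {
  route <- match.arg(route)
  check_number(medium_conc_um, "medium_conc_um", lower = 0)
  check_number(dose_mg_per_kg, "dose_mg_per_kg", lower = 0)
  check_number(body_weight_mg, "body_weight_mg", lower = 0, strict = TRUE)
  check_number(duration_h, "duration_h", lower = 0, strict = TRUE)
  check_number(sampling_times_h, "sampling_times_h", lower = 0)
  if (is.unsorted(sampling_times_h, strictly = TRUE)) {
    abort_zfpk("`sampling_times_h` must be strictly increasing",
               "zfpk_invalid_input")
  }
  if (medium_conc_um <= 0 && dose_mg_per_kg <= 0) {
    abort_zfpk("at least one of `medium_conc_um`, `dose_mg_per_kg` must be positive",
               "zfpk_invalid_input")
  }
  if (route == "combination" && (medium_conc_um <= 0 || dose_mg_per_kg <= 0)) {
    abort_zfpk("a combination regimen needs both a positive medium concentration and a positive dose",
               "zfpk_invalid_input")
  }
  if (route == "immersion" && dose_mg_per_kg > 0) {
    abort_zfpk("an immersion regimen must have dose_mg_per_kg = 0",
               "zfpk_invalid_input")
  }
  if (route %in% c("PC", "IP") && medium_conc_um > 0) {
    abort_zfpk("a pure injection regimen must have medium_conc_um = 0",
               "zfpk_invalid_input")
  }
  structure(list(route = route, medium_conc_um = medium_conc_um,
                 dose_mg_per_kg = dose_mg_per_kg,
                 body_weight_mg = body_weight_mg, duration_h = duration_h,
                 sampling_times_h = sampling_times_h),
            class = "exposure_regimen")
}

#' @export
print.exposure_regimen <- function(x, ...) {
  cat(sprintf("<exposure_regimen> %s: %g uM medium, %g mg/kg dose, %g h\n",
              x$route, x$medium_conc_um, x$dose_mg_per_kg, x$duration_h))
  invisible(x)
}

#' Reference compound panel: seven fluorescent alkyne dyes
#'
#' Molecular descriptors and experimental LogD values for the seven
#' biologically inert fluorescent alkyne compounds used to characterise
#' compound disposition in zebrafish eleuthero-embryos: three sulfonated
#' cyanines (S-CY3A, S-CY5.5A, S-CY5A), two xanthenes (FAMA, TAMRA), a
#' rhodamine (R6GA) and a non-sulfonated cyanine (CY3A). LogD spans -1.96 to
#' 1.73, i.e. from clearly hydrophilic to moderately lipophilic.
#'
#' @return A data.frame with one row per compound and columns `compound`,
#'   `mw`, `rotor`, `hba`, `hbd`, `mr`, `tpsa`, `logd`, `channel`.
#' @export
#' @examples
#' reference_compounds()
reference_compounds <- function() {
  data.frame(
    compound = c("S-CY3A", "S-CY5.5A", "S-CY5A", "FAMA", "TAMRA", "R6GA", "CY3A"),
    mw    = c(691.9, 1054.3, 547.79, 413.38, 467.52, 462.6, 530.14),
    rotor = c(13L, 18L, 11L, 3L, 6L, 7L, 10L),
    hba   = c(7L, 13L, 1L, 6L, 4L, 2L, 1L),
    hbd   = c(1L, 1L, 0L, 3L, 1L, 1L, 1L),
    mr    = c(180.42, 241.21, 185.18, 109.52, 135.27, 144.59, 169.95),
    tpsa  = c(152.68, 256.18, 23.32, 105.09, 88.62, 38.33, 35.35),
    logd  = c(-1.96, -1.68, -0.72, -0.14, 0.46, 1.07, 1.73),
    channel = c("dsRed", "CY5", "CY5", "GFP", "dsRed", "dsRed", "dsRed"),
    stringsAsFactors = FALSE
  )
}

#' Reference pharmacokinetic parameters for the seven-compound panel
#'
#' Fluorescence-independent PK parameter values (elimination rate constant
#' `ke`, its half-life `t_half`, passive exchange clearance `q`) and residual
#' standard errors, as estimated for the reference panel from whole-body
#' fluorescence time courses after immersion at 10 uM and 2 mg/kg
#' microinjection. These serve as the truth set for desk calculations of
#' exposure metrics and as realistic defaults for simulation.
#'
#' @return A data.frame with columns `compound`, `ke` (1/h), `t_half` (h),
#'   `q` (L/h), `residual_standard_error`.
#' @export
#' @examples
#' reference_pk_parameters()
reference_pk_parameters <- function() {
  data.frame(
    compound = c("S-CY3A", "S-CY5.5A", "S-CY5A", "FAMA", "TAMRA", "R6GA", "CY3A"),
    ke = c(0.012, 0.023, 0.014, 0.012, 0.052, 0.011, 0.049),
    t_half = c(57.40, 30.26, 50.41, 57.41, 13.35, 64.33, 13.92),
    q = c(0.23, 0.34, 1.61, 1.71, 1.45, 3.23, 8.37) * 1e-9,
    residual_standard_error = c(1.04, 0.28, 0.13, 0.61, 1.89, 0.24, 0.99),
    stringsAsFactors = FALSE
  )
}

#' Default study design
#'
#' The standard design of the disposition study: the seven-compound reference
#' panel, four exposure regimens (immersion at 10 uM, PC and IP microinjection
#' at 2 mg/kg, and the combination of immersion and PC injection), and the six
#' imaging times 15 min, 1 h, 3 h, 6 h, 24 h and 48 h.
#'
#' @return A list with elements `compounds` (list of [compound_record()]),
#'   `regimens` (named list of [exposure_regimen()], one per route) and
#'   `sampling_times_h`.
#' @export
#' @examples
#' d <- default_study_design()
#' names(d$regimens)
default_study_design <- function() {
  tab <- reference_compounds()
  compounds <- lapply(seq_len(nrow(tab)), function(i) {
    compound_record(tab$compound[i], mw = tab$mw[i], logd = tab$logd[i],
                    tpsa = tab$tpsa[i], mr = tab$mr[i], hba = tab$hba[i],
                    hbd = tab$hbd[i], rotor = tab$rotor[i],
                    channel = tab$channel[i])
  })
  names(compounds) <- tab$compound
  times <- c(0.25, 1, 3, 6, 24, 48)
  regimens <- list(
    immersion = exposure_regimen("immersion", medium_conc_um = 10,
                                 sampling_times_h = times),
    PC = exposure_regimen("PC", dose_mg_per_kg = 2, sampling_times_h = times),
    IP = exposure_regimen("IP", dose_mg_per_kg = 2, sampling_times_h = times),
    combination = exposure_regimen("combination", medium_conc_um = 10,
                                   dose_mg_per_kg = 2, sampling_times_h = times)
  )
  list(compounds = compounds, regimens = regimens, sampling_times_h = times)
}
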