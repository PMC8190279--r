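#' Load a fluorescence-time dataset from CSV
#'
#' Reads a tidy observation table (columns `compound`, `route`, `time_h`,
#' `replicate`, `rfu`, optional `censored`) and validates it. Malformed rows
#' are reported with their line numbers (header = line 1).
#'
#' @param path CSV file path.
#' @param regimens named list of [exposure_regimen()] covering every route
#'   present; defaults to the standard study design.
#' @param compounds list of [compound_record()] covering every compound
#'   present; defaults to the reference panel.
#' @return A `zfpk_dataset`.
#' @export
load_dataset <- function(path, regimens = NULL, compounds = NULL) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "route", "time_h", "replicate", "rfu")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    abort_zfpk(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "zfpk_schema_error")
  }
  if (!"censored" %in% names(obs)) obs$censored <- FALSE
  obs$censored <- as.logical(obs$censored)
  bad <- which(!is.finite(obs$rfu) | obs$rfu < 0)
  if (length(bad)) {
    abort_zfpk(sprintf("negative or non-numeric rfu at line(s): %s",
                       paste(bad + 1L, collapse = ", ")),
               "zfpk_validation_error")
  }
  bad_t <- which(!is.finite(obs$time_h) | obs$time_h < 0)
  if (length(bad_t)) {
    abort_zfpk(sprintf("negative or non-numeric time_h at line(s): %s",
                       paste(bad_t + 1L, collapse = ", ")),
               "zfpk_validation_error")
  }
  design <- default_study_design()
  regimens <- regimens %||% design$regimens
  compounds <- compounds %||% design$compounds
  routes <- vapply(regimens, function(r) r$route, character(1))
  unknown <- setdiff(unique(obs$route), routes)
  if (length(unknown)) {
    abort_zfpk(sprintf("route(s) without a regimen: %s",
                       paste(unknown, collapse = ", ")),
               "zfpk_invalid_design")
  }
  unknown_cmp <- setdiff(unique(obs$compound),
                         vapply(compounds, function(x) x$name, character(1)))
  if (length(unknown_cmp)) {
    abort_zfpk(sprintf("compound(s) without a record: %s",
                       paste(unknown_cmp, collapse = ", ")),
               "zfpk_invalid_design")
  }
  structure(list(observations = obs[c(required, "censored")],
                 regimens = regimens, compounds = compounds,
                 provenance = list(source = path)),
            class = "zfpk_dataset")
}

#' Write a dataset to CSV (with a provenance sidecar)
#'
#' @param dataset a `zfpk_dataset`.
#' @param path output CSV path; provenance is written next to it as
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(dataset$observations, path, row.names = FALSE)
  jsonlite::write_json(dataset$provenance,
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a pipeline configuration
#'
#' Reads a YAML or JSON configuration file into a named list; see
#' [run_pipeline()] for the recognised fields.
#'
#' @param path configuration file (.yaml/.yml/.json).
#' @return Named list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort_zfpk("config must be YAML or JSON", "zfpk_invalid_input")
  }
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end and writes their outputs to an output
#' directory: simulate a dataset (unless an input CSV is supplied), fit the
#' one-compartment model per compound with iterative censoring, compute the
#' exposure-metric table over the requested windows, and run the QSPkR
#' regression of Q and the RE ratios on the molecular descriptors. In
#' `metrics_only` mode, a supplied parameter table (columns `compound`,
#' `ke`, `q`) replaces the fitting stage, which is how desk calculations
#' from published parameter values are reproduced.
#'
#' Config fields (all optional unless noted): `outdir` (required), `seed`
#' (default 1), `input_csv`, `parameters_csv` + `metrics_only`,
#' `n_replicates` (10), `noise_cv` (0.2), `quench` (list: cutoff_time_h,
#' attenuation; `NULL` to disable), `windows` (3, 24, 48),
#' `censor_mode` ("residual"), `qspkr` (TRUE), `log_level` ("info").
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, a result bundle: `fits`, `pk_table`, `exposure`,
#'   `qspkr`, `dataset`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  if (is.null(config$outdir)) {
    abort_zfpk("config must name an `outdir`", "zfpk_config_error")
  }
  seed <- config$seed %||% 1L
  quiet <- identical(config$log_level, "quiet")
  say <- function(...) if (!quiet) message(sprintf(...))
  if (isTRUE(config$qspkr %||% TRUE) && !is.null(config$descriptors_csv) &&
      !file.exists(config$descriptors_csv)) {
    abort_zfpk("descriptor table requested for QSPkR but file does not exist",
               "zfpk_config_error")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  design <- default_study_design()
  windows <- config$windows %||% c(3, 24, 48)
  descriptors <- if (!is.null(config$descriptors_csv)) {
    read.csv(config$descriptors_csv, stringsAsFactors = FALSE)
  } else reference_compounds()

  metrics_only <- isTRUE(config$metrics_only)
  if (metrics_only) {
    ptab <- if (!is.null(config$parameters_csv)) {
      read.csv(config$parameters_csv, stringsAsFactors = FALSE)
    } else reference_pk_parameters()
    say("metrics-only mode: %d compounds", nrow(ptab))
    fits <- lapply(seq_len(nrow(ptab)), function(i) {
      pk_parameters(fluor = 1, ke = ptab$ke[i], q = ptab$q[i])
    })
    names(fits) <- ptab$compound
    pk_table <- ptab
    dataset <- NULL
  } else {
    if (!is.null(config$input_csv)) {
      say("loading dataset from %s", config$input_csv)
      dataset <- load_dataset(config$input_csv)
    } else {
      say("simulating dataset (seed %d)", seed)
      pk <- reference_pk_parameters()
      set.seed(seed)
      truth <- lapply(seq_len(nrow(pk)), function(i) {
        pk_parameters(fluor = runif(1, 1e3, 1e4), ke = pk$ke[i], q = pk$q[i])
      })
      names(truth) <- pk$compound
      quench <- if (is.null(config$quench)) quench_spec() else if
        (identical(config$quench, FALSE)) NULL else
        quench_spec(cutoff_time_h = config$quench$cutoff_time_h %||% 1,
                    attenuation = config$quench$attenuation %||% 0.5)
      dataset <- simulate_dataset(
        truth, design$compounds, design$regimens,
        n_replicates = config$n_replicates %||% 10,
        noise = noise_model(config$noise_cv %||% 0.2),
        quench = quench, seed = seed)
      write_dataset(dataset, file.path(config$outdir, "observations.csv"))
    }
    opts <- fit_options(censor_mode = config$censor_mode %||% "residual")
    say("fitting %d compounds", length(unique(dataset$observations$compound)))
    res <- fit_all_compounds(dataset, opts)
    fits <- res$fits
    pk_table <- res$table
    dataset <- res$dataset
    for (cmp in names(fits)) {
      say("  %s: n_used %d, censored %d", cmp, fits[[cmp]]$n_used,
          fits[[cmp]]$n_censored)
    }
  }
  write.csv(pk_table, file.path(config$outdir, "pk_parameters.csv"),
            row.names = FALSE)

  say("exposure metrics over windows: %s", paste(windows, collapse = ", "))
  expo <- exposure_table(fits, descriptors, windows = windows)
  write.csv(expo, file.path(config$outdir, "exposure_metrics.csv"),
            row.names = FALSE)

  qsp <- NULL
  if (isTRUE(config$qspkr %||% TRUE)) {
    say("QSPkR regression")
    ord <- match(names(fits), descriptors$compound)
    desc <- descriptors[ord, c("logd", "mw", "tpsa", "mr", "hba", "hbd", "rotor")]
    ke_vec <- vapply(fits, function(f)
      (if (inherits(f, "pk_fit")) f$params else f)$ke, numeric(1))
    q_vec <- vapply(fits, function(f)
      (if (inherits(f, "pk_fit")) f$params else f)$q, numeric(1))
    wide <- function(w) expo$re[expo$window_h == w][
      match(names(fits), expo$compound[expo$window_h == w])]
    responses <- data.frame(q = q_vec, ke = ke_vec,
                            t_half = log(2) / ke_vec)
    if (3 %in% windows) responses$re_3h <- wide(3)
    if (48 %in% windows) responses$re_48h <- wide(48)
    qsp <- qspkr_analysis(desc, responses)
    write.csv(qsp$report, file.path(config$outdir, "qspkr_models.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(qsp$screen$correlation),
              file.path(config$outdir, "descriptor_correlation.csv"))
  }

  provenance <- list(seed = seed, config_hash = config_hash(config),
                     package_version = as.character(utils::packageVersion("zfpk")),
                     metrics_only = metrics_only)
  jsonlite::write_json(provenance, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in %s", config$outdir)
  invisible(list(fits = fits, pk_table = pk_table, exposure = expo,
                 qspkr = qsp, dataset = dataset, provenance = provenance))
}
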