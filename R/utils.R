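abort_zfpk <- function(msg, class) {
  stop(structure(class = c(class, "zfpk_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_zfpk <- function(msg, class) {
  warning(structure(class = c(class, "zfpk_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x) || (finite && any(!is.finite(x)))) {
    abort_zfpk(sprintf("`%s` must be a finite numeric value", name),
               "zfpk_invalid_input")
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    op <- if (strict) ">" else ">="
    abort_zfpk(sprintf("`%s` must be %s %g", name, op, lower),
               "zfpk_invalid_input")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
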