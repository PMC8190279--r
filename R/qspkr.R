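#' Screen molecular descriptors for collinearity
#'
#' With only a handful of compounds, collinear descriptors make multiple
#' regression meaningless, so descriptors are first partitioned into groups
#' of mutually low-correlated columns and one representative per correlated
#' cluster is retained (greedy, in column order: a descriptor is kept if its
#' absolute Pearson correlation with every already-kept descriptor is at or
#' below the threshold). Constant columns are excluded with a warning.
#'
#' @param table data.frame of numeric descriptor columns (rows = compounds).
#' @param threshold maximum tolerated absolute pairwise Pearson correlation
#'   (default 0.7).
#' @return A list with `kept` (column names retained), `dropped` (named
#'   character vector mapping dropped column to the kept column it
#'   correlates with, or "constant"), and `correlation` (the full Pearson
#'   correlation matrix of the non-constant columns).
#' @export
#' @examples
#' covariance_screen(reference_compounds()[, c("logd", "mw", "tpsa", "hba")])
covariance_screen <- function(table, threshold = 0.7) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 3) {
    abort_zfpk("need at least 3 compounds to screen descriptors",
               "zfpk_invalid_input")
  }
  num <- table[vapply(table, is.numeric, logical(1))]
  dropped <- character(0)
  const <- vapply(num, function(x) var(x) == 0 || !is.finite(var(x)), logical(1))
  if (any(const)) {
    warn_zfpk(sprintf("constant descriptor column(s) excluded: %s",
                      paste(names(num)[const], collapse = ", ")),
              "zfpk_constant_column")
    dropped[names(num)[const]] <- "constant"
    num <- num[!const]
  }
  cm <- cor(num)
  kept <- character(0)
  for (col in names(num)) {
    conflicts <- kept[abs(cm[col, kept]) > threshold]
    if (length(conflicts) == 0) {
      kept <- c(kept, col)
    } else {
      dropped[col] <- conflicts[1]
    }
  }
  list(kept = kept, dropped = dropped, correlation = cm)
}

#' Centered-quadratic regression of a PK quantity on LogD
#'
#' Fits the parabolic lipophilicity model
#' \deqn{y = \beta_0 + \beta_1 LogD + \beta_2 (LogD - \overline{LogD})^2}
#' by ordinary least squares, where the quadratic term is centered at the
#' sample mean of LogD (recomputed from the data, never hard-coded).
#' Centering decorrelates the linear and quadratic terms; predictions are
#' invariant to the centering constant.
#'
#' @param x LogD values.
#' @param y response values (e.g. Q in L/h, or an RE ratio).
#' @param response_name label for the response.
#' @return An object of class `qspkr_model`: `coefficients` (intercept,
#'   linear, quadratic), `center`, `r2`, `r2_adj`, `rmse`, `f_statistic`,
#'   `p_value`, `n`, `response`, `fitted`, `lm` (the underlying [lm()] fit).
#' @export
#' @examples
#' cmp <- reference_compounds(); pk <- reference_pk_parameters()
#' fit_centered_quadratic(cmp$logd, pk$q, "Q")
fit_centered_quadratic <- function(x, y, response_name = "y") {
  check_number(x, "x")
  check_number(y, "y", finite = TRUE)
  n <- length(x)
  if (n != length(y)) abort_zfpk("`x` and `y` lengths differ", "zfpk_invalid_input")
  if (n < 4) abort_zfpk("need n >= 4 for a 3-parameter fit", "zfpk_invalid_input")
  if (var(x) == 0) abort_zfpk("all x equal: singular design", "zfpk_rank_deficient")
  center <- mean(x)
  xc2 <- (x - center)^2
  fit <- lm(y ~ x + xc2)
  stats <- model_stats(fit)
  structure(c(list(
    response = response_name,
    coefficients = setNames(coef(fit), c("intercept", "linear", "quadratic")),
    center = center, n = n, fitted = unname(fitted(fit)), lm = fit
  ), stats), class = "qspkr_model")
}

# shared OLS summary statistics: R2, adjusted R2, RMSE, overall F and p
model_stats <- function(fit) {
  y <- fitted(fit) + resid(fit)
  n <- length(y)
  p <- length(coef(fit)) - 1L
  sse <- sum(resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort_zfpk("zero-variance response: R2 undefined", "zfpk_undefined_r2")
  r2 <- 1 - sse / sst
  df_res <- n - p - 1L
  list(r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / df_res,
       rmse = sqrt(sse / df_res),
       f_statistic = if (p > 0) ((sst - sse) / p) / (sse / df_res) else NA_real_,
       p_value = if (p > 0) pf(((sst - sse) / p) / (sse / df_res), p, df_res,
                               lower.tail = FALSE) else NA_real_)
}

#' Fit statistics for a regression model
#'
#' Recomputes R2, adjusted R2, RMSE and the overall F-test from first
#' principles (SSE/SST): `r2_adj = 1 - (1 - r2)(n - 1)/(n - p - 1)` and
#' `rmse = sqrt(SSE/(n - p - 1))` with p non-intercept terms.
#'
#' @param model a `qspkr_model` or an [lm()] fit.
#' @return A list with `r2`, `r2_adj`, `rmse`, `f_statistic`, `p_value`.
#' @export
regression_stats <- function(model) {
  fit <- if (inherits(model, "qspkr_model")) model$lm else model
  stopifnot(inherits(fit, "lm"))
  model_stats(fit)
}

#' @export
print.qspkr_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<qspkr_model> %s = %.4g + %.4g LogD + %.4g (LogD - %.3f)^2\n",
              x$response, co[1], co[2], co[3], x$center))
  cat(sprintf("  n %d, R2 %.3f, R2adj %.3f, RMSE %.4g, F p-value %.4g\n",
              x$n, x$r2, x$r2_adj, x$rmse, x$p_value))
  invisible(x)
}

#' Bidirectional stepwise model selection by AIC
#'
#' Searches for the descriptor model that best explains a PK response,
#' starting from the intercept-only model and adding/removing candidate
#' terms to minimise AIC (Gaussian convention, `n log(SSE/n) + 2k`).
#' Candidate terms are the screened descriptor columns plus, optionally, the
#' mean-centered square of LogD (included only when the linear LogD term is
#' present, preserving hierarchy). With few observations the model size is
#' capped (default 2 non-intercept terms, i.e. 3 parameters). The selected
#' model is reported only if its overall F-test is significant at
#' `alpha`; otherwise the result is `NULL` (no significant model).
#'
#' @param table data.frame of candidate descriptor columns (should already
#'   have passed [covariance_screen()]).
#' @param y response values.
#' @param response_name label for the response.
#' @param quadratic_in name of the column whose centered square is offered
#'   as an extra candidate (default `"logd"` when present; `NULL` for none).
#' @param max_terms maximum non-intercept terms (default 2).
#' @param alpha significance level for the reporting gate (default 0.05).
#' @return A list with `model` (an [lm()] fit or `NULL`), `terms` (selected
#'   term names), `aic`, `stats` (as [regression_stats()], `NULL` for the
#'   intercept-only result) and `significant`.
#' @export
stepwise_select <- function(table, y, response_name = "y",
                            quadratic_in = if ("logd" %in% names(table)) "logd" else NULL,
                            max_terms = 2, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  n <- length(y)
  if (n != nrow(table)) abort_zfpk("`y` length must match table rows", "zfpk_invalid_input")
  dat <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(dat) >= n) {
    warn_zfpk("more candidate terms than observations: search restricted by the model-size cap",
              "zfpk_small_n")
  }
  quad_name <- NULL
  if (!is.null(quadratic_in) && quadratic_in %in% names(dat)) {
    quad_name <- paste0(quadratic_in, "_csq")
    dat[[quad_name]] <- (dat[[quadratic_in]] - mean(dat[[quadratic_in]]))^2
  }
  dat$.y <- y

  aic_of <- function(terms) {
    form <- if (length(terms) == 0) .y ~ 1 else
      stats::reformulate(terms, response = ".y")
    fit <- lm(form, data = dat)
    sse <- sum(resid(fit)^2)
    list(fit = fit, aic = n * log(sse / n) + 2 * (length(terms) + 1))
  }
  admissible <- function(terms) {
    if (length(terms) > max_terms) return(FALSE)
    if (!is.null(quad_name) && quad_name %in% terms &&
        !(quadratic_in %in% terms)) return(FALSE)
    TRUE
  }

  current <- character(0)
  cur <- aic_of(current)
  candidates <- setdiff(names(dat), ".y")
  repeat {
    best <- NULL
    # forward moves
    for (trm in setdiff(candidates, current)) {
      prop <- c(current, trm)
      if (!admissible(prop)) next
      res <- aic_of(prop)
      if (res$aic < (best$aic %||% cur$aic) - 1e-10) best <- c(res, list(terms = prop))
    }
    # backward moves
    for (trm in current) {
      prop <- setdiff(current, trm)
      if (!admissible(prop)) next
      res <- aic_of(prop)
      if (res$aic < (best$aic %||% cur$aic) - 1e-10) best <- c(res, list(terms = prop))
    }
    if (is.null(best)) break
    current <- best$terms
    cur <- best[c("fit", "aic")]
  }

  if (length(current) == 0) {
    return(list(model = NULL, terms = character(0), aic = cur$aic,
                stats = NULL, significant = FALSE))
  }
  st <- model_stats(cur$fit)
  sig <- is.finite(st$p_value) && st$p_value < alpha
  list(model = if (sig) cur$fit else NULL, terms = current, aic = cur$aic,
       stats = st, significant = sig)
}

#' Full QSPkR analysis over a response table
#'
#' Screens the descriptor table, then runs [stepwise_select()] for each
#' response column, assembling a report of the significant models only.
#'
#' @param descriptors data.frame of descriptor columns (rows = compounds).
#' @param responses data.frame of response columns, same row order.
#' @param threshold collinearity threshold for [covariance_screen()].
#' @param ... passed to [stepwise_select()].
#' @return A list with `screen` (the [covariance_screen()] result),
#'   `selections` (per-response [stepwise_select()] results) and `report`
#'   (data.frame of the significant models: response, terms, r2_adj, rmse,
#'   p_value).
#' @export
qspkr_analysis <- function(descriptors, responses, threshold = 0.7, ...) {
  scr <- covariance_screen(descriptors, threshold)
  kept <- descriptors[scr$kept]
  selections <- lapply(names(responses), function(rn) {
    stepwise_select(kept, responses[[rn]], response_name = rn, ...)
  })
  names(selections) <- names(responses)
  rows <- lapply(names(selections), function(rn) {
    s <- selections[[rn]]
    if (!isTRUE(s$significant)) return(NULL)
    data.frame(response = rn, terms = paste(s$terms, collapse = " + "),
               r2_adj = s$stats$r2_adj, rmse = s$stats$rmse,
               p_value = s$stats$p_value, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(screen = scr, selections = selections,
       report = report %||% data.frame(response = character(0),
                                       terms = character(0),
                                       r2_adj = numeric(0), rmse = numeric(0),
                                       p_value = numeric(0)))
}
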