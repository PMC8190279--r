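# shared builders for the test suite

cy3a_params <- function(fluor = 5000) pk_parameters(fluor, ke = 0.049, q = 8.37e-9)

three_route_design <- function() {
  d <- default_study_design()
  d$regimens <- d$regimens[c("immersion", "PC", "IP")]
  d
}

simulate_cy3a <- function(seed, cv = 0.1, quench = NULL, n_replicates = 10,
                          fluor = 5000, routes = c("immersion", "PC", "IP")) {
  d <- default_study_design()
  simulate_dataset(list(CY3A = cy3a_params(fluor)), d$compounds,
                   d$regimens[routes], n_replicates = n_replicates,
                   noise = noise_model(cv), quench = quench, seed = seed)
}

# independent OLS oracle: explicit normal-equations solve on {1, x, (x-c)^2}
normal_equations_quadratic <- function(x, y, center = mean(x)) {
  X <- cbind(1, x, (x - center)^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- as.vector(X %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y); p <- 2L
  r2 <- 1 - sse / sst
  list(beta = as.vector(beta), fitted = fitted, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       rmse = sqrt(sse / (n - p - 1)))
}

# reference-panel RE values computed straight from the closed-form AUCs
reference_re <- function(t1) {
  pk <- reference_pk_parameters()
  cmp <- reference_compounds()
  vapply(seq_len(nrow(pk)), function(i) {
    relative_exposure(pk_parameters(1, pk$ke[i], pk$q[i]),
                      mw = cmp$mw[i], t1 = t1)
  }, numeric(1))
}
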