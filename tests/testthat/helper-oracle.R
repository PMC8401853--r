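# Independent oracles and small generators shared across tests.

# Explicit normal-equations least squares: the brute-force reference the
# QR-based production fit is checked against.
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Brute-force pure-error sum of squares: sum over replicate groups of the
# squared deviations from the group mean.
pure_error_oracle <- function(coded, y) {
  key <- apply(coded, 1, paste, collapse = ",")
  sum(unlist(tapply(y, key, function(v) (v - mean(v))^2)))
}

# Three factor specs with randomized (symmetric) level spacing.
random_factors <- function() {
  lapply(1:3, function(j) {
    center <- runif(1, 10, 100)
    half <- runif(1, 1, 20)
    factor_spec(paste0("f", j), center - half, center, center + half)
  })
}

# The shipped 17-run study, loaded once per test file.
ber <- ber_study()

ber_fits <- function() {
  specs <- ber_model_specs()
  lapply(specs, function(s) fit_rsm(ber$data, s$response, s$terms, s$transform))
}

# coded rows of the published run table, in published order
ber_coded <- function() {
  nm <- vapply(ber$data$design$factors, `[[`, character(1), "name")
  m <- as.matrix(ber$data$design$runs[, paste0(nm, "_coded")])
  colnames(m) <- c("x1", "x2", "x3")
  m
}
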