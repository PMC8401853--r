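#' Define a ground-truth response model for simulation
#'
#' A truth model is a coefficient vector on the coded quadratic term
#' vocabulary plus a homoscedastic Gaussian noise SD on the transform
#' scale. With `transform = "ln"` the polynomial and the noise live on the
#' log scale and simulated responses are exponentiated afterwards
#' (yielding log-normal responses on the original scale).
#'
#' @param response Response name.
#' @param coefficients Named numeric vector: `"(Intercept)"` plus any
#'   subset of `x1, x2, x3, x1:x2, x1:x3, x2:x3, x1^2, x2^2, x3^2`.
#' @param transform `"identity"` or `"ln"`.
#' @param noise_sd Per-run Gaussian noise SD on the transform scale
#'   (>= 0).
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(response, coefficients,
                        transform = c("identity", "ln"), noise_sd = 0) {
  transform <- match.arg(transform)
  if (is.null(names(coefficients)) || !all(nzchar(names(coefficients))))
    stop("'coefficients' must be a named vector", call. = FALSE)
  bad <- setdiff(names(coefficients), c("(Intercept)", rsm_all_terms()))
  if (length(bad))
    stop("unknown terms in truth model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0))
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  structure(list(response = response, coefficients = coefficients,
                 transform = transform, noise_sd = noise_sd),
            class = "truth_model")
}

# evaluate a truth model's polynomial (transform scale) at coded points
truth_eta <- function(truth, coded) {
  terms <- setdiff(names(truth$coefficients), "(Intercept)")
  X <- rsm_model_matrix(coded, terms)
  drop(X %*% truth$coefficients[colnames(X)])
}

#' Simulate Box-Behnken responses from known truth models
#'
#' For every run and truth model, the simulated response mean is the
#' truth polynomial evaluated at the run's coded point plus Gaussian
#' noise on the transform scale; ln-scale truths are exponentiated after
#' the noise is added. The same seed always reproduces the same table.
#'
#' @param design A [bbd_design()].
#' @param truths List of [truth_model()]s (or a single one).
#' @param seed Integer seed (required; there is no implicit entropy).
#' @return An [rsm_data()] with one simulated response column per truth.
#' @export
simulate_bbd_responses <- function(design, truths, seed) {
  stopifnot(inherits(design, "bbd_design"))
  if (inherits(truths, "truth_model")) truths <- list(truths)
  if (!all(vapply(truths, inherits, logical(1), "truth_model")))
    stop("'truths' must be truth_model objects", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(as.integer(seed))
  coded <- design_coded(design)
  resp <- lapply(truths, function(tr) {
    z <- truth_eta(tr, coded) + stats::rnorm(nrow(coded), 0, tr$noise_sd)
    if (tr$transform == "ln") exp(z) else z
  })
  names(resp) <- vapply(truths, `[[`, character(1), "response")
  rsm_data(design, resp)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeats simulate-then-fit `n_reps` times and summarizes, per
#' coefficient of each truth model, the empirical bias, RMSE and the
#' fraction of 95% confidence intervals (coefficient +/- t_crit * SE)
#' covering the true value. Replicate r uses seed `seed + r`, a
#' counter-based derivation that makes the replicates order-independent
#' and individually reproducible. Fit failures are counted and reported
#' in the `failures` attribute, never silently dropped.
#'
#' @param design A [bbd_design()].
#' @param truths List of [truth_model()]s.
#' @param n_reps Number of Monte-Carlo replicates (>= 2).
#' @param seed Integer base seed.
#' @param level Confidence level for the coverage check (default 0.95).
#' @return A data frame (`response`, `term`, `truth`, `bias`, `rmse`,
#'   `coverage`, `mc_se`), with attribute `"failures"` giving the number
#'   of failed replicates.
#' @export
recovery_study <- function(design, truths, n_reps, seed, level = 0.95) {
  if (inherits(truths, "truth_model")) truths <- list(truths)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 2L)
    stop("'n_reps' must be an integer >= 2", call. = FALSE)
  tcrit <- function(df) stats::qt(1 - (1 - level) / 2, df)
  failures <- 0L
  est <- vector("list", n_reps)
  cov <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    dat <- simulate_bbd_responses(design, truths, seed = as.integer(seed) + r)
    res <- try({
      lapply(truths, function(tr) {
        terms <- setdiff(names(tr$coefficients), "(Intercept)")
        fit <- fit_rsm(dat, tr$response, terms, tr$transform)
        truth_b <- tr$coefficients[names(fit$coefficients)]
        half <- tcrit(fit$residual_df) * fit$se
        list(est = fit$coefficients,
             cover = abs(fit$coefficients - truth_b) <= half)
      })
    }, silent = TRUE)
    if (inherits(res, "try-error")) { failures <- failures + 1L; next }
    est[[r]] <- res
  }
  ok <- !vapply(est, is.null, logical(1))
  if (!any(ok)) stop("all replicates failed to fit", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    terms <- c("(Intercept)", setdiff(names(tr$coefficients), "(Intercept)"))
    e <- do.call(rbind, lapply(est[ok], function(x) x[[i]]$est[terms]))
    cv <- do.call(rbind, lapply(est[ok], function(x) x[[i]]$cover[terms]))
    truth_b <- tr$coefficients[terms]
    data.frame(response = tr$response, term = terms,
               truth = unname(truth_b),
               bias = colMeans(e) - unname(truth_b),
               rmse = sqrt(colMeans(sweep(e, 2, truth_b)^2)),
               coverage = colMeans(cv),
               mc_se = apply(e, 2, stats::sd) / sqrt(sum(ok)),
               row.names = NULL)
  }))
  attr(out, "failures") <- failures
  out
}
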