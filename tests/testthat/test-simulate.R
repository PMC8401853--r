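test_that("simulation is seed-deterministic and noiseless means hit the truth", {
  des <- bbd_design(ber_factors(), 5)
  truths <- ber_truth_models()
  a <- simulate_bbd_responses(des, truths, seed = 1)
  b <- simulate_bbd_responses(des, truths, seed = 1)
  c <- simulate_bbd_responses(des, truths, seed = 2)
  expect_identical(a$responses, b$responses)
  expect_false(identical(a$responses, c$responses))

  # zero noise: the PS truth evaluates to its intercept at the center runs
  tr0 <- ber_truth_models(noise_sd = c(PS = 0, ZP = 0, EE = 0))
  d0 <- simulate_bbd_responses(des, tr0, seed = 3)
  center <- rowSums(bbdopt:::design_coded(des) != 0) == 0
  expect_equal(unique(d0$responses$PS[center]),
               unname(tr0$PS$coefficients["(Intercept)"]))
  # ln-scale truth exponentiates: center ZP is exp(intercept)
  expect_equal(unique(d0$responses$ZP[center]),
               exp(unname(tr0$ZP$coefficients["(Intercept)"])))
})

test_that("fitting noiseless simulations returns the generator coefficients", {
  des <- bbd_design(ber_factors(), 5)
  tr0 <- ber_truth_models(noise_sd = c(PS = 0, ZP = 0, EE = 0))
  d0 <- simulate_bbd_responses(des, tr0, seed = 5)
  for (tr in tr0) {
    terms <- setdiff(names(tr$coefficients), "(Intercept)")
    fit <- fit_rsm(d0, tr$response, terms, tr$transform)
    expect_equal(fit$coefficients[names(tr$coefficients)], tr$coefficients,
                 tolerance = 1e-9)
  }
})

test_that("the full pipeline on noiseless data recovers the study optimum cell", {
  des <- bbd_design(ber_factors(), 5)
  tr0 <- ber_truth_models(noise_sd = c(PS = 0, ZP = 0, EE = 0))
  d0 <- simulate_bbd_responses(des, tr0, seed = 7)
  fits <- lapply(tr0, function(tr)
    fit_rsm(d0, tr$response, setdiff(names(tr$coefficients), "(Intercept)"),
            tr$transform))
  # pin the anchors so the comparison is between identical objectives
  # (default anchors would track each table's own observed range)
  goals <- list(desirability_goal("PS", "minimize",
                                  min(ber$data$responses$PS),
                                  max(ber$data$responses$PS)),
                desirability_goal("ZP", "maximize",
                                  min(ber$data$responses$ZP),
                                  max(ber$data$responses$ZP)),
                desirability_goal("EE", "maximize",
                                  min(ber$data$responses$EE),
                                  max(ber$data$responses$EE)))
  opt <- optimize_desirability(fits, goals, resolution = 0.05)
  ref <- optimize_desirability(ber_fits(), goals, resolution = 0.05)
  expect_equal(unname(opt$coded_optimum), unname(ref$coded_optimum),
               tolerance = 1e-6)
})

test_that("recovery study reports zero error at zero noise", {
  des <- bbd_design(ber_factors(), 5)
  tr0 <- ber_truth_models(noise_sd = c(PS = 0, ZP = 0, EE = 0))
  rs <- recovery_study(des, tr0, n_reps = 3, seed = 1)
  expect_equal(rs$bias, rep(0, nrow(rs)), tolerance = 1e-9)
  expect_equal(rs$rmse, rep(0, nrow(rs)), tolerance = 1e-9)
  expect_equal(attr(rs, "failures"), 0L)
})

test_that("doubling the noise SD doubles every coefficient RMSE exactly under shared seeds", {
  # OLS is linear in the noise and replicate r reuses seed + r, so the
  # same standard-normal draws are scaled by noise_sd: the ratio is exact
  des <- bbd_design(ber_factors(), 5)
  t1 <- list(truth_model("PS", c("(Intercept)" = 178, x1 = 4, x2 = 43, x3 = 14),
                         noise_sd = 6))
  t2 <- list(truth_model("PS", c("(Intercept)" = 178, x1 = 4, x2 = 43, x3 = 14),
                         noise_sd = 12))
  r1 <- recovery_study(des, t1, n_reps = 40, seed = 10)
  r2 <- recovery_study(des, t2, n_reps = 40, seed = 10)
  expect_equal(r2$rmse, 2 * r1$rmse, tolerance = 1e-9)
})

test_that("Monte-Carlo spread matches the analytic OLS standard error", {
  des <- bbd_design(ber_factors(), 5)
  truth <- truth_model("PS", c("(Intercept)" = 178.382, x1 = 4.1125,
                               x2 = 43.475, x3 = 13.5625), noise_sd = 6)
  rs <- recovery_study(des, list(truth), n_reps = 500, seed = 1)
  coded <- bbdopt:::design_coded(des)
  X <- bbdopt:::rsm_model_matrix(coded, c("x1", "x2", "x3"))
  analytic <- 6 * sqrt(diag(solve(t(X) %*% X)))
  # bias ~ 0, so RMSE estimates the sampling SD of each coefficient
  expect_equal(rs$rmse, unname(analytic), tolerance = 0.1)
})

test_that("truth models validate their terms and noise", {
  expect_error(truth_model("y", c(a = 1)), "unknown terms")
  expect_error(truth_model("y", c("(Intercept)" = 1), noise_sd = -1),
               "non-negative")
  des <- bbd_design(ber_factors(), 5)
  expect_error(simulate_bbd_responses(des, ber_truth_models()), "seed")
})
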