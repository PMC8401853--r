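test_that("QR fit matches the explicit normal-equations oracle on random problems", {
  set.seed(101)
  all_terms <- c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                 "x1^2", "x2^2", "x3^2")
  for (i in 1:100) {
    des <- bbd_design(random_factors(), n_center = sample(2:6, 1))
    k <- sample(3:7, 1)
    terms <- sort(sample(all_terms, k))
    dat <- rsm_data(des, list(y = rnorm(nrow(des$runs), 100, 20)))
    fit <- fit_rsm(dat, "y", terms)
    coded <- bbdopt:::design_coded(des)
    X <- bbdopt:::rsm_model_matrix(coded, terms)
    expect_equal(unname(fit$coefficients), unname(ols_oracle(X, dat$responses$y)),
                 tolerance = 1e-9)
  }
})

test_that("noiseless synthetic data is interpolated exactly", {
  des <- bbd_design(ber_factors(), 5)
  truth <- truth_model("y", c("(Intercept)" = 50, x1 = 3, x2 = -8, x3 = 1.5,
                              "x2:x3" = 2, "x3^2" = -4), noise_sd = 0)
  dat <- simulate_bbd_responses(des, truth, seed = 11)
  fit <- fit_rsm(dat, "y", c("x1", "x2", "x3", "x2:x3", "x3^2"))
  expect_equal(fit$coefficients[names(truth$coefficients)],
               truth$coefficients, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("on the orthogonal BBD the intercept is the grand mean and mains are contrasts", {
  fit <- fit_rsm(ber$data, "PS", c("x1", "x2", "x3"))
  y <- ber$data$responses$PS
  coded <- ber_coded()
  expect_equal(unname(fit$coefficients["(Intercept)"]), mean(y))
  for (j in 1:3) {
    contrast <- (sum(y[coded[, j] == 1]) - sum(y[coded[, j] == -1])) / 8
    expect_equal(unname(fit$coefficients[paste0("x", j)]), contrast)
  }
})

test_that("adding an orthogonal term leaves existing estimates unchanged", {
  f0 <- fit_rsm(ber$data, "EE", c("x1", "x2", "x3"))
  f1 <- fit_rsm(ber$data, "EE", c("x1", "x2", "x3", "x2:x3"))
  expect_equal(f1$coefficients[c("x1", "x2", "x3")],
               f0$coefficients[c("x1", "x2", "x3")], tolerance = 1e-12)
})

test_that("residual SS decomposes into lack of fit plus pure error", {
  for (fit in ber_fits()) {
    a <- fit$anova
    expect_equal(a$residual_ss, a$lack_of_fit_ss + a$pure_error_ss,
                 tolerance = 1e-9)
    expect_equal(a$residual_df, 17L - (length(fit$terms) + 1L))
    expect_gte(fit$r2, 0); expect_lte(fit$r2, 1)
  }
})

test_that("standard errors and t-statistics follow from the Gram inverse", {
  fit <- fit_rsm(ber$data, "EE", c("x1", "x2", "x3", "x2:x3", "x3^2"))
  coded <- ber_coded()
  X <- bbdopt:::rsm_model_matrix(coded, fit$terms)
  s2 <- sum((ber$data$responses$EE - X %*% fit$coefficients)^2) /
    (17 - ncol(X))
  se <- sqrt(s2 * diag(solve(t(X) %*% X)))
  expect_equal(unname(fit$se), unname(se), tolerance = 1e-9)
  expect_equal(unname(fit$tstat), unname(fit$coefficients / se),
               tolerance = 1e-9)
})

test_that("fit validates its inputs", {
  set.seed(21)
  expect_error(fit_rsm(ber$data, "nope"), "not found")

  # too few runs for the requested terms
  des <- bbd_design(ber_factors(), 5)
  small <- des; small$runs <- des$runs[1:9, ]
  dat <- rsm_data(small, list(y = rnorm(9)))
  expect_error(fit_rsm(dat, "y", bbdopt:::rsm_all_terms()), "at least")

  # x3 is identically 0 on the (x1, x2) edge block plus centers, so an x3
  # term is confounded there
  conf <- des; conf$runs <- des$runs[c(1:4, 13:17), ]
  datc <- rsm_data(conf, list(y = rnorm(9)))
  expect_error(fit_rsm(datc, "y", c("x1", "x2", "x3")), "singular")

  neg <- ber$data
  neg$responses$ZP[1] <- -1
  expect_error(fit_rsm(neg, "ZP", "x1", transform = "ln"), "positive")
})

test_that("prediction evaluates the polynomial and back-transforms ln fits", {
  fits <- ber_fits()
  expect_equal(predict(fits$PS, c(0, 0, 0)),
               unname(fits$PS$coefficients["(Intercept)"]))
  expect_equal(predict(fits$ZP, c(0, 0, 0)),
               exp(unname(fits$ZP$coefficients["(Intercept)"])))
  # hand evaluation at an off-center point
  b <- fits$EE$coefficients
  pt <- c(0.5, -0.25, 0.75)
  expect_equal(predict(fits$EE, pt),
               unname(b["(Intercept)"] + b["x1"] * 0.5 + b["x2"] * -0.25 +
                        b["x3"] * 0.75 + b["x2:x3"] * (-0.25 * 0.75) +
                        b["x3^2"] * 0.75^2))
  expect_error(predict(fits$PS, c(2, 0, 0)), "extrapolate")
  expect_silent(predict(fits$PS, c(2, 0, 0), extrapolate = TRUE))
})

test_that("surface grids agree with direct prediction and show the known trends", {
  fits <- ber_fits()
  g2 <- surface_grid(fits$PS, c("x2", "x3"), 0, resolution = 2)
  expect_equal(nrow(g2), 4L)
  corners <- as.matrix(g2[, c("x1", "x2", "x3")])
  expect_equal(g2$predicted, unname(predict(fits$PS, corners)))

  # PS increases in both chitosan and IPM everywhere on the x1 = 0 slice
  g <- surface_grid(fits$PS, c("x2", "x3"), 0, resolution = 11)
  m <- matrix(g$predicted, nrow = 11)  # rows: x2, cols: x3
  expect_true(all(diff(m) > 0))
  expect_true(all(t(diff(t(m))) > 0))

  # random spot checks against brute-force polynomial evaluation
  set.seed(3)
  idx <- sample(nrow(g), 10)
  b <- fits$PS$coefficients
  direct <- b["(Intercept)"] + b["x1"] * g$x1[idx] + b["x2"] * g$x2[idx] +
    b["x3"] * g$x3[idx]
  expect_equal(g$predicted[idx], unname(direct))

  expect_error(surface_grid(fits$PS, c("x2", "x2")), "distinct")
  expect_error(surface_grid(fits$PS, c("x2", "x3"), 0, 1), ">= 2")
})

test_that("simulate() from a fit is reproducible and scales with sigma", {
  fit <- fit_rsm(ber$data, "PS", c("x1", "x2", "x3"))
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate(fit, nsim = 2, seed = 6)))
})
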