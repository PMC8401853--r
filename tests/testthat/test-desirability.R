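test_that("one-sided desirability ramps behave at and between anchors", {
  up <- desirability_goal("y", "maximize", 10, 20)
  dn <- desirability_goal("y", "minimize", 10, 20)
  expect_equal(desirability(20, up), 1)
  expect_equal(desirability(10, up), 0)
  expect_equal(desirability(15, up), 0.5)
  expect_equal(desirability(20, dn), 0)
  expect_equal(desirability(10, dn), 1)
  expect_equal(desirability(15, dn), 0.5)
  # beyond the anchors the ramp saturates
  expect_equal(desirability(c(5, 25), up), c(0, 1))
  # weight bends the ramp but keeps the endpoints
  w2 <- desirability_goal("y", "maximize", 10, 20, weight = 2)
  expect_equal(desirability(15, w2), 0.25)
  expect_equal(desirability(c(10, 20), w2), c(0, 1))
  expect_error(desirability_goal("y", "maximize", 20, 10), "less than")
  expect_error(desirability_goal("y", "maximize", 1, 2, weight = 0), "positive")
})

test_that("desirability is monotone and bounded for both directions", {
  v <- seq(0, 30, by = 0.25)
  for (w in c(0.5, 1, 3)) {
    up <- desirability(v, desirability_goal("y", "maximize", 10, 20, weight = w))
    dn <- desirability(v, desirability_goal("y", "minimize", 10, 20, weight = w))
    expect_true(all(diff(up) >= 0))
    expect_true(all(diff(dn) <= 0))
    expect_true(all(up >= 0 & up <= 1 & dn >= 0 & dn <= 1))
  }
})

test_that("overall desirability is the weighted geometric mean", {
  d <- rbind(c(0.5, 0.8, 0.9), c(0.2, 0, 0.7))
  w <- c(1, 2, 1)
  D <- bbdopt:::overall_desirability(d, w)
  expect_equal(D[1], (0.5 * 0.8^2 * 0.9)^(1 / 4))
  expect_equal(D[2], 0)  # any zero component kills the geometric mean
})

test_that("single minimize goal on a linear model lands on the all-low corner", {
  fits <- ber_fits()
  opt <- optimize_desirability(fits["PS"],
                               list(desirability_goal("PS", "minimize")),
                               resolution = 0.25)
  expect_equal(unname(opt$coded_optimum), c(-1, -1, -1))
  # all three printed PS coefficients are positive, so exhaustive corner
  # enumeration must agree
  corners <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1),
                                   x3 = c(-1, 1)))
  expect_equal(min(predict(fits$PS, corners)),
               unname(predict(fits$PS, opt$coded_optimum)))
})

test_that("a constant model ties everywhere and resolves to the canonical point", {
  des <- bbd_design(ber_factors(), 5)
  truth <- truth_model("y", c("(Intercept)" = 50), noise_sd = 0)
  dat <- simulate_bbd_responses(des, truth, seed = 2)
  fit <- fit_rsm(dat, "y", c("x1", "x2", "x3"))
  opt <- optimize_desirability(list(y = fit),
                               list(desirability_goal("y", "maximize", 0, 100)),
                               resolution = 0.5, polish = FALSE)
  # no minimize goal: ties fall through to lexicographically smallest coords
  expect_equal(unname(opt$coded_optimum), c(-1, -1, -1))
})

test_that("finer grids never lower the reported overall desirability", {
  fits <- ber_fits()
  goals <- list(desirability_goal("PS", "minimize"),
                desirability_goal("ZP", "maximize"),
                desirability_goal("EE", "maximize"))
  D <- vapply(c(0.5, 0.25, 0.125), function(r)
    optimize_desirability(fits, goals, resolution = r, polish = FALSE)$overall_D,
    numeric(1))
  expect_true(all(diff(D) >= 0))
})

test_that("the optimum dominates every design point and reports consistent pieces", {
  fits <- ber_fits()
  goals <- list(desirability_goal("PS", "minimize"),
                desirability_goal("ZP", "maximize"),
                desirability_goal("EE", "maximize"))
  opt <- optimize_desirability(fits, goals, resolution = 0.05)
  coded <- ber_coded()
  colnames(coded) <- c("x1", "x2", "x3")
  d_runs <- sapply(seq_along(goals), function(i)
    desirability(predict(fits[[i]], coded), opt$goals[[i]]))
  D_runs <- bbdopt:::overall_desirability(d_runs, rep(1, 3))
  expect_true(all(opt$overall_D >= D_runs))
  # overall D recomputes from the reported individual desirabilities
  expect_equal(opt$overall_D, prod(opt$desirabilities)^(1 / 3),
               tolerance = 1e-9)
  expect_true(all(opt$desirabilities >= 0 & opt$desirabilities <= 1))
  # actual optimum decodes the coded optimum
  for (j in 1:3)
    expect_equal(unname(opt$actual_optimum[j]),
                 decode_level(fits$PS$design$factors[[j]],
                              unname(opt$coded_optimum[j])))
})

test_that("optimizer rejects bad inputs", {
  fits <- ber_fits()
  expect_error(optimize_desirability(fits, list()), "at least one goal")
  expect_error(optimize_desirability(fits,
                                     list(desirability_goal("PS", "minimize")),
                                     resolution = 0), "positive")
  expect_error(optimize_desirability(fits,
                                     list(desirability_goal("XX", "minimize"))),
               "reference")
})

test_that("checkpoint validation reproduces the error formula and flags failures", {
  fits <- ber_fits()
  rep <- validate_checkpoint(c(PS = 168.4, ZP = 33.1, EE = 82.3), fits,
                             ber$checkpoint$coded_optimum)
  expect_equal(rep$prediction_error_pct,
               abs(rep$estimated - rep$expected) / rep$estimated * 100)
  expect_true(all(rep$pass))

  # exact agreement gives 0% error
  pt <- c(0, 0, 0)
  exact <- vapply(fits, function(f) predict(f, pt), numeric(1))
  rep0 <- validate_checkpoint(exact, fits, pt)
  expect_equal(rep0$prediction_error_pct, rep(0, 3), tolerance = 1e-12)

  # a wildly wrong measurement fails the 10% gate
  bad <- validate_checkpoint(c(PS = 500), fits["PS"], pt)
  expect_false(bad$pass)
  expect_error(validate_checkpoint(c(QQ = 1), fits, pt), "no fitted model")
  expect_error(prediction_error(0, 5), "undefined")
})
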