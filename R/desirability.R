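#' Define a desirability goal for one response
#'
#' Derringer-Suich one-sided desirability. For a maximized response the
#' desirability ramps from 0 at `anchor_low` to 1 at `anchor_high` as
#' `((value - low)/(high - low))^weight`; for a minimized response the
#' ramp is mirrored. Anchors default, at optimization time, to the
#' observed range of the response over the run table (the convention of
#' common DoE software) when left `NULL`.
#'
#' @param response Response name the goal applies to.
#' @param direction `"minimize"` or `"maximize"`.
#' @param anchor_low,anchor_high Ramp anchors (`anchor_low < anchor_high`),
#'   or `NULL` to use the observed response range.
#' @param weight Positive ramp exponent (1 = linear ramp).
#' @return An object of class `desirability_goal`.
#' @export
desirability_goal <- function(response, direction = c("minimize", "maximize"),
                              anchor_low = NULL, anchor_high = NULL,
                              weight = 1) {
  direction <- match.arg(direction)
  if (!is.null(anchor_low) && !is.null(anchor_high) &&
      !(anchor_low < anchor_high))
    stop("anchor_low must be strictly less than anchor_high", call. = FALSE)
  if (!(is.numeric(weight) && length(weight) == 1L && weight > 0))
    stop("weight must be a positive number", call. = FALSE)
  structure(list(response = response, direction = direction,
                 anchor_low = anchor_low, anchor_high = anchor_high,
                 weight = weight),
            class = "desirability_goal")
}

#' Individual desirability of a response value
#'
#' @param value Numeric vector of response values.
#' @param goal A [desirability_goal()] with both anchors set.
#' @return Desirabilities in `[0, 1]`, same length as `value`.
#' @export
desirability <- function(value, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  lo <- goal$anchor_low; hi <- goal$anchor_high
  if (is.null(lo) || is.null(hi))
    stop("goal anchors are unset; supply anchors or use optimize_desirability()",
         call. = FALSE)
  ramp <- pmin(1, pmax(0, (value - lo) / (hi - lo)))
  if (goal$direction == "minimize") ramp <- 1 - ramp
  ramp^goal$weight
}

# weighted geometric mean of individual desirabilities (rows of d_mat),
# weights w; 0 whenever any component is 0
overall_desirability <- function(d_mat, w) {
  if (is.null(dim(d_mat))) d_mat <- matrix(d_mat, nrow = 1L)
  lw <- matrix(0, nrow(d_mat), ncol(d_mat))
  pos <- d_mat > 0
  lw[pos] <- log(d_mat[pos])
  D <- exp(as.vector(lw %*% w) / sum(w))
  D[rowSums(!pos) > 0L] <- 0
  D
}

#' Multi-response desirability optimization over the design cube
#'
#' Maximizes the overall desirability -- the weighted geometric mean of the
#' per-response Derringer-Suich desirabilities of the model predictions --
#' over the coded cube `[-1, 1]^3`. The search is an exhaustive regular
#' grid at the given resolution followed by a Nelder-Mead polish started
#' from the best grid point (evaluations outside the cube are clamped to
#' it), so the whole procedure is deterministic. Exact grid ties are broken
#' by lower predicted value of the first minimized response, then by
#' lexicographically smallest coded coordinates.
#'
#' @param models Named list of three [rsm_fit()] objects fitted on the same
#'   design (names are the response names).
#' @param goals List of [desirability_goal()]s, one per model response.
#'   `NULL` anchors are filled from each response's observed min/max over
#'   the run table.
#' @param resolution Coded grid spacing (default 0.01).
#' @param polish Run the Nelder-Mead refinement (default TRUE).
#' @return An object of class `rsm_optim`: `coded_optimum`,
#'   `actual_optimum`, `predicted`, `desirabilities`, `overall_D`, and the
#'   resolved `goals`.
#' @export
optimize_desirability <- function(models, goals, resolution = 0.01,
                                  polish = TRUE) {
  if (!length(goals)) stop("at least one goal is required", call. = FALSE)
  if (!(is.numeric(resolution) && resolution > 0))
    stop("'resolution' must be positive", call. = FALSE)
  if (!all(vapply(models, inherits, logical(1), "rsm_fit")))
    stop("'models' must be a list of rsm_fit objects", call. = FALSE)
  resp <- vapply(goals, `[[`, character(1), "response")
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "response")
  if (!all(resp %in% names(models)))
    stop("every goal must reference a fitted model by response name",
         call. = FALSE)
  models <- models[resp]
  des <- models[[1L]]$design
  # resolve default anchors from the observed run-table range
  goals <- lapply(seq_along(goals), function(i) {
    g <- goals[[i]]
    obs <- models[[g$response]]$y_obs
    if (is.null(g$anchor_low)) g$anchor_low <- min(obs)
    if (is.null(g$anchor_high)) g$anchor_high <- max(obs)
    if (!(g$anchor_low < g$anchor_high))
      stop("degenerate anchors for response ", g$response, call. = FALSE)
    g
  })
  w <- vapply(goals, `[[`, numeric(1), "weight")
  min_idx <- which(vapply(goals, `[[`, character(1), "direction") == "minimize")
  tiebreak_model <- if (length(min_idx)) min_idx[1L] else NA_integer_

  eval_D <- function(pts) {
    d <- vapply(seq_along(goals), function(i)
      desirability(predict(models[[i]], pts), goals[[i]]),
      numeric(nrow(pts)))
    if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
    list(D = overall_desirability(d, w), d = d)
  }

  g <- seq(-1, 1, by = resolution)
  if (g[length(g)] < 1) g <- c(g, 1)
  # slice over x1 to bound memory; within a slice, row order is
  # lexicographic in (x2, x3) so ties resolve to the smallest coordinates
  slice <- as.matrix(expand.grid(x3 = g, x2 = g,
                                 KEEP.OUT.ATTRS = FALSE))[, c(2, 1)]
  best <- list(D = -Inf, tb = Inf, point = c(0, 0, 0))
  for (a in g) {
    pts <- cbind(x1 = a, slice)
    ev <- eval_D(pts)
    tb <- if (!is.na(tiebreak_model))
      predict(models[[tiebreak_model]], pts) else rep(0, nrow(pts))
    Dmax <- max(ev$D)
    better <- Dmax > best$D
    if (!better && Dmax == best$D) {
      ties <- which(ev$D == Dmax)
      i <- ties[order(tb[ties], ties)][1L]
      if (tb[i] < best$tb) { best <- list(D = Dmax, tb = tb[i], point = pts[i, ]) }
      next
    }
    if (better) {
      ties <- which(ev$D == Dmax)
      i <- ties[order(tb[ties], ties)][1L]
      best <- list(D = Dmax, tb = tb[i], point = pts[i, ])
    }
  }

  opt <- unname(best$point)
  if (polish) {
    obj <- function(p) {
      p <- pmin(1, pmax(-1, p))
      -eval_D(matrix(p, nrow = 1L))$D
    }
    pol <- stats::optim(opt, obj, method = "Nelder-Mead")
    cand <- pmin(1, pmax(-1, pol$par))
    if (-pol$value > best$D) opt <- cand
  }

  pts <- matrix(opt, nrow = 1L, dimnames = list(NULL, c("x1", "x2", "x3")))
  ev <- eval_D(pts)
  predicted <- vapply(models, function(m) predict(m, pts), numeric(1))
  d_ind <- stats::setNames(as.vector(ev$d), resp)
  actual <- vapply(seq_len(3L), function(j)
    decode_level(des$factors[[j]], opt[j]), numeric(1))
  names(actual) <- vapply(des$factors, `[[`, character(1), "name")
  structure(list(coded_optimum = stats::setNames(opt, c("x1", "x2", "x3")),
                 actual_optimum = actual, predicted = predicted,
                 desirabilities = d_ind, overall_D = ev$D,
                 goals = goals, resolution = resolution),
            class = "rsm_optim")
}

#' @export
print.rsm_optim <- function(x, ...) {
  cat("Desirability optimum (overall D =", format(x$overall_D, digits = 4), ")\n")
  cat("  coded:", paste(sprintf("%s = %.3g", names(x$coded_optimum),
                                x$coded_optimum), collapse = ", "), "\n")
  cat("  actual:", paste(sprintf("%s = %.4g", names(x$actual_optimum),
                                 x$actual_optimum), collapse = ", "), "\n")
  for (r in names(x$predicted))
    cat(sprintf("  %s: predicted %.4g (d = %.3f)\n", r, x$predicted[r],
                x$desirabilities[r]))
  invisible(x)
}

#' Prediction-error percentage of a checkpoint measurement
#'
#' `|estimated - expected| / estimated * 100`, the absolute percentage
#' deviation of a model's expected value from the measured (estimated)
#' value of a checkpoint formulation.
#'
#' @param estimated Measured value(s).
#' @param expected Model-predicted value(s).
#' @return Absolute prediction error in percent.
#' @export
prediction_error <- function(estimated, expected) {
  if (any(estimated == 0))
    stop("prediction error is undefined for a measured value of 0", call. = FALSE)
  abs(estimated - expected) / abs(estimated) * 100
}

#' Validate a checkpoint formulation against model predictions
#'
#' Predicts each response at a coded checkpoint and compares with the
#' measured values by [prediction_error()]. Errors above `threshold`
#' percent flag a validation failure for that response.
#'
#' @param measured Named numeric vector of measured responses.
#' @param models Named list of [rsm_fit()]s covering those responses.
#' @param coded_point Length-3 coded coordinates of the checkpoint.
#' @param threshold Failure threshold in percent (default 10).
#' @return A data frame of class `validation_report`: `response`,
#'   `estimated`, `expected`, `prediction_error_pct`, `pass`.
#' @export
validate_checkpoint <- function(measured, models, coded_point,
                                threshold = 10) {
  if (is.null(names(measured)) || !all(nzchar(names(measured))))
    stop("'measured' must be a named vector", call. = FALSE)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "response")
  miss <- setdiff(names(measured), names(models))
  if (length(miss))
    stop("no fitted model for measured response(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pt <- as_coded_matrix(coded_point)
  out <- do.call(rbind, lapply(names(measured), function(r) {
    expd <- predict(models[[r]], pt)
    err <- prediction_error(measured[[r]], expd)
    data.frame(response = r, estimated = measured[[r]], expected = expd,
               prediction_error_pct = err, pass = err <= threshold)
  }))
  rownames(out) <- NULL
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Checkpoint validation (fail above threshold):\n")
  y <- as.data.frame(x)
  y$expected <- signif(y$expected, 6)
  y$prediction_error_pct <- round(y$prediction_error_pct, 1)
  print(y, row.names = FALSE)
  invisible(x)
}
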