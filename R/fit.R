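#' @keywords internal
"_PACKAGE"

# Full quadratic term vocabulary for a 3-factor response surface, in the
# labels used throughout: main effects "x1".."x3", two-way interactions
# "x1:x2" etc., pure quadratics "x1^2" etc. The intercept is implicit.
rsm_all_terms <- function() {
  c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3", "x1^2", "x2^2", "x3^2")
}

# Build the coded model matrix (with intercept) for a set of term labels.
# 'coded' is an n x 3 matrix with columns x1, x2, x3.
rsm_model_matrix <- function(coded, terms) {
  bad <- setdiff(terms, rsm_all_terms())
  if (length(bad))
    stop("unknown model terms: ", paste(bad, collapse = ", "), call. = FALSE)
  cols <- lapply(terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      ij <- strsplit(tm, ":", fixed = TRUE)[[1]]
      coded[, ij[1]] * coded[, ij[2]]
    } else if (grepl("^", tm, fixed = TRUE)) {
      v <- sub("\\^2$", "", tm)
      coded[, v]^2
    } else {
      coded[, tm]
    }
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

# parent main effects of a higher-order term ("x2:x3" -> c("x2","x3"),
# "x3^2" -> "x3", main effect -> character(0))
term_parents <- function(tm) {
  if (grepl(":", tm, fixed = TRUE)) strsplit(tm, ":", fixed = TRUE)[[1]]
  else if (grepl("^", tm, fixed = TRUE)) sub("\\^2$", "", tm)
  else character(0)
}

#' Fit a response-surface model in coded units
#'
#' Ordinary least squares on the coded Box-Behnken model matrix. The
#' response may be fitted on its original scale (`transform = "identity"`)
#' or on the natural-log scale (`transform = "ln"`), in which case
#' coefficients, standard errors and the ANOVA decomposition all live on
#' the log scale and [predict.rsm_fit()] back-transforms with `exp()`.
#'
#' Standard errors come from the unbiased residual variance and the
#' diagonal of the inverse Gram matrix \eqn{(X'X)^{-1}}; t-statistics are
#' coefficient / SE. When the design contains replicated runs (the center
#' replicates), the residual sum of squares is split into lack-of-fit and
#' pure error, and the lack-of-fit F-test is carried in the `anova`
#' component (see [lack_of_fit()]).
#'
#' @param data An [rsm_data()] object.
#' @param response Name of the response column to fit.
#' @param terms Character vector of non-intercept model terms from the
#'   quadratic vocabulary `x1, x2, x3, x1:x2, x1:x3, x2:x3, x1^2, x2^2,
#'   x3^2`. The intercept is always included. Defaults to the three main
#'   effects.
#' @param transform `"identity"` or `"ln"` (natural log of the response
#'   before fitting; requires strictly positive responses).
#' @return An object of class `rsm_fit` with components `coefficients`,
#'   `se`, `tstat`, `pvalue`, `residual_df`, `sigma2`, `r2`, `anova` (sum
#'   of squares decomposition incl. lack of fit when replicates exist),
#'   `terms`, `transform`, `response`, plus the design and observed
#'   responses needed by the downstream methods.
#' @seealso [lack_of_fit()], [standardized_effects()], [select_terms()],
#'   [predict.rsm_fit()], [surface_grid()]
#' @export
fit_rsm <- function(data, response, terms = c("x1", "x2", "x3"),
                    transform = c("identity", "ln")) {
  stopifnot(inherits(data, "rsm_data"))
  transform <- match.arg(transform)
  if (!response %in% names(data$responses))
    stop(sprintf("response '%s' not found in the data", response), call. = FALSE)
  y_obs <- data$responses[[response]]
  if (transform == "ln") {
    if (any(y_obs <= 0))
      stop("ln transform requires strictly positive responses", call. = FALSE)
    y <- log(y_obs)
  } else {
    y <- y_obs
  }
  terms <- unique(terms)
  coded <- design_coded(data$design)
  X <- rsm_model_matrix(coded, terms)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L)
    stop(sprintf("need at least %d runs to fit %d terms with an error estimate",
                 p + 1L, p), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("singular model matrix: terms are confounded on this design", call. = FALSE)
  coefs <- qr.coef(qrX, y)
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  residual_df <- n - p
  ss_res <- sum(res^2)
  sigma2 <- ss_res / residual_df
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  names(se) <- colnames(X)
  tstat <- coefs / se
  pvalue <- 2 * stats::pt(abs(tstat), residual_df, lower.tail = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot

  anova <- list(model_ss = ss_tot - ss_res, model_df = p - 1L,
                residual_ss = ss_res, residual_df = residual_df,
                pure_error_ss = NA_real_, pure_error_df = NA_integer_,
                lack_of_fit_ss = NA_real_, lack_of_fit_df = NA_integer_,
                lof_F = NA_real_, lof_p = NA_real_)
  key <- apply(coded, 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    groups <- split(y, key)
    pe_ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
    pe_df <- sum(vapply(groups, length, integer(1)) - 1L)
    lof_ss <- ss_res - pe_ss
    lof_df <- residual_df - pe_df
    anova$pure_error_ss <- pe_ss; anova$pure_error_df <- pe_df
    anova$lack_of_fit_ss <- lof_ss; anova$lack_of_fit_df <- lof_df
    if (lof_df > 0L && pe_df > 0L) {
      Fv <- (lof_ss / lof_df) / (pe_ss / pe_df)
      anova$lof_F <- Fv
      anova$lof_p <- stats::pf(Fv, lof_df, pe_df, lower.tail = FALSE)
    }
  }

  structure(list(coefficients = coefs, se = se, tstat = tstat,
                 pvalue = pvalue, residual_df = residual_df,
                 sigma2 = sigma2, r2 = r2, anova = anova,
                 terms = terms, transform = transform, response = response,
                 design = data$design, y = y, y_obs = y_obs,
                 fitted_transformed = fitted, residuals = res,
                 XtX_inv = XtX_inv),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, digits = 6, ...) {
  lab <- if (x$transform == "ln") sprintf("Ln(%s)", x$response) else x$response
  eq <- paste0(signif(x$coefficients[1], digits),
               paste0(vapply(seq_along(x$terms), function(i) {
                 b <- x$coefficients[i + 1L]
                 sprintf(" %s %s*%s", if (b < 0) "-" else "+",
                         signif(abs(b), digits), x$terms[i])
               }, character(1)), collapse = ""))
  cat(sprintf("Response-surface fit (coded units)\n%s = %s\n", lab, eq))
  cat(sprintf("R-squared %.4f on %d residual df\n", x$r2, x$residual_df))
  if (!is.na(x$anova$lof_p))
    cat(sprintf("Lack of fit: F = %.4g on (%d, %d) df, p = %.4g\n",
                x$anova$lof_F, x$anova$lack_of_fit_df,
                x$anova$pure_error_df, x$anova$lof_p))
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
summary.rsm_fit <- function(object, ...) {
  tab <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(object$se),
                    t = unname(object$tstat),
                    p = unname(object$pvalue))
  structure(list(fit = object, coefficients = tab), class = "summary.rsm_fit")
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 6)
  tab$se <- signif(tab$se, 4)
  tab$t <- round(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  a <- x$fit$anova
  cat(sprintf("\nANOVA: model SS %.4g (%d df), residual SS %.4g (%d df)\n",
              a$model_ss, a$model_df, a$residual_ss, a$residual_df))
  if (!is.na(a$pure_error_df))
    cat(sprintf("  lack of fit SS %.4g (%d df), pure error SS %.4g (%d df)\n",
                a$lack_of_fit_ss, a$lack_of_fit_df,
                a$pure_error_ss, a$pure_error_df))
  invisible(x)
}

# coerce a point or matrix of coded coordinates to an n x 3 matrix
as_coded_matrix <- function(point) {
  if (is.data.frame(point)) point <- as.matrix(point)
  if (is.null(dim(point))) {
    if (length(point) != 3L)
      stop("a coded point must have exactly 3 coordinates", call. = FALSE)
    point <- matrix(point, nrow = 1L)
  }
  if (ncol(point) != 3L)
    stop("coded points must have exactly 3 columns (x1, x2, x3)", call. = FALSE)
  colnames(point) <- c("x1", "x2", "x3")
  point
}

#' Predict from a response-surface fit
#'
#' Evaluates the fitted polynomial at coded points and returns predictions
#' on the original response scale (models fitted with `transform = "ln"`
#' are back-transformed with `exp()`, with no bias correction). Points
#' outside the design cube `[-1, 1]^3` are refused unless
#' `extrapolate = TRUE`.
#'
#' @param object An [rsm_fit()].
#' @param newdata A length-3 coded point, or an n x 3 matrix / data frame
#'   of coded points (columns x1, x2, x3). Defaults to the design points.
#' @param extrapolate Allow points outside the design cube.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, extrapolate = FALSE, ...) {
  if (is.null(newdata)) {
    pt <- design_coded(object$design)
  } else {
    pt <- as_coded_matrix(newdata)
  }
  if (!extrapolate && any(abs(pt) > 1 + 1e-9))
    stop("coded point outside [-1, 1]^3; set extrapolate = TRUE to allow",
         call. = FALSE)
  X <- rsm_model_matrix(pt, object$terms)
  eta <- as.vector(X %*% object$coefficients)
  if (object$transform == "ln") exp(eta) else eta
}

#' @export
fitted.rsm_fit <- function(object, ...) {
  if (object$transform == "ln") exp(object$fitted_transformed)
  else object$fitted_transformed
}

#' Simulate new response vectors from a fitted surface
#'
#' Draws Gaussian noise with the fit's residual standard deviation on the
#' transform scale around the fitted values at the design points, mirroring
#' the model's own error assumption.
#'
#' @param object An [rsm_fit()].
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed (required: simulation is always reproducible).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses on the
#'   original response scale.
#' @export
simulate.rsm_fit <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(as.integer(seed))
  mu <- object$fitted_transformed
  out <- replicate(nsim, {
    z <- mu + stats::rnorm(length(mu), 0, sqrt(object$sigma2))
    if (object$transform == "ln") exp(z) else z
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
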