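#' Lack-of-fit F-test against pure error
#'
#' Splits the residual sum of squares of a response-surface fit into
#' lack-of-fit and pure error. Pure error is estimated solely from
#' replicated design points (rows with identical coded coordinates -- in a
#' Box-Behnken design, the center replicates): within each replicate group
#' the deviations from the group mean contribute to pure error with
#' (group size - 1) degrees of freedom. The lack-of-fit mean square is
#' compared with the pure-error mean square by an F-test; a large p-value
#' means the model's residuals are indistinguishable from replicate noise.
#'
#' @param fit An [rsm_fit()].
#' @return A list with `F`, `p`, the two mean squares and their degrees of
#'   freedom.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  a <- fit$anova
  if (is.na(a$pure_error_df) || a$pure_error_df < 1L)
    stop("lack of fit is undefined: the design has no replicated runs",
         call. = FALSE)
  if (is.na(a$lof_F))
    stop("lack of fit is undefined: no residual degrees of freedom remain beyond pure error",
         call. = FALSE)
  list(F = a$lof_F, p = a$lof_p,
       lack_of_fit_ms = a$lack_of_fit_ss / a$lack_of_fit_df,
       pure_error_ms = a$pure_error_ss / a$pure_error_df,
       lack_of_fit_df = a$lack_of_fit_df, pure_error_df = a$pure_error_df)
}

#' Standardized effects (Pareto ranking)
#'
#' Each model term's standardized effect is its t-statistic: the
#' coefficient divided by its standard error. Terms are ranked by absolute
#' t, and a term is flagged significant when |t| exceeds the two-tailed
#' critical t at the given level with the fit's residual degrees of
#' freedom -- the dashed reference line of a Pareto chart.
#'
#' @param fit An [rsm_fit()].
#' @param level Confidence level for the critical t (default 0.95).
#' @return A data frame (`term`, `t`, `abs_t`, `significant`), sorted by
#'   decreasing |t|, intercept excluded; the critical value is attached as
#'   attribute `"critical_t"`.
#' @export
standardized_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (fit$residual_df < 1L)
    stop("standardized effects need at least 1 residual degree of freedom",
         call. = FALSE)
  keep <- names(fit$tstat) != "(Intercept)"
  t <- fit$tstat[keep]
  crit <- stats::qt(1 - (1 - level) / 2, fit$residual_df)
  out <- data.frame(term = names(t), t = unname(t), abs_t = abs(unname(t)),
                    significant = abs(unname(t)) > crit)
  out <- out[order(-out$abs_t, out$term), ]
  rownames(out) <- NULL
  attr(out, "critical_t") <- crit
  out
}

#' Backward term selection for a reduced response-surface model
#'
#' Starts from the full quadratic model (3 main effects, 3 two-way
#' interactions, 3 pure quadratics) and repeatedly removes the
#' least-significant removable term with p > `alpha`, refitting after each
#' removal, until every retained non-intercept term has p <= `alpha`.
#' With `hierarchy = TRUE` (default) a main effect is not removable while
#' any interaction or quadratic term involving it remains. Ties in p-value
#' are broken by alphabetical term label, making the procedure
#' deterministic. On an orthogonal Box-Behnken design the retained
#' main-effect estimates are unchanged by the reduction.
#'
#' @param data An [rsm_data()].
#' @param response Response name.
#' @param transform `"identity"` or `"ln"`.
#' @param alpha Retention threshold on the coefficient p-value (default
#'   0.05).
#' @param hierarchy Enforce model hierarchy during elimination.
#' @return A list of class `rsm_spec` with `response`, `transform`,
#'   `terms` (the selected non-intercept terms, in canonical order) and
#'   `selection = "backward"`.
#' @export
select_terms <- function(data, response, transform = c("identity", "ln"),
                         alpha = 0.05, hierarchy = TRUE) {
  transform <- match.arg(transform)
  terms <- rsm_all_terms()
  repeat {
    fit <- fit_rsm(data, response, terms, transform)
    p <- fit$pvalue[names(fit$pvalue) != "(Intercept)"]
    removable <- names(p)
    if (hierarchy) {
      needed <- unique(unlist(lapply(terms, term_parents)))
      removable <- setdiff(removable, needed)
    }
    cand <- removable[p[removable] > alpha]
    if (!length(cand)) break
    # drop the worst p; alphabetical tie-break
    worst <- cand[order(-p[cand], cand)][1L]
    terms <- setdiff(terms, worst)
    if (!length(terms)) break
  }
  structure(list(response = response, transform = transform,
                 terms = intersect(rsm_all_terms(), terms),
                 selection = "backward"),
            class = "rsm_spec")
}

#' @export
print.rsm_spec <- function(x, ...) {
  cat(sprintf("Model spec for %s%s: 1 + %s (%s selection)\n",
              x$response, if (x$transform == "ln") " (ln scale)" else "",
              paste(x$terms, collapse = " + "), x$selection))
  invisible(x)
}

#' Evaluate a fitted surface on a regular coded grid
#'
#' Predicts the response over a regular grid in two coded factors with the
#' third held fixed, in long format ready for contour or perspective
#' plotting (or export).
#'
#' @param fit An [rsm_fit()].
#' @param vary Character vector of the two coded factor names to vary
#'   (from `"x1"`, `"x2"`, `"x3"`).
#' @param fixed_value Coded value of the remaining factor (default 0).
#' @param resolution Number of grid points per axis (>= 2, default 21).
#' @return A data frame with columns `x1`, `x2`, `x3` and `predicted`
#'   (original response scale), one row per grid point.
#' @export
surface_grid <- function(fit, vary = c("x2", "x3"), fixed_value = 0,
                         resolution = 21) {
  stopifnot(inherits(fit, "rsm_fit"))
  axes <- c("x1", "x2", "x3")
  vary <- as.character(vary)
  if (length(vary) != 2L || !all(vary %in% axes) || vary[1] == vary[2])
    stop("'vary' must name two distinct coded factors among x1, x2, x3",
         call. = FALSE)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L)
    stop("'resolution' must be an integer >= 2", call. = FALSE)
  fixed <- setdiff(axes, vary)
  g <- seq(-1, 1, length.out = resolution)
  grid <- expand.grid(a = g, b = g, KEEP.OUT.ATTRS = FALSE)
  pt <- matrix(fixed_value, nrow = nrow(grid), ncol = 3L,
               dimnames = list(NULL, axes))
  pt[, vary[1]] <- grid$a
  pt[, vary[2]] <- grid$b
  out <- as.data.frame(pt)
  out$predicted <- predict(fit, pt)
  out
}

#' Perspective plot of a fitted response surface
#'
#' Base-graphics `persp()` view of the surface over two coded factors with
#' the third fixed, the response on its original scale.
#'
#' @param x An [rsm_fit()].
#' @param vary Two coded factor names to vary.
#' @param fixed_value Coded value of the third factor.
#' @param resolution Grid points per axis.
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @param ... Further arguments to [graphics::persp()].
#' @return The perspective transformation matrix, invisibly.
#' @export
plot.rsm_fit <- function(x, vary = c("x2", "x3"), fixed_value = 0,
                         resolution = 30, theta = 40, phi = 25, ...) {
  grid <- surface_grid(x, vary, fixed_value, resolution)
  g <- sort(unique(grid[[vary[1]]]))
  z <- matrix(grid$predicted, nrow = length(g))
  graphics::persp(g, g, z, xlab = vary[1], ylab = vary[2],
                  zlab = x$response, theta = theta, phi = phi,
                  ticktype = "detailed", ...)
}
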