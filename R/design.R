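#' Define an experimental factor with three levels
#'
#' A factor in a three-level response-surface design is described by its
#' low, center and high settings in actual (physical) units. Coded units
#' place these at -1, 0 and +1. Symmetric spacing (center exactly midway
#' between low and high) is the usual convention and makes the coding
#' linear both ways; asymmetric spacing is permitted but flagged, because
#' the coded center then no longer sits at the midpoint of the coded range.
#'
#' @param name Factor name (single string), e.g. `"lecithin"`.
#' @param low,center,high Actual-unit settings, strictly increasing.
#' @param units Unit label for display, e.g. `"mg"`.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("lecithin", 100, 150, 200, "mg")
#' @export
factor_spec <- function(name, low, center, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); center <- as.numeric(center); high <- as.numeric(high)
  if (!(is.finite(low) && is.finite(center) && is.finite(high)))
    stop("factor levels must be finite numbers", call. = FALSE)
  if (high == low)
    stop("degenerate factor spec: high == low", call. = FALSE)
  if (!(low < center && center < high))
    stop("factor levels must satisfy low < center < high", call. = FALSE)
  if (abs(center - (low + high) / 2) > 1e-8 * (high - low))
    warning(sprintf("factor '%s': center is not midway between low and high (asymmetric spacing)", name),
            call. = FALSE)
  structure(list(name = name, low = low, center = center, high = high,
                 units = units),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s (%s): %g / %g / %g at coded -1 / 0 / +1\n",
              x$name, if (nzchar(x$units)) x$units else "unitless",
              x$low, x$center, x$high))
  invisible(x)
}

#' Convert between actual and coded factor levels
#'
#' Standard design-of-experiments coding: `coded = (actual - center) /
#' half-range`, where the half-range is `(high - low) / 2`. `decode_level()`
#' is the exact inverse. Values outside `[-1, 1]` are allowed (the formula
#' is linear everywhere) but raise a warning, since they lie outside the
#' experimental region.
#'
#' @param spec A [factor_spec()].
#' @param actual Actual-unit value(s).
#' @param coded Coded value(s).
#' @param warn Warn when the coded value falls outside `[-1, 1]`.
#' @return Numeric vector of the converted values.
#' @examples
#' lc <- factor_spec("lecithin", 100, 150, 200, "mg")
#' code_level(lc, 100)    # -1
#' decode_level(lc, 0.5)  # 175
#' @export
code_level <- function(spec, actual, warn = TRUE) {
  stopifnot(inherits(spec, "factor_spec"))
  half <- (spec$high - spec$low) / 2
  coded <- (actual - spec$center) / half
  if (warn && any(abs(coded) > 1 + 1e-12))
    warning(sprintf("factor '%s': value outside the [-1, 1] design region", spec$name),
            call. = FALSE)
  coded
}

#' @rdname code_level
#' @export
decode_level <- function(spec, coded) {
  stopifnot(inherits(spec, "factor_spec"))
  spec$center + coded * (spec$high - spec$low) / 2
}

#' Construct a three-factor Box-Behnken design
#'
#' The three-factor Box-Behnken design (BBD) consists of the 12 midpoints
#' of the edges of the design cube -- all four sign combinations of each
#' factor pair, with the third factor held at its center -- plus replicated
#' center runs. With 5 center replicates this gives the classic 17-run
#' layout. Center replication supplies the pure-error degrees of freedom
#' used by the lack-of-fit test.
#'
#' Runs are emitted in a fixed canonical order: factor-pair blocks (1,2),
#' (1,3), (2,3), each in sign order (-,-), (+,-), (-,+), (+,+), followed by
#' the center runs. Published run tables are usually randomized; a mapping
#' from this canonical order to a printed order can be carried separately
#' (see the shipped `run_order_map.csv` fixture for the worked dataset).
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param n_center Number of center replicates (>= 1), default 5.
#' @return An object of class `bbd_design`: a list with `factors`, a
#'   `runs` data frame (`run_id`, one `<name>_coded` and `<name>_actual`
#'   column per factor), and `n_center`.
#' @examples
#' des <- bbd_design(list(
#'   factor_spec("lecithin", 100, 150, 200, "mg"),
#'   factor_spec("chitosan", 10, 25, 40, "mg"),
#'   factor_spec("ipm", 1, 2, 3, "% w/v")))
#' nrow(des$runs)  # 17
#' @export
bbd_design <- function(factors, n_center = 5) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("'factors' must be a list of exactly three factor_spec objects", call. = FALSE)
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L)
    stop("'n_center' must be a positive integer", call. = FALSE)

  signs <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  coded <- matrix(0, nrow = 12L + n_center, ncol = 3L)
  row <- 0L
  for (p in seq_len(3L)) {
    for (s in seq_len(4L)) {
      row <- row + 1L
      coded[row, pairs[p, ]] <- signs[s, ]
    }
  }
  actual <- vapply(seq_len(3L),
                   function(j) decode_level(factors[[j]], coded[, j]),
                   numeric(nrow(coded)))
  nm <- vapply(factors, `[[`, character(1), "name")
  runs <- data.frame(run_id = seq_len(nrow(coded)))
  for (j in seq_len(3L)) {
    runs[[paste0(nm[j], "_coded")]] <- coded[, j]
    runs[[paste0(nm[j], "_actual")]] <- actual[, j]
  }
  structure(list(factors = factors, runs = runs, n_center = n_center),
            class = "bbd_design")
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: 3 factors, %d runs (12 edge + %d center)\n",
              nrow(x$runs), x$n_center))
  for (f in x$factors) print(f)
  invisible(x)
}

# n x 3 matrix of coded levels, columns x1..x3 in factor order
design_coded <- function(design) {
  stopifnot(inherits(design, "bbd_design"))
  nm <- vapply(design$factors, `[[`, character(1), "name")
  m <- as.matrix(design$runs[, paste0(nm, "_coded")])
  colnames(m) <- paste0("x", seq_along(nm))
  m
}

design_actual <- function(design) {
  nm <- vapply(design$factors, `[[`, character(1), "name")
  m <- as.matrix(design$runs[, paste0(nm, "_actual")])
  colnames(m) <- nm
  m
}

#' Read and write design tables and factor specifications
#'
#' Designs round-trip through CSV with one `<factor>_coded` and
#' `<factor>_actual` column per factor plus `run_id`; factor
#' specifications through a small CSV (`name, low, center, high, units`)
#' or a JSON array of the same fields.
#'
#' @param design A [bbd_design()].
#' @param factors List of three [factor_spec()] objects (for
#'   `read_design_csv()`, the specs matching the file's columns).
#' @param path File path.
#' @return Readers return the reconstructed object; writers return the
#'   path invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "bbd_design"))
  utils::write.csv(design$runs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, factors) {
  runs <- utils::read.csv(path, check.names = FALSE)
  nm <- vapply(factors, `[[`, character(1), "name")
  need <- c("run_id", paste0(rep(nm, each = 2), c("_coded", "_actual")))
  miss <- setdiff(need, names(runs))
  if (length(miss))
    stop("design CSV is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  coded <- as.matrix(runs[, paste0(nm, "_coded")])
  is_center <- rowSums(coded != 0) == 0L
  structure(list(factors = factors, runs = runs[, need],
                 n_center = sum(is_center)),
            class = "bbd_design")
}

#' @rdname write_design_csv
#' @export
write_factors_csv <- function(factors, path) {
  df <- do.call(rbind, lapply(factors, function(f)
    data.frame(name = f$name, low = f$low, center = f$center,
               high = f$high, units = f$units)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_factors_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    factor_spec(df$name[i], df$low[i], df$center[i], df$high[i],
                units = if ("units" %in% names(df)) df$units[i] else ""))
}

#' @rdname write_design_csv
#' @export
factors_to_json <- function(factors, path = NULL) {
  x <- lapply(factors, function(f)
    list(name = f$name, low = f$low, center = f$center, high = f$high,
         units = f$units))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(path))
  }
  json
}

#' @rdname write_design_csv
#' @export
factors_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x, function(f)
    factor_spec(f$name, f$low, f$center, f$high, units = f$units %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
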