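#' Attach measured responses to a design
#'
#' Bundles a Box-Behnken design with per-run response means (and optional
#' replicate standard deviations) into the container the fitting functions
#' consume. Each response must supply exactly one value per run.
#'
#' @param design A [bbd_design()].
#' @param responses Data frame or named list of numeric vectors, one value
#'   per run, named by response.
#' @param sd Optional data frame / named list of per-run replicate SDs
#'   (non-negative), same shape as `responses`.
#' @param units Optional named character vector of unit labels per response.
#' @return An object of class `rsm_data`.
#' @export
rsm_data <- function(design, responses, sd = NULL, units = NULL) {
  stopifnot(inherits(design, "bbd_design"))
  responses <- as.data.frame(responses, optional = TRUE)
  n <- nrow(design$runs)
  if (nrow(responses) != n)
    stop(sprintf("responses have %d rows but the design has %d runs",
                 nrow(responses), n), call. = FALSE)
  if (!all(vapply(responses, is.numeric, logical(1))))
    stop("all response columns must be numeric", call. = FALSE)
  if (anyNA(responses))
    stop("responses must not contain missing values", call. = FALSE)
  if (!is.null(sd)) {
    sd <- as.data.frame(sd, optional = TRUE)
    if (nrow(sd) != n || !all(names(sd) %in% names(responses)))
      stop("'sd' must align with 'responses' by run and by name", call. = FALSE)
    if (any(unlist(sd) < 0, na.rm = TRUE))
      stop("replicate SDs must be non-negative", call. = FALSE)
  }
  structure(list(design = design, responses = responses, sd = sd,
                 units = units),
            class = "rsm_data")
}

#' @export
print.rsm_data <- function(x, ...) {
  cat(sprintf("RSM data: %d runs, responses: %s\n",
              nrow(x$responses), paste(names(x$responses), collapse = ", ")))
  invisible(x)
}

#' Read and write response tables
#'
#' Long-format CSV with columns `run_id, response, mean` and optionally
#' `sd`, one row per run and response.
#'
#' @param data An [rsm_data()] object.
#' @param path File path.
#' @param design The [bbd_design()] the responses belong to (reader).
#' @return The reader returns an [rsm_data()]; the writer returns the path
#'   invisibly.
#' @export
write_responses_csv <- function(data, path) {
  stopifnot(inherits(data, "rsm_data"))
  long <- do.call(rbind, lapply(names(data$responses), function(r) {
    data.frame(run_id = data$design$runs$run_id,
               response = r,
               mean = data$responses[[r]],
               sd = if (!is.null(data$sd) && r %in% names(data$sd))
                 data$sd[[r]] else NA_real_)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path, design) {
  long <- utils::read.csv(path, check.names = FALSE)
  need <- c("run_id", "response", "mean")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("response CSV is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  rid <- design$runs$run_id
  resp <- list(); sds <- list()
  for (r in unique(long$response)) {
    block <- long[long$response == r, ]
    idx <- match(rid, block$run_id)
    if (anyNA(idx))
      stop(sprintf("response '%s' is missing values for some runs", r), call. = FALSE)
    resp[[r]] <- block$mean[idx]
    if ("sd" %in% names(block) && !all(is.na(block$sd)))
      sds[[r]] <- block$sd[idx]
  }
  rsm_data(design, resp, sd = if (length(sds)) sds else NULL)
}
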