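#' Configuration for a full formulation-optimization study
#'
#' `ber_study_config()` returns the configuration that reproduces the
#' shipped berberine nanoparticle study end to end: the three fixed
#' reduced model specs, minimize-PS / maximize-ZP / maximize-EE goals with
#' observed-range anchors and unit weights, a 0.01 coded grid, and the
#' study's checkpoint measurements.
#'
#' A configuration is a plain list (serializable to JSON) with fields:
#' `factors_csv`/`design_csv`/`responses_csv` (file paths; all `NULL` to
#' use the shipped study), `models` (per response: `terms` as a character
#' vector or `"auto"` for backward selection, and `transform`), `goals`
#' (per response: `direction`, optional `anchor_low`/`anchor_high`/
#' `weight`), `resolution`, `checkpoint` (optional: `measured` named list
#' and either `coded_point` or nothing to use the optimizer's optimum),
#' and `seed`.
#'
#' @return A named list.
#' @export
ber_study_config <- function() {
  specs <- ber_model_specs()
  list(factors_csv = NULL, design_csv = NULL, responses_csv = NULL,
       models = lapply(specs, function(s)
         list(terms = s$terms, transform = s$transform)),
       goals = list(PS = list(direction = "minimize"),
                    ZP = list(direction = "maximize"),
                    EE = list(direction = "maximize")),
       resolution = 0.01,
       checkpoint = list(measured = list(PS = 168.4, ZP = 33.1, EE = 82.3),
                         actual_point = list(lecithin = 100, chitosan = 23.5,
                                             ipm = 2.6)),
       seed = 1L)
}

#' Run a complete formulation-optimization study
#'
#' Orchestrates the whole pipeline: load (or default) the design and
#' responses, fit the configured reduced model per response (backward
#' selection when `terms = "auto"`), run the lack-of-fit tests and
#' standardized-effect rankings, optimize the overall desirability over
#' the design cube, and validate the checkpoint if one is configured.
#' When `out_dir` is given, every stage's result is written there as
#' JSON/CSV (design echo, per-response model JSON, ANOVA table, Pareto
#' tables, surface grids, optimization result, validation report) along
#' with a stage-by-stage `log.txt` recording an MD5 checksum of every
#' input file. Numeric outputs are deterministic: rerunning an identical
#' configuration reproduces identical files.
#'
#' @param config A configuration list (see [ber_study_config()]) or a
#'   path to a JSON file holding one.
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing.
#' @return Invisibly, a list with `data`, `fits`, `lof`, `effects`,
#'   `optimum`, and (if configured) `validation`.
#' @export
run_study <- function(config = ber_study_config(), out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  log <- character(0)
  stage <- function(name, inputs = character(0)) {
    h <- if (length(inputs)) paste(sprintf("%s md5=%s", basename(inputs),
                                           unname(tools::md5sum(inputs))),
                                   collapse = "; ") else ""
    log <<- c(log, trimws(sprintf("[%s] %s", name, h)))
  }

  # --- data -----------------------------------------------------------
  if (is.null(config$design_csv) && is.null(config$responses_csv)) {
    study <- ber_study()
    data <- study$data
    stage("load", c(system.file("extdata", "table1_factors.csv", package = "bbdopt"),
                    system.file("extdata", "table2_runs.csv", package = "bbdopt")))
  } else {
    factors <- read_factors_csv(config$factors_csv)
    design <- read_design_csv(config$design_csv, factors)
    data <- read_responses_csv(config$responses_csv, design)
    stage("load", c(config$factors_csv, config$design_csv,
                    config$responses_csv))
  }

  # --- fits -----------------------------------------------------------
  fits <- list()
  for (r in names(config$models)) {
    m <- config$models[[r]]
    if (!r %in% names(data$responses))
      stop(sprintf("stage fit: response column '%s' not found", r),
           call. = FALSE)
    terms <- m$terms
    transform <- m$transform %||% "identity"
    if (identical(terms, "auto"))
      terms <- select_terms(data, r, transform)$terms
    fits[[r]] <- fit_rsm(data, r, unlist(terms), transform)
  }
  stage("fit")
  lof <- lapply(fits, lack_of_fit)
  effects <- lapply(fits, standardized_effects)
  stage("diagnostics")

  # --- optimization ---------------------------------------------------
  goals <- lapply(names(config$goals), function(r) {
    g <- config$goals[[r]]
    desirability_goal(r, g$direction, g$anchor_low, g$anchor_high,
                      g$weight %||% 1)
  })
  optimum <- optimize_desirability(fits, goals,
                                   resolution = config$resolution %||% 0.01)
  stage("optimize")

  # --- checkpoint validation ------------------------------------------
  validation <- NULL
  if (!is.null(config$checkpoint)) {
    cp <- config$checkpoint
    pt <- if (!is.null(cp$coded_point)) unlist(cp$coded_point)
    else if (!is.null(cp$actual_point)) {
      ap <- unlist(cp$actual_point)
      vapply(seq_len(3L), function(j)
        code_level(data$design$factors[[j]], ap[[j]]), numeric(1))
    } else optimum$coded_optimum
    validation <- validate_checkpoint(unlist(cp$measured), fits, pt)
    stage("validate")
  }

  out <- list(data = data, fits = fits, lof = lof, effects = effects,
              optimum = optimum, validation = validation)

  # --- reports --------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wj <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                              auto_unbox = TRUE, digits = NA,
                                              pretty = TRUE)
    write_design_csv(data$design, file.path(out_dir, "design.csv"))
    anova_tab <- do.call(rbind, lapply(names(fits), function(r) {
      a <- fits[[r]]$anova
      data.frame(response = r, model_ss = a$model_ss, model_df = a$model_df,
                 residual_ss = a$residual_ss, residual_df = a$residual_df,
                 lack_of_fit_ss = a$lack_of_fit_ss,
                 lack_of_fit_df = a$lack_of_fit_df,
                 pure_error_ss = a$pure_error_ss,
                 pure_error_df = a$pure_error_df,
                 lof_F = a$lof_F, lof_p = a$lof_p)
    }))
    utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    for (r in names(fits)) {
      f <- fits[[r]]
      wj(list(response = r, transform = f$transform, terms = f$terms,
              coefficients = as.list(f$coefficients),
              se = as.list(f$se), t = as.list(f$tstat),
              residual_df = f$residual_df, r2 = f$r2, anova = f$anova),
         sprintf("model_%s.json", r))
      utils::write.csv(effects[[r]], file.path(out_dir,
                                               sprintf("pareto_%s.csv", r)),
                       row.names = FALSE)
      pairs <- list(c("x1", "x2"), c("x1", "x3"), c("x2", "x3"))
      grids <- do.call(rbind, lapply(pairs, function(p) {
        g <- surface_grid(f, p, 0, 21)
        g$slice <- paste(p, collapse = "-")
        g
      }))
      utils::write.csv(grids, file.path(out_dir,
                                        sprintf("surface_%s.csv", r)),
                       row.names = FALSE)
    }
    wj(list(coded_optimum = as.list(optimum$coded_optimum),
            actual_optimum = as.list(optimum$actual_optimum),
            predicted = as.list(optimum$predicted),
            desirabilities = as.list(optimum$desirabilities),
            overall_D = optimum$overall_D),
       "optimization.json")
    if (!is.null(validation))
      wj(as.data.frame(validation), "validation.json")
    stage("report")
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  invisible(out)
}
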