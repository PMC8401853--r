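#' The berberine lecithin-chitosan nanoparticle formulation study
#'
#' Loads the worked dataset shipped with the package: a 17-run, 3-factor
#' Box-Behnken formulation study of berberine-loaded lecithin-chitosan
#' nanoparticles. Factors are lecithin amount (100/150/200 mg), chitosan
#' amount (10/25/40 mg) and isopropyl-myristate concentration (1/2/3 %
#' w/v); responses are particle size (PS, nm), zeta potential (ZP, mV) and
#' entrapment efficiency (EE, %), each a per-run mean with replicate SD.
#' A checkpoint formulation (the study optimum) with measured and
#' model-expected responses is included for validation.
#'
#' `ber_factors()` returns the three factor specifications;
#' `ber_study()` returns the full bundle; `ber_model_specs()` returns the
#' reduced model term sets used for the three responses (PS linear;
#' ln ZP linear + chitosan quadratic; EE linear + chitosan:IPM interaction
#' + IPM quadratic); `ber_truth_models()` returns simulation truth models
#' whose coefficients are the fitted study equations, with noise SDs at
#' typical replicate scale.
#'
#' @return `ber_study()`: a list with `data` (an [rsm_data()] whose design
#'   carries the published run order), `checkpoint` (list: `coded_optimum`,
#'   `actual_optimum`, `estimated`, `expected`, `error_pct`), and
#'   `run_order` (canonical-to-published permutation).
#' @examples
#' study <- ber_study()
#' fit <- fit_rsm(study$data, "PS", c("x1", "x2", "x3"))
#' round(coef(fit), 4)
#' @export
ber_study <- function() {
  ext <- function(f) system.file("extdata", f, package = "bbdopt",
                                 mustWork = TRUE)
  factors <- read_factors_csv(ext("table1_factors.csv"))
  runs <- utils::read.csv(ext("table2_runs.csv"), check.names = FALSE)
  nm <- vapply(factors, `[[`, character(1), "name")
  tab <- data.frame(run_id = runs$run_id)
  for (j in seq_along(nm)) {
    act <- runs[[paste0(nm[j], "_actual")]]
    tab[[paste0(nm[j], "_coded")]] <- code_level(factors[[j]], act)
    tab[[paste0(nm[j], "_actual")]] <- act
  }
  coded <- as.matrix(tab[, paste0(nm, "_coded")])
  design <- structure(list(factors = factors, runs = tab,
                           n_center = sum(rowSums(coded != 0) == 0L)),
                      class = "bbd_design")
  data <- rsm_data(design,
                   responses = runs[, c("PS_mean", "ZP_mean", "EE_mean")] |>
                     stats::setNames(c("PS", "ZP", "EE")),
                   sd = runs[, c("PS_sd", "ZP_sd", "EE_sd")] |>
                     stats::setNames(c("PS", "ZP", "EE")),
                   units = c(PS = "nm", ZP = "mV", EE = "%"))
  chk <- utils::read.csv(ext("table3_checkpoint.csv"), check.names = FALSE)
  pick <- function(kind) stats::setNames(chk$value[chk$kind == kind],
                                         chk$name[chk$kind == kind])
  actual_opt <- pick("factor")[nm]
  coded_opt <- vapply(seq_along(nm), function(j)
    code_level(factors[[j]], actual_opt[[j]]), numeric(1))
  names(coded_opt) <- c("x1", "x2", "x3")
  run_order <- utils::read.csv(ext("run_order_map.csv"), check.names = FALSE)
  list(data = data,
       checkpoint = list(coded_optimum = coded_opt,
                         actual_optimum = actual_opt,
                         estimated = pick("estimated"),
                         expected = pick("expected"),
                         error_pct = pick("error_pct")),
       run_order = run_order)
}

#' @rdname ber_study
#' @export
ber_factors <- function() {
  read_factors_csv(system.file("extdata", "table1_factors.csv",
                               package = "bbdopt", mustWork = TRUE))
}

#' @rdname ber_study
#' @export
ber_model_specs <- function() {
  list(PS = list(response = "PS", transform = "identity",
                 terms = c("x1", "x2", "x3")),
       ZP = list(response = "ZP", transform = "ln",
                 terms = c("x1", "x2", "x3", "x2^2")),
       EE = list(response = "EE", transform = "identity",
                 terms = c("x1", "x2", "x3", "x2:x3", "x3^2")))
}

#' @rdname ber_study
#' @param noise_sd Named numeric vector of per-response noise SDs on the
#'   transform scale. Defaults are typical replicate SDs of the study
#'   responses: 6 nm for PS, 0.04 ln-units for ln ZP, 4 percentage points
#'   for EE.
#' @export
ber_truth_models <- function(noise_sd = c(PS = 6, ZP = 0.04, EE = 4)) {
  study <- ber_study()
  specs <- ber_model_specs()
  lapply(specs, function(s) {
    fit <- fit_rsm(study$data, s$response, s$terms, s$transform)
    truth_model(s$response, coef(fit), transform = s$transform,
                noise_sd = unname(noise_sd[s$response]))
  })
}
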