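#' Entrapment efficiency
#'
#' Percentage of drug incorporated in the nanoparticles, determined
#' indirectly from the free (unentrapped) drug:
#' `EE% = (total - free) / total * 100`.
#'
#' @param total_drug Total drug used in the formulation (mass, > 0).
#' @param free_drug Free drug measured in the supernatant (same units,
#'   `0 <= free <= total`).
#' @return Entrapment efficiency in percent.
#' @examples
#' entrapment_efficiency(10, 1.77)  # 82.3
#' @export
entrapment_efficiency <- function(total_drug, free_drug) {
  if (any(total_drug <= 0))
    stop("total_drug must be positive", call. = FALSE)
  if (any(free_drug < 0) || any(free_drug > total_drug))
    stop("free_drug must lie in [0, total_drug]", call. = FALSE)
  (total_drug - free_drug) / total_drug * 100
}

#' Define an in-vitro release profile
#'
#' Receptor-compartment concentrations sampled over time in a diffusion
#' (Franz) cell where each sample is replaced by fresh medium. `dose` is
#' the drug originally loaded in the donor compartment.
#'
#' @param times Sampling times (hours), strictly increasing.
#' @param sampled_conc Measured receptor concentrations at those times
#'   (mass/volume, >= 0).
#' @param receptor_volume Receptor compartment volume (mL).
#' @param sample_volume Withdrawn sample volume (mL, < receptor volume).
#' @param dose Drug originally loaded (mg).
#' @return An object of class `release_profile`.
#' @export
release_profile <- function(times, sampled_conc, receptor_volume,
                            sample_volume, dose) {
  if (length(times) != length(sampled_conc))
    stop("'times' and 'sampled_conc' must have the same length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(sampled_conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (!(sample_volume < receptor_volume))
    stop("sample_volume must be smaller than receptor_volume", call. = FALSE)
  if (dose <= 0) stop("dose must be positive", call. = FALSE)
  structure(list(times = times, sampled_conc = sampled_conc,
                 receptor_volume = receptor_volume,
                 sample_volume = sample_volume, dose = dose),
            class = "release_profile")
}

#' Cumulative drug release percentage
#'
#' At each sampling time the cumulative released mass is
#' `Q_i = C_i * V_receptor`; the release percentage is `Q_i / dose * 100`.
#' With `correct_sampling = TRUE`, `Q_i` additionally accumulates the drug
#' removed in all earlier samples (`V_sample * C_j` for every j < i),
#' compensating for the mass withdrawn and replaced with fresh medium;
#' the corrected series is non-decreasing for non-negative concentration
#' profiles. The uncorrected form is the conventional direct reading of
#' the sampled concentration.
#'
#' @param profile A [release_profile()].
#' @param correct_sampling Apply the sampling-loss correction (default
#'   FALSE).
#' @param tolerance Slack (percentage points) above 100 before an input is
#'   declared inconsistent (default 0.01).
#' @return Numeric vector of release percentages, one per sampling time.
#' @export
cumulative_release <- function(profile, correct_sampling = FALSE,
                               tolerance = 0.01) {
  stopifnot(inherits(profile, "release_profile"))
  Qi <- profile$sampled_conc * profile$receptor_volume
  if (correct_sampling) {
    removed <- profile$sample_volume *
      c(0, cumsum(profile$sampled_conc)[-length(profile$sampled_conc)])
    Qi <- Qi + removed
  }
  pct <- Qi / profile$dose * 100
  if (any(pct > 100 + tolerance))
    stop("release exceeds 100% of the dose: inconsistent profile inputs",
         call. = FALSE)
  pct
}

#' Define a wound-area time series
#'
#' @param day Integer days post wounding; day 0 (the initial area) must be
#'   present.
#' @param area Wound areas (mm^2, >= 0), one per day.
#' @return An object of class `wound_series`.
#' @export
wound_series <- function(day, area) {
  if (length(day) != length(area))
    stop("'day' and 'area' must have the same length", call. = FALSE)
  day <- as.integer(day)
  if (!0L %in% day)
    stop("day 0 (initial wound area) must be present", call. = FALSE)
  if (any(area < 0))
    stop("wound areas must be non-negative", call. = FALSE)
  if (anyDuplicated(day))
    stop("duplicated days in the series", call. = FALSE)
  structure(list(day = day, area = area), class = "wound_series")
}

#' Wound closure rate
#'
#' Percentage reduction of the wound area relative to day 0:
#' `(W_0 - W_t) / W_0 * 100`.
#'
#' @param series A [wound_series()].
#' @param t Day at which to evaluate closure (must be present in the
#'   series).
#' @return Closure rate in percent.
#' @examples
#' ws <- wound_series(c(0, 7), c(100, 25))
#' wound_closure_rate(ws, 7)  # 75
#' @export
wound_closure_rate <- function(series, t) {
  stopifnot(inherits(series, "wound_series"))
  w0 <- series$area[series$day == 0L]
  if (w0 == 0) stop("initial wound area is 0; closure rate undefined",
                    call. = FALSE)
  i <- match(as.integer(t), series$day)
  if (is.na(i)) stop(sprintf("day %s is not present in the series", t),
                     call. = FALSE)
  (w0 - series$area[i]) / w0 * 100
}
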