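#' Instrument level to extract concentration
#'
#' Converts a detected instrument level (ng/mL of injected extract) to a
#' concentration in the sampled material (ng/g):
#' `concentration = level x dilution x volume / weight`. The dilution
#' factor models re-analysis of extracts diluted back into the calibration
#' range, which scales the observed level linearly.
#'
#' @param level_ng_per_ml Detected level, ng/mL (non-negative).
#' @param volume_ml Extraction solvent volume, mL (positive).
#' @param weight_g Sample aliquot weight, g (positive).
#' @param dilution Dilution factor applied before re-injection (>= 1).
#' @return Concentration in ng/g.
#' @examples
#' concentration_from_level(100, 25, 0.25)  # 10000 ng/g
#' @export
concentration_from_level <- function(level_ng_per_ml, volume_ml, weight_g,
                                     dilution = 1) {
  if (any(level_ng_per_ml < 0, na.rm = TRUE)) abort("detected level must be non-negative")
  if (any(volume_ml <= 0) || any(weight_g <= 0)) {
    abort("extract volume and sample weight must be positive")
  }
  if (any(dilution < 1)) abort("dilution factor must be >= 1")
  level_ng_per_ml * dilution * volume_ml / weight_g
}

#' Extract concentration to per-cigarette content
#'
#' `content (ug/cigarette) = concentration (ng/g) x weight (g) / 1000`.
#' Composed with [concentration_from_level()], the aliquot weight cancels:
#' content depends only on level x dilution x volume.
#'
#' @param concentration_ng_per_g Concentration, ng/g (non-negative).
#' @param weight_g Sample aliquot weight, g (positive).
#' @return Content in ug per cigarette part.
#' @export
content_from_concentration <- function(concentration_ng_per_g, weight_g) {
  if (any(concentration_ng_per_g < 0, na.rm = TRUE)) {
    abort("concentration must be non-negative")
  }
  if (any(weight_g <= 0)) abort("sample weight must be positive")
  concentration_ng_per_g * weight_g / 1000
}

#' Convert quantification records to per-part contents
#'
#' Applies the level-to-concentration and concentration-to-content
#' conversions to each quantified record. Below-LOQ records are censored:
#' they carry the LOQ-equivalent content (LOQ x extraction volume / 1000,
#' at dilution 1), the value later used by the substitution policy.
#' Non-detects carry zero content.
#'
#' @param records Quantification records, see [read_quant_table()].
#' @param limits Detection limits, see [flav_detection_limits()].
#' @return A tibble of content records: one row per record with
#'   `concentration_ng_per_g`, `content_ug_per_cigarette`, `censored`,
#'   and the carried-through `status`.
#' @export
quantify_contents <- function(records, limits = flav_detection_limits()) {
  lim <- limits_for(records$compound, records$part, limits)
  conc <- ifelse(records$status == "quantified",
                 concentration_from_level(
                   ifelse(is.na(records$detected_level_ng_per_ml), 0,
                          records$detected_level_ng_per_ml),
                   records$extract_volume_ml, records$sample_weight_g,
                   records$dilution_factor),
                 ifelse(records$status == "below_loq",
                        lim$loq_ng_per_ml * records$extract_volume_ml /
                          records$sample_weight_g,
                        0))
  tibble::tibble(
    cigarette_id = records$cigarette_id,
    has_capsule = records$has_capsule,
    part = records$part,
    capsule_index = records$capsule_index,
    compound = records$compound,
    status = records$status,
    concentration_ng_per_g = conc,
    content_ug_per_cigarette = content_from_concentration(conc, records$sample_weight_g),
    censored = records$status != "quantified"
  )
}

#' Fit a calibration curve
#'
#' Ordinary least-squares line through calibration points, with the
#' acceptance gate R^2 > 0.999 used to confirm linearity of the method.
#'
#' @param levels_ng_per_ml Calibration levels, ng/mL (>= 3 distinct values).
#' @param responses Instrument responses (peak areas), same length.
#' @param r2_gate Linearity acceptance threshold on R^2.
#' @return A list of class `flav_calibration`: `slope`, `intercept`,
#'   `r_squared`, `passes_linearity`, plus the input points.
#' @export
fit_calibration <- function(levels_ng_per_ml, responses, r2_gate = 0.999) {
  if (length(levels_ng_per_ml) != length(responses)) {
    abort("levels and responses must have equal length")
  }
  if (length(unique(levels_ng_per_ml)) < 3) {
    abort("need at least 3 distinct calibration levels")
  }
  if (any(levels_ng_per_ml <= 0)) abort("calibration levels must be positive")
  if (sd(responses) == 0) abort("degenerate fit: constant responses")
  fit <- lm(responses ~ levels_ng_per_ml)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    passes_linearity = r2 > r2_gate,
    levels_ng_per_ml = levels_ng_per_ml,
    responses = responses
  ), class = "flav_calibration")
}

#' @export
print.flav_calibration <- function(x, ...) {
  cat(sprintf("Calibration: response = %.6g + %.6g x level, R^2 = %.6f (%s)\n",
              x$intercept, x$slope, x$r_squared,
              if (x$passes_linearity) "linear" else "FAILS linearity gate"))
  invisible(x)
}

#' Detection and quantification limits from baseline noise
#'
#' Under the signal-to-noise definition the LOD is the level giving S/N 3
#' and the LOQ the level giving S/N 10: `lod = 3 x noise / slope`,
#' `loq = 10 x noise / slope`, so LOQ/LOD = 10/3 always. Applied to a
#' spiked blank matrix, the same computation yields the method detection
#' limit (MDL).
#'
#' @param noise Baseline noise in response units (positive scalar, e.g.
#'   RMS of the blank baseline).
#' @param slope Calibration slope, response units per ng/mL (positive).
#' @return A list with `lod_ng_per_ml` and `loq_ng_per_ml`.
#' @export
lod_loq_from_noise <- function(noise, slope) {
  if (any(noise <= 0) || any(slope <= 0)) abort("noise and slope must be positive")
  list(lod_ng_per_ml = 3 * noise / slope, loq_ng_per_ml = 10 * noise / slope)
}

#' Spike recovery
#'
#' Accuracy metric of the method: measured over spiked concentration,
#' as a percentage.
#'
#' @param measured Measured concentration (any unit).
#' @param spiked Nominal spiked concentration (same unit, positive).
#' @return Recovery in percent.
#' @export
recovery_pct <- function(measured, spiked) {
  if (any(spiked <= 0)) abort("spiked concentration must be positive")
  if (any(measured < 0)) abort("measured concentration must be non-negative")
  100 * measured / spiked
}

#' Relative standard deviation
#'
#' Precision metric: sample standard deviation over the mean, in percent.
#'
#' @param values Replicate measurements (length >= 2, nonzero mean).
#' @return RSD in percent.
#' @export
rsd_pct <- function(values) {
  if (length(values) < 2) abort("need at least 2 replicates")
  m <- mean(values)
  if (m == 0) abort("mean of replicates is zero; RSD undefined")
  100 * sd(values) / m
}

#' Regulatory unit conversion: mg/kg to percent by mass
#'
#' `1 mg/kg = 1e-4 %`. Used to compare capsule concentrations against
#' mass-percent restriction limits for leave-on cosmetic products
#' (0.0002 %).
#'
#' @param conc_mg_per_kg Concentration in mg/kg (non-negative).
#' @return Concentration in percent by mass.
#' @examples
#' mg_per_kg_to_pct(15)  # 0.0015 %
#' @export
mg_per_kg_to_pct <- function(conc_mg_per_kg) {
  if (any(conc_mg_per_kg < 0)) abort("concentration must be non-negative")
  conc_mg_per_kg / 10000
}

#' @rdname mg_per_kg_to_pct
#' @param pct Concentration in percent by mass.
#' @param limit_pct Restriction limit in percent (default: the 0.0002 %
#'   leave-on product limit).
#' @return `exceeds_leave_on_limit()`: logical.
#' @export
exceeds_leave_on_limit <- function(pct, limit_pct = 0.0002) {
  pct > limit_pct
}

#' Method-validation summary for a spiked-replicate fixture
#'
#' Computes per-compound, per-matrix, per-level recovery (from mean
#' measured vs nominal) and RSD across replicates, with the standard
#' acceptance gates (recovery within band, RSD below threshold).
#'
#' @param fixture Tibble with columns `compound`, `matrix`,
#'   `spike_ug_per_g`, `replicate`, `measured_ug_per_g`
#'   (see [generate_validation_fixture()]).
#' @param recovery_band Acceptable recovery range in percent.
#' @param rsd_gate Maximum acceptable RSD in percent.
#' @return Tibble with one row per compound x matrix x spike level.
#' @export
validate_method <- function(fixture, recovery_band = c(70, 120), rsd_gate = 10) {
  fixture |>
    dplyr::group_by(.data$compound, .data$matrix, .data$spike_ug_per_g) |>
    dplyr::summarise(
      n = dplyr::n(),
      recovery_pct = recovery_pct(mean(.data$measured_ug_per_g),
                                  .data$spike_ug_per_g[1]),
      rsd_pct = rsd_pct(.data$measured_ug_per_g),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      passes_recovery = .data$recovery_pct >= recovery_band[1] &
        .data$recovery_pct <= recovery_band[2],
      passes_rsd = .data$rsd_pct < rsd_gate
    )
}
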