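#' Exposure parameters for lifetime smoking inhalation
#'
#' Parameter set of the inhalation exposure-concentration model
#' `EC = C x N x ED x EF / (IR x AT)`. The exposure duration ED is derived
#' as life expectancy minus smoking-onset age, and the averaging time AT
#' as ED x 365 days/year, so ED x EF / AT = 1 when EF is 365 days/year.
#' Defaults are the Korean-population values used in the survey this
#' package models: life expectancy 82.7 y, onset age 13.2 y (hence
#' ED = 69.5 y, AT = 25,367.5 d), 13.2 cigarettes/day, inhalation rate
#' 14.25 m3/day, exposure on 365 days/year.
#'
#' @param life_expectancy_years Life expectancy, years.
#' @param smoking_onset_age_years Age at smoking onset, years (must be
#'   below life expectancy).
#' @param n_cigs_per_day Average cigarettes smoked per day (N).
#' @param inhalation_rate_m3_per_day Daily inhalation rate (IR), m3/day.
#' @param exposure_frequency_days_per_year Exposure frequency (EF),
#'   days/year.
#' @return An object of class `flav_exposure_params` with the inputs plus
#'   the derived `exposure_duration_years` (ED) and `averaging_time_days`
#'   (AT).
#' @examples
#' p <- exposure_params()
#' p$exposure_duration_years  # 69.5
#' p$averaging_time_days      # 25367.5
#' @export
exposure_params <- function(life_expectancy_years = 82.7,
                            smoking_onset_age_years = 13.2,
                            n_cigs_per_day = 13.2,
                            inhalation_rate_m3_per_day = 14.25,
                            exposure_frequency_days_per_year = 365) {
  if (smoking_onset_age_years < 0) abort("onset age must be non-negative")
  if (smoking_onset_age_years >= life_expectancy_years) {
    abort("smoking onset age must be below life expectancy")
  }
  if (n_cigs_per_day <= 0 || inhalation_rate_m3_per_day <= 0 ||
      exposure_frequency_days_per_year <= 0) {
    abort("N, IR and EF must be positive")
  }
  ed <- life_expectancy_years - smoking_onset_age_years
  structure(list(
    life_expectancy_years = life_expectancy_years,
    smoking_onset_age_years = smoking_onset_age_years,
    n_cigs_per_day = n_cigs_per_day,
    inhalation_rate_m3_per_day = inhalation_rate_m3_per_day,
    exposure_frequency_days_per_year = exposure_frequency_days_per_year,
    exposure_duration_years = ed,
    averaging_time_days = ed * 365
  ), class = "flav_exposure_params")
}

#' @export
print.flav_exposure_params <- function(x, ...) {
  cat(sprintf(
    "Inhalation exposure parameters:\n  N  = %g cigarettes/day\n  ED = %g years (life expectancy %g - onset %g)\n  EF = %g days/year\n  IR = %g m3/day\n  AT = %g days\n",
    x$n_cigs_per_day, x$exposure_duration_years, x$life_expectancy_years,
    x$smoking_onset_age_years, x$exposure_frequency_days_per_year,
    x$inhalation_rate_m3_per_day, x$averaging_time_days))
  invisible(x)
}

#' Substitute censored content records
#'
#' Applies the censoring policy used for exposure estimation: records
#' detected below the LOQ are set to the LOQ-equivalent content
#' (LOQ ng/mL x extraction volume / 1000, at dilution 1); non-detects
#' contribute zero; quantified records pass through unchanged. Compounds
#' never detected in any product are flagged `excluded_from_exposure` and
#' dropped from downstream risk characterization.
#'
#' @param contents Content records, see [quantify_contents()].
#' @param limits Detection limits, see [flav_detection_limits()].
#' @param volume_ml_by_part Named extraction volumes (mL) used to convert
#'   an LOQ in ng/mL of extract to a per-part content.
#' @return The content records with substituted
#'   `content_ug_per_cigarette` and a logical `excluded_from_exposure`
#'   column.
#' @export
substitute_censored <- function(contents, limits = flav_detection_limits(),
                                volume_ml_by_part = c(tobacco = 25,
                                                      filter_tip = 25,
                                                      capsule = 10)) {
  lim <- limits_for(contents$compound, contents$part, limits)
  is_cens <- contents$status == "below_loq"
  if (any(is_cens & is.na(lim$loq_ng_per_ml))) {
    abort("censored record without a configured LOQ")
  }
  vol <- unname(volume_ml_by_part[contents$part])
  contents$content_ug_per_cigarette <- ifelse(
    is_cens, lim$loq_ng_per_ml * vol / 1000,
    ifelse(contents$status == "not_detected", 0,
           contents$content_ug_per_cigarette))
  detected_somewhere <- contents |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(any_det = any(.data$status != "not_detected"),
                     .groups = "drop")
  contents$excluded_from_exposure <-
    !detected_somewhere$any_det[match(contents$compound, detected_somewhere$compound)]
  contents
}

#' Per-cigarette total content
#'
#' Sums the content of a compound over the parts separated from one
#' cigarette: tobacco + filter tip + every capsule (cigarettes holding
#' two capsules sum both). All cigarettes present in the records are kept,
#' including those in which the compound was never detected (total 0), so
#' the caller can choose the averaging denominator.
#'
#' @param contents Substituted content records, see
#'   [substitute_censored()].
#' @return Tibble with one row per compound x cigarette: `total_ug`,
#'   `detected` (any part quantified or below-LOQ), `has_capsule`.
#' @export
per_cigarette_totals <- function(contents) {
  key <- paste(contents$cigarette_id, contents$part,
               ifelse(is.na(contents$capsule_index), 0, contents$capsule_index),
               contents$compound)
  if (anyDuplicated(key)) {
    abort("duplicate (cigarette, part, capsule_index, compound) rows")
  }
  contents |>
    dplyr::group_by(.data$compound, .data$cigarette_id) |>
    dplyr::summarise(total_ug = sum(.data$content_ug_per_cigarette),
                     detected = any(.data$status != "not_detected"),
                     has_capsule = .data$has_capsule[1],
                     .groups = "drop")
}

#' Average or maximum per-cigarette content
#'
#' The maximum is taken over all cigarettes. The average is taken either
#' over cigarettes in which the compound was detected (the default,
#' matching detected-only summary semantics) or over all cigarettes
#' surveyed; under the latter, non-detecting cigarettes enter the
#' denominator with total 0, so the two averages differ exactly by the
#' factor n_detected / n_all.
#'
#' @param totals Per-cigarette totals in ug (numeric vector).
#' @param stat `"average"` or `"maximum"`.
#' @param detected Logical vector flagging cigarettes in which the
#'   compound was detected.
#' @param denominator `"detected_cigarettes"` or `"all_cigarettes"`.
#' @return A single content value in ug/cigarette (`NA` if no cigarette
#'   detected the compound and the detected denominator is requested).
#' @export
content_stat <- function(totals, stat = c("average", "maximum"),
                         detected = rep(TRUE, length(totals)),
                         denominator = c("detected_cigarettes", "all_cigarettes")) {
  stat <- match.arg(stat)
  denominator <- match.arg(denominator)
  if (!length(totals)) abort("no per-cigarette totals supplied")
  if (stat == "maximum") return(max(totals))
  if (denominator == "all_cigarettes") return(sum(totals[detected]) / length(totals))
  if (!any(detected)) return(NA_real_)
  mean(totals[detected])
}

#' Inhalation exposure concentration
#'
#' `EC (mg/m3) = C x N x ED x EF / (IR x AT) / 1000`, with C the content
#' in ug/cigarette; the division by 1000 converts ug to mg. AT is carried
#' in days so that ED x EF / AT is dimensionless (and equals 1 under the
#' default EF of 365 days/year). The model assumes complete transfer of
#' the flavoring agent from the cigarette to the smoker (no combustion
#' loss, mouth spill, or filter retention), a deliberately conservative
#' bound.
#'
#' @param content_ug_per_cigarette Content C, ug/cigarette (non-negative).
#' @param params Exposure parameters, see [exposure_params()].
#' @return Exposure concentration in mg/m3.
#' @examples
#' exposure_concentration(1565.01, exposure_params())  # 1.44969 mg/m3
#' @export
exposure_concentration <- function(content_ug_per_cigarette,
                                   params = exposure_params()) {
  stopifnot(inherits(params, "flav_exposure_params"))
  if (any(content_ug_per_cigarette < 0, na.rm = TRUE)) {
    abort("content must be non-negative")
  }
  content_ug_per_cigarette * params$n_cigs_per_day *
    params$exposure_duration_years * params$exposure_frequency_days_per_year /
    (params$inhalation_rate_m3_per_day * params$averaging_time_days) / 1000
}

#' Risk characterization ratio
#'
#' RCR = exposure concentration / DNEL. RCR < 1 indicates controlled
#' risk; RCR > 0.1 (one tenth of the DNEL) is flagged as warranting
#' attention.
#'
#' @param exposure_mg_per_m3 Exposure concentration, mg/m3.
#' @param dnel_mg_per_m3 Derived no-effect level, mg/m3 (positive).
#' @return Tibble with `rcr`, `attention` (RCR > 0.1) and `exceeds`
#'   (RCR > 1).
#' @export
risk_characterization <- function(exposure_mg_per_m3, dnel_mg_per_m3) {
  if (any(is.na(dnel_mg_per_m3)) || any(dnel_mg_per_m3 <= 0)) {
    abort("DNEL must be present and positive")
  }
  rcr <- exposure_mg_per_m3 / dnel_mg_per_m3
  tibble::tibble(rcr = rcr, attention = rcr > 0.1, exceeds = rcr > 1)
}

#' Risk table from per-compound contents
#'
#' Direct entry point for risk characterization when compound-level
#' contents (ug/cigarette) are already available, e.g. published summary
#' values. Compounds without a DNEL are skipped with a notice.
#'
#' @param content_tbl Tibble with columns `compound`, `stat`
#'   (`"average"`/`"maximum"`) and `content_ug_per_cigarette`.
#' @param params Exposure parameters, see [exposure_params()].
#' @param compounds Compound reference carrying DNELs.
#' @return Risk-row tibble: `compound`, `stat`, `content_ug_per_cigarette`,
#'   `exposure_mg_per_m3`, `dnel_mg_per_m3`, `rcr`, `attention`, `exceeds`.
#' @export
risk_from_content <- function(content_tbl, params = exposure_params(),
                              compounds = flav_compounds()) {
  stopifnot(all(c("compound", "stat", "content_ug_per_cigarette") %in%
                  names(content_tbl)))
  unknown <- setdiff(content_tbl$compound, compounds$name)
  if (length(unknown)) {
    abort(paste0("unknown compound(s): ", paste(unknown, collapse = ", ")))
  }
  dnel <- compounds$dnel_mg_per_m3[match(content_tbl$compound, compounds$name)]
  skip <- is.na(dnel)
  if (any(skip)) {
    inform(paste0("skipping compound(s) without DNEL: ",
                  paste(unique(content_tbl$compound[skip]), collapse = ", ")))
  }
  out <- content_tbl[!skip, c("compound", "stat", "content_ug_per_cigarette")]
  out$exposure_mg_per_m3 <- exposure_concentration(
    out$content_ug_per_cigarette, params)
  out$dnel_mg_per_m3 <- dnel[!skip]
  cbind_risk <- risk_characterization(out$exposure_mg_per_m3, out$dnel_mg_per_m3)
  dplyr::bind_cols(tibble::as_tibble(out), cbind_risk)
}

#' Full risk table from content records
#'
#' The headline pipeline: censoring substitution, per-cigarette totals,
#' average and maximum content per compound, exposure concentration, and
#' RCR against the DNEL. Compounds never detected in any product, and
#' compounds without a DNEL, are excluded.
#'
#' @param contents Content records, see [quantify_contents()].
#' @param params Exposure parameters.
#' @param compounds Compound reference carrying DNELs.
#' @param limits Detection limits (for censoring substitution).
#' @param denominator Averaging denominator, see [content_stat()].
#' @return Risk-row tibble as in [risk_from_content()], one average and
#'   one maximum row per retained compound.
#' @export
build_risk_table <- function(contents, params = exposure_params(),
                             compounds = flav_compounds(),
                             limits = flav_detection_limits(),
                             denominator = c("detected_cigarettes",
                                             "all_cigarettes")) {
  denominator <- match.arg(denominator)
  subst <- substitute_censored(contents, limits)
  subst <- subst[!subst$excluded_from_exposure, , drop = FALSE]
  if (!nrow(subst)) {
    return(tibble::tibble(compound = character(), stat = character(),
                          content_ug_per_cigarette = double(),
                          exposure_mg_per_m3 = double(),
                          dnel_mg_per_m3 = double(), rcr = double(),
                          attention = logical(), exceeds = logical()))
  }
  totals <- per_cigarette_totals(subst)
  stats_tbl <- totals |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      average = content_stat(.data$total_ug, "average", .data$detected,
                             denominator),
      maximum = content_stat(.data$total_ug, "maximum"),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("average", "maximum"), names_to = "stat",
                        values_to = "content_ug_per_cigarette")
  risk_from_content(stats_tbl, params, compounds)
}

#' Render a risk table for reporting
#'
#' Formats exposures to 5 decimal places and RCRs to 2 significant
#' figures in scientific notation, the conventional precision of
#' published risk-characterization tables.
#'
#' @param risk_tbl Risk rows, see [build_risk_table()].
#' @return Tibble with character columns `exposure_mg_per_m3` and `rcr`.
#' @export
render_risk_table <- function(risk_tbl) {
  risk_tbl |>
    dplyr::mutate(
      exposure_mg_per_m3 = sprintf("%.5f", .data$exposure_mg_per_m3),
      rcr = format_rcr(.data$rcr)
    )
}

#' @rdname render_risk_table
#' @param x Numeric RCR values.
#' @export
format_rcr <- function(x) {
  formatC(x, format = "e", digits = 1)
}
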