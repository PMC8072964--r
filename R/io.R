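#' Read a per-part quantification table
#'
#' Reads instrument-side measurements, one row per
#' (cigarette, part, capsule, compound): the detected level in ng/mL of
#' extract (absent for non-detects), the dilution factor applied on
#' re-analysis, the extraction volume and the sample aliquot weight.
#' Rows are validated against the compound reference and the per-matrix
#' detection limits; the censoring status (`quantified`, `below_loq`,
#' `not_detected`) is checked when supplied and derived from the level
#' versus LOD/LOQ when the column is absent.
#'
#' @param path CSV file. Required columns: `cigarette_id`, `has_capsule`,
#'   `part`, `capsule_index`, `compound`, `detected_level_ng_per_ml`,
#'   `dilution_factor`, `extract_volume_ml`, `sample_weight_g`; optional:
#'   `status`.
#' @param compounds Compound reference, see [flav_compounds()].
#' @param limits Detection limits, see [flav_detection_limits()].
#' @return A tibble of validated quantification records with a `status`
#'   column.
#' @export
read_quant_table <- function(path, compounds = flav_compounds(),
                             limits = flav_detection_limits()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  required <- c("cigarette_id", "has_capsule", "part", "capsule_index",
                "compound", "detected_level_ng_per_ml", "dilution_factor",
                "extract_volume_ml", "sample_weight_g")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("quant table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("cigarette_id", "part", "compound")) {
    tbl[[col]] <- as.character(tbl[[col]])
  }
  tbl$capsule_index <- as.integer(tbl$capsule_index)
  tbl$has_capsule <- as.logical(tbl$has_capsule)
  tbl$detected_level_ng_per_ml <- as.numeric(tbl$detected_level_ng_per_ml)
  validate_quant_records(tbl, compounds, limits)
}

# shared validator; `line` reporting assumes a single header line
validate_quant_records <- function(tbl, compounds, limits) {
  line <- seq_len(nrow(tbl)) + 1L
  fail <- function(which, msg) {
    abort(paste0(msg, " (line ", paste(line[which][1], collapse = ", "), ")"))
  }
  unknown <- !(tbl$compound %in% compounds$name)
  if (any(unknown)) {
    fail(unknown, paste0("unknown compound '", tbl$compound[unknown][1], "'"))
  }
  bad_part <- !(tbl$part %in% .parts)
  if (any(bad_part)) fail(bad_part, paste0("invalid part '", tbl$part[bad_part][1], "'"))
  neg <- !is.na(tbl$detected_level_ng_per_ml) & tbl$detected_level_ng_per_ml < 0
  if (any(neg)) fail(neg, "negative detected level")
  no_idx <- tbl$part == "capsule" & is.na(tbl$capsule_index)
  if (any(no_idx)) fail(no_idx, "capsule row without capsule_index")
  stray_idx <- tbl$part != "capsule" & !is.na(tbl$capsule_index)
  if (any(stray_idx)) fail(stray_idx, "capsule_index on a non-capsule row")
  bad_idx <- !is.na(tbl$capsule_index) & tbl$capsule_index < 1L
  if (any(bad_idx)) fail(bad_idx, "capsule_index must be >= 1")
  capsule_on_noncap <- tbl$part == "capsule" & !tbl$has_capsule
  if (any(capsule_on_noncap)) fail(capsule_on_noncap, "capsule part on a non-capsule cigarette")
  if (any(tbl$dilution_factor < 1, na.rm = TRUE)) {
    fail(tbl$dilution_factor < 1, "dilution_factor must be >= 1")
  }
  if (any(tbl$extract_volume_ml <= 0 | tbl$sample_weight_g <= 0, na.rm = TRUE)) {
    fail(tbl$extract_volume_ml <= 0 | tbl$sample_weight_g <= 0,
         "extract volume and sample weight must be positive")
  }
  lim <- limits_for(tbl$compound, tbl$part, limits)
  if (anyNA(lim$loq_ng_per_ml)) {
    fail(is.na(lim$loq_ng_per_ml), "no detection limits configured for compound/matrix")
  }
  derived <- derive_status(tbl$detected_level_ng_per_ml, lim$lod_ng_per_ml,
                           lim$loq_ng_per_ml)
  if ("status" %in% names(tbl)) {
    bad_status <- !(tbl$status %in% .statuses)
    if (any(bad_status)) fail(bad_status, "invalid status literal")
    mismatch <- tbl$status != derived
    if (any(mismatch)) {
      fail(mismatch, paste0("status '", tbl$status[mismatch][1],
                            "' inconsistent with detected level vs LOD/LOQ"))
    }
  } else {
    tbl$status <- derived
  }
  tibble::as_tibble(tbl)
}

derive_status <- function(level, lod, loq) {
  ifelse(is.na(level) | level < lod, "not_detected",
         ifelse(level < loq, "below_loq", "quantified"))
}

#' Write and read report tables
#'
#' Plain-CSV writers/readers for the package's tabular outputs (summaries,
#' test results, risk tables, quantification records). Values round-trip
#' losslessly: numbers are written at full precision.
#'
#' @param x A data frame.
#' @param path Destination (or source) CSV path.
#' @return `write_report_table()` returns `path` invisibly;
#'   `read_report_table()` returns a tibble.
#' @export
write_report_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read an exposure-parameter configuration
#'
#' YAML or JSON file with keys `life_expectancy_years`,
#' `smoking_onset_age_years`, `n_cigs_per_day`, `inhalation_rate_m3_per_day`,
#' `exposure_frequency_days_per_year`. Missing keys fall back to the
#' package defaults (see [exposure_params()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ExposureParams` list, see [exposure_params()].
#' @export
read_exposure_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- formals(exposure_params)
  known <- names(defaults)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown exposure-config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- utils::modifyList(lapply(defaults, eval), cfg)
  do.call(exposure_params, args)
}
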