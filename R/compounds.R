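#' Validate CAS Registry Numbers
#'
#' A CAS RN has the form `NN...NN-NN-N`; the final digit is a checksum:
#' the preceding digits, weighted 1, 2, 3, ... from the right, sum to the
#' check digit modulo 10.
#'
#' @param cas Character vector of candidate CAS RNs.
#' @return Logical vector, `TRUE` where the format and check digit are valid.
#' @examples
#' cas_is_valid(c("89-78-1", "89-78-2", "not-a-cas"))
#' @export
cas_is_valid <- function(cas) {
  ok_format <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  vapply(seq_along(cas), function(i) {
    if (is.na(cas[i]) || !ok_format[i]) return(FALSE)
    d <- as.integer(strsplit(gsub("-", "", cas[i]), "")[[1]])
    n <- length(d)
    sum(d[-n] * ((n - 1):1)) %% 10 == d[n]
  }, logical(1))
}

#' Bundled allergenic-flavoring-agent reference table
#'
#' The 25 allergenic flavoring agents restricted for use in food, cosmetics
#' or toys in Europe, plus menthol, with CAS RN and the long-term systemic
#' inhalation DNEL (derived no-effect level, general population, mg/m3)
#' where one exists. Compounds without a DNEL are excluded from risk
#' characterization.
#'
#' @param file Optional path to a user-supplied CSV with columns
#'   `name,cas_rn,dnel_mg_per_m3`; defaults to the bundled table.
#' @return A tibble with columns `name`, `cas_rn`, `dnel_mg_per_m3`.
#' @export
flav_compounds <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "compound_reference.csv", package = "flavrisk")
  }
  tbl <- readr::read_csv(file, show_col_types = FALSE,
                         col_types = readr::cols(
                           name = readr::col_character(),
                           cas_rn = readr::col_character(),
                           dnel_mg_per_m3 = readr::col_double()
                         ))
  if (anyDuplicated(tbl$cas_rn)) {
    abort("compound reference table contains duplicated CAS RNs")
  }
  if (anyDuplicated(tbl$name)) {
    abort("compound reference table contains duplicated compound names")
  }
  bad <- !cas_is_valid(tbl$cas_rn)
  if (any(bad)) {
    abort(paste0("invalid CAS RN in compound table: ",
                 paste(tbl$cas_rn[bad], collapse = ", ")))
  }
  if (any(!is.na(tbl$dnel_mg_per_m3) & tbl$dnel_mg_per_m3 <= 0)) {
    abort("DNEL values must be positive where present")
  }
  tbl
}

#' Per-matrix detection and quantification limits
#'
#' Limits of detection (signal-to-noise 3) and quantification
#' (signal-to-noise 10) per compound and validation matrix. Capsule
#' extracts are quantified against the solvent limits. The bundled values
#' are synthetic: representative per-compound limits spread across the
#' validated per-matrix ranges (solvent LOD 0.12-5.59 ng/mL, tobacco
#' 0.49-7.81 ng/mL, filter tip 0.49-5.59 ng/mL), since per-compound limits
#' are instrument-specific. The LOQ is derived as (10/3) x LOD, the exact
#' ratio forced by the signal-to-noise definition.
#'
#' @param file Optional path to a CSV with columns
#'   `compound,matrix,lod_ng_per_ml`; defaults to the bundled synthetic table.
#' @return A tibble with columns `compound`, `matrix`, `lod_ng_per_ml`,
#'   `loq_ng_per_ml`.
#' @export
flav_detection_limits <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "detection_limits_synthetic.csv",
                        package = "flavrisk")
  }
  tbl <- readr::read_csv(file, show_col_types = FALSE,
                         col_types = readr::cols(
                           compound = readr::col_character(),
                           matrix = readr::col_character(),
                           lod_ng_per_ml = readr::col_double()
                         ))
  if (any(tbl$lod_ng_per_ml <= 0)) abort("LODs must be positive")
  if (!all(tbl$matrix %in% c("solvent", "tobacco", "filter_tip"))) {
    abort("detection-limit matrix must be one of solvent, tobacco, filter_tip")
  }
  tbl$loq_ng_per_ml <- tbl$lod_ng_per_ml * 10 / 3
  tbl
}

#' Bundled survey content summaries
#'
#' Published compound-level per-cigarette content summaries from the
#' 54-cigarette Korean market survey this package models: the average
#' (over detecting cigarettes) and maximum total content in
#' ug/cigarette for every compound detected in at least one product.
#' Suitable as direct input to [risk_from_content()].
#'
#' @param file Optional path to a user CSV with the same columns.
#' @return Tibble with columns `compound`, `stat`,
#'   `content_ug_per_cigarette`.
#' @export
flav_survey_contents <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "survey_contents.csv", package = "flavrisk")
  }
  readr::read_csv(file, show_col_types = FALSE,
                  col_types = readr::cols(
                    compound = readr::col_character(),
                    stat = readr::col_character(),
                    content_ug_per_cigarette = readr::col_double()
                  ))
}

# look up the (lod, loq) applying to given compound/part pairs
limits_for <- function(compound, part, limits) {
  key <- paste(limits$compound, limits$matrix, sep = "\r")
  idx <- match(paste(compound, matrix_for_part(part), sep = "\r"), key)
  tibble::tibble(lod_ng_per_ml = limits$lod_ng_per_ml[idx],
                 loq_ng_per_ml = limits$loq_ng_per_ml[idx])
}
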