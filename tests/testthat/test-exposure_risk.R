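toy_limits <- tibble::tibble(
  compound = c("Menthol", "Menthol", "Menthol", "Linalool", "Linalool", "Linalool"),
  matrix = rep(c("tobacco", "filter_tip", "solvent"), 2),
  lod_ng_per_ml = 0.123,
  loq_ng_per_ml = c(0.41, 0.41, 0.41, 0.50, 0.50, 0.50)
)

test_that("censoring substitution sets below-LOQ records to the LOQ-equivalent content", {
  contents <- dplyr::bind_rows(
    content_row(status = "below_loq", content = 0),
    content_row(cigarette_id = "NC02", status = "quantified", content = 3.5),
    content_row(cigarette_id = "NC03", status = "not_detected", content = 0)
  )
  out <- substitute_censored(contents, toy_limits)
  # LOQ 0.41 ng/mL x 25 mL / 1000 = 0.01025 ug
  expect_equal(out$content_ug_per_cigarette[1], 0.01025)
  expect_equal(out$content_ug_per_cigarette[2], 3.5)  # quantified unchanged
  expect_equal(out$content_ug_per_cigarette[3], 0)    # ND contributes zero
  expect_false(any(out$excluded_from_exposure))
})

test_that("compounds never detected in any product are excluded from exposure", {
  contents <- dplyr::bind_rows(
    content_row(compound = "Menthol", status = "quantified", content = 2),
    content_row(cigarette_id = "NC02", compound = "Linalool",
                status = "not_detected", content = 0),
    content_row(cigarette_id = "NC03", compound = "Linalool",
                status = "not_detected", content = 0)
  )
  out <- substitute_censored(contents, toy_limits)
  expect_equal(out$excluded_from_exposure, c(FALSE, TRUE, TRUE))
  risk <- build_risk_table(contents, compounds = flav_compounds(),
                           limits = toy_limits)
  expect_false("Linalool" %in% risk$compound)
  expect_true("Menthol" %in% risk$compound)
})

test_that("a censored record without a configured LOQ is a configuration error", {
  contents <- content_row(compound = "Citral", status = "below_loq")
  expect_error(substitute_censored(contents, toy_limits), "without a configured LOQ")
})

test_that("per-cigarette totals sum tobacco, filter and every capsule", {
  contents <- dplyr::bind_rows(
    content_row("C01", TRUE, "tobacco", NA, content = 1),
    content_row("C01", TRUE, "filter_tip", NA, content = 2),
    content_row("C01", TRUE, "capsule", 1, content = 3),
    content_row("C01", TRUE, "capsule", 2, content = 3),
    content_row("C02", TRUE, "tobacco", NA, status = "not_detected", content = 0),
    content_row("C02", TRUE, "filter_tip", NA, status = "not_detected", content = 0)
  )
  tot <- per_cigarette_totals(contents)
  expect_equal(tot$total_ug[tot$cigarette_id == "C01"], 9)
  # all-ND cigarette is retained with total 0
  expect_equal(tot$total_ug[tot$cigarette_id == "C02"], 0)
  expect_false(tot$detected[tot$cigarette_id == "C02"])
  dup <- dplyr::bind_rows(contents, contents[1, ])
  expect_error(per_cigarette_totals(dup), "duplicate")
})

test_that("a two-capsule cigarette can push the max total above the sum of part maxima", {
  contents <- dplyr::bind_rows(
    content_row("C01", TRUE, "tobacco", NA, content = 5),
    content_row("C01", TRUE, "filter_tip", NA, content = 5),
    content_row("C01", TRUE, "capsule", 1, content = 10),
    content_row("C02", TRUE, "tobacco", NA, content = 4),
    content_row("C02", TRUE, "filter_tip", NA, content = 4),
    content_row("C02", TRUE, "capsule", 1, content = 9),
    content_row("C02", TRUE, "capsule", 2, content = 9)
  )
  part_maxima <- contents |>
    dplyr::group_by(part) |>
    dplyr::summarise(mx = max(content_ug_per_cigarette))
  tot <- per_cigarette_totals(contents)
  expect_gt(max(tot$total_ug), sum(part_maxima$mx))
})

test_that("content statistics honour the averaging denominator", {
  expect_equal(content_stat(c(1, 3), "average"), 2)
  expect_equal(content_stat(c(1, 3), "maximum"), 3)
  expect_equal(content_stat(5, "average"), content_stat(5, "maximum"))
  # denominator switch rescales the average by exactly n_detected / n_all
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    detected <- runif(n) < 0.7
    totals <- ifelse(detected, runif(n, 0.1, 10), 0)
    if (!any(detected)) next
    a_det <- content_stat(totals, "average", detected, "detected_cigarettes")
    a_all <- content_stat(totals, "average", detected, "all_cigarettes")
    expect_equal(a_all, a_det * sum(detected) / n, tolerance = 1e-12)
  }
})

test_that("exposure-parameter derivation is exact and validates its domain", {
  p <- exposure_params()
  expect_identical(p$exposure_duration_years, 82.7 - 13.2)
  expect_identical(p$averaging_time_days, (82.7 - 13.2) * 365)
  expect_error(exposure_params(80, 80), "below life expectancy")
  expect_error(exposure_params(smoking_onset_age_years = -1), "non-negative")
  set.seed(9)
  for (i in 1:20) {
    le <- runif(1, 40, 100); on <- runif(1, 0, le - 1)
    p <- exposure_params(le, on)
    expect_equal(p$averaging_time_days / p$exposure_duration_years, 365)
  }
})

test_that("exposure concentration is linear in content with the closed-form slope", {
  p <- exposure_params()
  expect_equal(exposure_concentration(0, p), 0)
  set.seed(4)
  for (cval in runif(10, 0, 5000)) {
    ec <- exposure_concentration(cval, p)
    # under defaults ED*EF/AT = 1, so EC in ug/m3 is C * N / IR
    expect_equal(ec * 1000, cval * 13.2 / 14.25, tolerance = 1e-12)
    expect_equal(exposure_concentration(3 * cval, p), 3 * ec, tolerance = 1e-12)
  }
  expect_error(exposure_concentration(-1, p), "non-negative")
})

test_that("risk characterization flags attention above one tenth of the DNEL", {
  r <- risk_characterization(1.44969, 8.17)
  expect_equal(r$rcr, 0.177441, tolerance = 1e-5)
  expect_true(r$attention)
  expect_false(r$exceeds)
  expect_equal(risk_characterization(0.5, 0.5)$rcr, 1)
  expect_equal(format_rcr(risk_characterization(0.27962, 0.7)$rcr), "4.0e-01")
  expect_error(risk_characterization(1, NA_real_), "DNEL")
  expect_error(risk_characterization(1, 0), "DNEL")
  # RCR is linear in exposure
  expect_equal(risk_characterization(2 * 1.44969, 8.17)$rcr,
               2 * risk_characterization(1.44969, 8.17)$rcr)
})

test_that("risk table skips compounds without DNEL and handles empty input", {
  expect_message(
    risk <- risk_from_content(
      tibble::tibble(compound = c("Menthol", "Coumarin"),
                     stat = "average",
                     content_ug_per_cigarette = c(10, 10))),
    "without DNEL.*Coumarin")
  expect_equal(risk$compound, "Menthol")
  expect_error(risk_from_content(
    tibble::tibble(compound = "unknownium", stat = "average",
                   content_ug_per_cigarette = 1)), "unknown compound")
  empty <- build_risk_table(content_row()[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("compound", "stat", "exposure_mg_per_m3", "rcr") %in%
                    names(empty)))
})

test_that("rendered risk tables use 5-decimal exposures and 2-significant-figure RCRs", {
  risk <- risk_from_content(
    tibble::tibble(compound = "Menthol", stat = c("average", "maximum"),
                   content_ug_per_cigarette = c(1565.01, 7870.83)))
  out <- render_risk_table(risk)
  expect_equal(out$exposure_mg_per_m3, c("1.44969", "7.29087"))
  expect_equal(out$rcr, c("1.8e-01", "8.9e-01"))
})

test_that("full risk pipeline emits one average and one maximum row per compound", {
  contents <- dplyr::bind_rows(
    content_row("C01", TRUE, "tobacco", NA, "Menthol", content = 100),
    content_row("C01", TRUE, "capsule", 1, "Menthol", content = 900),
    content_row("C02", TRUE, "tobacco", NA, "Menthol", content = 300),
    content_row("C02", TRUE, "capsule", 1, "Menthol", content = 700)
  )
  risk <- build_risk_table(contents, limits = toy_limits)
  expect_equal(nrow(risk), 2)
  expect_equal(sort(risk$stat), c("average", "maximum"))
  expect_equal(risk$content_ug_per_cigarette[risk$stat == "average"], 1000)
  expect_equal(risk$content_ug_per_cigarette[risk$stat == "maximum"], 1000)
})
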