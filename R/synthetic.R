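# run code under a temporary RNG state so generators are seed-pure
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Truncated log-normal draws and moments
#'
#' Samples a log-normal distribution conditioned on `lower <= X <= upper`
#' by inverse-CDF sampling, and computes the analytic mean of the
#' truncated distribution. `sdlog = 0` denotes a point mass at
#' `exp(meanlog)`.
#'
#' @param n Number of draws.
#' @param meanlog,sdlog Log-scale location and scale.
#' @param lower,upper Truncation bounds (0 < lower <= upper).
#' @return `rtrunclnorm()`: numeric vector of draws;
#'   `trunclnorm_mean()` / `trunclnorm_sd()`: scalar moments.
#' @export
rtrunclnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  meanlog <- rep_len(meanlog, n)
  sdlog <- rep_len(sdlog, n)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  out <- exp(meanlog)
  i <- sdlog > 0
  if (any(i)) {
    p_lo <- plnorm(lower[i], meanlog[i], sdlog[i])
    p_hi <- plnorm(upper[i], meanlog[i], sdlog[i])
    out[i] <- qlnorm(runif(sum(i), p_lo, p_hi), meanlog[i], sdlog[i])
  }
  out
}

#' @rdname rtrunclnorm
#' @export
trunclnorm_mean <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  if (sdlog == 0) return(exp(meanlog))
  denom <- plnorm(upper, meanlog, sdlog) - plnorm(lower, meanlog, sdlog)
  num <- pnorm((log(upper) - meanlog - sdlog^2) / sdlog) -
    pnorm((log(lower) - meanlog - sdlog^2) / sdlog)
  exp(meanlog + sdlog^2 / 2) * num / denom
}

#' @rdname rtrunclnorm
#' @export
trunclnorm_sd <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  if (sdlog == 0) return(0)
  denom <- plnorm(upper, meanlog, sdlog) - plnorm(lower, meanlog, sdlog)
  m2 <- exp(2 * meanlog + 2 * sdlog^2) *
    (pnorm((log(upper) - meanlog - 2 * sdlog^2) / sdlog) -
       pnorm((log(lower) - meanlog - 2 * sdlog^2) / sdlog)) / denom
  m1 <- trunclnorm_mean(meanlog, sdlog, lower, upper)
  sqrt(pmax(m2 - m1^2, 0))
}

#' Bundled per-compound content distributions
#'
#' Survey-shaped generator defaults: per compound and cigarette part, the
#' detection count out of the parts surveyed (54 tobacco rods, 54 filter
#' tips, 42 capsules) and the mean/SD/min/max of the detected contents in
#' ug/cigarette. From these the generator derives a detection probability
#' (`n_detected / n_total`) and a log-normal distribution matched to the
#' mean and SD by moments, truncated to the observed [min, max] range —
#' content distributions in such surveys are strongly right-skewed (means
#' far above medians), for which the log-normal is the simplest standard
#' family.
#'
#' @param file Optional path to a user CSV with the same columns.
#' @return Tibble with the raw columns plus `detection_probability`,
#'   `meanlog`, `sdlog`.
#' @export
flav_content_distributions <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "content_distributions.csv",
                        package = "flavrisk")
  }
  tbl <- readr::read_csv(file, show_col_types = FALSE)
  tbl$detection_probability <- tbl$n_detected / tbl$n_total
  cv2 <- (tbl$sd / tbl$mean)^2
  tbl$sdlog <- ifelse(is.na(tbl$sd) | tbl$sd == 0, 0, sqrt(log(1 + cv2)))
  tbl$meanlog <- log(tbl$mean) - tbl$sdlog^2 / 2
  tbl
}

#' Synthetic study configuration
#'
#' Settings for [generate_study()]. The defaults emulate the market
#' survey this package models: 24 non-capsule and 30 capsule cigarettes;
#' 40% of capsule cigarettes carry two capsules (30 capsule cigarettes
#' yielding 42 capsules fixes that fraction); detection probabilities and
#' truncated log-normal content distributions per compound x part from
#' the bundled survey summaries; 0.25 g aliquots of tobacco and filter
#' tip extracted in 25 mL of acetone and whole capsules (nominal 0.30 g)
#' in 10 mL.
#'
#' @param n_noncapsule,n_capsule Numbers of cigarettes of each class.
#' @param two_capsule_fraction Probability that a capsule cigarette holds
#'   two capsules.
#' @param censor_fraction Probability that a detected measurement falls
#'   between LOD and LOQ (reported as `below_loq`).
#' @param distributions Content distributions, see
#'   [flav_content_distributions()].
#' @param limits Detection limits, see [flav_detection_limits()].
#' @param weights_g,volumes_ml Named per-part aliquot weights (g) and
#'   extraction volumes (mL).
#' @return A list of class `flav_synth_config`.
#' @export
synthetic_study_config <- function(n_noncapsule = 24, n_capsule = 30,
                                   two_capsule_fraction = 0.4,
                                   censor_fraction = 0.05,
                                   distributions = flav_content_distributions(),
                                   limits = flav_detection_limits(),
                                   weights_g = c(tobacco = 0.25,
                                                 filter_tip = 0.25,
                                                 capsule = 0.30),
                                   volumes_ml = c(tobacco = 25,
                                                  filter_tip = 25,
                                                  capsule = 10)) {
  if (two_capsule_fraction < 0 || two_capsule_fraction > 1 ||
      censor_fraction < 0 || censor_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (any(distributions$detection_probability < 0 |
            distributions$detection_probability > 1)) {
    abort("detection probabilities must lie in [0, 1]")
  }
  if (n_noncapsule < 0 || n_capsule < 0 || n_noncapsule + n_capsule < 1) {
    abort("need at least one cigarette")
  }
  structure(list(
    n_noncapsule = n_noncapsule, n_capsule = n_capsule,
    two_capsule_fraction = two_capsule_fraction,
    censor_fraction = censor_fraction,
    distributions = distributions, limits = limits,
    weights_g = weights_g, volumes_ml = volumes_ml
  ), class = "flav_synth_config")
}

#' Generate a synthetic cigarette survey
#'
#' Produces instrument-level quantification records for a study of
#' `n_noncapsule + n_capsule` cigarettes. For every part x compound cell
#' with a configured distribution, detection occurs with the configured
#' probability; detected contents are drawn from the truncated
#' log-normal, a configurable fraction of detections falls between LOD
#' and LOQ (censored), and instrument levels are back-computed from the
#' target content through the inverse of the level-to-content conversion
#' (level = content x 1000 / volume at dilution 1). Output is
#' deterministic given the seed and passes the quantification-table
#' validator.
#'
#' @param config See [synthetic_study_config()].
#' @param seed Integer seed.
#' @return A validated quantification-record tibble, as returned by
#'   [read_quant_table()].
#' @export
generate_study <- function(config = synthetic_study_config(), seed = 1) {
  stopifnot(inherits(config, "flav_synth_config"))
  with_seed(seed, {
    ids_nc <- sprintf("NC%02d", seq_len(config$n_noncapsule))
    ids_c <- sprintf("C%02d", seq_len(config$n_capsule))
    n_caps <- 1L + rbinom(config$n_capsule, 1L, config$two_capsule_fraction)
    parts <- dplyr::bind_rows(
      tidyr::expand_grid(cigarette_id = c(ids_nc, ids_c),
                         part = c("tobacco", "filter_tip"),
                         capsule_index = NA_integer_),
      if (config$n_capsule > 0) {
        purrr::map_dfr(seq_along(ids_c), function(i) {
          tibble::tibble(cigarette_id = ids_c[i], part = "capsule",
                         capsule_index = seq_len(n_caps[i]))
        })
      }
    )
    parts$has_capsule <- parts$cigarette_id %in% ids_c
    # every compound x part cell is reported; undetectable cells get p = 0
    grid <- tidyr::expand_grid(parts,
                               compound = unique(config$distributions$compound))
    grid <- dplyr::left_join(
      grid,
      config$distributions[, c("compound", "part", "detection_probability",
                               "meanlog", "sdlog", "min", "max")],
      by = c("compound", "part"))
    grid$detection_probability[is.na(grid$detection_probability)] <- 0

    n <- nrow(grid)
    detected <- runif(n) < grid$detection_probability
    content <- rep(NA_real_, n)
    idx <- which(detected)
    content[idx] <- rtrunclnorm(length(idx), grid$meanlog[idx],
                                grid$sdlog[idx], grid$min[idx], grid$max[idx])
    vol <- unname(config$volumes_ml[grid$part])
    wt <- unname(config$weights_g[grid$part])
    level <- content * 1000 / vol
    lim <- limits_for(grid$compound, grid$part, config$limits)
    censored <- detected & runif(n) < config$censor_fraction
    level[censored] <- runif(sum(censored), lim$lod_ng_per_ml[censored],
                             lim$loq_ng_per_ml[censored])
    level[!detected] <- NA_real_
    out <- tibble::tibble(
      cigarette_id = grid$cigarette_id,
      has_capsule = grid$has_capsule,
      part = grid$part,
      capsule_index = grid$capsule_index,
      compound = grid$compound,
      detected_level_ng_per_ml = level,
      dilution_factor = 1,
      extract_volume_ml = vol,
      sample_weight_g = wt
    )
    out <- dplyr::arrange(out, .data$cigarette_id, .data$part,
                          .data$capsule_index, .data$compound)
    validate_quant_records(out, flav_compounds(), config$limits)
  })
}

#' Generate a method-validation fixture
#'
#' Spiked-replicate measurements for recovery and precision assessment:
#' for each compound, matrix and spike level, replicates are drawn as
#' `spike x recovery_bias x (1 + e)` with Gaussian noise `e` of standard
#' deviation `noise_cv` (truncated at -1 so measurements stay positive).
#' The default design mirrors standard fortification studies: spike
#' levels 2.5, 5.0 and 50 ug/g in triplicate for tobacco and filter-tip
#' matrices.
#'
#' @param compounds Character vector of compound names.
#' @param matrices Matrices to spike.
#' @param spike_levels_ug_per_g Nominal spike concentrations, ug/g.
#' @param n_replicates Replicates per level.
#' @param recovery_bias Multiplicative extraction bias (1 = complete
#'   recovery).
#' @param noise_cv Coefficient of variation of measurement noise.
#' @param seed Integer seed.
#' @return Tibble with columns `compound`, `matrix`, `spike_ug_per_g`,
#'   `replicate`, `measured_ug_per_g`.
#' @export
generate_validation_fixture <- function(compounds = flav_compounds()$name,
                                        matrices = c("tobacco", "filter_tip"),
                                        spike_levels_ug_per_g = c(2.5, 5, 50),
                                        n_replicates = 3,
                                        recovery_bias = 1,
                                        noise_cv = 0.03,
                                        seed = 1) {
  if (recovery_bias <= 0) abort("recovery bias must be positive")
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  with_seed(seed, {
    grid <- tidyr::expand_grid(compound = compounds, matrix = matrices,
                               spike_ug_per_g = spike_levels_ug_per_g,
                               replicate = seq_len(n_replicates))
    e <- pmax(stats::rnorm(nrow(grid), 0, noise_cv), -1 + 1e-12)
    grid$measured_ug_per_g <- grid$spike_ug_per_g * recovery_bias * (1 + e)
    grid
  })
}
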