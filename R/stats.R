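#' Descriptive content summaries
#'
#' Per-compound summary rows in the shape of a survey content table:
#' detection count and mean/median/SD/min/max of the content in
#' ug/cigarette over quantified records only (censored and non-detected
#' records carry no reliable value and are excluded unless
#' `include_censored` substitutes them at the LOQ).
#'
#' @param contents Content records, see [quantify_contents()].
#' @param group Grouping column in addition to compound: `"part"` (rows
#'   per cigarette part) or `"class"` (capsule vs non-capsule cigarettes).
#' @param include_censored If `TRUE`, below-LOQ records enter the
#'   statistics at their LOQ-substituted content.
#' @param sd_single SD reported for a single detected value: `"zero"`
#'   (0, the survey-table convention) or `"na"`.
#' @return Tibble of summary rows; compounds with no detections have
#'   `n_detected = 0` and `NA` statistics (rendered as "ND" in reports).
#' @export
summarize_contents <- function(contents, group = c("part", "class"),
                               include_censored = FALSE,
                               sd_single = c("zero", "na")) {
  group <- match.arg(group)
  sd_single <- match.arg(sd_single)
  keep <- if (include_censored) contents$status != "not_detected"
          else contents$status == "quantified"
  contents$.group <- if (group == "part") contents$part
                     else ifelse(contents$has_capsule, "capsule_cigarette",
                                 "non_capsule_cigarette")
  all_cells <- dplyr::distinct(contents, .data$compound, group = .data$.group)
  det <- contents[keep, , drop = FALSE]
  stats_tbl <- det |>
    dplyr::group_by(.data$compound, group = .data$.group) |>
    dplyr::summarise(
      n_detected = dplyr::n(),
      mean = mean(.data$content_ug_per_cigarette),
      median = median(.data$content_ug_per_cigarette),
      sd = if (dplyr::n() > 1) sd(.data$content_ug_per_cigarette)
           else if (sd_single == "zero") 0 else NA_real_,
      min = min(.data$content_ug_per_cigarette),
      max = max(.data$content_ug_per_cigarette),
      .groups = "drop"
    )
  out <- dplyr::left_join(all_cells, stats_tbl, by = c("compound", "group"))
  out$n_detected[is.na(out$n_detected)] <- 0L
  dplyr::arrange(out, .data$compound, .data$group)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees
#' of freedom. When every observation is identical there is no rank
#' variance and H is reported as 0 with p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length (>= 2 nonempty groups).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
kw_test <- function(values, groups) {
  groups <- as.factor(groups)
  check_groups(values, groups, min_groups = 2)
  if (length(unique(values)) == 1) {
    return(tibble::tibble(test = "kruskal_wallis", statistic = 0,
                          df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 df = as.integer(kt$parameter),
                 p_value = kt$p.value)
}

#' Dunn post hoc test with Bonferroni adjustment
#'
#' All pairwise mean-rank comparisons on the pooled ranking underlying
#' the Kruskal-Wallis test. For groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t)` over tie groups. Two-sided
#' normal p-values are Bonferroni-multiplied by the number of
#' comparisons k(k-1)/2 and capped at 1.
#'
#' @inheritParams kw_test
#' @return Tibble with one row per pair: `group_a`, `group_b`,
#'   `mean_rank_diff`, `z`, `p_value`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  check_groups(values, groups, min_groups = 3)
  n_tot <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  k <- nlevels(groups)
  n_comp <- k * (k - 1) / 2
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- unname(rbar[a] - rbar[b])
    se <- sqrt(sigma2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- diff / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(group_a = a, group_b = b, mean_rank_diff = diff,
                   z = z, p_value = p, p_adj = min(1, p * n_comp))
  })
}

#' Mann-Whitney U test
#'
#' U statistic for two independent samples. The p-value is exact (by
#' enumeration of the U distribution) when the smaller sample has at
#' most `exact_max_n` observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact_max_n Largest min(n, m) for which the exact distribution
#'   is used.
#' @return One-row tibble: `test`, `statistic` (U for `x` relative to
#'   `y`), `p_value`, `method`.
#' @export
mw_test <- function(x, y, exact_max_n = 8) {
  if (!length(x) || !length(y)) abort("both samples must be nonempty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= exact_max_n && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(test = "mann_whitney",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal_approximation")
}

#' Shapiro-Wilk normality test
#'
#' Pass-through to the standard Shapiro-Wilk implementation, used as the
#' gateway justifying the nonparametric battery.
#'
#' @param x Numeric sample (3 to 5000 observations).
#' @return One-row tibble: `test`, `statistic`, `p_value`.
#' @export
normality_test <- function(x) {
  st <- shapiro.test(x)
  tibble::tibble(test = "shapiro_wilk", statistic = unname(st$statistic),
                 p_value = st$p.value)
}

check_groups <- function(values, groups, min_groups) {
  if (length(values) != length(groups)) {
    abort("values and groups must have equal length")
  }
  if (nlevels(groups) < min_groups) {
    abort(paste0("need at least ", min_groups, " groups"))
  }
  if (any(tabulate(groups, nlevels(groups)) == 0)) {
    abort("every group must be nonempty")
  }
}

#' Cigarette-by-compound content matrix
#'
#' Wide matrix for chemometric analysis: one row per cigarette (summing
#' parts) or per physical part sample, one column per compound.
#' Non-detected entries are 0.
#'
#' @param contents Content records.
#' @param rows `"cigarette"` (totals per cigarette) or `"part_sample"`
#'   (one row per separated part).
#' @return List with `x` (numeric matrix) and `info` (tibble of row
#'   metadata: `cigarette_id`, `has_capsule`, and `part` for part rows).
#' @export
content_matrix <- function(contents, rows = c("cigarette", "part_sample")) {
  rows <- match.arg(rows)
  if (rows == "cigarette") {
    long <- contents |>
      dplyr::group_by(.data$cigarette_id, .data$has_capsule, .data$compound) |>
      dplyr::summarise(value = sum(.data$content_ug_per_cigarette),
                       .groups = "drop")
    wide <- tidyr::pivot_wider(long, names_from = "compound",
                               values_from = "value", values_fill = 0)
    info <- wide[, c("cigarette_id", "has_capsule")]
    x <- as.matrix(wide[, setdiff(names(wide), c("cigarette_id", "has_capsule"))])
  } else {
    long <- contents |>
      dplyr::mutate(sample_id = paste(.data$cigarette_id, .data$part,
                                      dplyr::coalesce(.data$capsule_index, 0L),
                                      sep = ":"))
    wide <- tidyr::pivot_wider(
      long[, c("sample_id", "cigarette_id", "has_capsule", "part", "compound",
               "content_ug_per_cigarette")],
      names_from = "compound", values_from = "content_ug_per_cigarette",
      values_fill = 0)
    info <- wide[, c("sample_id", "cigarette_id", "has_capsule", "part")]
    x <- as.matrix(wide[, setdiff(names(wide), names(info))])
  }
  rownames(x) <- NULL
  list(x = x, info = info)
}

#' Principal component analysis of content profiles
#'
#' Chemometric fingerprinting of cigarettes by their flavoring-agent
#' profile. Columns are mean-centered and scaled to unit variance (the
#' standard chemometric preprocessing); missing entries are imputed as 0
#' beforehand; zero-variance columns are dropped with a warning.
#'
#' @param x Numeric matrix, samples in rows, compounds in columns.
#' @param n_components Number of components to retain (default: all).
#' @return List of class `flav_pca`: `scores`, `loadings`,
#'   `explained_variance` (proportions, non-increasing), `center`,
#'   `scale`, `dropped` (names of constant columns).
#' @export
pca_contents <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need at least 2 samples for PCA")
  x[is.na(x)] <- 0
  v <- apply(x, 2, sd)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warn(paste0("dropping constant column(s): ", paste(dropped, collapse = ", ")))
    x <- x[, v > 0, drop = FALSE]
  }
  if (!ncol(x)) abort("no variable columns left for PCA")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- if (is.null(n_components)) ncol(pc$rotation)
       else min(n_components, ncol(pc$rotation))
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
    center = pc$center,
    scale = pc$scale,
    dropped = dropped
  ), class = "flav_pca")
}

#' @export
print.flav_pca <- function(x, ...) {
  cat(sprintf("PCA on %d samples, %d components; variance explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}

#' Score plot of a content PCA
#'
#' Simple PC1/PC2 scatter colored by a class label, for visual
#' inspection of capsule vs non-capsule (or part) separation.
#'
#' @param pca A `flav_pca` object.
#' @param class Factor/character vector of row classes.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca, class) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  df <- tibble::tibble(PC1 = pca$scores[, 1],
                       PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else 0,
                       class = as.factor(class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance[1]),
      y = if (ncol(pca$scores) > 1)
        sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance[2]) else "")
}
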