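# small in-code fixtures shared across test files

# one quantification row with sensible defaults, overridable per field
quant_row <- function(cigarette_id = "NC01", has_capsule = FALSE,
                      part = "tobacco", capsule_index = NA_integer_,
                      compound = "Menthol",
                      detected_level_ng_per_ml = 100,
                      dilution_factor = 1,
                      extract_volume_ml = if (part == "capsule") 10 else 25,
                      sample_weight_g = if (part == "capsule") 0.30 else 0.25) {
  tibble::tibble(cigarette_id, has_capsule, part,
                 capsule_index = as.integer(capsule_index), compound,
                 detected_level_ng_per_ml, dilution_factor,
                 extract_volume_ml, sample_weight_g)
}

write_quant_csv <- function(tbl, path = tempfile(fileext = ".csv")) {
  readr::write_csv(tbl, path, na = "")
  path
}

# content records built directly (bypassing instrument levels) for
# exposure-stage tests; content in ug/cigarette
content_row <- function(cigarette_id = "NC01", has_capsule = FALSE,
                        part = "tobacco", capsule_index = NA_integer_,
                        compound = "Menthol", status = "quantified",
                        content = 1) {
  tibble::tibble(cigarette_id, has_capsule, part,
                 capsule_index = as.integer(capsule_index), compound, status,
                 concentration_ng_per_g = content * 1000 /
                   (if (part == "capsule") 0.30 else 0.25),
                 content_ug_per_cigarette = content,
                 censored = status != "quantified")
}

# mean silhouette width over Euclidean distances (used on PCA scores)
mean_silhouette <- function(x, class) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  class <- as.character(class)
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- class == class[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(class), class[i]),
                    function(cl) mean(d[i, class == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# brute-force exact two-sided Mann-Whitney p-value by enumeration of all
# rank assignments (tie-free data only)
mwu_enumerate <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(ix) sum(ix) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# tie-corrected Kruskal-Wallis H from the textbook rank-sum formula
kw_formula <- function(values, groups) {
  groups <- as.factor(groups)
  n_tot <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  n <- tapply(r, groups, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rs^2 / n) - 3 * (n_tot + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n_tot^3 - n_tot))
}

# scalar, loop-based Dunn z/p recomputation
dunn_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  n_tot <- length(values)
  r <- rank(values)
  lv <- levels(groups)
  k <- length(lv)
  ties <- table(values)
  s2 <- n_tot * (n_tot + 1) / 12 - sum(ties^3 - ties) / (12 * (n_tot - 1))
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ri <- r[groups == lv[i]]; rj <- r[groups == lv[j]]
    z <- (mean(ri) - mean(rj)) / sqrt(s2 * (1 / length(ri) + 1 / length(rj)))
    p <- 2 * stats::pnorm(-abs(z))
    out <- rbind(out, data.frame(group_a = lv[i], group_b = lv[j], z = z,
                                 p_value = p,
                                 p_adj = min(1, p * k * (k - 1) / 2)))
  }
  out
}
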