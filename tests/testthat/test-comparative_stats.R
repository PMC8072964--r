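test_that("content summaries use detected values only and render ND cells", {
  contents <- dplyr::bind_rows(
    content_row("NC01", FALSE, "tobacco", NA, "Menthol", "quantified", 1),
    content_row("NC02", FALSE, "tobacco", NA, "Menthol", "quantified", 2),
    content_row("NC03", FALSE, "tobacco", NA, "Menthol", "not_detected", 0),
    content_row("NC01", FALSE, "filter_tip", NA, "Menthol", "not_detected", 0)
  )
  s <- summarize_contents(contents, "part")
  tob <- s[s$group == "tobacco", ]
  expect_equal(tob$n_detected, 2L)
  expect_equal(tob$mean, 1.5)
  expect_equal(tob$sd, sd(c(1, 2)))
  expect_equal(tob$sd, 0.7071068, tolerance = 1e-6)
  flt <- s[s$group == "filter_tip", ]
  expect_equal(flt$n_detected, 0L)
  expect_true(is.na(flt$mean))
  # single detected value: SD 0 by default, NA on request
  one <- summarize_contents(contents[1, ], "part")
  expect_equal(one$sd, 0)
  expect_true(is.na(summarize_contents(contents[1, ], "part",
                                       sd_single = "na")$sd))
})

test_that("class summaries split capsule and non-capsule cigarettes", {
  contents <- dplyr::bind_rows(
    content_row("NC01", FALSE, "tobacco", NA, "Menthol", "quantified", 1),
    content_row("C01", TRUE, "tobacco", NA, "Menthol", "quantified", 5)
  )
  s <- summarize_contents(contents, "class")
  expect_setequal(s$group, c("capsule_cigarette", "non_capsule_cigarette"))
  expect_equal(s$mean[s$group == "capsule_cigarette"], 5)
})

test_that("Kruskal-Wallis H matches the rank-sum formula, with and without ties", {
  res <- kw_test(c(1:3, 4:6, 7:9), rep(letters[1:3], each = 3))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  # all observations equal: H = 0 convention
  res0 <- kw_test(rep(5, 9), rep(letters[1:3], each = 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  set.seed(14)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    g <- rep(seq_len(k), sizes)
    v <- sample(1:6, sum(sizes), replace = TRUE)  # forces ties
    if (length(unique(v)) == 1) next
    expect_equal(kw_test(v, g)$statistic, kw_formula(v, g), tolerance = 1e-8)
  }
  expect_error(kw_test(1:3, c("a", "a", "a")), "2 groups")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z on tie-free data", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(4:9, 1); m <- sample(4:9, 1)
    v <- sample(1:1000, n + m)
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    h <- kw_test(v, rep(1:2, c(n, m)))$statistic
    u <- sum(rank(v)[seq_len(n)]) - n * (n + 1) / 2
    z <- (u - n * m / 2) / sqrt(n * m * (n + m + 1) / 12)
    expect_equal(h, z^2, tolerance = 1e-10)
  }
})

test_that("Dunn-Bonferroni pairwise comparisons match the mean-rank oracle", {
  d <- dunn_test(c(1:3, 4:6, 7:9), rep(c("g1", "g2", "g3"), each = 3))
  pair13 <- d[d$group_a == "g1" & d$group_b == "g3", ]
  expect_equal(pair13$mean_rank_diff, -6)   # mean ranks 2 vs 8
  expect_equal(pair13$z, -6 / sqrt(7.5 * (2 / 3)))
  expect_true(all(d$p_adj >= d$p_value))    # Bonferroni never lowers p
  expect_true(all(d$p_adj <= 1))
  set.seed(16)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    sizes <- sample(3:6, k, replace = TRUE)
    g <- rep(letters[seq_len(k)], sizes)
    v <- sample(1:8, sum(sizes), replace = TRUE)  # heavy ties
    d <- dunn_test(v, g)
    o <- dunn_oracle(v, g)
    expect_equal(d$z, o$z, tolerance = 1e-8)
    expect_equal(d$p_adj, o$p_adj, tolerance = 1e-8)
  }
  expect_error(dunn_test(1:4, rep(1:2, 2)), "3 groups")
})

test_that("Mann-Whitney U agrees with exhaustive enumeration on small samples", {
  res <- mw_test(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "exact")
  # identical multisets: U = nm/2
  same <- mw_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(1:1000, n + m)  # tie-free
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    got <- mw_test(x, y)
    ora <- mwu_enumerate(x, y)
    expect_equal(got$statistic, ora$u)
    expect_equal(got$p_value, ora$p, tolerance = 1e-8)
  }
  expect_error(mw_test(numeric(), 1:3), "nonempty")
})

test_that("rank tests are invariant under strictly increasing transforms", {
  set.seed(18)
  v <- runif(12, 1, 100)
  g <- rep(letters[1:3], each = 4)
  for (f in list(function(z) z, log, sqrt, function(z) z^3)) {
    expect_equal(kw_test(f(v), g)$statistic, kw_test(v, g)$statistic,
                 tolerance = 1e-10)
    expect_equal(dunn_test(f(v), g)$z, dunn_test(v, g)$z, tolerance = 1e-10)
    expect_equal(mw_test(f(v[1:4]), f(v[5:8]))$p_value,
                 mw_test(v[1:4], v[5:8])$p_value, tolerance = 1e-10)
  }
})

test_that("Shapiro-Wilk gateway delegates to the standard implementation", {
  set.seed(19)
  x <- rnorm(30)
  res <- normality_test(x)
  ref <- shapiro.test(x)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("PCA scales to unit variance and orders explained variance", {
  set.seed(20)
  x <- matrix(rnorm(30 * 5), 30, 5)
  colnames(x) <- paste0("c", 1:5)
  pc <- pca_contents(x)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_equal(sum(pc$explained_variance), 1)
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction
  xs <- scale(x)
  expect_equal(unname(pc$scores %*% t(pc$loadings)), unname(xs),
               tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 data: PC1 explains everything
  r1 <- outer(runif(10, 1, 2), c(1, 2, 3))
  colnames(r1) <- paste0("c", 1:3)
  pc1 <- pca_contents(r1)
  expect_equal(pc1$explained_variance[1], 1, tolerance = 1e-10)
  # constant columns are dropped with a warning
  x[, 2] <- 7
  expect_warning(pc2 <- pca_contents(x), "constant column")
  expect_equal(ncol(pc2$loadings), 4)
})

test_that("capsule and non-capsule cigarettes separate in PCA score space", {
  records <- generate_study(seed = 23)
  contents <- quantify_contents(records)
  cm <- content_matrix(contents, "cigarette")
  pc <- suppressWarnings(pca_contents(cm$x, n_components = 2))
  sil <- mean_silhouette(pc$scores, cm$info$has_capsule)
  expect_gt(sil, 0)
})

test_that("part-sample content matrices carry row metadata", {
  records <- generate_study(synthetic_study_config(n_noncapsule = 3,
                                                   n_capsule = 3), seed = 2)
  contents <- quantify_contents(records)
  cm <- content_matrix(contents, "part_sample")
  expect_equal(nrow(cm$x), nrow(cm$info))
  expect_true(all(c("tobacco", "filter_tip", "capsule") %in% cm$info$part))
})
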