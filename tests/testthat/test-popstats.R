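test_that("PCA frequency filter drops sums of 1, 2 and n", {
  set.seed(91)
  m <- matrix(0L, nrow = 5L, ncol = 6L,
              dimnames = list(sprintf("s%d", 1:5), sprintf("n%d", 1:6)))
  m[1, 1] <- 1L                 # singleton
  m[1:2, 2] <- 1L               # doubleton
  m[1:3, 3] <- 1L               # kept
  m[1:4, 4] <- 1L               # kept
  m[1:5, 5] <- 1L               # all samples: no variance
  m[2:4, 6] <- 1L               # kept
  out <- pca_filter(m)
  expect_equal(colnames(out), c("n3", "n4", "n6"))
})

test_that("occurrence PCA separates blocks and matches an eigen oracle", {
  m <- matrix(c(1, 1, 1, 0, 0, 0,
                1, 1, 1, 0, 0, 1,
                0, 0, 0, 1, 1, 0,
                0, 0, 1, 1, 1, 0), nrow = 4L, byrow = TRUE,
              dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  p <- occurrence_pca(m)
  # PC1 separates the two sample blocks by sign
  expect_true(prod(sign(p$scores[c("a1", "a2"), 1L])) > 0)
  expect_true(sign(p$scores["a1", 1L]) != sign(p$scores["b1", 1L]))
  expect_true(all(diff(p$explained) <= 1e-12))

  # eigen-decomposition oracle on the centred matrix
  cm <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(cm))
  oracle_scores <- cm %*% ev$vectors[, 1:2]
  for (k in 1:2)
    expect_equal(abs(unname(p$scores[, k])), abs(unname(oracle_scores[, k])),
                 tolerance = 1e-8)

  # identical samples get identical scores
  m2 <- rbind(m, a3 = m[1, ])
  p2 <- occurrence_pca(m2)
  expect_equal(unname(p2$scores["a1", ]), unname(p2$scores["a3", ]))
})

test_that("one-way ANOVA matches the direct sum-of-squares oracle", {
  set.seed(92)
  for (rep in 1:5) {
    g <- factor(sample(letters[1:3], 20L, TRUE))
    y <- rnorm(20L, mean = as.integer(g))
    res <- anova_oneway(y, g)
    # direct decomposition
    gm <- mean(y)
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    k <- nlevels(g)
    f_direct <- (ssb / (k - 1)) / (ssw / (length(y) - k))
    expect_equal(res$f_stat, f_direct, tolerance = 1e-10)
    expect_equal(res$df_between, k - 1L)
    expect_equal(res$df_within, length(y) - k)
    expect_equal(res$p_value,
                 pf(f_direct, k - 1, length(y) - k, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # equal group means give F near zero
  res <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3L))
  expect_lt(res$f_stat, 1e-20)
})

test_that("ANOVA F is shift- and scale-invariant", {
  df <- nui_cohort17()
  f0 <- anova_oneway(df$count, df$population)$f_stat
  expect_equal(anova_oneway(df$count + 1000, df$population)$f_stat, f0)
  expect_equal(anova_oneway(df$count * 3.7, df$population)$f_stat, f0)
})

test_that("Tukey HSD matches the studentized-range formula", {
  df <- nui_cohort17()
  tk <- tukey_hsd(df$count, df$population)
  # independent recomputation through ptukey with Tukey-Kramer SE
  fit <- anova_oneway(df$count, df$population)
  msw <- sum(tapply(df$count, df$population,
                    function(v) sum((v - mean(v))^2))) / fit$df_within
  ns <- table(df$population)
  means <- tapply(df$count, df$population, mean)
  for (i in seq_len(nrow(tk))) {
    gs <- strsplit(tk$pair[i], "-")[[1]]
    q <- abs(means[gs[1]] - means[gs[2]]) /
      sqrt(msw / 2 * (1 / ns[gs[1]] + 1 / ns[gs[2]]))
    p <- stats::ptukey(q, nmeans = 5, df = fit$df_within,
                       lower.tail = FALSE)
    expect_equal(tk$p_adj[i], unname(p), tolerance = 1e-8)
  }
  # identical groups: all adjusted p equal 1
  tk1 <- tukey_hsd(rep(c(5, 6, 7), 3L), rep(c("a", "b", "c"), each = 3L))
  expect_true(all(tk1$p_adj > 0.9999))
})

test_that("Fisher's exact test gives the conditional-MLE odds ratio", {
  res <- fisher_2x2(1, 1, 1, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(res$p_value, 1)

  # conditional MLE shrinks toward 1 relative to the cross-product OR
  tables <- list(c(90, 39, 553, 1160), c(20, 5, 10, 30), c(8, 2, 3, 12),
                 c(50, 20, 30, 60))
  for (tb in tables) {
    r <- do.call(fisher_2x2, as.list(tb))
    expect_gt(r$sample_odds_ratio, 1)
    expect_gt(r$odds_ratio, 1)
    expect_lt(r$odds_ratio, r$sample_odds_ratio)
  }
  expect_warning(fisher_2x2(5, 0, 3, 0), "zero margin")
})

test_that("chi-square matches the direct formula and closed forms", {
  set.seed(93)
  for (rep in 1:5) {
    tab <- matrix(sample(5:60, 10L, TRUE), nrow = 5L)
    res <- chi_square_sharing(tab)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - exp_tab)^2 / exp_tab),
                 tolerance = 1e-10)
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1))
  }
  # independent table gives statistic ~ 0
  ind <- outer(c(10, 20, 30), c(40, 60)) / 10
  expect_lt(chi_square_sharing(ind)$statistic, 1e-20)
  # perfectly associated 2x2 of n observations gives n
  n <- 48
  assoc <- matrix(c(n / 2, 0, 0, n / 2), 2L)
  expect_equal(chi_square_sharing(assoc)$statistic, n)
})

test_that("Pearson correlation matches its definitional oracle", {
  set.seed(94)
  x <- rnorm(15L)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  y <- rnorm(15L)
  res <- pearson_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(13 / (1 - r_direct^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df = 13L),
               tolerance = 1e-12)
  expect_error(pearson_correlation(x, y[1:10]), "equal length")
  expect_error(pearson_correlation(rep(1, 5L), 1:5), "zero variance")
})
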