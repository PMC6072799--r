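# Population statistics on the occurrence matrix and per-sample summaries.

#' Per-sample NUI summary for a 17-genome, five-population cohort
#'
#' Bundled reference dataset: per-individual NUI counts and total inserted
#' base pairs for seventeen individuals across the five continental
#' super-populations (AFR, AMR, EAS, EUR, SAS), as used in the worked
#' examples and the package's statistical acceptance checks.
#'
#' @return `data.frame` with `sample`, `population`, `count`, `bp`.
#' @export
nui_cohort17 <- function() {
  data.frame(
    sample = c("HG02623", "HG03115", "NA19240", "NA19440", "NA19921",
               "HG00733", "HG01971", "NA19789",
               "HG00512", "HG00851", "NA18552", "NA19068",
               "HG00250", "HG00353", "NA20587",
               "HG03838", "NA21125"),
    population = rep(c("AFR", "AMR", "EAS", "EUR", "SAS"),
                     times = c(5L, 3L, 4L, 3L, 2L)),
    count = c(747L, 727L, 762L, 784L, 703L,
              657L, 670L, 709L,
              648L, 667L, 708L, 664L,
              639L, 663L, 621L,
              635L, 730L),
    bp = c(751291, 742200, 777935, 829736, 763748,
           687094, 677269, 724723,
           651655, 692452, 726857, 705625,
           652081, 696507, 622096,
           662632, 728111),
    stringsAsFactors = FALSE
  )
}

#' Frequency filter applied to the occurrence matrix before PCA
#'
#' Removes NUIs carried by exactly 1 or 2 samples (genotype ambiguity) and
#' NUIs carried by every sample (no variance).
#'
#' @param matrix Binary occurrence matrix (samples x NUIs).
#' @return Filtered matrix.
#' @export
pca_filter <- function(matrix) {
  cs <- colSums(matrix)
  matrix[, !(cs %in% c(1L, 2L, nrow(matrix))), drop = FALSE]
}

#' Principal components of the occurrence matrix
#'
#' Columns are centred but not scaled (all entries share the presence/absence
#' scale). Components come out ordered by decreasing explained variance.
#'
#' @param matrix Filtered binary matrix (samples x NUIs).
#' @param k Number of components to return.
#' @param scale. Scale columns to unit variance before decomposition.
#' @return List with `scores` (samples x k), `explained` (variance fractions)
#'   and the full `prcomp` fit.
#' @export
occurrence_pca <- function(matrix, k = 2L, scale. = FALSE) {
  if (nrow(matrix) < 2L || ncol(matrix) < 2L)
    stop("need at least 2 samples and 2 NUIs for PCA")
  fit <- prcomp(matrix, center = TRUE, scale. = scale.)
  k_eff <- min(k, ncol(fit$x))
  if (k_eff < k) warning("rank supports only ", k_eff, " component(s)")
  vars <- fit$sdev^2
  list(scores = fit$x[, seq_len(k_eff), drop = FALSE],
       explained = vars / sum(vars),
       fit = fit)
}

#' One-way analysis of variance across groups
#'
#' Classical between/within decomposition via [stats::aov].
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor).
#' @return List with `f_stat`, `df_between`, `df_within`, `p_value`,
#'   `group_means`, and the underlying `aov` fit.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(f_stat = tab[["F value"]][1L],
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p_value = tab[["Pr(>F)"]][1L],
       group_means = tapply(values, groups, mean),
       fit = fit)
}

#' Tukey honest significant differences after one-way ANOVA
#'
#' Studentized-range adjusted pairwise p-values using the within-group mean
#' square; the Tukey-Kramer correction applies automatically for unbalanced
#' group sizes.
#'
#' @param values,groups As in [anova_oneway()].
#' @param conf_level Confidence level for the intervals.
#' @return `data.frame` with `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit, conf.level = conf_level)$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration and the conditional
#' maximum-likelihood odds ratio; the sample (cross-product) odds ratio is
#' reported alongside since the two estimates differ slightly.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`matrix(c(a, c, b, d), 2, 2)` orientation: `a`/`b` share the first row).
#' @return List with `odds_ratio` (conditional MLE), `sample_odds_ratio`,
#'   `p_value`, and `table`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  ft <- fisher.test(tab)
  sample_or <- if (b * c == 0) {
    warning("zero margin: sample odds ratio degenerate")
    Inf
  } else (a * d) / (b * c)
  list(odds_ratio = unname(ft$estimate),
       sample_odds_ratio = sample_or,
       p_value = ft$p.value,
       table = tab)
}

#' Pearson chi-square test of a sharing-level contingency table
#'
#' @param counts r x c matrix of NUI counts (e.g. sharing level by
#'   primate-presence).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_sharing <- function(counts) {
  counts <- as.matrix(counts)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(ct$expected < 1)) warning("expected cell count below 1")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
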