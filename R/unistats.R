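## Univariate statistics: Shannon diversity, Kruskal-Wallis, Dunn's
## post hoc, Wilcoxon rank-sum, multiplicity corrections, and OLS
## regressions of per-sample minimum novelty on environmental covariates.

#' Shannon diversity index
#'
#' H = -sum p_i log p_i over nonzero proportions, in nats.
#'
#' @param counts Nonnegative count (or proportion) vector, not all zero.
#' @return H in nats.
#' @export
shannon <- function(counts) {
  check_that(all(counts >= 0), "counts must be nonnegative")
  tot <- sum(counts)
  check_that(tot > 0, "counts must not be all zero")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-squared p on g - 1 df (wraps
#' `stats::kruskal.test`). All-identical values yield a degenerate
#' result (NA statistic) rather than an error.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List: `statistic` (H), `df`, `p`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  check_that(nlevels(groups) >= 2L, "need >= 2 groups")
  check_that(all(table(groups) >= 1L), "every group must be non-empty")
  if (length(unique(values)) == 1L) {
    return(list(statistic = NA_real_, df = nlevels(groups) - 1L,
                p = NA_real_, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, degenerate = FALSE)
}

#' Dunn's post hoc test for pairwise group comparisons
#'
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with
#' tie correction T = sum(t^3 - t) / (12(N - 1)), two-sided normal
#' p-values, adjusted by Holm (step-down) or Benjamini-Hochberg
#' (step-up). Intended after a significant omnibus test (not enforced).
#'
#' @param values Numeric response.
#' @param groups Group labels (each group non-empty).
#' @param adjust `"holm"` or `"BH"`.
#' @return `data.frame`: `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("holm", "BH")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  check_that(all(table(groups) >= 1L) && nlevels(droplevels(groups)) >= 2L,
             "every group must be non-empty and >= 2 groups present")
  groups <- droplevels(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- table(groups)
  tie <- table(r)
  tie_term <- sum(tie^3 - tie) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
             p = unname(p),
             p_adjusted = adjust_pvalues(unname(p), method = adjust),
             stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Exact p by enumeration when the pooled size is at most `exact_max_n`
#' and there are no ties; otherwise a normal approximation with tie and
#' continuity corrections (wraps `stats::wilcox.test`).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max_n Largest pooled size for exact enumeration.
#' @return List: `statistic` (U for `x`), `p`, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20) {
  check_that(length(x) >= 1L && length(y) >= 1L,
             "both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y) <= exact_max_n)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), statistic_name = "U",
       p = wt$p.value, exact = exact)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up or Holm step-down with monotonicity
#' enforcement, clipped to \[0, 1\] (wraps `stats::p.adjust`).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"holm"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  check_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Regress per-sample minimum novelty on an environmental covariate
#'
#' Ordinary least squares with R2, the two-sided F-test p, and a fitted
#' line with 95% confidence band for plotting.
#'
#' @param novelty Per-sample minimum novelty values.
#' @param covariate Paired covariate (temperature, pH or crustal
#'   thickness); must not be constant.
#' @return List: `slope`, `intercept`, `r_squared`, `p`, `n`, `band`
#'   (`data.frame` of covariate, fit, lwr, upr).
#' @export
novelty_regression <- function(novelty, covariate) {
  ok <- stats::complete.cases(novelty, covariate)
  novelty <- novelty[ok]; covariate <- covariate[ok]
  check_that(length(novelty) >= 3L, "need >= 3 paired observations")
  check_that(stats::sd(covariate) > 0, "covariate is constant")
  fit <- stats::lm(novelty ~ covariate)
  sm <- summary(fit)
  fp <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE)
  grid <- data.frame(covariate = seq(min(covariate), max(covariate),
                                     length.out = 50))
  band <- cbind(grid,
                stats::predict(fit, grid, interval = "confidence",
                               level = 0.95))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p = unname(fp), n = length(novelty),
       band = band)
}

#' Significance stars for figure-caption thresholds
#'
#' @param p Vector of p-values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for
#'   p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
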