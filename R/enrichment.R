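#' Spearman correlation of GWAS significance with selection scores
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the asymptotic two-sided p-value comes from the t approximation with
#' n - 2 degrees of freedom. Pairs with a missing value in either vector
#' are dropped pairwise.
#'
#' @param x numeric vector (conventionally -log10 GWAS p-values).
#' @param y numeric vector (selection scores), same length.
#' @return list(rho, p_asymptotic, n).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero variance in ranks; correlation undefined")
  rho <- cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (!is.finite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_asymptotic = p, n = n)
}

#' Permutation test for the score-significance correlation
#'
#' Permutes x against fixed y `n_perm` times and recomputes the Spearman
#' rho; the empirical p-value uses the add-one rule
#' (1 + #\{rho_perm >= rho_obs\}) / (n_perm + 1), one-sided greater by
#' default (the question is whether the observed correlation is higher
#' than chance).
#'
#' @inheritParams spearman_correlation
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param scenario optional label carried into the result.
#' @return a `correlation_result` list: scenario, rho, p_asymptotic,
#'   p_permutation, null_rho, n_perm, seed, n.
#' @export
permute_correlation <- function(x, y, n_perm = 10000, seed = 1,
                                alternative = c("greater", "two.sided"),
                                scenario = NA_character_) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical p-value")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  # canonical pair order: the null stream (hence the empirical p) depends
  # only on the multiset of pairs, not on analysis-set row order
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  obs <- spearman_correlation(x, y)
  rxc <- rank(x); rxc <- rxc - mean(rxc)
  ryc <- rank(y); ryc <- ryc - mean(ryc)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  set.seed(seed)
  null_rho <- vapply(seq_len(n_perm),
                     function(i) sum(rxc[sample.int(length(rxc))] * ryc) / denom,
                     numeric(1))
  p_perm <- if (alternative == "greater") empirical_pvalue(null_rho, obs$rho)
            else empirical_pvalue(abs(null_rho), abs(obs$rho))
  structure(list(scenario = scenario, rho = obs$rho,
                 p_asymptotic = obs$p_asymptotic, p_permutation = p_perm,
                 null_rho = null_rho, n_perm = n_perm, seed = seed,
                 n = obs$n, alternative = alternative),
            class = "correlation_result")
}

# 2x2 odds ratio, Woolf CI and p-value.
# counts: a = in-threshold & selected, b = in-threshold & not,
#         c = out & selected, d = out & not.
or_test_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  row_m <- rowSums(tab); col_m <- colSums(tab)
  if (any(row_m == 0) || any(col_m == 0)) {
    return(list(odds_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                p_value = NA_real_, test = NA_character_,
                reason = "zero margin: OR undefined"))
  }
  or <- (a * d) / (b * c)
  if (all(tab > 0)) {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  } else ci <- c(NA_real_, NA_real_)
  if (min(tab) < 5) {
    p <- fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    test <- "chisq"
  }
  list(odds_ratio = or, ci_lo = ci[1], ci_hi = ci[2], p_value = p,
       test = test,
       reason = if (min(tab) == 0) "zero cell: CI undefined" else NA_character_)
}

#' Default GWAS p-value threshold grids
#'
#' Six thresholds for a moderately powered study and nine for a highly
#' powered one (the extra thresholds reach genome-wide significance).
#' These grids are reconstructions — override freely.
#'
#' @param style `"six"` or `"nine"`.
#' @return numeric vector of thresholds.
#' @export
default_thresholds <- function(style = c("six", "nine")) {
  style <- match.arg(style)
  switch(style,
         six = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5),
         nine = c(5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5))
}

#' Threshold-scan contingency enrichment
#'
#' For each GWAS p-value threshold t, cross-classifies the analysis
#' variants (those with a non-missing score for the scenario) by
#' (p < t) x (score >= top-quantile cutoff) and reports the odds ratio,
#' its Woolf 95% confidence interval
#' exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)), and a two-sided
#' p-value (chi-square without continuity correction; Fisher's exact test
#' when any cell is below 5). Significance is judged against a Bonferroni
#' alpha of `alpha` divided by the number of thresholds scanned.
#'
#' @param annotated output of [assign_scores()] on the clumped set.
#' @param scenario `"incomplete"` or `"complete"`.
#' @param p_thresholds thresholds in (0,1); see [default_thresholds()].
#' @param quantile top-score quantile (default 0.95).
#' @param alpha family-wise error rate before Bonferroni division.
#' @return data.frame, one row per threshold: counts a,b,c,d, odds_ratio,
#'   ci_lo, ci_hi, p_value, test, bonferroni_alpha, significant, reason.
#' @export
threshold_enrichment <- function(annotated,
                                 scenario = c("incomplete", "complete"),
                                 p_thresholds = default_thresholds("six"),
                                 quantile = 0.95, alpha = 0.05) {
  scenario <- match.arg(scenario)
  stopifnot(all(p_thresholds > 0 & p_thresholds <= 1))
  thr <- score_cutoff(annotated, scenario, quantile)
  keep <- !is.na(annotated[[paste0("score_", scenario)]])
  dat <- annotated[keep, , drop = FALSE]
  sel <- is_selected(dat, thr)
  bonf <- alpha / length(p_thresholds)
  rows <- lapply(p_thresholds, function(t) {
    assoc <- dat$p_value < t
    a <- sum(assoc & sel); b <- sum(assoc & !sel)
    c_ <- sum(!assoc & sel); d <- sum(!assoc & !sel)
    r <- or_test_2x2(a, b, c_, d)
    data.frame(scenario = scenario, p_threshold = t,
               a = a, b = b, c = c_, d = d,
               odds_ratio = r$odds_ratio, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
               p_value = r$p_value, test = r$test %||% NA_character_,
               bonferroni_alpha = bonf,
               significant = !is.na(r$p_value) && r$p_value < bonf,
               reason = r$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "score_cutoff") <- thr
  out
}

#' Minor-allele effect-direction permutation test
#'
#' The focal set is the associated-and-selected variants (GWAS p below
#' `p_threshold` and score in the top quantile). The observed statistic is
#' the median of their minor-allele odds ratios; under the default
#' `"subset"` null a draw is the median OR of an equally sized variant
#' subset sampled without replacement from the associated margin (variants
#' with GWAS p below the threshold) — equivalent to permuting the score
#' labels given the focal-set size, and exactly calibrated when scores are
#' exchangeable against the GWAS columns. The empirical p-value is
#' (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' Two alternative nulls are provided: `"fullset"` samples subsets from
#' the whole analysis set, ignoring the association margin — when OR
#' magnitude and significance are linked (they are, in real summary
#' statistics) this null under-disperses and is anti-conservative, so it
#' is not the default; `"signflip"` inverts each focal OR with
#' probability 1/2, conditioning on the focal magnitudes.
#'
#' @param annotated minor-allele-oriented, score-annotated clumped set.
#' @param scenario `"incomplete"` or `"complete"`.
#' @param p_threshold GWAS p-value threshold defining "associated".
#' @param quantile top-score quantile (default 0.95).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param null `"subset"` (default), `"fullset"` or `"signflip"`.
#' @return a `direction_result` list: set_size, observed_median_or,
#'   null_medians, p_permutation, n_perm, seed.
#' @export
direction_test <- function(annotated, scenario = c("incomplete", "complete"),
                           p_threshold = 0.1, quantile = 0.95,
                           n_perm = 10000, seed = 1,
                           null = c("subset", "fullset", "signflip")) {
  scenario <- match.arg(scenario)
  null <- match.arg(null)
  thr <- score_cutoff(annotated, scenario, quantile)
  sel <- is_selected(annotated, thr)
  assoc <- annotated$p_value < p_threshold
  focal <- sel & assoc
  m <- sum(focal)
  if (m == 0)
    stop("focal set empty: no variant has p < ", p_threshold,
         " and ", scenario, " score >= ", signif(thr$cutoff, 4))
  or_all <- annotated$odds_ratio
  observed <- median(or_all[focal])
  set.seed(seed)
  null_medians <- if (null %in% c("subset", "fullset")) {
    pool <- if (null == "subset") which(assoc) else seq_len(nrow(annotated))
    # sorted pool makes the null stream row-order invariant
    pool_or <- sort(or_all[pool])
    vapply(seq_len(n_perm),
           function(i) median(pool_or[sample.int(length(pool_or), m)]),
           numeric(1))
  } else {
    or_f <- sort(or_all[focal])
    vapply(seq_len(n_perm),
           function(i) median(or_f^sample(c(-1, 1), m, replace = TRUE)),
           numeric(1))
  }
  structure(list(scenario = scenario, set_size = m,
                 observed_median_or = observed, null_medians = null_medians,
                 p_permutation = empirical_pvalue(null_medians, observed),
                 n_perm = n_perm, seed = seed, null = null),
            class = "direction_result")
}

#' Multiple-testing adjustment
#'
#' Bonferroni (min(1, m p)) or Benjamini-Hochberg step-up FDR with
#' monotonicity enforcement; both delegate to [stats::p.adjust()].
#'
#' @param pvalues numeric vector in (0,1]; empty input gives empty output.
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust <- function(pvalues, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p.adjust(pvalues, method = if (method == "bonferroni") "bonferroni" else "BH")
}
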