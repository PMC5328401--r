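test_that("Spearman rho handles monotone and tied inputs", {
  expect_equal(spearman_correlation(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_correlation(1:3, c(30, 20, 10))$rho, -1)
  # tied case against mid-rank Pearson with hand-enumerated ranks:
  # x=(1,2,2,4) -> ranks (1, 2.5, 2.5, 4); y=(1,3,2,4) -> ranks (1,3,2,4)
  got <- spearman_correlation(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(got$rho, cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)))
  # cross-check rho and t-approximation p against the stats implementation
  set.seed(3)
  x <- rnorm(50); y <- x + rnorm(50)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  got2 <- spearman_correlation(x, y)
  expect_equal(got2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got2$p_asymptotic, ct$p.value, tolerance = 1e-4)
  expect_error(spearman_correlation(1:3, c(2, 2, 2)), "variance")
})

test_that("permutation correlation p-values follow the add-one rule", {
  set.seed(5)
  x <- rnorm(100)
  r1 <- permute_correlation(x, x, n_perm = 200, seed = 9)
  expect_equal(r1$p_permutation, 1 / 201)  # observed rho=1 is maximal
  # determinism: same seed gives identical null vector
  r2 <- permute_correlation(x, x, n_perm = 200, seed = 9)
  expect_identical(r1$null_rho, r2$null_rho)
  # invariance to analysis-set row order
  y <- rnorm(100)
  o <- sample(100)
  a <- permute_correlation(x, y, n_perm = 200, seed = 7)
  b <- permute_correlation(x[o], y[o], n_perm = 200, seed = 7)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_permutation, b$p_permutation)
  expect_gte(a$p_permutation, 1 / 201)
  expect_warning(permute_correlation(x, y, n_perm = 50, seed = 1), "coarse")
})

test_that("2x2 odds ratios, Woolf CIs and p-values match direct arithmetic", {
  r <- sweepenrich:::or_test_2x2(10, 90, 5, 95)
  expect_equal(r$odds_ratio, (10 * 95) / (90 * 5))  # 2.111...
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(r$ci_lo, exp(log(19 / 9) - 1.96 * se))
  expect_equal(r$ci_hi, exp(log(19 / 9) + 1.96 * se))
  set.seed(13)
  for (i in 1:100) {
    cells <- rpois(4, sample(c(3, 20, 80), 1)) + 1
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    r <- sweepenrich:::or_test_2x2(a, b, c_, d)
    expect_equal(r$odds_ratio, (a * d) / (b * c_))
    expect_equal(r$ci_hi / r$ci_lo,
                 exp(2 * 1.96 * sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)))
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expected_p <- if (min(tab) < 5) fisher.test(tab)$p.value
                  else chisq.test(tab, correct = FALSE)$p.value
    expect_equal(r$p_value, expected_p)
  }
})

test_that("threshold scan builds full-margin tables and flags zero margins", {
  set.seed(17)
  ann <- make_variants(pos = 1:200, p = runif(200))
  ann$score_incomplete <- rnorm(200)
  scan <- threshold_enrichment(ann, "incomplete",
                               p_thresholds = c(0.05, 0.5, 1.0))
  expect_equal(nrow(scan), 3)
  expect_true(all(scan$a + scan$b + scan$c + scan$d == 200))
  expect_equal(scan$bonferroni_alpha, rep(0.05 / 3, 3))
  # threshold 1.0 puts everything in-threshold: c = d = 0, OR undefined
  last <- scan[scan$p_threshold == 1.0, ]
  expect_equal(last$c + last$d, 0)
  expect_true(is.na(last$odds_ratio))
  expect_match(last$reason, "margin")
  expect_equal(last$a, sum(is_selected(ann, attr(scan, "score_cutoff"))))
})

test_that("variants without a score are excluded from the scan", {
  ann <- make_variants(pos = 1:100, p = seq(0.001, 1, length.out = 100))
  ann$score_incomplete <- c(rnorm(60), rep(NA, 40))
  scan <- threshold_enrichment(ann, "incomplete", p_thresholds = 0.5)
  expect_equal(scan$a + scan$b + scan$c + scan$d, 60)
})

test_that("direction test statistic, determinism and degenerate ties", {
  set.seed(23)
  ann <- make_variants(pos = 1:400, p = runif(400),
                       or = exp(rnorm(400, 0, 0.1)))
  ann$score_incomplete <- rnorm(400)
  d1 <- direction_test(ann, "incomplete", p_threshold = 0.5, n_perm = 300,
                       seed = 31)
  d2 <- direction_test(ann, "incomplete", p_threshold = 0.5, n_perm = 300,
                       seed = 31)
  expect_identical(d1$null_medians, d2$null_medians)
  expect_gte(d1$p_permutation, 1 / 301)
  thr <- score_cutoff(ann, "incomplete")
  focal <- is_selected(ann, thr) & ann$p_value < 0.5
  expect_equal(d1$observed_median_or, median(ann$odds_ratio[focal]))
  expect_equal(d1$set_size, sum(focal))
  # all ORs identical: ties count as >=, p is maximal
  ann$odds_ratio <- 1
  dt <- direction_test(ann, "incomplete", p_threshold = 0.5, n_perm = 100,
                       seed = 1)
  expect_equal(dt$observed_median_or, 1)
  expect_equal(dt$p_permutation, 1)
  # empty focal set is a hard error
  expect_error(direction_test(ann, "incomplete", p_threshold = 1e-12),
               "focal set empty")
})

test_that("multiplicity adjustment matches hand-computed values", {
  expect_equal(adjust(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust(0.04, "bonferroni"), 0.04)
  expect_equal(adjust(0.04, "bh_fdr"), 0.04)
  # BH step-up: (0.01, 0.011, 0.8) -> (0.0165, 0.0165, 0.8)
  expect_equal(adjust(c(0.01, 0.011, 0.8), "bh_fdr"),
               c(0.0165, 0.0165, 0.8))
  expect_identical(adjust(numeric(0), "bonferroni"), numeric(0))
})
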