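test_that("QC filter applies strict MAF and info cutoffs", {
  v <- make_variants(pos = c(100, 200, 300, 400),
                     eaf = c(0.01, 0.98, 0.3, 0.021),
                     info = c(1, 1, 0.95, 0.9))
  out <- qc_filter(v, clump_params())
  # eaf 0.01 and 0.98 fail MAF > 0.02; info 0.9 is not > 0.9
  expect_equal(out$pos, 300)
  # boundary: MAF exactly 0.02 removed (strict inequality)
  v2 <- make_variants(pos = 1, eaf = 0.02)
  expect_equal(nrow(qc_filter(v2)), 0)
  # missing info passes by default, fails in strict mode
  v3 <- make_variants(pos = 1, eaf = 0.3, info = NA_real_)
  expect_equal(nrow(qc_filter(v3)), 1)
  expect_equal(nrow(qc_filter(v3, clump_params(strict_info = TRUE))), 0)
})

test_that("clumping keeps the more significant member of a tight pair", {
  v <- make_variants(pos = c(100000, 110000), p = c(1e-6, 1e-4))
  ld_hi <- ld_pairs("v001", "v002", 0.9)
  ld_lo <- ld_pairs("v001", "v002", 0.1)
  expect_equal(clump(v, ld_hi)$snp_id, "v001")
  expect_equal(sort(clump(v, ld_lo)$snp_id), c("v001", "v002"))
  # r2 exactly at the cutoff claims the neighbour (removal is >= r2_max)
  ld_eq <- ld_pairs("v001", "v002", 0.25)
  expect_equal(clump(v, ld_eq)$snp_id, "v001")
  # outside the window: both kept regardless of r2
  v_far <- make_variants(pos = c(100000, 700000), p = c(1e-6, 1e-4))
  expect_equal(nrow(clump(v_far, ld_hi)), 2)
})

test_that("variants absent from the LD reference are kept with a warning", {
  v <- make_variants(pos = c(100, 200), p = c(1e-6, 1e-4))
  ld <- ld_pairs("x", "y", 0.5)  # neither variant known
  expect_warning(out <- clump(v, ld), "absent")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_missing_ld"), 2)
})

test_that("greedy clump matches the exhaustive oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_clump_instance(seed)
    ld <- if (nrow(inst$pairs) > 0)
      ld_pairs(inst$pairs$a, inst$pairs$b, inst$pairs$r2)
    else ld_blocks(setNames("B1", inst$variants$snp_id[1]))
    got <- suppressWarnings(
      clump(inst$variants, ld,
            clump_params(window_bp = inst$window_bp, r2_max = inst$r2_max)))
    expect_identical(got$snp_id, oracle_clump(inst), label = paste("seed", seed))
  }
})

test_that("clump output satisfies the independence invariant", {
  for (seed in 101:110) {
    inst <- random_clump_instance(seed)
    if (nrow(inst$pairs) == 0) next
    ld <- ld_pairs(inst$pairs$a, inst$pairs$b, inst$pairs$r2)
    kept <- suppressWarnings(
      clump(inst$variants, ld,
            clump_params(window_bp = inst$window_bp, r2_max = inst$r2_max)))
    expect_true(all(kept$snp_id %in% inst$variants$snp_id))
    if (nrow(kept) > 1) {
      cmb <- combn(nrow(kept), 2)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        if (kept$chrom[i] == kept$chrom[j] &&
            abs(kept$pos[i] - kept$pos[j]) <= inst$window_bp)
          expect_lt(ld_r2(ld, kept$snp_id[i], kept$snp_id[j]), inst$r2_max)
      }
    }
  }
})

test_that("the MHC region keeps only its most significant variant", {
  v <- make_variants(pos = c(26e6, 27e6, 28e6, 40e6), chrom = "6",
                     p = c(1e-5, 1e-9, 1e-3, 0.5))
  out <- restrict_mhc(v)
  expect_equal(out$pos, c(27e6, 40e6))
  # no MHC variants: unchanged
  v2 <- make_variants(pos = c(1e6, 2e6), chrom = "6", p = c(0.1, 0.2))
  expect_identical(restrict_mhc(v2), v2)
  # tie in p: smallest position kept
  v3 <- make_variants(pos = c(27e6, 26e6, 28e6), chrom = "6",
                      p = c(1e-4, 1e-4, 1e-2))
  expect_equal(restrict_mhc(v3)$pos, 26e6)
})

test_that("minor-allele orientation inverts ORs and is idempotent", {
  v <- make_variants(pos = c(1, 2, 3), eaf = c(0.7, 0.3, 0.5),
                     or = c(2.0, 1.2, 1.5))
  out <- orient_to_minor(v)
  expect_equal(out$eaf, c(0.3, 0.3, 0.5))
  expect_equal(out$odds_ratio, c(0.5, 1.2, 1.5))  # eaf 0.5: no flip
  expect_equal(out$effect_allele[1], "G")
  expect_equal(out$other_allele[1], "A")
  # idempotence (re-orienting an oriented table changes nothing) and
  # preserved quantities on random variants
  set.seed(4)
  r <- make_variants(pos = 1:50, eaf = runif(50, 0.01, 0.99),
                     or = exp(rnorm(50, 0, 0.5)))
  once <- orient_to_minor(r)
  expect_equal(orient_to_minor(once), once)
  expect_equal(pmin(once$eaf, 1 - once$eaf), pmin(r$eaf, 1 - r$eaf))
  expect_equal(abs(log(once$odds_ratio)), abs(log(r$odds_ratio)))
  expect_true(all(once$eaf <= 0.5))
})
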