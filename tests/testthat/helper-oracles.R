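# Independent brute-force oracles and random-instance generators.
# Everything here is deliberately naive (quadratic loops, explicit
# enumeration) and shares no code with the package internals it checks.

# ---- random clumping instances ------------------------------------------

random_clump_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:50, 1)
  chrom <- sample(c("1", "2"), n, replace = TRUE)
  pos <- sample(1:2000000, n)
  v <- data.frame(
    snp_id = sprintf("s%03d", seq_len(n)),
    chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    odds_ratio = exp(rnorm(n, 0, 0.1)),
    p_value = runif(n),
    eaf = runif(n, 0.05, 0.5), info = 1, stringsAsFactors = FALSE)
  # sprinkle p-value ties to exercise the tie-break
  if (n > 4) v$p_value[sample(n, 2)] <- 0.5
  # random sparse r2 pairs, biased to nearby variants, incl. exact 0.25
  npair <- sample(0:(n * 2), 1)
  if (npair > 0) {
    a <- sample(n, npair, replace = TRUE)
    b <- sample(n, npair, replace = TRUE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    r2 <- sample(c(runif(length(a)), 0.25, 0.9), length(a))
  } else a <- b <- integer(0)
  # some variants absent from the LD reference entirely
  present <- unique(c(a, b))
  pairs <- if (length(a) > 0)
    data.frame(a = v$snp_id[a], b = v$snp_id[b], r2 = r2[seq_along(a)],
               stringsAsFactors = FALSE)
  else data.frame(a = character(), b = character(), r2 = numeric())
  window <- sample(c(100000, 250000, 500000), 1)
  list(variants = v, pairs = pairs, window_bp = window, r2_max = 0.25)
}

# symmetric r2 matrix lookup built directly from the pair list
oracle_r2_matrix <- function(inst) {
  n <- nrow(inst$variants)
  M <- diag(1, n)
  if (nrow(inst$pairs) > 0) {
    ia <- match(inst$pairs$a, inst$variants$snp_id)
    ib <- match(inst$pairs$b, inst$variants$snp_id)
    for (k in seq_along(ia)) {
      M[ia[k], ib[k]] <- inst$pairs$r2[k]
      M[ib[k], ia[k]] <- inst$pairs$r2[k]
    }
  }
  M
}

# exhaustive greedy clump: explicit loop over the p-ranked order
oracle_clump <- function(inst) {
  v <- inst$variants
  M <- oracle_r2_matrix(inst)
  chrom_num <- ifelse(v$chrom == "1", 1, 2)
  remaining <- seq_len(nrow(v))
  kept <- integer(0)
  while (length(remaining) > 0) {
    o <- order(v$p_value[remaining], chrom_num[remaining], v$pos[remaining])
    i <- remaining[o[1]]
    kept <- c(kept, i)
    drop <- vapply(remaining, function(j) {
      j != i && v$chrom[j] == v$chrom[i] &&
        abs(v$pos[j] - v$pos[i]) <= inst$window_bp &&
        M[i, j] >= inst$r2_max
    }, logical(1))
    remaining <- setdiff(remaining[!drop], i)
  }
  v$snp_id[kept][order(chrom_num[kept], v$pos[kept])]
}

# ---- brute-force interval overlap ---------------------------------------

# score per variant: max score over regions with start <= pos-1 < end
oracle_assign <- function(variants, regions, scenario) {
  vapply(seq_len(nrow(variants)), function(i) {
    best <- NA_real_
    for (j in seq_len(nrow(regions))) {
      if (regions$scenario[j] != scenario) next
      if (regions$chrom[j] != variants$chrom[i]) next
      p0 <- variants$pos[i] - 1
      if (regions$start[j] <= p0 && p0 < regions$end[j])
        best <- max(best, regions$score[j], na.rm = TRUE)
    }
    best
  }, numeric(1))
}

# genes whose [start - flank, end + flank) covers pos-1
oracle_map_genes <- function(variants, genes, flank) {
  lapply(seq_len(nrow(variants)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != variants$chrom[i]) next
      p0 <- variants$pos[i] - 1
      if (genes$start[j] - flank <= p0 && p0 < genes$end[j] + flank)
        hits <- c(hits, genes$gene_id[j])
    }
    sort(unique(hits))
  })
}

# ---- exact hypergeometric tail ------------------------------------------

oracle_hyper_upper <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# ---- tiny variant-table builder -----------------------------------------

make_variants <- function(pos, p = NULL, or = NULL, eaf = NULL,
                          chrom = "1", info = 1) {
  n <- length(pos)
  data.frame(snp_id = sprintf("v%03d", seq_len(n)), chrom = chrom, pos = pos,
             effect_allele = "A", other_allele = "G",
             odds_ratio = or %||% rep(1.1, n),
             p_value = p %||% rep(0.5, n),
             eaf = eaf %||% rep(0.3, n), info = info,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
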