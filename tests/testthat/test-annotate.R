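region_df <- function(chrom, start, end, score, scenario = "incomplete") {
  data.frame(chrom = chrom, start = start, end = end, scenario = scenario,
             score = score, stringsAsFactors = FALSE)
}

test_that("score assignment follows the half-open coordinate rule", {
  v <- make_variants(pos = c(150, 100, 101, 200, 201))
  reg <- region_df("1", 100, 200, 2.0)
  out <- assign_scores(v, reg)
  # pos p overlaps [s,e) iff s <= p-1 < e: 101..200 inside, 100 and 201 out
  expect_equal(out$score_incomplete, c(2, NA, 2, 2, NA))
  expect_true(all(is.na(out$score_complete)))
})

test_that("overlapping regions resolve to the maximum score", {
  v <- make_variants(pos = 150)
  reg <- rbind(region_df("1", 100, 200, 1.0), region_df("1", 140, 160, 3.0))
  expect_equal(assign_scores(v, reg)$score_incomplete, 3.0)
})

test_that("both scenarios are carried independently", {
  v <- make_variants(pos = 150)
  reg <- rbind(region_df("1", 100, 200, 1.5, "incomplete"),
               region_df("1", 100, 200, -0.5, "complete"))
  out <- assign_scores(v, reg)
  expect_equal(out$score_incomplete, 1.5)
  expect_equal(out$score_complete, -0.5)
})

test_that("nearest-rank cutoff flags the top score set", {
  ann <- make_variants(pos = 1:100)
  ann$score_incomplete <- sample(1:100)  # order must not matter
  thr <- score_cutoff(ann, "incomplete", 0.95)
  expect_equal(thr$cutoff, 95)
  expect_equal(sum(is_selected(ann, thr)), 6)  # 95..100 under >=
  ann20 <- make_variants(pos = 1:20)
  ann20$score_incomplete <- 1:20
  expect_equal(score_cutoff(ann20, "incomplete", 0.95)$cutoff, 19)
  # constant scores: everyone is flagged
  annc <- make_variants(pos = 1:30)
  annc$score_incomplete <- rep(2.5, 30)
  thrc <- suppressWarnings(score_cutoff(annc, "incomplete"))
  expect_true(all(is_selected(annc, thrc)))
  # all-missing scores: hard error
  annm <- make_variants(pos = 1:25)
  annm$score_incomplete <- NA_real_
  expect_error(score_cutoff(annm, "incomplete"), "non-missing")
})

test_that("flagged fraction respects the nearest-rank guarantee", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(25:400, 1)
    q <- runif(1, 0.8, 0.99)
    ann <- make_variants(pos = seq_len(n))
    ann$score_incomplete <- rnorm(n)  # continuous: distinct a.s.
    thr <- score_cutoff(ann, "incomplete", q)
    expect_lte(mean(is_selected(ann, thr)), (1 - q) + 1 / n)
  }
})

test_that("gene mapping honours the 50 kb flank, many-to-many", {
  genes <- data.frame(gene_id = c("A", "B", "C"), chrom = "1",
                      start = c(100000, 150000, 500000),
                      end = c(160000, 210000, 520000),
                      stringsAsFactors = FALSE)
  v <- make_variants(pos = c(90000,    # 10 kb upstream of A
                             155000,   # inside A and B
                             580000,   # 60 kb past C: not mapped
                             565000))  # 45 kb past C: mapped
  out <- map_genes(v, genes, flank_bp = 50000)
  expect_equal(out$genes[[1]], "A")
  expect_equal(out$genes[[2]], c("A", "B"))
  expect_equal(out$genes[[3]], character(0))
  expect_equal(out$genes[[4]], "C")
  # nearest-only mode collapses multi-hits to the closest gene body
  v2 <- make_variants(pos = 120000)  # inside A, 30 kb before B
  expect_equal(map_genes(v2, genes, nearest_only = TRUE)$genes[[1]], "A")
})

test_that("overlap joins match the quadratic brute-force oracle", {
  set.seed(21)
  for (i in 1:40) {
    nv <- sample(10:200, 1); nr <- sample(2:50, 1); ng <- sample(2:30, 1)
    v <- make_variants(pos = sample(1:500000, nv),
                       chrom = sample(c("1", "2"), nv, replace = TRUE))
    reg <- data.frame(chrom = sample(c("1", "2"), nr, replace = TRUE),
                      start = sample(0:400000, nr), stringsAsFactors = FALSE)
    reg$end <- reg$start + sample(1000:200000, nr, replace = TRUE)
    reg$scenario <- sample(c("incomplete", "complete"), nr, replace = TRUE)
    reg$score <- rnorm(nr)
    got <- assign_scores(v, reg)
    expect_equal(got$score_incomplete, oracle_assign(v, reg, "incomplete"))
    expect_equal(got$score_complete, oracle_assign(v, reg, "complete"))
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(ng)),
                        chrom = sample(c("1", "2"), ng, replace = TRUE),
                        start = sample(0:400000, ng), stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(1000:100000, ng, replace = TRUE)
    flank <- sample(c(0, 10000, 50000), 1)
    gm <- map_genes(v, genes, flank_bp = flank)
    expect_equal(gm$genes, oracle_map_genes(v, genes, flank))
  }
})
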