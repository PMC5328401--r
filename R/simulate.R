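#' Synthetic-study configuration
#'
#' Describes a complete synthetic study: GWAS summary statistics laid out
#' on one synthetic chromosome in contiguous LD blocks, a tiling
#' selection-score track for both sweep scenarios, gene intervals, and
#' term annotations — with plantable coupling between GWAS significance
#' and score (`assoc_coupling`), excess risk-direction minor alleles in
#' the selected-and-associated set (`direction_prob`), and one
#' over-represented term (`planted_term_fold`).
#'
#' The generative model: minor-allele log OR ~ Normal(0, `effect_sd`);
#' the standard error implied by the minor allele frequency and a nominal
#' study size (`n_study`) gives z = log(OR)/SE and a two-sided p-value, so
#' effect magnitude and significance are linked the way real summary
#' statistics are; for variants inside top-`quantile` score regions,
#' -log10 p is then shifted by `assoc_coupling` times the region score.
#' Within the selected-and-associated set, the minor-allele risk direction
#' (OR > 1) is resampled to probability `direction_prob` (sign flips leave
#' |z|, hence p, unchanged). MAF is uniform on (`maf_min`, 0.5).
#'
#' @param n_variants number of variants.
#' @param n_blocks number of LD blocks (within-block r2 = `block_r2`,
#'   cross-block r2 = 0).
#' @param block_r2 within-block r-squared.
#' @param window_bp physical span allocated to one LD block, in bp.
#' @param n_regions number of tiling score regions.
#' @param score_mean,score_sd normal score distribution, named per
#'   scenario (`incomplete`, `complete`).
#' @param coupling_scenario scenario whose scores drive the planted
#'   coupling and directionality.
#' @param assoc_coupling gamma: shift in -log10 p per unit score for
#'   variants in top-quantile regions (0 = null).
#' @param direction_prob pi: probability of minor-allele OR > 1 within the
#'   selected-and-associated set (0.5 = null).
#' @param assoc_p_threshold GWAS p threshold defining "associated" for the
#'   planted directionality and the planted term.
#' @param quantile top-score quantile defining "selected" regions.
#' @param effect_sd tau: SD of the minor-allele log OR.
#' @param n_study nominal study size implying the log-OR standard error
#'   1/sqrt(2 maf (1-maf) n_study).
#' @param maf_min lower MAF bound.
#' @param info_range range of the uniform imputation info score.
#' @param n_genes number of tiling gene intervals.
#' @param gene_flank_bp flank used to define the planted term's focal
#'   gene pool.
#' @param n_terms number of random annotation terms.
#' @param term_size_range inclusive range of random term sizes.
#' @param planted_term_fold target fold enrichment of the planted term
#'   (0 = no planted term).
#' @param planted_term_size gene count of the planted term.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_variants = 2000, n_blocks = 400, block_r2 = 0.9,
                       window_bp = 10000, n_regions = 100,
                       score_mean = c(incomplete = 0, complete = 0),
                       score_sd = c(incomplete = 1, complete = 1),
                       coupling_scenario = "incomplete",
                       assoc_coupling = 0, direction_prob = 0.5,
                       assoc_p_threshold = 0.1, quantile = 0.95,
                       effect_sd = 0.02, n_study = 10000, maf_min = 0.02,
                       info_range = c(0.95, 1), n_genes = 150,
                       gene_flank_bp = 50000, n_terms = 50,
                       term_size_range = c(5, 30), planted_term_fold = 0,
                       planted_term_size = 20, seed = 1) {
  stopifnot(n_variants > 0, n_blocks > 0, n_blocks <= n_variants,
            block_r2 >= 0, block_r2 <= 1, window_bp > 0, n_regions > 0,
            coupling_scenario %in% c("incomplete", "complete"),
            assoc_coupling >= 0, direction_prob >= 0, direction_prob <= 1,
            assoc_p_threshold > 0, assoc_p_threshold <= 1,
            quantile > 0, quantile < 1, effect_sd > 0, n_study > 0,
            maf_min > 0, maf_min < 0.5, length(info_range) == 2,
            n_genes > 0, n_terms >= 0, length(term_size_range) == 2,
            term_size_range[1] >= 1, term_size_range[2] >= term_size_range[1],
            planted_term_fold >= 0, planted_term_size >= 1, seed == round(seed))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic study bundle
#'
#' Deterministically (given `config$seed`) generates GWAS summary
#' statistics, a pairwise LD reference, score tracks for both scenarios,
#' gene intervals, term annotations, and a `truth` record of every
#' planted membership, per the model described in [sim_config()].
#'
#' @param config a [sim_config()].
#' @return a `sim_bundle` list: gwas, ld (an `ld_reference`),
#'   ld_pairs_df, track, genes, terms, truth, config.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_variants
  per_block <- ceiling(n / config$n_blocks)
  block <- rep(seq_len(config$n_blocks), each = per_block)[seq_len(n)]
  spacing <- max(1, floor(config$window_bp / per_block))
  within <- unlist(lapply(table(block), seq_len), use.names = FALSE)
  pos <- (block - 1) * config$window_bp + within * spacing
  genome_end <- config$n_blocks * config$window_bp + config$window_bp

  # score regions tile [0, genome_end)
  b <- round(seq(0, genome_end, length.out = config$n_regions + 1))
  region_of <- findInterval(pos - 1, b)  # 1..n_regions
  scen_names <- c("incomplete", "complete")
  region_scores <- lapply(setNames(scen_names, scen_names), function(sc) {
    rnorm(config$n_regions, config$score_mean[[sc]], config$score_sd[[sc]])
  })
  track <- do.call(rbind, lapply(scen_names, function(sc) {
    data.frame(chrom = "1", start = b[-length(b)], end = b[-1],
               scenario = sc, score = region_scores[[sc]],
               stringsAsFactors = FALSE)
  }))

  # selected = variants inside top-quantile regions of the coupling scenario
  rs <- region_scores[[config$coupling_scenario]]
  cutoff_r <- nearest_rank_quantile(rs, config$quantile)
  selected_regions <- which(rs >= cutoff_r)
  selected <- region_of %in% selected_regions
  v_score <- rs[region_of]

  # alleles, frequencies, info
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(x) sample(setdiff(bases, x), 1), character(1))
  maf <- runif(n, config$maf_min, 0.5)
  eaf <- ifelse(runif(n) < 0.5, maf, 1 - maf)
  info <- runif(n, config$info_range[1], config$info_range[2])

  # effects and p-values: z-linked, coupling shift on -log10 p, then the
  # log-OR magnitude is re-derived from the final p so that |log OR| and
  # significance stay coherently linked for shifted variants too
  lor <- rnorm(n, 0, config$effect_sd)
  se <- 1 / sqrt(2 * maf * (1 - maf) * config$n_study)
  p <- 2 * pnorm(-abs(lor / se))
  mlp <- -log10(p)
  mlp[selected] <- mlp[selected] + config$assoc_coupling * v_score[selected]
  p <- pmax(pmin(10^(-mlp), 1), 1e-300)
  lor <- sign(lor) * se * qnorm(1 - p / 2)
  associated <- p < config$assoc_p_threshold
  focal <- selected & associated
  if (any(focal)) {
    sgn <- ifelse(runif(sum(focal)) < config$direction_prob, 1, -1)
    lor[focal] <- sgn * abs(lor[focal])
  }
  or_effect <- exp(ifelse(eaf <= 0.5, lor, -lor))

  snp_id <- sprintf("rs%06d", seq_len(n))
  gwas <- data.frame(snp_id = snp_id, chrom = "1", pos = pos,
                     effect_allele = ea, other_allele = oa,
                     odds_ratio = or_effect, p_value = p, eaf = eaf,
                     info = info, stringsAsFactors = FALSE)

  # pairwise LD: all within-block pairs at block_r2
  pair_idx <- do.call(cbind, lapply(split(seq_len(n), block), function(ii) {
    if (length(ii) < 2) matrix(integer(0), nrow = 2) else combn(ii, 2)
  }))
  ld_pairs_df <- data.frame(snp_a = snp_id[pair_idx[1, ]],
                            snp_b = snp_id[pair_idx[2, ]],
                            r2 = rep(config$block_r2, ncol(pair_idx)),
                            stringsAsFactors = FALSE)
  ld <- ld_pairs(ld_pairs_df$snp_a, ld_pairs_df$snp_b, ld_pairs_df$r2)

  # genes tile the genome with gaps (70% occupancy of each slot)
  slot <- genome_end / config$n_genes
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                      chrom = "1",
                      start = round((seq_len(config$n_genes) - 1) * slot),
                      end = round((seq_len(config$n_genes) - 1) * slot +
                                    0.7 * slot),
                      stringsAsFactors = FALSE)

  # term annotations; optionally one planted over-represented term
  all_genes <- genes$gene_id
  # the focal gene pool is only needed to place the planted term
  focal_genes <- if (config$planted_term_fold > 0 && any(focal)) {
    gene_list_of(map_genes(gwas[focal, , drop = FALSE], genes,
                           flank_bp = config$gene_flank_bp))
  } else character(0)
  terms <- lapply(seq_len(config$n_terms), function(i) {
    size <- sample(seq(config$term_size_range[1],
                       config$term_size_range[2]), 1)
    list(term_id = sprintf("T%04d", i),
         term_name = sprintf("random term %d", i),
         genes = sort(sample(all_genes, min(size, length(all_genes)))))
  })
  planted_term_id <- NA_character_
  if (config$planted_term_fold > 0) {
    K <- config$planted_term_size
    n0 <- length(focal_genes)
    k <- round(config$planted_term_fold * K * n0 / length(all_genes))
    if (n0 == 0 || k < 1 || k > K || k > n0)
      stop("infeasible planted term: fold ", config$planted_term_fold,
           " with term size ", K, ", ", n0, " focal genes and ",
           length(all_genes), " genes implies overlap k = ", k)
    planted_term_id <- "T_PLANTED"
    terms <- c(terms, list(list(
      term_id = planted_term_id, term_name = "planted enriched term",
      genes = sort(c(sample(focal_genes, k),
                     sample(setdiff(all_genes, focal_genes), K - k))))))
  }
  annotations <- data.frame(
    term_id = vapply(terms, `[[`, character(1), "term_id"),
    term_name = vapply(terms, `[[`, character(1), "term_name"),
    stringsAsFactors = FALSE)
  annotations$genes <- lapply(terms, `[[`, "genes")

  truth <- list(config = config,
                block_of = setNames(sprintf("B%04d", block), snp_id),
                selected_regions = selected_regions,
                selected = snp_id[selected],
                associated = snp_id[associated],
                focal = snp_id[focal],
                focal_genes = focal_genes,
                planted_term_id = planted_term_id)
  structure(list(gwas = gwas, ld = ld, ld_pairs_df = ld_pairs_df,
                 track = track, genes = genes, terms = annotations,
                 truth = truth, config = config),
            class = "sim_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle in the package's external formats: `gwas.tsv` (header
#' SNP CHR BP A1 A2 OR P FRQ INFO), `ld.tsv` (snp_a, snp_b, r2),
#' `track_incomplete.bed` / `track_complete.bed` and `genes.bed`
#' (headerless 4-column BED-like), `terms.gmt`, and `truth.json`. Output
#' is byte-deterministic given the bundle.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  g <- bundle$gwas
  gw <- data.frame(SNP = g$snp_id, CHR = g$chrom, BP = g$pos,
                   A1 = g$effect_allele, A2 = g$other_allele,
                   OR = sprintf("%.17g", g$odds_ratio),
                   P = sprintf("%.17g", g$p_value),
                   FRQ = sprintf("%.17g", g$eaf),
                   INFO = sprintf("%.17g", g$info), stringsAsFactors = FALSE)
  write.table(gw, path("gwas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$ld_pairs_df, path("ld.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (sc in c("incomplete", "complete")) {
    tr <- bundle$track[bundle$track$scenario == sc, , drop = FALSE]
    write.table(data.frame(paste0("chr", tr$chrom), tr$start, tr$end,
                           sprintf("%.17g", tr$score)),
                path(paste0("track_", sc, ".bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(data.frame(paste0("chr", bundle$genes$chrom),
                         bundle$genes$start, bundle$genes$end,
                         bundle$genes$gene_id),
              path("genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(vapply(seq_len(nrow(bundle$terms)), function(i) {
    paste(c(bundle$terms$term_id[i], bundle$terms$term_name[i],
            bundle$terms$genes[[i]]), collapse = "\t")
  }, character(1)), path("terms.gmt"))
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(gwas = path("gwas.tsv"), ld = path("ld.tsv"),
             track_incomplete = path("track_incomplete.bed"),
             track_complete = path("track_complete.bed"),
             genes = path("genes.bed"), terms = path("terms.gmt"),
             truth = path("truth.json"))
  invisible(files)
}

#' Compare pipeline output against the generator's truth record
#'
#' Reports how well the pipeline recovered the planted structure: recall
#' and false-positive rate of the top-score flag against the truly
#' selected variants, the direction of the observed median OR against the
#' planted risk-direction probability, and whether the planted term (if
#' any) was recovered among the Bonferroni-significant terms.
#'
#' @param bundle the `sim_bundle` the pipeline ran on.
#' @param output a [run_pipeline()] result.
#' @return a list report with components `selected`, `direction`, `terms`
#'   and `ok` (all-clear flag for null bundles).
#' @export
truth_check <- function(bundle, output) {
  stopifnot(inherits(bundle, "sim_bundle"))
  ann <- output$annotated
  sc <- bundle$config$coupling_scenario
  thr <- score_cutoff(ann, sc, bundle$config$quantile)
  flagged <- ann$snp_id[is_selected(ann, thr)]
  true_sel <- intersect(bundle$truth$selected, ann$snp_id)
  sel_report <- list(
    n_flagged = length(flagged),
    recall = if (length(true_sel) > 0)
      length(intersect(flagged, true_sel)) / length(true_sel) else NA_real_,
    false_positive_rate =
      length(setdiff(flagged, true_sel)) /
        max(1, length(setdiff(ann$snp_id, true_sel))))
  dirres <- output$direction[[sc]]
  dir_report <- if (inherits(dirres, "direction_result")) {
    list(observed_median_or = dirres$observed_median_or,
         risk_direction_excess = dirres$observed_median_or > 1,
         planted_direction_prob = bundle$config$direction_prob,
         p_permutation = dirres$p_permutation)
  } else list(observed_median_or = NA_real_, note = "direction test not run")
  planted <- bundle$truth$planted_term_id
  sig_terms <- if (!is.null(output$geneset$terms))
    output$geneset$terms$term_id[output$geneset$terms$p_bonferroni <
                                   output$geneset$alpha %||% 0.05]
  else character(0)
  term_report <- list(planted_term_id = planted,
                      n_significant = length(sig_terms),
                      planted_recovered = !is.na(planted) &&
                        planted %in% sig_terms)
  ok <- is.na(planted) && bundle$config$assoc_coupling == 0 &&
    bundle$config$direction_prob == 0.5
  list(selected = sel_report, direction = dir_report, terms = term_report,
       ok = ok)
}
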