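#' Read term-to-gene annotations (GMT-style)
#'
#' Each tab-delimited line is: term_id, term_name, then one or more gene
#' ids. A term with no genes or a duplicated term_id is a hard error.
#'
#' @param path file path.
#' @return data.frame(term_id, term_name) with a `genes` list-column.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("annotation line(s) without genes: ",
                     paste(which(bad), collapse = ", "))
  out <- data.frame(term_id = vapply(parts, `[[`, character(1), 1),
                    term_name = vapply(parts, `[[`, character(1), 2),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$term_id))
    stop("duplicate term_id: ",
         paste(unique(out$term_id[duplicated(out$term_id)]), collapse = ", "))
  out$genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  out
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term with at least one background gene, tests whether the
#' focal gene list contains more of the term's genes than expected under
#' random sampling from the background: upper-tail hypergeometric
#' p = P(X >= k) with N background genes, K of them in the term, a list of
#' n genes and k list genes in the term. Fold enrichment is
#' (k/n) / (K/N). Bonferroni uses the number of terms actually tested;
#' Benjamini-Hochberg FDR is also reported.
#'
#' @param gene_list character vector of focal genes; must be a subset of
#'   `background`.
#' @param background character vector: the gene universe (by default, all
#'   genes reachable from the clumped analysis variants).
#' @param annotations data.frame from [read_annotations()] (or built in
#'   code with a `genes` list-column).
#' @return data.frame sorted by p-value: term_id, term_name, k, n, K, N,
#'   fold_enrichment, p_value, p_bonferroni, p_fdr.
#' @export
overrepresentation_test <- function(gene_list, background, annotations) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  outside <- setdiff(gene_list, background)
  if (length(outside) > 0)
    stop("gene_list not a subset of background: ",
         paste(head(outside, 10), collapse = ", "))
  N <- length(background)
  n <- length(gene_list)
  K <- vapply(annotations$genes,
              function(g) length(intersect(g, background)), integer(1))
  keep <- K > 0
  ann <- annotations[keep, , drop = FALSE]
  K <- K[keep]
  k <- vapply(ann$genes, function(g) length(intersect(g, gene_list)),
              integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  out <- data.frame(term_id = ann$term_id, term_name = ann$term_name,
                    k = k, n = n, K = K, N = N,
                    fold_enrichment = fold, p_value = p,
                    p_bonferroni = pmin(1, p * nrow(ann)),
                    p_fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Focal-set rule
#'
#' Bundles the definition of the focal variant set used for the gene-level
#' follow-up: GWAS p below a threshold, selection score in the top
#' quantile, and (optionally) a risk-direction minor-allele OR > 1.
#'
#' @param scenario `"incomplete"` or `"complete"`.
#' @param p_threshold GWAS p-value threshold.
#' @param quantile top-score quantile.
#' @param or_gt_1 restrict to minor-allele OR > 1?
#' @return a `set_rule` list.
#' @export
set_rule <- function(scenario = "incomplete", p_threshold = 0.1,
                     quantile = 0.95, or_gt_1 = TRUE) {
  stopifnot(scenario %in% c("incomplete", "complete"),
            p_threshold > 0, p_threshold <= 1, quantile > 0, quantile < 1)
  structure(list(scenario = scenario, p_threshold = p_threshold,
                 quantile = quantile, or_gt_1 = isTRUE(or_gt_1)),
            class = "set_rule")
}

# logical index of the focal variants under a set_rule
apply_set_rule <- function(annotated, rule) {
  thr <- score_cutoff(annotated, rule$scenario, rule$quantile)
  f <- is_selected(annotated, thr) & annotated$p_value < rule$p_threshold
  if (rule$or_gt_1) f <- f & annotated$odds_ratio > 1
  f
}

#' Permutation validation of the enrichment count
#'
#' Recomputes, under the null, the number of Bonferroni-significant terms:
#' the observed count comes from the real focal gene list; each of
#' `n_perm` permutations draws a random variant set of the same size from
#' the analysis set, maps it to genes and reruns the over-representation
#' test. The empirical p-value uses the add-one rule.
#'
#' @param annotated clumped, score-annotated, minor-oriented variant table;
#'   must already carry a `genes` list-column (see [map_genes()]).
#' @param rule a [set_rule()].
#' @param annotations term annotations (see [read_annotations()]).
#' @param n_perm number of permutations (default 100).
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @param seed RNG seed.
#' @return list(observed_count, null_counts, p_permutation, n_perm, alpha,
#'   seed, set_size, observed_terms).
#' @export
enrichment_count_permutation <- function(annotated, rule, annotations,
                                         n_perm = 100, alpha = 0.05,
                                         seed = 1) {
  if (is.null(annotated$genes))
    stop("annotated table has no 'genes' column; run map_genes() first")
  background <- gene_list_of(annotated)
  focal <- apply_set_rule(annotated, rule)
  m <- sum(focal)
  if (m == 0) stop("focal set empty under the given rule")
  count_for <- function(idx) {
    gl <- gene_list_of(annotated[idx, , drop = FALSE])
    if (length(gl) == 0) return(list(count = 0L, res = NULL))
    res <- overrepresentation_test(gl, background, annotations)
    list(count = sum(res$p_bonferroni < alpha), res = res)
  }
  obs <- count_for(which(focal))
  n <- nrow(annotated)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    count_for(sample.int(n, m))$count
  }, integer(1))
  list(observed_count = obs$count, null_counts = null_counts,
       p_permutation = empirical_pvalue(null_counts, obs$count),
       n_perm = n_perm, alpha = alpha, seed = seed, set_size = m,
       observed_terms = if (!is.null(obs$res))
         obs$res[obs$res$p_bonferroni < alpha, , drop = FALSE] else NULL)
}
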