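#' Attach selection scores to variants by genomic overlap
#'
#' Each variant inherits, per scenario, the score of the scored region
#' covering its position; when several regions of one scenario overlap the
#' position the maximum score is taken, and a variant covered by no region
#' gets a missing score. Coordinates: variant positions are 1-based, score
#' regions half-open 0-based, so a variant at position p overlaps [s, e)
#' iff s <= p - 1 < e.
#'
#' @param variants variant data.frame.
#' @param regions scored regions (see [read_score_track()]); may mix both
#'   scenarios in one table.
#' @return the variant table with `score_incomplete` and `score_complete`
#'   columns added (NA where no region overlaps).
#' @export
assign_scores <- function(variants, regions) {
  stopifnot(nrow(regions) == 0 ||
              all(regions$scenario %in% c("incomplete", "complete")))
  v_gr <- GenomicRanges::GRanges(normalize_chrom(variants$chrom),
                                 IRanges::IRanges(variants$pos, variants$pos))
  for (sc in c("incomplete", "complete")) {
    col <- paste0("score_", sc)
    variants[[col]] <- NA_real_
    reg <- regions[regions$scenario == sc, , drop = FALSE]
    if (nrow(reg) == 0) next
    # BED half-open [s, e) covers 1-based positions s+1 .. e
    r_gr <- GenomicRanges::GRanges(normalize_chrom(reg$chrom),
                                   IRanges::IRanges(reg$start + 1, reg$end))
    hits <- GenomicRanges::findOverlaps(v_gr, r_gr)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      best <- tapply(reg$score[S4Vectors::subjectHits(hits)], qh, max)
      variants[[col]][as.integer(names(best))] <- as.numeric(best)
    }
  }
  variants
}

#' Top-score cutoff over the analysis set
#'
#' The "selected" set is the top q-fraction of assigned scores over the
#' clumped analysis variants: the cutoff is the nearest-rank (ceiling)
#' empirical quantile of the non-missing scores, and a variant is selected
#' iff its score is >= the cutoff.
#'
#' @param annotated output of [assign_scores()].
#' @param scenario `"incomplete"` or `"complete"`.
#' @param quantile quantile in (0,1); default 0.95 (top-5%).
#' @return a `score_threshold` list: scenario, quantile, cutoff, n_scores.
#' @export
score_cutoff <- function(annotated, scenario = c("incomplete", "complete"),
                         quantile = 0.95) {
  scenario <- match.arg(scenario)
  s <- annotated[[paste0("score_", scenario)]]
  s <- s[!is.na(s)]
  if (length(s) == 0)
    stop("no non-missing '", scenario, "' scores in the analysis set")
  if (length(s) < 20)
    warning("fewer than 20 non-missing scores; cutoff is unstable")
  structure(list(scenario = scenario, quantile = quantile,
                 cutoff = nearest_rank_quantile(s, quantile),
                 n_scores = length(s)),
            class = "score_threshold")
}

# logical selected flag per variant (NA score -> FALSE)
is_selected <- function(annotated, threshold) {
  s <- annotated[[paste0("score_", threshold$scenario)]]
  !is.na(s) & s >= threshold$cutoff
}

#' Map variants to genes within a flank
#'
#' A variant maps to every gene whose interval, expanded by `flank_bp` on
#' both sides, covers its position — the "in the gene and/or within 50 kb"
#' rule. With `nearest_only = TRUE`, of the genes within the flank only the
#' one(s) at minimal distance to the gene body are kept (distance 0 inside
#' the gene).
#'
#' @param variants variant data.frame.
#' @param genes gene intervals (see [read_genes()]).
#' @param flank_bp flank in base pairs; default 50000.
#' @param nearest_only keep only the closest gene(s) per variant.
#' @return the variant table with a `genes` list-column of gene ids
#'   (character(0) where no gene is within reach).
#' @export
map_genes <- function(variants, genes, flank_bp = 50000,
                      nearest_only = FALSE) {
  v_gr <- GenomicRanges::GRanges(normalize_chrom(variants$chrom),
                                 IRanges::IRanges(variants$pos, variants$pos))
  start1 <- pmax(genes$start - flank_bp, 0) + 1   # to 1-based closed
  end1 <- genes$end + flank_bp
  g_gr <- GenomicRanges::GRanges(normalize_chrom(genes$chrom),
                                 IRanges::IRanges(start1, end1))
  hits <- GenomicRanges::findOverlaps(v_gr, g_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (nearest_only && length(hits) > 0) {
    # distance of the variant to the unexpanded gene body, 0 if inside
    d <- pmax(genes$start[sh] + 1 - variants$pos[qh],
              variants$pos[qh] - genes$end[sh], 0)
    keep <- unlist(lapply(split(seq_along(qh), qh), function(ii) {
      ii[d[ii] == min(d[ii])]
    }), use.names = FALSE)
    qh <- qh[keep]; sh <- sh[keep]
  }
  gl <- rep(list(character(0)), nrow(variants))
  if (length(qh) > 0) {
    found <- split(genes$gene_id[sh], qh)
    gl[as.integer(names(found))] <- lapply(found, function(g) sort(unique(g)))
  }
  variants$genes <- gl
  variants
}

# unique sorted gene list over a set of annotated variants
gene_list_of <- function(annotated) {
  sort(unique(unlist(annotated$genes, use.names = FALSE)))
}
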