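#' Clumping / QC parameters
#'
#' Defaults follow the standard summary-statistics pipeline for this
#' analysis: a 500 kb window, survival r-squared < 0.25, imputation info
#' score > 0.9 and minor allele frequency > 0.02.
#'
#' @param window_bp clumping window in base pairs (symmetric distance).
#' @param r2_max a non-index variant within the window is claimed by the
#'   index when its r-squared with the index is >= this value.
#' @param info_min variants must have imputation info > this to survive QC.
#' @param maf_min variants must have minor allele frequency > this.
#' @param strict_info if TRUE, variants with missing info are removed;
#'   by default they pass (summary-statistics files often omit info).
#' @return a `clump_params` list.
#' @export
clump_params <- function(window_bp = 500000, r2_max = 0.25,
                         info_min = 0.9, maf_min = 0.02,
                         strict_info = FALSE) {
  stopifnot(window_bp > 0, r2_max > 0, r2_max <= 1,
            info_min > 0, maf_min > 0, maf_min < 0.5)
  structure(list(window_bp = window_bp, r2_max = r2_max,
                 info_min = info_min, maf_min = maf_min,
                 strict_info = isTRUE(strict_info)),
            class = "clump_params")
}

#' Quality-control filter
#'
#' Retains variants with imputation info > `info_min` (missing info passes
#' unless `strict_info`) and minor allele frequency strictly above
#' `maf_min`, where MAF = min(eaf, 1 - eaf). Row order is preserved.
#'
#' @param variants variant data.frame (see [read_gwas()]).
#' @param params a [clump_params()] object.
#' @return the retained subset, order preserved.
#' @export
qc_filter <- function(variants, params = clump_params()) {
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  info_ok <- if (params$strict_info) {
    !is.na(variants$info) & variants$info > params$info_min
  } else {
    is.na(variants$info) | variants$info > params$info_min
  }
  # strict inequality with a representation tolerance, so that e.g.
  # 1 - 0.98 compares as exactly the 0.02 boundary and is removed
  out <- variants[info_ok & maf - params$maf_min > 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy p-value-ranked LD clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest p-value as an
#' index SNP (ties broken by ascending chromosome then position) and claims
#' every unclaimed variant on the same chromosome within `window_bp` whose
#' r-squared with the index is >= `r2_max`. Index SNPs are returned sorted
#' by (chromosome, position). A variant absent from the LD reference is
#' treated as r-squared 0 with everything; the count of such variants is
#' attached as attribute `n_missing_ld` and a warning is raised.
#'
#' @param variants qc-filtered variant data.frame.
#' @param ld an `ld_reference` (see [read_ld()]).
#' @param params a [clump_params()] object.
#' @return index variants, sorted by (chrom, pos).
#' @export
clump <- function(variants, ld, params = clump_params()) {
  n <- nrow(variants)
  if (n == 0) return(variants)
  miss <- !ld_has(ld, variants$snp_id)
  if (any(miss))
    warning(sum(miss), " variant(s) absent from LD reference; treated as r2 = 0")

  ord <- order(variants$p_value, chrom_rank(variants$chrom), variants$pos)
  claimed <- rep(FALSE, n)
  keep <- rep(FALSE, n)
  # per-chromosome position index so each window lookup is O(log n)
  by_chrom <- split(seq_len(n), variants$chrom)
  by_chrom <- lapply(by_chrom, function(ii) ii[order(variants$pos[ii])])
  for (i in ord) {
    if (claimed[i]) next
    keep[i] <- TRUE
    claimed[i] <- TRUE
    ii <- by_chrom[[variants$chrom[i]]]
    pos <- variants$pos[ii]
    win <- findInterval(c(variants$pos[i] - params$window_bp - 1,
                          variants$pos[i] + params$window_bp), pos)
    cand <- ii[seq.int(win[1] + 1, win[2])]
    cand <- cand[!claimed[cand]]
    if (length(cand) > 0) {
      hit <- ld_partners_at(ld, variants$snp_id[i], variants$snp_id[cand],
                            params$r2_max)
      claimed[cand[variants$snp_id[cand] %in% hit]] <- TRUE
    }
  }
  out <- variants[keep, , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_ld") <- sum(miss)
  out
}

#' Keep a single variant in the MHC region
#'
#' The extended major histocompatibility complex has LD too strong for
#' clumping to thin reliably, so among variants falling inside the region
#' only the one with the smallest p-value is retained (ties broken by
#' ascending chromosome, position); variants outside are untouched.
#'
#' @param variants variant data.frame.
#' @param region `"chr6:25000000-34000000"`-style string or
#'   list(chrom, start, end); 1-based inclusive coordinates.
#' @return data.frame with at most one MHC variant.
#' @export
restrict_mhc <- function(variants, region = "chr6:25000000-34000000") {
  reg <- parse_region(region)
  inside <- normalize_chrom(variants$chrom) == reg$chrom &
    variants$pos >= reg$start & variants$pos <= reg$end
  if (sum(inside) <= 1) return(variants)
  idx <- which(inside)
  o <- order(variants$p_value[idx], chrom_rank(variants$chrom[idx]),
             variants$pos[idx])
  drop <- idx[o[-1]]
  out <- variants[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_region <- function(region) {
  if (is.list(region))
    return(list(chrom = normalize_chrom(region$chrom),
                start = region$start, end = region$end))
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4) stop("cannot parse region: ", region)
  list(chrom = normalize_chrom(m[2]),
       start = as.numeric(gsub(",", "", m[3])),
       end = as.numeric(gsub(",", "", m[4])))
}

#' Orient effect sizes to the minor allele
#'
#' Where the effect allele is the major allele (eaf > 0.5) the alleles are
#' swapped, eaf becomes 1 - eaf and the odds ratio is inverted, so every
#' odds ratio is expressed per copy of the minor allele. eaf exactly 0.5 is
#' left unchanged. The operation is an involution and preserves
#' min(eaf, 1 - eaf) and |log OR|.
#'
#' @param variants variant data.frame.
#' @return the same table, minor-allele oriented.
#' @export
orient_to_minor <- function(variants) {
  flip <- variants$eaf > 0.5
  if (!any(flip)) return(variants)
  ea <- variants$effect_allele
  variants$effect_allele[flip] <- variants$other_allele[flip]
  variants$other_allele[flip] <- ea[flip]
  variants$eaf[flip] <- 1 - variants$eaf[flip]
  variants$odds_ratio[flip] <- 1 / variants$odds_ratio[flip]
  variants
}
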