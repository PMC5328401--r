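#' Default GWAS column mapping
#'
#' Maps the fields of a summary-statistics row to the column names of a
#' tab-delimited GWAS file. The defaults follow the common PLINK-style header
#' (SNP, CHR, BP, A1, A2, OR, P, FRQ, INFO). Set `beta = TRUE` when the
#' effect column carries a log odds ratio instead of an odds ratio; it is
#' exponentiated at read time.
#'
#' @param snp,chrom,pos,effect_allele,other_allele,effect,p,eaf,info column
#'   names in the file header. `info` may be `NA` if the file has no
#'   imputation-quality column.
#' @param beta logical; is the effect column on the log-odds scale?
#' @return a named list used by [read_gwas()].
#' @export
gwas_column_map <- function(snp = "SNP", chrom = "CHR", pos = "BP",
                            effect_allele = "A1", other_allele = "A2",
                            effect = "OR", p = "P", eaf = "FRQ",
                            info = "INFO", beta = FALSE) {
  list(snp = snp, chrom = chrom, pos = pos, effect_allele = effect_allele,
       other_allele = other_allele, effect = effect, p = p, eaf = eaf,
       info = info, beta = isTRUE(beta))
}

#' Read GWAS summary statistics
#'
#' Parses a tab-delimited summary-statistics file into the package's variant
#' table. Rows violating the variant invariants (odds ratio > 0, p-value in
#' (0,1], effect-allele frequency strictly inside (0,1), distinct A/C/G/T
#' alleles, unique (chrom, pos, alleles)) are dropped, each with a recorded
#' reason; valid rows are returned with chromosome names normalized (no
#' "chr" prefix). Rejected rows are available via `attr(x, "rejects")`.
#'
#' @param path tab-delimited file with a header row.
#' @param column_map a mapping from [gwas_column_map()].
#' @return data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, odds_ratio, p_value, eaf, info; attribute `rejects` holds
#'   a data.frame (row, snp_id, reason).
#' @export
read_gwas <- function(path, column_map = gwas_column_map()) {
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  needed <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
              "effect", "p", "eaf")
  for (f in needed) {
    if (!column_map[[f]] %in% names(raw))
      stop("mapped column not found in header: '", column_map[[f]],
           "' (field ", f, ")")
  }
  has_info <- !is.na(column_map$info) && column_map$info %in% names(raw)

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  eff <- num(column_map$effect)
  x <- data.frame(
    snp_id = raw[[column_map$snp]],
    chrom = normalize_chrom(raw[[column_map$chrom]]),
    pos = num(column_map$pos),
    effect_allele = toupper(raw[[column_map$effect_allele]]),
    other_allele = toupper(raw[[column_map$other_allele]]),
    odds_ratio = if (column_map$beta) exp(eff) else eff,
    p_value = num(column_map$p),
    eaf = num(column_map$eaf),
    info = if (has_info) num(column_map$info) else NA_real_,
    stringsAsFactors = FALSE
  )
  validate_variants(x, info_optional = TRUE)
}

# shared row-level validation; returns accepted rows + rejects attribute
validate_variants <- function(x, info_optional = TRUE) {
  n <- nrow(x)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why

  bases <- c("A", "C", "G", "T")
  flag(is.na(x$pos) | x$pos != round(x$pos) | x$pos < 1, "bad position")
  flag(!(x$effect_allele %in% bases) | !(x$other_allele %in% bases),
       "allele not in A/C/G/T")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(is.na(x$odds_ratio) | !is.finite(x$odds_ratio) | x$odds_ratio <= 0,
       "OR not positive")
  flag(is.na(x$p_value) | x$p_value <= 0 | x$p_value > 1, "p out of (0,1]")
  flag(is.na(x$eaf) | x$eaf <= 0 | x$eaf >= 1, "eaf out of (0,1)")
  if (!info_optional) flag(is.na(x$info), "missing info")
  flag(!is.na(x$info) & (x$info < 0 | x$info > 1), "info out of [0,1]")
  key <- paste(x$chrom, x$pos, x$effect_allele, x$other_allele)
  flag(duplicated(key), "duplicate (chrom,pos,alleles)")

  bad <- !is.na(reason)
  rejects <- data.frame(row = which(bad), snp_id = x$snp_id[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  if (nrow(rejects) > 0)
    message(nrow(rejects), " of ", n, " rows rejected during GWAS parsing")
  out
}

#' Read a selection-score track
#'
#' BED-like, tab-delimited, no header: chrom, start, end, score with
#' half-open 0-based intervals. Rows with start >= end or a non-numeric
#' score are rejected with a reason (attribute `rejects`). Intervals may
#' overlap; resolution (maximum score) happens in [assign_scores()].
#'
#' @param path file path.
#' @param scenario which sweep scenario the track scores:
#'   `"incomplete"` or `"complete"`.
#' @return data.frame(chrom, start, end, scenario, score).
#' @export
read_score_track <- function(path, scenario = c("incomplete", "complete")) {
  scenario <- match.arg(scenario)
  raw <- tryCatch(
    read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    warning("empty score track: ", path)
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), scenario = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    attr(out, "rejects") <- data.frame(row = integer(), reason = character())
    return(out)
  }
  if (ncol(raw) < 4) stop("score track needs 4 columns: chrom start end score")
  x <- data.frame(chrom = normalize_chrom(raw[[1]]),
                  start = suppressWarnings(as.numeric(raw[[2]])),
                  end = suppressWarnings(as.numeric(raw[[3]])),
                  scenario = scenario,
                  score = suppressWarnings(as.numeric(raw[[4]])),
                  stringsAsFactors = FALSE)
  bad <- is.na(x$start) | is.na(x$end) | x$start >= x$end | is.na(x$score)
  reason <- ifelse(is.na(x$score), "non-numeric score", "start >= end")
  rejects <- data.frame(row = which(bad), reason = reason[bad],
                        stringsAsFactors = FALSE)
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Read gene annotation intervals
#'
#' BED-like, tab-delimited, no header: chrom, start, end, gene_id
#' (half-open 0-based). A duplicated gene_id is a hard error.
#'
#' @param path file path.
#' @return data.frame(gene_id, chrom, start, end).
#' @export
read_genes <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 4) stop("gene file needs 4 columns: chrom start end gene_id")
  x <- data.frame(gene_id = raw[[4]],
                  chrom = normalize_chrom(raw[[1]]),
                  start = suppressWarnings(as.numeric(raw[[2]])),
                  end = suppressWarnings(as.numeric(raw[[3]])),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", "))
  if (any(x$start >= x$end, na.rm = TRUE) || anyNA(x$start) || anyNA(x$end))
    stop("gene intervals must satisfy start < end")
  x
}

#' Read an LD reference
#'
#' Two dialects, both headerless TSV: a 2-column block file (snp_id,
#' block_id) where same-block pairs have r-squared 1 and cross-block pairs
#' 0, or a 3-column sparse pair file (snp_a, snp_b, r2) where unlisted
#' pairs have r-squared 0. Self-pairs are implicitly 1; pair storage is
#' symmetric.
#'
#' @param path file path.
#' @return an `ld_reference` object; query with [ld_r2()].
#' @export
read_ld <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) == 2) {
    ld_blocks(setNames(raw[[2]], raw[[1]]))
  } else if (ncol(raw) >= 3) {
    r2 <- suppressWarnings(as.numeric(raw[[3]]))
    if (anyNA(r2) || any(r2 < 0 | r2 > 1))
      stop("pairwise r2 values must be numeric in [0,1]")
    ld_pairs(raw[[1]], raw[[2]], r2)
  } else stop("LD file needs 2 (snp, block) or 3 (snp_a, snp_b, r2) columns")
}

#' Construct an LD reference from block memberships
#' @param block_of named character vector: names are snp ids, values block ids.
#' @return an `ld_reference` object.
#' @export
ld_blocks <- function(block_of) {
  stopifnot(!is.null(names(block_of)))
  structure(list(type = "blocks", block_of = block_of),
            class = "ld_reference")
}

#' Construct an LD reference from sparse pairwise r-squared values
#' @param a,b snp id vectors (pair endpoints); @param r2 r-squared in [0,1].
#' @return an `ld_reference` object.
#' @export
ld_pairs <- function(a, b, r2) {
  stopifnot(length(a) == length(b), length(a) == length(r2),
            all(r2 >= 0 & r2 <= 1))
  key <- ifelse(a < b, paste0(a, "\r", b), paste0(b, "\r", a))
  # a pair listed twice keeps its last value everywhere
  keep <- !duplicated(key, fromLast = TRUE)
  a <- a[keep]; b <- b[keep]; r2 <- r2[keep]; key <- key[keep]
  env <- new.env(parent = emptyenv(), size = max(length(a), 16L))
  for (i in seq_along(key)) assign(key[i], r2[i], envir = env)
  # adjacency index (snp -> named r2 vector of its partners) lets
  # consumers such as clump() visit only listed pairs
  adj <- new.env(parent = emptyenv(), size = max(length(a), 16L))
  both <- c(a, b); partner <- c(b, a); rr <- c(r2, r2)
  for (grp in split(seq_along(both), both)) {
    assign(both[grp[1]], setNames(rr[grp], partner[grp]), envir = adj)
  }
  known <- unique(both)
  structure(list(type = "pairs", env = env, adj = adj,
                 known = setNames(rep(TRUE, length(known)), known)),
            class = "ld_reference")
}

#' Query pairwise r-squared from an LD reference
#'
#' Vectorised over pairs. Self-pairs return 1; a pair absent from the
#' reference returns 0.
#'
#' @param ld an `ld_reference`.
#' @param a,b snp id vectors of equal length.
#' @return numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"), length(a) == length(b))
  out <- numeric(length(a))
  self <- a == b
  out[self] <- 1
  idx <- which(!self)
  if (ld$type == "blocks") {
    ba <- ld$block_of[a[idx]]
    bb <- ld$block_of[b[idx]]
    out[idx] <- as.numeric(!is.na(ba) & !is.na(bb) & ba == bb)
  } else if (length(idx) > 0) {
    key <- ifelse(a[idx] < b[idx],
                  paste0(a[idx], "\r", b[idx]), paste0(b[idx], "\r", a[idx]))
    out[idx] <- unlist(mget(key, envir = ld$env, ifnotfound = 0),
                       use.names = FALSE)
  }
  unname(out)
}

# is each snp id present anywhere in the LD reference?
ld_has <- function(ld, ids) {
  if (ld$type == "blocks") ids %in% names(ld$block_of)
  else !is.na(ld$known[ids])
}

# of cand_ids, those whose r2 with id is >= r2_min (used by clump)
ld_partners_at <- function(ld, id, cand_ids, r2_min) {
  if (ld$type == "blocks") {
    bi <- ld$block_of[id]
    if (is.na(bi)) return(character(0))
    if (r2_min > 1) return(character(0))
    cb <- ld$block_of[cand_ids]
    cand_ids[!is.na(cb) & cb == bi]
  } else {
    adj <- get0(id, envir = ld$adj, inherits = FALSE)
    if (is.null(adj)) return(character(0))
    intersect(cand_ids, names(adj)[adj >= r2_min])
  }
}

#' Write / read result tables
#'
#' Results are written as tab-delimited text with a header, the column order
#' of the data.frame, and full double precision (17 significant digits), so
#' that `read_results(write_results(x))` round-trips counts exactly and
#' doubles to machine precision.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- x
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
      fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}
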