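#' Pipeline configuration
#'
#' Collects every input and tunable of the end-to-end analysis. Inputs are
#' either a `sim_bundle` (in-memory, from [simulate_bundle()]) or file
#' paths; all statistical knobs default to the pipeline's standard
#' conditions (500 kb / r2 0.25 clumping, top-5% score set, six-threshold
#' scan, 10,000-draw permutation nulls, 100-draw gene-set count
#' validation).
#'
#' @param bundle optional `sim_bundle`; when given, file paths are ignored.
#' @param gwas,ld,track_incomplete,track_complete,genes,annotations input
#'   file paths (see the `read_*` readers); `track_complete` and
#'   `annotations` may be NULL.
#' @param column_map GWAS column mapping ([gwas_column_map()]).
#' @param params [clump_params()].
#' @param mhc MHC region string or NULL to skip the single-MHC-SNP rule.
#' @param scenarios scenarios to analyse (default: those with a track).
#' @param p_thresholds threshold grid for the scan ([default_thresholds()]).
#' @param quantile top-score quantile.
#' @param flank_bp gene-mapping flank.
#' @param rule focal-set rule for the gene-level follow-up ([set_rule()]).
#' @param n_perm_corr,n_perm_dir,n_perm_geneset permutation draws per stage.
#' @param direction_null null scheme for [direction_test()].
#' @param alpha family-wise error rate.
#' @param n_datasets number of GWAS datasets in the wider study; the
#'   correlation-stage Bonferroni alpha is alpha / (n_datasets x
#'   n_scenarios).
#' @param seed master seed; per-stage substreams are derived from it.
#' @param out_dir optional directory for result tables and the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(bundle = NULL, gwas = NULL, ld = NULL,
                            track_incomplete = NULL, track_complete = NULL,
                            genes = NULL, annotations = NULL,
                            column_map = gwas_column_map(),
                            params = clump_params(), mhc = NULL,
                            scenarios = NULL,
                            p_thresholds = default_thresholds("six"),
                            quantile = 0.95, flank_bp = 50000,
                            rule = set_rule(), n_perm_corr = 10000,
                            n_perm_dir = 10000, n_perm_geneset = 100,
                            direction_null = "subset", alpha = 0.05,
                            n_datasets = 1, seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(bundle) && is.null(gwas))
    stop("either a bundle or a gwas file path is required")
  structure(cfg, class = "pipeline_config")
}

# derived per-stage seeds; kept well below 2^31 for 32-bit R integers
stage_seed <- function(seed, stage, scenario_index = 0) {
  (seed %% 1000000L) * 1000L + scenario_index * 100L + stage
}

#' Run the full enrichment pipeline
#'
#' Executes read -> QC / clump / (MHC) / minor-orient -> score assignment
#' -> per-scenario correlation (asymptotic + permutation), threshold-scan
#' enrichment and direction test -> gene mapping -> gene-set
#' over-representation with the permutation count validation. Every stage
#' is seeded from the master seed, and a manifest records the config,
#' input digests, per-stage row counts and package version; rerunning the
#' same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list: manifest, clumped, annotated, cutoffs, correlation, scan,
#'   direction (per-scenario lists), geneset, report (see
#'   [render_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_pipeline_impl(config)
}

run_pipeline_impl <- function(config) {
  counts <- list()
  digests <- list()
  file_inputs <- c("gwas", "ld", "track_incomplete", "track_complete",
                   "genes", "annotations")

  if (!is.null(config$bundle)) {
    b <- config$bundle
    gwas <- b$gwas; ld <- b$ld; track <- b$track
    genes <- b$genes; annotations <- b$terms
  } else {
    for (f in file_inputs) {
      if (!is.null(config[[f]]))
        digests[[f]] <- unname(tools::md5sum(config[[f]]))
    }
    gwas <- read_gwas(config$gwas, config$column_map)
    ld <- if (!is.null(config$ld)) read_ld(config$ld) else ld_blocks(
      setNames(character(0), character(0)))
    track <- rbind(
      if (!is.null(config$track_incomplete))
        read_score_track(config$track_incomplete, "incomplete"),
      if (!is.null(config$track_complete))
        read_score_track(config$track_complete, "complete"))
    genes <- if (!is.null(config$genes)) read_genes(config$genes) else NULL
    annotations <- if (!is.null(config$annotations))
      read_annotations(config$annotations) else NULL
  }
  counts$n_input <- nrow(gwas) + nrow(attr(gwas, "rejects") %||% data.frame())
  counts$n_parsed <- nrow(gwas)

  scenarios <- config$scenarios %||% intersect(c("incomplete", "complete"),
                                               unique(track$scenario))
  if (length(scenarios) == 0) stop("no score track for any scenario")

  x <- qc_filter(gwas, config$params)
  counts$n_qc <- nrow(x)
  x <- clump(x, ld, config$params)
  counts$n_clumped <- nrow(x)
  if (!is.null(config$mhc)) {
    x <- restrict_mhc(x, config$mhc)
    counts$n_after_mhc <- nrow(x)
  }
  x <- orient_to_minor(x)
  ann <- assign_scores(x, track)
  if (!is.null(genes)) ann <- map_genes(ann, genes, config$flank_bp)

  corr_alpha <- config$alpha / (config$n_datasets * length(scenarios))
  correlation <- list(); scan <- list(); direction <- list(); cutoffs <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[i]
    s <- ann[[paste0("score_", sc)]]
    counts[[paste0("n_scored_", sc)]] <- sum(!is.na(s))
    cutoffs[[sc]] <- score_cutoff(ann, sc, config$quantile)
    cr <- permute_correlation(-log10(ann$p_value), s,
                              n_perm = config$n_perm_corr,
                              seed = stage_seed(config$seed, 1, i),
                              scenario = sc)
    cr$bonferroni_alpha <- corr_alpha
    cr$significant <- cr$p_permutation < corr_alpha
    correlation[[sc]] <- cr
    scan[[sc]] <- threshold_enrichment(ann, sc, config$p_thresholds,
                                       config$quantile, config$alpha)
    direction[[sc]] <- tryCatch(
      direction_test(ann, sc, p_threshold = config$rule$p_threshold,
                     quantile = config$quantile,
                     n_perm = config$n_perm_dir,
                     seed = stage_seed(config$seed, 2, i),
                     null = config$direction_null),
      error = function(e) list(error = e$message))
  }

  geneset <- NULL
  if (!is.null(genes) && !is.null(annotations)) {
    geneset <- tryCatch({
      rule <- config$rule
      if (!rule$scenario %in% scenarios) rule$scenario <- scenarios[1]
      focal <- apply_set_rule(ann, rule)
      focal_genes <- gene_list_of(ann[focal, , drop = FALSE])
      background <- gene_list_of(ann)
      terms <- overrepresentation_test(focal_genes, background, annotations)
      count_perm <- enrichment_count_permutation(
        ann, rule, annotations, n_perm = config$n_perm_geneset,
        alpha = config$alpha, seed = stage_seed(config$seed, 3))
      list(rule = rule, focal_genes = focal_genes, background = background,
           terms = terms, count_perm = count_perm, alpha = config$alpha)
    }, error = function(e) list(error = e$message, alpha = config$alpha))
  }

  manifest <- list(
    package = "sweepenrich",
    version = as.character(utils::packageVersion("sweepenrich")),
    seed = config$seed,
    config = config[setdiff(names(config), c("bundle", "out_dir"))],
    bundle_seed = if (!is.null(config$bundle)) config$bundle$config$seed,
    input_digests = digests,
    counts = counts,
    scenarios = scenarios,
    correlation_bonferroni_alpha = corr_alpha)

  out <- list(manifest = manifest, clumped = x, annotated = ann,
              cutoffs = cutoffs, correlation = correlation, scan = scan,
              direction = direction, geneset = geneset)
  out$report <- render_report(out)

  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  # verify input files were not modified while the pipeline ran
  for (f in names(digests)) {
    if (!identical(unname(tools::md5sum(config[[f]])), digests[[f]]))
      stop("input file changed during the run: ", config[[f]])
  }
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  flat <- out$annotated
  if (!is.null(flat$genes))
    flat$genes <- vapply(flat$genes, paste, character(1), collapse = ";")
  write_results(flat, path("annotated.tsv"))
  corr_tab <- do.call(rbind, lapply(out$correlation, function(cr) {
    data.frame(scenario = cr$scenario, n = cr$n, rho = cr$rho,
               p_asymptotic = cr$p_asymptotic,
               p_permutation = cr$p_permutation, n_perm = cr$n_perm,
               seed = cr$seed, bonferroni_alpha = cr$bonferroni_alpha,
               significant = cr$significant, stringsAsFactors = FALSE)
  }))
  write_results(corr_tab, path("correlation.tsv"))
  for (sc in names(out$scan))
    write_results(out$scan[[sc]], path(paste0("scan_", sc, ".tsv")))
  for (sc in names(out$direction)) {
    d <- out$direction[[sc]]
    if (inherits(d, "direction_result"))
      write_results(data.frame(scenario = d$scenario, set_size = d$set_size,
                               observed_median_or = d$observed_median_or,
                               p_permutation = d$p_permutation,
                               n_perm = d$n_perm, seed = d$seed,
                               stringsAsFactors = FALSE),
                    path(paste0("direction_", sc, ".tsv")))
  }
  if (!is.null(out$geneset) && !is.null(out$geneset$terms))
    write_results(out$geneset$terms, path("terms.tsv"))
  writeLines(out$report, path("report.txt"))
  jsonlite::write_json(out$manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(NULL)
}

#' Render a plain-text run report
#'
#' A deterministic, idempotent text summary: per-scenario correlation
#' results, the per-threshold odds-ratio table (OR, 95% CI, p, Bonferroni
#' verdict), the direction test's observed median OR against its null
#' distribution summary, and the gene-set table with fold enrichment,
#' Bonferroni p and raw p (or an explicit "no significant terms" line).
#'
#' @param out a [run_pipeline()] result (the `report` element is ignored).
#' @return character vector of report lines.
#' @export
render_report <- function(out) {
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")
  lines <- c(paste0("sweepenrich run report (v",
                    out$manifest$version, ", seed ", out$manifest$seed, ")"),
             paste0("analysis variants: ", nrow(out$annotated)), "")
  for (sc in names(out$correlation)) {
    cr <- out$correlation[[sc]]
    lines <- c(lines,
      paste0("== scenario: ", sc, " =="),
      paste0("Spearman rho = ", fmt(cr$rho), ", asymptotic p = ",
             fmt(cr$p_asymptotic), ", permutation p = ",
             fmt(cr$p_permutation), " (", cr$n_perm, " draws, alpha = ",
             fmt(cr$bonferroni_alpha), ifelse(cr$significant,
                                              ", significant)", ")")),
      "threshold scan (p_threshold a b c d OR [95% CI] p signif):")
    tab <- out$scan[[sc]]
    lines <- c(lines, vapply(seq_len(nrow(tab)), function(i) {
      r <- tab[i, ]
      paste0("  p<", fmt(r$p_threshold), ": ", r$a, " ", r$b, " ", r$c, " ",
             r$d, "  OR=", fmt(r$odds_ratio), " [", fmt(r$ci_lo), ",",
             fmt(r$ci_hi), "] p=", fmt(r$p_value),
             if (isTRUE(r$significant)) " *" else "",
             if (!is.na(r$reason)) paste0(" (", r$reason, ")") else "")
    }, character(1)))
    d <- out$direction[[sc]]
    if (inherits(d, "direction_result")) {
      q <- quantile(d$null_medians, c(0.025, 0.5, 0.975), names = FALSE)
      lines <- c(lines,
        paste0("direction: median minor-allele OR = ",
               fmt(d$observed_median_or), " over ", d$set_size,
               " focal variants; null median [2.5%,50%,97.5%] = [",
               fmt(q[1]), ",", fmt(q[2]), ",", fmt(q[3]),
               "]; permutation p = ", fmt(d$p_permutation)))
    } else {
      lines <- c(lines, paste0("direction test skipped: ",
                               d$error %||% "not run"))
    }
    lines <- c(lines, "")
  }
  if (!is.null(out$geneset)) {
    lines <- c(lines, "== gene-set over-representation ==")
    if (!is.null(out$geneset$error)) {
      lines <- c(lines, paste0("skipped: ", out$geneset$error))
    } else {
      sig <- out$geneset$terms[out$geneset$terms$p_bonferroni <
                                 out$geneset$alpha, , drop = FALSE]
      if (nrow(sig) == 0) {
        lines <- c(lines, "no significant terms")
      } else {
        lines <- c(lines,
          "term_id  fold_enrichment  bonferroni_p  p_value",
          vapply(seq_len(nrow(sig)), function(i) {
            paste0("  ", sig$term_id[i], "  ", fmt(sig$fold_enrichment[i]),
                   "  ", fmt(sig$p_bonferroni[i]), "  ", fmt(sig$p_value[i]))
          }, character(1)))
      }
      cp <- out$geneset$count_perm
      lines <- c(lines,
        paste0("enrichment-count validation: observed ", cp$observed_count,
               " significant term(s); permutation p = ",
               fmt(cp$p_permutation), " (", cp$n_perm, " draws)"))
    }
  }
  lines
}
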