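#' Run the full post-GWAS pipeline
#'
#' Orchestrates QC filtering, the unconditional genome-wide scan, iterative
#' conditional lead-SNP detection per chromosome, QTL-interval
#' delineation, LD linking of significant SNPs to each lead, the
#' gene-based principal-components scan, and evidence-based candidate-gene
#' prioritization. Inputs may be in-memory objects or file paths
#' (genotypes: VCF/dosage TSV; genes: GFF3/BED; phenotype and evidence:
#' TSV). When `out_dir` is given every stage's table is written as TSV
#' along with a JSON run summary; reruns with the same inputs are
#' byte-identical.
#'
#' @param geno A [genotype_matrix()] or path.
#' @param pheno Phenotype table (`id`, `value`), `phenotype_sim`, or path.
#' @param genes A `gene_model_set` or path; `NULL` skips the gene-based
#'   and prioritization stages.
#' @param evidence An `evidence_catalog`, path, or `NULL` (skips evidence
#'   attachment; all potential candidates are then reported unsupported).
#' @param thr A [thresholds()] object.
#' @param mode `"ols"` (default) or `"mlm"`; `"mlm"` builds a GRM from the
#'   QC-passing variants and fits the polygenic random effect.
#' @param out_dir Output directory or `NULL` for in-memory results only.
#' @param seed Recorded in the summary (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `qtl_pipeline_result` list: `qc_report`, `assoc` (round-1
#'   genome-wide scan), `qtl`, `ld_sets`, `gene_results`, `candidates`,
#'   `unsupported`, `summary`, `threshold_neglogp`.
#' @export
run_pipeline <- function(geno, pheno, genes = NULL, evidence = NULL,
                         thr = thresholds(), mode = c("ols", "mlm"),
                         out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(geno)) geno <- read_genotypes(geno)
  if (is.character(pheno)) pheno <- read_phenotype(pheno)
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (is.character(evidence)) evidence <- read_evidence(evidence)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  qc <- stage("qc", qc_filter(geno, thr))
  geno_qc <- qc$geno
  grm <- if (mode == "mlm") stage("grm", make_grm(geno_qc)) else NULL
  n_tests <- thr$n_tests_snp %||% n_variants(geno_qc)
  cutoff <- bonferroni_neglogp_threshold(thr$alpha, n_tests)

  chroms <- unique(geno_qc$variants$chrom)
  assoc <- stage("scan", mlm_scan(geno_qc, pheno, grm = grm, thr = thr))

  qtl_rows <- list()
  ld_sets <- list()
  for (ch in chroms) {
    r1 <- assoc[assoc$chrom == ch, , drop = FALSE]
    leads <- stage("qtl_detect",
                   detect_leads(geno_qc, pheno, thr, chrom = ch, grm = grm,
                                round1 = r1, n_tests = n_tests))
    rounds <- attr(leads, "rounds")
    if (nrow(leads) == 0L) next
    for (i in seq_len(nrow(leads))) {
      iv <- stage("interval",
                  delineate_interval(leads[i, ], rounds[[i]], thr))
      nsig <- sum(r1$neglogp >= cutoff & r1$flag == "" &
                    r1$pos >= iv[1] & r1$pos <= iv[2])
      qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
        chrom = leads$chrom[i], lead_pos = leads$pos[i],
        lead_id = leads$id[i], effect = leads$beta[i],
        neglogp = leads$neglogp[i], interval_start = iv[1],
        interval_end = iv[2], iteration = leads$iteration[i],
        n_significant_in_interval = nsig, stringsAsFactors = FALSE)
      ld_sets[[leads$id[i]]] <- stage("ld",
        ld_linked_significant(leads[i, ], r1, geno_qc, thr,
                              n_tests = n_tests))
    }
  }
  qtl <- if (length(qtl_rows) > 0L) do.call(rbind, qtl_rows) else
    data.frame(chrom = character(0), lead_pos = integer(0),
               lead_id = character(0), effect = numeric(0),
               neglogp = numeric(0), interval_start = numeric(0),
               interval_end = numeric(0), iteration = integer(0),
               n_significant_in_interval = integer(0),
               stringsAsFactors = FALSE)
  class(qtl) <- c("qtl_table", "data.frame")

  gene_results <- NULL
  cands <- list(candidates = NULL, unsupported = NULL)
  if (!is.null(genes)) {
    gene_results <- stage("gene_scan", gene_scan(geno_qc, pheno, genes, thr))
    if (nrow(qtl) > 0L) {
      catalog <- evidence %||% simulate_evidence_empty()
      cands <- stage("prioritize",
                     build_candidate_table(qtl, ld_sets, gene_results,
                                           genes, catalog))
    }
  }

  summary <- list(
    seed = seed,
    mode = mode,
    thresholds = unclass(thr),
    snp_neglogp_threshold = cutoff,
    n_individuals = n_individuals(geno),
    n_variants_input = n_variants(geno),
    n_variants_excluded = nrow(qc$report),
    n_variants_tested = n_variants(geno_qc),
    n_significant_snps = sum(assoc$neglogp >= cutoff & assoc$flag == ""),
    n_qtl = nrow(qtl),
    n_qtl_per_chrom = as.list(table(qtl$chrom)),
    n_ld_linked = sum(vapply(ld_sets, nrow, 0L)),
    n_genes_tested = if (is.null(gene_results)) 0L else
      sum(!gene_results$untestable),
    n_genes_significant = if (is.null(gene_results)) 0L else
      sum(gene_results$significant),
    n_candidates = if (is.null(cands$candidates)) 0L else
      nrow(cands$candidates),
    n_unsupported = if (is.null(cands$unsupported)) 0L else
      nrow(cands$unsupported))

  res <- structure(list(qc_report = qc$report, assoc = assoc, qtl = qtl,
                        ld_sets = ld_sets, gene_results = gene_results,
                        candidates = cands$candidates,
                        unsupported = cands$unsupported,
                        summary = summary,
                        threshold_neglogp = cutoff),
                   class = "qtl_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

simulate_evidence_empty <- function() {
  structure(data.frame(gene = character(0), source = character(0),
                       label = character(0), direction = character(0),
                       study = character(0), tissue = character(0),
                       comparison = character(0), stringsAsFactors = FALSE),
            class = c("evidence_catalog", "data.frame"))
}

#' Write every pipeline table plus the JSON run summary
#'
#' Coordinates in all outputs are 1-based inclusive.
#'
#' @param res A `qtl_pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(qc_report = "qc_report.tsv", assoc = "sumstats.tsv",
             qtl = "qtl.tsv", ld = "ld_linked.tsv",
             genes = "gene_tests.tsv", candidates = "candidates.tsv",
             unsupported = "unsupported.tsv", summary = "summary.json")
  paths <- stats::setNames(file.path(out_dir, paths), names(paths))
  write_tsv(res$qc_report, paths[["qc_report"]])
  write_tsv(as.data.frame(res$assoc), paths[["assoc"]])
  write_tsv(as.data.frame(res$qtl), paths[["qtl"]])
  ld_all <- if (length(res$ld_sets) > 0L) {
    do.call(rbind, lapply(res$ld_sets, as.data.frame))
  } else {
    data.frame(lead_id = character(0), member_id = character(0),
               chrom = character(0), pos = integer(0),
               r2 = numeric(0), neglogp = numeric(0))
  }
  write_tsv(ld_all, paths[["ld"]])
  if (!is.null(res$gene_results))
    write_tsv(as.data.frame(res$gene_results), paths[["genes"]])
  if (!is.null(res$candidates))
    write_tsv(res$candidates, paths[["candidates"]])
  if (!is.null(res$unsupported))
    write_tsv(res$unsupported, paths[["unsupported"]])
  jsonlite::write_json(res$summary, paths[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' @export
print.qtl_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "qtl_pipeline_result\n",
    "  %d individuals, %d/%d variants kept after QC\n",
    "  significance: -log10(P) >= %.2f; %d significant SNPs\n",
    "  %d QTL detected; %d LD-linked variants\n",
    "  %d genes tested, %d significant; %d final candidates\n"),
    s$n_individuals, s$n_variants_tested, s$n_variants_input,
    s$snp_neglogp_threshold, s$n_significant_snps, s$n_qtl, s$n_ld_linked,
    s$n_genes_tested, s$n_genes_significant, s$n_candidates))
  invisible(x)
}

#' Manhattan plot of an association scan
#'
#' Minimal base-graphics Manhattan plot with the significance line.
#'
#' @param assoc An `assoc_result`.
#' @param threshold Genome-wide -log10(P) threshold to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
manhattan_plot <- function(assoc, threshold = NULL, ...) {
  chroms <- unique(assoc$chrom)
  offset <- 0
  xs <- numeric(nrow(assoc))
  cols <- integer(nrow(assoc))
  for (i in seq_along(chroms)) {
    sel <- assoc$chrom == chroms[i]
    xs[sel] <- assoc$pos[sel] + offset
    cols[sel] <- (i %% 2) + 1L
    offset <- offset + max(assoc$pos[sel])
  }
  graphics::plot(xs, assoc$neglogp, pch = 20, cex = 0.4,
                 col = c("grey30", "steelblue")[cols],
                 xlab = "genome position", ylab = "-log10(P)", ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
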