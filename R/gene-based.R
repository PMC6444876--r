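#' Assign variants to gene models
#'
#' A variant belongs to every gene whose `[start, end]` span (1-based,
#' inclusive, UTRs included in the model coordinates) contains its
#' position; overlapping genes share variants. Genes without any variant
#' are excluded from testing.
#'
#' @param geno A [genotype_matrix()].
#' @param genes A `gene_model_set` data frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @return Named list mapping `gene_id` to a character vector of variant
#'   ids; genes with zero variants are absent.
#' @export
assign_snps_to_genes <- function(geno, genes) {
  v <- GenomicRanges::GRanges(geno$variants$chrom,
                              IRanges::IRanges(geno$variants$pos, width = 1L))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(g, v)
  if (length(hits) == 0L) return(stats::setNames(list(), character(0)))
  sp <- split(geno$variants$id[S4Vectors::subjectHits(hits)],
              genes$gene_id[S4Vectors::queryHits(hits)])
  sp[unique(genes$gene_id[S4Vectors::queryHits(hits)])]
}

#' Gene-based association by principal-components regression
#'
#' The joint association of a gene's variants with the trait, tested the
#' way gene-level "linreg" models do it: the gene's dosage columns are
#' centred, projected onto their principal components, and the phenotype is
#' regressed on the smallest set of leading components explaining at least
#' `var_explained` (99.9%) of the genotypic variance (always at least one).
#' The reported statistic is the overall F test of the retained components.
#' For a single polymorphic SNP this reduces exactly to the single-marker
#' OLS test, and duplicating columns does not change the span and so leaves
#' F unchanged.
#'
#' @param pheno Numeric phenotype vector aligned to the rows of
#'   `gene_dosages`, or a phenotype table (`id`, `value`) whose ids match
#'   the matrix rownames.
#' @param gene_dosages Individuals x SNPs dosage matrix for one gene.
#' @param var_explained Cumulative variance fraction retained.
#' @return A one-row data frame: `n_snps`, `n_pcs`, `F`, `p`, `neglogp`,
#'   `untestable` (`TRUE` when the gene matrix has no variance).
#' @export
gene_pc_regression <- function(pheno, gene_dosages, var_explained = 0.999) {
  M <- as.matrix(gene_dosages)
  if (inherits(pheno, "phenotype_sim")) pheno <- pheno$phenotype
  y <- if (is.data.frame(pheno)) {
    idx <- match(rownames(M), as.character(pheno$id))
    if (anyNA(idx)) stop("phenotype ids do not cover the gene matrix rows")
    pheno$value[idx]
  } else as.numeric(pheno)
  if (length(y) != nrow(M)) stop("phenotype not aligned to gene dosages")
  k <- ncol(M)
  if (k < 1L) stop("gene must carry at least one SNP")
  Mc <- scale(M, center = TRUE, scale = FALSE)
  untestable <- all(abs(Mc) < 1e-12)
  if (untestable) {
    return(data.frame(n_snps = k, n_pcs = 0L, F = NA_real_, p = NA_real_,
                      neglogp = NA_real_, untestable = TRUE))
  }
  sv <- svd(Mc)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-10
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  q <- max(1L, which(cum >= var_explained)[1L])
  S <- sv$u[, seq_len(q), drop = FALSE] %*% diag(sv$d[seq_len(q)], q)
  n <- length(y)
  if (n - q - 1L < 1L) stop("not enough residual degrees of freedom")
  fit <- stats::lm.fit(cbind(1, S), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  Fstat <- ((tss - rss) / q) / (rss / (n - q - 1L))
  logp <- stats::pf(Fstat, q, n - q - 1L, lower.tail = FALSE, log.p = TRUE)
  data.frame(n_snps = k, n_pcs = q, F = Fstat, p = exp(logp),
             neglogp = -logp / log(10), untestable = FALSE)
}

#' Gene-based scan over a gene model set
#'
#' Runs [gene_pc_regression()] for every gene carrying at least one variant
#' and applies the gene-wise Bonferroni threshold.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno Phenotype table or `phenotype_sim`.
#' @param genes A `gene_model_set` data frame.
#' @param thr A [thresholds()] object; `thr$n_tests_gene` overrides the
#'   test count in the gene threshold (default: number of genes tested).
#' @param var_explained Passed to [gene_pc_regression()].
#' @return A `gene_test_result` data frame: `gene_id`, `name`, `chrom`,
#'   `start`, `end`, `n_snps`, `n_pcs`, `F`, `p`, `neglogp`, `significant`;
#'   attribute `p_threshold` records the cutoff applied.
#' @export
gene_scan <- function(geno, pheno, genes, thr = thresholds(),
                      var_explained = 0.999) {
  al <- align_phenotype(geno, pheno)
  assign <- assign_snps_to_genes(geno, genes)
  rows <- list()
  for (gid in names(assign)) {
    cols <- match(assign[[gid]], geno$variants$id)
    res <- gene_pc_regression(al$y,
                              geno$dosages[al$rows, cols, drop = FALSE],
                              var_explained = var_explained)
    gi <- match(gid, genes$gene_id)
    rows[[gid]] <- cbind(data.frame(gene_id = gid, name = genes$name[gi],
                                    chrom = genes$chrom[gi],
                                    start = genes$start[gi],
                                    end = genes$end[gi],
                                    stringsAsFactors = FALSE),
                         res)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(0), name = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               n_snps = integer(0), n_pcs = integer(0), F = numeric(0),
               p = numeric(0), neglogp = numeric(0),
               untestable = logical(0), stringsAsFactors = FALSE)
  n_tested <- sum(!out$untestable)
  cutoff <- gene_threshold(thr$alpha,
                           thr$n_tests_gene %||% max(n_tested, 1L))
  out$significant <- !out$untestable & !is.na(out$p) & out$p <= cutoff
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- cutoff
  class(out) <- c("gene_test_result", "data.frame")
  out
}
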