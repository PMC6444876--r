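#' Significance and filtering thresholds for the pipeline
#'
#' Bundles every tunable cutoff used across the QC, association, QTL
#' delineation and LD-linking stages. Defaults follow common practice for
#' sequence-level GWAS on dairy cattle: variants below 0.5% minor allele
#' frequency or failing a Hardy-Weinberg goodness-of-fit test at P < 1e-6
#' are removed before scanning; genome-wide significance is Bonferroni at an
#' experiment-wise 0.05; QTL intervals are scanned up to 1 Mb either side of
#' the lead with a minimum half-width of 0.25 Mb and a boundary triggered by
#' a drop of more than 3 -log10(P) units; LD linking uses r2 > 0.2; solo-SNP
#' screening uses a 1 Mb window.
#'
#' @param alpha Experiment-wise type-I error rate.
#' @param n_tests_snp Number of SNP tests used for the Bonferroni threshold.
#'   `NULL` (default) means "use the number of variants in the scan".
#' @param n_tests_gene Number of gene tests for the gene-wise threshold;
#'   `NULL` means "use the number of genes actually tested".
#' @param maf_min Minimum minor allele frequency retained by [qc_filter()].
#' @param hwe_p_min Minimum Hardy-Weinberg test P retained by [qc_filter()].
#' @param ld_r2_min r2 cutoff for LD linking (members must exceed it).
#' @param flank_bp Maximum distance scanned either side of a lead SNP when
#'   delineating a QTL interval.
#' @param default_halfwidth_bp Minimum interval half-width; also the
#'   fallback half-width when no boundary SNP qualifies.
#' @param drop_units -log10(P) drop relative to the lead that marks a
#'   boundary SNP.
#' @param solo_window_bp Window used by [is_solo_snp()]: a significant SNP
#'   with no other significant SNP within this distance is "solo".
#' @return An object of class `qtl_thresholds` (a named list).
#' @export
thresholds <- function(alpha = 0.05,
                       n_tests_snp = NULL,
                       n_tests_gene = NULL,
                       maf_min = 0.005,
                       hwe_p_min = 1e-6,
                       ld_r2_min = 0.2,
                       flank_bp = 1e6,
                       default_halfwidth_bp = 250000,
                       drop_units = 3,
                       solo_window_bp = 1e6) {
  if (!(alpha > 0 && alpha < 1)) stop_config("alpha", "must be in (0,1)")
  if (!(maf_min > 0 && maf_min < 0.5)) stop_config("maf_min", "must be in (0,0.5)")
  if (!(hwe_p_min > 0 && hwe_p_min < 1)) stop_config("hwe_p_min", "must be in (0,1)")
  if (!(ld_r2_min > 0 && ld_r2_min < 1)) stop_config("ld_r2_min", "must be in (0,1)")
  for (f in c("flank_bp", "default_halfwidth_bp", "drop_units", "solo_window_bp")) {
    v <- get(f)
    if (!(is.numeric(v) && length(v) == 1L && v > 0)) stop_config(f, "must be a positive number")
  }
  if (default_halfwidth_bp > flank_bp)
    stop_config("default_halfwidth_bp", "cannot exceed flank_bp")
  structure(list(alpha = alpha, n_tests_snp = n_tests_snp,
                 n_tests_gene = n_tests_gene, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, ld_r2_min = ld_r2_min,
                 flank_bp = flank_bp,
                 default_halfwidth_bp = default_halfwidth_bp,
                 drop_units = drop_units, solo_window_bp = solo_window_bp),
            class = "qtl_thresholds")
}

#' Genome-wide Bonferroni threshold on the -log10(P) scale
#'
#' The per-test significance level is `alpha / n_tests`; the threshold is
#' returned as `-log10(alpha / n_tests)` so it can be compared directly with
#' the `neglogp` column of an association result. For 15,551,021 tests at
#' alpha = 0.05 this is about 8.5.
#'
#' @param alpha Experiment-wise type-I error rate, in (0,1).
#' @param n_tests Number of simultaneous tests (>= 1).
#' @return The threshold on the -log10(P) scale.
#' @export
bonferroni_neglogp_threshold <- function(alpha, n_tests) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop_config("alpha", "must be in (0,1)")
  if (!(is.numeric(n_tests) && n_tests >= 1))
    stop_config("n_tests", "must be >= 1")
  log10(n_tests) - log10(alpha)
}

#' Gene-wise Bonferroni P-value threshold
#'
#' @param alpha Experiment-wise type-I error rate.
#' @param n_genes_tested Number of genes carrying at least one SNP.
#' @return The per-gene P-value threshold `alpha / n_genes_tested`. With
#'   20,356 testable genes at alpha = 0.05 this is about 2.46e-6.
#' @export
gene_threshold <- function(alpha, n_genes_tested) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop_config("alpha", "must be in (0,1)")
  if (!(is.numeric(n_genes_tested) && n_genes_tested >= 1))
    stop_config("n_genes_tested", "must be >= 1")
  alpha / n_genes_tested
}

# Resolve the SNP significance threshold for a scan of n_variants markers.
snp_neglogp_threshold <- function(thr, n_variants) {
  bonferroni_neglogp_threshold(thr$alpha, thr$n_tests_snp %||% n_variants)
}
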