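#' Pairwise linkage-disequilibrium r-squared between two dosage vectors
#'
#' The squared Pearson correlation of allele dosages — the standard
#' genotype-level LD surrogate for unphased or imputed data. It is
#' symmetric and invariant to allele recoding (`g -> 2 - g`). For a
#' monomorphic input the quantity is undefined and `NA` is returned with a
#' warning.
#'
#' @param g1,g2 Numeric dosage vectors of equal length (>= 3).
#' @return r2 in `[0, 1]`, or `NA` for monomorphic input.
#' @export
pairwise_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors must have equal length")
  if (length(g1) < 3L) stop("need at least 3 individuals")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) {
    warning("monomorphic input: r2 undefined")
    return(NA_real_)
  }
  min(stats::cor(g1, g2)^2, 1)
}

#' Significant SNPs in LD with a lead SNP
#'
#' Extracts, from the unconditional (round 1) association results, every
#' genome-wide significant SNP on the lead's chromosome whose dosage r2
#' with the lead exceeds `thr$ld_r2_min` (0.2 by default). Membership uses
#' the marginal scan: this is the set subsequently annotated and used to
#' pull in gene-based candidates.
#'
#' @param lead A list or one-row data frame with `id`, `chrom`, `pos`.
#' @param assoc Round-1 `assoc_result` covering the lead's chromosome.
#' @param geno The [genotype_matrix()] the scan was run on.
#' @param thr A [thresholds()] object.
#' @param n_tests SNP-test count for the significance cutoff; defaults to
#'   `thr$n_tests_snp`, then `n_variants(geno)`.
#' @return An `ld_linked_set` data frame: `lead_id`, `member_id`, `chrom`,
#'   `pos`, `r2`, `neglogp`, sorted by position.
#' @export
ld_linked_significant <- function(lead, assoc, geno, thr = thresholds(),
                                  n_tests = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  li <- match(lead$id, geno$variants$id)
  if (is.na(li)) stop("lead SNP absent from genotypes: ", lead$id)
  gl <- geno$dosages[, li]
  if (stats::sd(gl) == 0) stop("lead SNP is monomorphic")
  cutoff <- bonferroni_neglogp_threshold(
    thr$alpha, n_tests %||% thr$n_tests_snp %||% n_variants(geno))
  sig <- assoc[assoc$chrom == lead$chrom & assoc$flag == "" &
                 assoc$neglogp >= cutoff & assoc$id != lead$id, ,
               drop = FALSE]
  out <- data.frame(lead_id = character(0), member_id = character(0),
                    chrom = character(0), pos = integer(0),
                    r2 = numeric(0), neglogp = numeric(0),
                    stringsAsFactors = FALSE)
  if (nrow(sig) > 0L) {
    cols <- match(sig$id, geno$variants$id)
    if (anyNA(cols)) stop("significant SNPs absent from genotypes")
    G <- geno$dosages[, cols, drop = FALSE]
    sds <- apply(G, 2, stats::sd)
    r2 <- rep(NA_real_, length(cols))
    r2[sds > 0] <- as.vector(stats::cor(gl, G[, sds > 0, drop = FALSE]))^2
    keep <- !is.na(r2) & r2 > thr$ld_r2_min
    out <- data.frame(lead_id = rep(lead$id, sum(keep)),
                      member_id = sig$id[keep],
                      chrom = sig$chrom[keep], pos = sig$pos[keep],
                      r2 = pmin(r2[keep], 1), neglogp = sig$neglogp[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(out$pos), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("ld_linked_set", "data.frame")
  out
}
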