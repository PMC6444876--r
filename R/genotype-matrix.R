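#' Construct a genotype dosage matrix
#'
#' The central genotype container: an individuals x variants matrix of
#' allele dosages in `[0, 2]` plus per-variant metadata. Variants must be
#' unique on (chrom, pos, alt) and sorted by position within chromosome,
#' mirroring how imputed sequence data is stored.
#'
#' @param dosages Numeric matrix, individuals in rows, variants in columns.
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`; one row per column of `dosages`.
#' @param individual_ids Character vector of individual identifiers, one per
#'   row of `dosages`.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `variants`, `individual_ids`.
#' @export
genotype_matrix <- function(dosages, variants, individual_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variants rows must match dosage columns")
  if (length(individual_ids) != nrow(dosages))
    stop("individual_ids must match dosage rows")
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$id <- as.character(variants$id)
  key <- paste(variants$chrom, variants$pos, variants$alt)
  if (anyDuplicated(key)) stop("duplicated variant (chrom, pos, alt)")
  if (anyDuplicated(variants$id)) stop("duplicated variant ids")
  if (length(dosages) > 0L) {
    rng <- range(dosages)
    if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
      stop("dosage entries must lie in [0, 2]")
  }
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(dosages) <- list(individual_ids, variants$id)
  structure(list(dosages = dosages, variants = variants,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Number of variants / individuals
#' @param geno A `genotype_matrix`.
#' @return Integer count.
#' @export
n_variants <- function(geno) ncol(geno$dosages)

#' @rdname n_variants
#' @export
n_individuals <- function(geno) nrow(geno$dosages)

#' Subset a genotype matrix by variant index or chromosome
#'
#' @param geno A `genotype_matrix`.
#' @param variants Integer/logical index into the variant columns, or `NULL`.
#' @param chrom Optional chromosome name; applied before `variants`.
#' @param individuals Optional individual ids or row index.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, variants = NULL, chrom = NULL,
                             individuals = NULL) {
  idx <- seq_len(n_variants(geno))
  if (!is.null(chrom)) idx <- idx[geno$variants$chrom %in% chrom]
  if (!is.null(variants)) idx <- idx[variants]
  rows <- seq_len(n_individuals(geno))
  if (!is.null(individuals)) {
    rows <- if (is.character(individuals))
      match(individuals, geno$individual_ids) else rows[individuals]
    if (anyNA(rows)) stop("unknown individual ids in subset")
  }
  genotype_matrix(geno$dosages[rows, idx, drop = FALSE],
                  geno$variants[idx, , drop = FALSE],
                  geno$individual_ids[rows])
}

#' Per-variant allele frequency and minor allele frequency
#'
#' @param geno A `genotype_matrix`.
#' @return For `variant_freq`, the alt-allele frequency (mean dosage / 2);
#'   for `variant_maf`, the folded minor allele frequency.
#' @export
variant_freq <- function(geno) colMeans(geno$dosages) / 2

#' @rdname variant_freq
#' @export
variant_maf <- function(geno) {
  f <- variant_freq(geno)
  pmin(f, 1 - f)
}

#' Genomic relationship matrix from dosages
#'
#' VanRaden method-1 GRM: dosages are centred by twice the allele frequency
#' and the cross-product is scaled by `sum(2 p (1-p))`. Monomorphic variants
#' are ignored. Used as the covariance structure of the polygenic random
#' effect in the mixed-model scan.
#'
#' @param geno A `genotype_matrix`.
#' @return An n x n symmetric matrix with individual ids as dimnames.
#' @export
make_grm <- function(geno) {
  p <- variant_freq(geno)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants for GRM")
  Z <- sweep(geno$dosages[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(Z) / sum(2 * p[poly] * (1 - p[poly]))
  dimnames(K) <- list(geno$individual_ids, geno$individual_ids)
  K
}
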