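`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' Align a phenotype table to a genotype matrix
#'
#' Intersects individual identifiers and returns the phenotype values in the
#' genotype row order. Individuals present in only one of the two inputs are
#' dropped.
#'
#' @param geno A `genotype_matrix`.
#' @param pheno A data frame with columns `id` and `value` (or a
#'   `phenotype_sim` object from [simulate_phenotype()]).
#' @return A list with `y` (numeric vector), `ids` (character) and `rows`
#'   (row indices into the genotype matrix).
#' @export
align_phenotype <- function(geno, pheno) {
  if (inherits(pheno, "phenotype_sim")) pheno <- pheno$phenotype
  stopifnot(is.data.frame(pheno), all(c("id", "value") %in% names(pheno)))
  if (!all(is.finite(pheno$value))) stop("phenotype values must be finite")
  ids <- intersect(geno$individual_ids, as.character(pheno$id))
  if (length(ids) == 0L) stop("no individuals shared between genotypes and phenotypes")
  rows <- match(ids, geno$individual_ids)
  y <- pheno$value[match(ids, as.character(pheno$id))]
  list(y = as.numeric(y), ids = ids, rows = rows)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", "")))
}
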