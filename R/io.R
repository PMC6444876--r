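#' Write a genotype matrix as VCF v4.2 with dosages
#'
#' Emits one record per variant with a `DS` (alternate-allele dosage)
#' FORMAT field, the representation imputation software produces. Dosages
#' are written with four decimals.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path (uncompressed `.vcf`).
#' @param contig_lengths Optional named vector of chromosome lengths for
#'   the `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf_dosages <- function(geno, path, contig_lengths = NULL) {
  v <- geno$variants
  hdr <- c("##fileformat=VCFv4.2", "##source=qtlgene")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  } else {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(v$chrom)))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$individual_ids), collapse = "\t"))
  ds <- formatC(t(geno$dosages), format = "f", digits = 4)
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "DS",
                apply(ds, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

gt_to_dosage <- function(gt) {
  # "0/1", "1|1", "./." -> alt-allele count; mixed ploidy is an error
  parts <- strsplit(gt, "[/|]")
  ploidy <- lengths(parts)
  if (length(unique(ploidy[!is.na(gt)])) > 1L)
    stop("mixed ploidy in GT field")
  vapply(parts, function(a) {
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }, 0)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' For VCF, the `DS` FORMAT field is preferred; when absent, dosages fall
#' back to the alternate-allele count of the `GT` field. The dosage-TSV
#' alternative has one row per variant with columns `chrom`, `pos`, `id`,
#' `ref`, `alt` followed by one column per individual.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(vcf)
    fx <- if (is.null(dim(fx))) as.data.frame(t(fx)) else as.data.frame(fx)
    variants <- data.frame(chrom = as.character(fx$CHROM),
                           pos = as.integer(fx$POS),
                           id = as.character(fx$ID),
                           ref = as.character(fx$REF),
                           alt = as.character(fx$ALT),
                           stringsAsFactors = FALSE)
    noid <- is.na(variants$id) | variants$id == "."
    variants$id[noid] <- paste0(variants$chrom[noid], "_", variants$pos[noid])
    fmt <- vcf@gt[, 1]
    if (all(grepl("(^|:)DS(:|$)", fmt))) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- matrix(gt_to_dosage(as.vector(gt)), nrow = nrow(gt),
                   dimnames = dimnames(gt))
    }
    if (anyNA(ds)) stop("missing dosages/genotypes are not supported")
    genotype_matrix(t(ds), variants, colnames(vcf@gt)[-1])
  } else {
    tab <- read_tsv(path)
    meta_cols <- c("chrom", "pos", "id", "ref", "alt")
    if (!all(meta_cols %in% names(tab)))
      stop("dosage TSV must have columns chrom, pos, id, ref, alt + individuals")
    ind <- setdiff(names(tab), meta_cols)
    genotype_matrix(t(as.matrix(tab[, ind, drop = FALSE])),
                    tab[, meta_cols], ind)
  }
}

#' Write a dosage TSV (variants in rows, individuals in columns)
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_tsv <- function(geno, path) {
  tab <- cbind(geno$variants,
               as.data.frame(t(geno$dosages), check.names = FALSE))
  write_tsv(tab, path)
}

#' Read a phenotype table (columns `id`, `value`)
#' @param path TSV path.
#' @return Data frame with `id` (character) and `value` (numeric).
#' @export
read_phenotype <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("id", "value") %in% names(tab)))
    stop("phenotype table must have columns id, value")
  tab$id <- as.character(tab$id)
  tab$value <- as.numeric(tab$value)
  tab
}

#' Write gene models as GFF3
#'
#' Gene features with `ID` and `Name` attributes, 1-based inclusive
#' coordinates.
#'
#' @param genes A `gene_model_set` data frame.
#' @param path Output `.gff3` path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand %||% "*")
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$name %||% genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3: features with type `gene` are used, identified by their `ID` (and
#' `Name`) attributes. BED (0-based, half-open) is converted to 1-based
#' inclusive coordinates on read.
#'
#' @param path Input path (`.gff3`/`.gff` or `.bed`).
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return A `gene_model_set` data frame (`gene_id`, `name`, `chrom`,
#'   `start`, `end`, `strand`).
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID)
  else if ("name" %in% names(md)) as.character(md$name)
  else sprintf("GENE%04d", seq_along(gr))
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  genes <- data.frame(gene_id = ids, name = nm,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "+"
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_model_set", "data.frame")
  genes
}
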