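#' Nearest gene/feature to a genomic position
#'
#' Distance is 0 when the position falls inside a feature's `[start, end]`
#' span, otherwise the gap to the nearer boundary in bp (bedtools-closest
#' convention: a position one base before a feature start is at distance
#' 1). All features tied at the minimum distance are returned. `relation`
#' says where the query lies relative to the feature in genomic
#' coordinates: `within`, `upstream` (query before the start) or
#' `downstream` (query past the end).
#'
#' @param chrom Chromosome of the query position.
#' @param pos Query position in bp.
#' @param features A `gene_model_set`-like data frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @return The tied nearest feature rows with added columns `distance` and
#'   `relation`; a zero-row data frame (with attribute `no_feature = TRUE`)
#'   when the chromosome carries no feature.
#' @export
nearest_feature <- function(chrom, pos, features) {
  feats <- features[features$chrom == chrom, , drop = FALSE]
  if (nrow(feats) == 0L) {
    out <- cbind(features[0, , drop = FALSE],
                 data.frame(distance = numeric(0), relation = character(0)))
    attr(out, "no_feature") <- TRUE
    return(out)
  }
  d <- ifelse(pos < feats$start, feats$start - pos,
              ifelse(pos > feats$end, pos - feats$end, 0))
  md <- min(d)
  out <- feats[d == md, , drop = FALSE]
  out$distance <- md
  out$relation <- ifelse(pos < out$start, "upstream",
                         ifelse(pos > out$end, "downstream", "within"))
  rownames(out) <- NULL
  out
}

#' Candidate genes from the gene-based test via LD-linked SNPs
#'
#' For every significant SNP in LD with the QTL's lead, the closest (or
#' containing) gene among the genome-wide significant gene-based results is
#' selected; the union over SNPs, deduplicated and ordered by position, is
#' the QTL's gene-based candidate list.
#'
#' @param qtl A one-row `qtl_table` entry (or list with `chrom`,
#'   `lead_id`).
#' @param ld_set An `ld_linked_set` for the QTL's lead.
#' @param gene_results A `gene_test_result` data frame already filtered to
#'   significant genes (or with a `significant` column, which is applied).
#' @param genes The full `gene_model_set` (used only for coordinates when
#'   `gene_results` lacks them).
#' @return Data frame of candidate genes (`gene_id`, `name`, `chrom`,
#'   `start`, `end`) ordered by position; zero rows when nothing qualifies.
#' @export
candidates_from_gene_based <- function(qtl, ld_set, gene_results,
                                       genes = NULL) {
  sig <- gene_results
  if ("significant" %in% names(sig)) sig <- sig[sig$significant, , drop = FALSE]
  if (!all(c("start", "end") %in% names(sig)) && !is.null(genes)) {
    gi <- match(sig$gene_id, genes$gene_id)
    sig$chrom <- genes$chrom[gi]; sig$start <- genes$start[gi]
    sig$end <- genes$end[gi]
  }
  empty <- data.frame(gene_id = character(0), name = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nrow(ld_set) == 0L || nrow(sig) == 0L) return(empty)
  hits <- list()
  for (i in seq_len(nrow(ld_set))) {
    nf <- nearest_feature(ld_set$chrom[i], ld_set$pos[i], sig)
    if (nrow(nf) > 0L) hits[[length(hits) + 1L]] <- nf
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out$gene_id),
             intersect(c("gene_id", "name", "chrom", "start", "end"),
                       names(out)), drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read or validate an evidence catalog
#'
#' The catalog is a TSV with columns `gene`, `source` (one of GO, KEGG,
#' MPD, DEG), `label`, and for DEG records `direction` (Up/Down), `study`,
#' `tissue`, `comparison`.
#'
#' @param x Path to a TSV file or a data frame.
#' @return An `evidence_catalog` data frame.
#' @export
read_evidence <- function(x) {
  cat <- if (is.character(x)) read_tsv(x) else as.data.frame(x)
  need <- c("gene", "source", "label")
  if (!all(need %in% names(cat)))
    stop("evidence catalog must have columns: ", paste(need, collapse = ", "))
  for (col in c("direction", "study", "tissue", "comparison"))
    if (!col %in% names(cat)) cat[[col]] <- ""
  cat$direction[is.na(cat$direction)] <- ""
  bad <- setdiff(unique(cat$source), c("GO", "KEGG", "MPD", "DEG"))
  if (length(bad) > 0L)
    stop("unknown evidence sources: ", paste(bad, collapse = ", "))
  deg <- cat$source == "DEG"
  if (any(deg & !cat$direction %in% c("Up", "Down")))
    stop("DEG records must carry a direction (Up/Down)")
  class(cat) <- c("evidence_catalog", "data.frame")
  cat
}

match_evidence_rows <- function(gene, catalog) {
  which(tolower(catalog$gene) == tolower(gene))
}

#' Direction concordance of a gene's differential-expression records
#'
#' A candidate is concordant when every DEG record for it, across studies
#' and comparisons, reports the same direction of change.
#'
#' @param gene Gene symbol or id (matched case-insensitively).
#' @param catalog An `evidence_catalog`.
#' @return A list: `n_comparisons` (number of DEG records) and `concordant`
#'   (`TRUE`/`FALSE`, or `NA` when the gene has no DEG record).
#' @export
deg_concordance <- function(gene, catalog) {
  rows <- match_evidence_rows(gene, catalog)
  deg <- catalog[rows, , drop = FALSE]
  deg <- deg[deg$source == "DEG", , drop = FALSE]
  if (nrow(deg) == 0L) return(list(n_comparisons = 0L, concordant = NA))
  list(n_comparisons = nrow(deg),
       concordant = length(unique(deg$direction)) == 1L)
}

#' Attach evidence to potential candidate genes
#'
#' A potential candidate becomes a final candidate when it has at least one
#' evidence record of any source (GO, KEGG, MPD, DEG); genes without
#' evidence are reported separately, never silently dropped. Gene names are
#' matched case-insensitively; names absent from the catalog simply attach
#' no evidence.
#'
#' @param potentials Data frame with at least a `gene` column; extra
#'   columns (e.g. `lead_snp`, `provenance`) are carried through.
#' @param catalog An `evidence_catalog` (or path to one).
#' @return A list: `candidates` (supported genes with `evidence_sources`
#'   — distinct sources joined by ","; `deg_n` and `deg_concordant`) and
#'   `unsupported` (the remaining potential candidates).
#' @export
attach_evidence <- function(potentials, catalog) {
  catalog <- read_evidence(catalog)
  stopifnot("gene" %in% names(potentials))
  sources <- character(nrow(potentials))
  deg_n <- integer(nrow(potentials))
  deg_conc <- rep(NA, nrow(potentials))
  for (i in seq_len(nrow(potentials))) {
    rows <- match_evidence_rows(potentials$gene[i], catalog)
    src <- sort(unique(catalog$source[rows]))
    sources[i] <- paste(src, collapse = ",")
    dc <- deg_concordance(potentials$gene[i], catalog)
    deg_n[i] <- dc$n_comparisons
    deg_conc[i] <- dc$concordant
  }
  out <- potentials
  out$evidence_sources <- sources
  out$deg_n <- deg_n
  out$deg_concordant <- deg_conc
  supported <- nzchar(sources)
  list(candidates = out[supported, , drop = FALSE],
       unsupported = out[!supported, , drop = FALSE])
}

# Consequence terms ordered from most to least severe (following the
# standard variant-effect ranking); terms not listed rank after these.
vep_severity_order <- c(
  "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "transcript_amplification", "inframe_insertion", "inframe_deletion",
  "missense_variant", "protein_altering_variant", "splice_region_variant",
  "incomplete_terminal_codon_variant", "start_retained_variant",
  "stop_retained_variant", "synonymous_variant", "coding_sequence_variant",
  "mature_miRNA_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "NMD_transcript_variant", "non_coding_transcript_variant",
  "upstream_gene_variant", "downstream_gene_variant", "TFBS_ablation",
  "TFBS_amplification", "TF_binding_site_variant",
  "regulatory_region_variant", "feature_elongation", "feature_truncation",
  "intergenic_variant")

coding_consequences <- c(
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "inframe_insertion", "inframe_deletion", "missense_variant",
  "protein_altering_variant", "start_retained_variant",
  "stop_retained_variant", "synonymous_variant",
  "coding_sequence_variant")

#' Summarize externally produced consequence annotations
#'
#' Consumes a variant-effect annotation table (VEP tab format or any table
#' with a `Consequence` column and a variant identifier in the first or
#' `Uploaded_variation` column). Each variant is counted once under its
#' most severe consequence (annotations may list several per row, comma
#' separated, and a variant may span several rows). Consequences that
#' alter the protein-coding sequence are tallied separately. Rows without
#' a usable consequence are skipped and counted.
#'
#' @param vep_table Path to the annotation TSV or a data frame.
#' @return A list: `counts` (named integer vector over most-severe
#'   consequences), `coding` (the coding subset), `n_variants`,
#'   `n_skipped`.
#' @export
summarize_consequences <- function(vep_table) {
  tab <- if (is.character(vep_table)) {
    lines <- readLines(vep_table)
    lines <- lines[!startsWith(lines, "##")]  # VEP meta-information header
    as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                    sep = "\t", header = TRUE))
  } else as.data.frame(vep_table)
  names(tab) <- sub("^#", "", names(tab))
  cons_col <- grep("^consequence$", names(tab), ignore.case = TRUE, value = TRUE)
  if (length(cons_col) == 0L) stop("no Consequence column found")
  id_col <- if ("Uploaded_variation" %in% names(tab)) "Uploaded_variation"
  else names(tab)[1L]
  if (nrow(tab) == 0L) {
    return(list(counts = integer(0), coding = integer(0),
                n_variants = 0L, n_skipped = 0L))
  }
  cons <- as.character(tab[[cons_col[1L]]])
  ids <- as.character(tab[[id_col]])
  ok <- !is.na(cons) & nzchar(cons) & !is.na(ids) & nzchar(ids)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) warning(n_skipped, " malformed annotation row(s) skipped")
  rank_of <- function(terms) {
    r <- match(terms, vep_severity_order)
    r[is.na(r)] <- length(vep_severity_order) + 1L
    r
  }
  worst <- vapply(split(cons[ok], ids[ok]), function(x) {
    terms <- unique(trimws(unlist(strsplit(x, ","))))
    terms[which.min(rank_of(terms))]
  }, "")
  counts <- table(worst)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(rank_of(names(counts)))]
  coding <- counts[names(counts) %in% coding_consequences]
  list(counts = counts, coding = coding,
       n_variants = length(worst), n_skipped = n_skipped)
}

#' Build the prioritized candidate-gene table for a set of QTL
#'
#' For each QTL the potential candidates are (1) the nearest gene(s) to the
#' lead SNP and (2) the gene-based candidates pulled in through LD-linked
#' significant SNPs ([candidates_from_gene_based()]). Evidence is then
#' attached and genes with none are set aside, yielding the final
#' candidate table (one row per QTL x gene, with provenance, the distinct
#' evidence sources and the DEG direction-concordance flag).
#'
#' @param qtl A `qtl_table`.
#' @param ld_sets Named list of `ld_linked_set`s keyed by `lead_id`.
#' @param gene_results A `gene_test_result`.
#' @param genes The `gene_model_set`.
#' @param catalog An `evidence_catalog` (or path).
#' @return A list: `candidates`, `unsupported` (both data frames with
#'   `lead_snp`, `gene`, `provenance`, `evidence_sources`,
#'   `deg_concordant`).
#' @export
build_candidate_table <- function(qtl, ld_sets, gene_results, genes,
                                  catalog) {
  pots <- list()
  for (i in seq_len(nrow(qtl))) {
    lead_id <- qtl$lead_id[i]
    nf <- nearest_feature(qtl$chrom[i], qtl$lead_pos[i], genes)
    if (nrow(nf) > 0L) {
      pots[[length(pots) + 1L]] <- data.frame(
        lead_snp = lead_id, gene = nf$name %||% nf$gene_id,
        gene_id = nf$gene_id, provenance = "nearest_to_lead",
        distance_bp = nf$distance, stringsAsFactors = FALSE)
    }
    ld <- ld_sets[[lead_id]]
    if (!is.null(ld)) {
      gb <- candidates_from_gene_based(qtl[i, ], ld, gene_results, genes)
      if (nrow(gb) > 0L) {
        pots[[length(pots) + 1L]] <- data.frame(
          lead_snp = lead_id, gene = gb$name, gene_id = gb$gene_id,
          provenance = "gene_based_ld", distance_bp = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(lead_snp = character(0), gene = character(0),
                      gene_id = character(0), provenance = character(0),
                      distance_bp = numeric(0),
                      evidence_sources = character(0), deg_n = integer(0),
                      deg_concordant = logical(0), stringsAsFactors = FALSE)
  if (length(pots) == 0L) return(list(candidates = empty, unsupported = empty))
  pot <- do.call(rbind, pots)
  # one row per QTL x gene; merge provenance when both routes found it
  key <- paste(pot$lead_snp, pot$gene_id)
  prov <- vapply(split(pot$provenance, key), function(x)
    paste(sort(unique(x)), collapse = "+"), "")
  pot <- pot[!duplicated(key), , drop = FALSE]
  pot$provenance <- prov[paste(pot$lead_snp, pot$gene_id)]
  attach_evidence(pot, catalog)
}
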