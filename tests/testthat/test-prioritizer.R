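# Gene spans as printed in the cattle fertility study's gene-based results;
# used as exact nearest-gene fixtures.
bta_genes <- function() {
  g <- data.frame(
    gene_id = c("GK2", "FRAS1", "PAQR3", "LIF", "UMPS", "KALRN"),
    name = c("GK2", "FRAS1", "PAQR3", "LIF", "UMPS", "KALRN"),
    chrom = c("6", "6", "6", "17", "1", "1"),
    start = c(95882918, 94711652, 95409078, 71413855, 69732778, 69248613),
    end = c(95884576, 95055569, 95441932, 71418166, 69782823, 69724961),
    strand = "+", stringsAsFactors = FALSE)
  class(g) <- c("gene_model_set", "data.frame")
  g
}

test_that("nearest gene distances match the published lead-SNP annotations", {
  genes <- bta_genes()
  gk2 <- nearest_feature("6", 95867927, genes)
  expect_identical(gk2$gene_id, "GK2")
  expect_identical(gk2$distance, 14991)
  expect_identical(gk2$relation, "upstream")
  lif <- nearest_feature("17", 71393345, genes)
  expect_identical(lif$gene_id, "LIF")
  expect_identical(lif$distance, 20510)
  umps <- nearest_feature("1", 69742415, genes)
  expect_identical(umps$gene_id, "UMPS")
  expect_identical(umps$distance, 0)
  expect_identical(umps$relation, "within")
})

test_that("nearest feature agrees with a GenomicRanges oracle and reports ties", {
  set.seed(110)
  genes <- data.frame(gene_id = paste0("g", 1:40), name = paste0("g", 1:40),
                      chrom = rep(c("1", "2"), each = 20),
                      start = sample.int(9e5, 40))
  genes$end <- genes$start + sample(100:5000, 40)
  genes$strand <- "+"
  class(genes) <- c("gene_model_set", "data.frame")
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  for (i in 1:50) {
    chrom <- sample(c("1", "2"), 1)
    pos <- sample.int(1e6, 1)
    nf <- nearest_feature(chrom, pos, genes)
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hits <- GenomicRanges::nearest(q, gr, select = "all")
    oracle <- genes$gene_id[S4Vectors::subjectHits(hits)]
    oracle <- oracle[genes$chrom[S4Vectors::subjectHits(hits)] == chrom]
    expect_setequal(nf$gene_id, oracle)
  }
  # distance ties return every tied feature
  tie <- data.frame(gene_id = c("L", "R"), name = c("L", "R"), chrom = "3",
                    start = c(100L, 300L), end = c(150L, 350L), strand = "+")
  class(tie) <- c("gene_model_set", "data.frame")
  nf <- nearest_feature("3", 225, tie)
  expect_setequal(nf$gene_id, c("L", "R"))
  expect_true(all(nf$distance == 75))
  # empty chromosome: flagged no-feature result
  nf0 <- nearest_feature("9", 100, tie)
  expect_identical(nrow(nf0), 0L)
  expect_true(isTRUE(attr(nf0, "no_feature")))
})

test_that("gene-based candidates equal a brute-force nearest-gene mapping", {
  genes <- bta_genes()
  sig_genes <- genes[genes$chrom == "6", ]
  sig_genes$significant <- TRUE
  ld <- data.frame(lead_id = "lead6", member_id = paste0("m", 1:5),
                   chrom = "6",
                   pos = c(94800000L, 95100000L, 95420000L, 95700000L,
                           95890000L),
                   r2 = 0.5, neglogp = 10, stringsAsFactors = FALSE)
  class(ld) <- c("ld_linked_set", "data.frame")
  qtl <- list(chrom = "6", lead_id = "lead6")
  got <- candidates_from_gene_based(qtl, ld, sig_genes, genes)
  oracle <- unique(unlist(lapply(ld$pos, function(p)
    nearest_feature("6", p, sig_genes)$gene_id)))
  expect_setequal(got$gene_id, oracle)
  expect_false(is.unsorted(got$start))
  # empty LD set -> empty candidate list
  expect_identical(nrow(candidates_from_gene_based(qtl, ld[0, ], sig_genes,
                                                   genes)), 0L)
  # one LD SNP inside one significant gene -> that gene only
  one <- ld[3, , drop = FALSE]
  expect_identical(candidates_from_gene_based(qtl, one, sig_genes,
                                              genes)$gene_id, "PAQR3")
})

test_that("evidence attachment reproduces the published support patterns", {
  catalog <- data.frame(
    gene = c("LIF", "LIF", "ADCY5", "ADCY5", "ADCY5", "FRAS1", "FRAS1",
             "FRAS1"),
    source = c("GO", "MPD", "KEGG", "DEG", "DEG", "GO", "DEG", "DEG"),
    label = c("maternal process involved in female pregnancy",
              "failure of embryo implantation", "oocyte meiosis",
              "differential expression", "differential expression",
              "embryonic limb morphogenesis", "differential expression",
              "differential expression"),
    direction = c("", "", "", "Down", "Down", "", "Down", "Down"),
    study = c("", "", "", "studyC", "studyC", "", "studyB", "studyC"),
    tissue = c("", "", "", "endometrium", "endometrium", "",
               "uterine biopsies", "endometrium"),
    comparison = c("", "", "", "pregnant vs non-pregnant high-fertile",
                   "pregnant vs non-pregnant high-fertile", "",
                   "pregnant vs non-pregnant",
                   "pregnant vs non-pregnant high-fertile"),
    stringsAsFactors = FALSE)
  pots <- data.frame(gene = c("LIF", "ADCY5", "FRAS1", "BORING"),
                     stringsAsFactors = FALSE)
  got <- attach_evidence(pots, catalog)
  expect_identical(got$candidates$evidence_sources[
    got$candidates$gene == "LIF"], "GO,MPD")
  expect_identical(got$candidates$evidence_sources[
    got$candidates$gene == "ADCY5"], "DEG,KEGG")
  expect_identical(got$candidates$evidence_sources[
    got$candidates$gene == "FRAS1"], "DEG,GO")
  # genes without any record are excluded from the final list, not dropped
  expect_identical(got$unsupported$gene, "BORING")
  # DEG direction concordance across studies/tissues
  fras1 <- deg_concordance("FRAS1", read_evidence(catalog))
  expect_identical(fras1$n_comparisons, 2L)
  expect_true(fras1$concordant)
  # discordant and single-record cases
  disc <- data.frame(gene = "X", source = "DEG", label = "de",
                     direction = c("Up", "Down"), study = c("a", "b"),
                     tissue = "", comparison = "")
  expect_false(deg_concordance("X", read_evidence(disc))$concordant)
  single <- disc[1, ]
  one <- deg_concordance("X", read_evidence(single))
  expect_identical(one$n_comparisons, 1L)
  expect_true(one$concordant)
  # gene with no DEG record: flagged not applicable
  expect_true(is.na(deg_concordance("LIF", read_evidence(catalog))$concordant))
  # matching is case-insensitive
  expect_identical(attach_evidence(data.frame(gene = "lif"),
                                   catalog)$candidates$evidence_sources,
                   "GO,MPD")
})

test_that("consequence summaries count each variant once at its most severe term", {
  tab <- data.frame(
    Uploaded_variation = c("v1", "v2", "v3", "v4", "v5", "v6", "v6"),
    Consequence = c("intron_variant", "intron_variant", "intron_variant",
                    "intergenic_variant", "intergenic_variant",
                    "missense_variant,intron_variant", "intron_variant"),
    stringsAsFactors = FALSE)
  got <- summarize_consequences(tab)
  expect_identical(got$counts[["intron_variant"]], 3L)
  expect_identical(got$counts[["intergenic_variant"]], 2L)
  # v6 has two annotations and counts once under the more severe
  expect_identical(got$counts[["missense_variant"]], 1L)
  expect_identical(got$n_variants, 6L)
  expect_identical(got$coding, c(missense_variant = 1L))
  # empty table: all-zero counts
  empty <- summarize_consequences(tab[0, ])
  expect_identical(empty$n_variants, 0L)
  expect_identical(length(empty$counts), 0L)
  # malformed rows are skipped with a warning and counted
  bad <- rbind(tab, data.frame(Uploaded_variation = "v7", Consequence = ""))
  expect_warning(got2 <- summarize_consequences(bad), "skipped")
  expect_identical(got2$n_skipped, 1L)
  expect_identical(got2$n_variants, 6L)
})
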