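test_that("genotype simulation is deterministic and respects dosage bounds", {
  cfg <- small_config(seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosages %in% c(0, 1, 2)))
  expect_false(is.unsorted(g1$variants$pos))
  # planted site exists exactly
  expect_true(2e6 %in% g1$variants$pos)
})

test_that("realized minor allele frequencies stay near their targets", {
  cfg <- sim_config(n_individuals = 2000, chromosomes = c("1" = 4e6),
                    n_variants_per_chrom = 400, ld_decay_bp = 5e4,
                    maf_range = c(0.3, 0.5), h2_polygenic = 0, seed = 5)
  geno <- simulate_genotypes(cfg)
  maf <- variant_maf(geno)
  # binomial sampling tolerance around targets drawn in [0.3, 0.5]
  expect_true(all(maf >= 0.2 & maf <= 0.5))
})

test_that("LD decays with physical distance", {
  cfg <- sim_config(n_individuals = 500, chromosomes = c("1" = 5e6),
                    n_variants_per_chrom = 600, ld_decay_bp = 2e4,
                    maf_range = c(0.1, 0.5), h2_polygenic = 0, seed = 21)
  geno <- simulate_genotypes(cfg)
  D <- geno$dosages
  m <- ncol(D)
  # adjacent-site correlation vs sites ~10x the decay scale away (200 kb,
  # ~24 sites at the mean spacing), averaged over >= 500 site pairs
  lag_far <- 24L
  idx <- seq_len(m - lag_far)
  adj <- vapply(idx, function(j) stats::cor(D[, j], D[, j + 1L]), 0)
  far <- vapply(idx, function(j) stats::cor(D[, j], D[, j + lag_far]), 0)
  expect_gt(mean(abs(adj)), mean(abs(far)))
  expect_gt(mean(abs(adj)), 0.2)
  expect_lt(mean(abs(far)), 0.1)
})

test_that("r2 with a planted site decreases with distance (monotone trend)", {
  cfg <- recovery_config(seed = 31)
  geno <- simulate_genotypes(cfg)
  qcol <- which(geno$variants$pos == 7.5e6)
  d <- abs(geno$variants$pos - 7.5e6)
  r2 <- as.vector(stats::cor(geno$dosages[, qcol], geno$dosages))^2
  bins <- cut(d[-qcol], breaks = seq(0, 1e6, by = 2e5))
  mr <- tapply(r2[-qcol][!is.na(bins)], bins[!is.na(bins)], mean)
  expect_gt(mr[[1]], mr[[length(mr)]])
  expect_lt(stats::cor(seq_along(mr), as.numeric(mr), method = "spearman"), 0)
})

test_that("phenotype is pure standard Gaussian noise when nothing is planted", {
  cfg <- sim_config(n_individuals = 3000, chromosomes = c("1" = 2e6),
                    n_variants_per_chrom = 50, ld_decay_bp = 5e4,
                    maf_range = c(0.1, 0.5), h2_polygenic = 0, seed = 4)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(geno, cfg)
  y <- ph$phenotype$value
  expect_lt(abs(mean(y)), 0.1)
  expect_lt(abs(stats::sd(y) - 1), 0.05)
  expect_gt(stats::shapiro.test(sample(y, 1000))$p.value, 1e-4)
  expect_identical(nrow(ph$truth), 0L)
  # determinism
  expect_identical(y, simulate_phenotype(geno, cfg)$phenotype$value)
})

test_that("a strongly planted QTL is detectable at the genome-wide level", {
  cfg <- sim_config(n_individuals = 2000, chromosomes = c("1" = 4e6),
                    n_variants_per_chrom = 300, ld_decay_bp = 5e4,
                    maf_range = c(0.1, 0.5),
                    qtl = planted_qtl("1", 2e6, 0.5, maf = 0.3),
                    h2_polygenic = 0, seed = 12)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(geno, cfg)
  a <- mlm_scan(geno, ph)
  expect_gt(a$neglogp[a$pos == 2e6], 8.5)
})

test_that("phenotype simulation reports missing planted positions", {
  cfg <- small_config(seed = 3)
  geno <- simulate_genotypes(cfg)
  cfg_bad <- cfg
  cfg_bad$qtl <- list(planted_qtl("1", 999999L, 0.5))
  expect_error(simulate_phenotype(geno, cfg_bad), "absent")
})

test_that("gene models stay within bounds and can cover planted QTL", {
  cfg <- small_config(seed = 9)
  genes <- simulate_gene_models(cfg, n_genes = 100, mean_len = 20000)
  expect_s3_class(genes, "gene_model_set")
  expect_identical(nrow(genes), 100L)
  expect_true(all(genes$start >= 1))
  expect_true(all(genes$end <= 4e6))
  expect_true(all(genes$start <= genes$end))
  causal <- genes[genes$gene_id == "CAUSAL1", ]
  expect_identical(nrow(causal), 1L)
  expect_true(causal$start <= 2e6 && causal$end >= 2e6)
  expect_error(simulate_gene_models(cfg, n_genes = 5, mean_len = 5e6),
               "mean_len")
})

test_that("gene models round-trip through the GFF3 writer/reader", {
  cfg <- small_config(seed = 9)
  genes <- simulate_gene_models(cfg, n_genes = 30)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(genes, path)
  back <- read_gene_models(path)
  expect_equal(as.data.frame(back), as.data.frame(genes))
})

test_that("evidence simulation plants support exactly where asked", {
  cfg <- small_config(seed = 9)
  genes <- simulate_gene_models(cfg, n_genes = 30)
  # zero false positives: evidence exactly on the planted genes
  ev <- simulate_evidence(genes, "CAUSAL1", cfg, fp_rate = 0)
  expect_identical(sort(unique(ev$gene)), "CAUSAL1")
  deg <- ev[ev$source == "DEG", ]
  expect_identical(nrow(deg), 2L)
  expect_identical(length(unique(deg$direction)), 1L)
  expect_identical(length(unique(deg$study)), 2L)
  dc <- deg_concordance("CAUSAL1", read_evidence(ev))
  expect_identical(dc$n_comparisons, 2L)
  expect_true(dc$concordant)
  # empty planted list, zero fp rate: empty catalog
  ev0 <- simulate_evidence(genes, character(0), cfg, fp_rate = 0)
  expect_identical(nrow(ev0), 0L)
  expect_error(simulate_evidence(genes, "NOPE", cfg), "unknown planted")
})

test_that("simulator rejects inconsistent configurations by field name", {
  expect_error(sim_config(n_individuals = 1), "n_individuals")
  expect_error(sim_config(100, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(100, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(100, qtl = planted_qtl("9", 100, 0.5)), "qtl")
  expect_error(sim_config(100, chromosomes = c("1" = 1e6),
                          qtl = planted_qtl("1", 2e6, 0.5)), "qtl")
  expect_error(sim_config(100, h2_polygenic = 0.9,
                          qtl = planted_qtl("1", 100, 0.5)), "h2_polygenic")
})
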