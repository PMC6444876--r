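# Shared simulation scenarios.
#
# The "recovery" scenario emulates a dense imputed-sequence GWAS at desk
# scale: 2000 individuals, one 15 Mb chromosome carrying 1500 markers
# (~10 kb spacing, LD decay scale 50 kb), one planted QTL of 0.5 SD at a
# MAF-0.3 site over a polygenic background of h2 = 0.3. Significance uses
# the genome-wide threshold of the full-scale study (-log10 P ~ 8.5),
# since the single simulated chromosome stands in for a genome-wide scan.

gw_thresholds <- function(...) thresholds(n_tests_snp = 15551021, ...)

recovery_config <- function(seed, effect = 0.5, maf = 0.3) {
  sim_config(n_individuals = 2000, chromosomes = c("1" = 1.5e7),
             n_variants_per_chrom = 1500, ld_decay_bp = 5e4,
             maf_range = c(0.05, 0.5),
             qtl = planted_qtl("1", 7.5e6, effect, maf = maf,
                               causal_gene_id = "CAUSAL1"),
             h2_polygenic = 0.3, seed = seed)
}

run_recovery <- function(seed, fp_rate = 0.05) {
  cfg <- recovery_config(seed)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(geno, cfg)
  genes <- simulate_gene_models(cfg, n_genes = 50)
  ev <- simulate_evidence(genes, "CAUSAL1", cfg, fp_rate = fp_rate)
  res <- run_pipeline(geno, ph, genes, ev, thr = gw_thresholds())
  q <- res$qtl
  list(
    n_qtl = nrow(q),
    qtl_hit = nrow(q) == 1 && q$interval_start <= 7.5e6 &&
      q$interval_end >= 7.5e6,
    cand_hit = !is.null(res$candidates) &&
      "CAUSAL1" %in% res$candidates$gene_id,
    res = res)
}

# Small fast scenario for IO / pipeline plumbing tests.
small_config <- function(seed, qtl = list(planted_qtl("1", 2e6, 0.8,
                                                      maf = 0.3,
                                                      causal_gene_id = "CAUSAL1")),
                         h2 = 0.2) {
  sim_config(n_individuals = 500, chromosomes = c("1" = 4e6),
             n_variants_per_chrom = 400, ld_decay_bp = 5e4,
             maf_range = c(0.1, 0.5), qtl = qtl, h2_polygenic = h2,
             seed = seed)
}

# Hard-genotype matrix from explicit genotype counts (n_AA, n_Aa, n_aa)
# per variant; useful for HWE / QC fixtures.
geno_from_counts <- function(counts_list) {
  n <- sum(counts_list[[1]])
  dos <- vapply(counts_list, function(cc) {
    stopifnot(sum(cc) == n)
    rep(c(0, 1, 2), times = cc)
  }, numeric(n))
  variants <- data.frame(chrom = "1",
                         pos = seq_len(length(counts_list)) * 1000L,
                         id = paste0("v", seq_along(counts_list)),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, sprintf("i%03d", seq_len(n)))
}
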