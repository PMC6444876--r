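test_that("Hardy-Weinberg chi-square test matches closed-form tails", {
  # perfect proportions at p = 0.5 and p = 0.3: chi-square 0, P ~ 1
  expect_equal(hwe_test(c(25, 50, 25)), 1, tolerance = 1e-12)
  expect_equal(hwe_test(c(9, 42, 49)), 1, tolerance = 1e-12)
  # total heterozygote deficit: chi-square 100 on 1 df; the 1-df chi-square
  # is a squared standard normal, so P = 2 * pnorm(-10)
  expect_equal(hwe_test(c(50, 0, 50)), 2 * stats::pnorm(-10),
               tolerance = 1e-8)
  expect_lt(hwe_test(c(50, 0, 50)), 1e-6)
  expect_error(hwe_test(c(0, 0, 0)), "at least one")
  expect_error(hwe_test(c(1, 2)), "three")
})

test_that("QC filter removes low-MAF and HWE-failing variants with reasons", {
  geno <- geno_from_counts(list(c(25, 50, 25),   # perfect HWE, MAF 0.5
                                c(50, 0, 50),    # HWE P ~ 1.5e-23
                                c(100, 0, 0),    # monomorphic
                                c(60, 30, 10)))  # ordinary variant
  qc <- qc_filter(geno, thresholds())
  expect_setequal(qc$geno$variants$id, c("v1", "v4"))
  expect_identical(qc$report$reason[qc$report$id == "v2"], "hwe")
  expect_identical(qc$report$reason[qc$report$id == "v3"], "low_maf")
  expect_error(qc_filter(subset_genotypes(geno, variants = integer(0))),
               "empty|at least")
})

test_that("OLS scan agrees with a brute-force normal-equations oracle", {
  set.seed(71)
  n <- 20
  dos <- matrix(sample(0:2, n * 6, replace = TRUE), n, 6)
  variants <- data.frame(chrom = "1", pos = 1:6 * 100L,
                         id = paste0("s", 1:6), ref = "A", alt = "G")
  geno <- genotype_matrix(dos, variants, sprintf("i%02d", 1:n))
  y <- rnorm(n) + 0.7 * dos[, 3]
  pheno <- data.frame(id = geno$individual_ids, value = y)
  res <- mlm_scan(geno, pheno, covariate_snps = "s5")
  for (j in c(1, 2, 3, 4, 6)) {
    X <- cbind(1, dos[, 5], dos[, j])
    bhat <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% bhat
    s2 <- sum(r^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[3, 3])
    pv <- 2 * stats::pt(-abs(bhat[3] / se), n - ncol(X))
    expect_equal(res$beta[j], bhat[3], tolerance = 1e-8)
    expect_equal(res$se[j], se, tolerance = 1e-8)
    expect_equal(res$p[j], pv, tolerance = 1e-8)
  }
  # the conditioned SNP is excluded from testing
  expect_identical(res$flag[5], "covariate")
  expect_identical(res$p[5], 1)
})

test_that("identity-GRM mixed model reduces exactly to OLS", {
  cfg <- small_config(seed = 41)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(geno, cfg)
  ols <- mlm_scan(geno, ph)
  I <- diag(n_individuals(geno))
  dimnames(I) <- list(geno$individual_ids, geno$individual_ids)
  mlm <- mlm_scan(geno, ph, grm = I)
  expect_equal(mlm$beta, ols$beta, tolerance = 1e-8)
  expect_equal(mlm$se, ols$se, tolerance = 1e-8)
  expect_equal(mlm$neglogp, ols$neglogp, tolerance = 1e-6)
})

test_that("a noiseless monogenic trait gives beta = 2 and vanishing p", {
  geno <- geno_from_counts(list(c(3, 4, 3), c(4, 3, 3)))
  y <- 2 * geno$dosages[, 1]
  res <- mlm_scan(geno, data.frame(id = geno$individual_ids, value = y))
  expect_equal(res$beta[1], 2, tolerance = 1e-10)
  expect_lt(res$p[1], 1e-100)
  expect_true(res$neglogp[1] > 100)
})

test_that("p-values are monotone in |t| and neglogp matches p", {
  cfg <- small_config(seed = 42)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(geno, cfg)
  res <- mlm_scan(geno, ph)
  ok <- res$flag == "" & res$p > 1e-300
  tt <- abs(res$beta / res$se)[ok]
  expect_identical(order(res$p[ok]), order(-tt))
  expect_equal(res$neglogp[ok], -log10(res$p[ok]), tolerance = 1e-6)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$se[ok] > 0))
})

test_that("perfect-LD copies of a conditioned lead are flagged collinear", {
  set.seed(8)
  n <- 50
  g <- sample(0:2, n, replace = TRUE)
  dos <- cbind(g, g, sample(0:2, n, replace = TRUE))
  variants <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                         id = c("lead", "copy", "other"), ref = "A",
                         alt = "C")
  geno <- genotype_matrix(dos, variants, sprintf("i%02d", 1:n))
  ph <- data.frame(id = geno$individual_ids, value = rnorm(n))
  res <- mlm_scan(geno, ph, covariate_snps = "lead")
  expect_identical(res$flag[res$id == "copy"], "collinear")
  expect_identical(res$p[res$id == "copy"], 1)
  expect_identical(res$flag[res$id == "other"], "")
})

test_that("conditioning on an uncorrelated covariate barely moves beta", {
  cfg <- sim_config(n_individuals = 1000, chromosomes = c("1" = 5e6),
                    n_variants_per_chrom = 200, ld_decay_bp = 2e4,
                    maf_range = c(0.2, 0.5),
                    qtl = planted_qtl("1", 2.5e6, 0.4, maf = 0.3),
                    h2_polygenic = 0, seed = 77)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(geno, cfg)
  base <- mlm_scan(geno, ph)
  # covariate at the far end of the chromosome, ~2.5 Mb from the QTL
  far_id <- geno$variants$id[n_variants(geno)]
  cond <- mlm_scan(geno, ph, covariate_snps = far_id)
  j <- which(base$pos == 2.5e6)
  expect_lt(abs(base$beta[j] - cond$beta[j]), 0.05)
})

test_that("Bonferroni thresholds reproduce the expected scales", {
  expect_equal(bonferroni_neglogp_threshold(0.05, 1), -log10(0.05),
               tolerance = 1e-12)
  expect_equal(bonferroni_neglogp_threshold(0.05, 15551021), 8.49,
               tolerance = 0.005)
  expect_equal(10^(-bonferroni_neglogp_threshold(0.05, 20356)), 2.46e-6,
               tolerance = 0.005)
  expect_error(bonferroni_neglogp_threshold(1.5, 10), "alpha")
})
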