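#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against the expected proportions `(p^2, 2pq, q^2)` at the sample allele
#' frequency. Dosages are rounded to the nearest hard genotype before
#' counting (see [qc_filter()]). A monomorphic sample fits its expected
#' proportions exactly and returns P = 1; the frequency filter is the one
#' that removes such sites.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return The chi-square upper-tail P-value.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be three non-negative genotype counts")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual required")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((counts - expected)^2 / expected)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

# Vectorized HWE over the columns of a dosage matrix (rounded genotypes).
hwe_test_matrix <- function(dosages) {
  g <- round(dosages)
  n0 <- colSums(g == 0)
  n1 <- colSums(g == 1)
  n2 <- colSums(g == 2)
  n <- n0 + n1 + n2
  p <- (2 * n0 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * p^2; e1 <- n * 2 * p * q; e2 <- n * q^2
  chisq <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  out <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  out
}

#' Quality-control filter on minor allele frequency and Hardy-Weinberg
#'
#' Retains variants with minor allele frequency at least `thr$maf_min`
#' (default 0.5%) and Hardy-Weinberg test P at least `thr$hwe_p_min`
#' (default 1e-6). Each excluded variant is listed with its reason.
#'
#' @param geno A [genotype_matrix()].
#' @param thr A [thresholds()] object.
#' @return A list: `geno` (the filtered matrix) and `report` (data frame of
#'   exclusions with columns `id`, `chrom`, `pos`, `reason`, `value`).
#' @export
qc_filter <- function(geno, thr = thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (n_variants(geno) == 0L) stop("empty genotype matrix")
  maf <- variant_maf(geno)
  hwe <- hwe_test_matrix(geno$dosages)
  low_maf <- maf < thr$maf_min
  bad_hwe <- !low_maf & hwe < thr$hwe_p_min
  keep <- !(low_maf | bad_hwe)
  excl_df <- function(sel, reason, value) {
    data.frame(id = geno$variants$id[sel],
               chrom = geno$variants$chrom[sel],
               pos = geno$variants$pos[sel],
               reason = rep(reason, sum(sel)), value = value[sel],
               stringsAsFactors = FALSE)
  }
  report <- rbind(excl_df(low_maf, "low_maf", maf),
                  excl_df(bad_hwe, "hwe", hwe))
  rownames(report) <- NULL
  list(geno = subset_genotypes(geno, variants = keep), report = report)
}

# Profile REML criterion (to maximize) for the variance ratio
# delta = sigma_e^2 / sigma_g^2, on rotated data (EMMA-style).
reml_criterion <- function(log_delta, lam, yr, Xr) {
  delta <- exp(log_delta)
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  Xs <- Xr * sw
  ys <- yr * sw
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  n <- length(yr); p <- ncol(Xr)
  ldet <- determinant(crossprod(Xs), logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(rss) - sum(log(w)) + as.numeric(ldet))
}

#' Single-marker association scan (OLS or mixed linear model)
#'
#' Fits, for every variant, `trait ~ intercept + covariate doses + variant
#' dose`. When a genomic relationship matrix is supplied a polygenic random
#' effect with covariance proportional to the GRM is included: the GRM is
#' spectrally decomposed once, the variance ratio is estimated by REML on
#' the null model, and every variant is then tested by generalized least
#' squares in the rotated coordinates. With an identity GRM the model
#' reduces exactly to ordinary least squares. P-values are two-sided from
#' the t distribution with the residual degrees of freedom; `neglogp` is
#' computed on the log scale and therefore stays finite (or `Inf` for an
#' exact fit) where `p` underflows.
#'
#' Variants supplied as covariates are excluded from testing and reported
#' with `p = 1` and flag `"covariate"`; variants collinear with the
#' covariates (e.g. a perfect LD copy of a conditioned lead SNP) are
#' flagged `"collinear"`, also with `p = 1`.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno Phenotype table (`id`, `value`) or `phenotype_sim`.
#' @param covariate_snps Character vector of variant ids to condition on.
#' @param grm Optional genomic relationship matrix with individual ids as
#'   dimnames (see [make_grm()]); `NULL` gives plain OLS.
#' @param thr A [thresholds()] object (carried through for reporting).
#' @return An `assoc_result` data frame: `chrom`, `pos`, `id`, `a1`, `a2`,
#'   `maf`, `n_used`, `beta`, `se`, `p`, `neglogp`, `flag`.
#' @export
mlm_scan <- function(geno, pheno, covariate_snps = character(0), grm = NULL,
                     thr = thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  al <- align_phenotype(geno, pheno)
  y <- al$y
  D <- geno$dosages[al$rows, , drop = FALSE]
  n <- length(y)
  miss_cov <- setdiff(covariate_snps, geno$variants$id)
  if (length(miss_cov) > 0L)
    stop("covariate snps absent from genotypes: ",
         paste(miss_cov, collapse = ", "))
  cov_idx <- match(covariate_snps, geno$variants$id)
  X0 <- cbind(`(Intercept)` = rep(1, n),
              D[, cov_idx, drop = FALSE])
  G <- D
  if (!is.null(grm)) {
    if (!is.null(dimnames(grm))) {
      ri <- match(al$ids, rownames(grm))
      if (anyNA(ri)) stop("GRM is missing some phenotyped individuals")
      grm <- grm[ri, ri, drop = FALSE]
    } else if (nrow(grm) != n) {
      stop("GRM dimension does not match the analysed individuals")
    }
    eig <- tryCatch(eigen(grm, symmetric = TRUE),
                    error = function(e) stop("GRM eigendecomposition failed: ",
                                             conditionMessage(e)))
    lam <- pmax(eig$values, 0)
    Ut <- t(eig$vectors)
    yr <- as.vector(Ut %*% y)
    Xr <- Ut %*% X0
    opt <- stats::optimize(reml_criterion, interval = c(-10, 10),
                           lam = lam, yr = yr, Xr = Xr, maximum = TRUE)
    w <- sqrt(1 / (lam + exp(opt$maximum)))
    y <- yr * w
    X0 <- Xr * w
    G <- (Ut %*% G) * w
  }
  p_cov <- ncol(X0)
  df <- n - p_cov - 1L
  if (df < 1L) stop("not enough residual degrees of freedom")
  qx <- qr.Q(qr(X0))
  y_r <- y - qx %*% crossprod(qx, y)
  G_r <- G - qx %*% crossprod(qx, G)
  sg2 <- colSums(G_r^2)
  scale0 <- colSums(G^2) + 1e-12
  testable <- sg2 > 1e-10 * scale0
  beta <- se <- p <- neglogp <- rep(NA_real_, ncol(G))
  gy <- crossprod(G_r, y_r)[, 1]
  beta[testable] <- gy[testable] / sg2[testable]
  rss <- pmax(sum(y_r^2) - beta^2 * sg2, 0)
  sigma2 <- rss / df
  se[testable] <- sqrt(sigma2[testable] / sg2[testable])
  tt <- beta / se
  logp <- log(2) + stats::pt(-abs(tt), df, log.p = TRUE)
  p[testable] <- exp(logp[testable])
  neglogp[testable] <- -logp[testable] / log(10)
  flag <- rep("", ncol(G))
  flag[!testable] <- "collinear"
  if (length(cov_idx) > 0L) flag[cov_idx] <- "covariate"
  drop <- flag != ""
  beta[drop] <- NA_real_; se[drop] <- NA_real_
  p[drop] <- 1; neglogp[drop] <- 0
  out <- data.frame(chrom = geno$variants$chrom,
                    pos = geno$variants$pos,
                    id = geno$variants$id,
                    a1 = geno$variants$ref,
                    a2 = geno$variants$alt,
                    maf = variant_maf(geno),
                    n_used = n,
                    beta = beta, se = se, p = p, neglogp = neglogp,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}
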