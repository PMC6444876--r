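#' Specify a QTL to plant in the simulated trait
#'
#' @param chrom Chromosome name (must match a simulated chromosome).
#' @param pos Position in bp; the simulator places a variant exactly here.
#' @param effect Allele-substitution effect, in phenotypic standard
#'   deviations per unit of the standardized dosage. An effect of 0.5
#'   contributes 25% of the phenotypic variance.
#' @param maf Optional target minor allele frequency of the causal site;
#'   defaults to a draw from the configured MAF range.
#' @param causal_gene_id Optional identifier used to label the gene placed
#'   over this QTL by [simulate_gene_models()].
#' @return A `planted_qtl` list.
#' @export
planted_qtl <- function(chrom, pos, effect, maf = NULL, causal_gene_id = NULL) {
  if (!(is.numeric(pos) && length(pos) == 1L && pos >= 1))
    stop_config("pos", "must be a positive position in bp")
  if (!is.null(maf) && !(maf > 0 && maf <= 0.5))
    stop_config("maf", "must be in (0, 0.5]")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 effect = as.numeric(effect), maf = maf,
                 causal_gene_id = causal_gene_id),
            class = "planted_qtl")
}

#' Configure the genotype/phenotype simulator
#'
#' The simulator emulates the shape of an imputed-sequence GWAS dataset on
#' progeny-tested bulls: diploid dosages in `[0, 2]` with linkage
#' disequilibrium that decays with physical distance, a minor-allele
#' frequency spectrum bounded below (0.5% by default, matching the usual QC
#' floor), and a continuous polygenic trait with a handful of planted QTL
#' on top of a polygenic background and Gaussian noise.
#'
#' LD is produced by a first-order autoregressive haplotype construction:
#' each of the two haplotypes per individual carries a latent standard
#' Gaussian process whose correlation between adjacent sites is
#' `exp(-d / ld_decay_bp)` (`d` = inter-site distance), and the allele at a
#' site is the indicator that the latent value falls below the site's
#' allele-frequency quantile. Marginal allele frequencies therefore hit
#' their targets exactly in expectation (sample frequencies are binomial
#' around them over 2n haplotypes) and dosage correlation decays
#' monotonically with physical distance at scale `ld_decay_bp`.
#'
#' @param n_individuals Number of diploid individuals.
#' @param chromosomes Named numeric vector: chromosome lengths in bp.
#' @param n_variants_per_chrom Variants simulated per chromosome.
#' @param ld_decay_bp Length scale of LD decay in bp.
#' @param maf_range Two-element vector `[min, max]` of target minor allele
#'   frequencies, within (0, 0.5].
#' @param qtl List of [planted_qtl()] specifications.
#' @param h2_polygenic Fraction of phenotypic variance from the polygenic
#'   background; `h2_polygenic + sum(effect^2)` must not exceed 1.
#' @param seed Integer RNG seed; every generator derives its stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals,
                       chromosomes = c("1" = 2e7),
                       n_variants_per_chrom = 1000,
                       ld_decay_bp = 50000,
                       maf_range = c(0.005, 0.5),
                       qtl = list(),
                       h2_polygenic = 0.3,
                       seed = 1L) {
  if (!(is.numeric(n_individuals) && n_individuals >= 2))
    stop_config("n_individuals", "must be >= 2")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop_config("chromosomes", "must be a named vector of lengths in bp")
  if (any(chromosomes < 1000)) stop_config("chromosomes", "lengths must be >= 1000 bp")
  if (!(is.numeric(n_variants_per_chrom) && n_variants_per_chrom >= 2))
    stop_config("n_variants_per_chrom", "must be >= 2")
  if (!(ld_decay_bp > 0)) stop_config("ld_decay_bp", "must be positive")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range", "must be [min, max] within (0, 0.5]")
  if (inherits(qtl, "planted_qtl")) qtl <- list(qtl)
  for (q in qtl) {
    if (!inherits(q, "planted_qtl")) stop_config("qtl", "entries must be planted_qtl objects")
    if (!q$chrom %in% names(chromosomes))
      stop_config("qtl", sprintf("chromosome '%s' not simulated", q$chrom))
    if (q$pos > chromosomes[[q$chrom]])
      stop_config("qtl", sprintf("position %d beyond chromosome '%s'", q$pos, q$chrom))
  }
  qvar <- sum(vapply(qtl, function(q) q$effect^2, 0))
  if (!(h2_polygenic >= 0 && h2_polygenic + qvar <= 1))
    stop_config("h2_polygenic", "h2_polygenic + summed QTL variance must be <= 1")
  structure(list(n_individuals = as.integer(n_individuals),
                 chromosomes = chromosomes,
                 n_variants_per_chrom = as.integer(n_variants_per_chrom),
                 ld_decay_bp = as.numeric(ld_decay_bp),
                 maf_range = as.numeric(maf_range),
                 qtl = qtl,
                 h2_polygenic = as.numeric(h2_polygenic),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype dosage matrix with distance-decaying LD
#'
#' See [sim_config()] for the autoregressive haplotype model. A variant is
#' placed exactly at every planted-QTL position (replacing the nearest
#' simulated site) and, when the QTL specifies a `maf`, the causal site is
#' simulated at that frequency.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()]; reproducible given `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  nh <- 2L * n
  blocks <- list()
  vmeta <- list()
  bases <- c("A", "C", "G", "T")
  for (chrom in names(config$chromosomes)) {
    len <- config$chromosomes[[chrom]]
    m <- config$n_variants_per_chrom
    pos <- sort(sample.int(len, m))
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    for (q in config$qtl) {
      if (q$chrom != chrom) next
      j <- which.min(abs(pos - q$pos))
      pos[j] <- q$pos
      if (!is.null(q$maf)) p[j] <- q$maf
    }
    ord <- order(pos)
    pos <- pos[ord]; p <- p[ord]
    if (anyDuplicated(pos)) {
      keep <- !duplicated(pos)
      pos <- pos[keep]; p <- p[keep]; m <- length(pos)
    }
    # latent AR(1) per haplotype, thresholded at the allele-freq quantile
    rho <- exp(-diff(pos) / config$ld_decay_bp)
    thresh <- stats::qnorm(p)
    z <- stats::rnorm(nh)
    alleles <- matrix(0L, nrow = nh, ncol = m)
    alleles[, 1] <- (z < thresh[1])
    for (j in seq_len(m - 1L)) {
      z <- rho[j] * z + sqrt(1 - rho[j]^2) * stats::rnorm(nh)
      alleles[, j + 1L] <- (z < thresh[j + 1L])
    }
    dos <- alleles[seq(1L, nh, 2L), , drop = FALSE] +
      alleles[seq(2L, nh, 2L), , drop = FALSE]
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    blocks[[chrom]] <- dos
    vmeta[[chrom]] <- data.frame(chrom = chrom, pos = pos,
                                 id = paste0(chrom, "_", pos),
                                 ref = ref, alt = alt,
                                 stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vmeta)
  rownames(variants) <- NULL
  dosages <- do.call(cbind, blocks)
  ids <- sprintf("ind_%04d", seq_len(n))
  genotype_matrix(dosages, variants, ids)
}

#' Simulate a continuous phenotype with planted QTL
#'
#' The trait is built as
#' `y = sum_k effect_k * z_k + g + e`, where `z_k` is the standardized
#' dosage at the k-th planted QTL, `g` is a polygenic term (a random-effect
#' sum over all non-causal polymorphic variants, rescaled to variance
#' `h2_polygenic`) and `e` is Gaussian noise with variance
#' `1 - h2_polygenic - sum(effect^2)`. With no QTL and `h2_polygenic = 0`
#' the trait is pure standard Gaussian noise.
#'
#' @param geno A [genotype_matrix()] containing every planted-QTL position.
#' @param config The [sim_config()] used to simulate `geno`.
#' @return A `phenotype_sim` list: `phenotype` (data frame `id`, `value`)
#'   and `truth` (data frame of planted effects and their variant ids).
#' @export
simulate_phenotype <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- n_individuals(geno)
  key <- paste(geno$variants$chrom, geno$variants$pos)
  qkey <- vapply(config$qtl, function(q) paste(q$chrom, q$pos), "")
  cols <- match(qkey, key)
  if (anyNA(cols)) {
    miss <- qkey[is.na(cols)]
    stop("planted QTL positions absent from genotypes: ",
         paste(miss, collapse = ", "))
  }
  effects <- vapply(config$qtl, function(q) q$effect, 0)
  y <- numeric(n)
  if (length(cols) > 0L) {
    Z <- scale(geno$dosages[, cols, drop = FALSE])
    if (any(!is.finite(Z))) stop("planted QTL site is monomorphic in the sample")
    y <- as.vector(Z %*% effects)
  }
  h2 <- config$h2_polygenic
  if (h2 > 0) {
    bg <- setdiff(seq_len(n_variants(geno)), cols)
    sds <- apply(geno$dosages[, bg, drop = FALSE], 2, stats::sd)
    bg <- bg[sds > 0]
    u <- stats::rnorm(length(bg))
    g <- as.vector(scale(geno$dosages[, bg, drop = FALSE],
                         scale = FALSE) %*% u)
    g <- g / stats::sd(g) * sqrt(h2)
    y <- y + g
  }
  ve <- 1 - h2 - sum(effects^2)
  y <- y + stats::rnorm(n, 0, sqrt(ve))
  truth <- data.frame(
    chrom = vapply(config$qtl, function(q) q$chrom, ""),
    pos = vapply(config$qtl, function(q) q$pos, 0L),
    id = geno$variants$id[cols],
    effect = effects,
    causal_gene_id = vapply(config$qtl,
                            function(q) q$causal_gene_id %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  structure(list(phenotype = data.frame(id = geno$individual_ids, value = y,
                                        stringsAsFactors = FALSE),
                 truth = truth),
            class = "phenotype_sim")
}

#' Simulate gene models tiling the simulated chromosomes
#'
#' Genes are placed uniformly at random with gamma-distributed lengths
#' around `mean_len`, distributed over chromosomes proportionally to their
#' length. When `cover_qtl` is `TRUE` (default) one gene is positioned to
#' contain each planted QTL so recovery of the causal gene can be tested;
#' that gene takes the QTL's `causal_gene_id` as its name when given.
#'
#' @param config A [sim_config()].
#' @param n_genes Total number of genes (>= 1).
#' @param mean_len Mean gene length in bp; must be smaller than every
#'   chromosome.
#' @param cover_qtl Place a gene over each planted QTL?
#' @return A data frame of class `gene_model_set` with columns `gene_id`,
#'   `name`, `chrom`, `start`, `end`, `strand` (1-based inclusive).
#' @export
simulate_gene_models <- function(config, n_genes, mean_len = 20000,
                                 cover_qtl = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!(n_genes >= 1)) stop_config("n_genes", "must be >= 1")
  if (mean_len >= min(config$chromosomes))
    stop("mean_len must be smaller than the shortest chromosome")
  set.seed(config$seed + 2L)
  lens <- config$chromosomes
  alloc <- pmax(round(n_genes * lens / sum(lens)), 1L)
  while (sum(alloc) > n_genes && any(alloc > 1L)) {
    i <- which.max(alloc); alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < n_genes) {
    i <- which.max(lens - alloc * mean_len); alloc[i] <- alloc[i] + 1L
  }
  rows <- list()
  for (chrom in names(lens)) {
    k <- alloc[[chrom]]
    if (k == 0L) next
    glen <- pmin(pmax(200L, round(stats::rgamma(k, shape = 4, rate = 4 / mean_len))),
                 lens[[chrom]] - 1L)
    start <- vapply(glen, function(l) sample.int(lens[[chrom]] - l, 1L), 0L)
    rows[[chrom]] <- data.frame(chrom = chrom, start = start,
                                end = start + glen - 1L,
                                stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  genes$name <- genes$gene_id
  if (cover_qtl) {
    for (i in seq_along(config$qtl)) {
      q <- config$qtl[[i]]
      len <- max(1000L, round(mean_len))
      start <- max(1L, q$pos - len %/% 2L)
      end <- min(config$chromosomes[[q$chrom]], start + len - 1L)
      j <- which(genes$chrom == q$chrom)[i]
      if (is.na(j)) j <- nrow(genes)  # overwrite somewhere if chrom exhausted
      genes$chrom[j] <- q$chrom
      genes$start[j] <- start
      genes$end[j] <- end
      if (!is.null(q$causal_gene_id)) {
        genes$gene_id[j] <- q$causal_gene_id
        genes$name[j] <- q$causal_gene_id
      }
    }
  }
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[order(genes$chrom, genes$start),
                 c("gene_id", "name", "chrom", "start", "end", "strand")]
  rownames(genes) <- NULL
  class(genes) <- c("gene_model_set", "data.frame")
  genes
}

fertility_go_labels <- c(
  "female pregnancy",
  "maternal process involved in female pregnancy",
  "embryo implantation",
  "oocyte maturation",
  "establishment of meiotic spindle localization")

background_labels <- c(
  "lipid metabolic process", "ion transport", "cilium assembly",
  "actin cytoskeleton organization", "tRNA processing")

#' Simulate an evidence catalog with planted supported genes
#'
#' Every planted gene receives a GO record with a fertility-related label
#' and differential-expression (DEG) records from two independent studies
#' with a common direction; KEGG and mouse-phenotype (MPD) records are
#' added with probability 1/2 each. Background genes receive records per
#' source independently at the false-positive rate, with generic labels and
#' random DEG directions.
#'
#' @param genes A `gene_model_set`.
#' @param planted Character vector of gene ids to support (subset of
#'   `genes$gene_id`).
#' @param config A [sim_config()] (provides the seed).
#' @param fp_rate Per-source probability that a background gene receives a
#'   spurious record.
#' @return A data frame of class `evidence_catalog` with columns `gene`,
#'   `source`, `label`, `direction`, `study`, `tissue`, `comparison`.
#' @export
simulate_evidence <- function(genes, planted, config, fp_rate = 0.05) {
  stopifnot(inherits(genes, "gene_model_set"))
  unknown <- setdiff(planted, genes$gene_id)
  if (length(unknown) > 0L)
    stop("unknown planted gene ids: ", paste(unknown, collapse = ", "))
  set.seed(config$seed + 3L)
  rec <- function(gene, source, label, direction = "", study = "",
                  tissue = "", comparison = "") {
    data.frame(gene = gene, source = source, label = label,
               direction = direction, study = study, tissue = tissue,
               comparison = comparison, stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in planted) {
    out[[length(out) + 1L]] <- rec(g, "GO", sample(fertility_go_labels, 1L))
    dirn <- sample(c("Up", "Down"), 1L)
    out[[length(out) + 1L]] <- rec(g, "DEG", "differential expression", dirn,
                                   "studyA", "endometrium",
                                   "pregnant vs non-pregnant")
    out[[length(out) + 1L]] <- rec(g, "DEG", "differential expression", dirn,
                                   "studyB", "uterine biopsies",
                                   "pregnant vs non-pregnant")
    if (stats::runif(1) < 0.5)
      out[[length(out) + 1L]] <- rec(g, "KEGG", "oocyte meiosis")
    if (stats::runif(1) < 0.5)
      out[[length(out) + 1L]] <- rec(g, "MPD", "female infertility")
  }
  for (g in setdiff(genes$gene_id, planted)) {
    for (src in c("GO", "KEGG", "MPD", "DEG")) {
      if (stats::runif(1) < fp_rate) {
        if (src == "DEG") {
          out[[length(out) + 1L]] <- rec(g, "DEG", "differential expression",
                                         sample(c("Up", "Down"), 1L),
                                         "studyC", "liver", "case vs control")
        } else {
          out[[length(out) + 1L]] <- rec(g, src, sample(background_labels, 1L))
        }
      }
    }
  }
  cat <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(gene = character(0), source = character(0),
               label = character(0), direction = character(0),
               study = character(0), tissue = character(0),
               comparison = character(0), stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  class(cat) <- c("evidence_catalog", "data.frame")
  cat
}

#' Simulate a complete study and write it to disk
#'
#' Convenience wrapper producing every input the pipeline consumes:
#' genotypes (VCF with DS), phenotype TSV, gene models (GFF3), an evidence
#' catalog TSV and a truth table TSV of the planted effects.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_genes Number of gene models to simulate.
#' @param fp_rate Evidence false-positive rate; see [simulate_evidence()].
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory objects.
#' @export
simulate_study <- function(config, out_dir, n_genes = 50, fp_rate = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotype(geno, config)
  genes <- simulate_gene_models(config, n_genes = n_genes)
  planted <- ph$truth$causal_gene_id[!is.na(ph$truth$causal_gene_id)]
  evidence <- simulate_evidence(genes, planted, config, fp_rate = fp_rate)
  paths <- list(
    genotypes = file.path(out_dir, "genotypes.vcf"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    genes = file.path(out_dir, "genes.gff3"),
    evidence = file.path(out_dir, "evidence.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_vcf_dosages(geno, paths$genotypes,
                    contig_lengths = config$chromosomes)
  write_tsv(ph$phenotype, paths$phenotype)
  write_gene_models_gff3(genes, paths$genes)
  write_tsv(as.data.frame(evidence), paths$evidence)
  write_tsv(ph$truth, paths$truth)
  invisible(c(paths, list(geno = geno, phenotype = ph, genes = genes,
                          evidence = evidence)))
}
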