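#' Is a significant SNP "solo" (isolated) within its window?
#'
#' A solo SNP is a significant SNP with no other significant SNP within
#' `thr$solo_window_bp` (1 Mb by default) on either side. Isolated signals
#' of this kind are treated as likely imputation or genotyping artifacts
#' and are never accepted as lead SNPs.
#'
#' @param variant A list or one-row data frame with `chrom` and `pos`
#'   (and optionally `id`, used to exclude the variant itself).
#' @param significant Data frame of the currently significant SNPs with
#'   columns `chrom`, `pos` and (optionally) `id`.
#' @param thr A [thresholds()] object.
#' @return `TRUE` if no other significant SNP lies within the window.
#' @export
is_solo_snp <- function(variant, significant, thr = thresholds()) {
  same <- significant$chrom == variant$chrom
  other <- same
  if (!is.null(variant$id) && "id" %in% names(significant)) {
    other <- other & significant$id != variant$id
  } else {
    other <- other & significant$pos != variant$pos
  }
  !any(abs(significant$pos[other] - variant$pos) <= thr$solo_window_bp)
}

#' Iterative conditional detection of lead SNPs on one chromosome
#'
#' Implements the conditional scan-and-condition loop: an unconditional
#' (round 1) scan defines the significant set; in each subsequent round the
#' scan is re-run with the dosages of all previously accepted leads as
#' covariates. A variant qualifies as the round's lead if it (a) exceeds
#' the genome-wide threshold in the current round, (b) exceeded it in round
#' 1, and (c) is not a solo SNP in the current round's significant set; the
#' qualifying variant with the largest -log10(P) wins (ties broken by
#' smaller position). The loop stops when no variant qualifies. Because
#' conditioned leads are untestable the lead set grows strictly, so the
#' loop terminates in at most as many rounds as round-1 significant SNPs.
#'
#' @param geno A [genotype_matrix()] (may span several chromosomes; the
#'   Bonferroni threshold defaults to its total variant count).
#' @param pheno Phenotype table or `phenotype_sim`.
#' @param thr A [thresholds()] object.
#' @param chrom Chromosome to analyse.
#' @param grm Optional GRM passed to [mlm_scan()].
#' @param round1 Optional precomputed unconditional `assoc_result` for this
#'   chromosome (saves a scan when already available).
#' @param n_tests Total number of SNP tests for the Bonferroni threshold;
#'   defaults to `thr$n_tests_snp`, then to `n_variants(geno)`.
#' @return A data frame of leads (`chrom`, `pos`, `id`, `beta`, `neglogp`,
#'   `iteration`), with attributes `rounds` (list of per-round
#'   `assoc_result`s; `rounds[[k]]` is the scan in which lead k was found),
#'   `threshold` (the -log10 P cutoff used) and `round1` (the unconditional
#'   scan).
#' @export
detect_leads <- function(geno, pheno, thr = thresholds(), chrom,
                         grm = NULL, round1 = NULL, n_tests = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!chrom %in% geno$variants$chrom)
    stop("chromosome not present in genotypes: ", chrom)
  cutoff <- bonferroni_neglogp_threshold(
    thr$alpha, n_tests %||% thr$n_tests_snp %||% n_variants(geno))
  gsub <- subset_genotypes(geno, chrom = chrom)
  r1 <- round1 %||% mlm_scan(gsub, pheno, grm = grm, thr = thr)
  sig1_ids <- r1$id[r1$neglogp >= cutoff & r1$flag == ""]
  leads <- list()
  rounds <- list()
  cur <- r1
  iter <- 1L
  max_iter <- length(sig1_ids)
  while (iter <= max(max_iter, 1L)) {
    sig_cur <- cur[cur$neglogp >= cutoff & cur$flag == "", , drop = FALSE]
    cand <- sig_cur[sig_cur$id %in% sig1_ids, , drop = FALSE]
    if (nrow(cand) > 0L) {
      solo <- vapply(seq_len(nrow(cand)), function(i)
        is_solo_snp(cand[i, ], sig_cur, thr), TRUE)
      cand <- cand[!solo, , drop = FALSE]
    }
    if (nrow(cand) == 0L) break
    best <- cand[order(-cand$neglogp, cand$pos)[1L], , drop = FALSE]
    rounds[[iter]] <- cur
    leads[[iter]] <- data.frame(chrom = best$chrom, pos = best$pos,
                                id = best$id, beta = best$beta,
                                neglogp = best$neglogp, iteration = iter,
                                stringsAsFactors = FALSE)
    iter <- iter + 1L
    cur <- mlm_scan(gsub, pheno,
                    covariate_snps = vapply(leads, function(l) l$id, ""),
                    grm = grm, thr = thr)
  }
  out <- if (length(leads) > 0L) do.call(rbind, leads) else
    data.frame(chrom = character(0), pos = integer(0), id = character(0),
               beta = numeric(0), neglogp = numeric(0),
               iteration = integer(0), stringsAsFactors = FALSE)
  attr(out, "rounds") <- rounds
  attr(out, "threshold") <- cutoff
  attr(out, "round1") <- r1
  out
}

#' Delineate the QTL interval around a lead SNP
#'
#' Scans outward from the lead on each side, through the association
#' results of the round in which the lead was discovered, up to
#' `thr$flank_bp` (1 Mb). The boundary on a side is the first SNP farther
#' than `thr$default_halfwidth_bp` (0.25 Mb) from the lead whose -log10(P)
#' lies more than `thr$drop_units` (3) below the lead's; if no SNP
#' qualifies within the flank, the boundary falls back to the lead
#' position plus/minus the default half-width. Half-widths therefore lie
#' in `[default_halfwidth_bp, flank_bp]`. Conditioned or collinear
#' (flagged) variants carry no measured signal in the round and are not
#' boundary candidates.
#'
#' @param lead A list or one-row data frame with `chrom`, `pos`, `id`,
#'   `neglogp`.
#' @param round_results The `assoc_result` of the lead's discovery round.
#' @param thr A [thresholds()] object.
#' @return Numeric `c(start, end)` in bp.
#' @export
delineate_interval <- function(lead, round_results, thr = thresholds()) {
  if (!lead$id %in% round_results$id)
    stop("lead SNP absent from the supplied round results: ", lead$id)
  rr <- round_results[round_results$chrom == lead$chrom &
                        round_results$flag == "", , drop = FALSE]
  side_boundary <- function(direction) {
    if (direction > 0) {
      cand <- rr[rr$pos > lead$pos & rr$pos - lead$pos <= thr$flank_bp, ,
                 drop = FALSE]
      cand <- cand[order(cand$pos), , drop = FALSE]
      dist <- cand$pos - lead$pos
    } else {
      cand <- rr[rr$pos < lead$pos & lead$pos - rr$pos <= thr$flank_bp, ,
                 drop = FALSE]
      cand <- cand[order(-cand$pos), , drop = FALSE]
      dist <- lead$pos - cand$pos
    }
    hit <- which(dist > thr$default_halfwidth_bp &
                   cand$neglogp < lead$neglogp - thr$drop_units)
    if (length(hit) > 0L) cand$pos[hit[1L]]
    else lead$pos + direction * thr$default_halfwidth_bp
  }
  c(side_boundary(-1), side_boundary(1))
}

#' Detect QTL genome-wide: leads plus delineated intervals
#'
#' Runs [detect_leads()] on every chromosome (or the ones requested) and
#' delineates each lead's interval from its discovery round. The number of
#' round-1 significant SNPs inside each interval is reported.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno Phenotype table or `phenotype_sim`.
#' @param thr A [thresholds()] object.
#' @param chroms Chromosomes to scan; default all in `geno`.
#' @param grm Optional GRM for the mixed-model scan.
#' @return A `qtl_table` data frame: `chrom`, `lead_pos`, `lead_id`,
#'   `effect`, `neglogp`, `interval_start`, `interval_end`, `iteration`,
#'   `n_significant_in_interval`; attribute `round1` holds the per-
#'   chromosome unconditional scans, `threshold` the cutoff used.
#' @export
detect_qtl <- function(geno, pheno, thr = thresholds(), chroms = NULL,
                       grm = NULL) {
  chroms <- chroms %||% unique(geno$variants$chrom)
  cutoff <- bonferroni_neglogp_threshold(
    thr$alpha, thr$n_tests_snp %||% n_variants(geno))
  rows <- list()
  round1 <- list()
  for (ch in chroms) {
    leads <- detect_leads(geno, pheno, thr, chrom = ch, grm = grm,
                          n_tests = thr$n_tests_snp %||% n_variants(geno))
    r1 <- attr(leads, "round1")
    round1[[ch]] <- r1
    rounds <- attr(leads, "rounds")
    if (nrow(leads) == 0L) next
    for (i in seq_len(nrow(leads))) {
      iv <- delineate_interval(leads[i, ], rounds[[i]], thr)
      nsig <- sum(r1$neglogp >= cutoff & r1$flag == "" &
                    r1$pos >= iv[1] & r1$pos <= iv[2])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = leads$chrom[i], lead_pos = leads$pos[i],
        lead_id = leads$id[i], effect = leads$beta[i],
        neglogp = leads$neglogp[i],
        interval_start = iv[1], interval_end = iv[2],
        iteration = leads$iteration[i],
        n_significant_in_interval = nsig,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chrom = character(0), lead_pos = integer(0),
               lead_id = character(0), effect = numeric(0),
               neglogp = numeric(0), interval_start = numeric(0),
               interval_end = numeric(0), iteration = integer(0),
               n_significant_in_interval = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "round1") <- round1
  attr(out, "threshold") <- cutoff
  class(out) <- c("qtl_table", "data.frame")
  out
}
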