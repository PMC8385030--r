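# Genotype quality control.
#
# Filter order is fixed: call rate (samples), call rate (SNPs), MAF, HWE,
# LD pruning, relatedness. Each filter returns the filtered data plus a
# report row; run_qc() chains them and reconciles counts. Missing calls are
# excluded pairwise in MAF, HWE and r-squared computations.

.qc_row <- function(step, removed_samples, removed_snps, threshold) {
  data.frame(step = step, removed_samples = removed_samples,
             removed_snps = removed_snps, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Call-rate filter
#'
#' Removes samples with call rate below `sample_min`, then SNPs with call
#' rate below `snp_min` (computed on the remaining samples).
#'
#' @param geno A [genotype_data].
#' @param sample_min,snp_min Minimum call-rate fractions in \\[0, 1\\].
#' @return List `geno` (filtered) and `report` (per-filter removal counts).
#' @export
filter_call_rate <- function(geno, sample_min = 0.98, snp_min = 0.98) {
  .assert(sample_min >= 0 && sample_min <= 1 && snp_min >= 0 && snp_min <= 1,
          "call-rate thresholds must lie in [0,1]", "rhmap_config")
  cr_sample <- rowMeans(!is.na(geno$calls))
  keep_s <- cr_sample >= sample_min
  .assert(any(keep_s), "call-rate filter removed every sample",
          "rhmap_empty")
  g1 <- subset_geno(geno, samples = which(keep_s))
  cr_snp <- colMeans(!is.na(g1$calls))
  keep_m <- cr_snp >= snp_min
  g2 <- subset_geno(g1, snps = which(keep_m))
  report <- rbind(
    .qc_row("call_rate_samples", sum(!keep_s), 0L, sample_min),
    .qc_row("call_rate_snps", 0L, sum(!keep_m), snp_min))
  list(geno = g2, report = report)
}

#' Minor-allele-frequency filter
#'
#' Keeps SNPs whose sample MAF (over non-missing calls) is at least
#' `maf_min`.
#'
#' @param geno A [genotype_data].
#' @param maf_min Minimum MAF in \\[0, 0.5\\].
#' @return List `geno` and `report`.
#' @export
filter_maf <- function(geno, maf_min = 0.01) {
  .assert(maf_min >= 0 && maf_min <= 0.5, "maf_min must lie in [0,0.5]",
          "rhmap_config")
  keep <- snp_maf(geno) >= maf_min
  list(geno = subset_geno(geno, snps = which(keep)),
       report = .qc_row("maf", 0L, sum(!keep), maf_min))
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided p-value for departure from Hardy-Weinberg proportions:
#' conditional on the observed allele counts, the probabilities of all
#' heterozygote counts no more probable than the observed one are summed.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (hom A1, het, hom A2).
#' @return p-value in (0, 1\\].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  .assert(n_hom1 >= 0 && n_het >= 0 && n_hom2 >= 0,
          "genotype counts must be non-negative", "rhmap_value")
  n <- n_hom1 + n_het + n_hom2
  .assert(n > 0, "Hardy-Weinberg test undefined for zero observations",
          "rhmap_undefined")
  nA <- 2 * n_hom1 + n_het       # A1 allele count
  nB <- 2 * n_hom2 + n_het
  # heterozygote counts with the same parity as nA, within feasibility
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  # log P(h | n, nA) = log[ n! / (nAA! h! nBB!) * 2^h * nA! nB! / (2n)! ]
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((nB - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg filter
#'
#' Removes SNPs whose exact HWE p-value (computed on all samples,
#' non-missing calls) falls below `p_min`.
#'
#' @param geno A [genotype_data].
#' @param p_min Minimum p-value (default `1e-6`).
#' @return List `geno` and `report`.
#' @export
filter_hwe <- function(geno, p_min = 1e-6) {
  pvals <- apply(geno$calls, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  keep <- pvals >= p_min
  list(geno = subset_geno(geno, snps = which(keep)),
       report = .qc_row("hwe", 0L, sum(!keep), p_min))
}

# Pairwise-complete genotype correlation squared for a call submatrix.
.r2_matrix <- function(calls) {
  suppressWarnings(cor(calls, use = "pairwise.complete.obs"))^2
}

#' Linkage-disequilibrium pruning
#'
#' Greedy windowed pruning: within each window of `window` SNPs, while any
#' retained pair has genotype correlation r-squared above `r2_max`, the
#' member of the worst pair with the lower MAF is removed (tie: the later
#' position). The window slides by `step` SNPs per chromosome, so no
#' retained within-window pair exceeds `r2_max`.
#'
#' @param geno A [genotype_data].
#' @param window Window size in SNPs (default 50).
#' @param step Window shift in SNPs (default 5).
#' @param r2_max Maximum allowed r-squared (default 0.8).
#' @return List `kept` (SNP ids), `geno` (pruned data) and `report`.
#' @export
ld_prune <- function(geno, window = 50L, step = 5L, r2_max = 0.8) {
  .assert(window >= 2 && step >= 1, "need window >= 2 and step >= 1",
          "rhmap_config")
  maf <- snp_maf(geno)
  keep <- rep(TRUE, ncol(geno$calls))
  for (chr in unique(geno$snps$chrom)) {
    idx <- which(geno$snps$chrom == chr)
    for (start in seq(1L, length(idx), by = step)) {
      win <- idx[start:min(start + window - 1L, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        r2 <- .r2_matrix(geno$calls[, act, drop = FALSE])
        r2[!upper.tri(r2)] <- NA
        worst <- suppressWarnings(max(r2, na.rm = TRUE))
        if (!is.finite(worst) || worst <= r2_max) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1, ]
        pair <- act[c(hit[["row"]], hit[["col"]])]
        drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
        else if (maf[pair[2]] < maf[pair[1]]) pair[2]
        else pair[which.max(geno$snps$pos[pair])]
        keep[drop] <- FALSE
      }
      if (start + window - 1L >= length(idx)) break
    }
  }
  list(kept = geno$snps$id[keep],
       geno = subset_geno(geno, snps = which(keep)),
       report = .qc_row("ld_prune", 0L, sum(!keep), r2_max))
}

#' Relatedness filter on GRM off-diagonals
#'
#' Iteratively removes one member of the pair with the largest off-diagonal
#' relatedness exceeding `threshold` (the member with the higher mean
#' relatedness to the remaining samples) until no pair exceeds it.
#'
#' @param grm A [grm] object.
#' @param threshold Maximum allowed off-diagonal relatedness (default 0.1).
#' @return List `kept` (sample iids) and `report`.
#' @export
filter_relatedness <- function(grm, threshold = 0.1) {
  A <- grm$mat
  n <- nrow(A)
  diag(A) <- NA
  alive <- rep(TRUE, n)
  removed <- 0L
  repeat {
    sub <- A[alive, alive, drop = FALSE]
    if (all(is.na(sub)) || max(sub, na.rm = TRUE) <= threshold) break
    hit <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair_local <- c(hit[["row"]], hit[["col"]])
    means <- rowMeans(sub[pair_local, , drop = FALSE], na.rm = TRUE)
    drop_local <- pair_local[which.max(means)]
    alive[which(alive)[drop_local]] <- FALSE
    removed <- removed + 1L
  }
  list(kept = grm$ids$iid[alive],
       report = .qc_row("relatedness", removed, 0L, threshold))
}

#' Run the full QC pipeline
#'
#' Applies, in fixed order: call rate (samples then SNPs), MAF, HWE exact
#' test, LD pruning, relatedness (on a GRM built from the LD-pruned data),
#' and a final screen for SNPs left monomorphic by the sample removals.
#' The report reconciles exactly with the dimension changes. The HWE test
#' uses all samples (cases and controls). Note the relatedness default
#' (0.1) presumes genome-scale SNP counts: null GRM off-diagonals have
#' standard deviation about `1/sqrt(N_snps)`, so with only a few hundred
#' SNPs unrelated pairs routinely exceed 0.1.
#'
#' @param geno A [genotype_data].
#' @param sample_min,snp_min,maf_min,hwe_min QC thresholds (defaults 0.98,
#'   0.98, 0.01, 1e-6).
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters (defaults 50, 5,
#'   0.8).
#' @param rel_max Relatedness threshold (default 0.1).
#' @return List `geno` (fully filtered), `report` (data frame of removal
#'   counts per step, in application order).
#' @export
run_qc <- function(geno, sample_min = 0.98, snp_min = 0.98, maf_min = 0.01,
                   hwe_min = 1e-6, ld_window = 50L, ld_step = 5L,
                   ld_r2 = 0.8, rel_max = 0.1) {
  s1 <- filter_call_rate(geno, sample_min, snp_min)
  s2 <- filter_maf(s1$geno, maf_min)
  s3 <- filter_hwe(s2$geno, hwe_min)
  s4 <- ld_prune(s3$geno, ld_window, ld_step, ld_r2)
  grm <- compute_grm(s4$geno)
  s5 <- filter_relatedness(grm, rel_max)
  keep_s <- match(s5$kept, s4$geno$samples$iid)
  out <- subset_geno(s4$geno, samples = keep_s)
  # sample removal can leave SNPs monomorphic in the retained cohort;
  # they would break GRM construction downstream, so screen them here
  poly <- snp_maf(out) > 0
  s6 <- list(report = .qc_row("monomorphic_after_relatedness", 0L,
                              sum(!poly), 0))
  out <- subset_geno(out, snps = which(poly))
  report <- rbind(s1$report, s2$report, s3$report, s4$report, s5$report,
                  s6$report)
  attr(report, "header") <- paste(
    "filter order: call_rate(samples) -> call_rate(snps) -> maf -> hwe",
    "-> ld_prune -> relatedness; HWE computed on all samples")
  list(geno = out, report = report)
}

#' Write a QC report as TSV
#'
#' @param report The report data frame from [run_qc].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- attr(report, "header")
  if (!is.null(hdr)) writeLines(paste0("# ", hdr), con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
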