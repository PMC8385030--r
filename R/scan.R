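# Regional heritability scan: overlapping windows of adjacent SNPs, one
# two-GRM mixed-model fit per window, boundary LRT against the null
# genome-wide model, Bonferroni thresholds over half the window count, and
# the observed-to-liability heritability transformation for ascertained
# case-control samples.

#' Build scan windows
#'
#' Per chromosome, windows of `size` adjacent SNPs start at offsets 0,
#' `shift`, 2 `shift`, ...; a window is emitted whenever its start index is
#' inside the chromosome, and the final window is clipped at the chromosome
#' end (so it may be shorter than `size`). Windows never span chromosomes.
#'
#' @param geno A [genotype_data].
#' @param size Window size in SNPs (default 50).
#' @param shift Window shift in SNPs (default 25, i.e. 50% overlap).
#' @return Data frame of class `window_spec`: `ordinal`, `chrom`, `start`,
#'   `end` (1-based global SNP indices, inclusive), `n_snps`, `pos_first`,
#'   `pos_last`, `clipped`.
#' @export
make_windows <- function(geno, size = 50L, shift = 25L) {
  .assert(size >= 2, "window size must be at least 2", "rhmap_config")
  .assert(shift >= 1 && shift <= size,
          "shift must satisfy 1 <= shift <= size", "rhmap_config")
  rows <- list()
  ordinal <- 0L
  for (chr in unique(geno$snps$chrom)) {
    idx <- which(geno$snps$chrom == chr)
    m <- length(idx)
    if (m == 0) next
    for (start0 in seq(0L, m - 1L, by = shift)) {
      ordinal <- ordinal + 1L
      end0 <- min(start0 + size, m)
      rows[[ordinal]] <- data.frame(
        ordinal = ordinal, chrom = chr,
        start = idx[start0 + 1L], end = idx[end0],
        n_snps = end0 - start0,
        pos_first = geno$snps$pos[idx[start0 + 1L]],
        pos_last = geno$snps$pos[idx[end0]],
        clipped = (end0 - start0) < size)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("window_spec", "data.frame")
  out
}

#' Regional heritability scan
#'
#' For every window: build the regional GRM from exactly the window's SNPs,
#' fit the alternative model (whole-genome GRM + regional GRM + residual)
#' by AI-REML starting from the null-fit estimates (regional component at
#' 10x the floor), and test the regional variance with the boundary LRT.
#' Windows with non-converged fits, degenerate (monomorphic) SNP sets, or
#' extreme estimates (any component beyond `extreme_mult` times the
#' phenotypic variance) are flagged excluded with a reason code and do not
#' count toward the number of tested regions.
#'
#' @param geno A [genotype_data] (QC'd; every SNP polymorphic).
#' @param phenocov Data frame with `PHENO` (0/1) plus the fixed-effect
#'   covariate columns (`SEX`, `ARRAY`, `PC1`...) in `geno`'s sample order.
#' @param grm The whole-genome [grm] (all SNPs).
#' @param windows Window table from [make_windows].
#' @param null_fit Optional null-model `variance_estimate`; fitted here
#'   when omitted. The null model is fitted once per dataset, not per
#'   window.
#' @param prevalence Population prevalence K used for the liability-scale
#'   transformation of regional heritability.
#' @param extreme_mult Exclusion multiplier for extreme estimates
#'   (default 10).
#' @param verbose Print a progress line every 25 windows.
#' @return List `records` (data frame of class `scan_record`, one row per
#'   window: location, variance components, LRT, mixture p, regional
#'   heritability on the observed and liability scales with delta-method
#'   SEs, exclusion flags) and `null_fit`.
#' @export
rhm_scan <- function(geno, phenocov, grm, windows, null_fit = NULL,
                     prevalence = 0.00042, extreme_mult = 10,
                     verbose = FALSE) {
  y <- phenocov$PHENO
  .assert(all(y %in% 0:1), "PHENO must be 0/1", "rhmap_value")
  X <- .design_matrix(phenocov)
  G <- grm$mat
  if (is.null(null_fit)) {
    null_fit <- fit_reml(model_spec(y, X, list(G = G)))
  }
  .assert(isTRUE(null_fit$converged), "null model fit did not converge",
          "rhmap_numeric")
  varP <- var(y)
  P_case <- mean(y)
  lp <- liability_params(prevalence, P_case)
  floor_v <- 1e-6 * varP
  start <- c(null_fit$components["sigma2_G"], 10 * floor_v,
             null_fit$components["sigma2_e"])

  rec <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    res <- tryCatch({
      Q <- compute_grm(geno, snp_subset = win$start:win$end)
      spec <- model_spec(y, X, list(G = G, Q = Q$mat))
      fit <- fit_reml(spec, start = start)
      lrt <- lrt_regional(null_fit, fit)
      vr <- variance_ratio(fit, "sigma2_Q")
      excl <- NA_character_
      if (!fit$converged) excl <- "convergence"
      else if (any(abs(fit$components) > extreme_mult * varP))
        excl <- "extreme-value"
      data.frame(sigma2_u = unname(fit$components["sigma2_G"]),
                 sigma2_w = unname(fit$components["sigma2_Q"]),
                 sigma2_e = unname(fit$components["sigma2_e"]),
                 lrt = lrt$lrt, p = lrt$p,
                 h2_obs = vr$ratio, h2_obs_se = vr$se,
                 h2_liab = observed_to_liability(vr$ratio, lp),
                 h2_liab_se = observed_to_liability(vr$se, lp),
                 excluded = !is.na(excl), reason = excl,
                 optimizer_failure = lrt$optimizer_failure)
    }, rhmap_error = function(e) {
      data.frame(sigma2_u = NA_real_, sigma2_w = NA_real_,
                 sigma2_e = NA_real_, lrt = NA_real_, p = NA_real_,
                 h2_obs = NA_real_, h2_obs_se = NA_real_,
                 h2_liab = NA_real_, h2_liab_se = NA_real_,
                 excluded = TRUE, reason = "degenerate",
                 optimizer_failure = FALSE)
    })
    rec[[w]] <- cbind(win, res)
    if (verbose && w %% 25 == 0)
      message(sprintf("  window %d/%d", w, nrow(windows)))
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  class(records) <- c("scan_record", "data.frame")
  attr(records, "liability_params") <- lp
  list(records = records, null_fit = null_fit)
}

# Fixed-effects design from a phenotype/covariate table: intercept plus
# every non-identifier, non-phenotype column.
.design_matrix <- function(phenocov) {
  drop <- c("FID", "IID", "PHENO")
  covs <- phenocov[, setdiff(names(phenocov), drop), drop = FALSE]
  X <- cbind(intercept = 1, as.matrix(covs))
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(c) sd(c) > 0))
  X[, keep, drop = FALSE]
}

#' Bonferroni scan thresholds
#'
#' With M tested (non-excluded) regions, half the window count is used as
#' the effective number of tests because consecutive windows overlap by
#' 50%: p threshold = alpha / (M/2). The matching LRT threshold solves
#' 0.5 * P(chi2_1 > x) = p threshold.
#'
#' @param M Number of tested regions (>= 2).
#' @param alpha Family-wise significance level in (0, 1).
#' @return An object of class `threshold_spec`: `alpha`, `M`,
#'   `effective_tests`, `p_threshold`, `lrt_threshold`.
#' @export
scan_thresholds <- function(M, alpha = 0.05) {
  .assert(alpha > 0 && alpha < 1, "alpha must lie in (0,1)", "rhmap_config")
  .assert(M >= 2, "need at least two regions", "rhmap_config")
  p_thr <- alpha / (M / 2)
  lrt_thr <- qchisq(min(1, 2 * p_thr), df = 1, lower.tail = FALSE)
  structure(list(alpha = alpha, M = M, effective_tests = M / 2,
                 p_threshold = p_thr, lrt_threshold = lrt_thr),
            class = "threshold_spec")
}

#' Liability-scale parameters
#'
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1).
#' @return An object of class `liability_params`: `K`, `P`, threshold
#'   `t = qnorm(1 - K)` and `z = dnorm(t)`.
#' @export
liability_params <- function(K, P) {
  .assert(K > 0 && K < 1, "prevalence K must lie in (0,1)", "rhmap_config")
  .assert(P > 0 && P < 1, "case proportion P must lie in (0,1)",
          "rhmap_config")
  t <- qnorm(1 - K)
  structure(list(K = K, P = P, t = t, z = dnorm(t)),
            class = "liability_params")
}

#' Observed-scale to liability-scale heritability
#'
#' Ascertainment-corrected transformation for case-control GREML:
#' h2_liab = h2_obs * K^2 (1-K)^2 / (z^2 P (1-P)), where z is the standard
#' normal density at the liability threshold. Standard errors scale by the
#' same factor.
#'
#' @param h2_obs Observed-scale heritability (or its SE), >= 0.
#' @param lp A [liability_params].
#' @return The liability-scale value.
#' @export
observed_to_liability <- function(h2_obs, lp) {
  .assert(all(is.na(h2_obs) | h2_obs >= 0), "h2_obs must be non-negative",
          "rhmap_value")
  factor <- lp$K^2 * (1 - lp$K)^2 / (lp$z^2 * lp$P * (1 - lp$P))
  h2_obs * factor
}

#' Merge significant windows into regions
#'
#' Windows at or above the LRT threshold that share at least one SNP
#' (overlapping index ranges on the same chromosome) are merged into one
#' region spanning min(first) to max(last) positions, reported with the
#' min/max LRT, min/max liability-scale regional heritability and the mean
#' SE of its windows.
#'
#' @param records Scan records from [rhm_scan].
#' @param thresholds A `threshold_spec` from [scan_thresholds].
#' @return Data frame, one row per merged region (empty with header when
#'   nothing is significant).
#' @export
significant_regions <- function(records, thresholds) {
  sig <- records[!records$excluded & !is.na(records$lrt) &
                   records$lrt >= thresholds$lrt_threshold, , drop = FALSE]
  empty <- data.frame(window_first = integer(), window_last = integer(),
                      chrom = integer(), pos_first = numeric(),
                      pos_last = numeric(), min_lrt = numeric(),
                      max_lrt = numeric(), min_reg_h2 = numeric(),
                      max_reg_h2 = numeric(), average_se = numeric())
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  groups <- list()
  cur <- sig[1, , drop = FALSE]
  for (i in seq_len(nrow(sig))[-1]) {
    row <- sig[i, , drop = FALSE]
    if (row$chrom == cur$chrom[nrow(cur)] &&
          row$start <= max(cur$end)) {
      cur <- rbind(cur, row)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- row
    }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(g) {
    data.frame(window_first = min(g$ordinal), window_last = max(g$ordinal),
               chrom = g$chrom[1], pos_first = min(g$pos_first),
               pos_last = max(g$pos_last), min_lrt = min(g$lrt),
               max_lrt = max(g$lrt), min_reg_h2 = min(g$h2_liab),
               max_reg_h2 = max(g$h2_liab),
               average_se = mean(g$h2_liab_se))
  }))
}

#' QQ-plot data for the scan
#'
#' Expected quantiles of the 50-50 chi-square(0):chi-square(1) mixture
#' against the ordered observed LRTs of non-excluded windows.
#'
#' @param records Scan records from [rhm_scan].
#' @return Data frame `expected`, `observed` (both LRT-scale), sorted
#'   ascending.
#' @export
scan_qq_data <- function(records) {
  obs <- sort(records$lrt[!records$excluded & !is.na(records$lrt)])
  M <- length(obs)
  u <- (seq_len(M)) / (M + 1)
  expected <- numeric(M)
  pos <- u > 0.5
  expected[pos] <- qchisq(2 * u[pos] - 1, df = 1)
  data.frame(expected = expected, observed = obs)
}

#' Write scan outputs
#'
#' Writes the full per-window record table, the merged significant-region
#' table, and QQ-plot data as TSVs.
#'
#' @param records Scan records from [rhm_scan].
#' @param thresholds A `threshold_spec`.
#' @param prefix Output path prefix (`_scan.tsv`, `_regions.tsv`,
#'   `_qq.tsv` appended).
#' @param gwas Optional association table from [gwas_logistic]; when given,
#'   Miami-plot data (`_miami.tsv`: RHM LRT on top, GWAS -log10 p below)
#'   are written too.
#' @return Named vector of the paths written, invisibly.
#' @export
report_scan <- function(records, thresholds, prefix, gwas = NULL) {
  paths <- c(scan = paste0(prefix, "_scan.tsv"),
             regions = paste0(prefix, "_regions.tsv"),
             qq = paste0(prefix, "_qq.tsv"))
  write.table(records, paths["scan"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(significant_regions(records, thresholds), paths["regions"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scan_qq_data(records), paths["qq"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(gwas)) {
    paths <- c(paths, miami = paste0(prefix, "_miami.tsv"))
    rhm_part <- data.frame(panel = "rhm", chrom = records$chrom,
                           pos = (records$pos_first + records$pos_last) / 2,
                           value = records$lrt)
    gwas_part <- data.frame(panel = "gwas", chrom = gwas$chr,
                            pos = gwas$bp, value = -log10(gwas$p))
    write.table(rbind(rhm_part, gwas_part), paths["miami"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read back a scan record TSV
#'
#' @param path Path written by [report_scan].
#' @return The scan record data frame.
#' @export
read_scan_records <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_record", "data.frame")
  out
}
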