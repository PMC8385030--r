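# Companion single-SNP association scan: additive logistic regression with
# covariate adjustment, Wald confidence intervals, Bonferroni adjustment,
# replication of discovery hits, and the genomic inflation factor.

#' Single-SNP logistic-regression GWAS
#'
#' Per SNP, the additive count of the effect allele (the sample minor
#' allele) enters a logistic model for case status alongside the
#' covariates; the model is maximized by iteratively reweighted least
#' squares (via `stats::glm.fit`, convergence tolerance `1e-10`, at most
#' 50 iterations). Missing genotypes are dropped per SNP (complete-case).
#' Monomorphic SNPs, separation and non-convergence are flagged and the
#' p-value set missing.
#'
#' @param geno A [genotype_data].
#' @param phenocov Data frame with `PHENO` (0/1) and covariate columns, in
#'   `geno`'s sample order.
#' @param covariates Character vector of covariate column names (default:
#'   every column except FID/IID/PHENO).
#' @return Data frame of class `assoc_record`, one row per SNP: `snp`,
#'   `chr`, `bp`, `ea` (effect allele), `beta` (log-odds per effect-allele
#'   copy), `se`, `or`, `z`, `p`, `n_used`, `flag`.
#' @export
gwas_logistic <- function(geno, phenocov, covariates = NULL) {
  y <- phenocov$PHENO
  .assert(all(y %in% 0:1), "PHENO must be 0/1", "rhmap_value")
  if (is.null(covariates))
    covariates <- setdiff(names(phenocov), c("FID", "IID", "PHENO"))
  C <- cbind(intercept = 1,
             as.matrix(phenocov[, covariates, drop = FALSE]))
  .assert(qr(C)$rank == ncol(C), "covariate matrix is rank deficient",
          "rhmap_rank")
  m <- ncol(geno$calls)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    g <- geno$calls[, j]
    keep <- !is.na(g)
    gk <- g[keep]
    p1 <- mean(gk) / 2                     # A1 frequency
    if (p1 <= 0.5) {
      ea <- geno$snps$a1[j]
      dose <- gk
    } else {
      ea <- geno$snps$a2[j]
      dose <- 2 - gk
    }
    rec <- data.frame(snp = geno$snps$id[j], chr = geno$snps$chrom[j],
                      bp = geno$snps$pos[j], ea = ea, beta = NA_real_,
                      se = NA_real_, or = NA_real_, z = NA_real_,
                      p = NA_real_, n_used = sum(keep), flag = "")
    if (sd(dose) == 0) {
      rec$flag <- "degenerate"
      out[[j]] <- rec
      next
    }
    Xj <- cbind(C[keep, , drop = FALSE], dose = dose)
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      tryCatch(glm.fit(Xj, y[keep], family = binomial(),
                       control = list(epsilon = 1e-10, maxit = 50)),
               error = function(e) NULL),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit) || !fit$converged || sep_warn) {
      rec$flag <- if (sep_warn) "separation" else "nonconverged"
      out[[j]] <- rec
      next
    }
    # Wald SE from the inverse Fisher information at the optimum
    W <- fit$weights
    info <- crossprod(Xj * sqrt(W))
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) {
      rec$flag <- "singular"
      out[[j]] <- rec
      next
    }
    b <- fit$coefficients[["dose"]]
    se <- sqrt(cov["dose", "dose"])
    rec$beta <- b
    rec$se <- se
    rec$or <- exp(b)
    rec$z <- b / se
    rec$p <- 2 * pnorm(abs(b / se), lower.tail = FALSE)
    out[[j]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("assoc_record", "data.frame")
  res
}

#' Wald confidence interval for an odds ratio
#'
#' `exp(ln OR +/- z * SE)` with the two-sided normal quantile for the given
#' level (1.959964 at 95%).
#'
#' @param or_value Odds ratio (> 0).
#' @param se_log Standard error of the log odds ratio (> 0).
#' @param level Confidence level (default 0.95).
#' @return Named vector `lower`, `upper`.
#' @export
wald_ci <- function(or_value, se_log, level = 0.95) {
  .assert(all(or_value > 0) && all(se_log > 0),
          "need positive OR and SE", "rhmap_value")
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = exp(log(or_value) - z * se_log),
    upper = exp(log(or_value) + z * se_log))
}

#' Bonferroni adjustment
#'
#' @param p P-value(s) in (0, 1\\].
#' @param n_tests Number of tests (>= 1).
#' @return `min(1, p * n_tests)`, elementwise.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  .assert(n_tests >= 1, "n_tests must be at least 1", "rhmap_value")
  .assert(all(p > 0 & p <= 1), "p must lie in (0,1]", "rhmap_value")
  pmin(1, p * n_tests)
}

#' Genomic inflation factor
#'
#' Converts each p-value to a chi-square(1) quantile via the survival
#' inverse and divides the median by the chi-square(1) median (0.4549364).
#'
#' @param p_values Vector of p-values; NAs are dropped.
#' @return Lambda.
#' @export
inflation_factor <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  .assert(length(p) >= 1, "no valid p-values", "rhmap_undefined")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Replicate discovery hits in an independent panel
#'
#' Runs the covariate-adjusted logistic GWAS restricted to the discovery
#' hits, adds the Wald confidence interval and the Bonferroni adjustment
#' over the number of hits tested. Hits absent from the replication data
#' are recorded as untested.
#'
#' @param hits Character vector of discovery SNP ids.
#' @param geno,phenocov Replication panel ([genotype_data] and its
#'   phenotype/covariate table).
#' @param covariates Covariate columns (see [gwas_logistic]).
#' @param level Confidence level for the interval (default 0.95).
#' @return Data frame of class `replication_record`: the association
#'   columns plus `l95`, `u95`, `adj_p`, and `tested`.
#' @export
replicate_hits <- function(hits, geno, phenocov, covariates = NULL,
                           level = 0.95) {
  present <- hits[hits %in% geno$snps$id]
  absent <- setdiff(hits, present)
  res <- NULL
  if (length(present)) {
    sub <- subset_geno(geno, snps = match(present, geno$snps$id))
    res <- gwas_logistic(sub, phenocov, covariates)
    ok <- !is.na(res$p)
    ci <- t(vapply(seq_len(nrow(res)), function(i) {
      if (ok[i]) wald_ci(res$or[i], res$se[i], level)
      else c(lower = NA_real_, upper = NA_real_)
    }, c(lower = 0, upper = 0)))
    res$l95 <- ci[, "lower"]
    res$u95 <- ci[, "upper"]
    res$adj_p <- NA_real_
    res$adj_p[ok] <- bonferroni_adjust(res$p[ok], length(hits))
    res$tested <- TRUE
  }
  if (length(absent)) {
    miss <- data.frame(snp = absent, chr = NA, bp = NA, ea = NA,
                       beta = NA_real_, se = NA_real_, or = NA_real_,
                       z = NA_real_, p = NA_real_, n_used = 0L,
                       flag = "absent", l95 = NA_real_, u95 = NA_real_,
                       adj_p = NA_real_, tested = FALSE)
    res <- rbind(res, miss)
  }
  class(res) <- c("replication_record", "data.frame")
  res
}

#' Write an association table as TSV
#'
#' Columns follow the SNP, CHR, BP, EA, OR, SE, L95, U95, P, ADJ_P, FLAGS
#' layout (interval/adjustment columns included when present).
#'
#' @param assoc An `assoc_record` or `replication_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(assoc, path) {
  cols <- c(SNP = "snp", CHR = "chr", BP = "bp", EA = "ea", OR = "or",
            SE = "se", L95 = "l95", U95 = "u95", P = "p", ADJ_P = "adj_p",
            FLAGS = "flag")
  cols <- cols[cols %in% names(assoc)]
  out <- assoc[, cols, drop = FALSE]
  names(out) <- names(cols)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
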