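# Liability-threshold case-control cohort simulator.
#
# Genotypes come from a founder-haplotype pool: within each LD block every
# individual draws two founder haplotypes at random (with replacement), so
# SNPs within a block are in LD while blocks recombine freely. Disease
# liability is a sum of standardized-genotype effects (a genome-wide
# polygenic component plus designated causal regions), covariate shifts and
# a normal residual, scaled so the liability-scale variance components sum
# to one. Cases are individuals whose liability exceeds the threshold
# t = qnorm(1 - K); batches of individuals are drawn until the requested
# numbers of cases and controls accrue (case oversampling / ascertainment).

#' Simulation configuration
#'
#' @param n_cases,n_controls Cohort sizes after ascertainment.
#' @param n_snps_per_chrom Integer vector, SNPs on each chromosome.
#' @param maf_range Length-2 vector in (0, 0.5]; per-SNP founder minor
#'   allele frequencies are drawn uniformly from this range.
#' @param ld_block_size SNPs per LD block (1 = all SNPs independent).
#' @param n_founder_haplotypes Size of the founder haplotype pool; smaller
#'   pools give stronger within-block LD.
#' @param prevalence Population prevalence K of the disease in (0, 1).
#' @param polygenic_variance Liability-scale variance fraction of the
#'   genome-wide polygenic component, in \\[0, 1).
#' @param regional_specs List of causal regions; each element is a list or
#'   vector with fields `chrom`, `start` (1-based SNP index within the
#'   chromosome), `n_qtls`, and `variance` (liability-scale fraction). QTLs
#'   are spread evenly over a `window_span`-SNP stretch from `start`.
#' @param covariate_effects Named numeric, liability shifts for the binary
#'   `sex` and `array` covariates (default 0: adjusted for, not confounded).
#' @param window_span SNP span of each causal region (matches the scan's
#'   window size; default 50).
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts byte for byte.
#' @param max_batches Ascertainment attempt cap: at most this many batches
#'   of `n_cases + n_controls` individuals are drawn before an accrual
#'   error is raised.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases, n_controls, n_snps_per_chrom,
                       maf_range = c(0.05, 0.5), ld_block_size = 1L,
                       n_founder_haplotypes = 200L, prevalence = 0.5,
                       polygenic_variance = 0, regional_specs = list(),
                       covariate_effects = c(sex = 0, array = 0),
                       window_span = 50L, seed = 1L, max_batches = 100L) {
  .assert(n_cases + n_controls >= 1, "cohort must contain individuals",
          "rhmap_config")
  .assert(length(n_snps_per_chrom) >= 1 && all(n_snps_per_chrom >= 1),
          "at least one SNP per chromosome required", "rhmap_config")
  .assert(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] <= maf_range[2],
          "maf_range must lie within (0, 0.5]", "rhmap_config")
  .assert(prevalence > 0 && prevalence < 1, "prevalence must be in (0,1)",
          "rhmap_config")
  .assert(ld_block_size >= 1 && n_founder_haplotypes >= 2,
          "need block size >= 1 and at least 2 founder haplotypes",
          "rhmap_config")
  regional_specs <- lapply(regional_specs, function(r) {
    r <- as.list(r)
    .assert(all(c("chrom", "start", "n_qtls", "variance") %in% names(r)),
            "regional spec needs chrom, start, n_qtls, variance",
            "rhmap_config")
    .assert(r$n_qtls >= 1 && r$n_qtls <= window_span,
            "n_qtls must be between 1 and the window span", "rhmap_config")
    .assert(r$chrom >= 1 && r$chrom <= length(n_snps_per_chrom) &&
              r$start >= 1 && r$start <= n_snps_per_chrom[r$chrom],
            "regional spec outside the simulated genome", "rhmap_config")
    r
  })
  reg_var <- sum(vapply(regional_specs, function(r) r$variance, 0))
  .assert(polygenic_variance >= 0 && reg_var >= 0 &&
            polygenic_variance + reg_var < 1,
          "liability variance fractions must sum to less than 1",
          "rhmap_config")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size),
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 prevalence = prevalence,
                 polygenic_variance = polygenic_variance,
                 regional_specs = regional_specs,
                 covariate_effects = covariate_effects,
                 window_span = as.integer(window_span),
                 seed = as.integer(seed),
                 max_batches = as.integer(max_batches)),
            class = "sim_config")
}

# Deterministic sub-seeds below 2^31 derived from the config seed.
.sub_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 69621) %% 2147483587
}

# Founder haplotype pool: per chromosome a list of 0/1 matrices
# (n_founder_haplotypes x block length), every site polymorphic among
# founders. Regenerated identically from the config seed whenever needed.
.founder_pool <- function(config) {
  set.seed(.sub_seed(config$seed, 1))
  nf <- config$n_founder_haplotypes
  lapply(config$n_snps_per_chrom, function(m) {
    starts <- seq(1L, m, by = config$ld_block_size)
    lapply(starts, function(s) {
      len <- min(config$ld_block_size, m - s + 1L)
      maf <- runif(len, config$maf_range[1], config$maf_range[2])
      H <- matrix(0L, nf, len)
      for (j in seq_len(len)) {
        col <- rbinom(nf, 1L, maf[j])
        tries <- 0L
        while (length(unique(col)) == 1L && tries < 50L) {
          col <- rbinom(nf, 1L, maf[j])
          tries <- tries + 1L
        }
        if (length(unique(col)) == 1L) col[1] <- 1L - col[1]
        H[, j] <- col
      }
      H
    })
  })
}

.draw_batch <- function(config, pool, n, batch, id_offset) {
  set.seed(.sub_seed(config$seed, 100 + batch))
  calls <- matrix(0L, n, sum(config$n_snps_per_chrom))
  col0 <- 0L
  nf <- config$n_founder_haplotypes
  for (c_i in seq_along(pool)) {
    for (H in pool[[c_i]]) {
      len <- ncol(H)
      g <- H[sample.int(nf, n, replace = TRUE), , drop = FALSE] +
        H[sample.int(nf, n, replace = TRUE), , drop = FALSE]
      calls[, col0 + seq_len(len)] <- g
      col0 <- col0 + len
    }
  }
  # guarantee in-sample polymorphism: flip one allele of one individual at
  # any SNP whose sample allele frequency hit 0 or 1
  p <- colMeans(calls) / 2
  for (j in which(p == 0 | p == 1)) {
    calls[sample.int(n, 1L), j] <- 1L   # make one individual heterozygous
  }
  ids <- paste0("S", id_offset + seq_len(n))
  chrom <- rep(seq_along(config$n_snps_per_chrom), config$n_snps_per_chrom)
  within <- unlist(lapply(config$n_snps_per_chrom, seq_len))
  genotype_data(calls,
                data.frame(fid = ids, iid = ids),
                data.frame(id = paste0("snp", chrom, "_", within),
                           chrom = chrom, pos = within * 1000L,
                           a1 = "A", a2 = "G"))
}

#' Simulate genotypes from the founder-haplotype pool
#'
#' @param config A [sim_config].
#' @param n Number of individuals (default `n_cases + n_controls`).
#' @return A [genotype_data] with hard calls in `{0, 1, 2}`; every SNP is
#'   polymorphic in-sample.
#' @export
simulate_genotypes <- function(config, n = NULL) {
  n <- as.integer(n %||% (config$n_cases + config$n_controls))
  .assert(n >= 1, "zero individuals requested", "rhmap_config")
  .draw_batch(config, .founder_pool(config), n, batch = 1L, id_offset = 0L)
}

# Causal architecture: global SNP indices and standardized effect sizes for
# the polygenic component and each causal region. Equal variance share per
# QTL within a component, random signs.
.causal_plan <- function(config) {
  set.seed(.sub_seed(config$seed, 2))
  chrom_offset <- c(0L, cumsum(config$n_snps_per_chrom))
  regions <- list()
  regional_idx <- integer(0)
  for (k in seq_along(config$regional_specs)) {
    r <- config$regional_specs[[k]]
    span_end <- min(r$start + config$window_span - 1L,
                    config$n_snps_per_chrom[r$chrom])
    span <- r$start:span_end
    qtl_within <- unique(round(seq(r$start, span_end,
                                   length.out = r$n_qtls)))
    idx <- chrom_offset[r$chrom] + qtl_within
    beta <- sample(c(-1, 1), length(idx), replace = TRUE) *
      sqrt(r$variance / length(idx))
    regions[[k]] <- list(name = paste0("region", k), idx = idx, beta = beta,
                         variance = r$variance,
                         span_idx = chrom_offset[r$chrom] + span)
    regional_idx <- c(regional_idx, chrom_offset[r$chrom] + span)
  }
  poly_idx <- integer(0)
  poly_beta <- numeric(0)
  if (config$polygenic_variance > 0) {
    poly_idx <- setdiff(seq_len(sum(config$n_snps_per_chrom)), regional_idx)
    .assert(length(poly_idx) > 0,
            "no SNPs left for the polygenic component", "rhmap_config")
    poly_beta <- sample(c(-1, 1), length(poly_idx), replace = TRUE) *
      sqrt(config$polygenic_variance / length(poly_idx))
  }
  list(poly_idx = poly_idx, poly_beta = poly_beta, regions = regions)
}

# Column-standardize a call matrix by sample mean/SD (zero-SD guard).
.standardize <- function(calls) {
  mu <- colMeans(calls)
  sdv <- apply(calls, 2, sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(calls, 2, mu), 2, sdv, "/")
}

.batch_liability <- function(geno, plan, config, batch) {
  set.seed(.sub_seed(config$seed, 300 + batch))
  n <- nrow(geno$calls)
  sex <- rbinom(n, 1L, 0.5)
  array <- rbinom(n, 1L, 0.5)
  reg_var <- sum(vapply(plan$regions, function(r) r$variance, 0))
  resid_var <- 1 - config$polygenic_variance - reg_var
  causal <- c(plan$poly_idx, unlist(lapply(plan$regions, `[[`, "idx")))
  beta <- c(plan$poly_beta, unlist(lapply(plan$regions, `[[`, "beta")))
  gscore <- if (length(causal))
    as.vector(.standardize(geno$calls[, causal, drop = FALSE]) %*% beta)
  else rep(0, n)
  ce <- config$covariate_effects
  eff <- function(nm) {
    v <- unname(ce[nm])
    if (length(v) != 1 || is.na(v)) 0 else v
  }
  liab <- gscore + sex * eff("sex") + array * eff("array") +
    rnorm(n, 0, sqrt(resid_var))
  data.frame(sex = sex, array = array, liability = as.vector(liab))
}

#' Simulate phenotypes under the liability-threshold model
#'
#' Assigns case/control status by thresholding liability at
#' `qnorm(1 - prevalence)` and ascertains the cohort: if the supplied batch
#' of genotypes does not contain `n_cases` cases and `n_controls` controls,
#' further batches are drawn internally from the same founder pool until the
#' quotas are met (or `max_batches` is exceeded). The emitted genotype
#' container therefore supersedes the input batch.
#'
#' @param geno A [genotype_data] from [simulate_genotypes] with the same
#'   configuration.
#' @param config The [sim_config] used to generate `geno`.
#' @return A list with elements `geno` (ascertained cohort genotypes),
#'   `pheno` (data frame `FID, IID, PHENO, SEX, ARRAY`; `PHENO` in
#'   \{0, 1\}) and `truth` (a `sim_truth`: causal SNPs and effects, true
#'   liability-scale variance components, threshold, realized
#'   pre-ascertainment prevalence).
#' @export
simulate_phenotypes <- function(geno, config) {
  plan <- .causal_plan(config)
  t_thr <- qnorm(1 - config$prevalence)
  need_case <- config$n_cases
  need_ctrl <- config$n_controls
  batch_n <- max(need_case + need_ctrl, 1L)

  genos <- list()
  phenos <- list()
  total <- 0L
  total_cases <- 0L
  got_case <- 0L
  got_ctrl <- 0L
  batch <- 1L
  pool <- NULL
  repeat {
    if (batch > 1L) {
      if (is.null(pool)) pool <- .founder_pool(config)
      geno_b <- .draw_batch(config, pool, batch_n, batch, id_offset = total)
    } else geno_b <- geno
    ph <- .batch_liability(geno_b, plan, config, batch)
    ph$case <- as.integer(ph$liability > t_thr)
    total <- total + nrow(ph)
    total_cases <- total_cases + sum(ph$case)
    keep <- logical(nrow(ph))
    for (i in seq_len(nrow(ph))) {
      if (ph$case[i] == 1L && got_case < need_case) {
        keep[i] <- TRUE; got_case <- got_case + 1L
      } else if (ph$case[i] == 0L && got_ctrl < need_ctrl) {
        keep[i] <- TRUE; got_ctrl <- got_ctrl + 1L
      }
    }
    genos[[batch]] <- subset_geno(geno_b, samples = which(keep))
    phenos[[batch]] <- ph[keep, , drop = FALSE]
    if (got_case >= need_case && got_ctrl >= need_ctrl) break
    batch <- batch + 1L
    .assert(batch <= config$max_batches,
            sprintf(paste0("could not accrue %d cases / %d controls within ",
                           "%d batches (prevalence %.3g too extreme?)"),
                    need_case, need_ctrl, config$max_batches,
                    config$prevalence),
            "rhmap_accrual")
  }
  calls <- do.call(rbind, lapply(genos, function(g) g$calls))
  samples <- do.call(rbind, lapply(genos, function(g) g$samples))
  out_geno <- genotype_data(calls, samples, genos[[1]]$snps)
  ph <- do.call(rbind, phenos)
  pheno <- data.frame(FID = samples$fid, IID = samples$iid,
                      PHENO = ph$case, SEX = ph$sex, ARRAY = ph$array)
  comp <- c(polygenic = config$polygenic_variance,
            setNames(vapply(plan$regions, function(r) r$variance, 0),
                     vapply(plan$regions, function(r) r$name, "")),
            residual = 1 - config$polygenic_variance -
              sum(vapply(plan$regions, function(r) r$variance, 0)))
  causal_tab <- data.frame(
    snp = out_geno$snps$id[c(plan$poly_idx,
                             unlist(lapply(plan$regions, `[[`, "idx")))],
    component = c(rep("polygenic", length(plan$poly_idx)),
                  unlist(lapply(plan$regions, function(r)
                    rep(r$name, length(r$idx))))),
    beta = c(plan$poly_beta, unlist(lapply(plan$regions, `[[`, "beta"))))
  truth <- structure(list(causal = causal_tab,
                          var_components = comp,
                          threshold = t_thr,
                          prevalence = config$prevalence,
                          realized_prevalence = total_cases / total,
                          n_generated = total,
                          seed = config$seed),
                     class = "sim_truth")
  list(geno = out_geno, pheno = pheno, truth = truth)
}

#' Simulate a complete ascertained case-control cohort
#'
#' Convenience wrapper: [simulate_genotypes] then [simulate_phenotypes].
#'
#' @inheritParams simulate_phenotypes
#' @param config A [sim_config].
#' @return See [simulate_phenotypes].
#' @export
simulate_cohort <- function(config) {
  simulate_phenotypes(simulate_genotypes(config), config)
}

#' Write / read the ground-truth sidecar
#'
#' Plain-text key-value format: one `key=value` line per scalar
#' (`prevalence`, `threshold`, `realized_prevalence`, `n_generated`, `seed`,
#' and `var_<name>` for each liability-scale variance component), then one
#' `causal<TAB>snp<TAB>component<TAB>beta` line per causal SNP.
#'
#' @param truth A `sim_truth` object.
#' @param path Output file path.
#' @return `path` invisibly; `read_truth` returns the `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sc <- c(prevalence = truth$prevalence, threshold = truth$threshold,
          realized_prevalence = truth$realized_prevalence,
          n_generated = truth$n_generated, seed = truth$seed)
  writeLines(sprintf("%s=%.17g", names(sc), sc), con)
  writeLines(sprintf("var_%s=%.17g", names(truth$var_components),
                     truth$var_components), con)
  if (nrow(truth$causal))
    writeLines(sprintf("causal\t%s\t%s\t%.17g", truth$causal$snp,
                       truth$causal$component, truth$causal$beta), con)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- lines[!startsWith(lines, "causal\t")]
  keys <- sub("=.*$", "", kv)
  vals <- as.numeric(sub("^[^=]*=", "", kv))
  names(vals) <- keys
  vc <- vals[startsWith(keys, "var_")]
  names(vc) <- sub("^var_", "", names(vc))
  cl <- lines[startsWith(lines, "causal\t")]
  causal <- if (length(cl)) {
    parts <- strsplit(cl, "\t", fixed = TRUE)
    data.frame(snp = vapply(parts, `[[`, "", 2),
               component = vapply(parts, `[[`, "", 3),
               beta = as.numeric(vapply(parts, `[[`, "", 4)))
  } else data.frame(snp = character(), component = character(),
                    beta = numeric())
  structure(list(causal = causal, var_components = vc,
                 threshold = unname(vals["threshold"]),
                 prevalence = unname(vals["prevalence"]),
                 realized_prevalence = unname(vals["realized_prevalence"]),
                 n_generated = unname(vals["n_generated"]),
                 seed = unname(vals["seed"])),
            class = "sim_truth")
}
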