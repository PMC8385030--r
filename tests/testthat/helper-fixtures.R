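# Shared fixture builders: everything is generated in code at test time.

# Genotype container from a bare call matrix (one chromosome unless given).
tiny_geno <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  n <- nrow(calls)
  ids <- paste0("S", seq_len(n))
  genotype_data(calls,
                data.frame(fid = ids, iid = ids),
                data.frame(id = paste0("v", seq_len(m)),
                           chrom = chrom %||% rep(1L, m),
                           pos = pos %||% seq_len(m) * 1000L,
                           a1 = "A", a2 = "G"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random hard-call matrix with binomial(2, maf) entries, all polymorphic.
random_calls <- function(n, m, maf = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    calls <- matrix(rbinom(n * m, 2L, maf), n, m)
    p <- colMeans(calls) / 2
    if (all(p > 0 & p < 1)) return(calls)
  }
}

# Phenotype/covariate table with PCs for a simulated cohort.
cohort_phenocov <- function(sim, grm, n_pcs = 10) {
  pcs <- grm_pca(grm, n_pcs)
  cbind(sim$pheno, pcs[, grep("^PC", names(pcs)), drop = FALSE])
}

# Brute-force GRM by the displayed formula, element by element.
bruteforce_grm <- function(calls) {
  n <- nrow(calls)
  m <- ncol(calls)
  p <- colMeans(calls, na.rm = TRUE) / 2
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) {
      xj <- calls[j, i]
      xk <- calls[k, i]
      if (!is.na(xj) && !is.na(xk))
        s <- s + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    }
    G[j, k] <- s / m
  }
  G
}

# Independent HWE enumeration oracle: conditional kernel
# P(h) proportional to 2^h / ( ((nA-h)/2)! h! ((nB-h)/2)! ).
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  logw <- hs * log(2) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((nB - hs) / 2)
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  sum(pr[pr <= pr[match(n_het, hs)] * (1 + 1e-12)])
}

# Grid + refine REML oracle over variance fractions, driven by
# reml_loglik only (independent of the AI-REML path).
oracle_reml_loglik <- function(spec) {
  varP <- stats::var(spec$y)
  m <- length(spec$K)
  obj <- function(fr) {
    # fr: fractions of varP*2 for each genetic component and the residual
    th <- pmax(fr, 1e-8) * 2 * varP
    tryCatch(reml_loglik(spec, th), error = function(e) -Inf)
  }
  grid <- seq(0.01, 0.99, length.out = 15)
  if (m == 1) {
    cand <- as.matrix(expand.grid(grid, grid))
  } else {
    cand <- as.matrix(expand.grid(grid, grid, grid))
  }
  vals <- apply(cand, 1, obj)
  best <- cand[which.max(vals), ]
  opt <- stats::optim(best, function(fr) -obj(fr),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  -opt$value
}
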