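# Direct log-likelihood maximization oracle for single-SNP logistic
# regression without covariates (grid + refine, independent of glm.fit).
oracle_logistic <- function(y, g) {
  nll <- function(par) {
    eta <- par[1] + par[2] * g
    -sum(y * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(a = seq(-2, 2, length.out = 21),
                      b = seq(-2, 2, length.out = 21))
  vals <- apply(grid, 1, nll)
  best <- as.numeric(grid[which.min(vals), ])
  optim(best, nll, method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = 1e-14))$par[2]
}

test_that("logistic GWAS estimates match the likelihood oracle", {
  set.seed(63)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  eta <- -0.5 + 0.6 * g
  y <- rbinom(n, 1, plogis(eta))
  geno <- tiny_geno(matrix(g, n, 1))
  pc <- data.frame(FID = paste0("S", 1:n), IID = paste0("S", 1:n),
                   PHENO = y)
  res <- gwas_logistic(geno, pc, covariates = character(0))
  expect_equal(res$beta, oracle_logistic(y, g), tolerance = 1e-4)
  expect_equal(res$or, exp(res$beta), tolerance = 1e-12)
  expect_identical(res$ea, "A")           # minor allele is the A1 allele

  # effect-allele coding flips when A1 is the major allele
  geno_flip <- tiny_geno(matrix(2L - g, n, 1))
  res_flip <- gwas_logistic(geno_flip, pc, covariates = character(0))
  expect_identical(res_flip$ea, "G")
  expect_equal(res_flip$beta, res$beta, tolerance = 1e-8)

  # null SNPs stay null
  g0 <- rbinom(n, 2, 0.4)
  res0 <- gwas_logistic(tiny_geno(matrix(g0, n, 1)), pc,
                        covariates = character(0))
  expect_lt(abs(res0$z), 4)

  # monomorphic SNP is flagged, p missing
  resm <- gwas_logistic(tiny_geno(matrix(c(1L, rep(0L, n - 1)), n, 1)), pc,
                        covariates = character(0))
  # (one het keeps it polymorphic; truly constant dose must flag)
  resc <- suppressWarnings(
    gwas_logistic(tiny_geno(matrix(rep(1L, n), n, 1)), pc,
                  covariates = character(0)))
  expect_identical(resc$flag, "degenerate")
  expect_true(is.na(resc$p))
})

test_that("type-I error is calibrated across many null SNPs", {
  set.seed(64)
  n <- 400
  m <- 2500
  y <- rbinom(n, 1, 0.4)
  sex <- rbinom(n, 1, 0.5)
  pc <- data.frame(FID = paste0("S", 1:n), IID = paste0("S", 1:n),
                   PHENO = y, SEX = sex)
  geno <- tiny_geno(random_calls(n, m, maf = 0.3, seed = 64))
  res <- gwas_logistic(geno, pc, covariates = "SEX")
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  expect_equal(inflation_factor(res$p), 1, tolerance = 0.08)
})

test_that("Wald intervals reproduce the published replication table", {
  ci_kcnh5 <- wald_ci(11.16, 0.2338)
  expect_equal(unname(ci_kcnh5["lower"]), 7.057, tolerance = 1e-3)
  ci_stat4 <- wald_ci(1.436, 0.1445)
  expect_equal(unname(ci_stat4["lower"]), 1.082, tolerance = 1e-3)
  expect_equal(unname(ci_stat4["upper"]), 1.907, tolerance = 1e-3)

  # OR 1: symmetric about 1 on the log scale
  ci1 <- wald_ci(1, 0.3)
  expect_equal(ci1[["lower"]] * ci1[["upper"]], 1, tolerance = 1e-12)
  # exactly invertible: midpoint of the log interval is ln OR
  ci <- wald_ci(2.5, 0.11)
  expect_equal((log(ci[["lower"]]) + log(ci[["upper"]])) / 2, log(2.5),
               tolerance = 1e-12)
  expect_error(wald_ci(-1, 0.1), class = "rhmap_value")
})

test_that("Bonferroni adjustment matches the published values and caps", {
  expect_equal(bonferroni_adjust(5.83e-25, 3), 1.749e-24, tolerance = 1e-4)
  expect_equal(bonferroni_adjust(0.01217, 3), 0.03651, tolerance = 1e-4)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_error(bonferroni_adjust(0, 3), class = "rhmap_value")
})

test_that("the inflation factor is anchored at the chi-square median", {
  expect_equal(inflation_factor(rep(0.5, 11)), 1, tolerance = 1e-12)
  set.seed(65)
  p <- runif(1e5)
  expect_equal(inflation_factor(p), 1, tolerance = 0.02)
  expect_gt(inflation_factor(p / 2), inflation_factor(p))
  expect_error(inflation_factor(c(NA_real_, NA_real_)),
               class = "rhmap_undefined")
})

test_that("replication of discovery hits adjusts over the hit count", {
  set.seed(66)
  n <- 500
  g_true <- rbinom(n, 2, 0.3)
  g_null <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.8 + log(2) * g_true))
  calls <- cbind(g_true, g_null, rbinom(n, 2, 0.2))
  geno <- tiny_geno(calls)
  pc <- data.frame(FID = paste0("S", 1:n), IID = paste0("S", 1:n),
                   PHENO = y, SEX = rbinom(n, 1, 0.5))
  hits <- c("v1", "v2", "v3")
  rep3 <- replicate_hits(hits, geno, pc, covariates = "SEX")
  expect_identical(nrow(rep3), 3L)
  expect_equal(rep3$adj_p, pmin(1, rep3$p * 3), tolerance = 1e-12)
  expect_true(all(rep3$l95 < rep3$or & rep3$or < rep3$u95))

  rep1 <- replicate_hits("v1", geno, pc, covariates = "SEX")
  expect_equal(rep1$adj_p, rep1$p, tolerance = 1e-12)

  # absent SNP recorded as untested
  rep_abs <- replicate_hits(c("v1", "nope"), geno, pc, covariates = "SEX")
  expect_false(rep_abs$tested[rep_abs$snp == "nope"])

  # a true OR-2 effect replicates in most seeds
  wins <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    gt <- rbinom(n, 2, 0.3)
    yy <- rbinom(n, 1, plogis(-0.8 + log(2) * gt))
    gg <- tiny_geno(matrix(gt, n, 1))
    ppc <- data.frame(FID = paste0("S", 1:n), IID = paste0("S", 1:n),
                      PHENO = yy)
    r <- replicate_hits("v1", gg, ppc, covariates = character(0))
    if (!is.na(r$p) && r$p < 0.05) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("association tables serialize in the documented layout", {
  set.seed(67)
  n <- 120
  geno <- tiny_geno(random_calls(n, 5, seed = 67))
  pc <- data.frame(FID = paste0("S", 1:n), IID = paste0("S", 1:n),
                   PHENO = rbinom(n, 1, 0.5))
  res <- replicate_hits(c("v1", "v2"), geno, pc,
                        covariates = character(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assoc(res, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(back)[1:4], c("SNP", "CHR", "BP", "EA"))
  expect_true(all(c("OR", "SE", "L95", "U95", "P", "ADJ_P")
                  %in% names(back)))
})
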