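# Enumeration oracle for the window rule: starts at 0, shift, 2*shift, ...
# while start < m; end clipped at m.
enumerate_windows <- function(m, size, shift) {
  starts <- seq(0, m - 1, by = shift)
  data.frame(start = starts + 1, end = pmin(starts + size, m))
}

test_that("window construction follows the enumeration rule", {
  geno100 <- tiny_geno(random_calls(4, 100, seed = 14))
  w <- make_windows(geno100, 50, 25)
  expect_identical(nrow(w), 4L)
  expect_identical(w$start, c(1L, 26L, 51L, 76L))
  expect_identical(w$end, c(50L, 75L, 100L, 100L))
  expect_identical(w$clipped, c(FALSE, FALSE, FALSE, TRUE))

  w50 <- make_windows(tiny_geno(random_calls(4, 50, seed = 15)), 50, 25)
  expect_identical(nrow(w50), 2L)
  expect_identical(w50$end, c(50L, 50L))

  # shift = size: non-overlapping tiling with ceiling(m/size) windows
  w_tile <- make_windows(geno100, 20, 20)
  expect_identical(nrow(w_tile), 5L)
  expect_identical(w_tile$start, seq(1L, 81L, by = 20L))

  # property: emitted count matches the rule across sizes, per chromosome
  set.seed(16)
  for (rep in 1:20) {
    m <- sample(2:400, 1)
    size <- sample(2:60, 1)
    shift <- sample(seq_len(size), 1)
    geno <- tiny_geno(matrix(rbinom(2 * m, 2, 0.5), 2, m))
    w <- make_windows(geno, size, shift)
    oracle <- enumerate_windows(m, size, shift)
    expect_identical(w$start, as.integer(oracle$start))
    expect_identical(w$end, as.integer(oracle$end))
  }

  # windows never span chromosomes
  geno2 <- tiny_geno(random_calls(4, 70, seed = 17),
                     chrom = rep(c(1L, 2L), c(40, 30)))
  w2 <- make_windows(geno2, 50, 25)
  expect_identical(w2$chrom, c(1L, 1L, 2L, 2L))
  expect_identical(w2$end[2], 40L)        # clipped at the chromosome end
  expect_error(make_windows(geno2, 1, 1), class = "rhmap_config")
  expect_error(make_windows(geno2, 50, 60), class = "rhmap_config")
})

test_that("thresholds reproduce the published table and invert the LRT map", {
  thr <- scan_thresholds(40890, 0.05)
  expect_equal(thr$p_threshold, 2.45e-6, tolerance = 2e-3)
  expect_equal(round(thr$lrt_threshold, 2), 20.88)
  thr10 <- scan_thresholds(40890, 0.1)
  expect_equal(thr10$p_threshold, 4.89e-6, tolerance = 2e-3)
  expect_equal(round(thr10$lrt_threshold, 2), 19.55)

  # M = 2: one effective test; LRT threshold at the chi-square survival
  # inverse of 2 * alpha
  thr2 <- scan_thresholds(2, 0.05)
  expect_equal(thr2$p_threshold, 0.05)
  expect_equal(thr2$lrt_threshold, qchisq(0.1, 1, lower.tail = FALSE))

  # exact inverse of the mixture p-value mapping
  for (M in c(10, 1000, 40890)) {
    t <- scan_thresholds(M, 0.05)
    p_back <- 0.5 * pchisq(t$lrt_threshold, 1, lower.tail = FALSE)
    expect_equal(p_back, t$p_threshold, tolerance = 1e-9)
  }
  expect_error(scan_thresholds(40890, 1.2), class = "rhmap_config")
  expect_error(scan_thresholds(1, 0.05), class = "rhmap_config")
})

test_that("liability transformation matches closed-form and quadrature", {
  lp <- liability_params(0.5, 0.5)
  # K = P = 0.5: factor = 0.25 / dnorm(0)^2 = pi/2
  expect_equal(observed_to_liability(0.1, lp), 0.1 * pi / 2,
               tolerance = 1e-12)
  expect_equal(observed_to_liability(0.1, lp), 0.15708, tolerance = 1e-4)
  expect_equal(observed_to_liability(0, lp), 0)

  # the seed study's design: K = 420 per million, P = 1953/5643;
  # verify t and z against numeric integration of the normal density
  K <- 0.00042
  P <- 1953 / 5643
  lp2 <- liability_params(K, P)
  t_quad <- uniroot(function(t)
    integrate(dnorm, t, 40, abs.tol = 1e-14)$value - K,
    c(0, 10), tol = 1e-12)$root
  expect_equal(lp2$t, t_quad, tolerance = 1e-6)
  h <- 1e-6
  z_quad <- (pnorm(t_quad + h) - pnorm(t_quad - h)) / (2 * h)
  expect_equal(lp2$z, z_quad, tolerance = 1e-4)
  factor <- K^2 * (1 - K)^2 / (z_quad^2 * P * (1 - P))
  expect_equal(observed_to_liability(1, lp2), factor, tolerance = 1e-4)

  # linear in h2_obs; decreasing in the threshold for fixed P
  expect_equal(observed_to_liability(0.4, lp2),
               4 * observed_to_liability(0.1, lp2), tolerance = 1e-12)
  Ks <- c(0.4, 0.2, 0.1, 0.01, 0.001)
  factors <- vapply(Ks, function(k)
    observed_to_liability(1, liability_params(k, 0.35)), 0)
  ts <- abs(qnorm(1 - Ks))
  expect_true(all(diff(factors[order(ts)]) < 0))

  expect_error(liability_params(0, 0.3), class = "rhmap_config")
  expect_error(liability_params(0.1, 1), class = "rhmap_config")
  expect_error(observed_to_liability(-0.1, lp), class = "rhmap_value")
})

test_that("significant windows merge into regions by SNP overlap", {
  # synthetic records: windows 1-2 overlap (share SNPs 26-50), window 4 is
  # distant; oracle = interval merge on index ranges
  rec <- data.frame(ordinal = 1:4, chrom = c(1L, 1L, 1L, 2L),
                    start = c(1L, 26L, 201L, 1L),
                    end = c(50L, 75L, 250L, 50L),
                    pos_first = c(1000, 26000, 201000, 1000),
                    pos_last = c(50000, 75000, 250000, 50000),
                    lrt = c(25, 30, 10, 22), p = 1e-7,
                    h2_liab = c(0.01, 0.02, 0.001, 0.015),
                    h2_liab_se = c(0.004, 0.006, 0.001, 0.005),
                    excluded = FALSE)
  thr <- list(lrt_threshold = 20.88)
  regions <- significant_regions(rec, thr)
  expect_identical(nrow(regions), 2L)
  expect_equal(regions$window_first, c(1, 4))
  expect_equal(regions$window_last, c(2, 4))
  expect_equal(regions$min_lrt[1], 25)
  expect_equal(regions$max_lrt[1], 30)
  expect_equal(regions$pos_first[1], 1000)
  expect_equal(regions$pos_last[1], 75000)
  expect_equal(regions$min_reg_h2[1], 0.01)
  expect_equal(regions$average_se[1], 0.005)

  # nothing significant: empty table with the full header
  none <- significant_regions(rec, list(lrt_threshold = 100))
  expect_identical(nrow(none), 0L)
  expect_true(all(c("window_first", "max_lrt", "average_se")
                  %in% names(none)))
})

test_that("a small null scan behaves like the boundary mixture", {
  cfg <- sim_config(60, 90, 500, prevalence = 0.4, seed = 53)
  sim <- simulate_cohort(cfg)
  grm <- compute_grm(sim$geno)
  pc <- cohort_phenocov(sim, grm, n_pcs = 5)
  windows <- make_windows(sim$geno)
  res <- rhm_scan(sim$geno, pc, grm, windows, prevalence = 0.4)
  rec <- res$records[!res$records$excluded, ]
  expect_gt(nrow(rec), 10)
  # around half of the null LRTs sit at the zero boundary
  frac0 <- mean(rec$lrt < 1e-6)
  expect_gt(frac0, 0.2)
  expect_lt(frac0, 0.8)
  expect_true(all(rec$p > 0 & rec$p <= 0.5))
  expect_true(all(rec$h2_obs >= 0 & rec$h2_obs <= 1))
  # ratio consistent with the components
  tot <- rec$sigma2_u + rec$sigma2_w + rec$sigma2_e
  expect_equal(rec$h2_obs, rec$sigma2_w / tot, tolerance = 1e-8)

  # outputs round-trip through the TSV layer
  thr <- scan_thresholds(nrow(rec), 0.05)
  prefix <- withr::local_tempfile()
  paths <- report_scan(res$records, thr, prefix)
  back <- read_scan_records(paths[["scan"]])
  expect_equal(back$lrt, res$records$lrt, tolerance = 1e-9)
  expect_identical(nrow(back), nrow(res$records))
  qq <- read.table(paths[["qq"]], header = TRUE, sep = "\t")
  expect_identical(nrow(qq), nrow(rec))
  expect_true(all(diff(qq$expected) >= 0))
})

test_that("a planted multi-QTL region is detected by the scan", {
  cfg <- sim_config(150, 150, 250, ld_block_size = 5,
                    n_founder_haplotypes = 60, prevalence = 0.35,
                    polygenic_variance = 0.05,
                    regional_specs = list(list(chrom = 1, start = 51,
                                               n_qtls = 5,
                                               variance = 0.15)),
                    seed = 59)
  sim <- simulate_cohort(cfg)
  grm <- compute_grm(sim$geno)
  pc <- cohort_phenocov(sim, grm, n_pcs = 5)
  windows <- make_windows(sim$geno)
  res <- rhm_scan(sim$geno, pc, grm, windows, prevalence = 0.35)
  rec <- res$records[!res$records$excluded, ]
  # the causal region spans SNPs 51-100 = windows starting at 26, 51, 76
  hit <- rec$ordinal[which.max(rec$lrt)]
  causal_windows <- rec$ordinal[rec$start <= 100 & rec$end >= 51]
  expect_true(hit %in% causal_windows)
  expect_gt(max(rec$lrt), 2)
})
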