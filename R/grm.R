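# Genomic relationship matrices and GRM-based PCA.
#
# g_jk = (1/N) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
# with p_i the in-sample reference (A1) allele frequency over non-missing
# calls. A missing genotype contributes 0 to the sum and the divisor stays
# N. Regional GRMs apply the same formula to a window's SNPs.

#' Compute a genomic relationship matrix
#'
#' @param geno A [genotype_data].
#' @param snp_subset Optional integer index vector: compute a regional GRM
#'   from exactly these SNPs (default: all SNPs).
#' @return An object of class `grm`: list with `mat` (n x n symmetric
#'   matrix), `ids` (sample fid/iid), `n_snps` (N in the divisor) and
#'   `freqs` (per-SNP A1 frequencies used).
#' @export
compute_grm <- function(geno, snp_subset = NULL) {
  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(geno$calls))
  .assert(all(snp_subset >= 1 & snp_subset <= ncol(geno$calls)),
          "snp_subset out of bounds", "rhmap_value")
  X <- geno$calls[, snp_subset, drop = FALSE]
  p <- .allele_freq(X)
  .assert(all(p > 0 & p < 1),
          "monomorphic SNP in GRM subset; filter before calling",
          "rhmap_degenerate")
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0                       # missing call contributes 0
  G <- tcrossprod(Z) / length(snp_subset)
  dimnames(G) <- NULL
  structure(list(mat = G, ids = geno$samples,
                 n_snps = length(snp_subset), freqs = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, built from %d SNPs (mean diagonal %.4f)\n",
              nrow(x$mat), x$n_snps, mean(diag(x$mat))))
  invisible(x)
}

#' Write a GRM in GCTA binary format
#'
#' Writes the triplet `.grm.bin` (lower triangle including the diagonal,
#' row-wise, float32), `.grm.N.bin` (SNP count per pair, float32) and
#' `.grm.id` (FID/IID, tab-separated).
#'
#' @param grm A [grm] object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$mat)
  # GCTA stores pairs (j, k <= j) row-wise: g11, g21, g22, g31, ...
  ord <- unlist(lapply(seq_len(n), function(j) grm$mat[j, seq_len(j)]))
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(ord), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps), length(ord)), con, size = 4)
  close(con)
  write.table(grm$ids[, c("fid", "iid")], paste0(prefix, ".grm.id"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from GCTA binary format
#'
#' @param prefix Path prefix of the `.grm.bin`/`.grm.N.bin`/`.grm.id`
#'   triplet.
#' @return A [grm] object (float32 precision; `freqs` unavailable).
#' @export
read_grm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    colClasses = "character")
  n <- nrow(ids)
  npair <- n * (n + 1) / 2
  bin_path <- paste0(prefix, ".grm.bin")
  vals <- readBin(bin_path, "numeric", n = file.size(bin_path) / 4 + 1,
                  size = 4)
  .assert(length(vals) == npair,
          sprintf(".grm.bin holds %d values but %d samples need %d",
                  length(vals), n, npair), "rhmap_format")
  G <- matrix(0, n, n)
  k <- 1L
  for (j in seq_len(n)) {
    G[j, seq_len(j)] <- vals[k:(k + j - 1L)]
    k <- k + j
  }
  G <- G + t(G) - diag(diag(G))
  nbin_path <- paste0(prefix, ".grm.N.bin")
  nvals <- readBin(nbin_path, "numeric",
                   n = file.size(nbin_path) / 4 + 1, size = 4)
  structure(list(mat = G, ids = data.frame(fid = ids[[1]], iid = ids[[2]]),
                 n_snps = as.integer(round(nvals[1])), freqs = NULL),
            class = "grm")
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors of the relationship matrix by descending eigenvalue,
#' unit norm, with a deterministic sign convention (the largest-magnitude
#' loading of each vector is positive).
#'
#' @param grm A [grm] object.
#' @param k Number of components (default 10; must be `< n`).
#' @return Data frame `FID, IID, PC1..PCk`, with the eigenvalues in
#'   attribute `"eigenvalues"`.
#' @export
grm_pca <- function(grm, k = 10L) {
  n <- nrow(grm$mat)
  .assert(all(is.finite(grm$mat)), "GRM contains non-finite entries",
          "rhmap_numeric")
  .assert(k >= 1 && k < n, "k must satisfy 1 <= k < n", "rhmap_config")
  ed <- eigen(grm$mat, symmetric = TRUE)
  vec <- ed$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  out <- data.frame(FID = grm$ids$fid, IID = grm$ids$iid, vec)
  names(out)[-(1:2)] <- paste0("PC", seq_len(k))
  attr(out, "eigenvalues") <- ed$values[seq_len(k)]
  out
}

#' Write eigenvectors as TSV
#'
#' @param pcs Data frame from [grm_pca].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca <- function(pcs, path) {
  write.table(pcs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
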