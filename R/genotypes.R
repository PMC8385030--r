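# Genotype container and PLINK binary input/output.
#
# Genotypes are hard calls stored as an n x m integer matrix counting copies
# of allele A1 (the first allele column of the SNP map, conventionally the
# minor allele), with NA for missing. SNPs are kept sorted by (chromosome,
# position), matching the order windows are built in.

#' Construct a genotype container
#'
#' Bundles a hard-call matrix with its sample identifiers and SNP map. Calls
#' count copies of allele `a1` (0, 1, 2, or `NA` for missing). SNPs are
#' sorted by (chromosome, position) on construction.
#'
#' @param calls Integer matrix, individuals in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param samples Data frame with columns `fid`, `iid`.
#' @param snps Data frame with columns `id`, `chrom`, `pos`, `a1`, `a2`.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  .assert(nrow(calls) == nrow(samples),
          "call matrix rows must match sample count", "rhmap_dim")
  .assert(ncol(calls) == nrow(snps),
          "call matrix columns must match SNP count", "rhmap_dim")
  .assert(all(c("fid", "iid") %in% names(samples)), "samples need fid, iid")
  .assert(all(c("id", "chrom", "pos", "a1", "a2") %in% names(snps)),
          "snps need id, chrom, pos, a1, a2")
  bad <- calls[!is.na(calls)]
  .assert(all(bad %in% 0:2), "calls must be 0, 1, 2 or NA", "rhmap_value")
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(snps) <- NULL
  dimnames(calls) <- list(samples$iid, snps$id)
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$calls)

#' Subset a genotype container
#'
#' @param geno A [genotype_data] object.
#' @param samples,snps Index vectors (integer or logical) into samples / SNPs.
#' @return A `genotype_data` with the selected rows/columns.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(geno$calls))
  if (is.null(snps)) snps <- seq_len(ncol(geno$calls))
  genotype_data(geno$calls[samples, snps, drop = FALSE],
                geno$samples[samples, , drop = FALSE],
                geno$snps[snps, , drop = FALSE])
}

# PLINK .bed 2-bit codes, SNP-major: 00 = hom A1, 10 = het, 11 = hom A2,
# 01 = missing. Stored little-endian within each byte (first sample in the
# two lowest bits).
.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

.code_from_call <- c(`0` = 3L, `1` = 2L, `2` = 0L)   # A1 count -> 2-bit code
.call_from_code <- c(2L, NA_integer_, 1L, 0L)        # code 0..3 -> A1 count

#' Write a PLINK bed/bim/fam fileset
#'
#' Writes hard calls in SNP-major binary format (magic bytes
#' `0x6c 0x1b 0x01`), with the companion `.bim` and `.fam` text files.
#'
#' @param geno A [genotype_data] object.
#' @param prefix Path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @param phenotype Optional numeric vector written to the `.fam` phenotype
#'   column (PLINK convention 1/2; default `-9` missing).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, phenotype = NULL) {
  n <- nrow(geno$calls)
  m <- ncol(geno$calls)
  fam <- data.frame(fid = geno$samples$fid, iid = geno$samples$iid,
                    pat = 0L, mat = 0L, sex = 0L,
                    pheno = if (is.null(phenotype)) rep(-9L, n) else phenotype)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = geno$snps$chrom, id = geno$snps$id, cm = 0L,
                    pos = geno$snps$pos, a1 = geno$snps$a1, a2 = geno$snps$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  codes <- matrix(1L, n, m)                       # default: missing (01)
  ok <- !is.na(geno$calls)
  codes[ok] <- .code_from_call[as.character(geno$calls[ok])]
  np <- 4L * ceiling(n / 4L)                      # samples padded to a byte
  padded <- matrix(0L, np, m)
  padded[seq_len(n), ] <- codes
  i4 <- seq(1L, np, by = 4L)
  bytes <- padded[i4, , drop = FALSE] +
    4L * padded[i4 + 1L, , drop = FALSE] +
    16L * padded[i4 + 2L, , drop = FALSE] +
    64L * padded[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A [genotype_data] object; calls count copies of the `.bim` A1
#'   allele.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam"))
    .assert(file.exists(paste0(prefix, ext)),
            paste0("missing ", ext, " file for prefix ", prefix),
            "rhmap_format")
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    colClasses = c("character", "character", rep(NA, 4)))
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    colClasses = c(NA, "character", NA, NA,
                                   "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  .assert(length(raw) >= 3 && all(raw[1:3] == .BED_MAGIC),
          "not a SNP-major PLINK bed file (bad magic bytes)", "rhmap_format")
  bpv <- ceiling(n / 4L)                          # bytes per variant
  payload <- raw[-(1:3)]
  .assert(length(payload) == bpv * m,
          sprintf("bed payload is %d bytes but %d expected for %d x %d",
                  length(payload), bpv * m, n, m), "rhmap_consistency")
  b <- as.integer(payload)
  codes <- rbind((b %/% 1L) %% 4L, (b %/% 4L) %% 4L,
                 (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  dim(codes) <- c(4L * bpv, m)
  calls <- matrix(.call_from_code[codes[seq_len(n), , drop = FALSE] + 1L],
                  n, m)
  genotype_data(calls,
                data.frame(fid = fam[[1]], iid = fam[[2]]),
                data.frame(id = bim[[2]], chrom = bim[[1]], pos = bim[[4]],
                           a1 = bim[[5]], a2 = bim[[6]]))
}

# Per-SNP A1 allele frequency over non-missing calls.
.allele_freq <- function(calls) {
  colMeans(calls, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls.
#'
#' @param geno A [genotype_data] object.
#' @return Numeric vector, one MAF per SNP.
#' @export
snp_maf <- function(geno) {
  p <- .allele_freq(geno$calls)
  pmin(p, 1 - p)
}
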