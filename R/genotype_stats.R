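#' Genotype counts for one SNP
#'
#' Counts the three genotype classes for a SNP, excluding missing calls.
#' `n11` is the `allele1` homozygote (code 0), `n12` the heterozygote,
#' `n22` the `allele2` homozygote (code 2).
#'
#' @param g a [genotype_matrix()].
#' @param snp SNP id.
#' @return named integer vector `c(n11, n12, n22)`.
#' @export
genotype_counts <- function(g, snp) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!snp %in% g$map$snp) stop("unknown SNP id: ", snp)
  x <- g$calls[, snp]
  c(n11 = sum(x == 0L, na.rm = TRUE),
    n12 = sum(x == 1L, na.rm = TRUE),
    n22 = sum(x == 2L, na.rm = TRUE))
}

#' Minor allele frequency from genotype counts
#'
#' `maf = min(p, 1 - p)` with `p = (2 n11 + n12) / (2 n)` the frequency of
#' allele1; invariant to swapping the allele labels.
#'
#' @param counts genotype count triple `(n11, n12, n22)`.
#' @return minor allele frequency in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("minor allele frequency undefined: zero genotyped individuals")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  min(p, 1 - p)
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' Pearson chi-square comparing observed genotype counts with the expected
#' counts `(n p^2, 2 n p q, n q^2)` computed from the sample allele
#' frequencies, on 1 degree of freedom (3 classes, 1 estimated frequency).
#' No continuity correction is applied.
#'
#' @param counts genotype count triple `(n11, n12, n22)`.
#' @return list with `chi2`, `df` (always 1) and `p`.
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("HWE test undefined: zero genotyped individuals")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1)
    stop("HWE test undefined for a monomorphic SNP")
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-SNP summary table
#'
#' Descriptive statistics for every SNP: genotype counts and frequencies,
#' minor allele frequency, and the Hardy-Weinberg chi-square p-value
#' (`NA` with a reason for monomorphic or all-missing SNPs).
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with one row per SNP: `snp`, `chrom`, `pos`, `alleles`,
#'   `n`, `n11`, `n12`, `n22`, `f11`, `f12`, `f22`, `maf`, `hwe_chi2`,
#'   `hwe_p`.
#' @export
snp_summary <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  rows <- lapply(g$map$snp, function(s) {
    cn <- genotype_counts(g, s)
    n <- sum(cn)
    freqs <- if (n > 0) cn / n else rep(NA_real_, 3)
    maf <- if (n > 0) minor_allele_frequency(cn) else NA_real_
    hwe <- tryCatch(hwe_test(cn), error = function(e) NULL)
    i <- match(s, g$map$snp)
    data.frame(snp = s, chrom = g$map$chrom[i], pos = g$map$pos[i],
               alleles = paste0(g$map$allele1[i], ">", g$map$allele2[i]),
               n = n, n11 = cn[1], n12 = cn[2], n22 = cn[3],
               f11 = freqs[1], f12 = freqs[2], f22 = freqs[3],
               maf = maf,
               hwe_chi2 = if (is.null(hwe)) NA_real_ else hwe$chi2,
               hwe_p = if (is.null(hwe)) NA_real_ else hwe$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the SNP summary table as TSV
#'
#' @param summary output of [snp_summary()].
#' @param path output path.
#' @export
write_snp_summary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
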