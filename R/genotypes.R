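#' Construct a genotype matrix
#'
#' Container for unphased biallelic SNP genotypes. Calls are coded 0/1/2 as
#' the number of copies of `allele2` carried, with `NA` for missing.
#'
#' @param calls integer matrix, individuals x SNPs, values in \{0, 1, 2, NA\}.
#' @param ids character vector of individual ids (rows).
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp),
#'   `allele1`, `allele2`; one row per column of `calls`.
#' @return list of class `"genotype_matrix"` with elements `ids`, `map`,
#'   `calls` (dimnames set to ids x snp ids).
#' @export
genotype_matrix <- function(calls, ids, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  ids <- as.character(ids)
  need <- c("snp", "chrom", "pos", "allele1", "allele2")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  map <- as.data.frame(map)[, need]
  map$snp <- as.character(map$snp)
  if (nrow(calls) != length(ids)) stop("nrow(calls) must equal length(ids)")
  if (ncol(calls) != nrow(map)) stop("ncol(calls) must equal nrow(map)")
  if (anyDuplicated(map$snp)) stop("duplicate SNP ids in map")
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (any(map$pos < 0)) stop("SNP positions must be non-negative")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(ids, map$snp)
  structure(list(ids = ids, map = map, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x",
      nrow(x$map), "SNPs\n")
  cat("missing rate:", round(mean(is.na(x$calls)), 4), "\n")
  invisible(x)
}

#' Orient genotype codes to count copies of the minor allele
#'
#' For each SNP, swaps allele labels (and recodes calls as `2 - code`) where
#' needed so that `allele2` is the minor allele in the loaded sample, i.e. a
#' code of 1 counts one copy of the minor allele. Ties (allele frequency
#' exactly 0.5) are left unchanged. The applied flips are recorded in
#' `attr(, "flipped")`.
#'
#' @param g a [genotype_matrix()].
#' @return a reoriented [genotype_matrix()].
#' @export
orient_minor <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p2 <- colMeans(g$calls, na.rm = TRUE) / 2  # sample frequency of allele2
  flip <- !is.na(p2) & p2 > 0.5
  if (any(flip)) {
    g$calls[, flip] <- 2L - g$calls[, flip]
    a1 <- g$map$allele1[flip]
    g$map$allele1[flip] <- g$map$allele2[flip]
    g$map$allele2[flip] <- a1
  }
  attr(g, "flipped") <- setNames(flip, g$map$snp)
  g
}

#' Read genotypes from PLINK text .ped/.map files
#'
#' Whitespace dialect: the .map has 3 or 4 columns (chrom, snp, \[cM,\] pos);
#' the .ped has 6 leading columns (family, individual, father, mother, sex,
#' phenotype) followed by two allele letters per SNP, `0` meaning missing.
#' Alleles observed per SNP must be at most two; `allele2` is set to the
#' second distinct allele observed (use [orient_minor()] for minor-allele
#' coding).
#'
#' @param prefix path prefix so that `<prefix>.ped` and `<prefix>.map` exist,
#'   or the path of the `.ped` file itself.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  prefix <- sub("\\.ped$", "", prefix)
  pedf <- paste0(prefix, ".ped"); mapf <- paste0(prefix, ".map")
  if (!file.exists(pedf)) stop("file not found: ", pedf)
  if (!file.exists(mapf)) stop("file not found: ", mapf)
  mp <- read.table(mapf, colClasses = "character", stringsAsFactors = FALSE)
  if (!ncol(mp) %in% 3:4) stop(".map must have 3 or 4 columns")
  map <- data.frame(snp = mp[[2]], chrom = mp[[1]],
                    pos = as.integer(mp[[ncol(mp)]]),
                    allele1 = NA_character_, allele2 = NA_character_,
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  pd <- read.table(pedf, colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(pd) != 6 + 2 * m)
    stop(".ped has ", ncol(pd), " columns; expected ", 6 + 2 * m,
         " for ", m, " SNPs in .map")
  ids <- pd[[2]]
  calls <- matrix(NA_integer_, nrow(pd), m)
  for (j in seq_len(m)) {
    a <- pd[[6 + 2 * j - 1]]; b <- pd[[6 + 2 * j]]
    miss <- a == "0" | b == "0"
    obs <- sort(unique(c(a[!miss], b[!miss])))
    if (length(obs) > 2)
      stop("SNP ", map$snp[j], " has >2 alleles in .ped: ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0) obs <- c("0", "0")
    a1 <- obs[1]; a2 <- if (length(obs) == 2) obs[2] else obs[1]
    map$allele1[j] <- a1; map$allele2[j] <- a2
    calls[, j] <- (a == a2) + (b == a2)
    calls[miss, j] <- NA_integer_
  }
  genotype_matrix(calls, ids, map)
}

#' Write genotypes to PLINK text .ped/.map files
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param pedinfo optional data.frame with columns `id`, `sire`, `dam` used to
#'   fill the .ped parental columns ("0" where unknown).
#' @return invisibly, the two paths written.
#' @export
write_plink <- function(g, prefix, pedinfo = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  write.table(data.frame(g$map$chrom, g$map$snp, 0, g$map$pos),
              mapf, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- length(g$ids); m <- nrow(g$map)
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    x <- g$calls[, j]
    a1 <- g$map$allele1[j]; a2 <- g$map$allele2[j]
    first <- ifelse(is.na(x), "0", ifelse(x >= 1, a2, a1))
    second <- ifelse(is.na(x), "0", ifelse(x == 2, a2, a1))
    al[, 2 * j - 1] <- first; al[, 2 * j] <- second
  }
  fid <- rep("FAM", n); pat <- rep("0", n); mat <- rep("0", n)
  if (!is.null(pedinfo)) {
    mi <- match(g$ids, pedinfo$id)
    pat <- ifelse(is.na(mi) | is.na(pedinfo$sire[mi]), "0", pedinfo$sire[mi])
    mat <- ifelse(is.na(mi) | is.na(pedinfo$dam[mi]), "0", pedinfo$dam[mi])
  }
  lines <- cbind(fid, g$ids, pat, mat, "0", "-9", al)
  write.table(lines, pedf, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = pedf, map = mapf))
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields of a VCF through the vcfR package. Multi-allelic or
#' non-SNP records are rejected with the offending site named. Calls `./.`
#' (or half-missing) become `NA`.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return a [genotype_matrix()] coding copies of the ALT allele.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1,
                                             dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multi-allelic VCF record(s): ",
         paste(ifelse(is.na(fix[multi, "ID"]), fix[multi, "POS"],
                      fix[multi, "ID"]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- if (is.matrix(gt)) gt else matrix(gt, nrow = nrow(fix))
  count_alt <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & !grepl("\\.", s)
    out[ok] <- vapply(strsplit(gsub("\\|", "/", s[ok]), "/"),
                      function(a) sum(a == "1"), integer(1))
    out
  }
  calls <- matrix(count_alt(as.vector(gt)), nrow = nrow(gt))
  snp <- fix[, "ID"]
  snp[is.na(snp) | snp == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(snp) | snp == "."]
  map <- data.frame(snp = snp, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  genotype_matrix(t(calls), colnames(gt), map)
}
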