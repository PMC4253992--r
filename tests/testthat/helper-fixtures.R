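# Shared fixtures and independent oracles, all built in code.

# published candidate-gene input tables shipped with the package
hal_freq_table <- function() {
  read.delim(system.file("extdata", "hal_snp_genotype_frequencies.tsv",
                         package = "haplomm"))
}
hal_block1 <- function() {
  read.delim(system.file("extdata", "hal_block1_haplotype_frequencies.tsv",
                         package = "haplomm"))
}
hal_block2 <- function() {
  read.delim(system.file("extdata", "hal_block2_haplotype_frequencies.tsv",
                         package = "haplomm"))
}

block1_sim_config <- function(seed, ...) {
  b1 <- hal_block1()
  sim_config(block_spec = list(haplotypes = b1$haplotype,
                               freq = b1$frequency_pct / sum(b1$frequency_pct),
                               pos = (1:6) * 1000 + 64520000),
             seed = seed, ...)
}

# random valid pedigree: founders first, then individuals drawing parents
# among earlier individuals (or unknown)
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1) {
  set.seed(seed)
  id <- sprintf("I%04d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1)
    if (runif(1) < 0.9) sire[i] <- id[sample(pool, 1)]
    if (runif(1) < 0.9) {
      d <- id[sample(pool, 1)]
      if (is.na(sire[i]) || d != sire[i]) dam[i] <- d
    }
  }
  pedigree(id, sire, dam)
}

# toy genotype container
toy_geno <- function(calls, alleles = NULL) {
  m <- ncol(calls)
  if (is.null(alleles))
    alleles <- data.frame(allele1 = rep("A", m), allele2 = rep("B", m))
  genotype_matrix(calls, sprintf("i%03d", seq_len(nrow(calls))),
                  data.frame(snp = sprintf("s%02d", seq_len(m)), chrom = "1",
                             pos = seq_len(m) * 100,
                             allele1 = alleles$allele1,
                             allele2 = alleles$allele2))
}

# genotypes from iid gametes drawn from given haplotype frequencies
iid_gamete_geno <- function(haps, freq, n, seed) {
  set.seed(seed)
  hb <- do.call(rbind, strsplit(haps, ""))
  m <- ncol(hb)
  alleles <- data.frame(
    allele1 = apply(hb, 2, function(a) sort(unique(a))[1]),
    allele2 = apply(hb, 2, function(a) {
      u <- sort(unique(a)); if (length(u) > 1) u[2] else u[1]
    }))
  bits <- t(apply(hb, 1, function(h) as.integer(h == alleles$allele2)))
  g1 <- sample.int(length(freq), n, TRUE, prob = freq)
  g2 <- sample.int(length(freq), n, TRUE, prob = freq)
  calls <- bits[g1, , drop = FALSE] + bits[g2, , drop = FALSE]
  list(geno = toy_geno(calls, alleles), g1 = g1, g2 = g2, bits = bits)
}

# naive dense GLS oracle for the weighted polygenic model
gls_oracle <- function(y, X, A_sub, rel, sigma2_a, sigma2_e) {
  V <- A_sub * sigma2_a + diag(1 / rel) * sigma2_e
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  list(beta = drop(beta), vcov = solve(XtVX))
}

# two-SNP maximum-likelihood haplotype frequencies by grid search over the
# single free parameter f(AB) at fixed (ML) allele frequencies
em_grid_oracle_2snp <- function(calls, grid_n = 200001) {
  stopifnot(ncol(calls) == 2)
  calls <- calls[rowSums(is.na(calls)) == 0, , drop = FALSE]
  pA <- 1 - mean(calls[, 1]) / 2   # frequency of allele1 at locus 1
  pB <- 1 - mean(calls[, 2]) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  fab <- seq(lo, hi, length.out = grid_n)
  f <- cbind(AB = fab, Ab = pA - fab, aB = pB - fab, ab = 1 - pA - pB + fab)
  f <- pmax(f, 0)
  ll <- numeric(length(fab))
  key <- paste(calls[, 1], calls[, 2])
  tab <- table(key)
  for (pat in names(tab)) {
    gg <- as.integer(strsplit(pat, " ")[[1]])
    # genotype probability as the sum over consistent phase pairs
    pr <- switch(paste0(gg[1], gg[2]),
      "00" = f[, "AB"]^2, "02" = f[, "Ab"]^2,
      "20" = f[, "aB"]^2, "22" = f[, "ab"]^2,
      "01" = 2 * f[, "AB"] * f[, "Ab"],
      "21" = 2 * f[, "aB"] * f[, "ab"],
      "10" = 2 * f[, "AB"] * f[, "aB"],
      "12" = 2 * f[, "Ab"] * f[, "ab"],
      "11" = 2 * f[, "AB"] * f[, "ab"] + 2 * f[, "Ab"] * f[, "aB"])
    ll <- ll + tab[[pat]] * log(pmax(pr, 1e-300))
  }
  f[which.max(ll), ]
}

# enumeration oracle for qualifying contiguous D' intervals
enumerate_blocks_oracle <- function(DP, INF, thr, frac) {
  m <- nrow(DP)
  out <- list()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    sel <- i:j
    ut <- which(upper.tri(diag(length(sel))), arr.ind = TRUE)
    inf <- INF[sel, sel][ut]
    if (sum(inf) < 1) next
    fr <- sum(DP[sel, sel][ut][inf] > thr, na.rm = TRUE) / sum(inf)
    if (fr >= frac) out[[length(out) + 1]] <- c(i, j)
  }
  out
}
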