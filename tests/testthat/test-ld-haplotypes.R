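test_that("d_prime matches hand arithmetic and boundary cases", {
  # only coupling gametes -> complete LD
  expect_equal(d_prime(c(0.6, 0, 0, 0.4))$Dprime, 1)
  # independence -> D' = 0
  expect_equal(d_prime(c(0.35, 0.35, 0.15, 0.15))$Dprime, 0)
  # hand oracle: pA = pB = 0.6, D = 0.5 - 0.36 = 0.14, Dmax = 0.24
  dp <- d_prime(c(0.5, 0.1, 0.1, 0.3))
  expect_equal(dp$D, 0.14)
  expect_equal(dp$Dprime, 0.14 / 0.24)
  expect_error(d_prime(c(0.7, 0.3, 0, 0)), "monomorphic")
})

test_that("d_prime is symmetric in loci and invariant to allele relabeling", {
  f <- c(0.42, 0.18, 0.25, 0.15)
  # swap loci: (AB, Ab, aB, ab) -> (BA, Ba, bA, ba) = reorder to (AB, aB, Ab, ab)
  expect_equal(d_prime(f)$Dprime, d_prime(f[c(1, 3, 2, 4)])$Dprime)
  # relabel locus-1 alleles: rows swap
  expect_equal(d_prime(f)$Dprime, d_prime(f[c(3, 4, 1, 2)])$Dprime)
  # relabel locus-2 alleles: columns swap
  expect_equal(d_prime(f)$Dprime, d_prime(f[c(2, 1, 4, 3)])$Dprime)
})

test_that("EM equals direct gamete counting when phase is unambiguous", {
  # every individual homozygous at >= 1 of 2 SNPs: no double heterozygotes
  calls <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2), c(0, 1), c(1, 0),
                 c(2, 1), c(1, 2), c(0, 0))
  g <- toy_geno(calls)
  em <- em_haplotype_frequencies(g, c("s01", "s02"))
  # count gametes directly: each row contributes two known haplotypes
  expect_true(em$converged)
  counted <- c("AA" = 0, "AB" = 0, "BA" = 0, "BB" = 0)
  for (i in seq_len(nrow(calls))) {
    gg <- calls[i, ]
    h <- function(b) paste(ifelse(b == 1, "B", "A"), collapse = "")
    het <- which(gg == 1)
    b1 <- as.integer(gg == 2); b2 <- b1
    if (length(het)) { b1[het] <- 0; b2[het] <- 1 }
    counted[h(b1)] <- counted[h(b1)] + 1
    counted[h(b2)] <- counted[h(b2)] + 1
  }
  counted <- counted / sum(counted)
  expect_equal(em$freq[names(counted)[counted > 0]],
               counted[counted > 0], tolerance = 1e-6)
})

test_that("EM matches grid-search likelihood maximization with ambiguity", {
  # a few double heterozygotes in a background of known haplotypes
  set.seed(11)
  calls <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c(2, 2), 10), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 2), 6), ncol = 2, byrow = TRUE),
                 matrix(rep(c(1, 1), 3), ncol = 2, byrow = TRUE))
  g <- toy_geno(calls)
  em <- em_haplotype_frequencies(g, c("s01", "s02"), tol = 1e-10)
  oracle <- em_grid_oracle_2snp(calls)
  key <- c(AA = "AB", AB = "Ab", BA = "aB", BB = "ab")
  for (h in names(em$freq))
    expect_equal(unname(em$freq[h]), unname(oracle[key[h]]), tolerance = 1e-4)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  for (seed in 1:5) {
    sim <- iid_gamete_geno(c("AAA", "ABB", "BAB", "BBA"),
                           c(0.4, 0.3, 0.2, 0.1), 80, seed)
    em <- em_haplotype_frequencies(sim$geno, sim$geno$map$snp)
    expect_true(all(diff(em$loglik_trace) > -1e-9))
  }
})

test_that("EM recovers iid-gamete frequencies within 3 binomial s.e.", {
  haps <- c("AA", "AB", "BA", "BB")
  freq <- c(0.45, 0.25, 0.2, 0.1)
  n <- 638
  ok <- logical(200)
  for (s in 1:200) {
    sim <- iid_gamete_geno(haps, freq, n, seed = 1000 + s)
    em <- em_haplotype_frequencies(sim$geno, sim$geno$map$snp)
    f <- setNames(rep(0, 4), haps)
    f[names(em$freq)] <- em$freq
    se <- sqrt(freq * (1 - freq) / (2 * n))
    ok[s] <- all(abs(f - freq) <= 3 * se)
  }
  expect_gte(mean(ok), 0.95)
})

test_that("EM excludes individuals with missing calls in the block only", {
  calls <- rbind(c(0, 0), c(NA, 1), c(2, 2))
  g <- toy_geno(calls)
  em <- em_haplotype_frequencies(g, c("s01", "s02"))
  expect_equal(em$ids, c("i001", "i003"))
  expect_equal(em$excluded, "i002")
  expect_error(em_haplotype_frequencies(toy_geno(cbind(NA_integer_, NA_integer_)),
                                        c("s01", "s02")), "no individuals")
})

test_that("find_blocks recovers simple LD structures", {
  # two haplotypes over 5 SNPs: all pairwise D' = 1 -> one block of 5
  sim <- iid_gamete_geno(c("AAAAA", "BBBBB"), c(0.6, 0.4), 120, seed = 5)
  bl <- find_blocks(sim$geno)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$snps, sim$geno$map$snp)
  # two independent 3-SNP clusters -> two blocks
  set.seed(6)
  left <- iid_gamete_geno(c("AAA", "BBB"), c(0.5, 0.5), 300, seed = 6)
  right <- iid_gamete_geno(c("AAA", "BBB"), c(0.5, 0.5), 300, seed = 7)
  calls <- cbind(left$geno$calls, right$geno$calls)
  g <- toy_geno(calls)
  bl <- find_blocks(g)
  expect_length(bl, 2)
  expect_equal(bl[[1]]$snps, g$map$snp[1:3])
  expect_equal(bl[[2]]$snps, g$map$snp[4:6])
  expect_equal(find_blocks(toy_geno(cbind(c(0L, 1L, 2L)))), list())
})

test_that("block qualification fraction uses >= at the boundary, matching enumeration", {
  # constructed D' matrix over 9 SNPs: within SNPs 1..5 exactly 9/10 pairs
  # strong; elsewhere weak
  m <- 9
  DP <- matrix(0.1, m, m); diag(DP) <- 1
  strong <- which(upper.tri(diag(5)), arr.ind = TRUE)
  for (r in seq_len(nrow(strong))) DP[strong[r, 1], strong[r, 2]] <- 0.95
  DP[1, 2] <- 0.5  # one weak pair inside the candidate
  DP[lower.tri(DP)] <- t(DP)[lower.tri(DP)]
  INF <- matrix(TRUE, m, m); diag(INF) <- FALSE
  snps <- sprintf("s%02d", 1:m)
  ld <- list(Dprime = DP, informative = INF, snps = snps)
  g <- toy_geno(matrix(rep(c(0L, 1L, 2L), m), ncol = m))
  bl <- find_blocks(g, dprime_threshold = 0.75, strong_fraction = 0.9, ld = ld)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$snps, snps[1:5])
  expect_equal(bl[[1]]$frac_strong, 0.9)
  # enumeration oracle agrees that [1,5] qualifies and [1,6] does not
  qual <- enumerate_blocks_oracle(DP, INF, 0.75, 0.9)
  spans <- vapply(qual, paste, character(1), collapse = "-")
  expect_true("1-5" %in% spans)
  expect_false("1-6" %in% spans)
})

test_that("rare haplotypes pool per the > 5% rule on the published tables", {
  b1 <- hal_block1()
  po <- pool_rare_haplotypes(b1$haplotype, b1$frequency_pct / 100)
  expect_equal(sum(!po$pooled), 5)
  expect_equal(po$k, 6)
  expect_equal(unname(po$class_freq["pooled"]), 0.0548, tolerance = 1e-10)
  b2 <- hal_block2()
  po2 <- pool_rare_haplotypes(b2$haplotype, b2$frequency_pct / 100)
  expect_equal(po2$k, 3)
  expect_false(any(po2$pooled))
  expect_false("pooled" %in% po2$classes)
  expect_error(pool_rare_haplotypes(letters[1:25], rep(0.04, 25)),
               "no distinguishable")
})

test_that("dosage design gives exact counts without ambiguity and rows sum to 2", {
  sim <- iid_gamete_geno(c("AAA", "BBB", "ABA"), c(0.5, 0.3, 0.2), 150, seed = 9)
  blk <- build_haplotype_block(sim$geno, sim$geno$map$snp, threshold = 0.05)
  expect_true(all(abs(rowSums(blk$design) - 2) < 1e-9))
  # homozygote for a kept haplotype: 2 in that column
  hom <- which(sim$g1 == 1 & sim$g2 == 1)[1]
  if (!is.na(hom)) {
    id <- sim$geno$ids[hom]
    expect_equal(unname(blk$design[id, "AAA"]), 2)
    expect_equal(sum(blk$design[id, ]), 2)
  }
  # heterozygote at a single site (AAA/ABA) has exactly one phase: 1 and 1
  het <- which((sim$g1 == 1 & sim$g2 == 3) | (sim$g1 == 3 & sim$g2 == 1))[1]
  if (!is.na(het)) {
    id <- sim$geno$ids[het]
    expect_equal(unname(blk$design[id, c("AAA", "ABA")]), c(1, 1))
  }
})

test_that("ambiguous dosages match the brute-force phase posterior", {
  # 2-SNP double heterozygote: posterior between AB/ab and Ab/aB phases
  calls <- rbind(matrix(rep(c(0, 0), 12), ncol = 2, byrow = TRUE),
                 matrix(rep(c(2, 2), 8), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 2), 5), ncol = 2, byrow = TRUE),
                 matrix(rep(c(2, 0), 5), ncol = 2, byrow = TRUE),
                 c(1, 1))
  g <- toy_geno(calls)
  em <- em_haplotype_frequencies(g, c("s01", "s02"), tol = 1e-12)
  po <- pool_rare_haplotypes(em$haplotypes, unname(em$freq), threshold = 0.0)
  X <- haplotype_dosage_design(em, po)
  f <- em$freq
  # brute force: P(AB/ab) over the two consistent phase pairs
  w_coupling <- (f["AA"] * f["BB"]) / (f["AA"] * f["BB"] + f["AB"] * f["BA"])
  i <- nrow(calls)
  expect_equal(unname(X[i, "AA"]), unname(w_coupling), tolerance = 1e-8)
  expect_equal(unname(X[i, "BB"]), unname(w_coupling), tolerance = 1e-8)
  expect_equal(sum(X[i, ]), 2, tolerance = 1e-12)
})

test_that("EM tracks realized gamete frequencies in the half-sib design", {
  cfg <- block1_sim_config(seed = 21)
  d <- simulate_population(cfg)
  em <- em_haplotype_frequencies(d$genotypes, d$genotypes$map$snp)
  # realized daughter gamete counts from the simulation truth
  th <- d$truth$hap
  hap_of <- cfg$block_spec$haplotypes
  realized <- table(factor(hap_of[c(th$daughter_sire_hap, th$daughter_dam_hap)],
                           levels = hap_of))
  realized <- realized / sum(realized)
  # sires are genotyped too; compare on shared support with a loose bound
  for (h in names(realized)[realized > 0.05]) {
    expect_lt(abs(em$freq[h] - realized[[h]]), 0.05)
  }
})
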