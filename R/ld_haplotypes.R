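#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies over a small set of SNPs by the
#' expectation-maximisation algorithm over all phase configurations
#' consistent with each multilocus genotype. Individuals with a missing call
#' at any member SNP are excluded. Frequencies are initialised at linkage
#' equilibrium (products of sample allele frequencies), which makes the run
#' deterministic; the log-likelihood is non-decreasing across iterations.
#'
#' @param g a [genotype_matrix()].
#' @param snps character vector of 2 or more member SNP ids (at most 14, so
#'   that the haplotype space stays enumerable).
#' @param tol convergence threshold on the maximum absolute frequency change
#'   per iteration (default `1e-6`).
#' @param max_iter iteration cap (default 1000); hitting it flags
#'   `converged = FALSE` rather than raising an error.
#' @return list of class `"hap_em"`: `snps`, `haplotypes` (allele strings),
#'   `hap_bits` (0/1 matrix, copies of allele2 per site), `freq` (named,
#'   sums to 1), `ids` (individuals used), `excluded` (ids dropped for
#'   missingness), `posteriors` (per-individual data.frame of compatible
#'   phase pairs `h1`, `h2` and posterior weight `w`), `loglik`, `n_iter`,
#'   `converged`.
#' @export
em_haplotype_frequencies <- function(g, snps, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(g, "genotype_matrix"))
  snps <- as.character(snps)
  if (!all(snps %in% g$map$snp))
    stop("unknown SNP id(s): ", paste(setdiff(snps, g$map$snp), collapse = ", "))
  m <- length(snps)
  if (m < 1) stop("need at least one SNP")
  if (m > 14) stop("haplotype space too large (> 14 SNPs)")
  X <- g$calls[, snps, drop = FALSE]
  keep <- rowSums(is.na(X)) == 0
  if (!any(keep)) stop("no individuals without missing calls in the block")
  ids <- g$ids[keep]
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)

  # group individuals by multilocus genotype pattern
  pat_key <- apply(X, 1, paste, collapse = "")
  patterns <- unique(pat_key)
  pat_of <- match(pat_key, patterns)
  pat_geno <- X[match(patterns, pat_key), , drop = FALSE]
  pat_n <- tabulate(pat_of, nbins = length(patterns))

  # enumerate compatible unordered phase pairs per pattern; haplotypes are
  # bit vectors (copies of allele2); first heterozygous site of h1 fixed to 0
  # so each unordered heterozygous pair appears once
  hap_key <- new.env(hash = TRUE)
  hap_bits <- list()
  hap_index <- function(bits) {
    k <- paste(bits, collapse = "")
    i <- hap_key[[k]]
    if (is.null(i)) {
      i <- length(hap_bits) + 1L
      hap_bits[[i]] <<- bits
      hap_key[[k]] <- i
    }
    i
  }
  pat_pairs <- vector("list", length(patterns))
  for (pi in seq_along(patterns)) {
    geno <- pat_geno[pi, ]
    het <- which(geno == 1L)
    base <- as.integer(geno == 2L)
    if (length(het) == 0) {
      i <- hap_index(base)
      pat_pairs[[pi]] <- list(h1 = i, h2 = i, mult = 1)
    } else {
      nh <- length(het)
      nconf <- 2L^(nh - 1L)
      h1v <- integer(nconf); h2v <- integer(nconf)
      for (conf in seq_len(nconf) - 1L) {
        bits1 <- base; bits2 <- base
        # first het site: h1 carries allele1 (0), h2 carries allele2 (1)
        bits1[het[1]] <- 0L; bits2[het[1]] <- 1L
        if (nh > 1) {
          assign1 <- as.integer(intToBits(conf))[seq_len(nh - 1L)]
          bits1[het[-1]] <- assign1
          bits2[het[-1]] <- 1L - assign1
        }
        h1v[conf + 1L] <- hap_index(bits1)
        h2v[conf + 1L] <- hap_index(bits2)
      }
      pat_pairs[[pi]] <- list(h1 = h1v, h2 = h2v, mult = 2)
    }
  }
  H <- length(hap_bits)
  B <- do.call(rbind, hap_bits)

  # linkage-equilibrium initialisation from sample allele frequencies
  p2 <- colMeans(X) / 2
  f <- apply(B, 1, function(b) prod(ifelse(b == 1L, p2, 1 - p2)))
  if (sum(f) <= 0) f <- rep(1, H)
  f <- f / sum(f)

  loglik <- -Inf
  loglik_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cnt <- numeric(H)
    ll <- 0
    for (pi in seq_along(patterns)) {
      pp <- pat_pairs[[pi]]
      pr <- f[pp$h1] * f[pp$h2] * pp$mult
      s <- sum(pr)
      if (s <= 0) { pr <- rep(1, length(pr)); s <- length(pr) }
      w <- pr / s * pat_n[pi]
      cnt_add <- c(pp$h1, pp$h2)
      cnt <- cnt + tabulate_weighted(cnt_add, c(w, w), H)
      ll <- ll + pat_n[pi] * log(s)
    }
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    loglik <- ll
    loglik_trace <- c(loglik_trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }

  # per-individual posterior phase weights under the final frequencies
  posteriors <- vector("list", n)
  pat_post <- lapply(seq_along(patterns), function(pi) {
    pp <- pat_pairs[[pi]]
    pr <- f[pp$h1] * f[pp$h2] * pp$mult
    s <- sum(pr)
    if (s <= 0) pr <- rep(1 / length(pr), length(pr)) else pr <- pr / s
    data.frame(h1 = pp$h1, h2 = pp$h2, w = pr)
  })
  for (i in seq_len(n)) posteriors[[i]] <- pat_post[[pat_of[i]]]
  names(posteriors) <- ids

  alle <- g$map[match(snps, g$map$snp), c("allele1", "allele2")]
  hap_strings <- apply(B, 1, function(b)
    paste(ifelse(b == 1L, alle$allele2, alle$allele1), collapse = ""))
  # drop numerically-zero candidates (phase configurations the EM ruled out)
  keep_h <- which(f > 1e-8)
  ord <- keep_h[order(f[keep_h], decreasing = TRUE)]
  f <- f[ord] / sum(f[ord])
  B <- B[ord, , drop = FALSE]
  hap_strings <- hap_strings[ord]
  remap <- rep(NA_integer_, H)
  remap[ord] <- seq_along(ord)
  posteriors <- lapply(posteriors, function(d) {
    d$h1 <- remap[d$h1]; d$h2 <- remap[d$h2]
    d <- d[!is.na(d$h1) & !is.na(d$h2), , drop = FALSE]
    d$w <- d$w / sum(d$w)
    d
  })
  structure(list(snps = snps,
                 haplotypes = hap_strings,
                 hap_bits = B,
                 freq = setNames(f, hap_strings),
                 ids = ids,
                 excluded = g$ids[!keep],
                 posteriors = posteriors,
                 loglik = loglik, loglik_trace = loglik_trace,
                 n_iter = it, converged = converged),
            class = "hap_em")
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Two-locus D and D-prime from haplotype frequencies
#'
#' Given the four two-locus haplotype frequencies (order `AB, Ab, aB, ab`
#' where `A`/`a` are the alleles at the first locus), computes the signed
#' disequilibrium `D = p(AB) - p(A) p(B)` and the normalised
#' `D' = |D| / Dmax`, where `Dmax = min(p(A) p(b), p(a) p(B))` for `D > 0`
#' and `min(p(A) p(B), p(a) p(b))` for `D < 0`. `D' = 0` is returned for
#' `D = 0`; a monomorphic locus is an error, not `D' = 0`.
#'
#' @param pair_freqs numeric vector of 4 frequencies summing to 1.
#' @return list with `D`, `Dprime`, `pA`, `pB`, `hap_freqs`.
#' @export
d_prime <- function(pair_freqs) {
  f <- as.numeric(pair_freqs)
  stopifnot(length(f) == 4, all(f >= -1e-12))
  if (abs(sum(f) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  f <- pmax(f, 0); f <- f / sum(f)
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("D' undefined: monomorphic locus")
  D <- f[1] - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  list(D = D, Dprime = min(Dprime, 1), pA = pA, pB = pB, hap_freqs = f)
}

#' Pairwise LD between two SNPs
#'
#' Estimates the four two-locus haplotype frequencies by [em_haplotype_frequencies()]
#' and derives [d_prime()]. The pair is "informative" when both SNPs have
#' MAF at or above `maf_min` (among the individuals used) and the EM
#' converged.
#'
#' @param g a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @param maf_min informativeness threshold on both MAFs (default 0.05).
#' @return list of class `"ld_pair"`: `snp_a`, `snp_b`, `hap_freqs`, `D`,
#'   `Dprime`, `informative`, `converged`, `n`.
#' @export
ld_pair <- function(g, snp_a, snp_b, maf_min = 0.05) {
  em <- em_haplotype_frequencies(g, c(snp_a, snp_b))
  # order frequencies as (AB, Ab, aB, ab): A = allele1 at snp_a, B = allele1 at snp_b
  key <- apply(em$hap_bits, 1, paste, collapse = "")
  f4 <- setNames(numeric(4), c("00", "01", "10", "11"))
  f4[key] <- em$freq
  mafs <- vapply(c(snp_a, snp_b), function(s) {
    x <- g$calls[em$ids, s]
    p <- mean(x) / 2
    min(p, 1 - p)
  }, numeric(1))
  dp <- tryCatch(d_prime(unname(f4)), error = function(e) NULL)
  structure(list(snp_a = snp_a, snp_b = snp_b,
                 hap_freqs = f4,
                 D = if (is.null(dp)) NA_real_ else dp$D,
                 Dprime = if (is.null(dp)) NA_real_ else dp$Dprime,
                 informative = !is.null(dp) && em$converged && all(mafs >= maf_min),
                 converged = em$converged,
                 n = length(em$ids)),
            class = "ld_pair")
}

#' Pairwise D-prime matrix
#'
#' @param g a [genotype_matrix()].
#' @param snps SNP ids (default all, ordered by map position).
#' @param maf_min informativeness threshold passed to [ld_pair()].
#' @return list with `Dprime` (symmetric matrix, `NA` on failures),
#'   `informative` (logical matrix), `snps`.
#' @export
ld_matrix <- function(g, snps = NULL, maf_min = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(snps)) {
    ord <- order(g$map$pos)
    snps <- g$map$snp[ord]
  }
  m <- length(snps)
  DP <- matrix(NA_real_, m, m, dimnames = list(snps, snps))
  INF <- matrix(FALSE, m, m, dimnames = list(snps, snps))
  diag(DP) <- 1
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      lp <- tryCatch(ld_pair(g, snps[i], snps[j], maf_min = maf_min),
                     error = function(e) NULL)
      if (!is.null(lp)) {
        DP[i, j] <- DP[j, i] <- lp$Dprime
        INF[i, j] <- INF[j, i] <- lp$informative
      }
    }
  }
  list(Dprime = DP, informative = INF, snps = snps)
}

#' Detect haplotype blocks from pairwise D-prime
#'
#' A contiguous run of two or more SNPs (in map order) qualifies as a block
#' when at least `strong_fraction` of its informative pairwise comparisons
#' have `D' > dprime_threshold` (and it has at least one informative pair).
#' Blocks are claimed greedily, longest first and left to right among equal
#' lengths, and do not overlap.
#'
#' @param g a [genotype_matrix()].
#' @param dprime_threshold strong-LD threshold on D' (default 0.75).
#' @param strong_fraction required fraction of strong informative pairs
#'   (default 0.9).
#' @param maf_min informativeness threshold (default 0.05).
#' @param ld optional precomputed [ld_matrix()] result.
#' @return list of blocks, each a list with `snps`, `chrom`, `start_idx`,
#'   `end_idx`, `frac_strong`.
#' @export
find_blocks <- function(g, dprime_threshold = 0.75, strong_fraction = 0.9,
                        maf_min = 0.05, ld = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(ld)) ld <- ld_matrix(g, maf_min = maf_min)
  snps <- ld$snps
  m <- length(snps)
  if (m < 2) return(list())
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sel <- i:j
    ut <- which(upper.tri(matrix(0, length(sel), length(sel))), arr.ind = TRUE)
    inf <- ld$informative[sel, sel][ut]
    dp <- ld$Dprime[sel, sel][ut]
    n_inf <- sum(inf)
    if (n_inf < 1) next
    frac <- sum(dp[inf] > dprime_threshold, na.rm = TRUE) / n_inf
    if (frac >= strong_fraction)
      cand[[length(cand) + 1L]] <- list(start = i, end = j, frac = frac)
  }
  if (!length(cand)) return(list())
  lens <- vapply(cand, function(b) b$end - b$start + 1L, integer(1))
  starts <- vapply(cand, function(b) b$start, integer(1))
  ord <- order(-lens, starts)
  taken <- rep(FALSE, m)
  blocks <- list()
  for (k in ord) {
    b <- cand[[k]]
    sel <- b$start:b$end
    if (any(taken[sel])) next
    taken[sel] <- TRUE
    member <- snps[sel]
    blocks[[length(blocks) + 1L]] <-
      list(snps = member,
           chrom = g$map$chrom[match(member[1], g$map$snp)],
           start_idx = b$start, end_idx = b$end, frac_strong = b$frac)
  }
  bs <- vapply(blocks, function(b) b$start_idx, integer(1))
  blocks[order(bs)]
}

#' Pool rare haplotypes into a single class
#'
#' Haplotypes with frequency strictly greater than `threshold` are kept as
#' distinguishable classes; all others are merged into one pooled class whose
#' frequency is their sum. The number of classes is then
#' `k = #kept + (1 if any pooled)`.
#'
#' @param haplotypes character vector of haplotype labels.
#' @param frequencies numeric vector summing to 1 (a small tolerance is
#'   allowed for tables given at printed precision).
#' @param threshold pooling threshold (default 0.05).
#' @return list with `haplotypes`, `frequencies`, `pooled` (logical mask of
#'   pooled haplotypes), `classes` (kept labels, plus `"pooled"` last when
#'   any haplotype was pooled), `class_freq`, `k`, `threshold`.
#' @export
pool_rare_haplotypes <- function(haplotypes, frequencies, threshold = 0.05) {
  stopifnot(length(haplotypes) == length(frequencies), all(frequencies >= 0))
  if (abs(sum(frequencies) - 1) > 0.02)
    stop("haplotype frequencies must sum to 1 (got ", round(sum(frequencies), 4), ")")
  keep <- frequencies > threshold
  if (!any(keep))
    stop("no distinguishable haplotype: all frequencies <= ", threshold)
  classes <- haplotypes[keep]
  class_freq <- frequencies[keep]
  if (any(!keep)) {
    classes <- c(classes, "pooled")
    class_freq <- c(class_freq, sum(frequencies[!keep]))
  }
  list(haplotypes = haplotypes, frequencies = frequencies,
       pooled = !keep, classes = classes,
       class_freq = setNames(class_freq, classes),
       k = length(classes), threshold = threshold)
}

#' Per-individual expected haplotype-class dosages
#'
#' Builds the n x k haplotype trend regression design: entry (i, j) is the
#' expected number of copies (0-2) of haplotype class j carried by individual
#' i under the EM posterior phase weights; the pooled class accumulates all
#' pooled haplotypes. Each row sums to 2. With `hard = TRUE` the single most
#' probable phase configuration is counted instead (integer dosages).
#'
#' @param em a [em_haplotype_frequencies()] fit.
#' @param pooling a [pool_rare_haplotypes()] result on the same haplotypes.
#' @param hard use the best phase configuration instead of the posterior
#'   expectation (default `FALSE`).
#' @return numeric matrix, individuals x classes (rownames ids, colnames
#'   classes).
#' @export
haplotype_dosage_design <- function(em, pooling, hard = FALSE) {
  stopifnot(inherits(em, "hap_em"))
  if (!identical(pooling$haplotypes, em$haplotypes))
    stop("pooling was computed on different haplotypes than the EM fit")
  k <- pooling$k
  cls <- ifelse(pooling$pooled, k, match(em$haplotypes, pooling$classes))
  n <- length(em$ids)
  X <- matrix(0, n, k, dimnames = list(em$ids, pooling$classes))
  for (i in seq_len(n)) {
    po <- em$posteriors[[i]]
    if (hard) {
      b <- which.max(po$w)
      X[i, cls[po$h1[b]]] <- X[i, cls[po$h1[b]]] + 1
      X[i, cls[po$h2[b]]] <- X[i, cls[po$h2[b]]] + 1
    } else {
      for (r in seq_len(nrow(po))) {
        X[i, cls[po$h1[r]]] <- X[i, cls[po$h1[r]]] + po$w[r]
        X[i, cls[po$h2[r]]] <- X[i, cls[po$h2[r]]] + po$w[r]
      }
    }
  }
  X
}

#' Build a haplotype block: EM frequencies, pooling and dosage design
#'
#' Convenience wrapper running [em_haplotype_frequencies()],
#' [pool_rare_haplotypes()] and [haplotype_dosage_design()] over a set of
#' member SNPs.
#'
#' @param g a [genotype_matrix()].
#' @param snps member SNP ids.
#' @param threshold pooling threshold (default 0.05).
#' @param hard hard phase assignment (default `FALSE`).
#' @param tol,max_iter EM controls.
#' @return list of class `"haplotype_block"`: `snps`, `haplotypes`,
#'   `frequencies`, `pooled`, `classes`, `class_freq`, `k`, `design`,
#'   `ids`, `em`.
#' @export
build_haplotype_block <- function(g, snps, threshold = 0.05, hard = FALSE,
                                  tol = 1e-6, max_iter = 1000) {
  em <- em_haplotype_frequencies(g, snps, tol = tol, max_iter = max_iter)
  pooling <- pool_rare_haplotypes(em$haplotypes, unname(em$freq),
                                  threshold = threshold)
  design <- haplotype_dosage_design(em, pooling, hard = hard)
  structure(list(snps = snps, haplotypes = em$haplotypes,
                 frequencies = unname(em$freq), pooled = pooling$pooled,
                 classes = pooling$classes, class_freq = pooling$class_freq,
                 k = pooling$k, design = design, ids = em$ids, em = em),
            class = "haplotype_block")
}

#' Write blocks as BED-like intervals
#'
#' Chromosome, 0-based half-open span covering the member SNPs, block name
#' and the member SNP ids (comma-separated).
#'
#' @param blocks output of [find_blocks()].
#' @param g the [genotype_matrix()] the blocks were found on.
#' @param path output path.
#' @export
write_blocks_bed <- function(blocks, g, path) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    pos <- g$map$pos[match(b$snps, g$map$snp)]
    data.frame(chrom = b$chrom, start = min(pos) - 1L, end = max(pos),
               name = paste0("block", i),
               snps = paste(b$snps, collapse = ","))
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a block's haplotype table as TSV
#'
#' Columns: haplotype string, frequency in percent, pooled flag.
#'
#' @param block a [build_haplotype_block()] result.
#' @param path output path.
#' @export
write_haplotype_table <- function(block, path) {
  out <- data.frame(haplotype = block$haplotypes,
                    frequency_pct = 100 * block$frequencies,
                    pooled = block$pooled)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
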