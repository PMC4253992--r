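#' Configuration for a synthetic half-sib daughter design
#'
#' Defaults emulate a paternal half-sib dairy design: 13 unrelated sires,
#' 638 daughters in families of 5-136 (mean about 49), each daughter with an
#' unrelated, ungenotyped dam. Genotypes are drawn either per SNP from
#' target minor-allele frequencies (`snp_panel`) or from multilocus
#' haplotype frequencies over a block (`block_spec`); the phenotype is a
#' noisy EBV with per-individual reliability.
#'
#' @param n_sires number of sire families (default 13).
#' @param n_daughters total daughters (default 638).
#' @param family_sizes explicit integer vector (length `n_sires`, summing to
#'   `n_daughters`) or `NULL` to sample sizes from a truncated
#'   negative-binomial matched to range 5-136 and mean `n_daughters/n_sires`.
#' @param snp_panel data.frame with columns `pos` and `maf` (ignored when
#'   `block_spec` is given).
#' @param block_spec optional list with `haplotypes` (character vector of
#'   allele strings over the member SNPs), `freq` (summing to 1), `pos`
#'   (member SNP positions) and optionally `alleles` (data.frame
#'   `allele1`/`allele2` per SNP; defaults to the distinct letters seen).
#' @param beta_snp named (by SNP id) or positional vector of true per-copy
#'   SNP effects in trait units (default none).
#' @param hap_effects optional named vector of true per-copy haplotype
#'   effects (names matching `block_spec$haplotypes`).
#' @param sigma2_a additive (polygenic) variance (default 1).
#' @param sigma2_e extra residual variance added on top of the
#'   reliability-implied EBV noise (default 0).
#' @param reliability_range range for the uniform reliability draw
#'   (default `c(0.4, 0.9)`).
#' @param seed integer seed; mandatory, drives every stochastic step.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_sires = 13, n_daughters = 638, family_sizes = NULL,
                       snp_panel = NULL, block_spec = NULL,
                       beta_snp = NULL, hap_effects = NULL,
                       sigma2_a = 1, sigma2_e = 0,
                       reliability_range = c(0.4, 0.9), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.null(snp_panel) && is.null(block_spec))
    stop("one of snp_panel or block_spec is required")
  if (!is.null(family_sizes)) {
    if (length(family_sizes) != n_sires)
      stop("family_sizes must have length n_sires")
    if (sum(family_sizes) != n_daughters)
      stop("family_sizes must sum to n_daughters")
    if (any(family_sizes < 1)) stop("family sizes must be >= 1")
  }
  if (!is.null(block_spec)) {
    if (abs(sum(block_spec$freq) - 1) > 1e-6)
      stop("block_spec frequencies must sum to 1")
    nch <- nchar(block_spec$haplotypes)
    if (length(unique(nch)) != 1)
      stop("block_spec haplotypes must have equal length")
    if (length(block_spec$pos) != nch[1])
      stop("block_spec pos must have one position per SNP in the haplotype strings")
    if (!is.null(hap_effects) &&
        !all(names(hap_effects) %in% block_spec$haplotypes))
      stop("hap_effects names must match block_spec haplotypes")
  }
  if (any(reliability_range <= 0) || any(reliability_range > 1) ||
      reliability_range[1] > reliability_range[2])
    stop("reliability_range must be increasing within (0, 1]")
  structure(list(n_sires = n_sires, n_daughters = n_daughters,
                 family_sizes = family_sizes, snp_panel = snp_panel,
                 block_spec = block_spec, beta_snp = beta_snp,
                 hap_effects = hap_effects, sigma2_a = sigma2_a,
                 sigma2_e = sigma2_e,
                 reliability_range = reliability_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# family sizes from a truncated negative binomial (size 2, mean = target),
# then +/-1 adjustments within [lo, hi] to hit the configured total exactly
sample_family_sizes <- function(n_sires, n_daughters, lo = 5, hi = 136) {
  mu <- n_daughters / n_sires
  sizes <- pmin(pmax(rnbinom(n_sires, size = 2, mu = mu), lo), hi)
  while (sum(sizes) != n_daughters) {
    gap <- n_daughters - sum(sizes)
    if (gap > 0) {
      j <- sample(which(sizes < hi), 1)
      sizes[j] <- sizes[j] + 1
    } else {
      j <- sample(which(sizes > lo), 1)
      sizes[j] <- sizes[j] - 1
    }
  }
  as.integer(sizes)
}

#' Simulate a half-sib daughter population
#'
#' Generates a pedigree (unrelated founder sires, one unrelated founder dam
#' per daughter), genotypes by gamete transmission (each daughter receives
#' one of her sire's two haplotypes and one dam haplotype;
#' recombination-free, appropriate for a short candidate-gene region), true
#' breeding values drawn jointly with covariance `A sigma2_a`, and EBV
#' phenotypes
#' `EBV = TBV + sum(effects x codes) + eps` with
#' `Var(eps) = ((1 - r)/r) sigma2_a + sigma2_e`, where the reliability `r`
#' is drawn uniformly from `reliability_range` — so that
#' `r = sigma2_a / (sigma2_a + Var(eps))` when `sigma2_e = 0`, the standard
#' approximation for treating EBVs as weighted observations.
#'
#' Deterministic given the seed; per-component sub-seeds are derived from
#' `cfg$seed` so components can be regenerated independently.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"sim_dataset"`: `pedigree`, `genotypes`
#'   ([genotype_matrix()], daughters and sires; dams are ungenotyped),
#'   `phenotypes` (data.frame `id`, `ebv`, `rel`; daughters only), `truth`
#'   (all generating parameters, realized family sizes, TBVs).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sub_seed <- function(k) (cfg$seed * 11L + k * 7919L) %% .Machine$integer.max

  set.seed(sub_seed(1L))
  sizes <- cfg$family_sizes
  if (is.null(sizes))
    sizes <- sample_family_sizes(cfg$n_sires, cfg$n_daughters)

  sires <- sprintf("S%02d", seq_len(cfg$n_sires))
  daughters <- sprintf("C%04d", seq_len(cfg$n_daughters))
  dams <- sprintf("D%04d", seq_len(cfg$n_daughters))
  sire_of <- rep(sires, sizes)
  ped <- pedigree(c(sires, dams, daughters),
                  c(rep(NA, cfg$n_sires + cfg$n_daughters), sire_of),
                  c(rep(NA, cfg$n_sires + cfg$n_daughters), dams))

  # founder haplotypes and gamete transmission
  set.seed(sub_seed(2L))
  if (!is.null(cfg$block_spec)) {
    bs <- cfg$block_spec
    m <- nchar(bs$haplotypes[1])
    hap_mat <- do.call(rbind, strsplit(bs$haplotypes, ""))
    alleles <- if (!is.null(bs$alleles)) bs$alleles else {
      data.frame(allele1 = apply(hap_mat, 2, function(a) sort(unique(a))[1]),
                 allele2 = apply(hap_mat, 2, function(a) {
                   u <- sort(unique(a)); if (length(u) > 1) u[2] else u[1]
                 }), stringsAsFactors = FALSE)
    }
    hap_bits <- t(apply(hap_mat, 1, function(h)
      as.integer(h == alleles$allele2)))
    draw_hap <- function(n) sample.int(length(bs$freq), n, replace = TRUE,
                                       prob = bs$freq)
    pos <- bs$pos
    snp_ids <- if (!is.null(bs$snp)) bs$snp else sprintf("snp%02d", seq_len(m))
  } else {
    sp <- cfg$snp_panel
    m <- nrow(sp)
    pos <- sp$pos
    snp_ids <- if (!is.null(sp$snp)) as.character(sp$snp)
               else sprintf("snp%02d", seq_len(m))
    alleles <- data.frame(allele1 = rep("A", m), allele2 = rep("B", m),
                          stringsAsFactors = FALSE)
  }

  n <- cfg$n_daughters
  if (!is.null(cfg$block_spec)) {
    sire_h <- matrix(draw_hap(2 * cfg$n_sires), ncol = 2)   # per sire
    dam_h <- matrix(draw_hap(2 * n), ncol = 2)              # per dam
    si <- match(sire_of, sires)
    from_sire <- sire_h[cbind(si, sample(c(1L, 2L), n, replace = TRUE))]
    from_dam <- dam_h[cbind(seq_len(n), sample(c(1L, 2L), n, replace = TRUE))]
    d_calls <- hap_bits[from_sire, , drop = FALSE] +
      hap_bits[from_dam, , drop = FALSE]
    s_calls <- hap_bits[sire_h[, 1], , drop = FALSE] +
      hap_bits[sire_h[, 2], , drop = FALSE]
    truth_hap <- list(sire_haplotypes = sire_h, daughter_sire_hap = from_sire,
                      daughter_dam_hap = from_dam)
  } else {
    # independent SNPs: per-gamete allele draws at the target MAFs
    maf <- cfg$snp_panel$maf
    gam <- function(nrow) {
      mm <- matrix(0L, nrow, m)
      for (j in seq_len(m)) mm[, j] <- rbinom(nrow, 1, maf[j])
      mm
    }
    sire_g1 <- gam(cfg$n_sires); sire_g2 <- gam(cfg$n_sires)
    si <- match(sire_of, sires)
    pick <- sample(c(TRUE, FALSE), n, replace = TRUE)
    from_sire <- ifelse(matrix(pick, n, m), sire_g1[si, , drop = FALSE],
                        sire_g2[si, , drop = FALSE])
    from_dam <- gam(n)
    d_calls <- from_sire + from_dam
    s_calls <- sire_g1 + sire_g2
    truth_hap <- NULL
  }
  geno <- genotype_matrix(rbind(d_calls, s_calls),
                          c(daughters, sires),
                          data.frame(snp = snp_ids, chrom = "5", pos = pos,
                                     allele1 = alleles$allele1,
                                     allele2 = alleles$allele2,
                                     stringsAsFactors = FALSE))

  # true breeding values jointly over the whole pedigree: TBV = L' z, A = L'L
  set.seed(sub_seed(3L))
  tbv <- setNames(rep(0, nrow(ped)), ped$id)
  if (cfg$sigma2_a > 0) {
    A <- build_A(ped)
    R <- chol(A + diag(1e-10, nrow(A)))
    tbv <- setNames(drop(crossprod(R, rnorm(nrow(A)))) * sqrt(cfg$sigma2_a),
                    rownames(A))
  }

  # genetic marker effects on the daughters' phenotypes
  d_idx <- match(daughters, geno$ids)
  eff <- rep(0, n)
  if (!is.null(cfg$beta_snp)) {
    b <- cfg$beta_snp
    jj <- if (!is.null(names(b))) match(names(b), snp_ids) else seq_along(b)
    for (k in seq_along(b))
      eff <- eff + b[k] * geno$calls[d_idx, jj[k]]
  }
  if (!is.null(cfg$hap_effects) && !is.null(cfg$block_spec)) {
    he <- cfg$hap_effects
    hidx <- match(names(he), cfg$block_spec$haplotypes)
    for (k in seq_along(he)) {
      eff <- eff + he[k] * ((truth_hap$daughter_sire_hap == hidx[k]) +
                              (truth_hap$daughter_dam_hap == hidx[k]))
    }
  }

  set.seed(sub_seed(4L))
  rel <- runif(n, cfg$reliability_range[1], cfg$reliability_range[2])
  noise_var <- (1 - rel) / rel * cfg$sigma2_a + cfg$sigma2_e
  ebv <- tbv[daughters] + eff + rnorm(n, sd = sqrt(noise_var))
  phen <- data.frame(id = daughters, ebv = unname(ebv), rel = rel,
                     stringsAsFactors = FALSE)

  structure(list(pedigree = ped, genotypes = geno, phenotypes = phen,
                 truth = list(config = cfg, family_sizes = sizes,
                              sire_of = sire_of, tbv = tbv,
                              marker_effect = eff, hap = truth_hap)),
            class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Emits PLINK `.ped`/`.map` genotypes, a pedigree TSV, a phenotype TSV
#' (`id`, `ebv`, `rel`) and the generating parameters as JSON
#' (`truth.json`). [read_dataset()] round-trips the genotype codes,
#' pedigree and phenotypes.
#'
#' @param d a [simulate_population()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of paths written.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    write_plink(d$genotypes, file.path(dir, "genotypes"),
                pedinfo = d$pedigree),
    pedigree = write_pedigree(d$pedigree, file.path(dir, "pedigree.tsv")),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"))
  write.table(d$phenotypes, paths[["phenotypes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- d$truth$config
  truth <- list(seed = cfg$seed, n_sires = cfg$n_sires,
                n_daughters = cfg$n_daughters,
                family_sizes = d$truth$family_sizes,
                sigma2_a = cfg$sigma2_a, sigma2_e = cfg$sigma2_e,
                reliability_range = cfg$reliability_range,
                beta_snp = cfg$beta_snp, hap_effects = cfg$hap_effects,
                block_spec = cfg$block_spec, snp_panel = cfg$snp_panel)
  writeLines(to_json(truth), paths[["truth"]])
  invisible(paths)
}

# minimal JSON writer for the truth record (atomic vectors, lists, data.frames)
to_json <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.null(x)) return("null")
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    if (is.null(names(x))) {
      items <- vapply(x, to_json, character(1), indent = paste0(indent, "  "))
      return(paste0("[", paste(items, collapse = ", "), "]"))
    }
    items <- vapply(seq_along(x), function(i)
      paste0('"', esc(names(x)[i]), '": ', to_json(x[[i]], paste0(indent, "  "))),
      character(1))
    return(paste0("{", paste(items, collapse = ", "), "}"))
  }
  if (is.character(x)) vals <- paste0('"', esc(x), '"')
  else if (is.logical(x)) vals <- ifelse(x, "true", "false")
  else vals <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (length(vals) == 1 && is.null(names(x))) return(vals)
  paste0("[", paste(vals, collapse = ", "), "]")
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `pedigree`, `genotypes`, `phenotypes`.
#' @export
read_dataset <- function(dir) {
  list(pedigree = read_pedigree(file.path(dir, "pedigree.tsv")),
       genotypes = read_plink(file.path(dir, "genotypes")),
       phenotypes = read.table(file.path(dir, "phenotypes.tsv"),
                               header = TRUE, stringsAsFactors = FALSE))
}
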