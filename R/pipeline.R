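#' Read genotypes from PLINK text or VCF input
#'
#' Thin front-end over [read_plink()] / [read_vcf_genotypes()] that also
#' orients the codes so 1 counts one copy of the minor allele in the loaded
#' sample (recorded in `attr(, "flipped")`).
#'
#' @param path `.ped` path (or prefix) for `format = "pedmap"`, VCF path for
#'   `format = "vcf"`.
#' @param format `"pedmap"` (default) or `"vcf"`.
#' @return a minor-allele-oriented [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("pedmap", "vcf")) {
  format <- match.arg(format)
  g <- switch(format,
              pedmap = read_plink(path),
              vcf = read_vcf_genotypes(path))
  orient_minor(g)
}

#' Run the full candidate-gene association workflow
#'
#' In order: per-SNP descriptive statistics with the Hardy-Weinberg test;
#' single-SNP weighted polygenic regression per trait (Wald df = 1);
#' D-prime haplotype block detection; rare-haplotype pooling; haplotype
#' trend regression per block per trait (Wald df = k - 1); and
#' Benjamini-Hochberg FDR correction over the declared test family.
#' Variance components are estimated once per trait by REML on the
#' intercept-only model and held fixed across the trait's tests.
#'
#' Inputs may be in-memory objects or file paths (pedigree TSV, PLINK
#' `.ped` prefix or VCF, phenotype TSV with columns `id` and, per trait,
#' `<trait>` and `<trait>_rel` — or `ebv`/`rel` for a single unnamed trait).
#' Individuals present in the genotype or phenotype data but absent from
#' the pedigree are added as founders with a warning.
#'
#' All result tables are written under `out_dir` (TSV), together with a
#' structured JSON log recording package version, seed, thresholds, the
#' FDR family definition and per-test sample sizes. Any stage failure
#' aborts with a stage-tagged error and removes partial outputs.
#'
#' @param genotypes a [genotype_matrix()] or path.
#' @param ped a [pedigree()] or path.
#' @param phenotypes a data.frame or path (see above).
#' @param traits trait names to analyse (default: all found).
#' @param geno_format `"pedmap"` or `"vcf"` when `genotypes` is a path.
#' @param dprime_threshold,strong_fraction,maf_min block-detection settings
#'   (defaults 0.75, 0.9, 0.05).
#' @param pool_threshold rare-haplotype pooling threshold (default 0.05).
#' @param fdr_alpha significance level on adjusted p-values (default 0.05).
#' @param fdr_family `"all"` (one family across SNPs, blocks and traits;
#'   default) or `"per_trait"`.
#' @param vc_mode `"reml"` or a list `list(sigma2_a=, sigma2_e=)` applied to
#'   every trait.
#' @param out_dir output directory (`NULL` for no files).
#' @param seed integer recorded in the log (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `"pipeline_run"`: `snp_summary`, `assoc_snp`,
#'   `blocks`, `hap_blocks`, `assoc_hap`, `vc` (per trait), `log`.
#' @export
run_pipeline <- function(genotypes, ped, phenotypes, traits = NULL,
                         geno_format = c("pedmap", "vcf"),
                         dprime_threshold = 0.75, strong_fraction = 0.9,
                         maf_min = 0.05, pool_threshold = 0.05,
                         fdr_alpha = 0.05, fdr_family = c("all", "per_trait"),
                         vc_mode = "reml", out_dir = NULL, seed = 1L) {
  fdr_family <- match.arg(fdr_family)
  geno_format <- match.arg(geno_format)
  stopifnot(dprime_threshold >= 0, dprime_threshold <= 1,
            strong_fraction >= 0, strong_fraction <= 1,
            pool_threshold >= 0, pool_threshold < 1)
  written <- character(0)
  stage <- "input"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (is.character(genotypes))
      genotypes <- read_genotypes(genotypes, geno_format)
    else genotypes <- orient_minor(genotypes)
    if (is.character(ped)) ped <- read_pedigree(ped)
    if (is.character(phenotypes))
      phenotypes <- read.table(phenotypes, header = TRUE,
                               stringsAsFactors = FALSE)
    ph_long <- pheno_long(phenotypes, traits)
    traits <- unique(ph_long$trait)

    # auto-add genotyped/phenotyped individuals missing from the pedigree
    extra <- setdiff(union(genotypes$ids, unique(ph_long$id)), ped$id)
    if (length(extra)) {
      warning(length(extra), " individual(s) absent from the pedigree ",
              "added as founders: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ...")
      ped <- pedigree(c(ped$id, extra),
                      c(ped$sire, rep(NA, length(extra))),
                      c(ped$dam, rep(NA, length(extra))))
    }

    stage <- "kinship"
    A <- build_A(ped)

    stage <- "snp_summary"
    summ <- snp_summary(genotypes)

    stage <- "variance_components"
    ctx_by_trait <- lapply(setNames(traits, traits), function(tr) {
      phtr <- ph_long[ph_long$trait == tr, ]
      mm_context(A, phtr$id, phtr$rel)
    })
    vc_by_trait <- lapply(setNames(traits, traits), function(tr) {
      if (!identical(vc_mode, "reml")) return(vc_mode)
      phtr <- ph_long[ph_long$trait == tr, ]
      reml_polygenic(ctx_by_trait[[tr]], phtr$ebv)
    })

    stage <- "assoc_snp"
    snp_rows <- list()
    for (tr in traits) {
      phtr <- ph_long[ph_long$trait == tr, c("id", "ebv", "rel")]
      for (s in genotypes$map$snp) {
        r <- test_snp(genotypes, phtr, A, s, vc = vc_by_trait[[tr]],
                      ctx = ctx_by_trait[[tr]])
        r$trait <- tr
        snp_rows[[length(snp_rows) + 1L]] <- r
      }
    }
    assoc_snp <- do.call(rbind, snp_rows)

    stage <- "blocks"
    ld <- ld_matrix(genotypes, maf_min = maf_min)
    blocks <- find_blocks(genotypes, dprime_threshold, strong_fraction,
                          maf_min = maf_min, ld = ld)

    stage <- "haplotypes"
    hap_blocks <- lapply(blocks, function(b)
      build_haplotype_block(genotypes, b$snps, threshold = pool_threshold))

    stage <- "assoc_hap"
    hap_rows <- list()
    for (tr in traits) {
      phtr <- ph_long[ph_long$trait == tr, c("id", "ebv", "rel")]
      for (i in seq_along(hap_blocks)) {
        r <- test_haplotype_block(hap_blocks[[i]], phtr, A,
                                  vc = vc_by_trait[[tr]],
                                  label = paste0("block", i))
        r$trait <- tr
        attr(r, "fit") <- NULL
        attr(r, "effects") <- NULL
        hap_rows[[length(hap_rows) + 1L]] <- r
      }
    }
    assoc_hap <- if (length(hap_rows)) do.call(rbind, hap_rows) else NULL

    stage <- "fdr"
    adj <- function(df) {
      if (is.null(df)) return(NULL)
      df$p_fdr <- NA_real_
      if (fdr_family == "per_trait") {
        for (tr in traits) {
          i <- df$trait == tr & !is.na(df$p_raw)
          df$p_fdr[i] <- fdr_adjust(df$p_raw[i])
        }
      }
      df
    }
    if (fdr_family == "all") {
      pall <- c(assoc_snp$p_raw, if (!is.null(assoc_hap)) assoc_hap$p_raw)
      ok <- !is.na(pall)
      pf <- rep(NA_real_, length(pall))
      pf[ok] <- fdr_adjust(pall[ok])
      ns <- nrow(assoc_snp)
      assoc_snp$p_fdr <- pf[seq_len(ns)]
      if (!is.null(assoc_hap)) assoc_hap$p_fdr <- pf[-seq_len(ns)]
    } else {
      assoc_snp <- adj(assoc_snp)
      assoc_hap <- adj(assoc_hap)
    }

    stage <- "output"
    log <- list(
      package = "haplomm",
      version = as.character(utils::packageVersion("haplomm")),
      seed = seed,
      thresholds = list(dprime_threshold = dprime_threshold,
                        strong_fraction = strong_fraction,
                        maf_min = maf_min, pool_threshold = pool_threshold,
                        fdr_alpha = fdr_alpha),
      fdr_family = paste0(fdr_family,
                          " (n_tests = ",
                          sum(!is.na(c(assoc_snp$p_raw,
                                       if (!is.null(assoc_hap)) assoc_hap$p_raw))),
                          ")"),
      traits = traits,
      vc = lapply(vc_by_trait, function(v)
        list(sigma2_a = v$sigma2_a, sigma2_e = v$sigma2_e)),
      n_used = setNames(as.list(assoc_snp$n_used),
                        paste(assoc_snp$trait, assoc_snp$test, sep = ":")))
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      wpath <- function(f) { p <- file.path(out_dir, f); written <<- c(written, p); p }
      write_snp_summary(summ, wpath("snp_summary.tsv"))
      write.table(assoc_snp, wpath("assoc_snp.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (length(blocks)) {
        write_blocks_bed(blocks, genotypes, wpath("blocks.bed"))
        for (i in seq_along(hap_blocks))
          write_haplotype_table(hap_blocks[[i]],
                                wpath(sprintf("haplotypes_block%d.tsv", i)))
      }
      if (!is.null(assoc_hap))
        write.table(assoc_hap, wpath("assoc_hap.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      dp <- ld$Dprime
      write.table(cbind(snp = rownames(dp), as.data.frame(dp)),
                  wpath("dprime.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      writeLines(to_json(log), wpath("run_log.json"))
    }
    structure(list(snp_summary = summ, assoc_snp = assoc_snp,
                   blocks = blocks, hap_blocks = hap_blocks,
                   assoc_hap = assoc_hap, vc = vc_by_trait, ld = ld,
                   log = log),
              class = "pipeline_run")
  }, error = on_fail)
}

# normalise phenotypes to long format: id, trait, ebv, rel
pheno_long <- function(phenotypes, traits = NULL) {
  stopifnot("id" %in% names(phenotypes))
  if (all(c("ebv", "rel") %in% names(phenotypes))) {
    tr <- if ("trait" %in% names(phenotypes)) phenotypes$trait else "trait"
    out <- data.frame(id = as.character(phenotypes$id), trait = tr,
                      ebv = phenotypes$ebv, rel = phenotypes$rel,
                      stringsAsFactors = FALSE)
  } else {
    cand <- setdiff(names(phenotypes), "id")
    tnames <- cand[paste0(cand, "_rel") %in% cand]
    if (!length(tnames))
      stop("phenotype table needs ebv/rel columns or <trait>/<trait>_rel pairs")
    out <- do.call(rbind, lapply(tnames, function(tr)
      data.frame(id = as.character(phenotypes$id), trait = tr,
                 ebv = phenotypes[[tr]], rel = phenotypes[[paste0(tr, "_rel")]],
                 stringsAsFactors = FALSE)))
  }
  if (!is.null(traits)) {
    out <- out[out$trait %in% traits, ]
    if (!nrow(out)) stop("no phenotype records for requested trait(s)")
  }
  out <- out[!is.na(out$ebv) & !is.na(out$rel), ]
  out
}
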