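make_instance <- function(n = 80, seed = 1, rel_range = c(0.4, 0.9)) {
  cfg <- sim_config(n_sires = 5, n_daughters = n,
                    snp_panel = data.frame(pos = c(100, 200), maf = c(0.3, 0.2)),
                    sigma2_a = 1, reliability_range = rel_range, seed = seed)
  d <- simulate_population(cfg)
  A <- build_A(d$pedigree)
  x <- as.numeric(d$genotypes$calls[match(d$phenotypes$id, d$genotypes$ids), 1])
  list(d = d, A = A, x = x, ph = d$phenotypes)
}

test_that("model degenerates to ordinary least squares without polygenic variance", {
  ins <- make_instance(seed = 2, rel_range = c(1, 1))
  ph <- ins$ph
  suppressWarnings(
    fit <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A,
                                     vc = list(sigma2_a = 0, sigma2_e = 1)))
  ols <- lm(ph$ebv ~ ins$x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$a_hat["C0001"]), 0)
})

test_that("MME solution equals the dense GLS oracle on random instances", {
  for (seed in 1:5) {
    n <- sample(40:200, 1)
    ins <- make_instance(n = n, seed = seed)
    ph <- ins$ph
    vc <- list(sigma2_a = runif(1, 0.5, 2), sigma2_e = runif(1, 0.3, 1.5))
    X <- cbind(1, snp = ins$x)
    orc <- gls_oracle(ph$ebv, X, ins$A[ph$id, ph$id], ph$rel,
                      vc$sigma2_a, vc$sigma2_e)
    f_gls <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A,
                                       vc = vc, engine = "gls")
    f_mme <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A,
                                       vc = vc, engine = "mme")
    expect_lt(max(abs(f_gls$beta - orc$beta)), 1e-8)
    expect_lt(max(abs(f_mme$beta - orc$beta)), 1e-8)
    expect_lt(max(abs(f_gls$vcov - orc$vcov)), 1e-8)
    expect_lt(max(abs(f_mme$vcov - orc$vcov)), 1e-8)
    expect_lt(max(abs(f_gls$a_hat - f_mme$a_hat)), 1e-6)
  }
})

test_that("estimates are invariant to jointly scaling both variance components", {
  ins <- make_instance(seed = 8)
  ph <- ins$ph
  f1 <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A,
                                  vc = list(sigma2_a = 0.7, sigma2_e = 0.9))
  f2 <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A,
                                  vc = list(sigma2_a = 1.4, sigma2_e = 1.8))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  # the plug-in sampling variance scales with sigma2_e, so the Wald statistic
  # is unchanged once sigma2_e is re-profiled from the residuals (as REML
  # does); equivalently vcov exactly doubles here
  expect_equal(f1$vcov["snp", "snp"] * 2, f2$vcov["snp", "snp"],
               tolerance = 1e-10)
  ctx <- mm_context(ins$A, ph$id, ph$rel)
  prof_wald <- function(s2a, s2e) {
    f <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A,
                                   vc = list(sigma2_a = s2a, sigma2_e = s2e))
    # re-profile the residual scale on the same lambda
    ty <- haplomm:::mm_rotate(ctx, ph$ebv)
    tX <- haplomm:::mm_rotate(ctx, cbind(1, ins$x))
    v <- s2a * ctx$d + s2e
    r <- ty - tX %*% solve(crossprod(tX, tX / v), crossprod(tX, ty / v))
    s2hat <- sum(r^2 / v) / (length(ty) - 2)
    f$beta["snp"]^2 / (f$vcov["snp", "snp"] * s2hat)
  }
  expect_equal(prof_wald(0.7, 0.9), prof_wald(1.4, 1.8), tolerance = 1e-9)
})

test_that("equal reliabilities rescale sigma2_e but leave p-values unchanged", {
  ins <- make_instance(seed = 12, rel_range = c(1, 1))
  ph <- ins$ph
  vc <- list(sigma2_a = 1, sigma2_e = 0.8)
  t_full <- test_snp(ins$d$genotypes, ph, ins$A, "snp01", vc = vc)
  ph_half <- ph; ph_half$rel <- rep(0.5, nrow(ph))
  # W doubles, so doubling sigma2_e reproduces the same V
  t_half <- test_snp(ins$d$genotypes, ph_half, ins$A, "snp01",
                     vc = list(sigma2_a = 1, sigma2_e = 0.4))
  expect_equal(t_full$p_raw, t_half$p_raw, tolerance = 1e-10)
  expect_equal(t_full$estimate, t_half$estimate, tolerance = 1e-10)
})

test_that("REML recovers variance components on average", {
  # fixed population; many phenotype draws at known vc (rel = 1 so the
  # generating model is exactly the analysis model)
  cfg <- sim_config(n_sires = 13, n_daughters = 300,
                    snp_panel = data.frame(pos = 100, maf = 0.3),
                    sigma2_a = 1, sigma2_e = 1, reliability_range = c(1, 1),
                    seed = 31)
  d <- simulate_population(cfg)
  A <- build_A(d$pedigree)
  ph <- d$phenotypes
  ctx <- mm_context(A, ph$id, ph$rel)
  Aph <- A[ph$id, ph$id]
  R <- chol(Aph + diag(1e-10, nrow(Aph)))
  set.seed(77)
  est <- t(replicate(40, {
    y <- drop(crossprod(R, rnorm(nrow(Aph)))) + rnorm(nrow(Aph))
    vc <- reml_polygenic(ctx, y)
    c(vc$sigma2_a, vc$sigma2_e)
  }))
  expect_equal(mean(est[, 1]), 1, tolerance = 0.25)
  expect_equal(mean(est[, 2]), 1, tolerance = 0.25)
})

test_that("test_snp is symmetric under allele-label swap and handles degenerate SNPs", {
  ins <- make_instance(seed = 14)
  ph <- ins$ph
  vc <- list(sigma2_a = 1, sigma2_e = 0.7)
  t1 <- test_snp(ins$d$genotypes, ph, ins$A, "snp01", vc = vc)
  g2 <- ins$d$genotypes
  g2$calls[, "snp01"] <- 2L - g2$calls[, "snp01"]
  t2 <- test_snp(g2, ph, ins$A, "snp01", vc = vc)
  # after minor-allele orientation the two codings test the same predictor
  expect_equal(t1$p_raw, t2$p_raw, tolerance = 1e-9)
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-9)
  # without re-orientation the slope is negated but the p-value identical
  f_a <- fit_weighted_animal_model(ph, cbind(snp = ins$x), ins$A, vc = vc)
  f_b <- fit_weighted_animal_model(ph, cbind(snp = 2 - ins$x), ins$A, vc = vc)
  expect_equal(unname(f_a$beta["snp"]), -unname(f_b$beta["snp"]),
               tolerance = 1e-9)
  expect_equal(f_a$vcov["snp", "snp"], f_b$vcov["snp", "snp"],
               tolerance = 1e-9)
  # monomorphic SNP: skipped with reason, not an error
  g3 <- ins$d$genotypes
  g3$calls[, "snp01"] <- 0L
  t3 <- test_snp(g3, ph, ins$A, "snp01", vc = vc)
  expect_true(t3$skipped)
  expect_match(t3$reason, "monomorphic")
  # constant phenotype: zero slope, Wald 0, p = 1
  ph0 <- ph; ph0$ebv <- 5
  t0 <- test_snp(ins$d$genotypes, ph0, ins$A, "snp01", vc = vc)
  expect_equal(t0$wald_chi2, 0, tolerance = 1e-12)
  expect_equal(t0$p_raw, 1)
})

test_that("a two-haplotype block test is equivalent to the tagging SNP test", {
  # two haplotypes over two SNPs in complete LD: dosage of one haplotype is
  # collinear with either member SNP, so df = 1 and p must match test_snp
  sim <- iid_gamete_geno(c("AA", "BB"), c(0.6, 0.4), 200, seed = 40)
  g <- sim$geno
  ped <- pedigree(g$ids, rep(NA, length(g$ids)), rep(NA, length(g$ids)))
  A <- build_A(ped)
  set.seed(41)
  ph <- data.frame(id = g$ids,
                   ebv = 0.3 * g$calls[, 1] + rnorm(length(g$ids)),
                   rel = runif(length(g$ids), 0.5, 1))
  vc <- list(sigma2_a = 0.5, sigma2_e = 1)
  blk <- build_haplotype_block(g, c("s01", "s02"))
  expect_equal(blk$k, 2)
  t_blk <- test_haplotype_block(blk, ph, A, vc = vc)
  t_snp <- test_snp(g, ph, A, "s01", vc = vc)
  expect_equal(t_blk$df, 1)
  expect_equal(t_blk$p_raw, t_snp$p_raw, tolerance = 1e-9)
  # k = 1 block: no contrast
  blk1 <- blk; blk1$k <- 1
  expect_error(test_haplotype_block(blk1, ph, A, vc = vc), "no contrast")
})

test_that("BH adjustment matches hand computation and preserves ordering", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  set.seed(50)
  p <- runif(30)^2
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # significance order preserved
})

test_that("relative expression follows the 2^-ddCt arithmetic", {
  expect_equal(relative_expression_ddct(20, 20), 1)
  expect_equal(relative_expression_ddct(19, 20), 2)
  expect_equal(relative_expression_ddct(23.32, 20), 2^-3.32)
  expect_equal(round(relative_expression_ddct(23.32, 20), 4), 0.1001)
  expect_equal(relative_expression_ddct(25, 20, calibrator_delta = 5), 1)
})

test_that("rank-deficient fixed designs fail with the aliased column named", {
  ins <- make_instance(seed = 16)
  X <- cbind(a = ins$x, b = ins$x)
  expect_error(fit_weighted_animal_model(ins$ph, X, ins$A,
                                         vc = list(sigma2_a = 1, sigma2_e = 1)),
               "aliased.*b")
})
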