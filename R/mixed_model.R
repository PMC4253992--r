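#' Precompute the eigen context of a weighted polygenic model
#'
#' For phenotyped individuals with relationship matrix block `A[ids, ids]`
#' and residual weight matrix `W = diag(1/rel)`, eigendecomposes
#' `K = W^{-1/2} A W^{-1/2}` once, so that REML and GLS solves for any
#' phenotype vector on the same individuals reduce to O(n) work after an
#' O(n^2) rotation. The rotated model has `Var(y~) = sigma2_a D + sigma2_e I`
#' with `D = diag(eigenvalues)`.
#'
#' @param kinship additive relationship matrix with id dimnames (from
#'   [build_A()]).
#' @param ids phenotyped individual ids (must be rows of `kinship`).
#' @param rel per-individual EBV reliabilities in (0, 1].
#' @return list of class `"mm_context"`: `U`, `d`, `sw` (`sqrt(rel)`),
#'   `ids`, `kinship` (full matrix, kept for polygenic back-solutions).
#' @export
mm_context <- function(kinship, ids, rel) {
  ids <- as.character(ids)
  if (!all(ids %in% rownames(kinship)))
    stop("individual(s) not in the relationship matrix: ",
         paste(utils::head(setdiff(ids, rownames(kinship)), 5), collapse = ", "))
  rel <- as.numeric(rel)
  if (any(!is.finite(rel)) || any(rel <= 0) || any(rel > 1))
    stop("reliabilities must be in (0, 1]")
  sw <- sqrt(rel)
  K <- kinship[ids, ids] * tcrossprod(sw)
  eg <- eigen(K, symmetric = TRUE)
  structure(list(U = eg$vectors, d = pmax(eg$values, 0), sw = sw,
                 ids = ids, kinship = kinship),
            class = "mm_context")
}

mm_rotate <- function(ctx, M) crossprod(ctx$U, M * ctx$sw)

#' REML variance components for the weighted polygenic model
#'
#' Profile restricted maximum likelihood for
#' `y = X beta + a + e`, `Var(a) = A sigma2_a`, `Var(e) = W sigma2_e`
#' (`W = diag(1/rel)`), maximised over the single ratio
#' `gamma = sigma2_a / sigma2_e` on the eigen-rotated scale, with
#' `sigma2_e` profiled out in closed form. Deterministic (golden-section
#' search over `log(gamma)`), no starting-value sensitivity.
#'
#' @param ctx a [mm_context()].
#' @param y phenotype vector (EBVs), aligned with `ctx$ids`.
#' @param X fixed-effect design (default intercept only).
#' @param interval search interval for `log(gamma)` (default `c(-20, 15)`).
#' @return list of class `"mm_vc"`: `sigma2_a`, `sigma2_e`, `lambda`
#'   (`sigma2_e / sigma2_a`), `gamma`, `loglik` (restricted, up to a
#'   constant), `boundary` (`TRUE` when `sigma2_a` hit the zero boundary).
#' @export
reml_polygenic <- function(ctx, y, X = NULL, interval = c(-20, 15)) {
  stopifnot(inherits(ctx, "mm_context"))
  n <- length(ctx$ids)
  if (length(y) != n) stop("length(y) must match ctx ids")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  ty <- mm_rotate(ctx, y)
  tX <- mm_rotate(ctx, X)
  d <- ctx$d
  neg2rll <- function(lg) {
    v <- exp(lg) * d + 1
    XtVX <- crossprod(tX, tX / v)
    beta <- solve(XtVX, crossprod(tX, ty / v))
    r <- ty - tX %*% beta
    rss <- sum(r^2 / v)
    s2e <- rss / (n - p)
    (n - p) * log(s2e) + sum(log(v)) +
      as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(neg2rll, interval = interval, tol = 1e-10)
  lg <- opt$minimum
  boundary <- lg <= interval[1] + 1e-4
  gamma <- if (boundary) 0 else exp(lg)
  v <- gamma * d + 1
  XtVX <- crossprod(tX, tX / v)
  beta <- solve(XtVX, crossprod(tX, ty / v))
  rss <- sum((ty - tX %*% beta)^2 / v)
  s2e <- rss / (n - p)
  if (boundary)
    warning("REML estimate of sigma2_a hit the zero boundary; ",
            "polygenic effects will be zero")
  structure(list(sigma2_a = gamma * s2e, sigma2_e = s2e,
                 lambda = if (gamma > 0) 1 / gamma else Inf,
                 gamma = gamma, loglik = -opt$objective / 2,
                 boundary = boundary),
            class = "mm_vc")
}

# GLS solve on the rotated scale; exact MME fixed-effect solution.
mm_gls <- function(ctx, y, X, sigma2_a, sigma2_e, a_hat = TRUE) {
  n <- length(ctx$ids)
  X <- as.matrix(X)
  ty <- mm_rotate(ctx, y)
  tX <- mm_rotate(ctx, X)
  v <- sigma2_a * ctx$d + sigma2_e
  XtVX <- crossprod(tX, tX / v)
  vcov_fixed <- solve(XtVX)
  dimnames(vcov_fixed) <- list(colnames(X), colnames(X))
  beta <- drop(vcov_fixed %*% crossprod(tX, ty / v))
  ah <- NULL
  if (a_hat) {
    r <- ty - tX %*% cbind(beta)
    vres <- ctx$sw * drop(ctx$U %*% (r / v))    # V^{-1}(y - X beta)
    ah <- sigma2_a * drop(ctx$kinship[, ctx$ids] %*% vres)
    names(ah) <- rownames(ctx$kinship)
  }
  list(beta = setNames(beta, colnames(X)), vcov = vcov_fixed,
       a_hat = ah)
}

#' Solve Henderson's mixed model equations directly
#'
#' Assembles and solves the weighted mixed model equations for
#' `y = X beta + Z a + e` with `Var(a) = A sigma2_a`,
#' `Var(e) = W sigma2_e`, `W = diag(1/rel)`:
#' \deqn{\left[\begin{array}{cc} X'W^{-1}X & X'W^{-1}Z \\ Z'W^{-1}X &
#'   Z'W^{-1}Z + A^{-1}\lambda \end{array}\right]
#'   \left[\begin{array}{c}\hat\beta\\ \hat a\end{array}\right] =
#'   \left[\begin{array}{c} X'W^{-1}y \\ Z'W^{-1}y \end{array}\right]}
#' with `lambda = sigma2_e / sigma2_a`. The fixed-effect sampling covariance
#' is the fixed block of the inverted coefficient matrix times `sigma2_e`.
#'
#' @param y phenotype vector.
#' @param X fixed design matrix (n x p, including intercept).
#' @param ids pedigree ids of the phenotype rows.
#' @param A_inv inverse relationship matrix (from [build_A_inverse()]).
#' @param rel reliabilities in (0, 1].
#' @param sigma2_a,sigma2_e variance components (`sigma2_a > 0`).
#' @return list with `beta`, `vcov` (fixed-effect sampling covariance),
#'   `a_hat` (named, all pedigree ids).
#' @export
solve_mme <- function(y, X, ids, A_inv, rel, sigma2_a, sigma2_e) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X); q <- nrow(A_inv)
  stopifnot(length(ids) == n, length(rel) == n)
  if (sigma2_a <= 0) stop("solve_mme requires sigma2_a > 0")
  zi <- match(as.character(ids), rownames(A_inv))
  if (anyNA(zi)) stop("phenotyped id(s) missing from A_inv")
  lambda <- sigma2_e / sigma2_a
  wi <- rel                              # W^{-1} diagonal
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), zi)] <- 1
  XtWX <- crossprod(X, X * wi)
  XtWZ <- crossprod(X, Z * wi)
  ZtWZ <- crossprod(Z, Z * wi)
  C <- rbind(cbind(XtWX, XtWZ),
             cbind(t(XtWZ), ZtWZ + A_inv * lambda))
  rhs <- c(crossprod(X, y * wi), crossprod(Z, y * wi))
  E <- diag(nrow(C))[, seq_len(p), drop = FALSE]
  Cinv_f <- solve(C, cbind(rhs, E))
  sol <- Cinv_f[, 1]
  vcov_fixed <- Cinv_f[seq_len(p), -1, drop = FALSE] * sigma2_e
  dimnames(vcov_fixed) <- list(colnames(X), colnames(X))
  list(beta = setNames(sol[seq_len(p)], colnames(X)),
       vcov = vcov_fixed,
       a_hat = setNames(sol[-seq_len(p)], rownames(A_inv)))
}

#' Fit the weighted polygenic mixed regression model
#'
#' Fits `y = 1 mu + F beta + Z a + e` where `y` are EBVs, `a` is the
#' polygenic effect with covariance `A sigma2_a` from the pedigree, and the
#' residual variance of each observation is `sigma2_e / rel` (EBVs with low
#' reliability get proportionally larger residual variance). With
#' `vc = "reml"` the variance components are first estimated by REML on the
#' intercept-only model and then held fixed for the fit (the usual
#' two-stage practice for candidate-gene panels); a list
#' `list(sigma2_a=, sigma2_e=)` fixes them directly.
#'
#' The default engine solves the model on the eigen-rotated scale (exact
#' generalized least squares, identical to the mixed-model-equation
#' solution); `engine = "mme"` assembles Henderson's equations explicitly
#' via [solve_mme()]. Both are cross-checked in the test suite.
#'
#' @param pheno data.frame with columns `id`, `ebv`, `rel`.
#' @param fixed_design optional numeric matrix of fixed covariates (an
#'   intercept is always added first); must be full rank given the intercept.
#' @param kinship relationship matrix from [build_A()] covering all `pheno$id`.
#' @param vc `"reml"` (default) or `list(sigma2_a=, sigma2_e=)`.
#' @param engine `"gls"` (eigen-rotated, default) or `"mme"`.
#' @param A_inv optional precomputed [build_A_inverse()] (only used by the
#'   `"mme"` engine; computed densely from `kinship` when absent).
#' @param ctx optional precomputed [mm_context()] for these ids/reliabilities.
#' @return list of class `"mm_fit"`: `mu`, `beta` (named fixed effects,
#'   intercept first), `vcov` (fixed-effect sampling covariance), `a_hat`
#'   (polygenic solutions, all pedigree ids), `vc`, `n`, `ids`, `engine`.
#' @export
fit_weighted_animal_model <- function(pheno, fixed_design = NULL, kinship,
                                      vc = "reml",
                                      engine = c("gls", "mme"),
                                      A_inv = NULL, ctx = NULL) {
  engine <- match.arg(engine)
  stopifnot(all(c("id", "ebv", "rel") %in% names(pheno)))
  ids <- as.character(pheno$id)
  y <- as.numeric(pheno$ebv)
  rel <- as.numeric(pheno$rel)
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(fixed_design)) {
    Fm <- as.matrix(fixed_design)
    if (is.null(colnames(Fm))) colnames(Fm) <- paste0("f", seq_len(ncol(Fm)))
    X <- cbind(X, Fm)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (is.null(ctx)) ctx <- mm_context(kinship, ids, rel)
  else if (!identical(ctx$ids, ids))
    stop("supplied mm_context was built for different individuals")
  if (identical(vc, "reml")) {
    vc <- reml_polygenic(ctx, y)
  } else if (!is.list(vc) || is.null(vc$sigma2_a) || is.null(vc$sigma2_e)) {
    stop("vc must be \"reml\" or list(sigma2_a=, sigma2_e=)")
  }
  if (vc$sigma2_a <= 0) {
    # boundary: weighted least squares, zero polygenic solutions
    sol <- mm_gls(ctx, y, X, 0, vc$sigma2_e, a_hat = FALSE)
    sol$a_hat <- setNames(rep(0, nrow(kinship)), rownames(kinship))
  } else if (engine == "gls") {
    sol <- mm_gls(ctx, y, X, vc$sigma2_a, vc$sigma2_e)
  } else {
    if (is.null(A_inv)) {
      A_inv <- chol2inv(chol(kinship))
      dimnames(A_inv) <- dimnames(kinship)
    }
    sol <- solve_mme(y, X, ids, A_inv, rel, vc$sigma2_a, vc$sigma2_e)
  }
  structure(list(mu = unname(sol$beta[1]), beta = sol$beta,
                 vcov = sol$vcov, a_hat = sol$a_hat,
                 vc = vc, n = n, ids = ids, engine = engine),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("weighted polygenic mixed model fit: n =", x$n, "\n")
  cat("  sigma2_a =", signif(x$vc$sigma2_a, 5),
      " sigma2_e =", signif(x$vc$sigma2_e, 5), "\n")
  print(signif(x$beta, 5))
  invisible(x)
}

#' Single-SNP association test
#'
#' Regresses the EBVs on the 0/1/2 genotype code of one SNP under the
#' weighted polygenic model and tests the regression coefficient with the
#' Wald chi-square `b^2 / Var(b)` on 1 df. The SNP is oriented so that the
#' code counts copies of the minor allele in the analysed subset;
#' individuals with a missing call are excluded (complete-case per SNP).
#' A SNP monomorphic in the analysed subset is skipped with the reason
#' recorded (`NA` statistics), not an error.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno data.frame with `id`, `ebv`, `rel`.
#' @param kinship relationship matrix from [build_A()].
#' @param snp SNP id.
#' @param vc `"reml"` or a fixed `list(sigma2_a=, sigma2_e=)` (pass the
#'   intercept-only REML fit for the trait to avoid per-SNP re-estimation).
#' @param ctx optional [mm_context()] for the full phenotyped set; used only
#'   when the SNP has no missing calls (the complete-case subset then equals
#'   the full set), saving one eigendecomposition per SNP.
#' @return one-row data.frame: `test`, `n_used`, `estimate`, `se`,
#'   `wald_chi2`, `df`, `p_raw`, `flipped`, `skipped`, `reason`.
#' @export
test_snp <- function(geno, pheno, kinship, snp, vc = "reml", ctx = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!snp %in% geno$map$snp) stop("unknown SNP id: ", snp)
  gi <- match(as.character(pheno$id), geno$ids)
  if (anyNA(gi)) stop("phenotyped id(s) missing from genotypes")
  x <- as.numeric(geno$calls[gi, snp])
  ok <- !is.na(x)
  skip_row <- function(reason)
    data.frame(test = snp, n_used = sum(ok), estimate = NA_real_,
               se = NA_real_, wald_chi2 = NA_real_, df = 1L,
               p_raw = NA_real_, flipped = FALSE, skipped = TRUE,
               reason = reason, stringsAsFactors = FALSE)
  if (!any(ok)) return(skip_row("all calls missing"))
  ph <- pheno[ok, , drop = FALSE]
  x <- x[ok]
  flipped <- mean(x) / 2 > 0.5
  if (flipped) x <- 2 - x
  if (var(x) == 0) return(skip_row("monomorphic in analysed subset"))
  if (!all(ok)) ctx <- NULL   # complete-case subset differs from the context
  fit <- fit_weighted_animal_model(ph, fixed_design = cbind(snp = x),
                                   kinship = kinship, vc = vc, ctx = ctx)
  b <- unname(fit$beta["snp"])
  vb <- fit$vcov["snp", "snp"]
  wald <- b^2 / vb
  data.frame(test = snp, n_used = nrow(ph), estimate = b, se = sqrt(vb),
             wald_chi2 = wald, df = 1L,
             p_raw = pchisq(wald, 1, lower.tail = FALSE),
             flipped = flipped, skipped = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Haplotype trend regression association test for one block
#'
#' Regresses the EBVs on the expected haplotype-class dosages of a block
#' under the weighted polygenic model. Because the dosage rows sum to 2 the
#' design is confounded with the intercept, so one class (the pooled class
#' when present, else the last) is dropped and the remaining effects are
#' contrasts against that reference; the joint Wald statistic
#' `h' Var(h)^{-1} h` is referred to chi-square with `df = k - 1`
#' (reduced further if an aliased class column must be dropped).
#'
#' @param block a [build_haplotype_block()] result.
#' @param pheno data.frame with `id`, `ebv`, `rel`.
#' @param kinship relationship matrix from [build_A()].
#' @param vc `"reml"` or fixed variance components (see [test_snp()]).
#' @param label test label in the result (default `"block"`).
#' @return one-row data.frame: `test`, `n_used`, `wald_chi2`, `df`, `p_raw`,
#'   `k`, `dropped` (reference class), plus the fit in
#'   `attr(, "fit")` and effect contrasts in `attr(, "effects")`.
#' @export
test_haplotype_block <- function(block, pheno, kinship, vc = "reml",
                                 label = "block") {
  stopifnot(inherits(block, "haplotype_block"))
  if (block$k < 2)
    stop("haplotype block has k = ", block$k, ": no contrast to test")
  ids <- intersect(as.character(pheno$id), rownames(block$design))
  if (!length(ids)) stop("no phenotyped individuals in the block design")
  ph <- pheno[match(ids, as.character(pheno$id)), , drop = FALSE]
  Xf <- block$design[ids, , drop = FALSE]
  ref <- if ("pooled" %in% colnames(Xf)) "pooled" else colnames(Xf)[ncol(Xf)]
  Xd <- Xf[, setdiff(colnames(Xf), ref), drop = FALSE]
  # drop aliased columns (zero variance or collinear) before fitting
  repeat {
    qrX <- qr(cbind(1, Xd))
    if (qrX$rank == ncol(Xd) + 1 || ncol(Xd) == 1) break
    drop_j <- qrX$pivot[qrX$rank + 1] - 1
    message("dropping aliased haplotype class: ", colnames(Xd)[drop_j])
    Xd <- Xd[, -drop_j, drop = FALSE]
  }
  fit <- fit_weighted_animal_model(ph, fixed_design = Xd, kinship = kinship,
                                   vc = vc)
  h <- fit$beta[-1]
  Vh <- fit$vcov[-1, -1, drop = FALSE]
  wald <- drop(crossprod(h, solve(Vh, h)))
  df <- length(h)
  out <- data.frame(test = label, n_used = nrow(ph), wald_chi2 = wald,
                    df = df, p_raw = pchisq(wald, df, lower.tail = FALSE),
                    k = block$k, dropped = ref, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "effects") <- h
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1.
#'
#' @param p vector of raw p-values in (0, 1\].
#' @return adjusted p-values in the input order (empty in, empty out).
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Relative gene expression by the 2^-ddCt method
#'
#' `2^-((ct_target - ct_reference) - calibrator_delta)`: cycle thresholds of
#' the target gene normalised to a reference gene, relative to a calibrator
#' sample's delta-Ct.
#'
#' @param ct_target Ct of the target gene.
#' @param ct_reference Ct of the reference (housekeeping) gene.
#' @param calibrator_delta delta-Ct of the calibrator sample (default 0).
#' @return fold change.
#' @export
relative_expression_ddct <- function(ct_target, ct_reference,
                                     calibrator_delta = 0) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference))
  2^(-((ct_target - ct_reference) - calibrator_delta))
}
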