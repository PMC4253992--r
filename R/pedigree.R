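#' Construct a pedigree
#'
#' Builds a validated, topologically sorted pedigree from individual / sire /
#' dam identifier vectors. Unknown parents are encoded as `NA`. Individuals
#' that appear only as parents are appended as founders, so every parent id in
#' the result is itself a pedigree record and parents always precede their
#' offspring.
#'
#' @param id character vector of individual ids (unique).
#' @param sire,dam character vectors of parent ids; `NA` for unknown.
#' @return A `data.frame` of class `"pedigree"` with columns `id`, `sire`,
#'   `dam`, topologically sorted (parents before offspring).
#' @examples
#' pedigree(c("D1", "S1"), c("S1", NA), c(NA, NA))
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  if (anyNA(id)) stop("individual ids must not be missing")
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(sire == id, na.rm = TRUE) || any(dam == id, na.rm = TRUE)) {
    bad <- id[which(sire == id | dam == id)]
    stop("pedigree cycle: individual(s) listed as their own parent: ",
         paste(bad, collapse = ", "))
  }
  # parents referenced but not listed become founders
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    id <- c(id, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
  }
  ord <- ped_toposort(id, sire, dam)
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn's algorithm; errors on cycles naming the individuals involved.
ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

#' Read a pedigree from a whitespace/TSV file
#'
#' Expects three columns: individual, sire, dam. A header row is detected
#' automatically (first row whose first field matches `"id"`, case-insensitive)
#' unless `header` is given explicitly.
#'
#' @param path path to the pedigree file.
#' @param unknown token encoding an unknown parent (default `"0"`); `NA` and
#'   empty fields are always treated as unknown.
#' @param header logical; `NA` (default) auto-detects.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, unknown = "0", header = NA) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.na(header)) {
    first <- scan(path, what = character(), nlines = 1, quiet = TRUE)
    header <- length(first) >= 1 && tolower(first[1]) %in% c("id", "individual")
  }
  tab <- read.table(path, header = header, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("pedigree file must have 3 columns (id, sire, dam)")
  tab <- tab[, 1:3]
  for (j in 2:3) tab[[j]][tab[[j]] %in% c(unknown, "", "NA")] <- NA_character_
  pedigree(tab[[1]], tab[[2]], tab[[3]])
}

#' Write a pedigree to a TSV file
#'
#' Inverse of [read_pedigree()]: columns `id`, `sire`, `dam` with header,
#' unknown parents written as the `unknown` token.
#'
#' @param ped a [pedigree()] object.
#' @param path output path.
#' @param unknown token for unknown parents (default `"0"`).
#' @export
write_pedigree <- function(ped, path, unknown = "0") {
  stopifnot(inherits(ped, "pedigree"))
  out <- ped
  out$sire[is.na(out$sire)] <- unknown
  out$dam[is.na(out$dam)] <- unknown
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Additive genetic relationship matrix (tabular method)
#'
#' Computes the numerator relationship matrix A by the tabular recurrence:
#' for individual i with parents s, d (processed in pedigree order),
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_js + a_jd) / 2` for earlier j, with
#' unknown parents contributing zero. Diagonals equal `1 + F` where F is the
#' inbreeding coefficient.
#'
#' @param ped a [pedigree()] object (topologically sorted by construction).
#' @return symmetric numeric matrix with the pedigree ids as dimnames.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + asd / 2
    if (i > 1L) {
      j <- seq_len(i - 1L)
      ajs <- if (s > 0L) A[j, s] else 0
      ajd <- if (d > 0L) A[j, d] else 0
      aij <- (ajs + ajd) / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  A
}

#' Inbreeding coefficients (Meuwissen-Luo algorithm)
#'
#' Computes per-individual inbreeding coefficients F without forming the full
#' relationship matrix, by accumulating squared Cholesky-row contributions
#' weighted by Mendelian-sampling variances. Founders (and individuals with
#' both parents unknown) have F = 0.
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  FF <- numeric(n)
  # Mendelian sampling variance; F of an unknown parent enters as -1 so that
  # founders get D = 1 and single-unknown-parent individuals D = 0.75 - F_s/4
  Dms <- function(i) {
    fs <- if (si[i] > 0L) FF[si[i]] else -1
    fd <- if (di[i] > 0L) FF[di[i]] else -1
    0.5 - 0.25 * (fs + fd)
  }
  Dv <- numeric(n)
  for (i in seq_len(n)) {
    Dv[i] <- Dms(i)
    if (si[i] == 0L && di[i] == 0L) { FF[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * Dv[j]
      if (si[j] > 0L) L[si[j]] <- L[si[j]] + L[j] / 2
      if (di[j] > 0L) L[di[j]] <- L[di[j]] + L[j] / 2
    }
    FF[i] <- aii - 1
  }
  setNames(FF, ped$id)
}

#' Inverse of the additive relationship matrix
#'
#' `method = "henderson"` uses Henderson's direct rules with inbreeding
#' handled through Meuwissen-Luo Mendelian-sampling variances; `method =
#' "dense"` inverts [build_A()] numerically. The two agree to numerical
#' precision on any valid pedigree and are cross-checked in the test suite.
#'
#' @param ped a [pedigree()] object.
#' @param method `"henderson"` (default) or `"dense"`.
#' @return symmetric numeric matrix, inverse of [build_A()].
#' @export
build_A_inverse <- function(ped, method = c("henderson", "dense")) {
  stopifnot(inherits(ped, "pedigree"))
  method <- match.arg(method)
  if (method == "dense") {
    A <- build_A(ped)
    Ainv <- tryCatch(chol2inv(chol(A)),
                     error = function(e) stop("A matrix is numerically singular: ",
                                              conditionMessage(e)))
    dimnames(Ainv) <- dimnames(A)
    return(Ainv)
  }
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  FF <- inbreeding(ped)
  Ainv <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    fs <- if (si[i] > 0L) FF[si[i]] else -1
    fd <- if (di[i] > 0L) FF[di[i]] else -1
    alpha <- 1 / (0.5 - 0.25 * (fs + fd))
    p <- c(si[i], di[i])
    p <- p[p > 0L]
    Ainv[i, i] <- Ainv[i, i] + alpha
    for (u in p) {
      Ainv[i, u] <- Ainv[i, u] - alpha / 2
      Ainv[u, i] <- Ainv[u, i] - alpha / 2
      for (v in p) Ainv[u, v] <- Ainv[u, v] + alpha / 4
    }
  }
  Ainv
}
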