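#' Relationship matrices
#'
#' All relationship matrices in this package are symmetric numeric matrices
#' whose dimnames carry animal IDs, classed as `relmat` with a `kind`
#' attribute (`"A"`, `"A22"`, `"G"`, `"G_adjusted"` or `"H"`).
#'
#' @param values symmetric numeric matrix with identical row/col names.
#' @param kind matrix kind label.
#' @return a `relmat`.
#' @export
new_relmat <- function(values, kind = c("A", "A22", "G", "G_adjusted", "H")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)),
            identical(rownames(values), colnames(values)))
  if (max(abs(values - t(values))) > 1e-8) {
    stop("relationship matrix is not symmetric")
  }
  values <- (values + t(values)) / 2
  structure(values, kind = kind, class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d animals, mean diag %.4f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Pedigree-based numerator relationship matrix A
#'
#' Builds A by the tabular (recursive) method with inbreeding: processing
#' animals in topological order,
#' \eqn{a_{ij} = (a_{j,sire(i)} + a_{j,dam(i)})/2} for earlier animals j and
#' \eqn{a_{ii} = 1 + a_{sire(i),dam(i)}/2}, a missing parent contributing 0.
#' The diagonal is \eqn{1 + F_i} with inbreeding coefficient \eqn{F_i \ge 0};
#' A is positive definite for any valid pedigree.
#'
#' @param ped pedigree (see [as_pedigree()]).
#' @return a `relmat` of kind `"A"` in pedigree order.
#' @export
pedigree_A <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(si[i])) v <- v + A[prev, si[i]]
      if (!is.na(di[i])) v <- v + A[prev, di[i]]
      v <- v / 2
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i])) A[si[i], di[i]] / 2 else 0
  }
  new_relmat(A, "A")
}

#' Genotyped block of A
#'
#' Principal submatrix of the pedigree relationship matrix on the genotyped
#' animals, in the order of `ids` (typically the genotype-matrix order).
#'
#' @param A a `relmat` of kind `"A"`.
#' @param ids character vector of genotyped animal IDs; if a pedigree with a
#'   `genotyped` column is supplied instead, its genotyped animals are used.
#' @return a `relmat` of kind `"A22"`.
#' @export
extract_A22 <- function(A, ids) {
  if (is.data.frame(ids)) {
    stopifnot("genotyped" %in% names(ids))
    ids <- ids$animal[ids$genotyped]
  }
  if (length(ids) == 0L) stop("genotyped set is empty")
  if (!all(ids %in% rownames(A))) stop("genotyped IDs missing from A")
  new_relmat(unclass(A)[ids, ids, drop = FALSE], "A22")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \deqn{G = Z Z' / \left(2 \sum_j p_j (1 - p_j)\right)}
#' where Z is the allele-count matrix with column j centred by \eqn{2 p_j}.
#' When the frequencies are computed from the same animals, the average
#' diagonal of G is close to 1, putting G on the same scale as A.
#'
#' @param geno a `genotype_matrix`, or an animals x SNPs allele-count matrix
#'   with animal rownames (then `freqs` must be supplied).
#' @param freqs per-SNP reference-allele frequencies; defaults to the
#'   frequencies carried by `geno`.
#' @return a `relmat` of kind `"G"` over the genotyped animals.
#' @export
vanraden_G <- function(geno, freqs = NULL) {
  if (inherits(geno, "genotype_matrix")) {
    M <- geno$counts
    if (is.null(freqs)) freqs <- geno$freqs
  } else {
    M <- geno
  }
  stopifnot(is.matrix(M), !is.null(rownames(M)), length(freqs) == ncol(M))
  if (anyNA(M)) stop("genotype matrix contains missing values")
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("degenerate SNP: allele frequencies must lie strictly inside (0, 1); ",
         "filter monomorphic SNPs upstream")
  }
  Z <- sweep(M, 2L, 2 * freqs)
  denom <- 2 * sum(freqs * (1 - freqs))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  new_relmat(G, "G")
}

#' Moment-match G to the pedigree scale
#'
#' Rescales the genomic matrix as \eqn{G_a = G\beta + \alpha} (the scalar
#' offset is added to every element) with \eqn{(\beta, \alpha)} solving
#' \deqn{Avg(diag(G))\beta + \alpha = Avg(diag(A_{22}))}
#' \deqn{Avg(offdiag(G))\beta + \alpha = Avg(offdiag(A_{22})),}
#' so the diagonal and off-diagonal averages of the adjusted matrix match
#' those of the pedigree block on the genotyped animals.  This removes the
#' scale incompatibility between pedigree and genomic information that can
#' distort their weighting in a hybrid matrix.
#'
#' @param G,A22 `relmat`s over the same animals in the same order.
#' @return list with elements `Ga` (a `relmat` of kind `"G_adjusted"`) and
#'   `adjustment` (class `g_adjustment`: `beta`, `alpha`, and the four
#'   `moments`).
#' @export
adjust_G <- function(G, A22) {
  stopifnot(nrow(G) == nrow(A22), identical(rownames(G), rownames(A22)))
  off <- function(m) {
    n <- nrow(m)
    (sum(m) - sum(diag(m))) / (n * (n - 1))
  }
  mom <- c(diag_G = mean(diag(G)), offdiag_G = off(G),
           diag_A22 = mean(diag(A22)), offdiag_A22 = off(A22))
  coefm <- rbind(c(mom[["diag_G"]], 1), c(mom[["offdiag_G"]], 1))
  if (abs(mom[["diag_G"]] - mom[["offdiag_G"]]) < 1e-12) {
    stop("moment system is singular: Avg(diag(G)) equals Avg(offdiag(G))")
  }
  sol <- solve(coefm, c(mom[["diag_A22"]], mom[["offdiag_A22"]]))
  beta <- sol[1]
  alpha <- sol[2]
  Ga <- unclass(G) * beta + alpha
  adj <- structure(list(beta = beta, alpha = alpha, moments = mom),
                   class = "g_adjustment")
  list(Ga = new_relmat(Ga, "G_adjusted"), adjustment = adj)
}

#' @export
print.g_adjustment <- function(x, ...) {
  cat(sprintf("G adjustment: beta = %.4f, alpha = %.4f\n", x$beta, x$alpha))
  invisible(x)
}

#' Hybrid relationship matrix H (one-step blending)
#'
#' Combines pedigree relationships among and with non-genotyped animals
#' (subscript 1) with genomic relationships among genotyped animals
#' (subscript 2):
#' \deqn{H_{11} = A_{11} + A_{12} A_{22}^{-1} (G - A_{22}) A_{22}^{-1} A_{12}'}
#' \deqn{H_{12} = A_{12} A_{22}^{-1} G, \qquad H_{22} = G.}
#' The direct block formula is used, so only \eqn{A_{22}} needs inverting
#' (G is never inverted).  Rows/columns are ordered with the non-genotyped
#' block first (in pedigree order) and the genotyped block second (in G's
#' order); callers should index by animal ID, never by position.
#'
#' @param A pedigree relationship matrix over all animals.
#' @param G genomic (or adjusted genomic) matrix over the genotyped subset;
#'   its rownames must be a subset of A's.
#' @return a `relmat` of kind `"H"`.
#' @export
blend_H <- function(A, G) {
  ids_g <- rownames(G)
  stopifnot(all(ids_g %in% rownames(A)))
  ids_n <- setdiff(rownames(A), ids_g)
  Au <- unclass(A)
  A22 <- Au[ids_g, ids_g, drop = FALSE]
  rc <- rcond(A22)
  if (rc < 1e-12) {
    stop(sprintf("A22 is numerically singular (reciprocal condition number %.3g)", rc))
  }
  Gu <- unclass(G)
  if (length(ids_n) == 0L) {
    return(new_relmat(Gu, "H"))
  }
  A11 <- Au[ids_n, ids_n, drop = FALSE]
  A12 <- Au[ids_n, ids_g, drop = FALSE]
  Tm <- t(solve(A22, t(A12)))            # A12 %*% A22^{-1}
  H12 <- Tm %*% Gu
  H11 <- A11 + Tm %*% (Gu - A22) %*% t(Tm)
  H11 <- (H11 + t(H11)) / 2
  H <- rbind(cbind(H11, H12), cbind(t(H12), Gu))
  ids <- c(ids_n, ids_g)
  dimnames(H) <- list(ids, ids)
  new_relmat(H, "H")
}

#' Shrink an ill-conditioned G towards its pedigree block
#'
#' Optional stabilisation \eqn{G^* = \tau G + (1 - \tau) A_{22}} for use
#' when G is numerically singular; not applied by default anywhere in the
#' package.
#'
#' @param G,A22 matching `relmat`s.
#' @param tau weight on G, default 0.95.
#' @return a `relmat` of kind `"G"`.
#' @export
stabilize_G <- function(G, A22, tau = 0.95) {
  stopifnot(identical(rownames(G), rownames(A22)), tau > 0, tau <= 1)
  new_relmat(tau * unclass(G) + (1 - tau) * unclass(A22), "G")
}

#' Write/read relationship matrices as plain text
#'
#' `write_relmat_dense()` writes a TSV with an `id` column and one column
#' per animal; `write_relmat_sparse()` writes the lower triangle as three
#' columns (`id_i`, `id_j`, `value`).
#'
#' @param x a `relmat`.
#' @param file output path.
#' @export
write_relmat_dense <- function(x, file) {
  out <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_relmat_dense
#' @export
write_relmat_sparse <- function(x, file) {
  idx <- which(lower.tri(x, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(id_i = rownames(x)[idx[, 1]], id_j = colnames(x)[idx[, 2]],
                    value = x[idx])
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_relmat_dense
#' @param kind matrix kind for the object read back.
#' @export
read_relmat_dense <- function(file, kind = "A") {
  tab <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  new_relmat(m, kind)
}
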