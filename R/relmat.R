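#' Weighted VanRaden genomic relationship matrix
#'
#' \deqn{G = Z D Z' / \sum_i 2 p_i (1 - p_i)}
#' where Z is the centered gene-content matrix, D a diagonal matrix of
#' per-SNP weights and p the counted-allele frequencies used for centering.
#' With unit weights this is VanRaden's method 1.
#'
#' @param Z centered gene-content matrix (individuals x SNPs), from
#'   [center_gene_content()].
#' @param d per-SNP positive weights (default all 1).
#' @param freqs frequencies used for centering; supply the same vector.
#' @return Dense symmetric matrix with the individuals' dimnames.
#' @export
build_G <- function(Z, d = rep(1, ncol(Z)), freqs) {
  Z <- as.matrix(Z)
  if (length(d) != ncol(Z)) stop("length(d) != ncol(Z)")
  if (any(!is.finite(d)) || any(d <= 0)) stop("weights must be positive")
  if (length(freqs) != ncol(Z)) stop("length(freqs) != ncol(Z)")
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP present (frequency 0 or 1); run apply_qc() first")
  denom <- sum(2 * freqs * (1 - freqs))
  G <- tcrossprod(sweep(Z, 2L, d, `*`), Z) / denom
  (G + t(G)) / 2
}

#' Blend G with the pedigree submatrix A22
#'
#' \eqn{G_\omega = \alpha G + \beta A_{22}}; the default 0.95/0.05 blend
#' makes G positive definite and compatible in scale with the pedigree
#' information.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship submatrix for the same animals, in the
#'   same order (checked via dimnames when present).
#' @param alpha,beta blending weights, must sum to 1.
#' @return Dense symmetric matrix \eqn{\alpha G + \beta A_{22}}.
#' @export
blend_G <- function(G, A22, alpha = 0.95, beta = 0.05) {
  if (abs(alpha + beta - 1) > 1e-12) stop("alpha + beta must equal 1")
  G <- as.matrix(G); A22 <- as.matrix(A22)
  if (!all(dim(G) == dim(A22))) stop("G and A22 dimensions differ")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 animal orderings differ")
  alpha * G + beta * A22
}

#' Single-step H-inverse
#'
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 &
#'   G_\omega^{-1} - A_{22}^{-1} \end{pmatrix}}
#' The genotyped animals need not form a trailing block: the correction is
#' scatter-added into the rows/columns of \code{genotyped_ids}.
#'
#' @param a_inv sparse A-inverse over all animals ([build_A_inverse()]).
#' @param g_omega blended genomic matrix for the genotyped animals
#'   ([blend_G()]), or its inverse via \code{g_omega_inv}.
#' @param a22 pedigree submatrix for the genotyped animals, or its inverse
#'   via \code{a22_inv}.
#' @param genotyped_ids animal ids of the genotyped block, in the order of
#'   \code{g_omega}/\code{a22}.
#' @param g_omega_inv,a22_inv optional pre-computed inverses.
#' @return Sparse symmetric H-inverse with all-animal dimnames.
#' @export
build_H_inverse <- function(a_inv, g_omega = NULL, a22 = NULL, genotyped_ids,
                            g_omega_inv = NULL, a22_inv = NULL) {
  ids <- rownames(a_inv)
  genotyped_ids <- as.character(genotyped_ids)
  if (length(genotyped_ids) == 0L) return(a_inv)
  pos <- match(genotyped_ids, ids)
  if (anyNA(pos))
    stop("genotyped ids missing from A-inverse: ",
         paste(genotyped_ids[is.na(pos)], collapse = ", "))
  inv_sym <- function(M, what) {
    M <- as.matrix(M)
    ch <- tryCatch(chol(M), error = function(e)
      stop("singular ", what, "; blend with A22 (alpha < 1) first",
           call. = FALSE))
    chol2inv(ch)
  }
  if (is.null(g_omega_inv)) g_omega_inv <- inv_sym(g_omega, "G_omega")
  if (is.null(a22_inv)) a22_inv <- inv_sym(a22, "A22")
  delta <- g_omega_inv - a22_inv
  ng <- length(genotyped_ids)
  corr <- Matrix::sparseMatrix(
    i = rep(pos, each = ng), j = rep(pos, times = ng),
    x = as.numeric(delta[cbind(rep(seq_len(ng), each = ng),
                               rep(seq_len(ng), times = ng))]),
    dims = dim(a_inv), dimnames = dimnames(a_inv))
  Matrix::forceSymmetric(Matrix::drop0(a_inv + corr))
}
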