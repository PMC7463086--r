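#' Symmetric positive-definite inverse with one ridge retry
#'
#' Cholesky-based inverse. If factorization fails, a ridge of
#' `1e-6 * mean(diag)` is added once and the factorization retried, with a
#' message. Used for blended G and A22 inversion in the single-step setup.
#'
#' @param M symmetric matrix.
#' @param label name used in messages.
#' @return Inverse matrix (dimnames preserved).
#' @export
chol_inverse <- function(M, label = "matrix") {
  M <- as.matrix(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-6 * mean(diag(M))
    message(label, ": Cholesky failed; retrying with ridge ", signif(ridge, 3))
    ch <- chol(M + diag(ridge, nrow(M)))
  }
  out <- chol2inv(ch)
  dimnames(out) <- dimnames(M)
  out
}

#' Single-step inverse relationship matrix H-inverse
#'
#' Assembles `Hinv = Ainv + [0 0; 0 tau * Ginv - omega * A22inv]`, where the
#' correction occupies the genotyped-by-genotyped block. Outside that block
#' H-inverse equals A-inverse exactly. `tau` and `omega` rescale the genomic
#' and pedigree-submatrix information in the correction.
#'
#' @param Ainv sparse inverse numerator relationship matrix over all
#'   pedigree animals ([nrm_inverse()]).
#' @param Ginv inverse of the (blended) genomic relationship matrix over the
#'   genotyped animals.
#' @param A22inv inverse of the pedigree relationship submatrix over the
#'   same genotyped animals, same order.
#' @param genotyped character vector of genotyped animal IDs (must match the
#'   order of `Ginv`/`A22inv` rows), or integer indices into `Ainv`.
#' @param tau,omega non-negative scalar adjustments (defaults 1).
#' @return Sparse symmetric matrix of class `Matrix::dsCMatrix` with
#'   attributes `tau`, `omega`, `genotyped_index`.
#' @export
h_inverse <- function(Ainv, Ginv, A22inv, genotyped, tau = 1, omega = 1) {
  n <- nrow(Ainv)
  if (length(genotyped) == 0) {
    H <- methods::as(Ainv, "symmetricMatrix")
    attr(H, "tau") <- tau; attr(H, "omega") <- omega
    attr(H, "genotyped_index") <- integer(0)
    return(H)
  }
  if (is.character(genotyped)) {
    idx <- match(genotyped, rownames(Ainv))
    if (anyNA(idx)) stop("genotyped IDs not found in Ainv")
  } else {
    idx <- as.integer(genotyped)
    if (any(idx < 1L | idx > n)) stop("genotyped index out of range")
  }
  m <- length(idx)
  if (!all(dim(Ginv) == m) || !all(dim(A22inv) == m))
    stop("Ginv and A22inv must be conformable with the genotyped set")
  if (max(abs(Ginv - t(Ginv))) > 1e-8 * max(abs(Ginv)))
    stop("Ginv is not symmetric")
  if (max(abs(A22inv - t(A22inv))) > 1e-8 * max(abs(A22inv)))
    stop("A22inv is not symmetric")
  if (tau < 0 || omega < 0) stop("tau and omega must be non-negative")
  corr <- tau * Ginv - omega * A22inv
  corr <- (corr + t(corr)) / 2
  block <- Matrix::sparseMatrix(
    i = rep(idx, each = m), j = rep(idx, times = m),
    x = as.numeric(t(corr)), dims = c(n, n), dimnames = dimnames(Ainv)
  )
  H <- methods::as(Matrix::forceSymmetric(Ainv + block), "symmetricMatrix")
  attr(H, "tau") <- tau
  attr(H, "omega") <- omega
  attr(H, "genotyped_index") <- idx
  H
}

#' Build H-inverse from a pedigree and a genomic relationship matrix
#'
#' Convenience wrapper: computes A-inverse from the pedigree, A22 over the
#' genotyped animals by the tabular method, blends G with A22, inverts both,
#' and assembles [h_inverse()].
#'
#' @param ped a [pedigree()] object.
#' @param G genomic relationship matrix with genotyped animal IDs as
#'   dimnames (subset of the pedigree).
#' @param tau,omega scalar adjustments (defaults 1).
#' @param blend_alpha weight on G in the blend with A22 (default 0.95).
#' @return Sparse symmetric H-inverse (see [h_inverse()]).
#' @export
single_step_hinv <- function(ped, G, tau = 1, omega = 1, blend_alpha = 0.95) {
  ids <- rownames(G)
  if (is.null(ids)) stop("G must carry animal IDs as dimnames")
  Ainv <- nrm_inverse(ped)
  A22 <- nrm(ped, ids)
  Gb <- blend_grm(G, A22, alpha = blend_alpha)
  h_inverse(Ainv,
            Ginv = chol_inverse(Gb, "blended G"),
            A22inv = chol_inverse(A22, "A22"),
            genotyped = ids, tau = tau, omega = omega)
}
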