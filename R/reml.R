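#' Multi-trait EM-REML variance components on the animal model
#'
#' Expectation-maximisation REML for the multi-trait animal model. Each
#' iteration solves the mixed-model equations at the current (G0, R0),
#' then updates G0 from breeding-value cross-products plus traces of the
#' inverse-coefficient-matrix blocks against `Kinv`, and R0 from residual
#' cross-products plus the corresponding prediction-variance corrections,
#' averaged per trait pair over the animals observed for both traits.
#' Updates that leave the positive-semidefinite cone are projected back by
#' eigenvalue clipping. With complete records the restricted log-likelihood
#' is non-decreasing at every iteration (the classical EM guarantee); with
#' missing multi-trait records the per-pair averaging is the standard
#' practical treatment and the trace is still reported.
#'
#' @param phen phenotype table (see [build_design()]).
#' @param model a [trait_model()]; its G0/R0 are *not* used as start values
#'   unless `start` says so.
#' @param ped a [pedigree()].
#' @param Kinv relationship inverse to fit under; default the sparse
#'   pedigree A-inverse (the pedigree-only fit used for additive variances).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence tolerance on the maximum relative change of any
#'   (co)variance component (default 1e-6).
#' @param start optional list with starting `G0`, `R0`; default assigns half
#'   the observed phenotypic (co)variance to each.
#' @param verbose print the likelihood trace while iterating.
#' @return Object of class `reml_fit`: estimated `G0`, `R0`, derived
#'   [genetic_parameters()], `loglik` trace, `iterations`, `converged`.
#' @export
em_reml <- function(phen, model, ped, Kinv = NULL, max_iter = 500,
                    tol = 1e-6, start = NULL, verbose = FALSE) {
  design <- build_design(phen, model, ped)
  t <- design$t; q <- design$q
  have <- sort(unique(design$rec$trait))
  if (length(have) < t)
    stop("trait(s) without records: ",
         paste(model$traits[setdiff(seq_len(t), have)], collapse = ", "))
  if (is.null(Kinv)) Kinv <- nrm_inverse(ped)
  ldetK <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)

  # starting values: half the phenotypic (co)variance each
  if (is.null(start)) {
    P0 <- matrix(0, t, t)
    vals <- split(data.frame(a = design$rec$animal, y = design$y),
                  design$rec$trait)
    for (s in seq_len(t)) for (r in s:t) {
      ys <- vals[[as.character(s)]]; yr <- vals[[as.character(r)]]
      m <- merge(ys, yr, by = "a")
      P0[s, r] <- P0[r, s] <- if (s == r) stats::var(ys$y)
        else if (nrow(m) > 2) stats::cov(m$y.x, m$y.y) else 0
    }
    P0 <- project_psd(P0, floor_frac = 1e-4)
    G0 <- P0 / 2
    R0 <- P0 / 2
  } else {
    G0 <- as.matrix(start$G0); R0 <- as.matrix(start$R0)
  }
  scale0 <- mean(diag(G0 + R0))

  Kt <- methods::as(methods::as(Kinv, "generalMatrix"), "TsparseMatrix")
  ki <- Kt@i + 1L; kj <- Kt@j + 1L; kx <- Kt@x
  rec <- design$rec
  # within-animal ordered record pairs for the R0 update
  ordA <- order(rec$animal, rec$trait)
  pair_i <- integer(0); pair_j <- integer(0)
  for (rows in split(ordA, rec$animal[ordA])) {
    k <- length(rows)
    pair_i <- c(pair_i, rep(rows, each = k))
    pair_j <- c(pair_j, rep(rows, times = k))
  }
  ps <- rec$trait[pair_i]; pt <- rec$trait[pair_j]
  pair_cell <- (pt - 1L) * t + ps
  n_cell <- tabulate(pair_cell, t * t)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    sys <- mme_system(design, G0, R0, Kinv)
    Cd <- as.matrix(sys$C)
    ch <- chol(Cd)
    theta <- backsolve(ch, backsolve(ch, sys$rhs, transpose = TRUE))
    Cinv <- chol2inv(ch)
    nf <- sys$n_fixed
    p <- sys$p

    # restricted log-likelihood at current parameters
    yRy <- as.numeric(Matrix::crossprod(design$y, sys$Rinv %*% design$y))
    yPy <- yRy - sum(theta * sys$rhs)
    ldetC <- 2 * sum(log(diag(ch)))
    ldetG <- q * as.numeric(determinant(G0, logarithm = TRUE)$modulus) +
      t * ldetK
    ll <- -0.5 * (sys$ldetR + ldetG + ldetC + yPy)
    loglik <- c(loglik, ll)
    if (verbose) message("iter ", iter, " logL ", format(ll, digits = 10))

    u <- matrix(theta[-seq_len(nf)], nrow = q, ncol = t)
    # G0 update: (u_s' Kinv u_t + tr(Kinv %*% Cuu_st)) / q
    G0n <- matrix(0, t, t)
    for (s in seq_len(t)) for (r in s:t) {
      quad <- sum(u[, s] * as.numeric(Kinv %*% u[, r]))
      rows <- nf + (s - 1L) * q + ki
      cols <- nf + (r - 1L) * q + kj
      tr <- sum(kx * Cinv[cbind(rows, cols)])
      G0n[s, r] <- G0n[r, s] <- (quad + tr) / q
    }

    # R0 update: residual cross-products plus W Cinv W' corrections,
    # averaged over animals observed for each trait pair
    W <- sys$W
    ehat <- design$y - as.numeric(W %*% theta)
    V <- as.matrix(W %*% Cinv)
    Wd_j <- as.matrix(W[pair_j, , drop = FALSE])
    tvals <- rowSums(V[pair_i, , drop = FALSE] * Wd_j)
    contrib <- ehat[pair_i] * ehat[pair_j] + tvals
    sums <- as.numeric(rowsum(contrib, pair_cell,
                              reorder = TRUE)[as.character(seq_len(t * t)), 1])
    sums[is.na(sums)] <- 0
    R0n <- matrix(sums / pmax(n_cell, 1L), t, t)
    never <- matrix(n_cell, t, t) == 0L
    R0n[never] <- R0[never] # trait pair never jointly observed: keep current
    R0n <- (R0n + t(R0n)) / 2

    G0n <- project_psd(G0n, floor_frac = 1e-8)
    R0n <- project_psd(R0n, floor_frac = 1e-8)
    rel <- max(abs(c(G0n - G0, R0n - R0)) / pmax(abs(c(G0, R0)), 1e-6 * scale0))
    G0 <- G0n; R0 <- R0n
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not reach tol = ", tol, " within ", iter, " iterations")
  dimnames(G0) <- dimnames(R0) <- list(design$traits, design$traits)
  structure(list(G0 = G0, R0 = R0,
                 params = genetic_parameters(G0, R0),
                 loglik = loglik, iterations = iter, converged = converged),
            class = "reml_fit")
}

# clip eigenvalues at a small positive floor relative to the mean diagonal
project_psd <- function(M, floor_frac = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  floor_val <- floor_frac * max(mean(diag(M)), .Machine$double.eps)
  if (min(e$values) >= floor_val) return((M + t(M)) / 2)
  e$vectors %*% diag(pmax(e$values, floor_val), nrow(M)) %*% t(e$vectors)
}

#' Derive heritabilities and correlations from covariance components
#'
#' `h2 = G0_tt / (G0_tt + R0_tt)`, genetic correlations from G0, phenotypic
#' correlations from `P = G0 + R0`.
#'
#' @param G0,R0 genetic and residual trait covariance matrices.
#' @return Object of class `genetic_params`: per-trait `sigma2_a`,
#'   `sigma2_e`, `sigma2_p`, `h2`, and correlation matrices `rg`, `rp`.
#' @export
genetic_parameters <- function(G0, R0) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  stopifnot(all(dim(G0) == dim(R0)))
  P <- G0 + R0
  if (any(diag(P) <= 0)) stop("zero phenotypic variance for some trait")
  traits <- rownames(G0)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(G0)))
  h2 <- diag(G0) / diag(P)
  rg <- stats::cov2cor(project_psd(G0, floor_frac = 1e-12))
  rp <- stats::cov2cor(P)
  dimnames(rg) <- dimnames(rp) <- list(traits, traits)
  structure(list(sigma2_a = stats::setNames(diag(G0), traits),
                 sigma2_e = stats::setNames(diag(R0), traits),
                 sigma2_p = stats::setNames(diag(P), traits),
                 h2 = stats::setNames(h2, traits), rg = rg, rp = rp),
            class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  t <- length(x$h2)
  M <- x$rg
  M[lower.tri(M)] <- x$rp[lower.tri(x$rp)]
  diag(M) <- x$h2
  cat("Genetic parameters (h2 on diagonal, genetic correlations above,\n",
      "phenotypic correlations below):\n", sep = "")
  print(round(M, 3))
  invisible(x)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("EM-REML fit:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      "| final logL", format(utils::tail(x$loglik, 1), digits = 8), "\n")
  print(x$params)
  invisible(x)
}

#' Write genetic parameters as JSON
#'
#' Layout mirrors the usual parameter table: a trait-by-trait matrix with
#' heritabilities on the diagonal, genetic correlations above and phenotypic
#' correlations below, plus the variance components.
#'
#' @param params a `genetic_params` object.
#' @param path output path.
#' @export
write_genetic_parameters <- function(params, path) {
  t <- length(params$h2)
  M <- params$rg
  M[lower.tri(M)] <- params$rp[lower.tri(params$rp)]
  diag(M) <- params$h2
  out <- list(
    traits = names(params$h2),
    table_h2_diag_rg_above_rp_below = apply(unname(M), 1, as.numeric,
                                            simplify = FALSE),
    sigma2_a = as.list(params$sigma2_a),
    sigma2_e = as.list(params$sigma2_e),
    sigma2_p = as.list(params$sigma2_p),
    h2 = as.list(params$h2)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
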