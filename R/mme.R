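#' Define a multi-trait animal model
#'
#' Declares the trait list, the trait-specific fixed effects (factors and
#' numeric covariates, named by phenotype-table columns), and the additive
#' genetic and residual covariance matrices between traits.
#'
#' @param traits ordered character vector of trait names.
#' @param fixed_factors named list mapping a trait to the factor columns
#'   fitted for it (composite contemporary-group effects). Traits absent
#'   from the list get an intercept only.
#' @param covariates named list mapping a trait to numeric covariate
#'   columns (e.g. age at slaughter for carcass traits).
#' @param G0 t x t additive genetic covariance matrix.
#' @param R0 t x t residual covariance matrix.
#' @return Object of class `trait_model`.
#' @export
trait_model <- function(traits, fixed_factors = list(), covariates = list(),
                        G0, R0) {
  t <- length(traits)
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  stopifnot(all(dim(G0) == t), all(dim(R0) == t))
  if (max(abs(G0 - t(G0))) > 1e-10 * max(abs(G0), 1)) stop("G0 must be symmetric")
  if (max(abs(R0 - t(R0))) > 1e-10 * max(abs(R0), 1)) stop("R0 must be symmetric")
  if (!all(names(fixed_factors) %in% traits) || !all(names(covariates) %in% traits))
    stop("fixed-effect map names must be a subset of traits")
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  structure(list(traits = traits, fixed_factors = fixed_factors,
                 covariates = covariates, G0 = G0, R0 = R0),
            class = "trait_model")
}

#' Build genetic and residual covariances from summary parameters
#'
#' Converts heritabilities, genetic correlations, phenotypic correlations
#' and phenotypic standard deviations into the G0/R0 pair they imply:
#' `G0 = diag(sa) rg diag(sa)` with `sa^2 = h2 * sd_p^2`, and
#' `R0 = P - G0` with `P = diag(sd_p) rp diag(sd_p)`.
#'
#' @param h2 per-trait heritabilities.
#' @param rg,rp genetic and phenotypic correlation matrices (unit diagonal).
#' @param sd_p per-trait phenotypic standard deviations.
#' @return List with matrices `G0` and `R0`.
#' @export
trait_covariances <- function(h2, rg, rp, sd_p) {
  stopifnot(length(h2) == length(sd_p), all(dim(rg) == length(h2)),
            all(dim(rp) == length(h2)))
  P <- rp * (sd_p %o% sd_p)
  sa <- sqrt(h2) * sd_p
  G0 <- rg * (sa %o% sa)
  R0 <- P - G0
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) < 0 ||
      min(eigen(R0, symmetric = TRUE, only.values = TRUE)$values) < 0)
    stop("implied G0/R0 are not positive semidefinite; check parameters")
  list(G0 = G0, R0 = R0)
}

#' The default five-trait beef evaluation model
#'
#' Yearling weight (WT12, kg) plus the four carcass traits: carcass weight
#' (CWT, kg), eye-muscle area (EMA, cm2), backfat thickness (BFT, mm) and
#' marbling score (MS, score 1-9). WT12 is fitted with the composite
#' batch-location-station factor `BLT`; the carcass traits with the
#' batch-station-slaughter-date factor `BTS` and an age-at-slaughter
#' covariate `age`. G0 and R0 are built with [trait_covariances()] from
#' moderate heritabilities (0.26-0.56) and the trait correlation structure
#' typical of beef carcass evaluations.
#'
#' @return A [trait_model()].
#' @export
default_trait_model <- function() {
  traits <- c("WT12", "CWT", "EMA", "BFT", "MS")
  h2 <- c(0.26, 0.35, 0.44, 0.46, 0.56)
  rg <- diag(5)
  rg[upper.tri(rg)] <- c(0.70, 0.33, 0.55, 0.01, 0.10, -0.24, -0.14, 0.17, 0.30, -0.04)
  rg <- rg + t(rg) - diag(5)
  rp <- diag(5)
  rp[lower.tri(rp)] <- c(0.71, 0.34, 0.17, 0.01, 0.54, 0.26, 0.09, 0.01, 0.22, 0.06)
  rp <- rp + t(rp) - diag(5)
  sd_p <- c(54.12, 42.07, 8.82, 3.82, 1.62)
  cv <- trait_covariances(h2, rg, rp, sd_p)
  carcass <- traits[-1]
  trait_model(
    traits,
    fixed_factors = c(list(WT12 = "BLT"),
                      stats::setNames(rep(list("BTS"), 4), carcass)),
    covariates = stats::setNames(rep(list("age"), 4), carcass),
    G0 = cv$G0, R0 = cv$R0
  )
}

#' Build multi-trait design matrices from a phenotype table
#'
#' One incidence row per observed (animal, trait) record. X gets, per trait,
#' an intercept, reference-coded factor columns (first level dropped for
#' identifiability) and covariate columns; Z maps each record to its
#' animal-by-trait genetic effect, stacked trait-major over all pedigree
#' animals (record-less animals included).
#'
#' @param phen data.frame with columns `animal`, `trait`, `value` plus any
#'   factor/covariate columns named by the model. Rows with missing `value`
#'   are dropped.
#' @param model a [trait_model()].
#' @param ped a [pedigree()] covering every phenotyped animal.
#' @return Object of class `mme_design`: sparse `X`, `Z`, numeric `y`,
#'   record index table `rec`, per-animal observed-trait `patterns`, and
#'   bookkeeping (trait/animal counts, fixed-effect column names).
#' @export
build_design <- function(phen, model, ped) {
  stopifnot(inherits(model, "trait_model"), inherits(ped, "pedigree"))
  need <- c("animal", "trait", "value")
  if (!all(need %in% names(phen)))
    stop("phenotype table must have columns animal, trait, value")
  phen <- phen[!is.na(phen$value), , drop = FALSE]
  if (!nrow(phen)) stop("no non-missing phenotype records")
  if (!all(phen$trait %in% model$traits))
    stop("unknown trait(s): ", paste(setdiff(unique(phen$trait), model$traits), collapse = ", "))
  ai <- match(as.character(phen$animal), ped$id)
  if (anyNA(ai))
    stop("animal(s) absent from pedigree: ",
         paste(utils::head(unique(phen$animal[is.na(ai)]), 3), collapse = ", "))
  ti <- match(phen$trait, model$traits)
  if (anyDuplicated(cbind(ai, ti)))
    stop("duplicate (animal, trait) record(s)")
  q <- length(ped$id)
  t <- length(model$traits)
  N <- nrow(phen)

  # X: block per trait; reference coding
  xi <- integer(0); xj <- integer(0); xv <- numeric(0)
  xnames <- character(0)
  col0 <- 0L
  for (k in seq_len(t)) {
    tr <- model$traits[k]
    rows <- which(ti == k)
    if (!length(rows)) next
    xnames <- c(xnames, paste0(tr, ":(Intercept)"))
    xi <- c(xi, rows); xj <- c(xj, rep(col0 + 1L, length(rows)))
    xv <- c(xv, rep(1, length(rows)))
    col0 <- col0 + 1L
    for (f in model$fixed_factors[[tr]]) {
      if (!f %in% names(phen)) stop("factor column '", f, "' missing from phenotype table")
      lev <- sort(unique(as.character(phen[[f]][rows])))
      if (length(lev) > 1) {
        use <- lev[-1] # first level is the reference
        m <- match(as.character(phen[[f]][rows]), use)
        keep <- !is.na(m)
        xi <- c(xi, rows[keep]); xj <- c(xj, col0 + m[keep])
        xv <- c(xv, rep(1, sum(keep)))
        xnames <- c(xnames, paste0(tr, ":", f, lev[-1]))
        col0 <- col0 + length(use)
      }
    }
    for (cv in model$covariates[[tr]]) {
      if (!cv %in% names(phen)) stop("covariate column '", cv, "' missing from phenotype table")
      v <- as.numeric(phen[[cv]][rows])
      if (anyNA(v)) stop("missing covariate '", cv, "' for observed records")
      xi <- c(xi, rows); xj <- c(xj, rep(col0 + 1L, length(rows)))
      xv <- c(xv, v)
      xnames <- c(xnames, paste0(tr, ":", cv))
      col0 <- col0 + 1L
    }
  }
  X <- Matrix::sparseMatrix(i = xi, j = xj, x = xv, dims = c(N, col0))
  colnames(X) <- xnames
  Z <- Matrix::sparseMatrix(i = seq_len(N), j = (ti - 1L) * q + ai,
                            x = rep(1, N), dims = c(N, q * t))
  pat <- split(ti, ai)
  structure(list(X = X, Z = Z, y = as.numeric(phen$value),
                 rec = data.frame(animal = ai, trait = ti),
                 patterns = lapply(pat, function(v) sort(unique(v))),
                 q = q, t = t, traits = model$traits, animal_ids = ped$id,
                 n_fixed = col0, fixed_names = xnames),
            class = "mme_design")
}

# Residual precision matrix over records: block-diagonal per animal, each
# block the inverse of the R0 submatrix for that animal's observed traits
# (the exact missing-record treatment). Also returns per-pattern log|R0_sub|
# totals for the REML likelihood.
residual_precision <- function(design, R0) {
  rec <- design$rec
  N <- nrow(rec)
  ord <- order(rec$animal, rec$trait)
  key <- vapply(split(rec$trait[ord], rec$animal[ord]),
                function(v) paste(v, collapse = ","), character(1))
  # rows of each animal, sorted by trait
  rows_by_animal <- split(ord, rec$animal[ord])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ldetR <- 0
  for (kval in unique(key)) {
    tset <- as.integer(strsplit(kval, ",")[[1]])
    k <- length(tset)
    Rsub <- R0[tset, tset, drop = FALSE]
    Rinv <- chol2inv(chol(Rsub))
    ldet <- as.numeric(determinant(Rsub, logarithm = TRUE)$modulus)
    animals <- names(key)[key == kval]
    ldetR <- ldetR + ldet * length(animals)
    recmat <- matrix(unlist(rows_by_animal[animals]), ncol = k, byrow = TRUE)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        ii <- c(ii, recmat[, a]); jj <- c(jj, recmat[, b])
        xx <- c(xx, rep(Rinv[a, b], nrow(recmat)))
      }
    }
  }
  list(Rinv = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N)),
       ldetR = ldetR)
}

# name one dependent fixed-effect column when the MME cannot be factorized
singular_message <- function(sys, design) {
  Xb <- as.matrix(sys$C[seq_len(sys$n_fixed), seq_len(sys$n_fixed), drop = FALSE])
  qrX <- qr(Xb)
  dep <- if (qrX$rank < sys$n_fixed)
    design$fixed_names[qrX$pivot[qrX$rank + 1L]] else "(unknown)"
  paste0("coefficient matrix is singular; dependent fixed-effect column: ", dep)
}

# Assemble the mixed-model equations C theta = rhs for given covariance
# components and relationship inverse. u is stacked trait-major:
# equation offset for trait k is n_fixed + (k-1)*q.
mme_system <- function(design, G0, R0, Kinv) {
  if (nrow(Kinv) != design$q)
    stop("Kinv must cover all pedigree animals")
  rp <- residual_precision(design, R0)
  Rinv <- rp$Rinv
  W <- cbind(design$X, design$Z)
  WtR <- Matrix::crossprod(W, Rinv)
  C <- WtR %*% W
  G0inv <- chol2inv(chol(G0))
  prior <- kronecker(G0inv, Kinv)
  nf <- design$n_fixed
  p <- nf + design$q * design$t
  pad <- Matrix::bdiag(Matrix::Matrix(0, nf, nf, sparse = TRUE), prior)
  C <- Matrix::forceSymmetric(C + pad)
  rhs <- as.numeric(WtR %*% design$y)
  list(C = C, rhs = rhs, W = W, Rinv = Rinv, ldetR = rp$ldetR,
       n_fixed = nf, p = p)
}

#' Solve the mixed-model equations
#'
#' Henderson's multi-trait mixed-model equations with residual precision
#' assembled per animal from the observed-trait R0 submatrix (exact missing
#' record treatment), and genetic prior `Kinv (x) G0-inverse` over all
#' pedigree animals. `Kinv` is the sparse A-inverse for a pedigree
#' evaluation or the single-step H-inverse for a genomic one. Prediction
#' error variances are read off the inverse coefficient matrix exactly.
#'
#' @param design an [build_design()] object.
#' @param G0,R0 genetic and residual trait covariance matrices.
#' @param Kinv sparse relationship inverse over all pedigree animals
#'   ([nrm_inverse()] or [h_inverse()]).
#' @param compute_pev extract per-equation prediction error variances from
#'   the inverse coefficient matrix (exact; requires a full inverse, so costs
#'   a dense factorization at the system size).
#' @param method label stored with the result (`"ped"`, `"ss"`, ...).
#' @return Object of class `blup_fit`: fixed-effect solutions `b`, breeding
#'   values `u` (animals x traits, all pedigree animals), `pev` and `sep`
#'   matrices (when requested), and system metadata.
#' @export
solve_mme <- function(design, G0, R0, Kinv, compute_pev = TRUE,
                      method = "ped") {
  stopifnot(inherits(design, "mme_design"))
  sys <- mme_system(design, G0, R0, Kinv)
  nf <- sys$n_fixed
  q <- design$q; t <- design$t
  if (compute_pev) {
    Cd <- as.matrix(sys$C)
    ch <- tryCatch(chol(Cd), error = function(e) NULL)
    rm(Cd) # at ~15k equations each dense copy is over a GiB
    if (is.null(ch)) stop(singular_message(sys, design))
    theta <- backsolve(ch, backsolve(ch, sys$rhs, transpose = TRUE))
  } else {
    fac <- tryCatch(Matrix::Cholesky(sys$C, LDL = FALSE),
                    error = function(e) NULL)
    if (is.null(fac)) stop(singular_message(sys, design))
    theta <- as.numeric(Matrix::solve(fac, sys$rhs))
  }
  b <- stats::setNames(theta[seq_len(nf)], design$fixed_names)
  u <- matrix(theta[-seq_len(nf)], nrow = q, ncol = t,
              dimnames = list(design$animal_ids, design$traits))
  pev <- sep <- NULL
  if (compute_pev) {
    dci <- diag(chol2inv(ch))
    rm(ch)
    pev <- matrix(dci[-seq_len(nf)], nrow = q, ncol = t,
                  dimnames = list(design$animal_ids, design$traits))
    pev[pev < 0 & pev > -1e-8] <- 0
    if (any(pev < 0)) stop("negative prediction error variance: numerical fault")
    sep <- sqrt(pev)
  }
  structure(list(method = method, b = b, u = u, pev = pev, sep = sep,
                 n_equations = sys$p, n_records = length(design$y),
                 traits = design$traits),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("BLUP fit (", x$method, "): ", nrow(x$u), " animals x ",
      length(x$traits), " traits, ", x$n_records, " records, ",
      x$n_equations, " equations\n", sep = "")
  invisible(x)
}

#' Write breeding-value solutions as TSV
#'
#' Long format: `animal, trait, method, u, sep, pev`.
#'
#' @param fit a `blup_fit` from [solve_mme()].
#' @param path output file path.
#' @export
write_solutions <- function(fit, path) {
  df <- data.frame(
    animal = rep(rownames(fit$u), times = ncol(fit$u)),
    trait = rep(colnames(fit$u), each = nrow(fit$u)),
    method = fit$method,
    u = as.numeric(fit$u),
    sep = if (is.null(fit$sep)) NA_real_ else as.numeric(fit$sep),
    pev = if (is.null(fit$pev)) NA_real_ else as.numeric(fit$pev)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
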