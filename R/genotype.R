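#' Read a dosage matrix (PLINK RAW or native TSV)
#'
#' Accepts a PLINK `--recode A` table (columns `FID IID PAT MAT SEX
#' PHENOTYPE` followed by one dosage column per marker) or a native
#' whitespace/tab-separated dialect whose first column is the animal ID and
#' whose remaining columns are per-marker dosages. Missing calls are `NA`.
#'
#' @param path file path.
#' @return Integer matrix, animals in rows (IDs as rownames), markers in
#'   columns, values in `{0, 1, 2, NA}`.
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  plink_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_cols %in% names(df))) {
    ids <- as.character(df$IID)
    M <- as.matrix(df[, setdiff(names(df), plink_cols), drop = FALSE])
  } else {
    ids <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
  }
  storage.mode(M) <- "integer"
  if (anyDuplicated(ids)) stop("duplicate animal IDs in genotype file")
  bad <- M[!is.na(M)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(M) <- ids
  M
}

#' Write a dosage matrix as tab-separated text
#'
#' @param M dosage matrix (animals x markers, rownames = IDs).
#' @param path output file path.
#' @export
write_dosage <- function(M, path) {
  df <- data.frame(animal = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Allele frequencies of the counted allele
#'
#' Per-marker frequency of the allele whose dosage is counted, computed over
#' non-missing calls only: `p = sum(dosage) / (2 * n_called)`. Markers with
#' no calls at all get `NA` and are flagged via the `"all_missing"`
#' attribute rather than raising an error.
#'
#' @param M dosage matrix (animals x markers).
#' @return Numeric vector of frequencies in `[0, 1]`, named by marker, with
#'   attribute `all_missing` (logical vector).
#' @export
allele_frequencies <- function(M) {
  if (length(M) == 0) stop("genotype matrix is empty")
  called <- colSums(!is.na(M))
  p <- colSums(M, na.rm = TRUE) / (2 * called)
  p[called == 0] <- NA_real_
  attr(p, "all_missing") <- called == 0
  p
}

#' Opposite-homozygote conflict rate between two genotype rows
#'
#' Fraction of jointly called markers where one individual is dosage 0 and
#' the other dosage 2 -- a Mendelian impossibility for a true parent-child
#' pair. Used for genotype-based parentage checking.
#'
#' @param child,parent dosage vectors over the same marker set.
#' @return Conflict rate in `[0, 1]`; `NA` (flagged, no error) when no
#'   marker is called in both. Attribute `n_called` holds the joint count.
#' @export
parentage_conflict_rate <- function(child, parent) {
  if (length(child) != length(parent)) stop("rows cover different marker sets")
  both <- !is.na(child) & !is.na(parent)
  n <- sum(both)
  rate <- if (n == 0) NA_real_ else
    sum((child[both] == 0L & parent[both] == 2L) |
        (child[both] == 2L & parent[both] == 0L)) / n
  structure(rate, n_called = n)
}

#' Genotype quality control
#'
#' Applies the marker filters first -- monomorphic, minor allele frequency
#' strictly below `maf_min`, call rate strictly below `call_rate_min` -- then
#' the animal filters: missing rate strictly above `animal_missing_max`, and
#' (when `parent_pairs` is given) genotype-based parentage errors with an
#' opposite-homozygote rate above `parentage_max`. Filtering is idempotent.
#'
#' @param M dosage matrix (animals x markers).
#' @param maf_min minimum minor allele frequency (default 0.05; a marker at
#'   exactly 0.05 is kept).
#' @param call_rate_min minimum per-marker call rate (default 0.90).
#' @param animal_missing_max maximum per-animal missing rate (default 0.10).
#' @param parent_pairs optional 2-column character matrix/data.frame of
#'   (animal, parent) ID pairs to check; both must be rows of `M`.
#' @param parentage_max opposite-homozygote rate above which the animal is
#'   removed (default 0.01).
#' @return List with `M` (the filtered matrix) and `report` (a `qc_report`
#'   object tallying removals by reason and the thresholds used).
#' @export
qc_filter <- function(M, maf_min = 0.05, call_rate_min = 0.90,
                      animal_missing_max = 0.10,
                      parent_pairs = NULL, parentage_max = 0.01) {
  n_animals_in <- nrow(M)
  n_markers_in <- ncol(M)
  p <- allele_frequencies(M)
  call_rate <- colSums(!is.na(M)) / nrow(M)
  mono <- is.na(p) | p == 0 | p == 1
  maf <- pmin(p, 1 - p)
  low_maf <- !mono & maf < maf_min
  low_cr <- !mono & !low_maf & call_rate < call_rate_min
  keep_marker <- !(mono | low_maf | low_cr)
  M2 <- M[, keep_marker, drop = FALSE]

  miss_rate <- if (ncol(M2)) rowMeans(is.na(M2)) else rep(0, nrow(M2))
  drop_missing <- miss_rate > animal_missing_max

  drop_parentage <- rep(FALSE, nrow(M2))
  if (!is.null(parent_pairs) && nrow(as.matrix(parent_pairs)) > 0) {
    pp <- as.matrix(parent_pairs)
    for (k in seq_len(nrow(pp))) {
      a <- pp[k, 1]; b <- pp[k, 2]
      if (!(a %in% rownames(M2)) || !(b %in% rownames(M2))) next
      r <- parentage_conflict_rate(M2[a, ], M2[b, ])
      if (!is.na(r) && r > parentage_max)
        drop_parentage[match(a, rownames(M2))] <- TRUE
    }
  }
  drop_parentage <- drop_parentage & !drop_missing
  keep_animal <- !(drop_missing | drop_parentage)
  M3 <- M2[keep_animal, , drop = FALSE]
  if (nrow(M3) == 0 || ncol(M3) == 0)
    stop("no markers/animals survive quality control")

  report <- structure(list(
    n_markers_in = n_markers_in,
    n_markers_out = ncol(M3),
    n_animals_in = n_animals_in,
    n_animals_out = nrow(M3),
    removed_markers = list(
      monomorphic = sum(mono),
      low_maf = sum(low_maf),
      low_call_rate = sum(low_cr)
    ),
    removed_animals = list(
      animal_missingness = sum(drop_missing),
      parentage_error = sum(drop_parentage)
    ),
    thresholds = list(maf_min = maf_min, call_rate_min = call_rate_min,
                      animal_missing_max = animal_missing_max,
                      parentage_max = parentage_max)
  ), class = "qc_report")
  list(M = M3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC:", x$n_markers_in, "->", x$n_markers_out, "markers;",
      x$n_animals_in, "->", x$n_animals_out, "animals\n")
  cat("  markers removed: monomorphic", x$removed_markers$monomorphic,
      "| MAF <", x$thresholds$maf_min, ":", x$removed_markers$low_maf,
      "| call rate <", x$thresholds$call_rate_min, ":",
      x$removed_markers$low_call_rate, "\n")
  cat("  animals removed: missing >", x$thresholds$animal_missing_max, ":",
      x$removed_animals$animal_missingness,
      "| parentage:", x$removed_animals$parentage_error, "\n")
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Center genotype dosages
#'
#' Subtracts twice the allele frequency from each dosage (the 0-2p / 1-2p /
#' 2-2p coding). Missing dosages are first imputed to `2p`, i.e. a centered
#' value of zero, which is neutral for the genomic relationship matrix.
#'
#' @param M dosage matrix (animals x markers).
#' @param p per-marker allele frequencies; defaults to
#'   [allele_frequencies()] of `M`.
#' @return Numeric matrix W of centered dosages.
#' @export
center_genotypes <- function(M, p = allele_frequencies(M)) {
  if (ncol(M) != length(p)) stop("p must have one entry per marker")
  W <- sweep(M, 2, 2 * p, `-`)
  W[is.na(W)] <- 0
  W
}

#' VanRaden genomic relationship matrix
#'
#' `G = W D W' / (2 * sum(p (1 - p)))`, where W holds centered dosages, D is
#' an optional per-marker weight (identity when all loci are assumed to have
#' equal variance) and the denominator sums the expected marker variances,
#' scaling G to the same footing as the pedigree relationship matrix.
#'
#' @param W centered dosage matrix from [center_genotypes()].
#' @param p per-marker allele frequencies used in the centering.
#' @param D optional per-marker weights (numeric vector); default identity.
#' @return Object of class `grm`: the symmetric G matrix with attributes
#'   `denom` and `blend` (NULL until [blend_grm()]).
#' @export
build_grm <- function(W, p, D = NULL) {
  if (ncol(W) != length(p)) stop("p must have one entry per marker")
  denom <- 2 * sum(p * (1 - p), na.rm = TRUE)
  if (denom <= 0) stop("all markers fixed: normalizing constant is zero")
  WD <- if (is.null(D)) W else sweep(W, 2, D, `*`)
  G <- tcrossprod(WD, W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(W), rownames(W))
  structure(G, denom = denom, blend = NULL, class = c("grm", "matrix"))
}

#' Blend a genomic relationship matrix with the pedigree submatrix
#'
#' `G_b = alpha * G + beta * A22`. With `beta > 0` and positive-definite
#' A22 the blend is invertible even when the marker count is below the
#' animal count. Applied before inversion in the single-step setup.
#'
#' @param G genomic relationship matrix ([build_grm()] output or plain
#'   matrix) over the genotyped animals.
#' @param A22 pedigree relationship submatrix over the same animals, in the
#'   same order.
#' @param alpha weight on G (default 0.95).
#' @param beta weight on A22 (default `1 - alpha`).
#' @return Blended `grm` with attribute `blend = c(alpha, beta)`.
#' @export
blend_grm <- function(G, A22, alpha = 0.95, beta = 1 - alpha) {
  if (!all(dim(G) == dim(A22))) stop("G and A22 are not conformable")
  if (abs(alpha + beta - 1) > 1e-12) stop("alpha + beta must equal 1")
  if (beta < 0) stop("beta must be >= 0")
  Gb <- alpha * unclass(G) + beta * A22
  structure(Gb, denom = attr(G, "denom"), blend = c(alpha = alpha, beta = beta),
            class = c("grm", "matrix"))
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", nrow(x), "animals; mean diagonal",
      signif(mean(diag(x)), 4))
  b <- attr(x, "blend")
  if (!is.null(b)) cat("; blended alpha =", b[["alpha"]])
  cat("\n")
  invisible(x)
}
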