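#' Prediction accuracy as EBV-GEBV correlation
#'
#' Pearson product-moment correlation between pedigree EBVs and genomic
#' EBVs over a set of animals: the population-level accuracy metric.
#'
#' @param ebv,gebv paired numeric vectors (same animals, same order).
#' @return Correlation in `[-1, 1]`; `NA` (with a warning) when either
#'   vector has zero variance or fewer than 3 pairs are available.
#' @export
r_m1 <- function(ebv, gebv) {
  if (length(ebv) != length(gebv)) stop("ebv and gebv must be paired")
  ok <- !is.na(ebv) & !is.na(gebv)
  if (sum(ok) < 3) {
    warning("fewer than 3 paired values; r_M1 undefined")
    return(NA_real_)
  }
  if (stats::sd(ebv[ok]) == 0 || stats::sd(gebv[ok]) == 0) {
    warning("zero variance; r_M1 undefined")
    return(NA_real_)
  }
  stats::cor(ebv[ok], gebv[ok])
}

#' Per-animal accuracy from prediction error variance
#'
#' `r_M2 = sqrt(max(0, 1 - PEV / V_A))`: the reliability-derived accuracy of
#' an individual breeding value, with the additive genetic variance `V_A`
#' taken from a pedigree-only REML fit. Animals whose PEV reaches the prior
#' variance carry no information and are clamped to 0.
#'
#' @param pev numeric vector/matrix of prediction error variances.
#' @param v_a additive genetic variance (scalar, or one per column of a
#'   matrix `pev`).
#' @return Accuracies in `[0, 1]`, same shape as `pev`.
#' @export
r_m2 <- function(pev, v_a) {
  if (any(v_a <= 0)) stop("v_a must be positive")
  if (any(pev < -1e-8, na.rm = TRUE)) stop("negative PEV: upstream numerical fault")
  pev <- pmax(pev, 0)
  if (is.matrix(pev)) {
    if (length(v_a) == 1) v_a <- rep(v_a, ncol(pev))
    if (length(v_a) != ncol(pev)) stop("one v_a per trait column required")
    out <- sqrt(pmax(1 - sweep(pev, 2, v_a, `/`), 0))
  } else {
    out <- sqrt(pmax(1 - pev / v_a, 0))
  }
  out
}

#' Stratified accuracy comparison of two evaluations
#'
#' Compares a pedigree and a single-step fit over the same animals: per
#' stratum and trait, the mean, SD and range of per-animal `r_M2` for both
#' methods, the EBV-GEBV correlation `r_M1`, and the percent change of the
#' stratum mean accuracy under the single-step fit. Strata are the whole
#' population, the info-type labels (PHEN / GEN / PH+GEN) and the bull-type
#' labels (YBULL / CBULL / PBULL). The percent change is computed on
#' unrounded stratum means; round only for display.
#'
#' @param fit_ped,fit_ss `blup_fit` objects from [solve_mme()] with PEV
#'   computed, covering the same animals and traits.
#' @param v_a named per-trait additive genetic variances (pedigree REML).
#' @param labels data.frame with columns `animal`, `info_type`,
#'   `bull_type`; animals missing from it fall outside the labelled strata
#'   but still count in the population stratum.
#' @return Object of class `accuracy_report`: a data.frame with columns
#'   `stratum_type`, `stratum`, `trait`, `n`, `r_m1`, per-method mean / sd /
#'   min / max of r_M2, and `pct_increase`. Empty strata yield NA rows.
#' @export
accuracy_report <- function(fit_ped, fit_ss, v_a, labels = NULL) {
  stopifnot(inherits(fit_ped, "blup_fit"), inherits(fit_ss, "blup_fit"))
  if (!identical(rownames(fit_ped$u), rownames(fit_ss$u)))
    stop("fits cover different animals")
  if (is.null(fit_ped$pev) || is.null(fit_ss$pev))
    stop("both fits need PEV (solve_mme(compute_pev = TRUE))")
  traits <- fit_ped$traits
  if (is.null(names(v_a))) names(v_a) <- traits
  acc_ped <- r_m2(fit_ped$pev, v_a[traits])
  acc_ss <- r_m2(fit_ss$pev, v_a[traits])
  ids <- rownames(fit_ped$u)

  strata <- list(list(type = "population", name = "population", ids = ids))
  if (!is.null(labels)) {
    for (lv in c("PHEN", "GEN", "PH+GEN"))
      strata[[length(strata) + 1]] <- list(
        type = "info", name = lv,
        ids = labels$animal[!is.na(labels$info_type) & labels$info_type == lv])
    for (lv in c("YBULL", "CBULL", "PBULL"))
      strata[[length(strata) + 1]] <- list(
        type = "bull", name = lv,
        ids = labels$animal[!is.na(labels$bull_type) & labels$bull_type == lv])
  }

  rows <- list()
  for (st in strata) {
    sel <- ids %in% st$ids
    for (tr in traits) {
      if (!any(sel)) {
        rows[[length(rows) + 1]] <- data.frame(
          stratum_type = st$type, stratum = st$name, trait = tr, n = 0L,
          r_m1 = NA_real_, mean_ss = NA_real_, sd_ss = NA_real_,
          min_ss = NA_real_, max_ss = NA_real_, mean_ped = NA_real_,
          sd_ped = NA_real_, min_ped = NA_real_, max_ped = NA_real_,
          pct_increase = NA_real_)
        next
      }
      as_ <- acc_ss[sel, tr]; ap <- acc_ped[sel, tr]
      mp <- mean(ap); ms <- mean(as_)
      rows[[length(rows) + 1]] <- data.frame(
        stratum_type = st$type, stratum = st$name, trait = tr, n = sum(sel),
        r_m1 = suppressWarnings(r_m1(fit_ped$u[sel, tr], fit_ss$u[sel, tr])),
        mean_ss = ms, sd_ss = stats::sd(as_), min_ss = min(as_), max_ss = max(as_),
        mean_ped = mp, sd_ped = stats::sd(ap), min_ped = min(ap), max_ped = max(ap),
        pct_increase = if (mp > 0) 100 * (ms - mp) / mp else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  y$pct_increase <- round(as.data.frame(x)$pct_increase, 1)
  print(y)
  invisible(x)
}

#' Write an accuracy report as TSV and/or JSON
#'
#' @param report an [accuracy_report()].
#' @param path output path; a `.json` suffix writes JSON, anything else TSV.
#' @export
write_accuracy_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Decile calibration of predicted accuracy against realized accuracy
#'
#' Bins animals into deciles of their predicted per-animal accuracy `r_M2`
#' and, within each decile, computes the realized accuracy: the correlation
#' between estimated and true breeding values (simulation only). Used to
#' check that the PEV-derived accuracies rank animals the way realized
#' accuracy does.
#'
#' @param acc per-animal predicted accuracy (r_M2).
#' @param u_hat estimated breeding values.
#' @param tbv true breeding values.
#' @param n_bins number of bins (default 10).
#' @return data.frame with per-bin mean predicted accuracy and realized
#'   correlation, plus the Spearman correlation between the two across bins
#'   as attribute `spearman`.
#' @export
decile_calibration <- function(acc, u_hat, tbv, n_bins = 10) {
  stopifnot(length(acc) == length(u_hat), length(acc) == length(tbv))
  br <- stats::quantile(acc, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- cut(acc, unique(br), labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- bin == b
    data.frame(bin = b, n = sum(s), mean_acc = mean(acc[s]),
               realized = if (sum(s) > 2) stats::cor(u_hat[s], tbv[s]) else NA_real_)
  }))
  ok <- !is.na(tab$realized)
  attr(tab, "spearman") <- if (sum(ok) > 2)
    stats::cor(tab$mean_acc[ok], tab$realized[ok], method = "spearman") else NA_real_
  tab
}
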