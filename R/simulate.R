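#' Configuration for the synthetic breeding-population generator
#'
#' Defines the study conditions the generator emulates: a multi-generation
#' pedigree with overlapping sire use (so that proven sires with large
#' progeny groups exist), unlinked biallelic markers gene-dropped through
#' the pedigree, a subset of markers acting as QTL that carry the
#' multi-trait genetic effects, trait-specific composite fixed effects, an
#' age-at-slaughter covariate on the carcass traits, and per-animal
#' information labels (phenotyped / genotyped / both) with the trait
#' missingness patterns of a proven-bull scheme.
#'
#' @param n_founders founder animals (generation 0).
#' @param n_generations total discrete generations including founders.
#' @param n_per_generation offspring per later generation.
#' @param n_sires_per_gen sires sampled per generation (small, so progeny
#'   groups are large).
#' @param n_markers biallelic SNP markers.
#' @param n_qtl markers carrying trait effects (subset of the panel).
#' @param maf_range founder minor-allele-frequency range (uniform draw).
#' @param model a [trait_model()]; its G0/R0 are the simulation truth.
#' @param trait_means per-trait phenotypic means.
#' @param mode `"qtl"` (marker-based breeding values; default) or
#'   `"polygenic"` (infinitesimal pedigree transmission).
#' @param polygenic_frac in `"qtl"` mode, fraction of genetic variance
#'   assigned to a polygenic remainder (default 0).
#' @param n_blt,n_bts level counts of the two composite fixed effects.
#' @param effect_sd_frac fixed-effect level SD as a fraction of the trait
#'   phenotypic SD.
#' @param age_mean,age_sd age-at-slaughter covariate distribution (months).
#' @param age_slope named slopes per carcass trait (units per month).
#' @param info_fractions named fractions of animals per info-type
#'   (`OTHER`, `PHEN`, `PH+GEN`, `GEN`); must sum to 1. GEN animals are
#'   drawn from the youngest generation, PHEN and PH+GEN from earlier ones.
#' @param pattern_phen,pattern_phgen trait-pattern fractions
#'   (first-trait-only / all traits / carcass-only) within the phenotyped
#'   info-types.
#' @param genotype_missing_rate random missing-call rate in the observed
#'   genotype matrix.
#' @param cbull_frac fraction of the youngest generation labelled CBULL
#'   (the selected candidates); the rest of that generation is YBULL.
#' @param pbull_min_progeny minimum progeny count for the PBULL label.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 600,
                       n_generations = 4,
                       n_per_generation = 800,
                       n_sires_per_gen = 25,
                       n_markers = 2000,
                       n_qtl = 200,
                       maf_range = c(0.05, 0.5),
                       model = default_trait_model(),
                       trait_means = NULL,
                       mode = c("qtl", "polygenic"),
                       polygenic_frac = 0,
                       n_blt = 8, n_bts = 10,
                       effect_sd_frac = 0.5,
                       age_mean = 30, age_sd = 2,
                       age_slope = NULL,
                       info_fractions = c(OTHER = 0.55, PHEN = 0.20,
                                          `PH+GEN` = 0.17, GEN = 0.08),
                       pattern_phen = c(first_only = 0.72, all = 0.12,
                                        carcass_only = 0.16),
                       pattern_phgen = c(first_only = 0.38, all = 0.62,
                                         carcass_only = 0),
                       genotype_missing_rate = 0.01,
                       cbull_frac = 0.3,
                       pbull_min_progeny = 10) {
  mode <- match.arg(mode)
  stopifnot(n_founders >= 2, n_generations >= 1,
            abs(sum(info_fractions) - 1) < 1e-8)
  traits <- model$traits
  if (is.null(trait_means)) {
    trait_means <- if (identical(traits, c("WT12", "CWT", "EMA", "BFT", "MS")))
      c(WT12 = 350, CWT = 371, EMA = 81.6, BFT = 9.7, MS = 3.6)
    else stats::setNames(rep(0, length(traits)), traits)
  }
  if (is.null(age_slope)) {
    age_slope <- if (identical(traits, c("WT12", "CWT", "EMA", "BFT", "MS")))
      c(CWT = 5, EMA = 0.8, BFT = 0.25, MS = 0.05)
    else stats::setNames(numeric(0), character(0))
  }
  structure(list(
    n_founders = n_founders, n_generations = n_generations,
    n_per_generation = n_per_generation, n_sires_per_gen = n_sires_per_gen,
    n_markers = n_markers, n_qtl = n_qtl, maf_range = maf_range,
    model = model, trait_means = trait_means, mode = mode,
    polygenic_frac = polygenic_frac, n_blt = n_blt, n_bts = n_bts,
    effect_sd_frac = effect_sd_frac, age_mean = age_mean, age_sd = age_sd,
    age_slope = age_slope, info_fractions = info_fractions,
    pattern_phen = pattern_phen, pattern_phgen = pattern_phgen,
    genotype_missing_rate = genotype_missing_rate,
    cbull_frac = cbull_frac, pbull_min_progeny = pbull_min_progeny
  ), class = "sim_config")
}

#' Simulate a discrete-generation pedigree with bull-type labels
#'
#' Founders form generation 0; each later generation draws a small set of
#' sires and random dams from the previous generation. The youngest
#' generation is split into candidate bulls (CBULL) and young bull calves
#' (YBULL); sires with at least `pbull_min_progeny` progeny are proven
#' bulls (PBULL, taking precedence).
#'
#' @param cfg a [sim_config()].
#' @return List with `ped` (a [pedigree()]) and `labels` (data.frame with
#'   `animal`, `generation`, `sex`, `bull_type`).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sprintf("A%05d", seq_len(cfg$n_founders))
  gen <- rep(0L, cfg$n_founders)
  sex <- sample(c("M", "F"), cfg$n_founders, replace = TRUE)
  sire <- dam <- rep("0", cfg$n_founders)
  counter <- cfg$n_founders
  if (cfg$n_generations > 1) {
    for (g in seq_len(cfg$n_generations - 1)) {
      prev <- which(gen == g - 1L)
      males <- prev[sex[prev] == "M"]
      females <- prev[sex[prev] == "F"]
      if (length(males) == 0 || length(females) == 0)
        stop("infeasible mating: a generation lacks one sex")
      sires_g <- sample(males, min(cfg$n_sires_per_gen, length(males)))
      n_off <- cfg$n_per_generation
      new_ids <- sprintf("A%05d", counter + seq_len(n_off))
      counter <- counter + n_off
      s_pick <- sample(sires_g, n_off, replace = TRUE)
      d_pick <- sample(females, n_off, replace = TRUE)
      ids <- c(ids, new_ids)
      gen <- c(gen, rep(g, n_off))
      sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
      sire <- c(sire, ids[s_pick])
      dam <- c(dam, ids[d_pick])
    }
  }
  ped <- pedigree(ids, sire, dam)
  ord <- match(ped$id, ids)
  gen <- gen[ord]; sex <- sex[ord]
  bull <- rep("OTHER", length(ids))
  if (cfg$n_generations > 1) {
    last <- which(gen == max(gen))
    ncb <- round(cfg$cbull_frac * length(last))
    cb <- if (ncb > 0) sample(last, ncb) else integer(0)
    bull[last] <- "YBULL"
    bull[cb] <- "CBULL"
    prog <- table(ped$sire[ped$sire > 0L])
    pb <- as.integer(names(prog)[prog >= cfg$pbull_min_progeny])
    bull[pb] <- "PBULL"
  }
  list(ped = ped,
       labels = data.frame(animal = ped$id, generation = gen, sex = sex,
                           bull_type = bull, stringsAsFactors = FALSE))
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders draw each allele independently at the founder frequency of the
#' marker; descendants inherit one random allele per parent per locus
#' (unlinked loci). Unknown parents contribute a fresh founder draw. The
#' latent dosages cover every pedigree animal; masking to the genotyped
#' subset happens downstream.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()].
#' @return List with `dosage` (animals x markers, all animals), the two
#'   allele matrices `h1`, `h2`, and founder frequencies `p_founder`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  n <- length(ped$id)
  m <- cfg$n_markers
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    h1[i, ] <- if (s > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, h1[s, ], h2[s, ])
    } else as.integer(stats::runif(m) < p)
    h2[i, ] <- if (d > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, h1[d, ], h2[d, ])
    } else as.integer(stats::runif(m) < p)
  }
  dosage <- h1 + h2
  dimnames(dosage) <- list(ped$id, sprintf("M%05d", seq_len(m)))
  list(dosage = dosage, h1 = h1, h2 = h2, p_founder = p)
}

#' Simulate true breeding values and phenotypes
#'
#' In `"qtl"` mode the true breeding values are sums of effects at QTL
#' markers inside the SNP panel; the drawn effect matrix is rescaled so the
#' frequency-weighted effect covariance equals the target G0 exactly, so
#' realized genetic variance matches the target up to Hardy-Weinberg
#' sampling noise. In `"polygenic"` mode breeding values follow the
#' infinitesimal model down the pedigree (founders N(0, G0), offspring
#' parent-average plus Mendelian sampling scaled by the pedigree `d`).
#' Phenotypes add trait means, composite fixed effects, the age covariate
#' on carcass traits, and residuals drawn jointly from R0.
#'
#' @param ped a [pedigree()].
#' @param geno result of [simulate_genotypes()] (may be NULL in polygenic
#'   mode).
#' @param cfg a [sim_config()].
#' @param info_type per-animal info labels (in sorted pedigree order);
#'   phenotype records are emitted for `PHEN` and `PH+GEN` animals.
#' @return List with `tbv` (animals x traits), `phen` (long phenotype
#'   table), and `truth` (QTL indices and effects, fixed-effect values).
#' @export
simulate_phenotypes <- function(ped, geno, cfg, info_type) {
  model <- cfg$model
  traits <- model$traits
  t <- length(traits)
  n <- length(ped$id)
  G0 <- model$G0; R0 <- model$R0

  qtl_idx <- integer(0); beta <- NULL
  if (cfg$mode == "qtl") {
    if (is.null(geno)) stop("qtl mode needs genotypes")
    qtl_idx <- sort(sample.int(cfg$n_markers, cfg$n_qtl))
    pq <- geno$p_founder[qtl_idx]
    w <- 2 * pq * (1 - pq)
    G0_qtl <- (1 - cfg$polygenic_frac) * G0
    B0 <- matrix(stats::rnorm(cfg$n_qtl * t), cfg$n_qtl, t)
    U0 <- chol(crossprod(sqrt(w) * B0))
    beta <- B0 %*% solve(U0) %*% chol(G0_qtl)
    Wq <- sweep(geno$dosage[, qtl_idx, drop = FALSE], 2, 2 * pq, `-`)
    tbv <- Wq %*% beta
    if (cfg$polygenic_frac > 0)
      tbv <- tbv + polygenic_tbv(ped, cfg$polygenic_frac * G0)
  } else {
    tbv <- polygenic_tbv(ped, G0)
  }
  dimnames(tbv) <- list(ped$id, traits)

  # fixed effects and covariates
  sd_p <- sqrt(diag(G0 + R0))
  blt_level <- sample.int(cfg$n_blt, n, replace = TRUE)
  bts_level <- sample.int(cfg$n_bts, n, replace = TRUE)
  blt_eff <- matrix(stats::rnorm(cfg$n_blt * t, 0, cfg$effect_sd_frac * rep(sd_p, each = cfg$n_blt)),
                    cfg$n_blt, t)
  bts_eff <- matrix(stats::rnorm(cfg$n_bts * t, 0, cfg$effect_sd_frac * rep(sd_p, each = cfg$n_bts)),
                    cfg$n_bts, t)
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  resid <- matrix(stats::rnorm(n * t), n, t) %*% chol(R0)

  yfull <- matrix(rep(cfg$trait_means[traits], each = n), n, t) + tbv + resid
  for (k in seq_len(t)) {
    tr <- traits[k]
    fac <- model$fixed_factors[[tr]]
    if ("BLT" %in% fac) yfull[, k] <- yfull[, k] + blt_eff[blt_level, k]
    if ("BTS" %in% fac) yfull[, k] <- yfull[, k] + bts_eff[bts_level, k]
    if ("age" %in% model$covariates[[tr]]) {
      slope <- if (tr %in% names(cfg$age_slope)) cfg$age_slope[[tr]] else 0
      yfull[, k] <- yfull[, k] + slope * age
    }
  }

  # which traits each phenotyped animal records
  phenotyped <- info_type %in% c("PHEN", "PH+GEN")
  obs <- matrix(FALSE, n, t)
  if (t == 1) {
    obs[phenotyped, 1] <- TRUE
  } else {
    first <- 1L
    carcass <- setdiff(seq_len(t), first)
    for (it in c("PHEN", "PH+GEN")) {
      idx <- which(info_type == it)
      if (!length(idx)) next
      pr <- if (it == "PHEN") cfg$pattern_phen else cfg$pattern_phgen
      patt <- sample(names(pr), length(idx), replace = TRUE, prob = pr)
      obs[idx[patt == "first_only"], first] <- TRUE
      obs[idx[patt == "all"], ] <- TRUE
      obs[idx[patt == "carcass_only"], carcass] <- TRUE
    }
  }
  rec <- which(obs, arr.ind = TRUE)
  phen <- data.frame(
    animal = ped$id[rec[, 1]],
    trait = traits[rec[, 2]],
    value = yfull[rec],
    BLT = paste0("B", blt_level[rec[, 1]]),
    BTS = paste0("S", bts_level[rec[, 1]]),
    age = age[rec[, 1]],
    stringsAsFactors = FALSE
  )
  list(tbv = tbv, phen = phen,
       truth = list(qtl_idx = qtl_idx, beta = beta,
                    blt_eff = blt_eff, bts_eff = bts_eff, age = age,
                    blt_level = blt_level, bts_level = bts_level))
}

# infinitesimal breeding values down the pedigree: founder N(0, S), child
# parent-average + Mendelian sampling with variance d_i * S
polygenic_tbv <- function(ped, S) {
  n <- length(ped$id)
  t <- nrow(as.matrix(S))
  L <- chol(as.matrix(S))
  tbv <- matrix(0, n, t)
  ms <- matrix(stats::rnorm(n * t), n, t) %*% L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pa <- numeric(t)
    if (s > 0L) pa <- pa + 0.5 * tbv[s, ]
    if (d > 0L) pa <- pa + 0.5 * tbv[d, ]
    tbv[i, ] <- pa + sqrt(ped$d[i]) * ms[i, ]
  }
  tbv
}

#' Generate a complete synthetic evaluation dataset
#'
#' Runs the whole generator under one seed: pedigree with bull-type labels,
#' gene-dropped genotypes, info-type assignment, true breeding values,
#' phenotypes with trait-pattern missingness, and the observed genotype
#' matrix (genotyped animals only, with random missing calls). Regeneration
#' from the same configuration and seed is identical.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_dataset`: `ped`, `genotypes`
#'   (observed dosage matrix or NULL), `phen`, `tbv`, `labels` (with
#'   `info_type` and `bull_type`), and `truth` (generator internals,
#'   including founder frequencies and QTL effects).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  pl <- simulate_pedigree(cfg)
  ped <- pl$ped
  labels <- pl$labels
  n <- length(ped$id)
  gen <- labels$generation

  # info-type assignment: GEN from the youngest generation, PHEN and
  # PH+GEN from older generations, remainder OTHER
  info <- rep("OTHER", n)
  counts <- round(cfg$info_fractions * n)
  young <- which(gen == max(gen))
  older <- which(gen < max(gen))
  if (max(gen) == 0) older <- young # single-generation edge case
  gsel <- sample(young, min(counts[["GEN"]], length(young)))
  info[gsel] <- "GEN"
  pool <- setdiff(c(older, young), gsel)
  pg <- sample(intersect(pool, older), min(counts[["PH+GEN"]], length(intersect(pool, older))))
  info[pg] <- "PH+GEN"
  pool <- setdiff(pool, pg)
  ph <- sample(intersect(pool, older), min(counts[["PHEN"]], length(intersect(pool, older))))
  info[ph] <- "PHEN"
  labels$info_type <- info

  geno <- if (cfg$mode == "qtl" || cfg$n_markers > 0)
    simulate_genotypes(ped, cfg) else NULL
  sp <- simulate_phenotypes(ped, geno, cfg, info)

  genotyped <- info %in% c("GEN", "PH+GEN")
  M <- NULL
  if (any(genotyped) && !is.null(geno)) {
    M <- geno$dosage[genotyped, , drop = FALSE]
    if (cfg$genotype_missing_rate > 0) {
      mask <- matrix(stats::runif(length(M)) < cfg$genotype_missing_rate,
                     nrow(M), ncol(M))
      M[mask] <- NA_integer_
    }
  }
  structure(list(ped = ped, genotypes = M, phen = sp$phen, tbv = sp$tbv,
                 labels = labels,
                 truth = c(sp$truth,
                           list(p_founder = geno$p_founder, seed = seed,
                                latent_dosage = geno$dosage))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$ped$id), "animals,",
      if (is.null(x$genotypes)) 0 else nrow(x$genotypes), "genotyped,",
      nrow(x$phen), "phenotype records\n")
  print(table(x$labels$info_type))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `pedigree.csv`, `genotypes.tsv`, `phenotypes.tsv`, `labels.tsv`
#' and `truth.json` (true breeding values and generator parameters) into a
#' directory.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(ds$ped, file.path(dir, "pedigree.csv"))
  if (!is.null(ds$genotypes))
    write_dosage(ds$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.table(ds$phen, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ds$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = ds$truth$seed, qtl_idx = ds$truth$qtl_idx,
         p_founder = ds$truth$p_founder,
         tbv = as.data.frame(ds$tbv)),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
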