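test_that("allele frequencies count non-missing calls only", {
  M <- cbind(m1 = c(0L, 1L, 2L, 2L, NA))
  p <- allele_frequencies(M)
  expect_equal(unname(p[1]), 5 / 8)
  expect_equal(unname(allele_frequencies(cbind(c(0L, 0L)))[1]), 0)
  expect_equal(unname(allele_frequencies(cbind(c(2L, 2L)))[1]), 1)
  # all-missing marker is flagged, not an error
  pm <- allele_frequencies(cbind(a = c(1L, 2L), b = c(NA, NA)))
  expect_true(is.na(pm["b"]))
  expect_identical(unname(attr(pm, "all_missing")), c(FALSE, TRUE))
})

test_that("parentage conflict rate counts opposite homozygotes", {
  expect_equal(as.numeric(parentage_conflict_rate(c(0L, NA), c(2L, 1L))), 1)
  expect_equal(as.numeric(parentage_conflict_rate(c(0L, 1L, 2L), c(0L, 1L, 2L))), 0)
  child <- rep(0L, 100); parent <- rep(0L, 100)
  parent[1:2] <- 2L
  expect_equal(as.numeric(parentage_conflict_rate(child, parent)), 0.02)
  # no jointly called markers: flagged NA
  expect_true(is.na(parentage_conflict_rate(c(NA, 1L), c(2L, NA))))
})

test_that("QC applies the marker filters then the animal filters", {
  # 10 animals x 3 markers: monomorphic, MAF exactly 0.05 (kept),
  # call rate 0.8 (removed)
  M <- cbind(
    mono = rep(0L, 10),
    rare = c(1L, rep(0L, 9)),
    lowcall = c(NA, NA, rep(1L, 4), rep(0L, 4))
  )
  rownames(M) <- paste0("a", 1:10)
  res <- qc_filter(M)
  expect_identical(colnames(res$M), "rare")
  expect_equal(res$report$removed_markers$monomorphic, 1)
  expect_equal(res$report$removed_markers$low_call_rate, 1)
  expect_equal(res$report$n_animals_out, 10)
  # tallies are consistent: in - removed = out
  expect_equal(res$report$n_markers_in - Reduce(`+`, res$report$removed_markers),
               res$report$n_markers_out)

  # a marker with MAF 0.04 falls under the strict 5% rule
  M2 <- cbind(ok = rep(c(0L, 1L), 25), maf04 = c(rep(1L, 4), rep(0L, 46)))
  expect_identical(colnames(qc_filter(M2)$M), "ok")

  # idempotence and the no-op case
  again <- qc_filter(res$M)
  expect_identical(again$M, res$M)
  expect_equal(again$report$n_markers_in, again$report$n_markers_out)
  expect_equal(again$report$n_animals_in, again$report$n_animals_out)
})

test_that("QC removes high-missingness animals and parentage conflicts", {
  set.seed(2)
  M <- matrix(sample(0:2, 40 * 60, replace = TRUE), 40, 60,
              dimnames = list(paste0("a", 1:40), paste0("m", 1:60)))
  M[1, 1:10] <- NA # 1/6 missing > 10%
  M[3, ] <- 2L - M[2, ] # animal 3 opposite-homozygous to its declared sire
  res <- qc_filter(M, parent_pairs = cbind("a3", "a2"))
  expect_false("a1" %in% rownames(res$M))
  expect_false("a3" %in% rownames(res$M))
  expect_equal(res$report$removed_animals$animal_missingness, 1)
  expect_equal(res$report$removed_animals$parentage_error, 1)
  # everything filtered away raises an explicit error
  expect_error(qc_filter(cbind(rep(0L, 5))), "survive")
})

test_that("centering uses the 0-2p coding and mean-imputes missing calls", {
  expect_equal(center_genotypes(cbind(1L), p = 0.5)[1, 1], 0)
  expect_equal(center_genotypes(cbind(2L), p = 0.8)[1, 1], 0.4)
  expect_equal(center_genotypes(cbind(0L), p = 0.8)[1, 1], -1.6)
  expect_equal(center_genotypes(cbind(NA), p = 0.3)[1, 1], 0)
})

test_that("the genomic relationship matrix matches the hand example", {
  W <- center_genotypes(cbind(c(0L, 1L, 2L)), p = 0.5)
  G <- build_grm(W, p = 0.5)
  expect_equal(unclass(G), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3),
               ignore_attr = TRUE)
  # identical animals at 2p give a zero matrix
  expect_equal(max(abs(build_grm(matrix(0, 4, 3), p = rep(0.5, 3)))), 0)
  # all markers fixed: no normalizing constant
  expect_error(build_grm(matrix(0, 2, 2), p = c(0, 1)), "fixed")
  # marker weights D rescale marker contributions
  W2 <- matrix(c(-1, 1, 0.5, -0.5), 2)
  p2 <- c(0.5, 0.25)
  Gw <- build_grm(W2, p2, D = c(2, 0))
  expect_equal(unclass(Gw), 2 * tcrossprod(W2[, 1]) / (2 * sum(p2 * (1 - p2))),
               ignore_attr = TRUE)
})

test_that("HWE genotypes give mean diagonal near 1 and centered off-diagonals", {
  set.seed(99)
  n <- 300; m <- 2000
  p <- stats::runif(m, 0.1, 0.5)
  M <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  rownames(M) <- paste0("a", 1:n)
  phat <- allele_frequencies(M)
  G <- build_grm(center_genotypes(M, phat), phat)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("blending is a convex combination and restores invertibility", {
  G <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  A22 <- matrix(c(0.5, 0, 0, 0.5), 2)
  expect_equal(unclass(blend_grm(G, A22, alpha = 1)), G, ignore_attr = TRUE)
  expect_equal(unclass(blend_grm(G, A22, alpha = 0)), A22, ignore_attr = TRUE)
  expect_equal(blend_grm(G, A22, alpha = 0.95)[1, 1], 0.88)
  expect_error(blend_grm(G, diag(3), 0.95), "conformable")

  # rank-deficient G (fewer markers than animals) becomes Cholesky-able
  set.seed(1)
  n <- 50; m <- 20
  p <- stats::runif(m, 0.2, 0.5)
  M <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  G2 <- build_grm(center_genotypes(M, allele_frequencies(M)), allele_frequencies(M))
  Gb <- blend_grm(G2, diag(n), alpha = 0.95)
  expect_silent(chol(unclass(Gb)))
})

test_that("dosage matrices round-trip through PLINK-RAW and native TSV", {
  M <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), 2, 3,
              dimnames = list(c("a1", "a2"), c("m1", "m2", "m3")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage(M, tsv)
  expect_identical(read_dosage(tsv), M)

  raw <- withr::local_tempfile(fileext = ".raw")
  df <- data.frame(FID = 1:2, IID = c("a1", "a2"), PAT = 0, MAT = 0, SEX = 0,
                   PHENOTYPE = -9, m1 = M[, 1], m2 = M[, 2], m3 = M[, 3])
  utils::write.table(df, raw, row.names = FALSE, quote = FALSE)
  expect_identical(read_dosage(raw), M)
  expect_error(read_dosage({
    bad <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(data.frame(animal = "a", m1 = 5), bad,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    bad
  }), "dosages")
})
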