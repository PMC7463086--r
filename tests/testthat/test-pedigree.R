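test_that("validation and sorting handle founders, reordering, appended parents", {
  # identity case: founders stay as-is
  p <- pedigree(c("a", "b", "c"), c("0", "0", "0"), c("0", "0", "0"))
  expect_equal(p$id, c("a", "b", "c"))
  expect_true(all(p$sire == 0L & p$dam == 0L))

  # child listed before its sire gets reordered below it
  p2 <- pedigree(c("C", "S"), c("S", "0"), c("0", "0"))
  expect_lt(match("S", p2$id), match("C", p2$id))

  # parents only ever referenced become founder records
  p3 <- pedigree("kid", "papa", "mama")
  expect_setequal(p3$id, c("kid", "papa", "mama"))
  expect_equal(sum(p3$sire == 0L & p3$dam == 0L), 2)

  expect_error(pedigree(c("x", "x"), c("0", "0"), c("0", "0")), "duplicate")
  expect_error(pedigree(c("X", "Y"), c("Y", "X"), c("0", "0")), "cycle")
})

test_that("inbreeding matches the classical closed forms", {
  # all founders
  p <- pedigree(c("a", "b"), c("0", "0"), c("0", "0"))
  expect_identical(unname(inbreeding(p)), c(0, 0))

  # full-sib mating: offspring F = 0.25 exactly
  fs <- pedigree(c("s", "d", "x", "y", "z"),
                 c("0", "0", "s", "s", "x"),
                 c("0", "0", "d", "d", "y"))
  expect_identical(inbreeding(fs)[["z"]], 0.25)

  # parent-offspring mating: F = 0.25 exactly
  po <- pedigree(c("s", "d", "x", "z"),
                 c("0", "0", "s", "s"),
                 c("0", "0", "d", "x"))
  expect_identical(inbreeding(po)[["z"]], 0.25)

  # any unknown parent side gives F = 0 under the unrelated-founder convention
  up <- pedigree(c("s", "x"), c("0", "s"), c("0", "0"))
  expect_identical(inbreeding(up)[["x"]], 0)
})

test_that("tabular A has the classical structure", {
  p <- pedigree(c("a", "b", "c"), c("0", "0", "0"), c("0", "0", "0"))
  expect_equal(nrm(p), diag(3), ignore_attr = TRUE)

  fs <- pedigree(c("s", "d", "x", "y"),
                 c("0", "0", "s", "s"), c("0", "0", "d", "d"))
  A <- nrm(fs)
  expect_equal(A["x", "y"], 0.5)
  expect_equal(diag(A), c(s = 1, d = 1, x = 1, y = 1))

  # diagonal minus one reproduces the inbreeding coefficients exactly
  set.seed(31)
  rp <- pedigree(random_trios(60))
  expect_identical(unname(diag(nrm(rp)) - 1), unname(rp$F))

  # subsetting errors on unknown IDs
  expect_error(nrm(fs, c("x", "nope")), "not in pedigree")
})

test_that("A agrees with gene-dropping IBD sharing on a random pedigree", {
  set.seed(77)
  ped <- pedigree(random_trios(30))
  n <- length(ped$id)
  L <- 100000L
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    a1[i, ] <- if (s > 0L) ifelse(stats::runif(L) < 0.5, a1[s, ], a2[s, ]) else
      rep.int(2L * i - 1L, L)
    a2[i, ] <- if (d > 0L) ifelse(stats::runif(L) < 0.5, a1[d, ], a2[d, ]) else
      rep.int(2L * i, L)
  }
  Ahat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    Ahat[i, j] <- Ahat[j, i] <- if (i == j) 1 + mean(a1[i, ] == a2[i, ]) else
      (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
       mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 2
  }
  A <- nrm(ped)
  expect_lt(mean(abs(A - Ahat)), 0.02)
})

test_that("Henderson A-inverse inverts the tabular A", {
  # founders only: identity
  p <- pedigree(c("a", "b"), c("0", "0"), c("0", "0"))
  expect_equal(as.matrix(nrm_inverse(p)), diag(2), ignore_attr = TRUE)

  # sire-offspring with unknown dam: analytic 2x2 inverse of [[1,.5],[.5,1]]
  so <- pedigree(c("S", "X"), c("0", "S"), c("0", "0"))
  expect_equal(as.matrix(nrm_inverse(so)),
               matrix(c(4, -2, -2, 4) / 3, 2), ignore_attr = TRUE)

  # A is symmetric PSD and Ainv densified inverts it
  set.seed(5)
  for (k in 1:3) {
    ped <- pedigree(random_trios(150))
    A <- nrm(ped)
    expect_lt(max(abs(A - t(A))), 1e-12)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_lt(max(abs(as.matrix(nrm_inverse(ped)) %*% A - diag(nrow(A)))), 1e-8)
  }
})

test_that("average relatedness is the off-diagonal row mean", {
  A <- matrix(c(1, 0.5, 0.25,
                0.5, 1, 0,
                0.25, 0, 1), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(mean_relatedness(A)[["a"]], 0.375)
  # founder unrelated to everyone
  expect_equal(mean_relatedness(A["c", "c", drop = FALSE])[["c"]], 0)
  # three-generation toy against hand-computed row means
  p <- pedigree(c("s", "d", "x", "z"), c("0", "0", "s", "x"), c("0", "0", "d", "0"))
  A3 <- nrm(p)
  # A rows: s-(d,x,z) = 0,.5,.25 ; x-(s,d,z) = .5,.5,.5
  expect_equal(mean_relatedness(A3)[["s"]], mean(c(0, 0.5, 0.25)))
  expect_equal(mean_relatedness(A3)[["x"]], mean(c(0.5, 0.5, 0.5)))
})

test_that("pedigree round-trips through CSV with order and F columns", {
  fs <- pedigree(c("x", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(fs, path)
  back <- read_pedigree(path)
  expect_identical(back$id, fs$id)
  expect_identical(back$F, fs$F)
  df <- utils::read.csv(path)
  expect_named(df, c("animal", "sire", "dam", "order", "F"))
})
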