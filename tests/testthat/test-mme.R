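test_that("design matrices enumerate records and patterns correctly", {
  ped <- pedigree(paste0("a", 1:5), rep("0", 5), rep("0", 5))
  m1 <- trait_model("T", G0 = matrix(1), R0 = matrix(1))
  phen <- data.frame(animal = c("a1", "a2"), trait = "T", value = c(1, 2))
  d <- build_design(phen, m1, ped)
  # overall mean: X is a column of ones; Z picks the two recorded animals
  expect_equal(as.numeric(as.matrix(d$X)), c(1, 1))
  expect_equal(dim(d$Z), c(2L, 5L))
  expect_equal(Matrix::rowSums(d$Z), c(1, 1), ignore_attr = TRUE)

  # 5 animals x 2 traits with one missing cell: 9 rows, patterns match
  m2 <- two_trait_model()
  ph2 <- rbind(
    data.frame(animal = paste0("a", 1:5), trait = "T1", value = 1:5),
    data.frame(animal = paste0("a", 1:4), trait = "T2", value = 1:4),
    data.frame(animal = "a5", trait = "T2", value = NA)
  )
  d2 <- build_design(ph2, m2, ped)
  expect_equal(length(d2$y), 9L)
  expect_equal(d2$patterns[["5"]], 1L)
  expect_true(all(vapply(d2$patterns[as.character(1:4)], identical,
                         logical(1), 1:2)))

  expect_error(build_design(data.frame(animal = "zz", trait = "T", value = 1),
                            m1, ped), "absent from pedigree")
  expect_error(build_design(phen[c(1, 1), ], m1, ped), "duplicate")
})

test_that("the two-animal overall-mean system matches the hand solve", {
  ped <- pedigree(c("1", "2"), c("0", "0"), c("0", "0"))
  m <- trait_model("T", G0 = matrix(1), R0 = matrix(1))
  phen <- data.frame(animal = c("1", "2"), trait = "T", value = c(10, 12))
  fit <- solve_mme(build_design(phen, m, ped), m$G0, m$R0, nrm_inverse(ped))
  expect_equal(unname(fit$b), 11)
  expect_equal(as.numeric(fit$u), c(-0.5, 0.5))
  # inverse coefficient matrix diagonal: PEV 0.75, SEP sqrt(0.75)
  expect_equal(as.numeric(fit$pev), c(0.75, 0.75))
  expect_equal(as.numeric(fit$sep), rep(sqrt(0.75), 2))
})

test_that("breeding values vanish as genetic variance goes to zero", {
  set.seed(3)
  ped <- pedigree(random_trios(30))
  m <- trait_model("T", G0 = matrix(1e-8), R0 = matrix(1))
  phen <- data.frame(animal = ped$id, trait = "T", value = rnorm(30, 5))
  fit <- solve_mme(build_design(phen, m, ped), m$G0, m$R0, nrm_inverse(ped),
                   compute_pev = FALSE)
  expect_lt(max(abs(fit$u)), 1e-3)
})

test_that("multi-trait solutions equal the dense GLS oracle", {
  set.seed(17)
  ped <- pedigree(random_trios(60))
  m <- two_trait_model()
  phen <- all_records_phen(ped, m, sd_e = 8)
  phen <- phen[-sample.int(nrow(phen), 20), ] # introduce missing cells
  d <- build_design(phen, m, ped)
  fit <- solve_mme(d, m$G0, m$R0, nrm_inverse(ped), compute_pev = FALSE)
  oracle <- gls_fit(d, m$G0, m$R0, nrm(ped))
  expect_equal(as.numeric(fit$u), as.numeric(oracle$u), tolerance = 1e-6)
  expect_equal(unname(fit$b), oracle$b, tolerance = 1e-6)
})

test_that("solutions are invariant to record order", {
  set.seed(23)
  ped <- pedigree(random_trios(40))
  m <- two_trait_model()
  phen <- all_records_phen(ped, m, sd_e = 8)
  d1 <- build_design(phen, m, ped)
  d2 <- build_design(phen[sample.int(nrow(phen)), ], m, ped)
  f1 <- solve_mme(d1, m$G0, m$R0, nrm_inverse(ped), compute_pev = FALSE)
  f2 <- solve_mme(d2, m$G0, m$R0, nrm_inverse(ped), compute_pev = FALSE)
  expect_lt(max(abs(f1$u - f2$u)), 1e-10)
})

test_that("with diagonal G0 and R0 the traits decouple into single-trait solves", {
  set.seed(29)
  ped <- pedigree(random_trios(40))
  mj <- trait_model(c("T1", "T2"), G0 = diag(c(20, 35)), R0 = diag(c(60, 45)))
  phen <- all_records_phen(ped, mj, sd_e = 8)
  fj <- solve_mme(build_design(phen, mj, ped), mj$G0, mj$R0, nrm_inverse(ped))
  for (k in 1:2) {
    mk <- trait_model("T", G0 = mj$G0[k, k, drop = FALSE],
                      R0 = mj$R0[k, k, drop = FALSE])
    pk <- phen[phen$trait == paste0("T", k), ]
    pk$trait <- "T"
    fk <- solve_mme(build_design(pk, mk, ped), mk$G0, mk$R0, nrm_inverse(ped))
    expect_equal(unname(fj$u[, k]), unname(fk$u[, 1]), tolerance = 1e-8)
    expect_equal(unname(fj$pev[, k]), unname(fk$pev[, 1]), tolerance = 1e-8)
  }
})

test_that("PEV is bounded by the prior variance and responds to information", {
  set.seed(37)
  ped <- pedigree(random_trios(50))
  m <- trait_model("T", G0 = matrix(1), R0 = matrix(1.5))
  phen <- data.frame(animal = ped$id[1:30], trait = "T", value = rnorm(30))
  fit <- solve_mme(build_design(phen, m, ped), m$G0, m$R0, nrm_inverse(ped))
  expect_true(all(fit$pev <= 1 + 1e-8))

  # an isolated record-less founder sits at the prior variance exactly
  iso <- pedigree(c(paste0("a", 1:3), "lone"), c("0", "0", "a1", "0"),
                  c("0", "0", "a2", "0"))
  ph <- data.frame(animal = c("a1", "a2", "a3"), trait = "T", value = c(1, 2, 3))
  f2 <- solve_mme(build_design(ph, m, iso), m$G0, m$R0, nrm_inverse(iso))
  expect_equal(f2$pev["lone", 1], 1, tolerance = 1e-10)

  # an extra progeny record never increases the sire's PEV (recorded
  # unrelated founders anchor the overall mean, otherwise the sire effect
  # is confounded with it and no progeny information accrues)
  sire_ped <- function(k) {
    ids <- c("S", paste0("u", 1:10), paste0("p", seq_len(k)))
    pedigree(ids, c("0", rep("0", 10), rep("S", k)), rep("0", 11 + k))
  }
  pev_sire <- sapply(2:5, function(k) {
    pd <- sire_ped(k)
    ph <- data.frame(animal = c(paste0("u", 1:10), paste0("p", 1:k)),
                     trait = "T", value = c(rnorm(10), seq_len(k) / 2))
    solve_mme(build_design(ph, m, pd), m$G0, m$R0, nrm_inverse(pd))$pev["S", 1]
  })
  expect_true(all(diff(pev_sire) < 0))
})

test_that("confounded fixed effects are reported by column", {
  ped <- pedigree(c("1", "2"), c("0", "0"), c("0", "0"))
  m <- trait_model("T", fixed_factors = list(T = c("f1", "f2")),
                   G0 = matrix(1), R0 = matrix(1))
  # f1 and f2 are identical factors: their columns are linearly dependent
  phen <- data.frame(animal = c("1", "2"), trait = "T", value = c(1, 2),
                     f1 = c("x", "y"), f2 = c("x", "y"))
  expect_error(solve_mme(build_design(phen, m, ped), m$G0, m$R0,
                         nrm_inverse(ped)), "dependent fixed-effect column")
})

test_that("solutions write out in the long TSV layout", {
  ped <- pedigree(c("1", "2"), c("0", "0"), c("0", "0"))
  m <- trait_model("T", G0 = matrix(1), R0 = matrix(1))
  phen <- data.frame(animal = c("1", "2"), trait = "T", value = c(10, 12))
  fit <- solve_mme(build_design(phen, m, ped), m$G0, m$R0, nrm_inverse(ped))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_solutions(fit, path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_named(df, c("animal", "trait", "method", "u", "sep", "pev"))
  expect_equal(df$u, c(-0.5, 0.5))
})
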