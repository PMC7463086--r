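# shared fixtures: random pedigrees, a dense GLS oracle, small simulations

# random pedigree of n animals; parents sampled among earlier animals with
# probability p_parent per side; rows shuffled so sorting is exercised
random_trios <- function(n, p_parent = 0.7) {
  sire <- dam <- rep("0", n)
  for (i in 3:n) {
    prev <- seq_len(i - 1)
    if (stats::runif(1) < p_parent) sire[i] <- as.character(sample(prev, 1))
    if (stats::runif(1) < p_parent) {
      d <- sample(prev, 1)
      if (as.character(d) != sire[i]) dam[i] <- as.character(d)
    }
  }
  df <- data.frame(animal = as.character(seq_len(n)), sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  df[sample.int(n), ]
}

# dense generalized-least-squares / conditional-expectation solution from
# the joint covariance V = Z (G0 x A) Z' + R: an independent route to the
# same estimands as the mixed-model equations
gls_fit <- function(design, G0, R0, A) {
  X <- as.matrix(design$X)
  Z <- as.matrix(design$Z)
  y <- design$y
  Gfull <- kronecker(G0, A)
  rec <- design$rec
  N <- length(y)
  R <- matrix(0, N, N)
  for (a in unique(rec$animal)) {
    rows <- which(rec$animal == a)
    R[rows, rows] <- R0[rec$trait[rows], rec$trait[rows]]
  }
  V <- Z %*% Gfull %*% t(Z) + R
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- Gfull %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b),
       u = matrix(u, nrow = design$q, ncol = design$t))
}

# two-trait model with fixed covariances for quick multi-trait tests
two_trait_model <- function() {
  trait_model(c("T1", "T2"),
              G0 = matrix(c(30, 15, 15, 30), 2),
              R0 = matrix(c(70, 10, 10, 70), 2))
}

# small phenotype table on a pedigree: every animal records every trait
all_records_phen <- function(ped, model, sd_e = 1) {
  t <- length(model$traits)
  n <- length(ped$id)
  data.frame(
    animal = rep(ped$id, times = t),
    trait = rep(model$traits, each = n),
    value = stats::rnorm(n * t, 0, sd_e)
  )
}
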