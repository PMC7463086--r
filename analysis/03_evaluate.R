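#!/usr/bin/env Rscript
# Step 3: the two evaluations.
#
# pedBLUP: multi-trait animal model with the sparse pedigree A-inverse.
# ssGBLUP: the same equations with the single-step H-inverse, built from the
# VanRaden genomic relationship matrix (blended 95:5 with A22 before
# inversion; tau = omega = 1). Exact prediction error variances come from
# the inverse coefficient matrix, so this step carries the dense
# factorization cost (about 10,500 equations here; expect a few minutes).

suppressMessages(library(ssgblup))

ped <- read_pedigree("results/data/pedigree.csv")
phen <- utils::read.table("results/data/phenotypes.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(animal = "character"))
M <- read_dosage("results/data/genotypes_qc.tsv")
model <- default_trait_model()

design <- build_design(phen, model, ped)
cat("Design:", length(design$y), "records,",
    design$n_fixed + design$q * design$t, "equations\n")

cat("Solving pedBLUP ...\n")
Ainv <- nrm_inverse(ped)
fit_ped <- solve_mme(design, model$G0, model$R0, Ainv, method = "ped")

cat("Building H-inverse and solving ssGBLUP ...\n")
p <- allele_frequencies(M)
G <- build_grm(center_genotypes(M, p), p)
print(G)
Hinv <- single_step_hinv(ped, G, tau = 1, omega = 1, blend_alpha = 0.95)
fit_ss <- solve_mme(design, model$G0, model$R0, Hinv, method = "ss")

write_solutions(fit_ped, "results/solutions_ped.tsv")
write_solutions(fit_ss, "results/solutions_ss.tsv")
cat("Correlation of the two sets of breeding values, per trait:\n")
print(round(diag(stats::cor(fit_ped$u, fit_ss$u)), 3))
cat("Solutions written under results/\n")
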