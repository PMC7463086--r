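#!/usr/bin/env Rscript
# Step 1: generate the synthetic proven-bull study population.
#
# A four-generation pedigree with a small sire pool so that proven sires
# accumulate large progeny groups, 2,000 unlinked biallelic markers (200 of
# them QTL carrying the five-trait genetic effects), heritabilities
# 0.26-0.56, and info-type labels that reserve genotype-only status for the
# youngest generation. This study uses 2,000 animals (400 founders, 530 per
# later generation) so the exact-PEV evaluations in step 3 stay within a
# small workstation's memory; the generator itself defaults to 3,000.

suppressMessages(library(ssgblup))

seed <- 2026
outdir <- "results/data"
cat("Simulating the study population (seed ", seed, ") ...\n", sep = "")
ds <- simulate_dataset(sim_config(n_founders = 400, n_per_generation = 530),
                       seed = seed)
print(ds)

cat("\nPedigree summary:\n")
print(ds$ped)
cat("Bull types:\n")
print(table(ds$labels$bull_type))
cat("Mean inbreeding F:", signif(mean(ds$ped$F), 3),
    "| max F:", signif(max(ds$ped$F), 3), "\n")
cat("Phenotype records by trait:\n")
print(table(ds$phen$trait))

write_dataset(ds, outdir)
cat("\nDataset written under", outdir, "\n")
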