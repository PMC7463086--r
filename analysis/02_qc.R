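#!/usr/bin/env Rscript
# Step 2: genotype quality control on the simulated dosage matrix.
#
# Filters mirror routine SNP-chip practice: monomorphic markers, minor
# allele frequency strictly below 5%, marker call rate below 90%, then
# animals with more than 10% missing calls. Parent-offspring pairs that are
# both genotyped are screened for opposite-homozygote conflicts.

suppressMessages(library(ssgblup))

M <- read_dosage("results/data/genotypes.tsv")
ped <- read_pedigree("results/data/pedigree.csv")

# genotyped parent-offspring pairs for the parentage screen
pdf <- as.data.frame(ped)
pairs <- pdf[pdf$sire != "0" & pdf$animal %in% rownames(M) &
               pdf$sire %in% rownames(M), c("animal", "sire")]
cat("Checking", nrow(pairs), "genotyped parent-offspring pairs\n")

res <- qc_filter(M, parent_pairs = pairs)
print(res$report)

dir.create("results", showWarnings = FALSE)
write_qc_report(res$report, "results/qc_report.json")
write_dosage(res$M, "results/data/genotypes_qc.tsv")
cat("Filtered genotypes and QC report written under results/\n")
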