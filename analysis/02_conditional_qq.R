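#!/usr/bin/env Rscript

# Stage 2: conditional Q-Q enrichment.
#
# Reads the simulated pair, harmonizes alleles, partitions variants into
# LD blocks, and computes conditional Q-Q curves of the primary trait
# within strata of secondary-trait significance (-log10 p >= 0, 1, 2, 3),
# averaged over 100 random-pruning iterations (one variant per block).
# Successive upward deflection of the stratified curves is the signature
# of pleiotropic enrichment.

library(conjfdr)

sim_dir <- "results/sim"
stopifnot(file.exists(file.path(sim_dir, "trait1.tsv")))

primary <- read_sumstats(file.path(sim_dir, "trait1.tsv"))
secondary <- read_sumstats(file.path(sim_dir, "trait2.tsv"))
paired <- harmonize_pair(primary, secondary)
cat(sprintf("harmonized %d variants (%s)\n", nrow(paired),
            paste(names(attr(paired, "meta")), attr(paired, "meta"),
                  sep = "=", collapse = ", ")))

ld <- read_ld_table(file.path(sim_dir, "pairs.ld"))
blocks <- ld_blocks(ld, paired$snp, r2_threshold = 0.1)
print(blocks)

qq <- conditional_qq(paired, blocks, qq_config(seed = 42))
enr <- attr(qq, "enrichment")

dir.create("results", showWarnings = FALSE)
write.table(qq, "results/qq_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, "results/qq_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nenrichment summary (mean curve lift over the all-SNP stratum,\n")
cat("at matched nominal quantiles):\n")
print(enr, row.names = FALSE)
if (all(diff(enr$enrichment) > 0)) {
  cat("\nenrichment increases strictly across conditioning strata:\n")
  cat("the stronger the secondary-trait association, the further the\n")
  cat("primary-trait p-values deflect from the null line.\n")
}
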