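#!/usr/bin/env Rscript

# Stage 5: two-sample Mendelian randomization.
#
# Estimates the causal effect of gene expression on disease risk from
# per-instrument summary statistics: Wald ratio (single instrument),
# fixed-effect inverse-variance weighting, and the weighted median
# (robust to up to half the weight coming from invalid instruments).
# Also converts a published OR with 95% CI back to beta/se/p as a
# reporting cross-check.

library(conjfdr)

sim <- simulate_mr_instruments(n_iv = 50, beta_true = 0.2, seed = 42)
iv <- sim$instruments

est <- list(
  wald_first = wald_ratio(iv[1, ]),
  ivw = ivw(iv),
  weighted_median = weighted_median(iv, seed = 42))

res <- do.call(rbind, lapply(est, as.data.frame))
dir.create("results", showWarnings = FALSE)
write.table(res, "results/mr_estimates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("true causal effect: %.3f\n", sim$truth$beta_true))
for (e in est) print(e)

## reporting cross-check: a published chronotype -> disease estimate
## (OR 1.37, 95% CI 1.09-1.72) implies p = 0.0068
s <- summarize_or_ci(1.37, 1.09, 1.72)
cat(sprintf("\nOR 1.37 (1.09-1.72) implies beta %.4f, se %.4f, p %.4f\n",
            s$beta, s$se, s$p))
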