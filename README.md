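# conjfdr

Cross-trait pleiotropy analysis from GWAS summary statistics: conditional
Q–Q enrichment, conditional/conjunctional false discovery rates
(condFDR/conjFDR), LD clumping of shared variants into independent loci,
and the downstream stages such studies run — two-sample Mendelian
randomization and case/control differential expression.

## Who this is for

Statistical geneticists who have two sets of GWAS summary statistics —
say type 2 diabetes and a sleep trait such as chronotype — and want to
know which variants plausibly drive *both*, without individual-level
data. Everything runs from plain text tables: two summary-statistics
files, a PLINK-style pairwise LD table, and optionally a SNP→gene map,
a GMT gene-set file, an expression matrix, and MR instrument tables.

## The statistics

For variant *i*, the conditional FDR of trait 1 given trait 2 is
estimated with the null proportion fixed conservatively at 1:

    FDR(1|2)_i = min(1, p1_i / F̂(p1_i | p2 ≤ p2_i))

where F̂ is the empirical conditional cdf of p1 among variants whose p2
is at most the observed one — estimated either by direct tie-inclusive
counting ("exact" mode, the reference definition) or on a grid averaged
over random LD-pruning iterations, one variant per LD block per draw
("strata" mode, the pipeline default, which keeps LD from manufacturing
spurious enrichment). The conjunctional FDR is the conservative maximum

    FDR(1&2)_i = max(FDR(1|2)_i, FDR(2|1)_i)

and variants with conjFDR < 0.01 are clumped into loci: connected
components of the r² > 0.1 graph among significant variants, each led by
its smallest-conjFDR member. MR estimators (Wald ratio, fixed-effect
IVW, weighted median with bootstrap SE) and the differential-expression
stage (per-gene scaling, |value| > 3 SD entry masking, Welch t-tests
with Benjamini–Hochberg correction) complete the workflow. The methods
vignette (`vignettes/cross-trait-pleiotropy.Rmd`) documents every
estimator and design choice.

## Worked example

The repository is organized as a numbered analysis over synthetic data
with a known truth (`analysis/01` … `05`). Running the first three
stages:

```sh
Rscript analysis/01_simulate_gwas.R
Rscript analysis/02_conditional_qq.R
Rscript analysis/03_conjfdr_loci.R
```

prints, with the shipped seeds:

```
simulated 100000 variants (33289 LD blocks); component counts:
       null pleiotropic      trait1      trait2
      89874        2054        3904        4168
...
enrichment summary (mean curve lift over the all-SNP stratum,
at matched nominal quantiles):
 stratum   n_mean enrichment
       0 33289.00  0.0000000
       1  4340.14  0.2055192
       2  1091.61  0.9920516
       3   573.79  1.5450448
...
201 variants significant at conjFDR < 0.01, clumped into 81 loci
lead-SNP truth: 78/81 pleiotropic (locus-level FDP 0.037)
```

Reading the output: the enrichment summary grows strictly across the
conditioning strata — primary-trait p-values deflect further from the
null line the stronger the secondary-trait association, the Q–Q
signature of pleiotropy. At conjFDR < 0.01, 81 independent loci are
recovered and almost all leads are truly pleiotropic (the generating
truth is known here).

Stage 3 also re-reads the published shared-locus table for type 2
diabetes and sleep traits shipped under `inst/extdata/` (58 distinct
loci; one lead SNP recurs in two trait pairs) as a round-trip check of
the locus-table format, and stages 4–5 run the differential-expression
and Mendelian-randomization estimators the same way.

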