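---
title: "Cross-trait pleiotropy with conditional and conjunctional FDR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait pleiotropy with conditional and conjunctional FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjfdr)
```

## The problem

Two polygenic traits -- say a metabolic disease and a sleep phenotype --
can share risk variants that neither GWAS detects on its own, because each
effect is individually small. Given only the two sets of summary
statistics (per-variant z-scores and p-values), the conditional FDR
framework re-ranks the evidence for the primary trait using the secondary
trait's association as auxiliary information, and the conjunctional FDR
identifies variants likely non-null for *both* traits. This package
implements that machinery end to end -- harmonization, conditional Q-Q
enrichment, condFDR/conjFDR, LD clumping into loci -- together with the
two downstream stages such studies typically run (two-sample Mendelian
randomization and case/control differential expression) and a synthetic
data generator so that every stage is testable without external downloads.

## The model and the estimators

### Conditional FDR

For variant $i$ with two-sided p-values $p_{1i}$ (primary trait) and
$p_{2i}$ (secondary), the conditional FDR of trait 1 given trait 2 is the
posterior probability that the variant is null for trait 1 given that both
observed p-values are at least as extreme as observed. With the null
proportion conservatively fixed at $\pi_0 = 1$, the empirical-Bayes
estimate is

$$\widehat{\mathrm{FDR}}_{1|2}(i) \;=\; \min\!\left(1,\;
  \frac{p_{1i}}{\hat F(p_{1i} \mid p_2 \le p_{2i})}\right),$$

where $\hat F$ is the empirical conditional cdf of $p_1$ within the subset
of variants whose $p_2$ is at or below the conditioning cutoff. Two
evaluation modes are provided:

* **exact** -- direct tie-inclusive counting over all variants,
  $\min\{1,\, p_{1i}\,\#\{j: p_{2j} \le p_{2i}\} / \#\{j: p_{1j} \le
  p_{1i},\, p_{2j} \le p_{2i}\}\}$, computed in $O(n \log n)$ by a sweep
  with a Fenwick tree (compiled code). This mode is the reference
  definition and the oracle the test suite checks against a naive
  $O(n^2)$ reimplementation.
* **strata** -- the pipeline default. The conditional cdf is estimated on
  a regular grid (step 0.1 on the $-\log_{10} p$ scale in both axes),
  averaging the per-stratum ratio over random-pruning iterations (one
  variant drawn uniformly per LD block, 100 iterations by default), and
  per-variant values are obtained by bilinear interpolation in
  $(-\log_{10} p_1, -\log_{10} p_2)$. Pruning controls the spurious
  enrichment that LD would otherwise inject into $\hat F$; the fitted
  lookup is then applied to *all* variants, so pruned-out variants still
  receive FDR values.

The averaged surface is regularized to be a proper cdf along the $p_1$
axis by monotone pooling that only ever raises values and leaves
already-monotone knots untouched. A variant whose $-\log_{10} p_2$ falls
beyond the last valid stratum is clamped to it (conditioning on a weaker
threshold than observed, which is conservative); a variant outside every
valid stratum gets FDR 1 and a flag.

The conjunctional FDR is the conservative combination
$\widehat{\mathrm{FDR}}_{1\&2} = \max(\widehat{\mathrm{FDR}}_{1|2},
\widehat{\mathrm{FDR}}_{2|1})$, and variants with conjFDR strictly below
the threshold (default 0.01) are declared shared. The threshold default
follows the stricter of the two values conventionally used (0.01 rather
than 0.05); it is exposed as `conjfdr_threshold` because published
analyses are not consistent about which of the two they report, and the
cost of the strict choice is only power, never validity.

### Conditional Q-Q curves

For the all-SNP stratum and each stratum $-\log_{10} p_2 \ge t$ (defaults
$t = 1, 2, 3$), the empirical quantiles of $-\log_{10} p_1$ are plotted
against the nominal quantiles $-\log_{10}(i/(n+1))$, averaged over the
pruning iterations. The scalar *enrichment summary* per stratum is the
mean lift of the stratum curve over the all-SNP curve, evaluated at
matched nominal quantiles and restricted to the quantile range over which
**every** retained stratum still holds at least 20 expected observations.
Restricting to a common, well-populated range matters: tail quantiles of
small strata are dominated by order-statistic noise, and averaging each
stratum over its own range would make summaries incomparable across
strata. Strata smaller than `min_stratum` (default 100) are omitted with
a warning rather than reported as noise.

### LD blocks, pruning and clumping

LD enters only as a pairwise table of $r^2$ values (the reference-panel
computation that produces it is out of scope). Blocks are the connected
components of the graph with edges where $r^2 > 0.1$ (strict inequality;
single linkage). Clumping applies the same construction to the
significant variants only; each component becomes one locus led by its
smallest-conjFDR member, with ties broken by larger $|z_1|$ and then by
smaller position -- the tie-break is this package's rule, since "most
significant SNP" does not define one. Loci are numbered by the
chromosome and position of the lead.

### Mendelian randomization

Per-instrument summary statistics (effect of the variant on exposure and
outcome with standard errors) feed three estimators:

* **Wald ratio** $\beta = b_y / b_x$ with first-order standard error
  $se_y / |b_x|$; the exposure-side uncertainty is ignored, which is the
  standard strong-instrument approximation and matches how
  single-instrument results are conventionally reported.
* **IVW**, the fixed-effect inverse-variance-weighted mean of the per-SNP
  ratios with weights $b_x^2 / se_y^2$; no overdispersion scaling is
  applied because the intended use is small instrument counts (a handful
  per gene).
* **Weighted median**: the ordered ratios interpolated at half the
  normalized weight, consistent when valid instruments carry at least 50%
  of the weight. Its standard error comes from a seeded parametric
  bootstrap (1000 draws by default) perturbing both $b_x$ and $b_y$ by
  their standard errors, because no closed form is standard.

Odds ratios with 95% CIs are interconverted with $\beta = \ln
\mathrm{OR}$, $se = (\ln \mathrm{CI_{hi}} - \ln \mathrm{CI_{lo}})/(2
\times 1.959964)$.

### Differential expression

Expression matrices are scaled per gene across **all** samples (the
alternative, within-group scaling, would erase the group difference being
tested; the choice is parameter-free but worth stating because "scaling"
alone does not pin it down). Outliers are masked entry-wise -- not
sample-wise -- where the absolute scaled value strictly exceeds 3 SD;
masking is applied after scaling. Welch's unequal-variance t-test is the
default (a pooled-variance flag exists) since case and control groups of
different sizes rarely justify equal variances. BH correction runs across
the tested gene subset, with q < 0.05 as the declared set. The
hypergeometric over-representation test for gene sets is one-sided
($P(X \ge k)$), BH-corrected across sets.

### Annotation thresholds

Variant-level annotations are filtered with the conventional cutoffs:
deleteriousness score strictly above 12.37, and regulatory-evidence
categories at or stronger than a configurable rank under the ordering
1a < 1b < ... < 1f < 2a < ... < 7. Unknown category tokens are flagged
rather than silently dropped.

## The synthetic-data generator

`simulate_sumstats_pair()` draws per-block true effect pairs
$(\delta_1, \delta_2)$ from a four-component mixture -- null,
trait-1-only, trait-2-only, pleiotropic -- and emits observed z-scores
$z = \delta + \varepsilon$ with unit-variance noise. Defaults encode the
study conditions the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_variants` | 1e5 | a desk-scale polygenome |
| `pi` | (0.90, 0.04, 0.04, 0.02) | mostly null, small shared component |
| `sigma_b1`, `sigma_b2` | 3 | SD of nonzero effects on the z scale |
| `rho_b` | 0.5 | correlation of pleiotropic effect pairs |
| `rho_ns` | 0 | cross-trait noise correlation (sample overlap) |
| `block_sizes` | 1..5 | LD-block sizes, drawn uniformly |
| `within_r2` | 0.8 | genotype r2 between a block's core and its tags |

Each block has one core variant carrying the full signal; tags load on the
core at $r = \sqrt{r^2}$, so tag z-scores are attenuated and the emitted
LD table (core-tag pairs at `within_r2`, tag-tag pairs at `within_r2`^2)
is consistent with the induced z-score correlations. Secondary-table
alleles are randomly swapped and strand-complemented with signs adjusted,
so the harmonization path is exercised end to end. The `rho_ns` knob
exists because overlapping GWAS samples inflate cross-trait enrichment;
simulating it lets the tests demonstrate that inflation rather than hide
it.

What the generator does **not** emulate: realistic human LD maps
(blocks are disjoint, equal-r2, and independent), allele-frequency
spectra and frequency-dependent power, and functional annotation
structure. Passing tests therefore demonstrate the statistical machinery
under the stated mixture model, not performance on any particular real
cohort.

`simulate_mr_instruments()` enforces instrument relevance by resampling
exposure effects until $|b_x| > 0.05$, and can contaminate a fraction of
instruments with balanced direct (pleiotropic) effects.
`simulate_expression()` produces the 50-case / 66-control layout typical
of whole-blood case/control series, with an optional outlier-injection
rate that plants entries of magnitude 4-8 SD.

## Numerical choices

* p-values from z-scores go through the log-scale normal tail, so
  conversions are exact over the entire double range; the
  `log10_p_from_z()` companion never underflows (|z| = 40 maps to
  $\approx 10^{-349}$).
* Input p-values of exactly 0 are clamped to the smallest positive normal
  double and flagged; records whose supplied p and z disagree by more
  than 5% (relative) are flagged, with p kept authoritative because the
  FDR machinery is p-based.
* Ambiguous-strand variants (A/T, C/G) are dropped by default: without
  allele frequencies their orientation is undecidable, and the two input
  studies need not share frequencies.
* Tie handling in all counting is exact (`<=` comparisons, no jitter).
* $-\log_{10}$ conjFDR values in plot data are capped at 300.
* Genomic-inflation correction ($\lambda = \mathrm{median}(z^2)/0.454936$)
  is available but **off** by default, and never inflates ($\lambda < 1$
  is not applied unless forced).
* The optional MHC exclusion window is chr6:25,000,000-35,000,000
  (closed, 1-based), off by default.
* All randomness flows through one seeded helper; pruning draw $k$ is a
  pure function of (seed, $k$), so reruns are byte-identical.

## Problem sizes in the test suite

The suite exercises the estimators at the scales the statistics require
rather than at data-warehouse scale: oracle equivalences on $10^3$-$10^4$
variant instances, condFDR null calibration on 200 replicates of $10^5$
independent variants, the conjunction false-discovery audit on 100
replicates of the default mixture with the full pruning-averaged
estimator, MR recovery on 500 replicates of 50 instruments, and
expression calibration on 200 null matrices of 100 genes. These sizes
give Monte-Carlo standard errors small enough for the stated bounds while
keeping a full run in minutes on one core.

## Known limitations

* The conjunction estimate $\max(\mathrm{FDR}_{1|2}, \mathrm{FDR}_{2|1})$
  is conservative in each conditional direction but can be mildly
  anti-conservative for the *conjunction* when single-trait components
  are abundant: trait-1-only variants with accidentally small $p_2$
  benefit from the enrichment of the conditioning stratum, and the same
  leakage in the other direction survives the maximum. On the default
  mixture the empirical conjunction FDP at conjFDR < 0.05 sits near
  0.085-0.09, not 0.05 -- the audit in the test suite measures exactly
  this, and the conditional (single-direction) calibration passes while
  the conjunction audit documents the excess.
* $\pi_0$ is fixed at 1; estimating it would increase power at some cost
  in robustness and is deliberately out of scope.
* Single-linkage LD blocks chain: two variants with $r^2 \le 0.1$ can
  share a block through intermediates. This mirrors the reference
  tooling's behavior but can merge nearby loci.
* The weighted-median bootstrap treats instruments as fixed and perturbs
  only their effect estimates; it does not capture instrument-selection
  uncertainty.
* With `rho_ns > 0`, sample overlap inflates enrichment and the FDR
  calibration degrades by design; the package simulates the problem but
  does not correct for it.
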