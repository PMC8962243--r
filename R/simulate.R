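# Seeded generators emulating the statistical structure of the real
# inputs: a polygenic four-component mixture of null / trait-specific /
# pleiotropic variants with LD-block correlation and optional
# sample-overlap correlation; MR instrument tables; and case/control
# expression matrices. Defaults encode the study conditions the analysis
# assumes (a mostly-null polygenome with a small pleiotropic component at
# standardized effect scale 3, tagged by LD blocks of up to five variants).

NON_AMBIGUOUS_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)

#' Simulate a pair of GWAS summary-statistics tables with shared signal
#'
#' Draws per-block true effect pairs `(delta1, delta2)` from a
#' four-component mixture -- null, trait-1-only, trait-2-only, pleiotropic
#' (bivariate normal with correlation `rho_b`) -- then emits observed
#' z-scores `z = delta + eps` with unit-variance noise correlated `rho_ns`
#' across traits (sample overlap). Each LD block has one core variant
#' carrying the full signal; the remaining members tag it at genotype
#' r-squared `within_r2`, so within-block z-score correlation and the
#' emitted pairwise LD table are mutually consistent (lead-tag pairs at
#' `within_r2`, tag-tag pairs at `within_r2^2`). Secondary-table alleles
#' are randomly swapped and/or strand-complemented (with signs adjusted)
#' so allele harmonization is exercised end-to-end.
#'
#' @param n_variants Total number of variants (default 1e5).
#' @param pi Mixture weights `(null, trait1-only, trait2-only, pleiotropic)`,
#'   nonnegative, summing to 1. Default `c(0.90, 0.04, 0.04, 0.02)`.
#' @param sigma_b1,sigma_b2 Standard deviation of nonzero true effects on
#'   the z scale (default 3).
#' @param rho_b Correlation of the pleiotropic effect pair (default 0.5).
#' @param rho_ns Cross-trait noise correlation from sample overlap
#'   (default 0).
#' @param block_sizes Integer vector of possible LD-block sizes, drawn
#'   uniformly per block (default 1:5); pass `1` for independent variants.
#' @param within_r2 Genotype r-squared between a block's core variant and
#'   its tags (default 0.8).
#' @param prop_swapped,prop_flipped Fractions of secondary-table records
#'   emitted with reversed alleles / on the opposite strand (default 0.3
#'   each).
#' @param seed Integer seed; the output is bit-reproducible given the seed
#'   and parameters.
#' @return A list with `primary` and `secondary` summary tables (`SNP, CHR,
#'   BP, A1, A2, Z, P`), `ld` (pairs `snp_a, snp_b, r2`), and `truth`
#'   (`snp, component, delta1, delta2, block`), plus `params`.
#' @export
simulate_sumstats_pair <- function(n_variants = 1e5,
                                   pi = c(0.90, 0.04, 0.04, 0.02),
                                   sigma_b1 = 3, sigma_b2 = 3,
                                   rho_b = 0.5, rho_ns = 0,
                                   block_sizes = 1:5,
                                   within_r2 = 0.8,
                                   prop_swapped = 0.3, prop_flipped = 0.3,
                                   seed = 42L) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop_input("simulate_sumstats_pair: pi must be 4 nonnegative weights summing to 1")
  }
  if (abs(rho_ns) >= 1 || abs(rho_b) > 1) {
    stop_input("simulate_sumstats_pair: need |rho_ns| < 1 and |rho_b| <= 1")
  }
  if (within_r2 <= 0 || within_r2 > 1) {
    stop_input("simulate_sumstats_pair: within_r2 must lie in (0, 1]")
  }

  with_seed(seed, {
    # block layout
    n_blk_guess <- ceiling(n_variants / min(block_sizes)) + 1L
    sizes <- sample(block_sizes, n_blk_guess, replace = TRUE)
    cum <- cumsum(sizes)
    n_blk <- which(cum >= n_variants)[1]
    sizes <- sizes[seq_len(n_blk)]
    sizes[n_blk] <- sizes[n_blk] - (cum[n_blk] - n_variants)
    block <- rep.int(seq_len(n_blk), sizes)

    # component and true effect per block (tags share the block's label)
    comp_blk <- sample.int(4, n_blk, replace = TRUE, prob = pi)
    d1 <- numeric(n_blk); d2 <- numeric(n_blk)
    i1 <- comp_blk == 2L; i3 <- comp_blk == 4L
    d1[i1] <- stats::rnorm(sum(i1), 0, sigma_b1)
    i2 <- comp_blk == 3L
    d2[i2] <- stats::rnorm(sum(i2), 0, sigma_b2)
    if (any(i3)) {
      a <- stats::rnorm(sum(i3)); b <- stats::rnorm(sum(i3))
      d1[i3] <- sigma_b1 * a
      d2[i3] <- sigma_b2 * (rho_b * a + sqrt(1 - rho_b^2) * b)
    }

    # bivariate noise with sample-overlap correlation rho_ns
    bvn <- function(n) {
      e1 <- stats::rnorm(n); e0 <- stats::rnorm(n)
      cbind(e1, rho_ns * e1 + sqrt(1 - rho_ns^2) * e0)
    }
    core_eps <- bvn(n_blk)
    core_z1 <- d1 + core_eps[, 1]
    core_z2 <- d2 + core_eps[, 2]

    is_core <- !duplicated(block)
    n <- length(block)
    r <- sqrt(within_r2)
    own <- bvn(n)
    z1 <- ifelse(is_core, core_z1[block],
                 r * core_z1[block] + sqrt(1 - within_r2) * own[, 1])
    z2 <- ifelse(is_core, core_z2[block],
                 r * core_z2[block] + sqrt(1 - within_r2) * own[, 2])

    snp <- sprintf("rs%07d", seq_len(n))
    chrom <- as.character((block - 1L) %% 22L + 1L)
    pos <- integer(n)
    for (ch in unique(chrom)) {
      j <- chrom == ch
      pos[j] <- seq_len(sum(j)) * 5000L + 1e6L
    }

    pair_idx <- sample.int(nrow(NON_AMBIGUOUS_PAIRS), n, replace = TRUE)
    a1 <- NON_AMBIGUOUS_PAIRS[pair_idx, 1]
    a2 <- NON_AMBIGUOUS_PAIRS[pair_idx, 2]

    primary <- data.frame(SNP = snp, CHR = chrom, BP = pos, A1 = a1, A2 = a2,
                          Z = z1, P = p_from_z(z1), stringsAsFactors = FALSE)

    swapped <- stats::runif(n) < prop_swapped
    flipped <- stats::runif(n) < prop_flipped
    sa1 <- ifelse(swapped, a2, a1)
    sa2 <- ifelse(swapped, a1, a2)
    sa1f <- ifelse(flipped, strand_complement(sa1), sa1)
    sa2f <- ifelse(flipped, strand_complement(sa2), sa2)
    sz <- ifelse(swapped, -z2, z2)
    secondary <- data.frame(SNP = snp, CHR = chrom, BP = pos,
                            A1 = sa1f, A2 = sa2f,
                            Z = sz, P = p_from_z(sz), stringsAsFactors = FALSE)

    # emitted LD pairs: core-tag at within_r2, tag-tag at within_r2^2.
    # block members are consecutive indices, so pairs come from per-size
    # templates applied to the block start offsets (vectorized).
    starts <- cumsum(sizes) - sizes + 1L
    ld_a <- integer(0); ld_b <- integer(0); ld_r <- numeric(0)
    for (s in unique(sizes[sizes > 1])) {
      bks <- which(sizes == s)
      tpl <- utils::combn(s, 2)
      m <- ncol(tpl)
      st <- rep(starts[bks], each = m)
      ia <- st + rep(tpl[1, ], length(bks)) - 1L
      ib <- st + rep(tpl[2, ], length(bks)) - 1L
      rr <- ifelse(rep(tpl[1, ], length(bks)) == 1L, within_r2, within_r2^2)
      ld_a <- c(ld_a, ia); ld_b <- c(ld_b, ib); ld_r <- c(ld_r, rr)
    }
    ld <- data.frame(snp_a = snp[ld_a], snp_b = snp[ld_b], r2 = ld_r,
                     stringsAsFactors = FALSE)

    truth <- data.frame(
      snp = snp,
      component = c("null", "trait1", "trait2", "pleiotropic")[comp_blk[block]],
      delta1 = ifelse(is_core, d1[block], r * d1[block]),
      delta2 = ifelse(is_core, d2[block], r * d2[block]),
      block = block,
      swapped = swapped, flipped = flipped,
      stringsAsFactors = FALSE)

    list(primary = primary, secondary = secondary, ld = ld, truth = truth,
         params = list(n_variants = n_variants, pi = pi, sigma_b1 = sigma_b1,
                       sigma_b2 = sigma_b2, rho_b = rho_b, rho_ns = rho_ns,
                       block_sizes = block_sizes, within_r2 = within_r2,
                       prop_swapped = prop_swapped, prop_flipped = prop_flipped,
                       seed = seed))
  })
}

#' Simulate two-sample MR instruments
#'
#' Exposure effects `bx ~ Normal(bx_mean, bx_sd^2)` are resampled until
#' `|bx| > 0.05` (instrument relevance); outcome effects are
#' `by = beta_true * bx + alpha + Normal(0, se_y^2)` with per-instrument
#' pleiotropic intercepts `alpha ~ Normal(0, pleiotropy_sd^2)`.
#'
#' @param n_iv Number of instruments (default 50).
#' @param beta_true True causal effect (default 0.2).
#' @param bx_mean,bx_sd Exposure-effect distribution (default 0.3, 0.1).
#' @param se_x Reported exposure standard error (default 0.01).
#' @param se_y Outcome standard error (default 0.05).
#' @param pleiotropy_sd Standard deviation of balanced direct effects
#'   (default 0: all instruments valid).
#' @param prop_pleiotropic Fraction of instruments receiving a direct
#'   effect (default 1 when `pleiotropy_sd > 0`).
#' @param seed Integer seed.
#' @return A list with `instruments` (a data frame usable by [ivw()] etc.)
#'   and `truth`.
#' @export
simulate_mr_instruments <- function(n_iv = 50, beta_true = 0.2,
                                    bx_mean = 0.3, bx_sd = 0.1,
                                    se_x = 0.01, se_y = 0.05,
                                    pleiotropy_sd = 0, prop_pleiotropic = 1,
                                    seed = 42L) {
  if (n_iv < 1) stop_input("simulate_mr_instruments: n_iv must be >= 1")
  if (se_y <= 0) stop_input("simulate_mr_instruments: se_y must be > 0")
  with_seed(seed, {
    bx <- stats::rnorm(n_iv, bx_mean, bx_sd)
    while (any(abs(bx) <= 0.05)) {
      j <- abs(bx) <= 0.05
      bx[j] <- stats::rnorm(sum(j), bx_mean, bx_sd)
    }
    is_pleio <- stats::runif(n_iv) < prop_pleiotropic & pleiotropy_sd > 0
    alpha <- ifelse(is_pleio, stats::rnorm(n_iv, 0, pleiotropy_sd), 0)
    by <- beta_true * bx + alpha + stats::rnorm(n_iv, 0, se_y)
    list(
      instruments = data.frame(
        snp = sprintf("iv%03d", seq_len(n_iv)),
        beta_exposure = bx, se_exposure = se_x,
        beta_outcome = by, se_outcome = se_y,
        stringsAsFactors = FALSE),
      truth = list(beta_true = beta_true, alpha = alpha, is_pleio = is_pleio,
                   seed = seed))
  })
}

#' Simulate a case/control expression matrix
#'
#' Gene values are standard normal; a fraction `de_fraction` of genes is
#' shifted by `effect_sd_units` (random sign) in cases. A fraction
#' `outlier_rate` of entries is replaced by draws of magnitude in (4, 8)
#' to exercise outlier masking. The default 50-case / 66-control layout
#' mirrors a typical whole-blood case/control series.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_case,n_control Group sizes (default 50 and 66).
#' @param de_fraction Fraction of truly differentially expressed genes
#'   (default 0.1).
#' @param effect_sd_units Case-group mean shift in SD units (default 1.5).
#' @param outlier_rate Fraction of entries replaced by outliers (default 0).
#' @param seed Integer seed.
#' @return A list with `expr` (genes x samples matrix), `labels`
#'   (`"case"`/`"control"` per sample) and `truth` (`gene, is_de, effect`).
#' @export
simulate_expression <- function(n_genes = 1000, n_case = 50, n_control = 66,
                                de_fraction = 0.1, effect_sd_units = 1.5,
                                outlier_rate = 0, seed = 42L) {
  if (de_fraction < 0 || de_fraction > 1) {
    stop_input("simulate_expression: de_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    n_s <- n_case + n_control
    expr <- matrix(stats::rnorm(n_genes * n_s), n_genes, n_s,
                   dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                   c(sprintf("case%03d", seq_len(n_case)),
                                     sprintf("ctrl%03d", seq_len(n_control)))))
    labels <- rep(c("case", "control"), c(n_case, n_control))
    n_de <- round(de_fraction * n_genes)
    is_de <- rep(FALSE, n_genes)
    effect <- rep(0, n_genes)
    if (n_de > 0) {
      de_idx <- sample.int(n_genes, n_de)
      is_de[de_idx] <- TRUE
      effect[de_idx] <- effect_sd_units * sample(c(-1, 1), n_de, replace = TRUE)
      expr[de_idx, seq_len(n_case)] <-
        expr[de_idx, seq_len(n_case)] + effect[de_idx]
    }
    if (outlier_rate > 0) {
      n_out <- round(outlier_rate * length(expr))
      if (n_out > 0) {
        j <- sample.int(length(expr), n_out)
        expr[j] <- sample(c(-1, 1), n_out, replace = TRUE) *
          stats::runif(n_out, 4, 8)
      }
    }
    list(expr = expr, labels = labels,
         truth = data.frame(gene = rownames(expr), is_de = is_de,
                            effect = effect, stringsAsFactors = FALSE))
  })
}
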