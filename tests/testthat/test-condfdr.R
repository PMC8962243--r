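test_that("exact condFDR reproduces the direct-counting definition by hand", {
  paired <- data.frame(snp = c("A", "B", "C", "D"),
                       p1 = c(0.02, 0.001, 0.5, 0.9),
                       p2 = c(0.005, 0.5, 0.4, 0.8))
  f <- cond_fdr(paired, direction = 1, method = "exact")
  # B: stratum p2 <= 0.5 holds {A,B,C}; only B has p1 <= 0.001 -> F = 1/3
  expect_equal(f[[2]], 0.001 / (1 / 3))
  # D: full stratum, F = 1
  expect_equal(f[[4]], 0.9)
  # single variant: own stratum, F = 1 -> condFDR = p1
  one <- data.frame(snp = "x", p1 = 0.07, p2 = 0.3)
  expect_equal(as.numeric(cond_fdr(one, direction = 1, method = "exact")), 0.07)
})

test_that("exact condFDR equals the brute-force oracle, ties included", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 400
    p1 <- round(10^runif(n, -6, 0), 3)  # rounding forces ties
    p1[p1 == 0] <- 1e-4
    p2 <- round(10^runif(n, -6, 0), 3)
    p2[p2 == 0] <- 1e-4
    paired <- data.frame(snp = paste0("v", 1:n), p1 = p1, p2 = p2)
    expect_equal(as.numeric(cond_fdr(paired, direction = 1, method = "exact")),
                 condfdr_bruteforce(p1, p2), tolerance = 1e-12)
    expect_equal(as.numeric(cond_fdr(paired, direction = 2, method = "exact")),
                 condfdr_bruteforce(p2, p1), tolerance = 1e-12)
  }
})

test_that("conditional cdf counts match the empirical cdf without pruning", {
  paired <- data.frame(snp = letters[1:4],
                       p1 = c(0.02, 0.001, 0.5, 0.9),
                       p2 = c(0.5, 0.5, 0.5, 0.5))
  cdf <- build_conditional_cdf(paired, NULL,
                               qq_config(pruning_iterations = 1, seed = 1))
  # all-SNP stratum row: F at knot x = #{-log10 p1 >= x} / 4
  row0 <- cdf$F[1, ]
  at <- function(x) row0[which.min(abs(cdf$p1_knots - x))]
  expect_equal(at(0), 1)                       # everything
  expect_equal(at(0.1), 3 / 4)                 # p1 <= 0.794: all but 0.9
  expect_equal(at(0.4), 2 / 4)                 # p1 <= 0.398: 0.02, 0.001
  expect_equal(at(1.8), 1 / 4)                 # p1 <= 0.0158: only 0.001
  expect_true(all(diff(row0) <= 1e-12))        # cdf non-increasing in -log10 p1
})

test_that("conditional cdf surface is monotone and strata denominators shrink", {
  sim <- simulate_sumstats_pair(n_variants = 5000, seed = 21)
  paired <- sim_to_paired(sim)
  blocks <- ld_blocks(sim$ld, paired$snp, 0.1)
  cfg <- qq_config(pruning_iterations = 5, seed = 9)
  cdf <- build_conditional_cdf(paired, blocks, cfg)
  for (k in which(cdf$valid)) {
    expect_true(all(diff(cdf$F[k, ]) <= 1e-12))
    expect_true(all(cdf$F[k, ] >= 0 & cdf$F[k, ] <= 1))
  }
  expect_true(all(diff(cdf$den) <= 1e-9))
  # determinism under the same seed
  cdf2 <- build_conditional_cdf(paired, blocks, cfg)
  expect_identical(cdf$F, cdf2$F)
  # a stratum stricter than any observed p2 is marked invalid
  small <- data.frame(snp = c("a", "b"), p1 = c(0.1, 0.5), p2 = c(0.9, 0.8))
  cdf3 <- build_conditional_cdf(small, NULL, qq_config(pruning_iterations = 1))
  expect_true(cdf3$valid[1])
  expect_false(all(cdf3$valid))
})

test_that("monotone regularization never lowers the cdf estimate", {
  sim <- simulate_sumstats_pair(n_variants = 3000, block_sizes = 1, seed = 4)
  paired <- sim_to_paired(sim)
  cfg <- qq_config(pruning_iterations = 1, seed = 2)
  cdf <- build_conditional_cdf(paired, NULL, cfg)
  # recompute the raw (unregularized) surface for the all-SNP stratum
  lp1 <- -log10(paired$p1)
  raw <- vapply(cdf$p1_knots, function(x) mean(lp1 >= x), numeric(1))
  expect_true(all(cdf$F[1, ] >= raw - 1e-12))
  # already-monotone knots are untouched
  expect_equal(cdf$F[1, ], rev(cummax(rev(raw))), tolerance = 1e-12)
})

test_that("strata-mode condFDR tracks the exact estimator without pruning", {
  sim <- simulate_sumstats_pair(n_variants = 4000, block_sizes = 1, seed = 31)
  paired <- sim_to_paired(sim)
  cfg <- qq_config(pruning_iterations = 1, seed = 5)
  res_s <- cond_fdr_result(paired, NULL, cfg, method = "strata")
  res_e <- cond_fdr_result(paired, NULL, cfg, method = "exact")
  # grid interpolation differs from exact counting, but ranks must agree
  expect_gt(cor(res_s$fdr_1_given_2, res_e$fdr_1_given_2, method = "spearman"),
            0.95)
  expect_gt(cor(res_s$conj_fdr, res_e$conj_fdr, method = "spearman"), 0.95)
})

test_that("conjFDR is the conservative maximum of the reciprocal condFDRs", {
  expect_equal(conj_fdr(0.003, 0.008), 0.008)
  x <- runif(20)
  expect_equal(conj_fdr(x, x), x)
  a <- runif(20); b <- runif(20)
  expect_equal(conj_fdr(a, b), conj_fdr(b, a))
  expect_true(all(conj_fdr(a, b) >= a & conj_fdr(a, b) >= b))
  expect_error(conj_fdr(a, b[1:3]), "length")
  expect_error(conj_fdr(c(0.5, 1.2), c(0.1, 0.1)), "\\[0, 1\\]")
})

test_that("conjFDR dominates both condFDRs on simulated data", {
  sim <- simulate_sumstats_pair(n_variants = 3000, seed = 12)
  paired <- sim_to_paired(sim)
  blocks <- ld_blocks(sim$ld, paired$snp, 0.1)
  res <- cond_fdr_result(paired, blocks, qq_config(pruning_iterations = 5, seed = 1))
  expect_true(all(res$conj_fdr >= res$fdr_1_given_2))
  expect_true(all(res$conj_fdr >= res$fdr_2_given_1))
  expect_true(all(res$conj_fdr >= 0 & res$conj_fdr <= 1))
})

test_that("significant-variant selection uses a strict threshold", {
  res <- data.frame(snp = c("a", "b", "c"),
                    conj_fdr = c(0.009, 0.01, 0.02))
  sel <- select_significant(res, 0.01)
  expect_equal(sel$snp, "a")
  expect_equal(nrow(select_significant(res[0, ], 0.01)), 0)
  expect_equal(nrow(select_significant(res, 1.0)), 3)
  expect_error(select_significant(res, 0), "\\(0, 1\\]")
  # sorted ascending
  sel_all <- select_significant(res, 1.0)
  expect_equal(sel_all$conj_fdr, sort(res$conj_fdr))
})

test_that("conditional Q-Q curves are flat under the null and a self-stratum is exact", {
  sim <- simulate_sumstats_pair(n_variants = 5e4, pi = c(1, 0, 0, 0),
                                block_sizes = 1, seed = 23)
  paired <- sim_to_paired(sim)
  expect_warning(
    qq <- conditional_qq(paired, NULL, qq_config(strata_thresholds = c(1, 2, 3),
                                                 pruning_iterations = 1, seed = 1)),
    "omitted")
  enr <- attr(qq, "enrichment")
  expect_true(all(abs(enr$enrichment) <= 0.05))
  # a stratum that contains every variant reproduces the all-SNP curve
  paired2 <- paired
  paired2$p2 <- pmin(paired2$p2, 0.99)
  qq2 <- conditional_qq(paired2, NULL,
                        qq_config(strata_thresholds = 1e-9,
                                  pruning_iterations = 1, seed = 1))
  c0 <- qq2[qq2$stratum == 0, ]
  c1 <- qq2[qq2$stratum > 0, ]
  expect_equal(c1$empirical_log10p, c0$empirical_log10p)
})

test_that("pleiotropic enrichment increases across conditioning strata", {
  sim <- simulate_sumstats_pair(n_variants = 3e4, seed = 11)
  paired <- sim_to_paired(sim)
  blocks <- ld_blocks(sim$ld, paired$snp, 0.1)
  qq <- conditional_qq(paired, blocks, qq_config(pruning_iterations = 20, seed = 2))
  enr <- attr(qq, "enrichment")
  expect_equal(enr$stratum, c(0, 1, 2, 3))
  expect_true(all(diff(enr$enrichment) > 0))
})
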