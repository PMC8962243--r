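test_that("z-to-p conversion matches high-precision tail values", {
  # frozen 60-digit oracle values, including the deep tail (|z| up to 40)
  got <- log10_p_from_z(mpmath_log10p$z)
  expect_equal(got, mpmath_log10p$log10p, tolerance = 1e-12)
  # p itself, where representable at full precision
  rep_ok <- mpmath_log10p$log10p > -300
  expect_equal(p_from_z(mpmath_log10p$z[rep_ok]),
               10^mpmath_log10p$log10p[rep_ok], tolerance = 1e-12)
  expect_identical(p_from_z(0), 1)
  # sign does not matter
  expect_equal(p_from_z(-5.73), p_from_z(5.73))
  # published z/p pairs reproduce to 3 significant figures
  expect_equal(signif(p_from_z(-7.86), 3), 3.84e-15)
  expect_equal(signif(p_from_z(5.73), 3), 1.00e-8)
  expect_error(p_from_z(Inf), "finite")
  expect_error(p_from_z(NA_real_), "finite")
})

test_that("p-to-z inverts the conversion with correct sign", {
  expect_equal(z_from_p(1), 0)
  expect_equal(z_from_p(0.05), 1.95996, tolerance = 1e-5)
  expect_equal(z_from_p(3.84e-15, sign = -1), -7.86, tolerance = 0.005)
  # roundtrip property across the representable range
  set.seed(42)
  p <- 10^runif(1e4, -300, 0)
  s <- sample(c(-1, 1), 1e4, replace = TRUE)
  z <- z_from_p(p, s)
  expect_equal(p_from_z(z), p, tolerance = 1e-10)
  expect_true(all(sign(z[p < 1]) == s[p < 1]))
  expect_error(z_from_p(0), "\\(0, 1\\]")
  expect_error(z_from_p(1.5), "\\(0, 1\\]")
})

test_that("genomic-inflation correction estimates and applies lambda", {
  # exact standard-normal quantiles: lambda = 1, scores untouched
  z <- qnorm(seq(0.0005, 0.9995, length.out = 2001))
  g <- gc_correct(z)
  expect_equal(g$lambda, 1, tolerance = 0.01)
  expect_identical(g$z, z)
  # scaling by sqrt(2) doubles lambda and is undone by the correction
  g2 <- gc_correct(z * sqrt(2))
  expect_equal(g2$lambda, 2, tolerance = 0.02)
  expect_equal(g2$z, z * sqrt(2) / sqrt(g2$lambda), tolerance = 1e-12)
  # deflation below 1 requires force
  gd <- gc_correct(z * 0.5)
  expect_identical(gd$z, z * 0.5)
  expect_lt(gd$lambda, 1)
  gf <- gc_correct(z * 0.5, force = TRUE)
  expect_equal(gf$z, z * 0.5 / sqrt(gf$lambda))
  # degenerate all-zero input
  expect_warning(g0 <- gc_correct(rep(0, 5)), "100")
  expect_identical(g0$z, rep(0, 5))
  expect_identical(g0$lambda, 1)
})

test_that("read_sumstats parses well-formed tables and derives z and p", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = 1, BP = 1:3 * 1000,
                   A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
                   Z = c(1.5, -2, 0.5))
  df$P <- p_from_z(df$Z)
  ss <- read_sumstats(write_sumstats_file(df))
  expect_equal(nrow(ss), 3)
  expect_false(any(ss$zp_inconsistent))
  expect_equal(ss$z, df$Z)

  # z derived from beta/se
  df2 <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", BETA = 0.1, SE = 0.05)
  ss2 <- read_sumstats(write_sumstats_file(df2))
  expect_equal(ss2$z, 2)
  expect_equal(ss2$p, p_from_z(2))

  # z recovered from p plus effect direction
  df3 <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", BETA = -0.1, P = 0.05)
  ss3 <- read_sumstats(write_sumstats_file(df3))
  expect_equal(ss3$z, -qnorm(0.975), tolerance = 1e-6)

  # no p/z/beta source at all -> configuration error
  df4 <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", N = 1000)
  expect_error(read_sumstats(write_sumstats_file(df4)), "derive")

  # explicit column mapping and custom names
  df5 <- data.frame(marker = "rs9", ea = "A", oa = "C", zstat = 3)
  p5 <- write_sumstats_file(df5)
  ss5 <- read_sumstats(p5, column_map = list(snp = "marker", a1 = "ea",
                                             a2 = "oa", z = "zstat"))
  expect_equal(ss5$z, 3)
  expect_error(read_sumstats(p5, column_map = list(snp = "nope", a1 = "ea",
                                                   a2 = "oa", z = "zstat")),
               "role 'snp'")
})

test_that("read_sumstats flags p=0, inconsistent records, and drops bad rows", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                   A1 = c("A", "C", "G", "A"), A2 = c("G", "T", "A", "A"),
                   Z = c(5, 2, 1, 1),
                   P = c(0, 0.5, p_from_z(1), 0.5))
  ss <- read_sumstats(write_sumstats_file(df))
  # rs4 has identical alleles -> dropped
  expect_equal(ss$snp, c("rs1", "rs2", "rs3"))
  expect_equal(attr(ss, "drops")[["bad_allele"]], 1L)
  expect_true(ss$p_clamped[ss$snp == "rs1"])
  expect_gt(ss$p[ss$snp == "rs1"], 0)
  # rs2: p=0.5 but z=2 -> inconsistent, p kept as authoritative
  expect_true(ss$zp_inconsistent[ss$snp == "rs2"])
  expect_equal(ss$p[ss$snp == "rs2"], 0.5)
  expect_false(ss$zp_inconsistent[ss$snp == "rs3"])
})

test_that("allele harmonization resolves swaps, strand flips, and ambiguity", {
  prim <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                     chrom = "1", pos = 1:4,
                     a1 = c("A", "A", "A", "A"), a2 = c("G", "G", "G", "T"),
                     z = 1, p = p_from_z(1), stringsAsFactors = FALSE)
  sec <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                    chrom = "1", pos = 1:4,
                    a1 = c("G", "T", "A", "A"), a2 = c("A", "C", "G", "T"),
                    z = c(1.5, 2.0, 0.7, 1), p = p_from_z(c(1.5, 2, 0.7, 1)),
                    stringsAsFactors = FALSE)
  h <- harmonize_pair(prim, sec)
  # s1: alleles reversed -> sign flip
  expect_equal(h$z2[h$snp == "s1"], -1.5)
  expect_true(h$allele_swapped[h$snp == "s1"])
  # s2: strand complement (T/C vs A/G) -> same sign
  expect_equal(h$z2[h$snp == "s2"], 2.0)
  expect_true(h$strand_flipped[h$snp == "s2"])
  expect_false(h$allele_swapped[h$snp == "s2"])
  # s3: direct match
  expect_equal(h$z2[h$snp == "s3"], 0.7)
  # s4: A/T ambiguous -> dropped by default
  expect_false("s4" %in% h$snp)
  expect_equal(attr(h, "meta")[["ambiguous_dropped"]], 1L)
  h_keep <- harmonize_pair(prim, sec, drop_ambiguous = FALSE)
  expect_true("s4" %in% h_keep$snp)

  # involution: applying the swap rule twice restores the sign
  sec_swapped <- sec
  sec_swapped$a1 <- sec$a2; sec_swapped$a2 <- sec$a1; sec_swapped$z <- -sec$z
  h2 <- harmonize_pair(prim, sec_swapped)
  expect_equal(h2$z2, h$z2)

  # role symmetry: swapping the traits keeps the variant set
  h_rev <- harmonize_pair(sec, prim)
  expect_setequal(h_rev$snp, h$snp)

  # mismatched alleles dropped and counted (A/C cannot be reconciled
  # with the primary A/G by swapping or strand complementation)
  sec_bad <- sec; sec_bad$a1[1] <- "A"; sec_bad$a2[1] <- "C"
  h3 <- harmonize_pair(prim, sec_bad)
  expect_false("s1" %in% h3$snp)
  expect_equal(attr(h3, "meta")[["mismatch_dropped"]], 1L)

  # empty intersection errors
  sec_other <- sec; sec_other$snp <- paste0("x", sec$snp)
  expect_error(harmonize_pair(prim, sec_other), "shared")
})

test_that("MHC window exclusion removes chr6:25-35Mb inclusively", {
  pr <- data.frame(snp = c("a", "b", "c", "d"),
                   chrom = c("6", "6", "6", "5"),
                   pos = c(25e6, 35e6, 35e6 + 1, 30e6),
                   z1 = 1, p1 = 0.3, z2 = 1, p2 = 0.3)
  out <- exclude_mhc(pr)
  expect_setequal(out$snp, c("c", "d"))
  expect_equal(attr(out, "mhc_removed"), 2L)
})
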