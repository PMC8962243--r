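test_that("LD blocks are connected components above a strict r2 threshold", {
  pairs <- data.frame(snp_a = c("a", "b"), snp_b = c("b", "c"),
                      r2 = c(0.5, 0.05))
  bs <- ld_blocks(pairs, c("a", "b", "c"), 0.1)
  expect_equal(bs$block[["a"]], bs$block[["b"]])
  expect_false(bs$block[["c"]] == bs$block[["a"]])
  expect_equal(length(bs$blocks), 2)

  # boundary: r2 exactly at the threshold does not link
  bs2 <- ld_blocks(data.frame(snp_a = "a", snp_b = "b", r2 = 0.1),
                   c("a", "b"), 0.1)
  expect_equal(length(bs2$blocks), 2)

  # no edges: all singletons
  bs3 <- ld_blocks(NULL, c("w", "x", "y", "z"), 0.1)
  expect_equal(length(bs3$blocks), 4)
  expect_equal(sort(unname(unlist(bs3$blocks))), c("w", "x", "y", "z"))

  expect_error(ld_blocks(data.frame(snp_a = "a", snp_b = "b", r2 = 1.2),
                         c("a", "b"), 0.1), "\\[0, 1\\]")
})

test_that("blocks agree with a brute-force component search on random graphs", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 200
    ids <- paste0("v", 1:n)
    m <- 150
    pairs <- data.frame(snp_a = sample(ids, m, replace = TRUE),
                        snp_b = sample(ids, m, replace = TRUE),
                        r2 = runif(m))
    pairs <- pairs[pairs$snp_a != pairs$snp_b, ]
    bs <- ld_blocks(pairs, ids, 0.3)
    keep <- pairs$r2 > 0.3
    oracle <- components_bruteforce(ids, pairs$snp_a[keep], pairs$snp_b[keep])
    # same partition: equal number of blocks and identical co-membership
    expect_equal(length(bs$blocks), length(unique(oracle)))
    expect_true(all(tapply(oracle[ids], bs$block[ids],
                           function(g) length(unique(g)) == 1)))
  }
})

test_that("random pruning draws one member per block, uniformly", {
  pairs <- data.frame(snp_a = c("a", "a"), snp_b = c("b", "c"), r2 = 0.9)
  bs <- ld_blocks(pairs, c("a", "b", "c", "d"), 0.1)
  # singleton blocks always contribute their only member
  expect_true("d" %in% random_prune(bs, seed = 1, iteration = 1))
  # all-singleton case returns the full variant set
  bs_single <- ld_blocks(NULL, c("x", "y", "z"), 0.1)
  expect_setequal(random_prune(bs_single, seed = 3, iteration = 1),
                  c("x", "y", "z"))
  # reproducibility given (seed, iteration)
  expect_identical(random_prune(bs, 7, 3), random_prune(bs, 7, 3))
  expect_false(identical(random_prune(bs, 7, 3), random_prune(bs, 7, 4)) &&
                 identical(random_prune(bs, 7, 3), random_prune(bs, 8, 3)))
  # uniformity over the 3-member block
  draws <- vapply(1:30000, function(it) {
    intersect(random_prune(bs, seed = 11, iteration = it), c("a", "b", "c"))
  }, character(1))
  freq <- table(draws) / 30000
  expect_true(all(abs(freq - 1 / 3) <= 0.01))
})

test_that("clumping merges linked significant variants and picks lead SNPs", {
  sig <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                    chrom = c("1", "1", "2", "2"), pos = c(100, 200, 100, 300),
                    a1 = "A", a2 = "G",
                    z1 = c(5, 3, 4, 6), z2 = 2,
                    p1 = 1e-6, p2 = 1e-4,
                    conj_fdr = c(0.002, 0.001, 0.004, 0.003))
  pairs <- data.frame(snp_a = c("s1", "s3"), snp_b = c("s2", "s4"),
                      r2 = c(0.3, 0.2))
  loci <- clump_loci(sig, pairs, 0.1)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$snp, c("s2", "s4"))   # min conjFDR per component
  expect_equal(loci$locus_no, 1:2)        # numbered by lead (chrom, pos)
  expect_equal(sort(unlist(strsplit(loci$members, ","))),
               c("s1", "s2", "s3", "s4")) # every variant in exactly one locus

  # single significant variant forms its own locus
  one <- clump_loci(sig[1, ], pairs, 0.1)
  expect_equal(nrow(one), 1)
  expect_equal(one$snp, "s1")

  # equal conjFDR resolved by larger |z1|
  tie <- sig[1:2, ]
  tie$conj_fdr <- 0.002
  loci_tie <- clump_loci(tie, pairs, 0.1)
  expect_equal(loci_tie$snp, "s1")  # |z1| = 5 beats 3

  # row-order invariance
  loci_rev <- clump_loci(sig[4:1, ], pairs, 0.1)
  expect_equal(loci_rev$snp, loci$snp)
  expect_equal(loci_rev$locus_no, loci$locus_no)

  # missing LD information: singleton with warning
  sig5 <- rbind(sig, data.frame(snp = "s9", chrom = "3", pos = 50, a1 = "A",
                                a2 = "G", z1 = 4, z2 = 2, p1 = 1e-5,
                                p2 = 1e-4, conj_fdr = 0.005))
  bs <- ld_blocks(pairs, sig$snp, 0.1)
  expect_warning(loci5 <- clump_loci(sig5, bs, 0.1), "without LD")
  expect_equal(nrow(loci5), 3)
})

test_that("locus count equals the component count of the significant subgraph", {
  set.seed(9)
  n <- 500
  ids <- paste0("v", 1:n)
  sig <- data.frame(snp = ids, chrom = as.character(sample(1:22, n, TRUE)),
                    pos = sample.int(1e6, n), a1 = "A", a2 = "G",
                    z1 = rnorm(n, 0, 5), z2 = rnorm(n, 0, 5),
                    p1 = runif(n, 0, 1e-4), p2 = runif(n, 0, 1e-4),
                    conj_fdr = runif(n, 0, 0.01))
  m <- 400
  pairs <- data.frame(snp_a = sample(ids, m, TRUE),
                      snp_b = sample(ids, m, TRUE), r2 = runif(m))
  pairs <- pairs[pairs$snp_a != pairs$snp_b, ]
  loci <- clump_loci(sig, pairs, 0.1)
  keep <- pairs$r2 > 0.1
  oracle <- components_bruteforce(ids, pairs$snp_a[keep], pairs$snp_b[keep])
  expect_equal(nrow(loci), length(unique(oracle)))
  expect_equal(sort(unlist(strsplit(loci$members, ","))), sort(ids))
})
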