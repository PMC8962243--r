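# Independent brute-force oracles used to cross-check the package's
# estimators, plus small fixture builders. The oracles deliberately use
# naive O(n^2) / enumeration formulations so they share no code path with
# the implementations they test.

# direct-counting condFDR: min(1, p1_i * #{p2_j <= p2_i} /
#                                  #{p1_j <= p1_i & p2_j <= p2_i})
condfdr_bruteforce <- function(p1, p2) {
  vapply(seq_along(p1), function(i) {
    den <- sum(p2 <= p2[i])
    num <- sum(p1 <= p1[i] & p2 <= p2[i])
    min(1, p1[i] * den / num)
  }, numeric(1))
}

# Benjamini-Hochberg step-up from the definition: q_(i) =
# min_{j >= i} ( m * p_(j) / j ), reported in input order
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# connected components by repeated breadth-first search over an edge list
components_bruteforce <- function(vertices, edges_a, edges_b) {
  comp <- setNames(rep(NA_integer_, length(vertices)), vertices)
  cid <- 0L
  for (v in vertices) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    frontier <- v
    comp[v] <- cid
    while (length(frontier)) {
      nb <- unique(c(edges_b[edges_a %in% frontier],
                     edges_a[edges_b %in% frontier]))
      nb <- nb[nb %in% vertices]
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- cid
      frontier <- nb
    }
  }
  comp
}

# Welch two-sample t-test from the textbook formulas
welch_bruteforce <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# hypergeometric upper tail by exhaustive enumeration of query draws
hyper_tail_enumeration <- function(N, K, n, k_min) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k_min)  # elements 1..K form the gene set
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# harmonized pair table straight from a simulation, bypassing file I/O
sim_to_paired <- function(sim) {
  z2 <- ifelse(sim$truth$swapped, -sim$secondary$Z, sim$secondary$Z)
  data.frame(snp = sim$primary$SNP, chrom = sim$primary$CHR,
             pos = sim$primary$BP, a1 = sim$primary$A1, a2 = sim$primary$A2,
             z1 = sim$primary$Z, p1 = sim$primary$P,
             z2 = z2, p2 = p_from_z(z2), stringsAsFactors = FALSE)
}

# Two-sided -log10 p-values computed with 60-digit arithmetic
# (erfc(|z|/sqrt(2)) via mpmath), frozen for the conversion accuracy tests.
mpmath_log10p <- data.frame(
  z = c(0.5, 1, 1.959964, 2.5, 3, 4, 5, 5.73, 6, 7, 7.86, 8, 10, 12, 15,
        16.19, 19.19, 20, 25, 30, 35, 37, 38, 40),
  log10p = c(-0.20966199360125957926, -0.49851554582798930482,
             -1.3010300113603846347, -1.9059018101313198811,
             -2.568669040265387882, -4.1983049118924976696,
             -6.2416156767266733011, -7.9981337935225241491,
             -8.704834331812723014, -11.591823641811508642,
             -14.415517861807833316, -14.905112555353173363,
             -22.817023409822094699, -32.449409165527879436,
             -50.134189618611530172, -58.226736076262944596,
             -81.348102418241433132, -88.259065347411610725,
             -137.21371765533154499, -197.00817926599696819,
             -267.64785195408898969, -298.94115118294594048,
             -315.2387597082985267, -349.13597646368186089))
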