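#' Configuration for conditional Q-Q and condFDR estimation
#'
#' @param strata_thresholds Conditioning cutoffs for the secondary trait,
#'   on the -log10 p scale (default 1, 2, 3; the all-SNP stratum at 0 is
#'   always included). Must be strictly increasing.
#' @param pruning_iterations Number of random-pruning iterations to average
#'   over (default 100).
#' @param r2_threshold LD r-squared above which two variants share a block
#'   (default 0.1, strict inequality).
#' @param seed Integer seed driving all pruning draws.
#' @param grid_step Resolution, in -log10 p units, of the conditioning and
#'   evaluation grids used by the interpolated FDR lookup (default 0.1).
#' @param min_stratum Minimum stratum size below which a Q-Q curve is
#'   omitted with a warning (default 100).
#' @return A list of class `qq_config`.
#' @export
qq_config <- function(strata_thresholds = c(1, 2, 3),
                      pruning_iterations = 100L,
                      r2_threshold = 0.1,
                      seed = 42L,
                      grid_step = 0.1,
                      min_stratum = 100L) {
  if (length(strata_thresholds) < 1 || is.unsorted(strata_thresholds, strictly = TRUE)) {
    stop_input("qq_config: strata_thresholds must be strictly increasing")
  }
  if (pruning_iterations < 1) stop_input("qq_config: pruning_iterations must be >= 1")
  structure(list(strata_thresholds = as.numeric(strata_thresholds),
                 pruning_iterations = as.integer(pruning_iterations),
                 r2_threshold = r2_threshold,
                 seed = as.integer(seed),
                 grid_step = grid_step,
                 min_stratum = as.integer(min_stratum)),
            class = "qq_config")
}

neg_log10 <- function(p) -log10(pmax(p, .Machine$double.xmin))

prune_indices <- function(paired, blocks, config, iteration) {
  if (is.null(blocks)) return(seq_len(nrow(paired)))
  random_prune(blocks, seed = config$seed, iteration = iteration,
               variants = paired$snp)
}

# vectorized column-wise cumulative sum from the bottom row up:
# out[m, k] = sum_{m' >= m} M[m', k]
rev_colcumsum <- function(M) {
  n <- nrow(M)
  Mr <- M[n:1, , drop = FALSE]
  cs <- cumsum(Mr)
  off <- rep.int(c(0, cs[seq(n, length(M) - n, by = n)]), rep.int(n, ncol(M)))
  matrix(cs - off, n)[n:1, , drop = FALSE]
}

# One shared pass over the pruning iterations computing the conditional
# cdf surfaces for both directions: the joint survival counts
# S[m, k] = #{-log10 p1 >= xg[m] & -log10 p2 >= tg[k]} serve direction 1
# (strata along tg) by column normalization and direction 2 (strata along
# xg) by row normalization.
build_cdf_both <- function(paired, blocks = NULL, config = qq_config()) {
  if (!is.data.frame(paired) || nrow(paired) == 0) {
    stop_input("build_conditional_cdf: paired table is empty")
  }
  lp1 <- neg_log10(paired$p1)
  lp2 <- neg_log10(paired$p2)
  step <- config$grid_step
  xg <- seq(0, max(min(max(lp1), 300), step), by = step)
  tg <- seq(0, max(min(max(lp2), 300), step), by = step)
  nx <- length(xg); nt <- length(tg)

  # accumulate the joint survival counts over iterations; the cdf is the
  # ratio of the summed counts (pooled over draws), which avoids the
  # small-denominator bias a mean of per-iteration ratios would add in
  # sparse strata
  Ssum <- matrix(0, nx, nt)
  for (it in seq_len(config$pruning_iterations)) {
    idx <- prune_indices(paired, blocks, config, it)
    ix <- findInterval(lp1[idx], xg)
    iy <- findInterval(lp2[idx], tg)
    tab <- matrix(tabulate(ix + nx * (iy - 1L), nbins = nx * nt), nx, nt)
    S <- rev_colcumsum(tab)
    Ssum <- Ssum + t(rev_colcumsum(t(S)))
  }

  finish <- function(num, den, strata, knots, direction) {
    Fbar <- num / den                 # rows with den 0 give NaN
    Fbar[den == 0, ] <- NA_real_
    # regularize: F must be non-increasing along the knot axis (a cdf in p);
    # pooling only ever raises values and leaves monotone rows untouched
    for (k in which(den > 0)) {
      Fbar[k, ] <- rev(cummax(rev(Fbar[k, ])))
    }
    structure(list(p1_knots = knots, p2_breaks = strata, F = Fbar,
                   den = den / config$pruning_iterations,
                   valid = den > 0, n_iter = config$pruning_iterations,
                   direction = direction, config = config),
              class = "conditional_cdf")
  }
  list(cdf1 = finish(t(Ssum), Ssum[1, ], tg, xg, 1L),
       cdf2 = finish(Ssum, Ssum[, 1], xg, tg, 2L))
}

#' Estimate the conditional cdf of primary p-values given secondary strata
#'
#' Builds the stratified empirical cdf `F(p1 <= x | p2 <= 10^-t)` on a
#' regular grid of -log10 p cutoffs (step `config$grid_step`), averaging
#' the per-stratum ratio over `config$pruning_iterations` random-pruning
#' draws of one variant per LD block. The averaged surface is regularized
#' to be a proper cdf along the p1 axis (monotone, never lowered) and is
#' the lookup table behind the interpolated condFDR estimator.
#'
#' @param paired Harmonized pair table from [harmonize_pair()].
#' @param blocks An `ld_block_set` from [ld_blocks()], or `NULL` to treat
#'   every variant as its own block (no pruning randomness).
#' @param config A [qq_config()].
#' @param direction 1 to condition the primary trait on the secondary
#'   (`F(p1 | p2)`), 2 for the reverse.
#' @return An object of class `conditional_cdf`.
#' @export
build_conditional_cdf <- function(paired, blocks = NULL, config = qq_config(),
                                  direction = 1) {
  stopifnot(direction %in% c(1, 2))
  both <- build_cdf_both(paired, blocks, config)
  if (direction == 1) both$cdf1 else both$cdf2
}

#' @export
print.conditional_cdf <- function(x, ...) {
  cat(sprintf(
    "conditional cdf: %d p1 knots x %d conditioning strata (direction %d, %d pruning iterations)\n",
    length(x$p1_knots), length(x$p2_breaks), x$direction, x$n_iter))
  invisible(x)
}

# bilinear interpolation of the cdf surface at (lp1, lp2)
lookup_cdf <- function(cdf, lp1, lp2) {
  xg <- cdf$p1_knots; tg <- cdf$p2_breaks; Fm <- cdf$F
  nx <- length(xg); nt <- length(tg)
  # clamp: conditioning at a weaker threshold than observed is conservative
  x <- pmin(pmax(lp1, 0), xg[nx])
  t <- pmin(pmax(lp2, 0), tg[nt])
  # snap each t to the nearest valid stratum at or below it
  valid_at_or_below <- cummax(ifelse(cdf$valid, seq_len(nt), 0L))
  kt <- findInterval(t, tg)
  kt <- valid_at_or_below[kt]
  none <- kt == 0L
  kt[none] <- 1L
  kx <- findInterval(x, xg)
  kx1 <- pmin(kx + 1L, nx)
  wx <- ifelse(kx1 > kx, (x - xg[kx]) / (xg[kx1] - xg[kx]), 0)
  kt1 <- pmin(kt + 1L, nt)
  kt1[!cdf$valid[kt1]] <- kt[!cdf$valid[kt1]]
  wt <- ifelse(kt1 > kt, (t - tg[kt]) / (tg[kt1] - tg[kt]), 0)
  wt <- pmin(pmax(wt, 0), 1)
  f00 <- Fm[cbind(kt, kx)];  f01 <- Fm[cbind(kt, kx1)]
  f10 <- Fm[cbind(kt1, kx)]; f11 <- Fm[cbind(kt1, kx1)]
  val <- (1 - wt) * ((1 - wx) * f00 + wx * f01) +
    wt * ((1 - wx) * f10 + wx * f11)
  val[none] <- NA_real_
  val
}

#' Per-variant conditional FDR
#'
#' Estimates, for every variant, the conditional false discovery rate of
#' the primary trait given the secondary: the probability that the variant
#' is null for the primary trait given that both traits' p-values are at
#' most the observed ones. The estimator is `min(1, p1 / F(p1 | p2 <= p2))`
#' with the null proportion conservatively fixed at 1.
#'
#' Two evaluation modes are available. `"exact"` uses direct tie-inclusive
#' counting over all variants (an O(n log n) sweep), and is the reference
#' definition: `min(1, p1_i * #{p2_j <= p2_i} / #{p1_j <= p1_i & p2_j <=
#' p2_i})`. `"strata"` evaluates the pruning-averaged interpolated cdf from
#' [build_conditional_cdf()], which is what the full pipeline uses so that
#' LD-induced spurious enrichment is controlled; pruned-out variants still
#' receive FDR values through the fitted lookup.
#'
#' @param paired Harmonized pair table.
#' @param cdf A `conditional_cdf` (required for `method = "strata"`); its
#'   direction must match `direction`.
#' @param direction 1 for FDR(trait1 | trait2), 2 for FDR(trait2 | trait1).
#' @param method `"exact"` or `"strata"`.
#' @return Numeric vector of condFDR values in \[0, 1\], with a `flagged`
#'   attribute marking variants that fell outside every valid stratum
#'   (their FDR is set to 1).
#' @export
cond_fdr <- function(paired, cdf = NULL, direction = 1,
                     method = c("strata", "exact")) {
  method <- match.arg(method)
  stopifnot(direction %in% c(1, 2))
  p1 <- if (direction == 1) paired$p1 else paired$p2
  p2 <- if (direction == 1) paired$p2 else paired$p1
  if (length(p1) == 0) stop_input("cond_fdr: empty input")

  if (method == "exact") {
    cc <- dominance_counts(p1, p2)
    fdr <- pmin(1, p1 * cc$n2 / cc$n12)
    attr(fdr, "flagged") <- rep(FALSE, length(fdr))
    return(fdr)
  }
  if (is.null(cdf)) stop_input("cond_fdr: method 'strata' needs a conditional_cdf")
  if (cdf$direction != direction) {
    stop_input("cond_fdr: cdf was built for direction %d, not %d",
               cdf$direction, direction)
  }
  Fv <- lookup_cdf(cdf, neg_log10(p1), neg_log10(p2))
  flagged <- is.na(Fv) | Fv <= 0
  fdr <- rep(1, length(p1))
  fdr[!flagged] <- pmin(1, p1[!flagged] / Fv[!flagged])
  attr(fdr, "flagged") <- flagged
  fdr
}

#' Conjunctional FDR from the two reciprocal condFDRs
#'
#' The conjunctional FDR -- the probability that a variant is null for
#' either trait -- is conservatively estimated as the elementwise maximum
#' of FDR(trait1 | trait2) and FDR(trait2 | trait1).
#'
#' @param fdr_1_given_2,fdr_2_given_1 Equal-length vectors in \[0, 1\].
#' @return Elementwise maximum.
#' @export
conj_fdr <- function(fdr_1_given_2, fdr_2_given_1) {
  if (length(fdr_1_given_2) != length(fdr_2_given_1)) {
    stop_input("conj_fdr: length mismatch")
  }
  rng <- range(c(fdr_1_given_2, fdr_2_given_1, 0, 1))
  if (rng[1] < 0 || rng[2] > 1) stop_input("conj_fdr: inputs must lie in [0, 1]")
  pmax(fdr_1_given_2, fdr_2_given_1)
}

#' Both condFDR directions plus the conjFDR, per variant
#'
#' Convenience wrapper running [cond_fdr()] in both directions (building
#' the two conditional cdf lookups when `method = "strata"`) and combining
#' them with [conj_fdr()].
#'
#' @inheritParams cond_fdr
#' @param blocks Optional `ld_block_set` used for pruning in strata mode.
#' @param config A [qq_config()].
#' @return A `data.frame` with columns `snp, fdr_1_given_2, fdr_2_given_1,
#'   conj_fdr`, of class `cond_fdr_result`.
#' @export
cond_fdr_result <- function(paired, blocks = NULL, config = qq_config(),
                            method = c("strata", "exact")) {
  method <- match.arg(method)
  if (method == "strata") {
    both <- build_cdf_both(paired, blocks, config)
    f12 <- cond_fdr(paired, both$cdf1, direction = 1, method = "strata")
    f21 <- cond_fdr(paired, both$cdf2, direction = 2, method = "strata")
  } else {
    f12 <- cond_fdr(paired, direction = 1, method = "exact")
    f21 <- cond_fdr(paired, direction = 2, method = "exact")
  }
  out <- data.frame(snp = paired$snp,
                    fdr_1_given_2 = as.numeric(f12),
                    fdr_2_given_1 = as.numeric(f21),
                    conj_fdr = conj_fdr(as.numeric(f12), as.numeric(f21)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cond_fdr_result", "data.frame")
  out
}

#' Conditional Q-Q curves and enrichment summaries
#'
#' For the all-SNP stratum and each secondary-trait stratum (-log10 p2 at
#' or above each configured threshold), computes the empirical quantile
#' curve of -log10 p1 against the nominal quantiles `-log10(i / (n + 1))`,
#' averaged over random-pruning iterations. Successive leftward (upward)
#' deflection of the stratified curves away from the all-SNP curve is the
#' signature of pleiotropic enrichment.
#'
#' The scalar enrichment summary per stratum is the mean difference between
#' the stratum curve and the all-SNP curve over the nominal grid, restricted
#' to quantiles where the stratum still holds at least 20 expected
#' observations (tail quantiles of small strata are too noisy to average).
#'
#' @inheritParams build_conditional_cdf
#' @return A `data.frame` of plot-ready curves with columns `stratum`
#'   (threshold on -log10 p2; 0 is the all-SNP stratum), `nominal_log10p`,
#'   `empirical_log10p`, and an `enrichment` attribute: a `data.frame`
#'   with `stratum`, `n_mean` (mean stratum size across iterations) and
#'   `enrichment`.
#' @export
conditional_qq <- function(paired, blocks = NULL, config = qq_config()) {
  if (!is.data.frame(paired) || nrow(paired) == 0) {
    stop_input("conditional_qq: paired table is empty")
  }
  lp1 <- neg_log10(paired$p1)
  lp2 <- neg_log10(paired$p2)
  strata <- c(0, config$strata_thresholds)
  n_str <- length(strata)
  qmax_master <- log10(nrow(paired) + 1)
  qs <- seq(0, qmax_master, by = 0.1)
  nq <- length(qs)

  emp_sum <- matrix(0, n_str, nq)
  emp_cnt <- matrix(0, n_str, nq)
  n_sum <- numeric(n_str)
  n_min <- rep(Inf, n_str)
  used <- numeric(n_str)

  for (it in seq_len(config$pruning_iterations)) {
    idx <- prune_indices(paired, blocks, config, it)
    l1 <- lp1[idx]; l2 <- lp2[idx]
    for (s in seq_len(n_str)) {
      sub <- l1[l2 >= strata[s]]
      n_s <- length(sub)
      if (n_s < config$min_stratum) next
      used[s] <- used[s] + 1
      n_sum[s] <- n_sum[s] + n_s
      n_min[s] <- min(n_min[s], n_s)
      srt <- sort(sub, decreasing = TRUE)
      ranks <- 10^(-qs) * (n_s + 1)
      ok <- ranks >= 1 & ranks <= n_s
      emp <- stats::approx(seq_len(n_s), srt, xout = ranks[ok])$y
      emp_sum[s, ok] <- emp_sum[s, ok] + emp
      emp_cnt[s, ok] <- emp_cnt[s, ok] + 1
    }
  }

  omitted <- used == 0
  if (any(omitted)) {
    warning(sprintf("conditional_qq: strata below minimum size omitted: %s",
                    paste(strata[omitted], collapse = ", ")))
  }

  curves <- do.call(rbind, lapply(which(!omitted), function(s) {
    ok <- emp_cnt[s, ] == used[s] & emp_cnt[s, ] > 0
    data.frame(stratum = strata[s], nominal_log10p = qs[ok],
               empirical_log10p = emp_sum[s, ok] / emp_cnt[s, ok])
  }))
  rownames(curves) <- NULL

  enr <- data.frame(stratum = strata[!omitted],
                    n_mean = n_sum[!omitted] / pmax(used[!omitted], 1),
                    enrichment = NA_real_)
  all_curve <- curves[curves$stratum == 0, ]
  # summaries are averaged over a quantile range common to every retained
  # stratum (each stratum must keep >= 20 expected observations beyond the
  # quantile), so strata are compared at matched nominal quantiles
  qcap <- min(log10((n_min[!omitted] + 1) / 20))
  for (r in seq_len(nrow(enr))) {
    s <- enr$stratum[r]
    if (nrow(all_curve) == 0) break
    sc <- curves[curves$stratum == s, ]
    qq <- intersect(sc$nominal_log10p, all_curve$nominal_log10p)
    qq <- qq[qq <= qcap]
    if (length(qq) == 0) next
    d <- sc$empirical_log10p[match(qq, sc$nominal_log10p)] -
      all_curve$empirical_log10p[match(qq, all_curve$nominal_log10p)]
    enr$enrichment[r] <- mean(d)
  }
  attr(curves, "enrichment") <- enr
  curves
}

#' Select variants below a conjFDR threshold
#'
#' @param result A `cond_fdr_result` (or any data frame with a `conj_fdr`
#'   column).
#' @param threshold conjFDR cutoff in (0, 1\]; selection is strict (`<`).
#' @return The selected rows, sorted by `conj_fdr` ascending.
#' @export
select_significant <- function(result, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_input("select_significant: threshold must lie in (0, 1]")
  }
  keep <- result$conj_fdr < threshold
  out <- result[keep, , drop = FALSE]
  out <- out[order(out$conj_fdr), , drop = FALSE]
  rownames(out) <- NULL
  out
}
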