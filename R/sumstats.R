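#' Convert a signed z-score to a two-sided p-value
#'
#' Computes `p = 2 * pnorm(-|z|)` through the log-scale tail of the normal
#' distribution, so the conversion does not underflow prematurely: the
#' returned p-value is exact down to the smallest representable double and
#' the companion [log10_p_from_z()] stays exact far beyond that (|z| of 40
#' corresponds to a p-value near 1e-349).
#'
#' @param z Numeric vector of signed z-scores; must be finite.
#' @return Two-sided p-values in (0, 1]. Values whose true magnitude lies
#'   below the smallest positive double are returned as the nearest
#'   representable (possibly subnormal) number; use [log10_p_from_z()] when
#'   the magnitude itself is needed.
#' @seealso [z_from_p()], [log10_p_from_z()]
#' @examples
#' p_from_z(c(0, -7.86, 5.73))
#' @export
p_from_z <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop_input("p_from_z: z must be finite and non-missing")
  }
  exp(stats::pnorm(-abs(z), log.p = TRUE) + log(2))
}

#' Base-10 log of the two-sided normal p-value
#'
#' @inheritParams p_from_z
#' @return `log10` of the two-sided p-value; no underflow for any double z.
#' @export
log10_p_from_z <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop_input("log10_p_from_z: z must be finite and non-missing")
  }
  (stats::pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
}

#' Convert a two-sided p-value to a signed z-score
#'
#' Inverse of [p_from_z()]: `|z| = qnorm(1 - p/2)` with the requested sign.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param sign Vector of +1/-1 (recycled) giving the direction of effect.
#' @return Signed z-scores.
#' @export
z_from_p <- function(p, sign = 1) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1)) {
    stop_input("z_from_p: p must lie in (0, 1]")
  }
  s <- base::sign(sign)
  s[s == 0] <- 1
  abs(stats::qnorm(p / 2, lower.tail = FALSE)) * s
}

#' Genomic-inflation (lambda) correction of z-scores
#'
#' The inflation factor is estimated as `lambda = median(z^2) / 0.454936`
#' (the median of a 1-df chi-square). When `lambda > 1` the z-scores are
#' deflated by `sqrt(lambda)`; deflation below 1 is not applied unless
#' `force = TRUE`, and an all-zero degenerate input leaves the scores
#' untouched with lambda reported as 1.
#'
#' @param z Numeric vector of z-scores.
#' @param force Apply the correction even when the estimated lambda is < 1.
#' @return A list with `z` (corrected scores) and `lambda` (the estimate).
#' @export
gc_correct <- function(z, force = FALSE) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop_input("gc_correct: z must be finite and non-missing")
  }
  if (length(z) < 100) {
    warning("gc_correct: fewer than 100 variants; lambda estimate is unstable")
  }
  lambda <- stats::median(z^2) / 0.454936
  if (!is.finite(lambda) || lambda <= 0) {
    return(list(z = z, lambda = 1))
  }
  if (lambda < 1 && !force) {
    return(list(z = z, lambda = lambda))
  }
  list(z = z / sqrt(lambda), lambda = lambda)
}

# Default header-name -> role guesses, in priority order per role.
default_column_map <- function() {
  list(
    snp   = c("SNP", "RSID", "ID", "MARKERNAME", "VARIANT_ID"),
    chrom = c("CHR", "CHROM", "CHROMOSOME"),
    pos   = c("BP", "POS", "POSITION", "BASE_PAIR_LOCATION"),
    a1    = c("A1", "EA", "EFFECT_ALLELE", "ALT"),
    a2    = c("A2", "OA", "OTHER_ALLELE", "NEA", "REF"),
    z     = c("Z", "ZSCORE", "Z_SCORE", "STAT"),
    beta  = c("BETA", "B", "EFFECT", "LOG_ODDS"),
    se    = c("SE", "STDERR", "STANDARD_ERROR"),
    p     = c("P", "PVAL", "P_VALUE", "PVALUE"),
    n     = c("N", "NMISS", "SAMPLE_SIZE")
  )
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab/whitespace-delimited file with a header row, resolves column
#' roles either from `column_map` or from common header-name conventions,
#' and returns one validated record per variant. A z-score column, a
#' beta + se pair, or a p-value plus a signed effect column must be present;
#' missing z is derived as `beta/se`, missing p as [p_from_z()] of z.
#' Input p-values of exactly zero are clamped to the smallest positive
#' normal double and flagged. Records whose supplied p and z disagree by
#' more than `consistency_tol` (relative, on p) are flagged but kept, with
#' the p column treated as authoritative downstream.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Optional named list/character vector mapping roles
#'   (`snp`, `chrom`, `pos`, `a1`, `a2`, `z`, `beta`, `se`, `p`, `n`) to
#'   header names; unmapped roles fall back to the built-in guesses.
#' @param consistency_tol Relative tolerance for the p-vs-z consistency
#'   check (default 0.05).
#' @return A `data.frame` with columns `snp, chrom, pos, a1, a2, z, p, n,
#'   p_clamped, zp_inconsistent`, plus a `drops` attribute counting records
#'   removed per reason.
#' @export
read_sumstats <- function(path, column_map = NULL, consistency_tol = 0.05) {
  if (!file.exists(path)) stop_input("read_sumstats: file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0) stop_input("read_sumstats: %s contains no records", path)
  hdr <- toupper(names(dt))

  resolve <- function(role) {
    cand <- column_map[[role]]
    if (!is.null(cand)) {
      j <- match(toupper(cand), hdr)
      if (is.na(j)) stop_input(
        "read_sumstats: mapped column '%s' for role '%s' not in header",
        cand, role)
      return(j)
    }
    j <- match(default_column_map()[[role]], hdr)
    j <- j[!is.na(j)]
    if (length(j)) j[1] else NA_integer_
  }

  idx <- vapply(names(default_column_map()), resolve, integer(1))
  for (role in c("snp", "a1", "a2")) {
    if (is.na(idx[[role]])) {
      stop_input("read_sumstats: no column found for mandatory role '%s'", role)
    }
  }
  has <- function(role) !is.na(idx[[role]])
  if (!has("z") && !(has("beta") && has("se")) && !(has("p") && has("beta"))) {
    stop_input(paste0(
      "read_sumstats: need a 'z' column, or 'beta'+'se', or 'p'+'beta' ",
      "(effect direction) to derive association statistics"))
  }

  num <- function(role) {
    if (!has(role)) return(rep(NA_real_, nrow(dt)))
    suppressWarnings(as.numeric(dt[[idx[[role]]]]))
  }
  out <- data.frame(
    snp = as.character(dt[[idx[["snp"]]]]),
    chrom = if (has("chrom")) as.character(dt[[idx[["chrom"]]]]) else NA_character_,
    pos = if (has("pos")) suppressWarnings(as.integer(dt[[idx[["pos"]]]])) else NA_integer_,
    a1 = toupper(as.character(dt[[idx[["a1"]]]])),
    a2 = toupper(as.character(dt[[idx[["a2"]]]])),
    z = num("z"), beta = num("beta"), se = num("se"), p = num("p"),
    n = num("n"),
    stringsAsFactors = FALSE
  )

  drops <- c(bad_numeric = 0L, bad_p = 0L, bad_allele = 0L, nonfinite_z = 0L,
             duplicate_snp = 0L)

  # derive z / p where absent
  need_z <- is.na(out$z)
  out$z[need_z] <- out$beta[need_z] / out$se[need_z]
  still <- is.na(out$z) & !is.na(out$p) & !is.na(out$beta)
  out$z[still] <- z_from_p(pmin(pmax(out$p[still], .Machine$double.xmin), 1),
                           sign(out$beta[still]))

  bad <- is.na(out$z)
  drops[["bad_numeric"]] <- sum(bad)
  out <- out[!bad, , drop = FALSE]

  nf <- !is.finite(out$z)
  drops[["nonfinite_z"]] <- sum(nf)
  out <- out[!nf, , drop = FALSE]

  out$p_clamped <- !is.na(out$p) & out$p == 0
  out$p[out$p_clamped] <- .Machine$double.xmin
  badp <- !is.na(out$p) & (out$p < 0 | out$p > 1)
  drops[["bad_p"]] <- sum(badp)
  out <- out[!badp, , drop = FALSE]
  need_p <- is.na(out$p)
  out$p[need_p] <- p_from_z(out$z[need_p])

  bada <- !grepl("^[ACGT]+$", out$a1) | !grepl("^[ACGT]+$", out$a2) |
    out$a1 == out$a2
  drops[["bad_allele"]] <- sum(bada)
  out <- out[!bada, , drop = FALSE]

  dup <- duplicated(out$snp)
  drops[["duplicate_snp"]] <- sum(dup)
  out <- out[!dup, , drop = FALSE]

  if (nrow(out) == 0) stop_input("read_sumstats: zero valid records in %s", path)

  pz <- p_from_z(out$z)
  out$zp_inconsistent <- abs(out$p - pz) / pmax(out$p, .Machine$double.xmin) >
    consistency_tol & !out$p_clamped
  out$beta <- NULL
  out$se <- NULL
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}

strand_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Merge and allele-harmonize two summary-statistics tables
#'
#' Intersects two traits' records on variant id and expresses the secondary
#' trait's z-score relative to the primary trait's effect allele. When the
#' secondary alleles are reversed, the z-score sign is flipped; when they
#' match only after strand complementation, the alleles are complemented
#' first. Ambiguous-strand variants (A/T, C/G) are dropped by default
#' because their orientation cannot be resolved without allele frequencies;
#' variants whose allele sets cannot be reconciled at all are dropped and
#' counted.
#'
#' @param primary,secondary Data frames as returned by [read_sumstats()].
#' @param drop_ambiguous Drop A/T and C/G variants (default `TRUE`).
#' @return A `data.frame` with columns `snp, chrom, pos, a1, a2, z1, p1,
#'   z2, p2, allele_swapped, strand_flipped`, sorted by (chrom, pos, snp),
#'   with a `meta` attribute of harmonization counts.
#' @export
harmonize_pair <- function(primary, secondary, drop_ambiguous = TRUE) {
  for (d in list(primary, secondary)) {
    if (!is.data.frame(d) || nrow(d) == 0) {
      stop_input("harmonize_pair: both inputs must be nonempty data frames")
    }
  }
  j <- match(primary$snp, secondary$snp)
  keep <- !is.na(j)
  if (!any(keep)) stop_input("harmonize_pair: no shared variant ids")
  p <- primary[keep, , drop = FALSE]
  s <- secondary[j[keep], , drop = FALSE]

  meta <- c(n_intersect = nrow(p), allele_swapped = 0L, strand_flipped = 0L,
            ambiguous_dropped = 0L, mismatch_dropped = 0L)

  amb <- is_ambiguous_pair(p$a1, p$a2) | is_ambiguous_pair(s$a1, s$a2)
  if (drop_ambiguous) {
    meta[["ambiguous_dropped"]] <- sum(amb)
    p <- p[!amb, , drop = FALSE]
    s <- s[!amb, , drop = FALSE]
  }

  same  <- s$a1 == p$a1 & s$a2 == p$a2
  swap  <- s$a1 == p$a2 & s$a2 == p$a1
  csame <- strand_complement(s$a1) == p$a1 & strand_complement(s$a2) == p$a2
  cswap <- strand_complement(s$a1) == p$a2 & strand_complement(s$a2) == p$a1
  ok <- same | swap | csame | cswap
  meta[["mismatch_dropped"]] <- sum(!ok)
  p <- p[ok, , drop = FALSE]
  s <- s[ok, , drop = FALSE]
  same <- same[ok]; swap <- swap[ok]; csame <- csame[ok]; cswap <- cswap[ok]
  if (nrow(p) == 0) stop_input("harmonize_pair: empty intersection after allele matching")

  flip_sign <- swap | (cswap & !csame)
  meta[["allele_swapped"]] <- sum(flip_sign)
  meta[["strand_flipped"]] <- sum((csame | cswap) & !same & !swap)

  out <- data.frame(
    snp = p$snp, chrom = p$chrom, pos = p$pos, a1 = p$a1, a2 = p$a2,
    z1 = p$z, p1 = p$p,
    z2 = ifelse(flip_sign, -s$z, s$z), p2 = s$p,
    allele_swapped = flip_sign,
    strand_flipped = (csame | cswap) & !same & !swap,
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_rank(out$chrom), out$pos, out$snp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- meta
  out
}

#' Drop variants inside the extended MHC region
#'
#' Removes variants in the closed window chr6:25,000,000-35,000,000, the
#' conventional exclusion for cross-trait FDR analyses because of the
#' region's extreme long-range LD.
#'
#' @param paired A harmonized pair table from [harmonize_pair()].
#' @return The table without MHC variants; the number removed is recorded
#'   in the `mhc_removed` attribute.
#' @export
exclude_mhc <- function(paired) {
  ch <- sub("^chr", "", as.character(paired$chrom), ignore.case = TRUE)
  inside <- !is.na(paired$pos) & ch == "6" &
    paired$pos >= 25e6 & paired$pos <= 35e6
  out <- paired[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- attr(paired, "meta")
  attr(out, "mhc_removed") <- sum(inside)
  out
}
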