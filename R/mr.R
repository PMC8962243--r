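# Two-sample Mendelian randomization from per-instrument summary
# statistics. All estimators work on a data.frame of instruments with
# columns beta_exposure, se_exposure, beta_outcome, se_outcome.

mr_estimate <- function(method, beta, se, n_iv) {
  z <- beta / se
  structure(list(method = method, beta = beta, se = se, z = z,
                 p = p_from_z(z),
                 or_ = exp(beta),
                 ci_low = exp(beta - 1.959964 * se),
                 ci_high = exp(beta + 1.959964 * se),
                 n_iv = as.integer(n_iv)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR (%s, %d IV): beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p %.3g\n",
              x$method, x$n_iv, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_iv = x$n_iv, beta = x$beta, se = x$se,
             z = x$z, p = x$p, or_ = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

check_instruments <- function(instruments, min_n = 1, need_nonzero_bx = TRUE) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(instruments))
  if (length(miss)) {
    stop_input("MR: instrument table lacks column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (nrow(instruments) < min_n) {
    stop_input("MR: at least %d instrument(s) required, got %d",
               min_n, nrow(instruments))
  }
  if (any(instruments$se_outcome <= 0)) {
    stop_input("MR: se_outcome must be positive")
  }
  if (need_nonzero_bx && any(instruments$beta_exposure == 0)) {
    stop_input("MR: beta_exposure must be nonzero for ratio-based estimators")
  }
  instruments
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect is `beta_outcome / beta_exposure`; the standard error
#' is the first-order approximation `se_outcome / |beta_exposure|`, which
#' ignores the exposure-side uncertainty (appropriate for strong
#' instruments).
#'
#' @param iv A one-row instrument `data.frame` (columns `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`).
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(iv) {
  iv <- check_instruments(iv, min_n = 1)
  if (nrow(iv) != 1) stop_input("wald_ratio: exactly one instrument expected")
  mr_estimate("wald", iv$beta_outcome / iv$beta_exposure,
              iv$se_outcome / abs(iv$beta_exposure), 1L)
}

#' Fixed-effect inverse-variance-weighted MR estimate
#'
#' Combines per-instrument Wald ratios `theta_j = beta_outcome_j /
#' beta_exposure_j` with weights `w_j = beta_exposure_j^2 / se_outcome_j^2`
#' (the inverse variance of each ratio): `beta = sum(w theta) / sum(w)`,
#' `se = 1 / sqrt(sum(w))`. With a single instrument this reproduces
#' [wald_ratio()] exactly.
#'
#' @param instruments Instrument `data.frame`, one row per SNP.
#' @return An `mr_estimate`.
#' @export
ivw <- function(instruments) {
  iv <- check_instruments(instruments, min_n = 1)
  theta <- iv$beta_outcome / iv$beta_exposure
  w <- iv$beta_exposure^2 / iv$se_outcome^2
  mr_estimate("ivw", sum(w * theta) / sum(w), 1 / sqrt(sum(w)), nrow(iv))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(s)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Orders the per-instrument ratio estimates and takes the weighted median
#' under IVW weights: with normalized weights `w'_j` and
#' `s_j = sum_{k<=j} w'_k - w'_j / 2`, the estimate linearly interpolates
#' the ordered ratios at `s = 0.5`. Consistent when instruments carrying at
#' least half the weight are valid, hence robust to balanced pleiotropy.
#' The standard error comes from a seeded parametric bootstrap that
#' perturbs both exposure and outcome effects by their standard errors.
#'
#' @param instruments Instrument `data.frame`; at least 2 rows (3 or more
#'   recommended).
#' @param n_boot Bootstrap draws for the standard error (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(instruments, n_boot = 1000L, seed = 42L) {
  iv <- check_instruments(instruments, min_n = 2)
  theta <- iv$beta_outcome / iv$beta_exposure
  w <- iv$beta_exposure^2 / iv$se_outcome^2
  est <- weighted_median_point(theta, w)
  se_x <- ifelse(is.na(iv$se_exposure), 0, iv$se_exposure)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(iv), iv$beta_exposure, se_x)
      by <- stats::rnorm(nrow(iv), iv$beta_outcome, iv$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      weighted_median_point(by / bx, bx^2 / iv$se_outcome^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, stats::sd(boot), nrow(iv))
}

#' Recover beta, se and p from an odds ratio with 95\% CI
#'
#' Inverts the standard Wald reporting: `beta = log(OR)`,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`, and the two-sided
#' normal p-value of `beta / se`.
#'
#' @param or_ Odds ratio (positive).
#' @param ci_low,ci_high 95\% confidence bounds, `0 < ci_low <= or_ <=
#'   ci_high`, with `ci_low < ci_high`.
#' @return A list with `beta`, `se`, `z`, `p`.
#' @export
summarize_or_ci <- function(or_, ci_low, ci_high) {
  if (any(c(or_, ci_low, ci_high) <= 0)) {
    stop_input("summarize_or_ci: inputs must be positive")
  }
  if (ci_low > or_ || or_ > ci_high) {
    stop_input("summarize_or_ci: require ci_low <= or_ <= ci_high")
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.959964)
  if (se <= 0) stop_input("summarize_or_ci: degenerate confidence interval")
  beta <- log(or_)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = p_from_z(z))
}

#' Read an MR instrument table
#'
#' Expects a whitespace/tab-delimited file with header columns `SNP`, `EA`,
#' `OA`, `BETA_EXP`, `SE_EXP`, `BETA_OUT`, `SE_OUT` (case-insensitive).
#'
#' @param path File path.
#' @return A `data.frame` with columns `snp`, `a1`, `a2`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @export
read_instruments <- function(path) {
  if (!file.exists(path)) stop_input("read_instruments: file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  hdr <- toupper(names(dt))
  need <- c("SNP", "EA", "OA", "BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT")
  j <- match(need, hdr)
  if (anyNA(j)) {
    stop_input("read_instruments: missing column(s): %s",
               paste(need[is.na(j)], collapse = ", "))
  }
  data.frame(snp = as.character(dt[[j[1]]]),
             a1 = toupper(as.character(dt[[j[2]]])),
             a2 = toupper(as.character(dt[[j[3]]])),
             beta_exposure = as.numeric(dt[[j[4]]]),
             se_exposure = as.numeric(dt[[j[5]]]),
             beta_outcome = as.numeric(dt[[j[6]]]),
             se_outcome = as.numeric(dt[[j[7]]]),
             stringsAsFactors = FALSE)
}
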