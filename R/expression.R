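# Differential-expression stage: per-gene scaling, entry-wise outlier
# masking, Welch t-tests with Benjamini-Hochberg correction, plus generic
# gene-set over-representation and annotation-threshold filtering.

#' Center and scale an expression matrix gene-wise
#'
#' Each gene (row) is centered to mean 0 and scaled to unit sample standard
#' deviation across all samples. Genes with fewer than two distinct values
#' (zero variance) cannot be scaled; they are removed and recorded in the
#' `excluded` attribute.
#'
#' @param mat Numeric genes x samples matrix with unique rownames.
#' @return The scaled matrix, with attribute `excluded` naming dropped
#'   genes.
#' @export
scale_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop_input("scale_expression: a numeric matrix is required")
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop_input("scale_expression: unique gene rownames are required")
  }
  m <- rowMeans(mat, na.rm = TRUE)
  centered <- mat - m
  s <- sqrt(rowSums(centered^2, na.rm = TRUE) /
              (rowSums(!is.na(mat)) - 1))
  bad <- !is.finite(s) | s == 0
  out <- centered[!bad, , drop = FALSE] / s[!bad]
  attr(out, "excluded") <- rownames(mat)[bad]
  out
}

#' Mask outlying entries of a scaled expression matrix
#'
#' Entries whose absolute scaled value is strictly greater than `sd_cutoff`
#' standard deviations are set to `NA`. The masked set is monotone in the
#' cutoff: a stricter cutoff masks a superset.
#'
#' @param scaled A matrix from [scale_expression()].
#' @param sd_cutoff Threshold in standard-deviation units (default 3,
#'   strict `>`).
#' @return The masked matrix with attribute `n_masked`.
#' @export
remove_outliers <- function(scaled, sd_cutoff = 3) {
  if (!is.matrix(scaled)) stop_input("remove_outliers: a matrix is required")
  mask <- !is.na(scaled) & abs(scaled) > sd_cutoff
  scaled[mask] <- NA_real_
  attr(scaled, "n_masked") <- sum(mask)
  scaled
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_input("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential-expression t-tests with BH correction
#'
#' Runs a two-tailed two-sample t-test per gene between the two label
#' groups (Welch unequal-variance by default) and applies the
#' Benjamini-Hochberg correction across the tested genes. Genes left with
#' fewer than two usable values in either group (e.g. after outlier
#' masking) are excluded and flagged.
#'
#' @param mat Genes x samples numeric matrix (possibly containing `NA`
#'   from [remove_outliers()]).
#' @param labels Factor/character vector of length `ncol(mat)` with exactly
#'   two levels; the first level (alphabetically, or by factor order) is
#'   treated as the case group.
#' @param genes Optional subset of rownames to test (default all).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A `data.frame` with one row per tested gene: `gene`,
#'   `mean_case`, `mean_control`, `n_case`, `n_control`, `t`, `p`, `q`,
#'   plus an `excluded` attribute naming untestable genes.
#' @export
de_ttest <- function(mat, labels, genes = NULL, var_equal = FALSE) {
  if (!is.matrix(mat)) stop_input("de_ttest: a matrix is required")
  if (length(labels) != ncol(mat)) {
    stop_input("de_ttest: labels must match the number of samples")
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop_input("de_ttest: exactly two groups required")
  if (is.null(genes)) genes <- rownames(mat)
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0) stop_input("de_ttest: empty gene subset")

  g1 <- labels == levels(labels)[1]
  res <- lapply(genes, function(g) {
    x <- mat[g, g1]
    y <- mat[g, !g1]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    data.frame(gene = g, mean_case = mean(x), mean_control = mean(y),
               n_case = length(x), n_control = length(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) stop_input("de_ttest: no testable genes")
  out <- do.call(rbind, res[keep])
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "excluded") <- genes[!keep]
  out
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("read_gmt: file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop_input("read_gmt: malformed line (need name, description, genes)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  sets
}

#' Hypergeometric gene-set over-representation test
#'
#' For each gene set, tests whether the query genes overlap the set more
#' than expected by chance within the universe: one-sided hypergeometric
#' tail `P(X >= k)`, BH-corrected across sets. Sets are intersected with
#' the universe first; the query must be a subset of the universe.
#'
#' @param query Character vector of genes of interest.
#' @param gene_sets Named list of gene vectors (see [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @return A `data.frame` with columns `set`, `n_set`, `n_query`,
#'   `overlap`, `p`, `q`, `genes` (comma-separated overlap), sorted by p.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_input("hypergeom_enrich: empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    stop_input("hypergeom_enrich: query must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_query = n, overlap = k, p = min(p, 1),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), c("set", "n_set", "n_query", "overlap", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

# RegulomeDB categories from strongest to weakest regulatory evidence.
regulome_levels <- function() {
  c("1a", "1b", "1c", "1d", "1e", "1f", "2a", "2b", "2c",
    "3a", "3b", "4", "5", "6", "7")
}

#' Flag variants by deleteriousness and regulatory-evidence thresholds
#'
#' Adds a `deleterious` flag where the CADD score is strictly greater than
#' `cadd_cutoff` (default 12.37, the conventional potentially-pathogenic
#' threshold) and a `regulatory` flag where the RegulomeDB category is at
#' or stronger than `regulome_max_rank` under the ordering
#' 1a < 1b < ... < 1f < 2a < ... < 7. Unparseable RegulomeDB tokens are
#' marked in `regulome_unparsed`.
#'
#' @param annotations A `data.frame` with a `snp` column and `cadd` and/or
#'   `regulomedb` columns (case-insensitive names).
#' @param cadd_cutoff CADD threshold (strict `>`); default 12.37.
#' @param regulome_max_rank Weakest category still flagged as regulatory
#'   (default `"1f"`).
#' @return The input with added logical columns `deleterious`,
#'   `regulatory`, `regulome_unparsed` (as applicable).
#' @export
filter_annotations <- function(annotations, cadd_cutoff = 12.37,
                               regulome_max_rank = "1f") {
  if (cadd_cutoff <= 0) stop_input("filter_annotations: cadd_cutoff must be > 0")
  nm <- tolower(names(annotations))
  out <- annotations
  j <- match("cadd", nm)
  if (!is.na(j)) {
    out$deleterious <- !is.na(annotations[[j]]) & annotations[[j]] > cadd_cutoff
  }
  j <- match("regulomedb", nm)
  if (!is.na(j)) {
    lv <- regulome_levels()
    cut_rank <- match(tolower(regulome_max_rank), lv)
    if (is.na(cut_rank)) stop_input("filter_annotations: unknown RegulomeDB category '%s'",
                                    regulome_max_rank)
    rk <- match(tolower(trimws(as.character(annotations[[j]]))), lv)
    out$regulome_unparsed <- is.na(rk) & !is.na(annotations[[j]])
    out$regulatory <- !is.na(rk) & rk <= cut_rank
  }
  out
}
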