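#' Read a PLINK-style pairwise LD table
#'
#' Reads a whitespace-delimited file containing (at least) the columns
#' `SNP_A`, `SNP_B`, and `R2`; extra columns (CHR_A, BP_A, ...) are
#' ignored.
#'
#' @param path Path to the `.ld`-style file.
#' @return A `data.frame` with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop_input("read_ld_table: file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  hdr <- toupper(names(dt))
  need <- c("SNP_A", "SNP_B", "R2")
  j <- match(need, hdr)
  if (anyNA(j)) {
    stop_input("read_ld_table: missing column(s): %s",
               paste(need[is.na(j)], collapse = ", "))
  }
  out <- data.frame(snp_a = as.character(dt[[j[1]]]),
                    snp_b = as.character(dt[[j[2]]]),
                    r2 = as.numeric(dt[[j[3]]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$r2) | out$r2 < 0 | out$r2 > 1)) {
    stop_input("read_ld_table: R2 values must lie in [0, 1]")
  }
  out
}

#' Partition variants into LD blocks
#'
#' An LD block is a connected component of the graph whose edges join
#' variant pairs with r-squared strictly above `r2_threshold` (single
#' linkage / transitive closure). Variants that appear in no retained pair
#' become singleton blocks.
#'
#' @param pairs A `data.frame` with columns `snp_a`, `snp_b`, `r2` (see
#'   [read_ld_table()]).
#' @param variants Character vector of all variant ids to partition
#'   (ids in `pairs` but not in `variants` are ignored).
#' @param r2_threshold Linking threshold; edges require `r2 > threshold`.
#' @return An object of class `ld_block_set`: a list with `block` (named
#'   integer vector, variant -> block id), `blocks` (list of member vectors)
#'   and `r2_threshold`.
#' @export
ld_blocks <- function(pairs, variants, r2_threshold = 0.1) {
  variants <- as.character(variants)
  if (anyDuplicated(variants)) stop_input("ld_blocks: duplicate variant ids")
  if (!is.null(pairs) && nrow(pairs)) {
    if (any(is.na(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
      stop_input("ld_blocks: r2 values must lie in [0, 1]")
    }
    e <- pairs[pairs$r2 > r2_threshold &
                 pairs$snp_a %in% variants & pairs$snp_b %in% variants, ,
               drop = FALSE]
  } else {
    e <- NULL
  }
  if (is.null(e) || nrow(e) == 0) {
    memb <- seq_along(variants)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("snp_a", "snp_b")], directed = FALSE,
      vertices = data.frame(name = variants))
    memb <- igraph::components(g)$membership[variants]
  }
  block <- as.integer(memb)
  names(block) <- variants
  structure(list(block = block,
                 blocks = split(variants, block),
                 r2_threshold = r2_threshold),
            class = "ld_block_set")
}

#' @export
print.ld_block_set <- function(x, ...) {
  sz <- lengths(x$blocks)
  cat(sprintf("ld_block_set: %d variants in %d blocks (max size %d, r2 > %g)\n",
              length(x$block), length(x$blocks), max(sz), x$r2_threshold))
  invisible(x)
}

#' Draw one random variant per LD block
#'
#' A single random-pruning iteration: exactly one member is drawn uniformly
#' from each block. The draw is reproducible given `(seed, iteration)` and
#' is independent of the caller's RNG state.
#'
#' @param blocks An `ld_block_set`.
#' @param seed Integer base seed.
#' @param iteration Iteration index (different iterations give independent
#'   draws under the same seed).
#' @param variants Optional character vector: when supplied, the returned
#'   subset is given as integer indices into `variants` (all block members
#'   must be present in it); otherwise variant ids are returned.
#' @return Selected variant ids, or indices into `variants`.
#' @export
random_prune <- function(blocks, seed, iteration = 1L, variants = NULL) {
  stopifnot(inherits(blocks, "ld_block_set"))
  ids <- names(blocks$block)
  if (length(ids) == 0) stop_input("random_prune: empty block set")
  sel <- with_seed(seed, {
    key <- stats::runif(length(ids))
    ord <- order(blocks$block, key)
    ord[!duplicated(blocks$block[ord])]
  }, stream = as.integer(iteration))
  picked <- ids[sel]
  if (is.null(variants)) return(picked)
  j <- match(picked, variants)
  if (anyNA(j)) stop_input("random_prune: block members missing from 'variants'")
  j
}

#' Clump significant variants into independent shared loci
#'
#' Computes LD components among the significant variants only (edges where
#' r-squared exceeds `r2_threshold`) and reduces each component to one
#' locus. The lead SNP is the member with the smallest conjFDR; ties are
#' broken by larger |z1|, then by smaller position. Loci are numbered by
#' the (chromosome, position) of their lead SNP. Significant variants with
#' no LD information become singleton loci with a warning.
#'
#' @param significant A `data.frame` with columns `snp`, `chrom`, `pos`,
#'   `a1`, `a2`, `z1`, `z2`, `p1`, `p2`, `conj_fdr` (the output of merging
#'   [select_significant()] with the harmonized pair table).
#' @param ld Either an `ld_block_set` or a pairs `data.frame`
#'   (`snp_a`, `snp_b`, `r2`).
#' @param r2_threshold Linking threshold used when `ld` is a pairs table.
#' @return A `data.frame` of class `shared_loci`: one row per locus with
#'   columns `locus_no`, `snp`, `chrom`, `pos`, `a1`, `a2`, `z1`, `z2`,
#'   `p1`, `p2`, `conj_fdr`, `n_members`, `members` (comma-separated ids).
#' @export
clump_loci <- function(significant, ld = NULL, r2_threshold = 0.1) {
  need <- c("snp", "chrom", "pos", "z1", "conj_fdr")
  miss <- setdiff(need, names(significant))
  if (length(miss)) {
    stop_input("clump_loci: significant table lacks column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (nrow(significant) == 0) {
    out <- significant[0, , drop = FALSE]
    class(out) <- c("shared_loci", "data.frame")
    return(out)
  }
  ids <- significant$snp
  if (inherits(ld, "ld_block_set")) {
    known <- ids %in% names(ld$block)
    if (any(!known)) {
      warning(sprintf("clump_loci: %d significant variant(s) without LD information; treated as singletons",
                      sum(!known)))
    }
    memb <- integer(length(ids))
    memb[known] <- match(ld$block[ids[known]],
                         unique(ld$block[ids[known]]))
    memb[!known] <- max(memb, 0L) + seq_len(sum(!known))
  } else {
    bs <- ld_blocks(ld, ids, r2_threshold)
    memb <- bs$block[ids]
  }

  sig <- significant
  sig$.memb <- memb
  groups <- split(seq_len(nrow(sig)), sig$.memb)
  rows <- lapply(groups, function(ii) {
    g <- sig[ii, , drop = FALSE]
    ord <- order(g$conj_fdr, -abs(g$z1), g$pos)
    lead <- g[ord[1], , drop = FALSE]
    lead$n_members <- nrow(g)
    lead$members <- paste(g$snp[order(g$pos)], collapse = ",")
    lead
  })
  out <- do.call(rbind, rows)
  out$.memb <- NULL
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  out$locus_no <- seq_len(nrow(out))
  rownames(out) <- NULL
  cols <- c("locus_no", setdiff(names(out), "locus_no"))
  out <- out[, cols]
  class(out) <- c("shared_loci", "data.frame")
  out
}
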