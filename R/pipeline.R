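# End-to-end conjFDR pipeline: read -> harmonize -> (optional inflation
# correction / MHC exclusion) -> LD blocks -> conditional Q-Q -> condFDR in
# both directions -> conjFDR -> selection -> clumping -> locus table, with
# all artifacts written as TSV plus a run log.

#' Assemble a pipeline configuration
#'
#' Defaults can be overridden from a YAML file and/or named arguments;
#' precedence is arguments > file > defaults.
#'
#' @param file Optional path to a YAML file of configuration keys.
#' @param ... Named overrides of individual keys: `primary`, `secondary`
#'   (summary-statistics paths), `ld` (pairwise LD table path),
#'   `gene_map` (optional SNP-to-gene TSV with columns `SNP`, `GENE`),
#'   `out_dir`, `seed`, `conjfdr_threshold` (default 0.01),
#'   `r2_threshold` (0.1), `strata_thresholds` (1, 2, 3),
#'   `pruning_iterations` (100), `min_stratum` (100),
#'   `fdr_method` (`"strata"` or `"exact"`), `mhc_exclude` (FALSE),
#'   `gc_correct` (FALSE), `drop_ambiguous` (TRUE),
#'   `primary_cols` / `secondary_cols` (column maps for [read_sumstats()]).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    primary = NULL, secondary = NULL, ld = NULL, gene_map = NULL,
    out_dir = "conjfdr_out", seed = 42L,
    conjfdr_threshold = 0.01, r2_threshold = 0.1,
    strata_thresholds = c(1, 2, 3), pruning_iterations = 100L,
    min_stratum = 100L, fdr_method = "strata",
    mhc_exclude = FALSE, gc_correct = FALSE, drop_ambiguous = TRUE,
    primary_cols = NULL, secondary_cols = NULL)
  if (!is.null(file)) {
    if (!file.exists(file)) stop_input("pipeline_config: file not found: %s", file)
    user <- yaml::read_yaml(file)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop_input("pipeline_config: unknown key(s): %s",
                                    paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_input("pipeline_config: unknown key(s): %s",
                                  paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$conjfdr_threshold <= 0 || cfg$conjfdr_threshold >= 1) {
    stop_input("pipeline_config: conjfdr_threshold must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

tsv_write <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
}

#' Run the full conjFDR shared-locus pipeline
#'
#' Executes every stage on the configured inputs and writes, under
#' `config$out_dir`: `fdr.tsv` (per-variant condFDR/conjFDR), `qq_curves.tsv`
#' and `qq_enrichment.tsv` (conditional Q-Q data), `manhattan.tsv`
#' (chromosome, position, -log10 conjFDR capped at 300, lead flag),
#' `loci.tsv` (the shared-locus table), and `run_log.txt` echoing the
#' configuration, seeds and drop counts. Outputs are byte-identical across
#' reruns with the same configuration and seed.
#'
#' @param config A `pipeline_config` (or a YAML path / named overrides
#'   forwarded to [pipeline_config()]).
#' @param ... Overrides forwarded to [pipeline_config()] when `config` is
#'   not already a `pipeline_config`.
#' @return Invisibly, a list with `paired`, `fdr`, `qq`, `loci`,
#'   `locus_table` and the paths written.
#' @export
run_conjfdr_pipeline <- function(config = NULL, ...) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config, ...)
  }
  for (key in c("primary", "secondary")) {
    if (is.null(config[[key]])) {
      stop_input("run_conjfdr_pipeline: config key '%s' is required", key)
    }
  }
  log_lines <- c(sprintf("conjfdr pipeline run %s",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 "config:",
                 vapply(names(config), function(k)
                   sprintf("  %s = %s", k,
                           paste(format(config[[k]]), collapse = ",")),
                   character(1)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  primary <- stage("read_primary",
                   read_sumstats(config$primary, config$primary_cols))
  secondary <- stage("read_secondary",
                     read_sumstats(config$secondary, config$secondary_cols))
  paired <- stage("harmonize",
                  harmonize_pair(primary, secondary,
                                 drop_ambiguous = config$drop_ambiguous))
  meta <- attr(paired, "meta")
  log_lines <- c(log_lines,
                 sprintf("variants: primary %d, secondary %d, merged %d",
                         nrow(primary), nrow(secondary), nrow(paired)),
                 sprintf("harmonization: %s",
                         paste(names(meta), meta, sep = "=", collapse = ", ")))

  if (isTRUE(config$mhc_exclude)) {
    paired <- stage("mhc_exclude", exclude_mhc(paired))
    log_lines <- c(log_lines,
                   sprintf("MHC exclusion removed %d variants",
                           attr(paired, "mhc_removed")))
  }
  if (isTRUE(config$gc_correct)) {
    g1 <- gc_correct(paired$z1); g2 <- gc_correct(paired$z2)
    paired$z1 <- g1$z; paired$p1 <- p_from_z(paired$z1)
    paired$z2 <- g2$z; paired$p2 <- p_from_z(paired$z2)
    log_lines <- c(log_lines, sprintf("genomic inflation: lambda1 %.4f, lambda2 %.4f",
                                      g1$lambda, g2$lambda))
  }

  ld_pairs <- if (!is.null(config$ld)) stage("read_ld", read_ld_table(config$ld)) else NULL
  blocks <- stage("ld_blocks",
                  ld_blocks(ld_pairs, paired$snp, config$r2_threshold))
  log_lines <- c(log_lines, sprintf("LD: %d blocks over %d variants",
                                    length(blocks$blocks), nrow(paired)))

  qcfg <- qq_config(strata_thresholds = config$strata_thresholds,
                    pruning_iterations = config$pruning_iterations,
                    r2_threshold = config$r2_threshold,
                    seed = config$seed, min_stratum = config$min_stratum)
  qq <- stage("conditional_qq", conditional_qq(paired, blocks, qcfg))
  fdr <- stage("cond_fdr",
               cond_fdr_result(paired, blocks, qcfg, method = config$fdr_method))

  sig <- select_significant(fdr, config$conjfdr_threshold)
  sig_full <- merge(sig, paired, by = "snp", sort = FALSE)
  loci <- stage("clump", clump_loci(sig_full, ld_pairs, config$r2_threshold))
  log_lines <- c(log_lines,
                 sprintf("significant variants at conjFDR < %g: %d; independent loci: %d",
                         config$conjfdr_threshold, nrow(sig), nrow(loci)))

  gene_map <- NULL
  if (!is.null(config$gene_map)) {
    gene_map <- stage("gene_map", {
      gm <- data.table::fread(config$gene_map, header = TRUE,
                              data.table = FALSE, showProgress = FALSE)
      names(gm) <- toupper(names(gm))
      gm
    })
  }
  locus_table <- write_locus_table(loci, gene_map)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fdr = file.path(config$out_dir, "fdr.tsv"),
    qq_curves = file.path(config$out_dir, "qq_curves.tsv"),
    qq_enrichment = file.path(config$out_dir, "qq_enrichment.tsv"),
    manhattan = file.path(config$out_dir, "manhattan.tsv"),
    loci = file.path(config$out_dir, "loci.tsv"),
    log = file.path(config$out_dir, "run_log.txt"))

  fdr_out <- data.frame(SNP = fdr$snp,
                        `FDR1|2` = fdr$fdr_1_given_2,
                        `FDR2|1` = fdr$fdr_2_given_1,
                        CONJFDR = fdr$conj_fdr, check.names = FALSE)
  tsv_write(fdr_out, paths$fdr)
  tsv_write(qq, paths$qq_curves)
  tsv_write(attr(qq, "enrichment"), paths$qq_enrichment)

  manhattan <- data.frame(
    SNP = paired$snp, CHR = paired$chrom, POS = paired$pos,
    NEG_LOG10_CONJFDR = pmin(-log10(pmax(fdr$conj_fdr, 1e-300)), 300),
    LEAD = paired$snp %in% loci$snp)
  tsv_write(manhattan, paths$manhattan)
  tsv_write(locus_table, paths$loci)
  writeLines(log_lines, paths$log)

  invisible(list(paired = paired, fdr = fdr, qq = qq, loci = loci,
                 locus_table = locus_table, blocks = blocks, paths = paths,
                 config = config))
}

#' Format shared loci as a publication-shaped locus table
#'
#' Produces the canonical locus-table layout: `Locus_No, SNP, Gene,
#' Chr:Pos, A1/A2, Z1, Z2, ConjFDR, P1, P2`. When a gene map assigns
#' several genes to a lead SNP, the locus row is duplicated once per gene
#' with identical statistics; unmapped leads get an empty `Gene`.
#'
#' @param loci A `shared_loci` table from [clump_loci()].
#' @param gene_map Optional `data.frame` with columns `SNP` and `GENE`.
#' @param path Optional path; when given the table is also written as TSV.
#' @return The formatted `data.frame`.
#' @export
write_locus_table <- function(loci, gene_map = NULL, path = NULL) {
  if (nrow(loci) == 0) {
    out <- data.frame(Locus_No = integer(0), SNP = character(0),
                      Gene = character(0), `Chr:Pos` = character(0),
                      `A1/A2` = character(0), Z1 = numeric(0), Z2 = numeric(0),
                      ConjFDR = numeric(0), P1 = numeric(0), P2 = numeric(0),
                      check.names = FALSE)
  } else {
    base <- data.frame(
      Locus_No = loci$locus_no, SNP = loci$snp, Gene = "",
      `Chr:Pos` = paste0(loci$chrom, ":", loci$pos),
      `A1/A2` = paste0(loci$a1, "/", loci$a2),
      Z1 = loci$z1, Z2 = loci$z2, ConjFDR = loci$conj_fdr,
      P1 = loci$p1, P2 = loci$p2,
      check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(gene_map) && nrow(gene_map)) {
      nm <- toupper(names(gene_map))
      js <- match("SNP", nm); jg <- match("GENE", nm)
      if (is.na(js) || is.na(jg)) {
        stop_input("write_locus_table: gene_map needs SNP and GENE columns")
      }
      rows <- lapply(seq_len(nrow(base)), function(i) {
        genes <- gene_map[[jg]][gene_map[[js]] == base$SNP[i]]
        genes <- genes[!is.na(genes) & nzchar(genes)]
        if (length(genes) == 0) return(base[i, , drop = FALSE])
        rep_rows <- base[rep(i, length(genes)), , drop = FALSE]
        rep_rows$Gene <- genes
        rep_rows
      })
      base <- do.call(rbind, rows)
    }
    rownames(base) <- NULL
    out <- base
  }
  if (!is.null(path)) tsv_write(out, path)
  out
}

#' Read a locus table back into shared-locus records
#'
#' Parses a TSV in the layout of [write_locus_table()] (the round-trip
#' counterpart); gene-duplicated rows are preserved as-is.
#'
#' @param path Path to the locus TSV.
#' @return A `data.frame` with columns `locus_no, snp, gene, chrom, pos,
#'   a1, a2, z1, z2, conj_fdr, p1, p2`.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop_input("read_locus_table: file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          showProgress = FALSE)
  need <- c("Locus_No", "SNP", "Gene", "Chr:Pos", "A1/A2", "Z1", "Z2",
            "ConjFDR", "P1", "P2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop_input("read_locus_table: missing column(s): %s",
                               paste(miss, collapse = ", "))
  cp <- strsplit(as.character(dt[["Chr:Pos"]]), ":", fixed = TRUE)
  al <- strsplit(as.character(dt[["A1/A2"]]), "/", fixed = TRUE)
  data.frame(
    locus_no = as.integer(dt$Locus_No),
    snp = as.character(dt$SNP),
    gene = as.character(dt$Gene),
    chrom = vapply(cp, `[`, character(1), 1),
    pos = as.integer(vapply(cp, `[`, character(1), 2)),
    a1 = vapply(al, `[`, character(1), 1),
    a2 = vapply(al, `[`, character(1), 2),
    z1 = as.numeric(dt$Z1), z2 = as.numeric(dt$Z2),
    conj_fdr = as.numeric(dt$ConjFDR),
    p1 = as.numeric(dt$P1), p2 = as.numeric(dt$P2),
    stringsAsFactors = FALSE)
}
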