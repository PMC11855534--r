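#' Default analysis configuration
#'
#' @param min_cds_len minimum CDS length in bp (default 300).
#' @param code genetic code id (default "11").
#' @param library_fraction ENc-extreme library fraction (default 0.10).
#' @param delta_rscu_threshold ΔRSCU cutoff for optimal codons (default 0.08).
#' @param ssr_thresholds per-unit-length minimum SSR repeat counts.
#' @param repeat_min_len,repeat_max_mismatch long-repeat detection knobs
#'   (defaults 30 bp, 3 mismatches).
#' @param min_ir minimum IR length for structure detection (default 1000).
#' @param dedupe_ir_genes keep one copy of IR-duplicated gene names before
#'   codon statistics (default TRUE).
#' @param pr2_scope "fourfold" or "all" (see [pr2_points()]).
#' @param rscu_scope "pooled" or "high_bias" (see [optimal_codon_set()]).
#' @param find_long_repeats run the dispersed-repeat scan (default TRUE).
#' @return list of class `run_config`.
#' @export
run_config <- function(min_cds_len = 300L, code = "11",
                       library_fraction = 0.10,
                       delta_rscu_threshold = 0.08,
                       ssr_thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                          `4` = 5L, `5` = 5L, `6` = 5L),
                       repeat_min_len = 30L, repeat_max_mismatch = 3L,
                       min_ir = 1000L, dedupe_ir_genes = TRUE,
                       pr2_scope = "fourfold", rscu_scope = "pooled",
                       find_long_repeats = TRUE) {
  stopifnot(min_cds_len > 0L, library_fraction > 0, library_fraction <= 0.5,
            delta_rscu_threshold > 0, all(ssr_thresholds > 0),
            repeat_min_len > 0L, repeat_max_mismatch >= 0L)
  structure(list(min_cds_len = as.integer(min_cds_len), code = code,
                 library_fraction = library_fraction,
                 delta_rscu_threshold = delta_rscu_threshold,
                 ssr_thresholds = ssr_thresholds,
                 repeat_min_len = as.integer(repeat_min_len),
                 repeat_max_mismatch = as.integer(repeat_max_mismatch),
                 min_ir = as.integer(min_ir),
                 dedupe_ir_genes = isTRUE(dedupe_ir_genes),
                 pr2_scope = pr2_scope, rscu_scope = rscu_scope,
                 find_long_repeats = isTRUE(find_long_repeats)),
            class = "run_config")
}

#' Run the full per-genome analysis
#'
#' Composes every stage on one genome record: quadripartite structure and
#' junction report, CDS extraction and rule-based filtering, per-gene codon
#' metrics (GC profile, ENc, CAI), aggregate RSCU, ENc-plot points,
#' PR2-bias points, neutrality regression, correspondence analysis with
#' index correlations, optimal-codon identification, and SSR/long-repeat
#' detection with summary.  The CAI reference set is the high-bias
#' (lowest-ENc) gene library of the same genome.
#'
#' @param record a `cp_genome` (from [read_genbank()] or
#'   [generate_genome()]`$record`).
#' @param config a [run_config()] (defaults used when omitted).
#' @return object of class `cp_analysis`; see the individual stage
#'   functions for the component formats.
#' @export
analyze_genome <- function(record, config = run_config()) {
  stopifnot(inherits(record, "cp_genome"), inherits(config, "run_config"))
  structure_q <- detect_quadripartite(record, min_ir = config$min_ir)
  junctions <- junction_report(structure_q, record$features)

  raw <- extract_cds(record)
  raw_n <- nrow(raw)
  deduped <- dedupe_genes(raw, config$dedupe_ir_genes)
  cds <- filter_cds(deduped, min_len = config$min_cds_len, code = config$code)

  genes <- cds$retained$gene
  counts <- lapply(cds$retained$sequence, count_codons)
  names(counts) <- genes
  profiles <- do.call(rbind, lapply(cds$retained$sequence, gc_profile,
                                    code = config$code))
  profiles <- cbind(gene = genes, profiles)
  enc_list <- lapply(counts, enc_observed, code = config$code)
  encs <- data.frame(gene = genes,
                     enc = vapply(enc_list, `[[`, 0, "enc"))

  rscu_all <- rscu(pool_counts(counts), config$code)
  rscu_mat <- t(vapply(counts, function(cc) {
    r <- rscu(cc, config$code); setNames(r$rscu, r$codon)
  }, numeric(61L)))
  rownames(rscu_mat) <- genes

  optimal <- optimal_codon_set(counts, encs,
                               fraction = config$library_fraction,
                               delta_min = config$delta_rscu_threshold,
                               rscu_scope = config$rscu_scope,
                               code = config$code)
  cai_ref <- rscu(pool_counts(counts[optimal$high_bias]), config$code)
  cais <- vapply(counts, function(cc)
    cai(cc, cai_ref, code = config$code)$cai, numeric(1L))

  coa <- coa_rscu(rscu_mat, code = config$code)
  ax <- coa$row_coords[genes, 1:2, drop = FALSE]
  metrics <- data.frame(gene = genes,
                        axis1 = ax[, 1L], axis2 = ax[, 2L],
                        enc = encs$enc, cai = cais,
                        gc1 = profiles$gc1, gc2 = profiles$gc2,
                        gc3 = profiles$gc3, gc3s = profiles$gc3s,
                        gc12 = profiles$gc12, gc_all = profiles$gc_all,
                        l_aa = cds$retained$l_aa,
                        class = unname(gene_class(genes)),
                        row.names = NULL, stringsAsFactors = FALSE)
  correlations <- correlate_indices(
    metrics[, c("axis1", "axis2", "enc", "cai", "gc3", "gc3s",
                "l_aa", "gc_all")])

  enc_plot <- enc_plot_points(profiles, encs)
  pr2 <- pr2_points(counts, scope = config$pr2_scope, code = config$code)
  neutrality <- neutrality_fit(profiles)

  ssrs <- find_ssrs(record$sequence, thresholds = config$ssr_thresholds,
                    circular = isTRUE(record$circular))
  long_reps <- if (config$find_long_repeats)
    find_long_repeats(record$sequence, min_len = config$repeat_min_len,
                      max_mismatch = config$repeat_max_mismatch) else NULL
  rep_summary <- summarize_repeats(ssrs, long_reps, exclude_ir = structure_q)

  structure(list(
    accession = record$accession, species = record$species,
    genome_length = record$length_bp,
    gc_percent = 100 * gc_fraction(record$sequence),
    structure = structure_q, junctions = junctions,
    n_cds_annotated = raw_n, cds = cds,
    counts = counts, metrics = metrics,
    rscu_all = rscu_all, rscu_matrix = rscu_mat,
    enc_plot = enc_plot, pr2 = pr2, neutrality = neutrality,
    coa = coa, correlations = correlations, optimal = optimal,
    ssrs = ssrs, long_repeats = long_reps, repeat_summary = rep_summary,
    config = config), class = "cp_analysis")
}

#' @export
print.cp_analysis <- function(x, ...) {
  cat("<cp_analysis> ", x$accession,
      if (!is.na(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  cat(sprintf("  genome: %s bp, GC %.2f%%\n",
              format(x$genome_length, big.mark = ","), x$gc_percent))
  if (x$structure$found)
    cat(sprintf("  quadripartite: LSC %s | IR %s x2 | SSC %s bp\n",
                format(circ_len(x$structure$lsc, x$genome_length),
                       big.mark = ","),
                format(x$structure$ir_len, big.mark = ","),
                format(circ_len(x$structure$ssc, x$genome_length),
                       big.mark = ",")))
  cat("  CDS:", x$n_cds_annotated, "annotated,",
      nrow(x$cds$retained), "retained after filtering\n")
  cat(sprintf("  mean ENc: %.2f   genes with ENc > 45: %d\n",
              mean(x$metrics$enc, na.rm = TRUE),
              attr(x$enc_plot, "n_enc_gt_45")))
  cat(sprintf("  neutrality slope: %.3f (r = %.3f)\n",
              x$neutrality$slope, x$neutrality$pearson_r))
  cat(sprintf("  COA axis 1: %.2f%%, axis 2: %.2f%%\n",
              100 * x$coa$contribution[1L], 100 * x$coa$contribution[2L]))
  cat("  optimal codons:", length(x$optimal$optimal),
      "  SSRs:", x$repeat_summary$n_ssr, "\n")
  invisible(x)
}

# header lines stamped into every output file: version, config hash, input id
output_header <- function(x) {
  ver <- as.character(utils::packageVersion("cpcodon"))
  cfg <- substr(jsonlite::base64_enc(serialize(
    lapply(unclass(x$config), unname), NULL)), 1, 16)
  c(sprintf("# cpcodon %s", ver),
    sprintf("# config_hash %s", cfg),
    sprintf("# input %s length %d", x$accession, x$genome_length))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all analysis artifacts of one genome to a directory
#'
#' Emits the per-stage TSV tables (metrics, aggregate RSCU, ENc-plot, PR2,
#' neutrality data, COA row/column coordinates, index correlations, optimal
#' codons, SSRs, long repeats, junctions) and a `summary.json`.  Every file
#' starts with comment lines recording the package version, a configuration
#' hash and the input identity.
#'
#' @param x a `cp_analysis`.
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "cp_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(x)
  out <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv_with_header(df, p, hdr)
    out <<- c(out, p)
  }
  put(x$metrics, "metrics.tsv")
  put(transform(x$rscu_all, codon = as_rna(codon)), "rscu.tsv")
  put(x$enc_plot, "enc_plot.tsv")
  put(x$pr2, "pr2.tsv")
  put(x$neutrality$data[, c("gene", "gc12", "gc3")], "neutrality.tsv")
  put(data.frame(gene = rownames(x$coa$row_coords),
                 round(x$coa$row_coords[, 1:min(4, ncol(x$coa$row_coords))], 6)),
      "coa_rows.tsv")
  put(data.frame(codon = as_rna(rownames(x$coa$col_coords)),
                 round(x$coa$col_coords[, 1:min(4, ncol(x$coa$col_coords))], 6)),
      "coa_cols.tsv")
  cm <- x$correlations
  put(data.frame(variable = rownames(cm$r), round(cm$r, 4)),
      "correlations.tsv")
  put(transform(x$optimal$table, codon = as_rna(codon)),
      "optimal_codons.tsv")
  put(x$ssrs, "ssr.tsv")
  if (!is.null(x$long_repeats)) put(x$long_repeats, "long_repeats.tsv")
  if (nrow(x$junctions)) put(x$junctions, "junctions.tsv")
  sm <- x$repeat_summary
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    accession = x$accession, genome_length = x$genome_length,
    gc_percent = x$gc_percent,
    structure = if (x$structure$found) list(
      lsc = circ_len(x$structure$lsc, x$genome_length),
      ir = x$structure$ir_len,
      ssc = circ_len(x$structure$ssc, x$genome_length)) else NULL,
    n_cds_retained = nrow(x$cds$retained),
    mean_enc = mean(x$metrics$enc, na.rm = TRUE),
    n_enc_gt_45 = attr(x$enc_plot, "n_enc_gt_45"),
    neutrality = list(slope = x$neutrality$slope,
                      r = x$neutrality$pearson_r),
    coa_axis1_pct = 100 * x$coa$contribution[1L],
    coa_axis2_pct = 100 * x$coa$contribution[2L],
    optimal_codons = x$optimal$optimal,
    ssr = list(total = sm$n_ssr, by_unit = sm$ssr_by_unit,
               at_pct = sm$ssr_at$pct)),
    js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(out, js))
}

#' Compare analysis bundles across genomes
#'
#' Reduces two or more per-genome analyses to cross-genome ranges of the
#' scalar metrics, the optimal-codon intersection/union with a per-genome
#' presence matrix, and SSR type shares per genome.  The result does not
#' depend on the input order.
#'
#' @param bundles list of `cp_analysis` objects (>= 2).
#' @return object of class `cp_comparison`: `ranges` (data.frame metric,
#'   min, max), `optimal` (from [intersect_species()]), `ssr_shares`
#'   (matrix genome x unit length, percentages).
#' @export
compare_genomes <- function(bundles) {
  stopifnot(length(bundles) >= 2L,
            all(vapply(bundles, inherits, TRUE, "cp_analysis")))
  acc <- vapply(bundles, `[[`, "", "accession")
  bundles <- bundles[order(acc)]            # permutation invariance
  acc <- sort(acc)
  scalar <- function(f) vapply(bundles, f, numeric(1L))
  vals <- list(
    genome_length = scalar(function(b) b$genome_length),
    gc_percent = scalar(function(b) b$gc_percent),
    ir_length = scalar(function(b) b$structure$ir_len),
    mean_enc = scalar(function(b) mean(b$metrics$enc, na.rm = TRUE)),
    n_enc_gt_45 = scalar(function(b) attr(b$enc_plot, "n_enc_gt_45")),
    neutrality_slope = scalar(function(b) b$neutrality$slope),
    neutrality_r = scalar(function(b) b$neutrality$pearson_r),
    coa_axis1_pct = scalar(function(b) 100 * b$coa$contribution[1L]),
    coa_axis2_pct = scalar(function(b) 100 * b$coa$contribution[2L]),
    n_ssr = scalar(function(b) b$repeat_summary$n_ssr),
    ssr_mono_pct = scalar(function(b) b$repeat_summary$ssr_by_unit$pct[1L]),
    n_optimal = scalar(function(b) length(b$optimal$optimal)))
  ranges <- data.frame(metric = names(vals),
                       min = vapply(vals, min, 0),
                       max = vapply(vals, max, 0), row.names = NULL)
  reports <- lapply(bundles, `[[`, "optimal")
  names(reports) <- acc
  optimal <- intersect_species(reports)
  shares <- t(vapply(bundles,
                     function(b) b$repeat_summary$ssr_by_unit$pct,
                     numeric(6L)))
  dimnames(shares) <- list(acc, paste0("unit", 1:6))
  structure(list(accessions = acc, ranges = ranges, optimal = optimal,
                 ssr_shares = shares), class = "cp_comparison")
}

#' @export
print.cp_comparison <- function(x, ...) {
  cat("<cp_comparison>", length(x$accessions), "genomes:",
      paste(x$accessions, collapse = ", "), "\n")
  print(transform(x$ranges, min = signif(min, 6), max = signif(max, 6)),
        row.names = FALSE)
  cat("  optimal codons: union", length(x$optimal$union),
      "/ common", length(x$optimal$common), "\n")
  invisible(x)
}
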