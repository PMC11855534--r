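#' ENc-extreme bias libraries
#'
#' Genes are sorted by ascending ENc (ties broken by gene name); the lowest
#' fraction forms the high-bias library and the highest fraction the
#' low-bias library.  Library size is `ceiling(fraction * N)` with a floor
#' of 2 genes.
#'
#' @param encs data.frame with columns `gene` and `enc`.
#' @param fraction library fraction (default 0.10).
#' @return list `high_bias` (low-ENc gene ids) and `low_bias` (high-ENc
#'   gene ids), both of equal size.
#' @export
build_bias_libraries <- function(encs, fraction = 0.10) {
  d <- encs[!is.na(encs$enc), , drop = FALSE]
  if (nrow(d) < 10L)
    stop("only ", nrow(d), " genes with defined ENc; ",
         "need >= 10 (or increase `fraction`)")
  d <- d[order(d$enc, d$gene), , drop = FALSE]
  size <- max(2L, ceiling(fraction * nrow(d)))
  list(high_bias = d$gene[seq_len(size)],
       low_bias = d$gene[seq.int(nrow(d) - size + 1L, nrow(d))])
}

#' RSCU difference between the bias libraries
#'
#' Pools the codon counts of each library (counts summed, then RSCU
#' computed once per pool) and returns `delta = RSCU_high_bias -
#' RSCU_low_bias` per sense codon.  A codon whose family is unobserved in
#' either pool has NA delta.
#'
#' @param counts_by_gene named list of `codon_counts`.
#' @param libraries list from [build_bias_libraries()].
#' @param code genetic code id (default "11").
#' @return data.frame `codon, amino_acid, rscu_high, rscu_low, delta_rscu`.
#' @export
delta_rscu <- function(counts_by_gene, libraries, code = "11") {
  hi <- rscu(pool_counts(counts_by_gene[libraries$high_bias]), code)
  lo <- rscu(pool_counts(counts_by_gene[libraries$low_bias]), code)
  data.frame(codon = hi$codon, amino_acid = hi$amino_acid,
             rscu_high = hi$rscu, rscu_low = lo$rscu,
             delta_rscu = hi$rscu - lo$rscu,
             stringsAsFactors = FALSE)
}

#' Identify high-frequency and optimal codons for one genome
#'
#' High-frequency codons have pooled all-gene RSCU > 1; optimal codons
#' additionally have `delta RSCU >= delta_min` between the high-bias
#' (low-ENc) and low-bias (high-ENc) gene libraries.  Met, Trp and stop
#' codons can never qualify (their RSCU is fixed at 1 or undefined).
#'
#' @param counts_by_gene named list of `codon_counts` for the filtered genes.
#' @param encs data.frame `gene, enc`.
#' @param fraction ENc-extreme library fraction (default 0.10).
#' @param delta_min ΔRSCU threshold (default 0.08).
#' @param rscu_scope "pooled" (default) evaluates "RSCU > 1" on the pooled
#'   all-gene RSCU; "high_bias" evaluates it on the high-bias library.
#' @param code genetic code id (default "11").
#' @return object of class `optimal_codon_report`: `table` (data.frame
#'   `codon, amino_acid, rscu_all, rscu_high, rscu_low, delta_rscu,
#'   high_frequency, optimal`), `high_bias`, `low_bias` (gene ids),
#'   `optimal` / `high_frequency` (codon sets, RNA alphabet), and
#'   `ending_base` (A/U/G/C composition of the optimal set).
#' @export
optimal_codon_set <- function(counts_by_gene, encs, fraction = 0.10,
                              delta_min = 0.08,
                              rscu_scope = c("pooled", "high_bias"),
                              code = "11") {
  rscu_scope <- match.arg(rscu_scope)
  libs <- build_bias_libraries(encs, fraction)
  dl <- delta_rscu(counts_by_gene, libs, code)
  all_tab <- rscu(pool_counts(counts_by_gene), code)
  tab <- data.frame(codon = dl$codon, amino_acid = dl$amino_acid,
                    rscu_all = all_tab$rscu,
                    rscu_high = dl$rscu_high, rscu_low = dl$rscu_low,
                    delta_rscu = dl$delta_rscu,
                    stringsAsFactors = FALSE)
  fam_n <- family_size_by_codon(code)
  eligible <- fam_n[tab$codon] >= 2L
  base_rscu <- if (rscu_scope == "pooled") tab$rscu_all else tab$rscu_high
  tab$high_frequency <- eligible & !is.na(base_rscu) & base_rscu > 1
  tab$optimal <- tab$high_frequency & !is.na(tab$delta_rscu) &
    tab$delta_rscu >= delta_min
  opt <- as_rna(tab$codon[tab$optimal])
  ends <- substr(opt, 3L, 3L)
  structure(list(table = tab,
                 high_bias = libs$high_bias, low_bias = libs$low_bias,
                 high_frequency = as_rna(tab$codon[tab$high_frequency]),
                 optimal = opt,
                 ending_base = table(factor(ends, c("A", "U", "G", "C"))),
                 fraction = fraction, delta_min = delta_min,
                 rscu_scope = rscu_scope),
            class = "optimal_codon_report")
}

#' @export
print.optimal_codon_report <- function(x, ...) {
  cat("Optimal codon report (libraries of", length(x$high_bias),
      "genes each;", sprintf("ΔRSCU >= %.2f)", x$delta_min), "\n")
  cat("  high-frequency codons (RSCU > 1):", length(x$high_frequency), "\n")
  cat("  optimal codons:", length(x$optimal), "\n   ",
      paste(sort(x$optimal), collapse = " "), "\n")
  eb <- x$ending_base
  cat("  optimal-codon ending bases:",
      paste(names(eb), as.integer(eb), sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Optimal codons shared across genomes
#'
#' @param reports list of `optimal_codon_report` objects (>= 2), ideally
#'   named by accession.
#' @return list `common` (intersection, RNA alphabet), `union`, and
#'   `presence` (logical matrix codon x genome).
#' @export
intersect_species <- function(reports) {
  stopifnot(length(reports) >= 2L)
  sets <- lapply(reports, function(r) r$optimal)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("genome", seq_along(sets))
  u <- sort(unique(unlist(sets)))
  presence <- vapply(sets, function(s) u %in% s,
                     logical(length(u)))
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = length(u))
  rownames(presence) <- u
  list(common = u[rowSums(presence) == length(sets)],
       union = u,
       presence = presence)
}
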