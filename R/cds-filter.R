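#' Filter coding sequences with the four selection rules
#'
#' A CDS is retained only if it (1) has a base count that is a multiple of
#' three, (2) is at least `min_len` bp long, (3) contains only the standard
#' bases A/C/G/T, and (4) is free of internal stop codons under the chosen
#' genetic code.  Rules are evaluated in order 1..4; the first violated rule
#' is recorded per rejection (all violated rules are kept for diagnostics).
#' A terminal stop codon is allowed and excluded from the amino-acid length.
#'
#' @param raw data.frame with columns `gene` and `sequence` (e.g. from
#'   [extract_cds()]), or a named character vector.
#' @param min_len minimum length in bp (default 300).
#' @param code genetic code id for the stop-codon check (default "11",
#'   bacterial/plastid).
#' @return object of class `cds_set`: list with `retained` (data.frame
#'   `gene, sequence, length_bp, l_aa`), `rejected` (data.frame
#'   `gene, length_bp, first_rule, rules_failed`), `min_len`, `code`.
#' @export
#' @examples
#' filter_cds(data.frame(gene = "toy",
#'                       sequence = paste0("ATG", strrep("AAA", 98), "TAA")))
filter_cds <- function(raw, min_len = 300L, code = "11") {
  if (!is.data.frame(raw))
    raw <- data.frame(gene = names(raw), sequence = unname(raw),
                      stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    warning("empty CDS input")
    return(structure(list(
      retained = data.frame(gene = character(0), sequence = character(0),
                            length_bp = integer(0), l_aa = integer(0),
                            stringsAsFactors = FALSE),
      rejected = data.frame(gene = character(0), length_bp = integer(0),
                            first_rule = integer(0),
                            rules_failed = character(0),
                            stringsAsFactors = FALSE),
      min_len = min_len, code = code), class = "cds_set"))
  }
  stops <- stop_codons(code)
  res <- lapply(seq_len(nrow(raw)), function(i) {
    s <- toupper(raw$sequence[i])
    len <- nchar(s)
    failed <- integer(0)
    if (len %% 3L != 0L) failed <- c(failed, 1L)
    if (len < min_len) failed <- c(failed, 2L)
    clean <- !grepl("[^ACGT]", s)
    if (!clean) failed <- c(failed, 3L)
    l_aa <- NA_integer_
    if (len %% 3L == 0L && clean && len >= 3L) {
      codons <- split_codons(s)
      internal <- codons[-length(codons)]
      if (any(internal %in% stops)) failed <- c(failed, 4L)
      l_aa <- as.integer(length(codons) -
                           (codons[length(codons)] %in% stops))
    }
    list(gene = raw$gene[i], sequence = s, length_bp = len, l_aa = l_aa,
         failed = failed)
  })
  ok <- lengths(lapply(res, `[[`, "failed")) == 0L
  retained <- data.frame(
    gene = vapply(res[ok], `[[`, "", "gene"),
    sequence = vapply(res[ok], `[[`, "", "sequence"),
    length_bp = vapply(res[ok], `[[`, 0L, "length_bp"),
    l_aa = vapply(res[ok], `[[`, 0L, "l_aa"),
    stringsAsFactors = FALSE)
  rej <- res[!ok]
  rejected <- data.frame(
    gene = vapply(rej, `[[`, "", "gene"),
    length_bp = vapply(rej, `[[`, 0L, "length_bp"),
    first_rule = vapply(rej, function(r) r$failed[1L], 0L),
    rules_failed = vapply(rej, function(r)
      paste(r$failed, collapse = ","), ""),
    stringsAsFactors = FALSE)
  structure(list(retained = retained, rejected = rejected,
                 min_len = min_len, code = code),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat("<cds_set>", nrow(x$retained), "retained,",
      nrow(x$rejected), "rejected (min_len =", x$min_len,
      "bp, code", paste0(x$code, ")"), "\n")
  if (nrow(x$rejected)) {
    tab <- table(factor(x$rejected$first_rule, levels = 1:4))
    cat("  first violated rule:",
        paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

# keep one copy of each gene name (IR-duplicated genes appear twice);
# suffixes added by extract_cds ("gene.2") are treated as duplicates
dedupe_genes <- function(raw, dedupe = TRUE) {
  if (!dedupe || !nrow(raw)) return(raw)
  base <- sub("\\.\\d+$", "", raw$gene)
  raw[!duplicated(base), , drop = FALSE]
}
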