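#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test lm median pnorm rnorm runif sd setNames
#' @importFrom utils head tail write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# 64 codons in lexicographic order, fixed once so downstream tables are stable
all_codons <- function() {
  g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as input and output.  IUPAC ambiguity codes are
#' handled by Biostrings.
#'
#' @param x character vector of DNA sequences (upper case).
#' @return character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("AAATTTG")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a CDS into consecutive triplets; errors unless length is a multiple of 3
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# genetic code as a named character vector codon -> amino acid ("*" for stop).
# Code "11" (bacterial/plastid) is the plastome default.
get_code <- function(code = "11") {
  gc <- Biostrings::getGeneticCode(as.character(code))
  # Biostrings names codons with T already; make sure of case/order
  setNames(as.character(gc), names(gc))
}

# synonymous families: list amino acid -> sense codons, stops excluded
syn_families <- function(code = "11") {
  gc <- get_code(code)
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

# family size per codon (0 for stops)
family_size_by_codon <- function(code = "11") {
  gc <- get_code(code)
  fam <- syn_families(code)
  sizes <- lengths(fam)
  out <- setNames(integer(length(gc)), names(gc))
  sense <- gc != "*"
  out[sense] <- sizes[gc[sense]]
  out
}

stop_codons <- function(code = "11") {
  gc <- get_code(code)
  names(gc)[gc == "*"]
}

# translate a frame-0 DNA sequence to one-letter amino acids ("*" = stop)
translate_dna <- function(seq, code = "11") {
  gc <- get_code(code)
  paste(gc[split_codons(seq)], collapse = "")
}

# GC fraction of a string (A/C/G/T only in denominator unless strict)
gc_fraction <- function(seq) {
  if (nchar(seq) == 0L) return(NA_real_)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(b %in% c("G", "C"))
}

# U-alphabet codon labels for reporting (RNA style, as printed in the field)
as_rna <- function(codons) chartr("T", "U", codons)
as_dna <- function(codons) chartr("U", "T", toupper(codons))

`%||%` <- function(a, b) if (is.null(a)) b else a
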