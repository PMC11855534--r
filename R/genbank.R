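#' Read an annotated genome from a GenBank flat file
#'
#' Parses a GenBank flat file (LOCUS/FEATURES/ORIGIN) into a `cp_genome`
#' record: the upper-cased sequence plus a feature table keeping CDS, tRNA,
#' rRNA and gene features with their full (possibly joined, possibly
#' complemented) locations in annotation order.  Coordinates are 1-based
#' inclusive, the GenBank convention.
#'
#' @param path path to a GenBank flat file.
#' @return object of class `cp_genome`: list with `accession`, `species`,
#'   `sequence`, `length_bp`, `circular` and `features` (data.frame with
#'   columns `kind`, `gene`, `strand`, `n_segments` and a list column
#'   `segments` of two-column start/end matrices).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)

  locus <- grep("^LOCUS", lines, value = TRUE)
  accession <- NA_character_
  circular <- FALSE
  if (length(locus)) {
    toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
    if (length(toks) >= 2L) accession <- toks[2L]
    circular <- any(grepl("circular", toks, ignore.case = TRUE))
  }
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    toks <- strsplit(trimws(acc_line[1L]), "\\s+")[[1L]]
    if (length(toks) >= 2L) accession <- toks[2L]
  }
  if (is.na(accession) || !nzchar(accession))
    stop("no accession found in ", path)
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  species <- if (length(org)) trimws(sub("^\\s+ORGANISM", "", org[1L])) else NA_character_

  # ---- sequence block ----
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("no ORIGIN sequence block in ", path)
  seq_lines <- lines[(o[1L] + 1L):length(lines)]
  end <- grep("^//", seq_lines)
  if (length(end)) seq_lines <- seq_lines[seq_len(end[1L] - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq)) stop("ORIGIN block contains no sequence in ", path)

  # ---- feature block ----
  f <- grep("^FEATURES", lines)
  features <- empty_feature_table()
  if (length(f)) {
    fend <- if (length(o)) o[1L] - 1L else length(lines)
    flines <- lines[(f[1L] + 1L):fend]
    features <- parse_feature_block(flines, nchar(seq))
  }

  structure(list(accession = accession, species = species,
                 sequence = seq, length_bp = nchar(seq),
                 circular = circular, features = features),
            class = "cp_genome")
}

empty_feature_table <- function() {
  data.frame(kind = character(0), gene = character(0),
             strand = character(0), n_segments = integer(0),
             segments = I(list()), stringsAsFactors = FALSE)
}

# feature keys we retain; anything else becomes "other" but is kept
KEPT_KINDS <- c("CDS", "tRNA", "rRNA", "gene")

parse_feature_block <- function(flines, genome_len) {
  # a new feature starts at indent 5 with a key; qualifiers/continuations at 21
  is_new <- grepl("^ {5}\\S", flines)
  idx <- which(is_new)
  out <- list()
  for (k in seq_along(idx)) {
    first <- flines[idx[k]]
    last <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    body <- flines[seq(idx[k], last)]
    key <- sub("^ {5}(\\S+).*$", "\\1", first)
    if (key == "source") next
    kind <- if (key %in% KEPT_KINDS) key else "other"
    # location may continue over lines until the first qualifier line ("/")
    loc_lines <- character(0)
    for (ln in body) {
      txt <- trimws(ln)
      if (identical(ln, first)) txt <- trimws(sub("^ {5}\\S+", "", ln))
      if (startsWith(txt, "/")) break
      loc_lines <- c(loc_lines, txt)
    }
    loc <- paste(loc_lines, collapse = "")
    parsed <- tryCatch(parse_location(loc, genome_len),
                       error = function(e)
                         stop("malformed location for feature '", key,
                              "' (", loc, "): ", conditionMessage(e),
                              call. = FALSE))
    quals <- paste(body, collapse = " ")
    gene <- NA_character_
    m <- regmatches(quals, regexpr('/gene="[^"]*"', quals))
    if (length(m) && nzchar(m)) gene <- sub('/gene="([^"]*)"', "\\1", m)
    if (is.na(gene)) {
      m <- regmatches(quals, regexpr('/locus_tag="[^"]*"', quals))
      if (length(m) && nzchar(m)) gene <- sub('/locus_tag="([^"]*)"', "\\1", m)
    }
    out[[length(out) + 1L]] <-
      list(kind = kind, gene = gene, strand = parsed$strand,
           n_segments = nrow(parsed$segments), segments = parsed$segments)
  }
  if (!length(out)) return(empty_feature_table())
  data.frame(kind = vapply(out, `[[`, "", "kind"),
             gene = vapply(out, `[[`, "", "gene"),
             strand = vapply(out, `[[`, "", "strand"),
             n_segments = vapply(out, `[[`, 0L, "n_segments"),
             segments = I(lapply(out, `[[`, "segments")),
             stringsAsFactors = FALSE)
}

# Parse a GenBank location string into ordered segments + strand.
# Handles complement(...), join(...), order(...), partial markers (< >).
parse_location <- function(loc, genome_len) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("complement", loc))
    stop("per-segment complement() not supported")
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("empty location")
  segs <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^\\d+$", p)) return(c(as.integer(p), as.integer(p)))
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1L]]
    if (length(m) != 3L) stop("cannot parse segment '", p, "'")
    c(as.integer(m[2L]), as.integer(m[3L]))
  }, integer(2L)))
  dimnames(segs) <- list(NULL, c("start", "end"))
  if (any(segs < 1L) || any(segs > genome_len) ||
      any(segs[, "end"] < segs[, "start"]))
    stop("segment out of bounds or inverted")
  list(strand = strand, segments = segs)
}

#' @export
print.cp_genome <- function(x, ...) {
  cat("<cp_genome> ", x$accession,
      if (!is.na(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  cat("  length:", format(x$length_bp, big.mark = ","), "bp",
      if (x$circular) "(circular)", "\n")
  cat("  GC:", sprintf("%.2f%%", 100 * gc_fraction(x$sequence)), "\n")
  if (nrow(x$features))
    print(table(x$features$kind))
  invisible(x)
}

#' Extract coding sequences from a genome record
#'
#' Concatenates the segments of every CDS feature in annotation order (so
#' origin-spanning and multi-exon joins come out contiguous), reverse-
#' complements minus-strand features, and disambiguates duplicate gene names
#' with positional suffixes (`.2`, `.3`, ...).
#'
#' @param record a `cp_genome` from [read_genbank()] or [generate_genome()].
#' @return data.frame with columns `gene`, `sequence`, `length_bp`.
#' @export
extract_cds <- function(record) {
  stopifnot(inherits(record, "cp_genome"))
  feats <- record$features
  cds <- feats[feats$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) {
    warning("record ", record$accession, " has no CDS features")
    return(data.frame(gene = character(0), sequence = character(0),
                      length_bp = integer(0), stringsAsFactors = FALSE))
  }
  seqs <- vapply(seq_len(nrow(cds)), function(i) {
    segs <- cds$segments[[i]]
    s <- paste(substring(record$sequence, segs[, "start"], segs[, "end"]),
               collapse = "")
    if (cds$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1L))
  genes <- cds$gene
  genes[is.na(genes)] <- sprintf("cds_%d", which(is.na(genes)))
  dup <- ave(seq_along(genes), genes, FUN = seq_along)
  genes <- ifelse(dup > 1L, paste0(genes, ".", dup), genes)
  data.frame(gene = genes, sequence = seqs, length_bp = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (names become headers) or the
#'   data.frame from [extract_cds()].
#' @param path output file.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$gene)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}
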