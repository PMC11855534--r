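#' Count codons in a coding sequence
#'
#' Tallies frame-0 triplets of a CDS into a fixed 64-entry table.  A terminal
#' stop codon, when present, is counted under the stop codons; stop counts are
#' excluded from all downstream synonymous-family statistics.
#'
#' @param cds a single DNA string whose length is a multiple of 3.
#' @return named integer vector of length 64 (codon -> count), class
#'   `codon_counts`, with attribute `total` (total codons counted).
#' @export
#' @examples
#' count_codons("ATGTGGTAA")
count_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  codons <- split_codons(cds)
  bad <- setdiff(unique(codons), all_codons())
  if (length(bad))
    stop("non-ACGT codons present: ", paste(bad, collapse = ", "))
  counts <- setNames(integer(64L), all_codons())
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  structure(counts, total = sum(counts), class = "codon_counts")
}

# pool several codon_counts (or bare named vectors) into one table
pool_counts <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1L]]) && !is.numeric(lst[[1L]]))
    lst <- lst[[1L]]
  counts <- setNames(integer(64L), all_codons())
  for (x in lst) counts[names(x)] <- counts[names(x)] + as.integer(x)
  structure(counts, total = sum(counts), class = "codon_counts")
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon j of amino acid i with synonymous-family size n_i and count x_ij,
#' RSCU_ij = x_ij / ((1/n_i) * sum_j x_ij): the observed count relative to the
#' expectation under uniform use within the family.  Values above 1 mark
#' favoured codons.  Single-codon families (Met, Trp) have RSCU exactly 1
#' whenever observed.  Stop codons are excluded; a family with zero observed
#' codons has undefined (NA) RSCU, not 0.
#'
#' @param counts a `codon_counts` vector (or any named numeric codon vector).
#' @param code genetic code id passed to [Biostrings::getGeneticCode()];
#'   default "11" (bacterial/plastid).
#' @return data.frame with columns `codon` (DNA alphabet), `amino_acid`,
#'   `family_size`, `count`, `rscu`.
#' @export
#' @examples
#' cc <- count_codons(paste0(strrep("AAA", 3), "AAG"))
#' subset(rscu(cc), amino_acid == "K")   # Lys: AAA 1.5, AAG 0.5
rscu <- function(counts, code = "11") {
  gc <- get_code(code)
  sense <- names(gc)[gc != "*"]
  x <- as.numeric(counts[sense])
  aa <- gc[sense]
  fam_tot <- tapply(x, aa, sum)[aa]
  fam_n <- family_size_by_codon(code)[sense]
  val <- ifelse(fam_tot > 0, x / (fam_tot / fam_n), NA_real_)
  data.frame(codon = sense, amino_acid = unname(aa),
             family_size = unname(fam_n), count = x,
             rscu = unname(val), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Positional GC content of a coding sequence
#'
#' GC1/GC2/GC3 are the G+C fractions at codon positions 1, 2 and 3 over all
#' codons of the CDS (a terminal stop codon is excluded); GC12 is the mean of
#' GC1 and GC2.  GC3s is the G+C fraction at third positions of synonymous
#' codons only, i.e. codons whose family has two or more members -- Met, Trp
#' and stop codons are excluded.  GC3s is the quantity S of the expected-ENc
#' curve.
#'
#' @param cds DNA string, length a multiple of 3 (a filtered CDS).
#' @param code genetic code id (default "11").
#' @param gc3s_scope "synonymous" (standard; default) restricts the GC3s
#'   denominator to synonymous third positions; "gene_wide" divides the same
#'   G+C count by the total base count of the gene instead.
#' @return one-row data.frame: `gc1, gc2, gc3, gc12, gc3s, gc_all, n_codons`.
#'   `gc3s` is NA when the gene has no synonymous codons.
#' @export
gc_profile <- function(cds, code = "11",
                       gc3s_scope = c("synonymous", "gene_wide")) {
  gc3s_scope <- match.arg(gc3s_scope)
  gcode <- get_code(code)
  codons <- split_codons(cds)
  # drop a terminal stop from positional statistics
  if (length(codons) && gcode[codons[length(codons)]] == "*")
    codons <- codons[-length(codons)]
  if (!length(codons))
    return(data.frame(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
                      gc12 = NA_real_, gc3s = NA_real_, gc_all = NA_real_,
                      n_codons = 0L))
  b1 <- substr(codons, 1L, 1L)
  b2 <- substr(codons, 2L, 2L)
  b3 <- substr(codons, 3L, 3L)
  isgc <- function(b) b %in% c("G", "C")
  gc1 <- mean(isgc(b1)); gc2 <- mean(isgc(b2)); gc3 <- mean(isgc(b3))
  fam_n <- family_size_by_codon(code)
  syn <- fam_n[codons] >= 2L & gcode[codons] != "*"
  gc3s <- if (!any(syn)) NA_real_ else if (gc3s_scope == "synonymous")
    mean(isgc(b3[syn])) else sum(isgc(b3[syn])) / (3L * length(codons))
  data.frame(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
             gc3s = gc3s,
             gc_all = mean(c(isgc(b1), isgc(b2), isgc(b3))),
             n_codons = length(codons))
}

#' Observed effective number of codons (ENc)
#'
#' Wright's estimator.  For each synonymous family with n >= 2 observed
#' codons, the codon homozygosity is F = (n * sum(p^2) - 1) / (n - 1) with p
#' the within-family codon frequencies.  F values are averaged within
#' degeneracy classes (2-, 3-, 4- and 6-fold under code 11: 9, 1, 5 and 3
#' families) and
#' \deqn{ENc = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' A family with fewer than 2 observed codons (or a non-positive F) is
#' dropped from its class; a wholly missing 3-fold class mean is imputed as
#' (F2 + F4)/2; any other missing class leaves ENc undefined.  The estimate
#' is capped into [20, 61].
#'
#' @param counts a `codon_counts` vector.
#' @param code genetic code id (default "11").
#' @return list of class `enc_result`: `enc` (NA if undefined), `f_bar`
#'   (named class means), `n_families` used per class, `capped`, `imputed_f3`,
#'   `undefined`.
#' @export
enc_observed <- function(counts, code = "11") {
  fam <- syn_families(code)
  fam <- fam[lengths(fam) >= 2L]          # degenerate families only
  f_hat <- deg <- numeric(0)
  for (aa in names(fam)) {
    x <- as.numeric(counts[fam[[aa]]])
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next                      # uninformative family (CodonW-style)
    f_hat <- c(f_hat, f)
    deg <- c(deg, length(fam[[aa]]))
  }
  class_sizes <- table(lengths(fam))      # families per degeneracy class
  classes <- as.integer(names(class_sizes))
  f_bar <- setNames(rep(NA_real_, length(classes)), paste0("F", classes))
  n_used <- setNames(integer(length(classes)), paste0("F", classes))
  for (i in seq_along(classes)) {
    sel <- deg == classes[i]
    if (any(sel)) {
      f_bar[i] <- mean(f_hat[sel])
      n_used[i] <- sum(sel)
    }
  }
  imputed <- FALSE
  if (is.na(f_bar["F3"]) && !is.na(f_bar["F2"]) && !is.na(f_bar["F4"])) {
    f_bar["F3"] <- (f_bar["F2"] + f_bar["F4"]) / 2
    imputed <- TRUE
  }
  undefined <- anyNA(f_bar)
  enc <- NA_real_; capped <- FALSE
  if (!undefined) {
    enc <- 2 + sum(as.numeric(class_sizes) / f_bar)
    if (enc < 20 || enc > 61) { capped <- TRUE; enc <- min(max(enc, 20), 61) }
  }
  structure(list(enc = enc, f_bar = f_bar, n_families = n_used,
                 capped = capped, imputed_f3 = imputed,
                 undefined = undefined),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat("ENc:", if (is.na(x$enc)) "undefined" else format(round(x$enc, 2)),
      if (x$capped) "(capped)" else "", "\n")
  print(round(x$f_bar, 4))
  invisible(x)
}

#' Expected ENc at a given GC3s
#'
#' The null expectation for a gene whose codon usage is shaped only by the
#' G+C content at synonymous third positions (S = GC3s):
#' \deqn{ENc_{exp}(S) = 2 + S + 29 / (S^2 + (1 - S)^2).}
#' This is the standard curve of the ENc-plot.
#'
#' @param s numeric vector of GC3s fractions in [0, 1] (NA allowed).
#' @return numeric vector of expected ENc values.
#' @export
#' @examples
#' enc_expected(0.5)  # 60.5
#' enc_expected(0)    # 31
enc_expected <- function(s) {
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("GC3s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Codon adaptation index (CAI)
#'
#' Sharp-Li convention: relative adaptiveness w_ij = RSCU_ij / max_j RSCU_ij
#' taken from a reference (highly biased) gene set; the CAI of a gene is the
#' geometric mean of w over its codons, excluding Met, Trp and stops.  Codons
#' missing from the reference (RSCU 0 or NA) are smoothed to a small floor so
#' the geometric mean stays defined.
#'
#' @param counts `codon_counts` of the gene.
#' @param reference RSCU table of the reference set, as returned by [rscu()].
#' @param code genetic code id (default "11").
#' @param w_floor smoothing floor for unobserved reference codons
#'   (default 0.01).
#' @return list of class `cai_result`: `cai`, `n_codons` used, `weights`.
#' @export
cai <- function(counts, reference, code = "11", w_floor = 0.01) {
  gcv <- get_code(code)
  fam_n <- family_size_by_codon(code)
  w <- setNames(rep(NA_real_, nrow(reference)), reference$codon)
  for (aa in unique(reference$amino_acid)) {
    sel <- reference$amino_acid == aa
    r <- reference$rscu[sel]
    if (all(is.na(r)) || max(r, na.rm = TRUE) == 0) {
      w[reference$codon[sel]] <- 1      # uninformative family
    } else {
      w[reference$codon[sel]] <- r / max(r, na.rm = TRUE)
    }
  }
  w[is.na(w) | w < w_floor] <- w_floor
  use <- names(counts)[gcv[names(counts)] != "*" &
                         fam_n[names(counts)] >= 2L]
  x <- as.numeric(counts[use])
  tot <- sum(x)
  if (tot == 0)
    return(structure(list(cai = NA_real_, n_codons = 0L, weights = w),
                     class = "cai_result"))
  val <- exp(sum(x * log(w[use])) / tot)
  structure(list(cai = val, n_codons = tot, weights = w),
            class = "cai_result")
}

#' @export
print.cai_result <- function(x, ...) {
  cat("CAI:", format(round(x$cai, 4)), "over", x$n_codons, "codons\n")
  invisible(x)
}
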