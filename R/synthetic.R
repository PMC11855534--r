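# Approximate amino-acid frequencies of plastid proteomes (AT-rich genomes:
# abundant Leu/Ile/Ser/Phe); used by the "hevea-like" preset.
PLASTOME_AA_FREQ <- local({
  x <- c(L = 0.105, I = 0.086, S = 0.078, G = 0.071, V = 0.060, A = 0.058,
         F = 0.054, T = 0.052, K = 0.051, N = 0.048, R = 0.047, E = 0.045,
         P = 0.043, D = 0.040, Y = 0.035, Q = 0.033, M = 0.028, H = 0.028,
         W = 0.022, C = 0.016)
  x / sum(x)
})

#' Specification for a synthetic plastome
#'
#' Bundles every knob of the generator into a validated spec whose seed
#' fully determines the output.  Three presets cover the common study
#' designs: `"hevea-like"` emulates the target genus (circular ~161 kb
#' genome, LSC/IRb/SSC/IRa with IR ~26.8 kb, overall GC ~35.7%, 91 genes
#' favouring A/U-ending codons with per-gene ENc spread of roughly 36-57,
#' SSRs dominated by A/T mononucleotide runs); `"uniform"` draws codons
#' uniformly within families on a small architecture (null model);
#' `"strong-bias"` implants designated preferred codons at high bias in the
#' low-ENc expression class, for recovery experiments.
#'
#' @param preset one of "hevea-like", "uniform", "strong-bias".
#' @param seed integer seed; same spec + seed gives byte-identical output.
#' @param ... overrides for any spec field (`n_genes`, `gene_length_range`
#'   (aa), `arch` (named bp vector `lsc`, `ir`, `ssc`), `gc_target`,
#'   `high_bias_fraction`, `bias_range_high`, `bias_range_low`, `gc3_sd`,
#'   `gc12_coupling`, `aa_freq`, `family_bias_p`, `preferred_codons`,
#'   `designated_p_high`, `ssr_implants` (data.frame `motif`, `repeats`),
#'   `n_ir_genes`, `n_ssc_genes`, `code`).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("hevea-like", "uniform", "strong-bias"),
                           seed = 1L, ...) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    "hevea-like" = list(
      n_genes = 91L, gene_length_range = c(100L, 500L),
      arch = c(lsc = 89100L, ir = 26810L, ssc = 18370L),
      gc_target = 0.357,
      high_bias_fraction = 0.2,
      bias_range_high = c(1.0, 1.7), bias_range_low = c(0.2, 1.0),
      gc3_sd = 0.25, gc12_coupling = 1.0,
      base3_pref = c(A = 0, T = 0.2, G = 0, C = 0.5),
      within_bias = 0.6,
      aa_freq = PLASTOME_AA_FREQ,
      family_bias_p = NA_real_,
      preferred_codons = character(0), designated_p_high = 0.95,
      ssr_implants = NULL,          # filled per seed in the generator
      n_ir_genes = 4L, n_ssc_genes = 8L, code = "11"),
    "uniform" = list(
      n_genes = 100L, gene_length_range = c(300L, 300L),
      arch = c(lsc = 10000L, ir = 3000L, ssc = 2000L),
      gc_target = 0.40,
      high_bias_fraction = 0,
      bias_range_high = c(0, 0), bias_range_low = c(0, 0),
      gc3_sd = 0, gc12_coupling = 0,
      base3_pref = c(A = 0, T = 0, G = 0, C = 0),
      within_bias = 0,
      aa_freq = NULL,               # uniform over amino acids
      family_bias_p = NA_real_,
      preferred_codons = character(0), designated_p_high = 0.95,
      ssr_implants = data.frame(motif = character(0), repeats = integer(0)),
      n_ir_genes = 2L, n_ssc_genes = 2L, code = "11"),
    "strong-bias" = list(
      n_genes = 100L, gene_length_range = c(1200L, 1800L),
      arch = NULL,                  # CDS-level studies; no genome assembly
      gc_target = 0.40,
      high_bias_fraction = 0.2,
      bias_range_high = c(0, 0), bias_range_low = c(0, 0),
      gc3_sd = 0, gc12_coupling = 0,
      base3_pref = c(A = 0, T = 0, G = 0, C = 0),
      within_bias = 0,
      aa_freq = NULL,
      family_bias_p = 0.995,
      preferred_codons = c("AAG", "AAT", "CAT", "CAA",
                           "GAA", "GCA", "GGA", "CCA"),
      designated_p_high = 0.95,
      ssr_implants = data.frame(motif = character(0), repeats = integer(0)),
      n_ir_genes = 0L, n_ssc_genes = 0L, code = "11"))
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(spec)))
  if (length(unknown)) stop("unknown spec fields: ",
                            paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  spec$preset <- preset
  spec$seed <- as.integer(seed)
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(spec) {
  stopifnot(spec$n_genes >= 1L,
            length(spec$gene_length_range) == 2L,
            all(spec$gene_length_range >= 10L),
            spec$high_bias_fraction >= 0, spec$high_bias_fraction <= 1)
  if (!is.null(spec$arch)) {
    stopifnot(all(c("lsc", "ir", "ssc") %in% names(spec$arch)),
              all(spec$arch > 0))
  }
  if (!is.null(spec$aa_freq)) {
    if (abs(sum(spec$aa_freq) - 1) > 0.02)
      stop("aa_freq must sum to ~1")
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> preset:", x$preset, " seed:", x$seed, "\n")
  cat("  genes:", x$n_genes, " length:",
      paste(x$gene_length_range, collapse = "-"), "aa\n")
  if (!is.null(x$arch))
    cat("  architecture: LSC", x$arch[["lsc"]], "+ IR", x$arch[["ir"]],
        "x2 + SSC", x$arch[["ssc"]], "bp;  GC target",
        x$gc_target, "\n")
  invisible(x)
}

# per-family codon weight vectors for one gene.
# b: strength of the A/T-third-base preference (exp scale);
# t: per-gene GC3 shift (multiplies G/C-ending codons by exp(t));
# pref: fixed per-codon log-weight offsets shared by all genes (the
# "tRNA-pool" preference profile: third-base asymmetries plus within-family
# perturbations), which is what places genes below the expected ENc curve;
# designated: named aa -> codon; in high-bias genes (`active`) the
# designated codon takes `p_hi` probability mass, in low-bias genes the
# designated family is uniform (so the contrast is class-specific).
gene_family_weights <- function(fam, b, t, family_bias_p,
                                designated, active, p_hi, pref = NULL) {
  lapply(names(fam), function(aa) {
    cods <- fam[[aa]]
    k <- length(cods)
    if (aa %in% names(designated)) {
      if (active && k >= 2L) {
        w <- rep((1 - p_hi) / (k - 1), k)
        w[cods == designated[[aa]]] <- p_hi
      } else w <- rep(1 / k, k)
    } else if (!is.na(family_bias_p) && k >= 2L) {
      w <- rep((1 - family_bias_p) / (k - 1), k)
      w[1L] <- family_bias_p                  # fixed favoured codon
    } else {
      at3 <- substr(cods, 3L, 3L) %in% c("A", "T")
      off <- if (is.null(pref)) 0 else pref[cods]
      w <- exp(b * at3 + t * (!at3) + off)
      w <- w / sum(w)
    }
    setNames(w, cods)
  }) |> setNames(names(fam))
}

#' Generate a synthetic coding-sequence set with known ground truth
#'
#' Draws each gene's protein from the spec's amino-acid frequencies and its
#' codons from class-specific per-family weight vectors, appends a stop
#' codon, and tallies the realized draws.  Two expression classes
#' (high-bias / low-bias, mixed at `high_bias_fraction`) give the ENc
#' distribution its spread, so ENc-extreme libraries are meaningful.  All
#' four CDS filter rules hold by construction.
#'
#' @param spec a `synthetic_spec`.
#' @return list of class `synthetic_cds`: `cds` (data.frame `gene`,
#'   `sequence`, `length_bp`, `class` with "high"/"low" expression class),
#'   `tally` (genes x 64 realized codon-count matrix), `preferred_codons`,
#'   `spec`.
#' @export
generate_cds_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  fam <- syn_families(spec$code)
  aa_freq <- spec$aa_freq
  if (is.null(aa_freq))
    aa_freq <- setNames(rep(1 / length(fam), length(fam)), names(fam))
  aa_freq <- aa_freq[names(aa_freq) %in% names(fam)]
  aa_freq <- aa_freq / sum(aa_freq)
  designated <- spec$preferred_codons
  if (length(designated)) {
    gcode <- get_code(spec$code)
    names(designated) <- unname(gcode[designated])
  }
  # GC content of codon positions 1+2 per amino acid, for the GC12 coupling
  gc12_aa <- vapply(fam, function(cods)
    mean(c(substr(cods, 1, 1), substr(cods, 2, 2)) %in% c("G", "C")),
    numeric(1L))

  # shared codon-preference profile, one draw per generation (a common
  # tRNA pool): third-base asymmetries plus a one-sided boost for one
  # preferred codon per family (usually T-ending).  The boost concentrates
  # usage beyond what third-base composition alone predicts, which is what
  # places genes below the expected ENc curve.
  cods64 <- all_codons()
  pref <- spec$base3_pref[substr(cods64, 3L, 3L)]
  pref <- setNames(as.numeric(pref), cods64)
  if (spec$within_bias > 0) {
    # composition-neutral concentration: within the A/T-ending codons of a
    # family, boost one preferred codon (T-ending favoured) and penalize
    # the rest, so family GC3 is untouched but homozygosity rises
    for (aa in names(fam)) {
      cods <- fam[[aa]]
      at <- cods[substr(cods, 3L, 3L) %in% c("A", "T")]
      if (length(at) < 2L) next
      wsel <- ifelse(substr(at, 3L, 3L) == "T", 8, 1)
      chosen <- at[sample.int(length(at), 1L, prob = wsel)]
      pref[chosen] <- pref[chosen] + spec$within_bias
      rest <- setdiff(at, chosen)
      pref[rest] <- pref[rest] - spec$within_bias
    }
  }

  n <- spec$n_genes
  lens <- if (spec$gene_length_range[1L] == spec$gene_length_range[2L])
    rep(spec$gene_length_range[1L], n) else
    sample(spec$gene_length_range[1L]:spec$gene_length_range[2L], n, TRUE)
  cls <- ifelse(runif(n) < spec$high_bias_fraction, "high", "low")
  b <- ifelse(cls == "high",
              runif(n, spec$bias_range_high[1L], spec$bias_range_high[2L]),
              runif(n, spec$bias_range_low[1L], spec$bias_range_low[2L]))
  t <- if (spec$gc3_sd > 0) rnorm(n, 0, spec$gc3_sd) else rep(0, n)

  tally <- matrix(0L, n, 64L, dimnames = list(NULL, all_codons()))
  seqs <- character(n)
  stops <- stop_codons(spec$code)
  for (i in seq_len(n)) {
    w <- gene_family_weights(fam, b[i], t[i], spec$family_bias_p,
                             designated, active = cls[i] == "high",
                             p_hi = spec$designated_p_high, pref = pref)
    af <- aa_freq
    if (spec$gc12_coupling > 0) {
      af <- af * exp(spec$gc12_coupling * t[i] * gc12_aa[names(af)])
      af <- af / sum(af)
    }
    aa_seq <- sample(names(af), lens[i], TRUE, prob = af)
    codons <- character(lens[i])
    for (aa in unique(aa_seq)) {
      idx <- which(aa_seq == aa)
      cods <- fam[[aa]]
      codons[idx] <- if (length(cods) == 1L) cods else
        sample(cods, length(idx), TRUE, prob = w[[aa]])
    }
    codons <- c(codons, sample(stops, 1L))
    tab <- table(codons)
    tally[i, names(tab)] <- as.integer(tab)
    seqs[i] <- paste(codons, collapse = "")
  }
  genes <- sprintf("sg%02d", seq_len(n))
  rownames(tally) <- genes
  structure(list(
    cds = data.frame(gene = genes, sequence = seqs,
                     length_bp = nchar(seqs), class = cls,
                     stringsAsFactors = FALSE),
    tally = tally,
    preferred_codons = unname(spec$preferred_codons),
    spec = spec), class = "synthetic_cds")
}

# default hevea-like SSR implant profile: counts per unit length follow the
# observed plastome mix (mono-A/T dominated); motifs drawn per seed
default_ssr_implants <- function() {
  mk <- function(motifs, n, reps) {
    data.frame(motif = motifs[sample.int(length(motifs), n, TRUE)],
               repeats = reps[sample.int(length(reps), n, TRUE)],
               stringsAsFactors = FALSE)
  }
  rbind(
    mk(c("A", "T"), 80L, 10:15),
    mk(c("C", "G"), 8L, 10:12),
    mk(c("AT", "TA"), 17L, 6:8),
    mk(c("AAT", "ATT", "TTA", "TAA"), 5L, 5:6),
    mk(c("AAAT", "ATTT", "TTTA", "TAAA"), 11L, 5:5),
    mk(c("AATAT", "TTATA", "ATTTA"), 3L, 5:5),
    mk(c("AATATT", "TTATAA", "ATAATT"), 2L, 5:5))
}

#' Generate a complete synthetic plastome with truth sidecar
#'
#' Assembles a circular genome as LSC + IRb + SSC + IRa with IRa the exact
#' reverse complement of IRb, places the genes from [generate_cds_set()] on
#' both strands with correct CDS features (one gene is written as a two-exon
#' join to exercise segmented locations), implants the spec's SSRs into
#' intergenic spacers at recorded coordinates, and tunes the intergenic base
#' composition so the realized genome GC meets the spec target.  IR genes
#' are duplicated into IRa with mirrored coordinates and flipped strand.
#'
#' @param spec a `synthetic_spec` whose `arch` is non-NULL.
#' @return list of class `synthetic_genome`: `record` (a `cp_genome`),
#'   `truth` (intervals, junctions, realized SSR implants, gene table with
#'   class and region, preferred codons), `cds` (the generated CDS set).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$arch)) stop("spec has no genome architecture")
  gen <- generate_cds_set(spec)
  set.seed(spec$seed + 1L)         # placement stream, independent of draws

  implants <- spec$ssr_implants
  if (is.null(implants)) implants <- default_ssr_implants()

  arch <- spec$arch
  n <- spec$n_genes
  n_ir <- min(spec$n_ir_genes, n)
  n_ssc <- min(spec$n_ssc_genes, n - n_ir)
  region_of <- c(rep("IR", n_ir), rep("SSC", n_ssc),
                 rep("LSC", n - n_ir - n_ssc))
  # smallest genes into the IR so the IR budget is safe
  ord <- order(gen$cds$length_bp)
  gene_region <- character(n)
  gene_region[ord] <- region_of
  strand <- sample(c("+", "-"), n, TRUE, prob = c(0.6, 0.4))

  # allocate implants to regions proportionally to spacer budget (all in LSC
  # and SSC; IRs stay implant-free so the two IR copies remain exact mirrors)
  imp_region <- sample(c("LSC", "SSC"), nrow(implants), TRUE,
                       prob = c(0.85, 0.15))

  coding_bp <- sum(gen$cds$length_bp) + sum(gen$cds$length_bp[gene_region == "IR"])
  imp_bp <- sum(nchar(implants$motif) * implants$repeats + 2L)
  total_bp <- arch[["lsc"]] + 2L * arch[["ir"]] + arch[["ssc"]]
  spacer_bp <- total_bp - coding_bp - imp_bp
  if (spacer_bp < 50L * n) stop("architecture too small for the gene set")
  coding_gc <- sum(vapply(gen$cds$sequence, function(s)
    sum(strsplit(s, "")[[1L]] %in% c("G", "C")), numeric(1L))) +
    sum(vapply(gen$cds$sequence[gene_region == "IR"], function(s)
      sum(strsplit(s, "")[[1L]] %in% c("G", "C")), numeric(1L)))
  gc_sp <- (spec$gc_target * total_bp - coding_gc -
              sum(vapply(strsplit(implants$motif, ""), function(b)
                sum(b %in% c("G", "C")), numeric(1L)) * implants$repeats)) /
    spacer_bp
  gc_sp <- min(max(gc_sp, 0.02), 0.98)
  bg <- function(len) if (len <= 0L) "" else
    paste(sample(DNA_BASES, len, TRUE,
                 prob = c((1 - gc_sp) / 2, gc_sp / 2,
                          gc_sp / 2, (1 - gc_sp) / 2)), collapse = "")

  # guard an implant so flanks cannot extend the repeat run
  guarded_implant <- function(motif, reps) {
    run <- strrep(motif, reps)
    first <- substr(motif, 1L, 1L); last <- substr(motif, nchar(motif), nchar(motif))
    gl <- setdiff(c("C", "G", "A", "T"), c(last, first))[1L]
    gr <- setdiff(c("C", "G", "A", "T"), c(first, last))[1L]
    list(seq = paste0(gl, run, gr), offset = 1L, len = nchar(run))
  }

  build_region <- function(idx, target_len, implant_rows, two_exon_idx = NA) {
    pieces <- character(0)
    feats <- list()
    ssr_truth <- list()
    items <- list()
    for (i in idx) items[[length(items) + 1L]] <- list(type = "gene", i = i)
    for (r in implant_rows) items[[length(items) + 1L]] <- list(type = "ssr", r = r)
    if (length(items) > 1L) items <- items[sample(length(items))]
    item_bp <- vapply(items, function(it)
      if (it$type == "gene") {
        extra <- if (!is.na(two_exon_idx) && it$i == two_exon_idx) 100L else 0L
        gen$cds$length_bp[it$i] + extra
      } else nchar(implants$motif[it$r]) * implants$repeats[it$r] + 2L,
      numeric(1L))
    free <- target_len - sum(item_bp)
    if (free < 10L * (length(items) + 1L))
      stop("region too small for its genes/implants")
    cuts <- sort(sample(seq_len(free - 1L), length(items)))
    gaps <- diff(c(0L, cuts, free))
    pos <- 0L
    add <- function(s) { pieces[[length(pieces) + 1L]] <<- s
                         pos <<- pos + nchar(s) }
    for (k in seq_along(items)) {
      add(bg(gaps[k]))
      it <- items[[k]]
      if (it$type == "gene") {
        i <- it$i
        s <- gen$cds$sequence[i]
        if (!is.na(two_exon_idx) && i == two_exon_idx) {
          cut <- 3L * (nchar(s) %/% 6L)
          ex1 <- substr(s, 1L, cut); ex2 <- substr(s, cut + 1L, nchar(s))
          st1 <- pos + 1L
          add(ex1); add(bg(100L)); st2 <- pos + 1L; add(ex2)
          segs <- cbind(start = c(st1, st2),
                        end = c(st1 + nchar(ex1) - 1L,
                                st2 + nchar(ex2) - 1L))
          feats[[length(feats) + 1L]] <- list(i = i, segs = segs, strand = "+")
        } else {
          ins <- if (strand[i] == "-") revcomp(s) else s
          st <- pos + 1L
          add(ins)
          segs <- cbind(start = st, end = st + nchar(ins) - 1L)
          feats[[length(feats) + 1L]] <- list(i = i, segs = segs,
                                              strand = strand[i])
        }
      } else {
        r <- it$r
        gi <- guarded_implant(implants$motif[r], implants$repeats[r])
        st <- pos + 1L + gi$offset
        add(gi$seq)
        ssr_truth[[length(ssr_truth) + 1L]] <-
          data.frame(motif = implants$motif[r],
                     repeats = implants$repeats[r],
                     start = st, end = st + gi$len - 1L,
                     stringsAsFactors = FALSE)
      }
    }
    add(bg(gaps[length(gaps)]))
    list(seq = paste(pieces, collapse = ""), feats = feats,
         ssrs = if (length(ssr_truth)) do.call(rbind, ssr_truth) else NULL)
  }

  lsc_idx <- which(gene_region == "LSC")
  two_exon <- if (length(lsc_idx)) lsc_idx[which.max(gen$cds$length_bp[lsc_idx])] else NA
  lsc <- build_region(lsc_idx, arch[["lsc"]], which(imp_region == "LSC"),
                      two_exon_idx = two_exon)
  irb <- build_region(which(gene_region == "IR"), arch[["ir"]], integer(0))
  ssc <- build_region(which(gene_region == "SSC"), arch[["ssc"]],
                      which(imp_region == "SSC"))
  ira_seq <- revcomp(irb$seq)

  offs <- c(lsc = 0L, irb = arch[["lsc"]],
            ssc = arch[["lsc"]] + arch[["ir"]],
            ira = arch[["lsc"]] + arch[["ir"]] + arch[["ssc"]])
  genome <- paste0(lsc$seq, irb$seq, ssc$seq, ira_seq)
  # guard the single-copy flanks so the IR pair cannot extend by a chance
  # complementary base across a region boundary (regions start/end in
  # intergenic background, so these single-base edits are safe)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_tot <- nchar(genome)
  fix_pair <- function(g, p_ext, p_mate) {
    b_ext <- substr(g, p_ext, p_ext)
    if (b_ext == comp[[substr(g, p_mate, p_mate)]]) {
      repl <- setdiff(DNA_BASES, c(b_ext, comp[[substr(g, p_mate, p_mate)]]))[1L]
      substr(g, p_ext, p_ext) <- repl
    }
    g
  }
  # IRb left flank (last LSC base) pairs with first genome base (circular)
  genome <- fix_pair(genome, offs[["irb"]], 1L)
  # IRb right flank (first SSC base) pairs with the last SSC base
  genome <- fix_pair(genome, offs[["ssc"]] + 1L, offs[["ira"]])

  shift_feats <- function(fl, off, region) lapply(fl, function(f) {
    f$segs <- f$segs + off; f$region <- region; f
  })
  feats <- c(shift_feats(lsc$feats, offs[["lsc"]], "LSC"),
             shift_feats(irb$feats, offs[["irb"]], "IRb"),
             shift_feats(ssc$feats, offs[["ssc"]], "SSC"))
  # IRa copies: mirror IRb-local coordinates
  ir_len <- arch[["ir"]]
  for (f in irb$feats) {
    local <- f$segs
    m_start <- ir_len - (local[, "end"]) + 1L
    m_end <- ir_len - (local[, "start"]) + 1L
    segs <- cbind(start = rev(m_start), end = rev(m_end)) + offs[["ira"]]
    feats[[length(feats) + 1L]] <-
      list(i = f$i, segs = segs,
           strand = if (f$strand == "+") "-" else "+", region = "IRa")
  }

  feature_df <- do.call(rbind, lapply(feats, function(f) {
    g <- gen$cds$gene[f$i]
    rbind(
      data.frame(kind = "gene", gene = g, strand = f$strand,
                 n_segments = nrow(f$segs), segments = I(list(f$segs)),
                 stringsAsFactors = FALSE),
      data.frame(kind = "CDS", gene = g, strand = f$strand,
                 n_segments = nrow(f$segs), segments = I(list(f$segs)),
                 stringsAsFactors = FALSE))
  }))

  acc <- sprintf("SYN%06d", spec$seed %% 1000000L)
  record <- structure(list(
    accession = acc,
    species = sprintf("Synthetica plastida (%s preset)", spec$preset),
    sequence = genome, length_bp = nchar(genome), circular = TRUE,
    features = feature_df), class = "cp_genome")

  ssr_truth <- rbind(
    if (!is.null(lsc$ssrs)) transform(lsc$ssrs, start = start + offs[["lsc"]],
                                      end = end + offs[["lsc"]]),
    if (!is.null(ssc$ssrs)) transform(ssc$ssrs, start = start + offs[["ssc"]],
                                      end = end + offs[["ssc"]]))
  gene_truth <- data.frame(
    gene = gen$cds$gene,
    class = gen$cds$class, region = gene_region, strand = strand,
    length_bp = gen$cds$length_bp, stringsAsFactors = FALSE)

  truth <- list(
    accession = acc, seed = spec$seed, preset = spec$preset,
    intervals = list(lsc = c(1L, arch[["lsc"]]),
                     irb = c(offs[["irb"]] + 1L, offs[["irb"]] + ir_len),
                     ssc = c(offs[["ssc"]] + 1L, offs[["ssc"]] + arch[["ssc"]]),
                     ira = c(offs[["ira"]] + 1L, offs[["ira"]] + ir_len)),
    junctions = c(JLB = offs[["irb"]] + 1L, JSB = offs[["ssc"]] + 1L,
                  JSA = offs[["ira"]] + 1L, JLA = 1L),
    ssr_implants = ssr_truth,
    genes = gene_truth,
    preferred_codons = unname(spec$preferred_codons),
    gc_target = spec$gc_target)
  structure(list(record = record, truth = truth, cds = gen),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", x$record$accession, "-",
      format(x$record$length_bp, big.mark = ","), "bp,",
      nrow(x$truth$genes), "genes,",
      if (is.null(x$truth$ssr_implants)) 0L else nrow(x$truth$ssr_implants),
      "implanted SSRs\n")
  invisible(x)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS, ACCESSION, ORGANISM, a FEATURES table with gene/CDS/tRNA/
#' rRNA entries (join/complement locations as needed) and the ORIGIN
#' sequence block, readable by [read_genbank()].
#'
#' @param record a `cp_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  # fixed date token keeps output byte-identical for a given record
  w(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2026",
            record$accession, record$length_bp,
            if (isTRUE(record$circular)) "circular" else "linear"))
  w("DEFINITION  ", record$species %||% "synthetic plastome", ", complete genome.")
  w("ACCESSION   ", record$accession)
  w("SOURCE      ", record$species %||% "synthetic")
  w("  ORGANISM  ", record$species %||% "synthetic")
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", record$length_bp))
  loc_string <- function(segs, strand) {
    parts <- sprintf("%d..%d", segs[, "start"], segs[, "end"])
    loc <- if (length(parts) > 1L)
      sprintf("join(%s)", paste(parts, collapse = ",")) else parts
    if (strand == "-") sprintf("complement(%s)", loc) else loc
  }
  f <- record$features
  for (i in seq_len(nrow(f))) {
    w(sprintf("     %-16s%s", f$kind[i],
              loc_string(f$segments[[i]], f$strand[i])))
    if (!is.na(f$gene[i])) w(sprintf("                     /gene=\"%s\"", f$gene[i]))
  }
  w("ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1L, nchar(s), 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w(sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' Write a synthetic genome and its truth sidecar to disk
#'
#' @param sim a `synthetic_genome` from [generate_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written (`genbank`, `fasta`,
#'   `truth`), invisibly.
#' @export
write_genome_files <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- sim$record$accession
  gb <- file.path(dir, paste0(acc, ".gb"))
  fa <- file.path(dir, paste0(acc, ".fasta"))
  tj <- file.path(dir, paste0(acc, ".truth.json"))
  write_genbank(sim$record, gb)
  write_fasta(setNames(sim$record$sequence, acc), fa)
  jsonlite::write_json(sim$truth, tj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(genbank = gb, fasta = fa, truth = tj))
}

#' Simulate per-gene GC profiles with a known neutrality relation
#'
#' Draws GC3 uniformly in `gc3_range` and sets
#' `GC12 = intercept + slope * GC3 + noise`, with truncated-normal noise so
#' fractions stay in [0, 1].  Used for parameter-recovery checks of
#' [neutrality_fit()].
#'
#' @param n number of genes (default 90).
#' @param slope,intercept the true relation (defaults 0.22, 0.40).
#' @param noise_sd noise standard deviation (default 0.02).
#' @param gc3_range range of GC3 values (default c(0.15, 0.45)).
#' @param seed integer seed.
#' @return data.frame `gene, gc12, gc3`.
#' @export
simulate_gc_profiles <- function(n = 90L, slope = 0.22, intercept = 0.40,
                                 noise_sd = 0.02,
                                 gc3_range = c(0.15, 0.45), seed = 1L) {
  set.seed(seed)
  gc3 <- runif(n, gc3_range[1L], gc3_range[2L])
  gc12 <- intercept + slope * gc3 + rnorm(n, 0, noise_sd)
  while (any(bad <- gc12 < 0 | gc12 > 1))     # truncated-normal noise
    gc12[bad] <- intercept + slope * gc3[bad] + rnorm(sum(bad), 0, noise_sd)
  data.frame(gene = sprintf("sim%02d", seq_len(n)), gc12 = gc12, gc3 = gc3,
             stringsAsFactors = FALSE)
}
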