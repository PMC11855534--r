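# Independent oracles, deliberately written with different algorithms than
# the package implementations they check.

# exhaustive maximal-perfect-tandem-repeat scan, O(n * 6)
oracle_ssr_scan <- function(seq, thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                                `4` = 5L, `5` = 5L, `6` = 5L)) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  hits <- list()
  for (k in as.integer(names(thresholds))) {
    i <- 1L
    while (i + k <= n) {
      # count repeats of the unit starting at i
      r <- 1L
      while (i + (r + 1L) * k - 1L <= n &&
             all(b[i:(i + k - 1L)] == b[(i + r * k):(i + (r + 1L) * k - 1L)]))
        r <- r + 1L
      if (r >= thresholds[[as.character(k)]]) {
        motif <- paste(b[i:(i + k - 1L)], collapse = "")
        # primitive motif only
        prim <- TRUE
        for (d in seq_len(k - 1L))
          if (k %% d == 0L &&
              motif == strrep(substr(motif, 1L, d), k / d)) prim <- FALSE
        # leftmost: not preceded by another full unit
        left_ext <- i - k >= 1L &&
          all(b[(i - k):(i - 1L)] == b[i:(i + k - 1L)])
        if (prim && !left_ext)
          hits[[length(hits) + 1L]] <-
            data.frame(motif = motif, unit_len = k, repeats = r,
                       start = i, end = i + r * k - 1L)
        i <- i + r * k
      } else i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(0), unit_len = integer(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0)))
  out <- do.call(rbind, hits)
  # containment dedupe, as the detector defines non-nesting
  o <- order(out$start, -out$end)
  out <- out[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(out)); max_end <- -1L
  for (i in seq_len(nrow(out))) {
    if (out$end[i] <= max_end) keep[i] <- FALSE else max_end <- out$end[i]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive all-diagonal maximal bounded-mismatch repeat scan (quadratic)
oracle_long_repeats <- function(seq, min_len = 30L, B = 3L) {
  si <- utf8ToInt(seq)
  rci <- utf8ToInt(cpcodon::revcomp(seq))
  n <- length(si)
  scan_vs <- function(yi, self) {
    rows <- list()
    dr <- if (self) 1L:(n - min_len) else (-(n - min_len)):(n - min_len)
    for (d in dr) {
      lo <- max(1L, 1L + d); hi <- min(n, n + d)
      L <- hi - lo + 1L
      if (L < min_len) next
      mm <- which(si[lo:hi] != yi[(lo:hi) - d])
      bounds <- c(0L, mm, L + 1L)
      nb <- length(bounds)
      if (nb <= B + 1L) {
        if (L >= min_len)
          rows[[length(rows) + 1L]] <-
            data.frame(d = d, i0 = lo, len = L, mm = length(mm))
      } else {
        for (t in seq_len(nb - B - 1L)) {
          a <- bounds[t] + 1L; bnd <- bounds[t + B + 1L] - 1L
          len <- bnd - a + 1L
          if (len >= min_len)
            rows[[length(rows) + 1L]] <-
              data.frame(d = d, i0 = lo + a - 1L, len = len,
                         mm = sum(mm > bounds[t] & mm < bounds[t + B + 1L]))
        }
      }
    }
    if (!length(rows))
      return(data.frame(d = integer(0), i0 = integer(0),
                        len = integer(0), mm = integer(0)))
    do.call(rbind, rows)
  }
  fw <- scan_vs(si, TRUE)
  pal <- scan_vs(rci, FALSE)
  rows <- list()
  if (nrow(fw))
    rows[[1L]] <- data.frame(kind = "forward", length = fw$len,
                             pos1 = pmin(fw$i0, fw$i0 - fw$d),
                             pos2 = pmax(fw$i0, fw$i0 - fw$d),
                             mismatches = fw$mm)
  if (nrow(pal)) {
    q2 <- n - ((pal$i0 - pal$d) + pal$len - 1L) + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "palindromic", length = pal$len,
                 pos1 = pmin(pal$i0, q2), pos2 = pmax(pal$i0, q2),
                 mismatches = pal$mm)
  }
  if (!length(rows))
    return(data.frame(kind = character(0), length = integer(0),
                      pos1 = integer(0), pos2 = integer(0),
                      mismatches = integer(0)))
  out <- unique(do.call(rbind, rows))
  out[order(out$kind, out$pos1, out$pos2), , drop = FALSE]
}

# direct Wright-formula evaluation on a codon count table (plain loops)
oracle_enc <- function(counts, code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  aa_by_codon <- gc[gc != "*"]
  fams <- split(names(aa_by_codon), aa_by_codon)
  fams <- fams[vapply(fams, length, 0L) >= 2L]
  fvals <- c(); degs <- c()
  for (f in fams) {
    x <- as.numeric(counts[f]); nn <- sum(x)
    if (nn < 2) next
    F <- (nn * sum((x / nn)^2) - 1) / (nn - 1)
    if (F <= 0) next
    fvals <- c(fvals, F); degs <- c(degs, length(f))
  }
  sizes <- table(vapply(fams, length, 0L))
  enc <- 2
  for (cl in as.integer(names(sizes))) {
    sel <- degs == cl
    fb <- if (any(sel)) mean(fvals[sel]) else NA_real_
    if (is.na(fb) && cl == 3L) {
      f2 <- mean(fvals[degs == 2L]); f4 <- mean(fvals[degs == 4L])
      fb <- (f2 + f4) / 2
    }
    if (is.na(fb)) return(NA_real_)
    enc <- enc + as.numeric(sizes[[as.character(cl)]]) / fb
  }
  min(max(enc, 20), 61)
}

# random codon count table over a plausible usage profile
random_counts <- function(seed, total = 300L) {
  set.seed(seed)
  cods <- cpcodon:::all_codons()
  gc <- Biostrings::getGeneticCode("11")
  sense <- cods[gc[cods] != "*"]
  w <- rexp(length(sense))
  draw <- sample(sense, total, TRUE, prob = w / sum(w))
  counts <- setNames(integer(64L), cods)
  tb <- table(draw)
  counts[names(tb)] <- as.integer(tb)
  structure(counts, total = sum(counts), class = "codon_counts")
}

# random background sequence with a given GC fraction
random_dna <- function(n, gc = 0.36) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
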