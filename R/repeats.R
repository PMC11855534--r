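#' Find perfect microsatellites (SSRs)
#'
#' MISA-style scan for maximal perfect tandem repeats of 1-6 nt motifs.
#' A run is reported when its repeat count reaches the per-unit-length
#' threshold; motifs that are themselves repeats of a shorter unit are
#' attributed to the shorter unit only, and a run fully contained inside a
#' longer reported run is dropped, so nothing is double-reported.
#'
#' @param seq DNA string (upper case A/C/G/T).
#' @param thresholds named integer vector, minimum repeat count per unit
#'   length 1..6.  Defaults follow MISA-web: 1:10, 2:6, 3:5, 4:5, 5:5, 6:5.
#' @param circular scan across the origin by appending a short window of the
#'   sequence start (default FALSE); coordinates of wrapping hits keep
#'   `end > nchar(seq)`.
#' @return data.frame with columns `motif` (as found), `family` (canonical
#'   motif: lexicographic minimum over rotations and the reverse complement),
#'   `unit_len`, `repeats`, `start`, `end`.
#' @export
#' @examples
#' find_ssrs(paste0("GG", strrep("AT", 6), "GG"))
find_ssrs <- function(seq,
                      thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                     `4` = 5L, `5` = 5L, `6` = 5L),
                      circular = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  scan_seq <- seq
  if (circular && n > 0L) {
    win <- min(n, 6L * max(thresholds) * 2L)
    scan_seq <- paste0(seq, substr(seq, 1L, win))
  }
  hits <- list()
  for (k in as.integer(names(thresholds))) {
    minrep <- thresholds[[as.character(k)]]
    if (minrep < 2L) minrep <- 2L
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minrep - 1L)
    m <- gregexpr(pat, scan_seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (h in seq_along(m)) {
      start <- m[h]
      reps <- len[h] %/% k
      motif <- substr(scan_seq, start, start + k - 1L)
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <-
        data.frame(motif = motif, family = canonical_motif(motif),
                   unit_len = k, repeats = reps,
                   start = start, end = start + reps * k - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(0), family = character(0),
                      unit_len = integer(0), repeats = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  if (circular) {
    out <- out[out$start <= n, , drop = FALSE]           # wrap duplicates
    out <- out[!(out$start == 1L & out$end > n), , drop = FALSE]
  }
  # drop runs fully contained in another reported run
  o <- order(out$start, -out$end)
  out <- out[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  max_end <- -1L
  for (i in seq_len(nrow(out))) {
    if (out$end[i] <= max_end) keep[i] <- FALSE
    else max_end <- out$end[i]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# motif is primitive if it is not a whole-number power of a shorter unit
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (motif == strrep(substr(motif, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

# canonical family: lexicographic minimum over cyclic rotations of the motif
# and of its reverse complement
canonical_motif <- function(motif) {
  k <- nchar(motif)
  rots <- function(m) vapply(seq_len(k), function(i)
    paste0(substr(m, i, k), substr(m, 1L, i - 1L)), character(1L))
  min(c(rots(motif), rots(revcomp(motif))))
}

#' Find dispersed long repeats (forward and palindromic)
#'
#' REPuter-style detection of maximal repeat pairs of at least `min_len` bp
#' under a Hamming-distance budget of `max_mismatch`.  Forward repeats pair a
#' segment with a second direct copy elsewhere; palindromic repeats pair it
#' with a reverse-complement copy.  Candidate diagonals are anchored with
#' exact seeds of length `floor(min_len / (max_mismatch + 1))` (pigeonhole:
#' every qualifying repeat contains such a seed) and extended to maximal
#' bounded-mismatch windows.  The score reported is matches minus mismatches.
#'
#' @param seq DNA string.
#' @param min_len minimum repeat length, bp (default 30).
#' @param max_mismatch maximum Hamming mismatches (default 3).
#' @return data.frame `kind` ("forward"/"palindromic"), `length`, `pos1`,
#'   `pos2` (1-based starts; `pos1 <= pos2`), `mismatches`, `score`.
#' @export
find_long_repeats <- function(seq, min_len = 30L, max_mismatch = 3L) {
  n <- nchar(seq)
  empty <- data.frame(kind = character(0), length = integer(0),
                      pos1 = integer(0), pos2 = integer(0),
                      mismatches = integer(0), score = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 2L * min_len) return(empty)
  s <- max(4L, min_len %/% (max_mismatch + 1L))
  si <- utf8ToInt(seq)
  rc <- revcomp(seq)
  ri <- utf8ToInt(rc)

  fw <- repeat_windows(si, si, seed_anchors(seq, seq, s, self = TRUE),
                       min_len, max_mismatch)
  pal <- repeat_windows(si, ri, seed_anchors(seq, rc, s, self = FALSE),
                        min_len, max_mismatch)
  rows <- list()
  if (nrow(fw)) {
    # window starting at i0 on diagonal d: copies at i0 and i0 - d
    p1 <- pmin(fw$i0, fw$i0 - fw$d)
    p2 <- pmax(fw$i0, fw$i0 - fw$d)
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "forward", length = fw$len,
                 pos1 = p1, pos2 = p2, mismatches = fw$mm,
                 stringsAsFactors = FALSE)
  }
  if (nrow(pal)) {
    # rc position j maps to sequence position n - j + 1 (complemented)
    q1 <- pal$i0
    j1 <- pal$i0 - pal$d                       # rc start of the mate
    q2 <- n - (j1 + pal$len - 1L) + 1L         # seq start of the mate
    p1 <- pmin(q1, q2); p2 <- pmax(q1, q2)
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "palindromic", length = pal$len,
                 pos1 = p1, pos2 = p2, mismatches = pal$mm,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))           # symmetric duplicates
  out$score <- out$length - 2L * out$mismatches
  out <- out[order(out$kind, out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact seed matches between x and y as (i, d) anchors with d = i - j.
# Anchors sharing a diagonal within s bp lie in one contiguous matched run
# and are collapsed to the run start.  Self comparison keeps d > 0 only.
seed_anchors <- function(x, y, s, self) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx < s || ny < s)
    return(data.frame(i = integer(0), d = integer(0)))
  kx <- substring(x, seq_len(nx - s + 1L), seq_len(nx - s + 1L) + s - 1L)
  ky <- if (self) kx else
    substring(y, seq_len(ny - s + 1L), seq_len(ny - s + 1L) + s - 1L)
  fx <- split(seq_along(kx), kx)
  fy <- if (self) fx else split(seq_along(ky), ky)
  common <- intersect(names(fx), names(fy))
  ii <- dd <- list()
  for (key in common) {
    a <- fx[[key]]; b <- fy[[key]]
    g <- expand.grid(i = a, j = b)
    ii[[key]] <- g$i
    dd[[key]] <- g$i - g$j
  }
  if (!length(ii)) return(data.frame(i = integer(0), d = integer(0)))
  an <- data.frame(i = unlist(ii, use.names = FALSE),
                   d = unlist(dd, use.names = FALSE))
  if (self) an <- an[an$d > 0L, , drop = FALSE]
  if (!nrow(an)) return(an)
  an <- an[order(an$d, an$i), , drop = FALSE]
  keep <- c(TRUE, diff(an$i) > s | diff(an$d) != 0L)
  an[keep, , drop = FALSE]
}

# Maximal windows with <= B mismatches and length >= min_len in the
# comparison x[i] vs y[i - d], grown locally around each exact seed anchor.
# For an anchor, the (B+1) nearest mismatch positions on each side bound all
# maximal windows containing the seed; anchors falling inside an already
# explored zero-mismatch run on the same diagonal are skipped.
repeat_windows <- function(xi, yi, anchors, min_len, B, seed_len = 4L) {
  n <- length(xi)
  res_d <- res_i0 <- res_len <- res_mm <- integer(0)
  last_d <- NA_integer_; gap_lo <- 0L; gap_hi <- -1L
  for (r in seq_len(nrow(anchors))) {
    d <- anchors$d[r]; a0 <- anchors$i[r]
    if (!is.na(last_d) && d == last_d && a0 >= gap_lo && a0 <= gap_hi) next
    lo <- max(1L, 1L + d)
    hi <- min(n, n + d)
    lmm <- scan_mismatch(xi, yi, d, from = a0 - 1L, lim = lo,
                         m = B + 1L, step = -1L)
    rmm <- scan_mismatch(xi, yi, d, from = a0 + 1L, lim = hi,
                         m = B + 1L, step = +1L)
    last_d <- d
    gap_lo <- if (length(lmm)) lmm[1L] + 1L else lo
    gap_hi <- if (length(rmm)) rmm[1L] - 1L else hi
    lpad <- c(lmm, rep(lo - 1L, B + 1L))[seq_len(B + 1L)]
    rpad <- c(rmm, rep(hi + 1L, B + 1L))[seq_len(B + 1L)]
    for (t in 0:B) {
      w0 <- lpad[t + 1L] + 1L
      w1 <- rpad[B - t + 1L] - 1L
      len <- w1 - w0 + 1L
      if (len < min_len) next
      res_d <- c(res_d, d); res_i0 <- c(res_i0, w0); res_len <- c(res_len, len)
      res_mm <- c(res_mm, min(t, length(lmm)) + min(B - t, length(rmm)))
    }
  }
  unique(data.frame(d = res_d, i0 = res_i0, len = res_len, mm = res_mm))
}

# positions of up to m mismatches of x[i] vs y[i - d], walking from `from`
# towards `lim` in chunks; returned nearest-first
scan_mismatch <- function(xi, yi, d, from, lim, m, step, chunk = 256L) {
  out <- integer(0)
  p <- from
  while (length(out) < m && ((step > 0L && p <= lim) ||
                             (step < 0L && p >= lim))) {
    q <- if (step > 0L) min(lim, p + chunk - 1L) else max(lim, p - chunk + 1L)
    rng <- if (step > 0L) p:q else q:p
    hits <- rng[xi[rng] != yi[rng - d]]
    if (length(hits)) {
      if (step < 0L) hits <- rev(hits)
      out <- c(out, hits)
    }
    p <- q + step
  }
  out[seq_len(min(m, length(out)))]
}

#' Summarise SSR and long-repeat detections
#'
#' Tallies SSRs by unit length and by A/T-only versus G/C-containing motif
#' family, and long repeats by kind and 10-bp length bin (30-39, 40-49, ...).
#'
#' @param ssrs data.frame from [find_ssrs()].
#' @param long_repeats data.frame from [find_long_repeats()] (optional).
#' @param exclude_ir optional `quadripartite` structure; the palindromic hit
#'   corresponding to the full IR pair is excluded from the tallies.
#' @return list of class `repeat_summary`: `ssr_by_unit` (counts and
#'   percentages for unit lengths 1-6), `ssr_at` (A/T-motif count and share),
#'   `n_ssr`, `long_by_kind`, `long_by_bin`, `n_long`.
#' @export
summarize_repeats <- function(ssrs, long_repeats = NULL, exclude_ir = NULL) {
  units <- factor(ssrs$unit_len, levels = 1:6)
  by_unit <- table(units)
  n_ssr <- nrow(ssrs)
  at_only <- if (n_ssr) !grepl("[GC]", ssrs$family) else logical(0)
  lr <- long_repeats
  if (!is.null(lr) && !is.null(exclude_ir) && exclude_ir$found && nrow(lr)) {
    irlen <- exclude_ir$ir_len
    drop <- lr$kind == "palindromic" & abs(lr$length - irlen) <= 2L
    lr <- lr[!drop, , drop = FALSE]
  }
  long_by_kind <- long_by_bin <- NULL
  n_long <- 0L
  if (!is.null(lr)) {
    n_long <- nrow(lr)
    long_by_kind <- table(factor(lr$kind, levels = c("forward", "palindromic")))
    bins <- if (n_long) paste0(10L * (lr$length %/% 10L), "-",
                               10L * (lr$length %/% 10L) + 9L) else character(0)
    long_by_bin <- table(bins)
  }
  structure(list(
    ssr_by_unit = data.frame(unit_len = 1:6,
                             count = as.integer(by_unit),
                             pct = if (n_ssr) 100 * as.integer(by_unit) / n_ssr
                                   else rep(0, 6L)),
    ssr_at = list(count = sum(at_only),
                  pct = if (n_ssr) 100 * sum(at_only) / n_ssr else 0),
    n_ssr = n_ssr,
    long_by_kind = long_by_kind, long_by_bin = long_by_bin,
    n_long = n_long), class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat("<repeat_summary>", x$n_ssr, "SSRs,", x$n_long, "long repeats\n")
  u <- x$ssr_by_unit
  cat("  SSR by unit length:",
      paste(sprintf("%d:%d (%.1f%%)", u$unit_len, u$count, u$pct),
            collapse = "  "), "\n")
  cat(sprintf("  A/T-only motifs: %d (%.1f%%)\n",
              x$ssr_at$count, x$ssr_at$pct))
  invisible(x)
}
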