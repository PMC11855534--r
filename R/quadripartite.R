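# --- circular-interval helpers (1-based inclusive; start > end means the
# interval wraps past the origin) -------------------------------------------

circ_len <- function(iv, n) {
  if (is.null(iv) || anyNA(iv)) return(0L)
  if (iv[2L] >= iv[1L]) iv[2L] - iv[1L] + 1L else n - iv[1L] + 1L + iv[2L]
}

circ_shift <- function(pos, off, n) ((pos - 1L + off) %% n) + 1L

#' Detect the quadripartite plastome structure
#'
#' Finds the longest pair of disjoint, reverse-complementary segments (the
#' inverted repeats IRa/IRb) by exact k-mer anchoring between the genome and
#' its reverse complement, followed by mismatch-tolerant extension.  The two
#' single-copy intervals between the IRs are labelled LSC (longer) and SSC
#' (shorter).  The sequence is treated as circular: detection is retried at
#' three rotations so IRs spanning the linearization point are still found,
#' and reported intervals may wrap (start > end).
#'
#' @param record a `cp_genome`, or a bare DNA string.
#' @param min_ir minimum IR length to accept, bp (default 1000).
#' @param k anchor k-mer length (default 25).
#' @param max_mismatch_rate mismatch fraction tolerated while extending IR
#'   ends (default 0.001, i.e. annotation-grade noise).
#' @return object of class `quadripartite`: list with intervals `lsc`,
#'   `irb`, `ssc`, `ira` (each `c(start, end)`), `junctions` (named vector
#'   JLB/JSB/JSA/JLA giving the first base of IRb, SSC, IRa and LSC), `ir_len`,
#'   `genome_len`, `found`.  When no IR of at least `min_ir` exists, the IR
#'   intervals are `NA` and `found` is `FALSE`.
#' @export
detect_quadripartite <- function(record, min_ir = 1000L, k = 25L,
                                 max_mismatch_rate = 0.001) {
  seq <- if (inherits(record, "cp_genome")) record$sequence else record
  n <- nchar(seq)
  empty <- structure(list(lsc = c(NA_integer_, NA_integer_),
                          irb = c(NA_integer_, NA_integer_),
                          ssc = c(NA_integer_, NA_integer_),
                          ira = c(NA_integer_, NA_integer_),
                          junctions = setNames(rep(NA_integer_, 4L),
                                               c("JLB", "JSB", "JSA", "JLA")),
                          ir_len = 0L, genome_len = n, found = FALSE),
                     class = "quadripartite")
  if (n < 2L * min_ir) return(empty)

  offsets <- unique(c(0L, floor(n / 3), floor(2 * n / 3)))
  best <- NULL
  for (off in offsets) {
    rot <- if (off == 0L) seq else
      paste0(substr(seq, off + 1L, n), substr(seq, 1L, off))
    hit <- find_ir_pair(rot, min_ir, k, max_mismatch_rate)
    if (!is.null(hit) && (is.null(best) || hit$len > best$len)) {
      hit$off <- off
      best <- hit
    }
  }
  if (is.null(best)) return(empty)

  # map rotated coordinates back to the input linearization
  mapiv <- function(iv) {
    s <- circ_shift(iv[1L], best$off, n)
    e <- circ_shift(iv[2L], best$off, n)
    c(s, e)
  }
  ir1 <- mapiv(best$a)
  ir2 <- mapiv(best$b)
  build_quadripartite(ir1, ir2, n)
}

build_quadripartite <- function(ir1, ir2, n) {
  # single-copy regions are the two circular gaps between the IR intervals
  gap_after <- function(x, y) {          # interval from end(x)+1 to start(y)-1
    s <- circ_shift(x[2L], 1L, n)
    e <- circ_shift(y[1L], -1L, n)
    c(s, e)
  }
  g1 <- gap_after(ir1, ir2)
  g2 <- gap_after(ir2, ir1)
  if (circ_len(g1, n) >= circ_len(g2, n)) {
    lsc <- g1; ssc <- g2; irb <- ir2; ira <- ir1
  } else {
    lsc <- g2; ssc <- g1; irb <- ir1; ira <- ir2
  }
  lsc <- as.integer(lsc); ssc <- as.integer(ssc)
  irb <- as.integer(irb); ira <- as.integer(ira)
  # order around the circle is LSC -> IRb -> SSC -> IRa
  junctions <- c(JLB = irb[1L], JSB = ssc[1L], JSA = ira[1L], JLA = lsc[1L])
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 junctions = junctions,
                 ir_len = circ_len(irb, n), genome_len = n, found = TRUE),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$found) {
    cat("<quadripartite> no inverted repeat found (genome",
        format(x$genome_len, big.mark = ","), "bp)\n")
    return(invisible(x))
  }
  fmt <- function(iv) sprintf("%s..%s (%s bp)",
                              format(iv[1L], big.mark = ","),
                              format(iv[2L], big.mark = ","),
                              format(circ_len(iv, x$genome_len),
                                     big.mark = ","))
  cat("<quadripartite> genome", format(x$genome_len, big.mark = ","), "bp\n")
  cat("  LSC:", fmt(x$lsc), "\n  IRb:", fmt(x$irb),
      "\n  SSC:", fmt(x$ssc), "\n  IRa:", fmt(x$ira), "\n")
  cat("  junctions:",
      paste(names(x$junctions), x$junctions, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Longest disjoint reverse-complementary pair in a linear string.
# Returns list(a=, b=, len=) in local coordinates, or NULL.
find_ir_pair <- function(seq, min_ir, k, rate) {
  n <- nchar(seq)
  if (n < 2L * k) return(NULL)
  starts <- seq_len(n - k + 1L)
  kf <- substring(seq, starts, starts + k - 1L)
  rc <- revcomp(seq)
  kr <- substring(rc, starts, starts + k - 1L)
  j <- match(kf, kr)
  i2 <- match(kr, kf)
  ok <- !is.na(j) & !is.na(i2[j]) & i2[j] == seq_along(kf)
  if (!any(ok)) return(NULL)
  i <- which(ok)
  jj <- j[ok]
  d <- i - jj
  si <- utf8ToInt(seq)
  ri <- utf8ToInt(rc)

  best <- NULL
  for (dd in names(sort(table(d), decreasing = TRUE))) {
    dv <- as.integer(dd)
    ii <- sort(i[d == dv])
    # split anchors into clusters when the gap between consecutive anchors
    # is large (distinct repeats on the same diagonal)
    cl <- cumsum(c(TRUE, diff(ii) > 5L * k))
    for (grp in split(ii, cl)) {
      i0 <- min(grp); i1 <- max(grp) + k - 1L
      ext <- extend_diagonal(si, ri, i0, i1, dv, rate)
      len <- ext[2L] - ext[1L] + 1L
      if (len < min_ir) next
      a <- c(ext[1L], ext[2L])
      b <- c(n - (ext[2L] - dv) + 1L, n - (ext[1L] - dv) + 1L)
      if (max(a[1L], b[1L]) <= min(a[2L], b[2L])) next  # overlapping copies
      if (is.null(best) || len > best$len) {
        pair <- if (a[1L] <= b[1L]) list(a = a, b = b) else list(a = b, b = a)
        best <- c(pair, list(len = len))
      }
    }
    # anchor-rich diagonals come first; once the best exceeds the anchor
    # support of remaining diagonals we can stop
    if (!is.null(best) && best$len >= min_ir &&
        sum(d == dv) < best$len / (2L * k)) break
  }
  best
}

# extend a matching run [i0, i1] on diagonal d (seq[i] vs rc[i - d]) both
# ways, tolerating a mismatch fraction `rate`; ends are trimmed to matches
extend_diagonal <- function(si, ri, i0, i1, d, rate) {
  n <- length(si)
  lo_lim <- max(1L, 1L + d)          # rc index i - d must be >= 1
  hi_lim <- min(n, n + d)            # rc index must be <= n
  budget <- function(len) max(0L, floor(rate * len))
  mism <- 0L
  probe_len <- 12L   # a mismatch is crossed only if a clean run follows
  run_after <- function(from, step) {
    idx <- from + step * (0:(probe_len - 1L))
    idx <- idx[idx >= lo_lim & idx <= hi_lim]
    length(idx) == probe_len && all(si[idx] == ri[idx - d])
  }
  # left
  while (i0 > lo_lim) {
    if (si[i0 - 1L] == ri[i0 - 1L - d]) { i0 <- i0 - 1L; next }
    if (mism + 1L > budget(i1 - i0 + 2L)) break
    if (!run_after(i0 - 2L, -1L)) break
    mism <- mism + 1L; i0 <- i0 - 1L
  }
  # right
  while (i1 < hi_lim) {
    if (si[i1 + 1L] == ri[i1 + 1L - d]) { i1 <- i1 + 1L; next }
    if (mism + 1L > budget(i1 - i0 + 2L)) break
    if (!run_after(i1 + 2L, +1L)) break
    mism <- mism + 1L; i1 <- i1 + 1L
  }
  # trim ends to exact matches
  while (i0 <= i1 && si[i0] != ri[i0 - d]) i0 <- i0 + 1L
  while (i1 >= i0 && si[i1] != ri[i1 - d]) i1 <- i1 - 1L
  c(i0, i1)
}

#' Genes at the four quadripartite junctions
#'
#' For each junction (JLB, JSB, JSA, JLA) reports the nearest feature on each
#' side, the gap to the junction and, for features straddling it, the overlap
#' (extension into the downstream region).
#'
#' @param structure a `quadripartite` from [detect_quadripartite()].
#' @param features the feature data.frame of a `cp_genome` (gene features are
#'   used if present, otherwise CDS/tRNA/rRNA).
#' @return data.frame with columns `region`, `junction`, `gene`, `side`,
#'   `distance_bp`, `overlap_bp`.
#' @export
junction_report <- function(structure, features) {
  stopifnot(inherits(structure, "quadripartite"))
  out <- data.frame(region = character(0), junction = integer(0),
                    gene = character(0), side = character(0),
                    distance_bp = integer(0), overlap_bp = integer(0),
                    stringsAsFactors = FALSE)
  if (!structure$found || is.null(features) || !nrow(features)) return(out)
  use <- features[features$kind == "gene", , drop = FALSE]
  if (!nrow(use))
    use <- features[features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (!nrow(use)) return(out)
  span <- t(vapply(use$segments, function(m)
    c(min(m[, "start"]), max(m[, "end"])), integer(2L)))
  genes <- use$gene
  genes[is.na(genes)] <- "(unnamed)"
  rows <- list()
  for (jn in names(structure$junctions)) {
    J <- structure$junctions[[jn]]       # first base of the downstream region
    gs <- span[, 1L]; ge <- span[, 2L]
    straddle <- which(gs <= J - 1L & ge >= J)
    for (s in straddle) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = jn, junction = J, gene = genes[s], side = "spanning",
        distance_bp = 0L, overlap_bp = ge[s] - J + 1L,
        stringsAsFactors = FALSE)
    }
    up <- which(ge <= J - 1L)
    if (length(up)) {
      b <- up[which.max(ge[up])]
      rows[[length(rows) + 1L]] <- data.frame(
        region = jn, junction = J, gene = genes[b], side = "upstream",
        distance_bp = (J - 1L) - ge[b], overlap_bp = 0L,
        stringsAsFactors = FALSE)
    }
    dn <- which(gs >= J)
    if (length(dn)) {
      b <- dn[which.min(gs[dn])]
      rows[[length(rows) + 1L]] <- data.frame(
        region = jn, junction = J, gene = genes[b], side = "downstream",
        distance_bp = gs[b] - J, overlap_bp = 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
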