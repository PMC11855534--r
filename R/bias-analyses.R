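#' ENc-plot points and deviations from the expected curve
#'
#' Combines per-gene GC3s with observed ENc and the expected ENc at that
#' GC3s; `deviation = expected - observed`, so genes lying below the standard
#' curve (selection-shaped usage) have positive deviation.
#'
#' @param profiles data.frame of per-gene GC profiles with columns `gene`
#'   and `gc3s` (see [gc_profile()]).
#' @param encs data.frame with columns `gene` and `enc`.
#' @return data.frame `gene, gc3s, enc, expected_enc, deviation`, with
#'   attribute `n_enc_gt_45` (count of genes with ENc > 45).  Genes with
#'   missing GC3s or ENc are excluded.
#' @export
enc_plot_points <- function(profiles, encs) {
  m <- merge(profiles[, c("gene", "gc3s")], encs[, c("gene", "enc")],
             by = "gene", sort = TRUE)
  m <- m[!is.na(m$gc3s) & !is.na(m$enc), , drop = FALSE]
  m$expected_enc <- enc_expected(m$gc3s)
  m$deviation <- m$expected_enc - m$enc
  attr(m, "n_enc_gt_45") <- sum(m$enc > 45)
  m
}

#' PR2-bias plot coordinates
#'
#' Parity-rule-2 coordinates per gene from third-codon-position base counts:
#' x = G3/(G3+C3) and y = A3/(A3+T3).  At (0.5, 0.5) the two strands are
#' used symmetrically.  By default only codons of four-fold degenerate
#' families enter (third-position changes there are always synonymous);
#' `scope = "all"` uses all synonymous codons instead.
#'
#' @param counts_by_gene named list of `codon_counts`, one per gene.
#' @param scope "fourfold" (default) or "all".
#' @param code genetic code id (default "11").
#' @return data.frame `gene, x, y, a3, t3, g3, c3, defined`, with attribute
#'   `quadrants`: counts of points per quadrant (x and y below/above 0.5).
#' @export
pr2_points <- function(counts_by_gene, scope = c("fourfold", "all"),
                       code = "11") {
  scope <- match.arg(scope)
  fam <- syn_families(code)
  use_fams <- if (scope == "fourfold") fam[lengths(fam) == 4L]
              else fam[lengths(fam) >= 2L]
  codons <- unlist(use_fams, use.names = FALSE)
  b3 <- substr(codons, 3L, 3L)
  rows <- lapply(names(counts_by_gene), function(g) {
    x <- as.numeric(counts_by_gene[[g]][codons])
    tot <- function(b) sum(x[b3 == b])
    a3 <- tot("A"); t3 <- tot("T"); g3 <- tot("G"); c3 <- tot("C")
    ok <- (g3 + c3) > 0 && (a3 + t3) > 0
    data.frame(gene = g,
               x = if (ok) g3 / (g3 + c3) else NA_real_,
               y = if (ok) a3 / (a3 + t3) else NA_real_,
               a3 = a3, t3 = t3, g3 = g3, c3 = c3, defined = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$defined
  attr(out, "quadrants") <- c(
    "x<0.5,y<0.5" = sum(ok & out$x < 0.5 & out$y < 0.5, na.rm = TRUE),
    "x<0.5,y>=0.5" = sum(ok & out$x < 0.5 & out$y >= 0.5, na.rm = TRUE),
    "x>=0.5,y<0.5" = sum(ok & out$x >= 0.5 & out$y < 0.5, na.rm = TRUE),
    "x>=0.5,y>=0.5" = sum(ok & out$x >= 0.5 & out$y >= 0.5, na.rm = TRUE))
  out
}

#' Neutrality plot regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3 with the Pearson
#' correlation and its two-sided p-value.  A slope near 1 indicates
#' mutation-driven codon usage (positions 1+2 drift with position 3); a
#' slope near 0 indicates selective constraint.  The slope times 100 is
#' conventionally read as the percentage contribution of mutational
#' pressure.
#'
#' @param profiles data.frame with columns `gene`, `gc12`, `gc3` (fractions).
#' @return object of class `neutrality_fit` with the fitted `lm`, `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n` and the `data` used.
#' @export
neutrality_fit <- function(profiles) {
  d <- profiles[!is.na(profiles$gc12) & !is.na(profiles$gc3), , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 genes with GC12 and GC3")
  if (sd(d$gc3) == 0)
    stop("GC3 has zero variance; neutrality regression undefined")
  fit <- lm(gc12 ~ gc3, data = d)
  ct <- cor.test(d$gc3, d$gc12)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = nrow(d), data = d),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Neutrality plot regression (GC12 ~ GC3), n =", x$n, "genes\n")
  cat(sprintf("  slope: %.4f  (mutational pressure ~ %.2f%%)\n",
              x$slope, 100 * x$slope))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  cat(sprintf("  Pearson r: %.4f  (p = %.3g)\n", x$pearson_r, x$p_value))
  invisible(x)
}

#' @export
#' @method coef neutrality_fit
coef.neutrality_fit <- function(object, ...) coef(object$fit)

#' @export
#' @method plot neutrality_fit
plot.neutrality_fit <- function(x, ...) {
  graphics::plot(x$data$gc3, x$data$gc12, xlab = "GC3", ylab = "GC12",
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.7), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(x$fit, col = "firebrick")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("slope = %.3f, r = %.3f",
                                    x$slope, x$pearson_r))
  invisible(x)
}

#' Correspondence analysis of an RSCU matrix
#'
#' Classical correspondence analysis: the genes x codons table is converted
#' to proportions P, centred by the outer product of its margins and
#' standardized, and the residual matrix is decomposed by SVD.  Axis
#' inertias are the squared singular values; an axis contribution is its
#' share of total inertia.  Codons for Met, Trp and the stop codons are
#' excluded before the analysis (59 sense codons remain under code 11), and
#' undefined RSCU values are treated as 0 so the table is complete.  Axis
#' signs are fixed by making the codon with the largest absolute loading
#' positive on each axis.
#'
#' @param rscu_mat numeric matrix, genes in rows, codons in columns (RSCU
#'   values, NAs allowed).
#' @param code genetic code id (default "11"), used to drop Met/Trp/stops.
#' @return object of class `rscu_coa`: `row_coords`, `col_coords`
#'   (principal coordinates), `inertia` (per axis), `contribution`
#'   (fractions summing to 1), `total_inertia`, `singular_values`.
#' @export
coa_rscu <- function(rscu_mat, code = "11") {
  stopifnot(is.matrix(rscu_mat))
  fam_n <- family_size_by_codon(code)
  keep <- colnames(rscu_mat)[fam_n[as_dna(colnames(rscu_mat))] >= 2L]
  m <- rscu_mat[, keep, drop = FALSE]
  m[is.na(m)] <- 0
  if (nrow(m) < 3L) stop("need at least 3 genes for correspondence analysis")
  tot <- sum(m)
  if (tot == 0) stop("all-zero RSCU matrix")
  P <- m / tot
  r <- rowSums(P)
  c_ <- colSums(P)
  ok_r <- r > 0; ok_c <- c_ > 0
  P <- P[ok_r, ok_c, drop = FALSE]
  r <- r[ok_r]; c_ <- c_[ok_c]
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c_)) %*% diag(1 / sqrt(c_))
  dimnames(S) <- dimnames(P)
  dec <- svd(S)
  k <- min(nrow(P), ncol(P)) - 1L
  sv <- dec$d[seq_len(k)]
  inertia <- sv^2
  total <- sum(dec$d^2)
  # sign convention: largest-|loading| codon positive per axis
  U <- dec$u[, seq_len(k), drop = FALSE]
  V <- dec$v[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {
    lead <- which.max(abs(V[, a]))
    if (V[lead, a] < 0) { V[, a] <- -V[, a]; U[, a] <- -U[, a] }
  }
  row_coords <- sweep(U, 1L, sqrt(r), "/") %*% diag(sv, k)
  col_coords <- sweep(V, 1L, sqrt(c_), "/") %*% diag(sv, k)
  dimnames(row_coords) <- list(rownames(P), paste0("axis", seq_len(k)))
  dimnames(col_coords) <- list(colnames(P), paste0("axis", seq_len(k)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = inertia,
                 contribution = if (total > 0) inertia / total
                                else rep(NA_real_, k),
                 total_inertia = total,
                 singular_values = sv),
            class = "rscu_coa")
}

#' @export
print.rscu_coa <- function(x, ...) {
  cat("Correspondence analysis of RSCU:",
      nrow(x$row_coords), "genes x", nrow(x$col_coords), "codons\n")
  cat(sprintf("  total inertia: %.5f\n", x$total_inertia))
  k <- min(4L, length(x$contribution))
  cat("  axis contributions:",
      paste(sprintf("axis%d %.2f%%", seq_len(k),
                    100 * x$contribution[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
#' @method plot rscu_coa
plot.rscu_coa <- function(x, axes = c(1L, 2L), classes = NULL, ...) {
  xy <- x$row_coords[, axes, drop = FALSE]
  col <- "steelblue"
  if (!is.null(classes)) {
    cls <- factor(classes[rownames(xy)])
    col <- grDevices::hcl.colors(nlevels(cls), "Dark 3")[as.integer(cls)]
  }
  graphics::plot(xy, pch = 19, col = grDevices::adjustcolor(col, 0.8),
                 xlab = sprintf("Axis %d (%.2f%%)", axes[1L],
                                100 * x$contribution[axes[1L]]),
                 ylab = sprintf("Axis %d (%.2f%%)", axes[2L],
                                100 * x$contribution[axes[2L]]), ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  if (!is.null(classes))
    graphics::legend("topright", legend = levels(cls), pch = 19,
                     col = grDevices::hcl.colors(nlevels(cls), "Dark 3"),
                     bty = "n", cex = 0.8)
  invisible(x)
}

#' Functional class of plastid genes from their names
#'
#' Assigns the five classes conventionally used when colouring
#' correspondence-analysis plots of plastome codon usage: photosystem and
#' photosynthesis genes (psa/psb/pet), ribosomal proteins (rps/rpl),
#' genetic-system genes (rpo/inf/mat), conserved open reading frames (ycf),
#' and other protein genes.
#'
#' @param genes character vector of gene names.
#' @return character vector of class labels.
#' @export
gene_class <- function(genes) {
  base <- tolower(sub("\\.\\d+$", "", genes))
  out <- rep("other protein", length(genes))
  out[grepl("^(psa|psb|pet)", base)] <- "photosystem"
  out[grepl("^(rps|rpl)", base)] <- "ribosomal protein"
  out[grepl("^(rpo|inf|mat)", base)] <- "genetic system"
  out[grepl("^ycf", base)] <- "conserved ORF"
  setNames(out, genes)
}

#' Pairwise Pearson correlations among codon-usage indices
#'
#' Correlates the standard per-gene indices (COA axes 1 and 2, ENc, CAI,
#' GC3, GC3s, amino-acid length, overall GC) pairwise, with two-sided
#' p-values from the exact t test of [cor.test()] and significance stars at
#' 0.05 and 0.01.  No multiple-testing correction is applied.
#'
#' @param metrics data.frame with one row per gene; all numeric columns are
#'   used.
#' @return object of class `index_correlations`: `r`, `p` (symmetric
#'   matrices) and `stars` (character matrix, "" / "*" / "**").
#' @export
correlate_indices <- function(metrics) {
  num <- metrics[, vapply(metrics, is.numeric, TRUE), drop = FALSE]
  vars <- colnames(num)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- num[[i]]; y <- num[[j]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3L && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      ct <- cor.test(x[ok], y[ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars),
            class = "index_correlations")
}

#' @export
print.index_correlations <- function(x, digits = 3L, ...) {
  cat("Pairwise Pearson correlations (", nrow(x$r), " indices )\n", sep = "")
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  cat("* p < 0.05, ** p < 0.01\n")
  invisible(x)
}
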