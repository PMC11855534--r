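test_that("ENc-plot deviations vanish when observed equals expected", {
  profiles <- data.frame(gene = c("a", "b"), gc3s = c(0.3, 0.5))
  encs <- data.frame(gene = c("a", "b"),
                     enc = enc_expected(c(0.3, 0.5)))
  pts <- enc_plot_points(profiles, encs)
  expect_equal(pts$deviation, c(0, 0))
  # missing gc3s drops the gene
  pts2 <- enc_plot_points(data.frame(gene = c("a", "b"),
                                     gc3s = c(0.3, NA)), encs)
  expect_equal(pts2$gene, "a")
})

test_that("uniform-usage genes scatter around the expected curve", {
  gen <- generate_cds_set(synthetic_spec("uniform", seed = 14, n_genes = 60L))
  profiles <- do.call(rbind, lapply(gen$cds$sequence, gc_profile))
  profiles <- cbind(gene = gen$cds$gene, profiles)
  encs <- data.frame(gene = gen$cds$gene,
                     enc = vapply(gen$cds$sequence, function(s)
                       enc_observed(count_codons(s))$enc, 0))
  pts <- enc_plot_points(profiles, encs)
  expect_lt(abs(mean(pts$deviation)), 1.5)
})

test_that("PR2 coordinates are third-position base ratios", {
  mk <- function(...) {
    counts <- setNames(integer(64L), cpcodon:::all_codons())
    v <- c(...)
    counts[names(v)] <- v
    structure(counts, class = "codon_counts")
  }
  # Gly family (GGN, four-fold): A3 == T3, G3 == C3 -> centre
  ctr <- pr2_points(list(g = mk(GGA = 2L, GGT = 2L, GGG = 3L, GGC = 3L)))
  expect_equal(c(ctr$x, ctr$y), c(0.5, 0.5))
  # G3 = 1, C3 = 3, A3 = 1, T3 = 3 -> (0.25, 0.25)
  toy <- pr2_points(list(g = mk(GGG = 1L, GGC = 3L, GGA = 1L, GGT = 3L)))
  expect_equal(c(toy$x, toy$y), c(0.25, 0.25))
  # no four-fold counts -> flagged undefined
  und <- pr2_points(list(g = mk(AAA = 5L)))
  expect_false(und$defined)
})

test_that("PR2 points are invariant to codon order within genes", {
  gen <- generate_cds_set(synthetic_spec("hevea-like", seed = 3, n_genes = 12L))
  counts <- lapply(gen$cds$sequence, count_codons)
  names(counts) <- gen$cds$gene
  p1 <- pr2_points(counts)
  set.seed(1)
  shuffled <- lapply(gen$cds$sequence, function(s) {
    cods <- cpcodon:::split_codons(s)
    paste(sample(cods), collapse = "")
  })
  counts2 <- lapply(shuffled, count_codons)
  names(counts2) <- gen$cds$gene
  p2 <- pr2_points(counts2)
  expect_equal(p1$x, p2$x)
  expect_equal(p1$y, p2$y)
})

test_that("neutrality regression recovers exact and noisy relations", {
  d <- data.frame(gene = letters[1:5],
                  gc3 = c(0.1, 0.2, 0.3, 0.4, 0.5))
  d$gc12 <- d$gc3
  nf <- neutrality_fit(d)
  expect_equal(nf$slope, 1)
  expect_equal(nf$pearson_r, 1)

  sim <- simulate_gc_profiles(n = 90L, slope = 0.22, intercept = 0.40,
                              noise_sd = 0.02, seed = 42L)
  nf2 <- neutrality_fit(sim)
  expect_lt(abs(nf2$slope - 0.22), 0.03)
  expect_gt(nf2$pearson_r, 0.5)

  # OLS identity: r^2 equals forward slope times reverse slope
  rev_slope <- unname(coef(lm(gc3 ~ gc12, data = sim))[2L])
  expect_equal(nf2$pearson_r^2, nf2$slope * rev_slope, tolerance = 1e-10)

  # order invariance
  nf3 <- neutrality_fit(sim[sample(nrow(sim)), ])
  expect_equal(nf3$slope, nf2$slope)

  expect_error(neutrality_fit(data.frame(gene = "x", gc12 = 1, gc3 = 1)),
               "at least 3")
  expect_error(neutrality_fit(data.frame(gene = letters[1:4],
                                         gc12 = c(.3, .4, .5, .6),
                                         gc3 = rep(.2, 4))), "variance")
})

test_that("correspondence analysis matches eigen and vegan oracles", {
  set.seed(9)
  m <- matrix(rpois(4 * 4, 8) + 1, 4, 4,
              dimnames = list(paste0("g", 1:4),
                              c("GGA", "GGT", "GGC", "GGG")))
  res <- coa_rscu(m)
  # oracle 1: dense eigendecomposition of the residual cross-product
  P <- m / sum(m); r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- sort(eigen(t(S) %*% S, symmetric = TRUE)$values, decreasing = TRUE)
  expect_lt(max(abs(res$inertia - ev[seq_along(res$inertia)])), 1e-9)
  # oracle 2: vegan correspondence analysis eigenvalues
  if (requireNamespace("vegan", quietly = TRUE)) {
    cca_ev <- unname(vegan::cca(m)$CA$eig)
    expect_equal(unname(res$inertia[seq_along(cca_ev)]), cca_ev,
                 tolerance = 1e-9)
  }
  # contributions are a partition of total inertia
  expect_equal(sum(res$contribution), 1, tolerance = 1e-9)
  # duality: row-side and column-side decompositions share the spectrum
  ev_row <- sort(eigen(S %*% t(S), symmetric = TRUE)$values,
                 decreasing = TRUE)
  expect_equal(ev_row[seq_along(res$inertia)],
               ev[seq_along(res$inertia)], tolerance = 1e-9)
})

test_that("identical rows give zero inertia and sign convention is fixed", {
  m <- matrix(rep(c(3, 1, 2, 2), each = 5), 5, 4,
              dimnames = list(paste0("g", 1:5),
                              c("GGA", "GGT", "GGC", "GGG")))
  res <- coa_rscu(m)
  expect_lt(res$total_inertia, 1e-12)
  # sign convention: leading codon loading positive on each axis
  gen <- generate_cds_set(synthetic_spec("hevea-like", seed = 4, n_genes = 20L))
  rmat <- t(vapply(gen$cds$sequence, function(s) {
    r <- rscu(count_codons(s)); setNames(r$rscu, r$codon)
  }, numeric(61L)))
  rownames(rmat) <- gen$cds$gene
  res2 <- coa_rscu(rmat)
  for (a in 1:2) {
    v <- res2$col_coords[, a]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("index correlations carry exact t-test p-values and stars", {
  set.seed(11)
  n <- 40L
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, 0, 0.4); z <- rnorm(n)
  cm <- correlate_indices(data.frame(x = x, y = y, z = z))
  expect_equal(diag(cm$r), c(x = 1, y = 1, z = 1))
  expect_equal(cm$r, t(cm$r))
  ct <- cor.test(x, y)
  expect_equal(cm$r["x", "y"], unname(ct$estimate))
  expect_equal(cm$p["x", "y"], ct$p.value)
  expect_equal(cm$stars["x", "y"], "**")
  # constant variable flagged undefined
  cm2 <- correlate_indices(data.frame(x = x, k = rep(1, n)))
  expect_true(is.na(cm2$r["x", "k"]))
})

test_that("GC3 and ENc correlate positively when bias drives both", {
  gen <- generate_cds_set(synthetic_spec("hevea-like", seed = 15))
  encs <- vapply(gen$cds$sequence, function(s)
    enc_observed(count_codons(s))$enc, 0)
  gc3 <- vapply(gen$cds$sequence, function(s) gc_profile(s)$gc3, 0)
  cm <- correlate_indices(data.frame(enc = encs, gc3 = gc3))
  expect_gt(cm$r["enc", "gc3"], 0)
})

test_that("gene functional classes follow plastid naming conventions", {
  cl <- gene_class(c("psbA", "rps12", "rpoB", "ycf2", "ndhF", "petD",
                     "rpl2.2", "matK", "ccsA"))
  expect_equal(unname(cl[c("psbA", "petD")]),
               rep("photosystem", 2))
  expect_equal(unname(cl[c("rps12", "rpl2.2")]),
               rep("ribosomal protein", 2))
  expect_equal(unname(cl[c("rpoB", "matK")]), rep("genetic system", 2))
  expect_equal(unname(cl["ycf2"]), "conserved ORF")
  expect_equal(unname(cl[c("ndhF", "ccsA")]), rep("other protein", 2))
})
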