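test_that("codon counting tallies frame-0 triplets", {
  cc <- count_codons("ATGTGGTAA")
  expect_equal(unname(cc[c("ATG", "TGG", "TAA")]), c(1L, 1L, 1L))
  expect_equal(attr(cc, "total"), 3L)
  cc2 <- count_codons("AAAAAAAAG")
  expect_equal(unname(cc2[c("AAA", "AAG")]), c(2L, 1L))
  expect_error(count_codons("ATGT"), "multiple of 3")
  # generator output matches its own emitted tally
  gen <- generate_cds_set(synthetic_spec("uniform", seed = 12, n_genes = 5L))
  for (i in seq_len(5L)) {
    cc <- count_codons(gen$cds$sequence[i])
    expect_equal(as.integer(cc), unname(gen$tally[i, names(cc)]))
  }
})

test_that("RSCU follows the synonymous-family formula", {
  # Lys observed AAA = 3, AAG = 1: RSCU = 2 * 3/4 and 2 * 1/4
  r <- rscu(count_codons(paste0(strrep("AAA", 3), "AAG")))
  expect_equal(r$rscu[r$codon == "AAA"], 1.5)
  expect_equal(r$rscu[r$codon == "AAG"], 0.5)
  # single-codon families are exactly 1 when observed
  r2 <- rscu(count_codons("ATGTGGATG"))
  expect_equal(r2$rscu[r2$codon == "ATG"], 1)
  expect_equal(r2$rscu[r2$codon == "TGG"], 1)
  # unobserved families are NA, not 0
  expect_true(is.na(r2$rscu[r2$codon == "AAA"]))
  # stop codons never appear
  expect_false(any(r$codon %in% c("TAA", "TAG", "TGA")))
})

test_that("RSCU normalization holds for every observed family (property)", {
  for (seed in 1:25) {
    r <- rscu(random_counts(seed))
    for (aa in unique(r$amino_acid)) {
      sel <- r$amino_acid == aa
      if (all(is.na(r$rscu[sel]))) next
      expect_equal(sum(r$rscu[sel]), r$family_size[sel][1L],
                   tolerance = 1e-9)
    }
    expect_true(all(r$rscu >= 0, na.rm = TRUE))
  }
})

test_that("GC profile computes positional fractions and GC3s scope", {
  p <- gc_profile("GGGGGG")
  expect_equal(unlist(p[c("gc1", "gc2", "gc3")]), c(gc1 = 1, gc2 = 1, gc3 = 1))
  expect_equal(p$gc3s, 1)
  # Met + Trp only: no synonymous third positions
  p2 <- gc_profile("ATGTGG")
  expect_true(is.na(p2$gc3s))
  expect_equal(p2$gc3, 1)       # third positions G, G
  expect_equal(p2$gc12, 0.25)
  # terminal stop excluded consistently
  p3 <- gc_profile("ATGTGGTAA")
  expect_equal(p3[, c("gc1", "gc2", "gc3")], p2[, c("gc1", "gc2", "gc3")])
})

test_that("GC profile matches a brute-force position tally", {
  set.seed(33)
  sense <- setdiff(cpcodon:::all_codons(), c("TAA", "TAG", "TGA"))
  for (rep in 1:10) {
    codons <- sample(sense, 60, TRUE)
    s <- paste(codons, collapse = "")
    b <- strsplit(s, "")[[1L]]
    pos <- rep(1:3, 60)
    want <- vapply(1:3, function(k) mean(b[pos == k] %in% c("G", "C")), 0)
    got <- gc_profile(s)
    expect_equal(c(got$gc1, got$gc2, got$gc3), want)
    # gc1/gc2/gc3 average equals the whole-CDS GC fraction
    expect_equal(mean(c(got$gc1, got$gc2, got$gc3)), got$gc_all)
    expect_equal(got$gc_all, mean(b %in% c("G", "C")))
  }
})

test_that("ENc is 20 under one codon per family and 61 under uniform usage", {
  fam <- cpcodon:::syn_families("11")
  one_each <- paste(rep(vapply(fam, `[`, "", 1L), each = 25L), collapse = "")
  e <- enc_observed(count_codons(one_each))
  expect_equal(e$enc, 20)
  set.seed(77)
  draw <- sample(unlist(fam), 30000L, TRUE)
  counts <- structure(setNames(integer(64L), cpcodon:::all_codons()),
                      class = "codon_counts")
  tb <- table(draw); counts[names(tb)] <- as.integer(tb)
  e2 <- enc_observed(counts)
  expect_lt(abs(e2$enc - 61), 0.5)
  expect_true(all(vapply(list(e, e2), function(x)
    x$enc >= 20 && x$enc <= 61, TRUE)))
})

test_that("ENc equals the direct-formula oracle on random tables", {
  for (seed in 1:50) {
    cc <- random_counts(seed, total = sample(60:400, 1))
    expect_equal(enc_observed(cc)$enc, oracle_enc(cc), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("stronger bias never raises ENc on a simulated gradient", {
  fam <- cpcodon:::syn_families("11")
  fam <- fam[lengths(fam) >= 2L]
  grad <- c(8, 4, 2, 1, 0.5, 0.25)      # Dirichlet concentration, decreasing
  mean_enc <- vapply(seq_along(grad), function(g) {
    encs <- vapply(1:20, function(seed) {
      set.seed(1000 * g + seed)
      counts <- setNames(integer(64L), cpcodon:::all_codons())
      for (aa in names(fam)) {
        k <- length(fam[[aa]])
        p <- rgamma(k, grad[g]); p <- p / sum(p)
        counts[fam[[aa]]] <- as.integer(stats::rmultinom(1, 400L, p))
      }
      enc_observed(structure(counts, class = "codon_counts"))$enc
    }, 0)
    mean(encs)
  }, 0)
  expect_true(all(diff(mean_enc) < 0))
})

test_that("expected ENc follows the closed-form curve", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  # the 29/(S^2 + (1-S)^2) term is symmetric about S = 0.5
  s <- seq(0.05, 0.45, by = 0.05)
  expect_equal(enc_expected(s) - s, enc_expected(1 - s) - (1 - s))
  expect_error(enc_expected(1.2), "\\[0, 1\\]")
  expect_error(enc_expected(-0.1), "\\[0, 1\\]")
})

test_that("CAI is the geometric mean of reference weights", {
  ref <- rscu(count_codons(paste0(strrep("AAA", 8), strrep("AAG", 2))))
  # gene using only the preferred codon: CAI = 1
  expect_equal(cai(count_codons(strrep("AAA", 10)), ref)$cai, 1)
  # equal use of weights 1 and 0.25 (RSCU 1.6 vs 0.4): sqrt(0.25)
  got <- cai(count_codons(paste0(strrep("AAA", 5), strrep("AAG", 5))), ref)
  expect_equal(got$cai, sqrt(0.25))
  # Met/Trp/stops do not contribute
  with_met <- cai(count_codons(paste0(strrep("AAA", 5), strrep("AAG", 5),
                                      "ATGTGGTAA")), ref)
  expect_equal(with_met$cai, got$cai)
  expect_equal(with_met$n_codons, 10L)
})
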