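test_that("SSR thresholds gate detection at the exact boundary", {
  flank <- "CGCGC"
  expect_equal(nrow(find_ssrs(paste0(flank, strrep("A", 9), flank))), 0L)
  one <- find_ssrs(paste0(flank, strrep("A", 10), flank))
  expect_equal(nrow(one), 1L)
  expect_equal(one$motif, "A")
  expect_equal(one$repeats, 10L)
  expect_equal(one$start, 6L)
  expect_equal(one$end, 15L)
})

test_that("dinucleotide runs report maximal primitive motifs only", {
  hit <- find_ssrs(paste0("GG", strrep("AT", 6), "GG"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_len, 2L)
  expect_equal(hit$repeats, 6L)
  # AT x 6 must not additionally be reported as ATAT x 3
  expect_false(any(hit$unit_len == 4L))
  # a poly-A run is mononucleotide only, never AA / AAA
  polya <- find_ssrs(paste0("CC", strrep("A", 14), "CC"))
  expect_equal(polya$unit_len, 1L)
  expect_equal(polya$repeats, 14L)
})

test_that("SSR detection matches the exhaustive oracle on random sequences", {
  thr <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
  for (seed in 1:6) {
    set.seed(seed)
    s <- random_dna(3000, gc = 0.30)
    # salt with implants so the comparison is not vacuous
    s <- paste0(s, "C", strrep("A", 12), "C", strrep("TA", 7), "G",
                strrep("AAT", 6), "C", random_dna(500, gc = 0.30))
    got <- find_ssrs(s, thr)
    want <- oracle_ssr_scan(s, thr)
    expect_equal(got[, c("motif", "unit_len", "repeats", "start", "end")],
                 want, info = paste("seed", seed))
  }
})

test_that("implanted SSRs are recovered at exact coordinates", {
  sim <- generate_genome(synthetic_spec("hevea-like", seed = 13))
  ssrs <- find_ssrs(sim$record$sequence, circular = TRUE)
  truth <- sim$truth$ssr_implants
  key <- function(d) paste(d$start, d$end, d$repeats)
  expect_true(all(key(truth) %in% key(ssrs)))
  # every reported SSR re-validates against the raw sequence
  for (i in seq_len(nrow(ssrs))) {
    sub <- substr(sim$record$sequence, ssrs$start[i],
                  min(ssrs$end[i], nchar(sim$record$sequence)))
    if (ssrs$end[i] <= nchar(sim$record$sequence))
      expect_identical(sub, strrep(ssrs$motif[i], ssrs$repeats[i]))
  }
})

test_that("SSR family tallies are strand-symmetric", {
  sim <- generate_genome(synthetic_spec("uniform", seed = 17,
                                        arch = c(lsc = 8000L, ir = 2000L,
                                                 ssc = 1500L),
                                        n_genes = 4L,
                                        gene_length_range = c(100L, 150L),
                                        ssr_implants = data.frame(
                                          motif = c("A", "T", "AT", "AAT"),
                                          repeats = c(12L, 11L, 7L, 6L))))
  s <- sim$record$sequence
  f1 <- sort(table(find_ssrs(s)$family))
  f2 <- sort(table(find_ssrs(revcomp(s))$family))
  expect_equal(f1, f2)
})

test_that("exact duplications and palindromes are found as long repeats", {
  set.seed(31)
  unit <- random_dna(35, gc = 0.5)
  # flanks chosen so the duplicated segment cannot extend
  s <- paste0("AAAA", unit, "CCCC", random_dna(300), "GGGG", unit, "TTTT")
  exact <- find_long_repeats(s, min_len = 35L, max_mismatch = 0L)
  fw <- exact[exact$kind == "forward", ]
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$length, 35L)
  expect_equal(fw$mismatches, 0L)
  expect_equal(fw$score, 35L)
  expect_identical(substr(s, fw$pos1, fw$pos1 + 34L),
                   substr(s, fw$pos2, fw$pos2 + 34L))

  p <- paste0(random_dna(150), unit, random_dna(200), revcomp(unit),
              random_dna(100))
  pal <- find_long_repeats(p, min_len = 30L, max_mismatch = 0L)
  pal <- pal[pal$kind == "palindromic", ]
  expect_gte(nrow(pal), 1L)
  best <- pal[which.max(pal$length), ]
  expect_gte(best$length, 35L)
  expect_identical(substr(p, best$pos1, best$pos1 + best$length - 1L),
                   revcomp(substr(p, best$pos2, best$pos2 + best$length - 1L)))
})

test_that("long-repeat detection matches the quadratic oracle", {
  for (seed in c(2, 7)) {
    set.seed(seed)
    s <- paste0(random_dna(900, gc = 0.35))
    dup <- random_dna(40, gc = 0.5)
    mut <- dup
    substr(mut, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, 12, 12))[1L]
    s <- paste0(s, dup, random_dna(400, gc = 0.35), mut,
                random_dna(200, gc = 0.35), revcomp(dup),
                random_dna(150, gc = 0.35))
    got <- find_long_repeats(s, min_len = 30L, max_mismatch = 3L)
    want <- oracle_long_repeats(s, min_len = 30L, B = 3L)
    cols <- c("kind", "length", "pos1", "pos2", "mismatches")
    g <- got[, cols]; w <- want[, cols]
    rownames(g) <- rownames(w) <- NULL
    expect_equal(g[do.call(order, g), ], w[do.call(order, w), ],
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("repeat summaries tally unit lengths, families and length bins", {
  empty <- summarize_repeats(find_ssrs("ACGTACGT"))
  expect_equal(empty$n_ssr, 0L)
  expect_equal(sum(empty$ssr_by_unit$count), 0L)

  # implant design: 7 of 10 SSRs mononucleotide -> 70%
  imp <- data.frame(motif = c(rep("A", 5), rep("T", 2), "AT", "AAT", "AATT"),
                    repeats = c(rep(12L, 5), 11L, 11L, 7L, 6L, 5L))
  sim <- generate_genome(synthetic_spec("uniform", seed = 23,
                                        arch = c(lsc = 9000L, ir = 2000L,
                                                 ssc = 1500L),
                                        n_genes = 4L,
                                        gene_length_range = c(100L, 150L),
                                        ssr_implants = imp))
  sm <- summarize_repeats(find_ssrs(sim$record$sequence))
  expect_equal(sm$n_ssr, 10L)
  expect_equal(sm$ssr_by_unit$pct[1L], 70)
  expect_equal(sm$ssr_at$count, 10L)  # every implanted motif is A/T-only

  lr <- data.frame(kind = c("forward", "forward", "palindromic"),
                   length = c(31L, 47L, 35L), pos1 = 1L, pos2 = 100L,
                   mismatches = 0L, score = c(31L, 47L, 35L))
  sm2 <- summarize_repeats(find_ssrs("ACGT"), lr)
  expect_equal(as.integer(sm2$long_by_kind), c(2L, 1L))
  expect_equal(as.integer(sm2$long_by_bin[c("30-39", "40-49")]),
               c(2L, 1L))
})
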