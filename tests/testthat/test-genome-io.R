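test_that("GenBank round trip preserves sequence and CDS features", {
  sp <- synthetic_spec("uniform", seed = 3,
                       arch = c(lsc = 10000L, ir = 3000L, ssc = 2000L),
                       n_genes = 6L, gene_length_range = c(100L, 200L))
  sim <- generate_genome(sp)
  gb <- tempfile(fileext = ".gb")
  write_genbank(sim$record, gb)
  rec <- read_genbank(gb)

  expect_identical(rec$sequence, sim$record$sequence)
  expect_identical(rec$length_bp, sim$record$length_bp)
  expect_true(rec$circular)

  cds1 <- extract_cds(sim$record)
  cds2 <- extract_cds(rec)
  m <- merge(cds1, cds2, by = "gene")
  expect_equal(nrow(m), nrow(cds1))
  expect_identical(m$sequence.x, m$sequence.y)

  # determinism: same file parsed twice is byte-identical
  expect_identical(extract_cds(read_genbank(gb)), cds2)
})

test_that("hand-written two-gene record parses with strands and joins", {
  seq60 <- strrep("ACGT", 15)
  lines <- c(
    "LOCUS       TOY01 60 bp    DNA     circular PLN 01-JAN-2026",
    "ACCESSION   TOY01",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             join(1..6,10..15)",
    '                     /gene="gA"',
    "     CDS             complement(20..25)",
    '                     /gene="gB"',
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(tolower(seq60),
                                         seq(1, 60, 10), seq(10, 60, 10)),
                               collapse = " ")),
    "//")
  f <- tempfile(fileext = ".gb")
  writeLines(lines, f)
  rec <- read_genbank(f)
  expect_equal(rec$accession, "TOY01")
  expect_equal(rec$length_bp, 60L)
  cds <- extract_cds(rec)
  expect_equal(nrow(cds), 2L)
  # two-exon join: 6 + 6 = 12 nt, concatenated in order
  expect_equal(cds$sequence[cds$gene == "gA"],
               paste0(substr(seq60, 1, 6), substr(seq60, 10, 15)))
  expect_equal(nchar(cds$sequence[cds$gene == "gA"]), 12L)
  # minus strand comes back reverse-complemented
  expect_equal(cds$sequence[cds$gene == "gB"],
               revcomp(substr(seq60, 20, 25)))
})

test_that("a CDS spanning the origin concatenates both segments", {
  set.seed(10)
  n <- 120L
  seq <- random_dna(n)
  rec <- structure(list(
    accession = "WRAP1", species = NA_character_, sequence = seq,
    length_bp = n, circular = TRUE,
    features = data.frame(kind = "CDS", gene = "wrapped", strand = "+",
                          n_segments = 2L,
                          segments = I(list(cbind(start = c(111L, 1L),
                                                  end = c(n, 9L)))),
                          stringsAsFactors = FALSE)), class = "cp_genome")
  cds <- extract_cds(rec)
  expect_equal(nchar(cds$sequence), (n - 111L + 1L) + 9L)
  expect_equal(cds$sequence, paste0(substr(seq, 111, n), substr(seq, 1, 9)))
})

test_that("malformed records fail with informative errors", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "ACCESSION   X",
               "FEATURES             Location/Qualifiers",
               "     CDS             5..2", "ORIGIN",
               "        1 acgtacgtac", "//"), f)
  expect_error(read_genbank(f), "location")
  writeLines(c("LOCUS       Y 10 bp", "ACCESSION   Y"), f)
  expect_error(read_genbank(f), "ORIGIN")
  # no CDS features -> empty result with warning
  writeLines(c("LOCUS       Z 10 bp", "ACCESSION   Z",
               "FEATURES             Location/Qualifiers",
               "     source          1..10", "ORIGIN",
               "        1 acgtacgtac", "//"), f)
  rec <- read_genbank(f)
  expect_warning(out <- extract_cds(rec), "no CDS")
  expect_equal(nrow(out), 0L)
})

test_that("quadripartite detection recovers generated architecture exactly", {
  sp <- synthetic_spec("uniform", seed = 4,
                       arch = c(lsc = 10000L, ir = 3000L, ssc = 2000L),
                       n_genes = 6L, gene_length_range = c(100L, 200L))
  sim <- generate_genome(sp)
  q <- detect_quadripartite(sim$record)
  expect_true(q$found)
  tr <- sim$truth$intervals
  expect_equal(unname(q$lsc), tr$lsc)
  expect_equal(unname(q$irb), tr$irb)
  expect_equal(unname(q$ssc), tr$ssc)
  expect_equal(unname(q$ira), tr$ira)
  expect_equal(unname(q$junctions), unname(sim$truth$junctions))

  # partition invariant: the four regions tile the circle
  n <- q$genome_len
  lens <- vapply(list(q$lsc, q$irb, q$ssc, q$ira),
                 cpcodon:::circ_len, 0L, n = n)
  expect_equal(sum(lens), n)

  # IRa is the reverse complement of IRb
  irb_seq <- substr(sim$record$sequence, q$irb[1], q$irb[2])
  ira_seq <- substr(sim$record$sequence, q$ira[1], q$ira[2])
  expect_identical(ira_seq, revcomp(irb_seq))
})

test_that("IR detection is invariant to rotation and reverse complement", {
  sp <- synthetic_spec("uniform", seed = 2,
                       arch = c(lsc = 12000L, ir = 3000L, ssc = 2500L),
                       n_genes = 8L, gene_length_range = c(100L, 200L))
  s <- generate_genome(sp)$record$sequence
  n <- nchar(s)
  q0 <- detect_quadripartite(s)
  rot <- paste0(substr(s, 5001, n), substr(s, 1, 5000))
  q1 <- detect_quadripartite(rot)     # IRb now spans the linearization point
  expect_equal(q1$ir_len, q0$ir_len)
  expect_equal(cpcodon:::circ_len(q1$lsc, n), cpcodon:::circ_len(q0$lsc, n))
  expect_equal(cpcodon:::circ_len(q1$ssc, n), cpcodon:::circ_len(q0$ssc, n))
  q2 <- detect_quadripartite(revcomp(s))
  expect_equal(q2$ir_len, q0$ir_len)
  expect_equal(cpcodon:::circ_len(q2$lsc, n), cpcodon:::circ_len(q0$lsc, n))
})

test_that("no qualifying IR yields an empty flagged structure", {
  set.seed(5)
  q <- detect_quadripartite(random_dna(6000), min_ir = 1000L)
  expect_false(q$found)
  expect_true(all(is.na(q$irb)))
  expect_equal(q$ir_len, 0L)
})

test_that("junction report measures gaps and gene extensions", {
  q <- structure(list(
    lsc = c(1L, 1000L), irb = c(1001L, 1300L), ssc = c(1301L, 1500L),
    ira = c(1501L, 1800L),
    junctions = c(JLB = 1001L, JSB = 1301L, JSA = 1501L, JLA = 1L),
    ir_len = 300L, genome_len = 1800L, found = TRUE),
    class = "quadripartite")
  feats <- data.frame(
    kind = "gene",
    gene = c("abut", "straddle", "inside"),
    strand = "+", n_segments = 1L,
    segments = I(list(cbind(start = 1201L, end = 1300L),   # ends at JSB - 1
                      cbind(start = 881L, end = 1120L),    # 120 bp into IRb
                      cbind(start = 1350L, end = 1400L))),
    stringsAsFactors = FALSE)
  jr <- junction_report(q, feats)
  abut <- jr[jr$gene == "abut" & jr$region == "JSB" & jr$side == "upstream", ]
  expect_equal(abut$distance_bp, 0L)
  expect_equal(abut$overlap_bp, 0L)
  strad <- jr[jr$gene == "straddle" & jr$region == "JLB" &
                jr$side == "spanning", ]
  expect_equal(strad$overlap_bp, 120L)
  expect_equal(strad$distance_bp, 0L)
  expect_equal(nrow(junction_report(q, feats[0, ])), 0L)
})
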