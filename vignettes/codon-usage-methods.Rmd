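---
title: "Codon usage bias and plastome structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and plastome structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcodon)
```

cpcodon analyses annotated chloroplast genomes: it extracts and filters
coding sequences, quantifies codon usage bias per gene and per genome,
separates the mutational and selective components of that bias with the
standard graphical analyses of the field, identifies optimal codons from
ENc-extreme gene libraries, mines microsatellites and dispersed repeats,
and resolves the quadripartite LSC/IRb/SSC/IRa architecture.  This
vignette explains the statistical models behind each stage, the defaults
and why they were chosen, and what the synthetic-plastome generator does
and does not emulate.

## Coding-sequence selection

Reliable codon statistics need clean coding sequences.  `filter_cds()`
applies four rules in order: (1) the base count must be a multiple of
three; (2) the sequence must be at least 300 bp (`min_cds_len`), so
per-gene frequency estimates are not dominated by sampling noise; (3)
only the standard bases A/C/G/T are allowed; (4) no internal stop codon
under the working genetic code.  The bacterial/plastid code (NCBI
translation table 11) is the default because plastid genomes use it; the
code id is configurable everywhere it matters (stop codons, synonymous
families, degeneracy classes).  A terminal stop codon is tolerated and
excluded from the amino-acid length `l_aa`; a CDS that simply lacks a
terminal stop is retained, since only internal stops indicate a broken
frame.  Genes duplicated by the inverted repeat (rpl2, ycf2, ndhB, ...)
are deduplicated by name before codon statistics, keeping the first
copy; a switch (`dedupe_ir_genes = FALSE`) counts both copies instead.

## Per-gene codon statistics

**RSCU.** For codon *j* of amino acid *i* with family size $n_i$ and
count $x_{ij}$,

$$\mathrm{RSCU}_{ij} = \frac{x_{ij}}{\tfrac{1}{n_i}\sum_j x_{ij}},$$

the observed count relative to uniform use within the synonymous
family.  Families with zero observations have *undefined* RSCU (NA),
not zero — a distinction that matters when averaging across genes.  In
the complete table required by correspondence analysis, those NAs are
replaced by 0, the conventional completion for a non-negative
contingency-style table.

**Positional GC.** GC1/GC2/GC3 are computed over all codons with a
terminal stop removed.  GC3s — the quantity *S* of the ENc-plot — is
restricted to synonymous third positions: Met, Trp and stops carry no
degeneracy and are excluded.  One published wording defines GC3s
against the total base count of the gene, which is incompatible with
the way the statistic is used on the ENc-plot (it must be a fraction of
third positions in [0, 1]); the standard definition is the default and
a `gc3s_scope = "gene_wide"` switch reproduces the literal wording.

**ENc.** Wright's estimator: per family with $n \ge 2$ observed codons
the codon homozygosity is $\hat F = (n\sum \hat p^2 - 1)/(n-1)$; class
averages over the 2-, 3-, 4- and 6-fold families (9, 1, 5, 3 families
under code 11) give

$$\mathrm{ENc} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
  \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Small genes raise two practical issues the estimator must survive: a
family with fewer than two observations (or a non-positive $\hat F$) is
dropped from its class, and a wholly missing 3-fold class (Ile is its
only member) is imputed as $(\bar F_2 + \bar F_4)/2$ — both behaviours
chosen for compatibility with long-standing practice in codon-usage
software.  Any other missing class leaves ENc undefined rather than
silently extrapolated.  Estimates are capped into [20, 61]; the cap is
recorded on the result.  The theoretical expectation under pure
compositional bias is the standard curve
$\mathrm{ENc}_{exp}(S) = 2 + S + 29/(S^2 + (1-S)^2)$, and
`enc_plot_points()` reports each gene's deviation from it (positive =
below the curve = more biased than composition explains).

**CAI.** Relative adaptiveness weights $w_{ij} =
\mathrm{RSCU}_{ij}/\max_j \mathrm{RSCU}_{ij}$ come from a reference set;
CAI is the geometric mean of $w$ over the gene's codons (Met, Trp,
stops excluded).  No external reference organism is assumed: the
reference is the genome's own high-bias library (the lowest-ENc 10% of
genes), which is the natural choice when no expression data exist.
Codons unobserved in the reference are floored at $w = 0.01$ so the
geometric mean stays defined; the floor only matters for rare codons
and is reported in the weights.

## The four bias analyses

**ENc-plot** (ENc against GC3s with the expected curve) separates
genes whose bias is explained by third-position composition from genes
under additional selective constraint.

**PR2-bias plot** places each gene at $x = G_3/(G_3+C_3)$,
$y = A_3/(A_3+T_3)$.  By default only four-fold degenerate families
contribute, because every third-position change there is synonymous, so
deviations from (0.5, 0.5) cannot be caused by amino-acid composition;
`scope = "all"` uses all synonymous codons for comparison with studies
that do.

**Neutrality plot.** `neutrality_fit()` is an ordinary least-squares
regression of GC12 on GC3 (plus the Pearson correlation with its exact
two-sided t-test p-value).  The object carries its data and the
underlying `lm`, and has `print`, `coef` and `plot` methods.  The slope
is conventionally multiplied by 100 and read as the percentage
contribution of mutational pressure.

**Correspondence analysis.** `coa_rscu()` is classical CA: the
genes-by-codons RSCU table is converted to proportions, centred by the
outer product of its margins, standardized by $1/\sqrt{r_i c_j}$, and
decomposed by SVD; axis inertia is the squared singular value and an
axis contribution is its share of *total* inertia (not of the first k
axes).  Met, Trp and stop codons are excluded, leaving 59 columns under
code 11.  SVD leaves axis signs arbitrary; they are fixed by making the
codon with the largest absolute loading positive on each axis, so
correlations of gene indices with axis 1 are reproducible and their
reported signs meaningful.  The unit tests verify the implementation
against two independent oracles: a dense eigendecomposition of the
standardized-residual cross-product and the eigenvalues of
`vegan::cca()`.

Pearson correlations among the indices (axes 1-2, ENc, CAI, GC3, GC3s,
L_aa, overall GC) use `cor.test()`'s exact t distribution, starred at
0.05/0.01, with no multiple-testing correction — the convention of the
comparative-plastome literature this package serves.

## Optimal codons

Genes are ranked by ENc; the lowest and highest `fraction` (default
10%, ceiling, floor of two genes, ENc ties broken by gene name) form
the high-bias and low-bias libraries.  Library RSCU is computed from
*summed* codon counts, not averaged per-gene RSCU, so long genes weigh
in proportion to their codons.  A codon is *high-frequency* when its
pooled all-gene RSCU exceeds 1 and *optimal* when additionally
$\Delta\mathrm{RSCU} = \mathrm{RSCU}_{high} - \mathrm{RSCU}_{low} \ge
0.08$.  The "RSCU > 1" side is evaluated on the pooled table by
default because genome-wide high-frequency codon counts are what
comparative studies report; `rscu_scope = "high_bias"` selects the
alternative reading.  Cross-genome reports intersect optimal-codon
sets on codon identity.

A caveat worth stating: because both libraries are selected on ENc,
sampling noise in family frequencies leaks into $\Delta$RSCU with a
positive bias for each family's majority codon (a winner's-curse
effect, strongest in 6-fold families where RSCU noise is amplified
sixfold).  With plastome-scale genes the 0.08 threshold sits above
this leakage; the recovery simulations below were sized by that power
analysis.

## Repeat mining

`find_ssrs()` reports maximal perfect tandem repeats of primitive 1-6
nt motifs above per-unit-length minimum repeat counts.  The thresholds
default to the MISA-web convention (10, 6, 5, 5, 5, 5) and are
config-exposed, since published SSR totals depend entirely on them.  A
run attributable to a shorter unit (poly-A inside an "AA" pattern) is
reported once, under the shortest unit; runs fully contained in a
longer reported run are dropped.  Motif families are canonicalized as
the lexicographic minimum over cyclic rotations and the reverse
complement, which makes family tallies strand-symmetric.  Circular
genomes are scanned with a short wrap-around window so origin-spanning
runs are found once.

`find_long_repeats()` finds maximal forward and palindromic repeat
pairs of at least 30 bp under a Hamming budget of 3 mismatches — the
explicit dispersed-repeat parameters of the study design this package
reproduces, with the score reported as matches minus mismatches.
Candidate diagonals are anchored by exact seeds of length
$\lfloor \mathrm{min\_len}/(\mathrm{mismatches}+1)\rfloor$ (pigeonhole:
every qualifying repeat contains one), then grown into all maximal
bounded-mismatch windows around each seed.  The unit tests check exact
equivalence against an exhaustive all-diagonal quadratic scan on
sequences of a few kilobases — the size at which the quadratic oracle
itself remains fast enough to be run routinely; the seeded
implementation has no such size restriction.

## Quadripartite structure

`detect_quadripartite()` anchors exact 25-mers between the genome and
its reverse complement, groups anchors by diagonal, and extends the
best runs with a mismatch tolerance of 0.1% (annotation-grade noise; a
mismatch is only crossed when a clean 12-base run follows, so
extension cannot creep through random flanks).  Sequences are treated
as circular: detection is retried at three rotations, which guarantees
at least one linearization leaves both IR copies intact, and reported
intervals may wrap.  The longer single-copy interval is LSC, the
shorter SSC, and junctions JLB/JSB/JSA/JLA are the first bases of IRb,
SSC, IRa and LSC in circular order.  `junction_report()` lists, for
each junction, the nearest feature on each side with its gap and any
extension across the boundary.  Coordinates are 1-based inclusive
(the GenBank convention) throughout — R's string functions are
natively 1-based, so no internal coordinate translation exists to get
wrong.

## The synthetic-plastome generator

`generate_genome()` exists so that every stage can be tested against
known ground truth without downloads.  The `"hevea-like"` preset fixes
the study conditions: a circular 161,090 bp genome (LSC 89,100 + IR
26,810 x 2 + SSC 18,370), overall GC targeted at 35.7% by solving for
the intergenic base composition after the coding GC is realized, 91
protein-coding genes of 100-500 aa drawn from plastome-like amino-acid
frequencies, and an SSR implant profile of 126 repeats dominated by
A/T mononucleotide runs (~70%), matching the published genus-wide
proportions.

Codon usage is modelled per family as
$w \propto \exp(b\,\mathrm{AT3} + t\,\mathrm{GC3end} + \mathrm{pref})$:

* $b$, the gene's A/U-ending preference, is drawn per gene — uniform
  on (0.2, 1.0) for the low-bias class (80% of genes) and (1.0, 1.7)
  for the high-bias class (20%) — calibrated so the per-gene ENc
  distribution spans roughly the published 36-57 range with a mean
  near 46;
* $t$, a per-gene GC3 shift (normal, sd 0.25), spreads GC3 and, through
  a coupling that tilts amino-acid frequencies toward GC-rich residues
  when $t$ is high, induces a positive GC12-GC3 relation;
* `pref` is a preference profile shared by all genes of a genome (a
  common tRNA pool): third-base offsets favouring U over A and C over
  G (which concentrates PR2 points in the x < 0.5, y < 0.5 quadrant),
  plus a composition-neutral concentration that boosts one preferred
  A/T-ending codon per family and penalizes its same-ending partners.
  The neutral construction matters: it raises within-family
  homozygosity — pushing genes below the expected ENc curve, as real
  plastome genes sit — without moving GC3s, so the two effects stay
  experimentally separable.

The `"strong-bias"` preset drives recovery experiments: eight
designated codons are implanted at probability 0.95 in the high-bias
expression class while their families stay uniform in the low-bias
class, and every other family uses one fixed codon at probability
0.995 in both classes.  The background concentration is deliberately
extreme: the power analysis above shows that at 0.95 the ENc-selection
leakage into ΔRSCU reaches ~0.06 for 6-fold families — right at the
0.08 threshold — whereas at 0.995 both the leakage and the sampling
noise fall an order of magnitude below it, so recovered optimal codons
are attributable to the implants alone.

`simulate_gc_profiles()` generates (GC12, GC3) pairs directly from the
linear relation with truncated-normal noise, for quantitative
parameter-recovery checks of the neutrality regression (slope 0.22
recovered within ±0.03 from 90 genes at noise sd 0.02).  The
full-genome route induces the same relation only loosely through
composition coupling, so the genome-level check is directional
(positive slope), and the quantitative check runs on the profile
simulator.

What the generator does **not** emulate: real gene content and order
(gene names are synthetic, so junction gene identities are
placeholders), introns and trans-splicing, RNA editing, indel and
rearrangement variation, compound/interrupted SSRs, and phylogenetic
correlation between genomes.  Passing the closed-loop tests therefore
demonstrates correctness of the computations under the stated
statistical model, not robustness to annotation errors in public
records — the six-accession regression suite covers that separately
when the records are supplied locally (the package performs no
downloads).

## Problem sizes and numerical choices

The test suite generates everything it needs at run time.  Closed-loop
genome tests run on 38-50 kb architectures (full stages, exact IR and
SSR recovery); figure-level and SSR-profile checks use the full
161 kb preset, whose SSR scan is regex-based and fast; oracle
equivalence for repeats runs on 2-4 kb sequences where the quadratic
oracle is cheap; the uniform-usage RSCU check uses 250,000 codons so
the law-of-large-numbers band (|RSCU − 1| < 0.1) holds with margin.
Determinism is integer-seeded everywhere; identical seeds give
byte-identical FASTA/GenBank/JSON output.  Degenerate inputs are
handled explicitly rather than by NA propagation: empty CDS sets warn,
genes without synonymous codons flag GC3s and ENc undefined, zero
GC3 variance aborts the neutrality fit, constant RSCU matrices return
zero inertia, and PR2 points with empty denominators are flagged
rather than dropped silently.

## Known limitations

* The GenBank reader supports the feature constructs that occur in
  plastome records (join, complement, origin-spanning segments,
  multi-line locations); it is not a general GenBank parser (no
  per-segment `complement()` inside `join`, no external references).
* trans-spliced rps12 is handled as annotated, per location block; the
  package does not reassemble trans-spliced transcripts, which affects
  gene counting only.
* IR detection assumes the canonical two-IR architecture; plastomes
  that have lost one IR return `found = FALSE` rather than a partial
  structure.
* ΔRSCU-based optimal codons inherit the ENc-selection leakage
  discussed above; with few or short genes the 0.08 threshold loses
  specificity, which is why `build_bias_libraries()` refuses fewer
  than 10 genes.
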