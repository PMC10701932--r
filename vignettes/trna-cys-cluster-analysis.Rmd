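---
title: "Methods: tRNA gene cluster structure, variability and expression"
author: "cystra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tRNA gene cluster structure, variability and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystra)
```

## The biological problem

Eukaryotic tRNA genes are mostly dispersed, but gene duplication can
produce clusters: genomic regions containing only tRNA genes, usually
delimited with a maximum intergenic distance of about 1 kbp. In
*Arabidopsis thaliana*, the smallest such cluster is a tandem array of
tRNA-Cys-GCA genes on chromosome 5: roughly 420 bp repeating units, each
holding one tRNA gene plus spacer, flanked upstream by a conserved
tRNA-derived pseudogene. Across natural accessions (ecotypes) the array
varies in copy number — four to six whole units — and, in one accession,
by a deletion that removes part of one unit together with the tRNA gene
of the next. Two further two-gene "mini-clusters" sit on chromosomes 1
and 2, the latter with divergently transcribed (head-to-head) genes.
Because the gene copies are nearly identical, bulk small-RNA sequencing
cannot directly tell which copy a mature tRNA read came from; only reads
retaining genomic 5' leader or 3' trailer sequence (unprocessed
precursors) discriminate the copies.

`cystra` implements this whole analysis as reusable, tested components:
cluster detection and orientation classification from annotations,
tandem repeat-unit decomposition with cross-accession structural-event
calling, neighbor-joining (NJ) grouping of repeat units, mature-variant
deduplication and greedy identity clustering, cloverleaf stem-mispair
assessment, a tRNA-seq quantification pipeline, Helitron terminal-signal
and hairpin scans, and in-silico PCR. A seeded synthetic-data module
generates multi-accession genomes and read libraries with recorded
ground truth so that every stage can be validated without downloads.

## Cluster detection and orientation

`findClusters()` builds maximal runs of tRNA genes on one sequence in
which every adjacent gap is at most `maxGap` (default 1000 bp, the
conventional criterion). Strand is ignored for membership, so
divergently transcribed pairs cluster. Pseudogenes never become members;
when one lies within `maxGap` of a cluster edge it is reported as a
flanking feature, which is exactly the situation of the conserved
upstream pseudogene. Spacers are counted as bases strictly between
genes; overlapping genes produce negative spacers and set an overlap
flag rather than an error, because real tRNA clusters can overlap
introns of protein-coding genes on the opposite strand.

Orientation uses ascending-coordinate strands: all equal is
`head_to_tail`; a two-gene `-`,`+` pattern is `head_to_head`
(transcription starts facing each other), `+`,`-` is `tail_to_tail`;
anything else is `mixed`.

## Alignment and the identity statistic

All comparisons rest on one statistic: percent identity of the optimal
global alignment, with every alignment column — including terminal gap
columns — in the denominator. The aligner is an affine-gap
Needleman–Wunsch (Gotoh three-state recursion) with defaults frozen to
the constants of the EMBOSS `needle` tradition: match +5, mismatch −4,
gap open 10, gap extend 0.5, end gaps free. A gap of length L costs
`open + L·extend`; positions involving N never score as matches (N vs
base −2, N vs N −1), and genes whose sequence contains N are excluded
from identity statistics. Traceback ties are resolved deterministically
(diagonal, then gap in the second sequence, then gap in the first), so
alignments are reproducible. The implementation is validated two ways:
exhaustive enumeration of all alignments on short strings, and score
agreement with an independent affine-gap implementation
(`Biostrings::pairwiseAlignment`) on longer sequences. One consequence
of free end gaps worth knowing: for sequences with no common symbols
(e.g. `AAAA` vs `TTTT`) the optimum is the staggered alignment of score
0, not the mismatch-only alignment.

## Repeat-unit decomposition and structural events

`decomposeCluster()` anchors unit boundaries at gene starts: unit i runs
from gene i's start to the base before gene i+1's start, so each unit is
one gene plus its downstream spacer. No boundary rule is dictated by the
biology; anchoring at the gene start makes the decomposition independent
of spacer alignment ambiguity and keeps each unit's spacer unambiguous.
The last unit extends by the rounded median of the earlier unit lengths,
clipped at the region end; regions whose genes mostly lie on the minus
strand are reverse-complemented first. The region handed in should be
the syntenic cluster span (with real assemblies this delimitation comes
from flank homology; the synthetic panel records it as truth).

`buildUnitPanel()` pools units across accessions, computes all pairwise
identities, and groups units by cutting every NJ-tree branch longer than
0.03 p-distance — the tree-cut analogue of the 97% sequence identity
convention used to color corresponding repeats. The distance is the
alignment-derived p-distance `(100 − identity)/100`; the distance
function is a parameter, so other models can be substituted. The
reference accession for event calling defaults to the one with the most
units, because only the longest clusters exhibit every unit group.

`callStructuralEvents()` matches each accession's units one-to-one to
the reference units (greedy, by decreasing identity, with a 50% identity
floor). Unmatched reference units are whole-unit deletions, surplus
accession units whole-unit insertions. Partial events come from a length
residual: the observed region length minus the total expected from the
matched whole units. A positive residual smaller than a missing unit
means that unit is partially present and the event size is the number of
bases missing from it; a negative residual is a deletion inside a
matched unit. Residuals within 20% of a unit length are treated as
jitter. On the default synthetic panel this reports the planted
junction-spanning deletion as exactly one `partial_deletion` of 167 bp
(95 bp of one unit plus the following 72 bp gene).

The NJ implementation is the standard Saitou–Nei agglomeration with the
two-point branch-length formula, a three-taxon closed form for the final
join, negative branch lengths clamped to zero, and a deterministic
smallest-pair tie-break. It is checked against the closed form, against
additivity on quartets under every labeled split, and against `ape::nj`
topologies on random additive trees.

## Mature variants and stem mispairing

`dedupeMature()` collapses mature tRNA bodies by exact string identity,
naming variants after the first carrying gene. `greedyCluster()` is a
USEARCH-style greedy centroid clustering: sequences are visited sorted
by decreasing length (ties broken lexicographically), each joining the
best centroid at or above the identity threshold (default 0.97) or
seeding a new one; identity is matches over alignment columns from the
package's own global aligner, not a k-mer heuristic, and the fixed visit
order makes the result deterministic. Greedy clustering is
order-dependent by nature; at threshold 1.0 it coincides with exact
deduplication, and group counts are non-increasing in the threshold.

`stemMispairCheck()` aligns a variant to a reference body, transfers the
cloverleaf pairing positions (acceptor 7 pairs, D 4, anticodon 5, T 5)
through the alignment, and counts transferred pairs that are neither
Watson–Crick nor G·U wobble (G:T in DNA space). Wobble pairs are
tolerated because they are structurally accepted in tRNA stems; only
true mispairings are counted as deviations. A stem position landing in
an alignment gap sets an indel flag for that stem — the structure is
not evaluable there, as for an 11 nt deletion spanning a T-loop and part
of the T-stem. The canonical reference and its pairing map are provided
by the template generator (`makeTrnaTemplate()`, `defaultPairingMap()`);
any 71–72 nt body with a consistent cloverleaf map is acceptable.

## Expression quantification

The pipeline mirrors a tRNA-seq design with a control library and a
deacylated library (deacylation makes aminoacyl-charged tRNAs ligatable,
so charged species gain representation). Stages, in order: exact
unique-read collapse per library with replicate files summed
(`collapseUnique()`); inclusive 55–110 nt length filter; contamination
filter; locus assignment; TMM normalization; library contrast. The order
is logged by the pipeline report.

**Contamination filter.** The contract is a matcher function: reads not
matching the expected taxon's sequence set are removed, removals are
logged, and a matcher failure is an error. The packaged matcher scores
each read against a reference set with the local aligner and keeps reads
whose best score reaches that of a 72%-identity alignment covering the
read. Full-read coverage is assumed because the reads are whole small-RNA
molecules; the 0.72 level is set where chance local alignments of random
55–110 nt sequences essentially never reach while genuine relatives
always do. An adapter composing the equivalent external BLAST command at
the classical sensitivity settings (`-word_size 6 -perc_identity 65
-dust no`) is provided for real-database searches.

**Assignment.** Each locus carries two references: the mature sequence
(gene body plus post-transcriptional 3'-CCA) and a precursor (genomic
leader + body + trailer, 30 nt flanks by default, no CCA). Reads are
scored against both with an affine Smith–Waterman (same scoring
constants; exact DP is affordable and deterministic at tRNA scale), the
locus score being the better of the two. A read is assigned to a gene
iff exactly one locus attains the maximum; ties are discarded at gene
level but still count at variant level when all tied loci share one
mature variant. This dual level is what lets identical gene copies be
quantified jointly while their precursor reads separate them. Reads
scoring below half of a perfect full-length match are left unassigned.
Read accounting (gene-assigned, variant-only, multi-discarded,
unassigned) is exact per library.

**Normalization and contrast.** Between-library scaling uses the trimmed
mean of M-values: reference library chosen by the 75th-percentile rule,
rows zero in either library dropped, M and A values doubly trimmed (30%
and 5%), inverse-asymptotic-variance weighting, factors rescaled to
geometric mean 1. The implementation follows the published method and is
verified against `edgeR::calcNormFactors` to 1e-6. Normalized counts
divide by effective library size and rescale by its geometric mean, so a
normalized count is zero exactly when the raw count is. The contrast
flags a variant `undetected` when both libraries are zero, `ambiguous`
when exactly one is, `charged` when the deacylated signal exceeds the
control, and `low` when a detected variant falls below the 10th
percentile of positive variants.

## The synthetic-data generators

The generators define the study conditions; their defaults are fixed:

* **Template tRNA** (`makeTrnaTemplate()`): a 72 nt body whose stem pairs
  are complementary and whose anticodon reads GCA.
* **Cluster panel** (`makeClusterPanel()`): 420 bp units, accessions with
  4, 5 and 6 units plus one accession carrying the 167 bp
  junction-spanning deletion; six unit-group prototypes at substitution
  probability 0.05 from a common ancestor (which reproduces the observed
  mid-80s to low-90s percent within-cluster unit identities); accession
  copies of a group at 0.01 (inside the 97% grouping convention);
  identical 500 bp flanks carrying the cluster primer sites; an upstream
  pseudogene (template with 3 substitutions, anticodon intact); one
  CTAG[TC] motif planted per unit; spacer base composition at 36% GC,
  the genomic neighbourhood's typical value. Because prototypes are
  drawn randomly, occasional seeds place two prototypes within the 97%
  convention, and the grouping then honestly reports fewer groups.
* **Locus set** (`makeLocusSet()`): 16 loci carrying 13 unique mature
  variants; three variants present at two loci each with distinct
  genomic flanks; variant-distinguishing substitutions placed within the
  first 50 nt of the body so every read passing the 55 nt filter covers
  them; the loci of the last two variants silent by default.
* **Reads** (`simulateReads()`): mature reads are the CCA-tailed mature
  reference truncated from the 3' end into 55–110 nt; precursor reads
  carry 5–30 nt of genomic flank on one side; substitution errors at
  0.01; 10% random contaminants; the deacylated library contributes
  `chargedFactor` (default 2) times more molecules for charged genes,
  with the library yield growing accordingly, so the expected
  deacylated/control raw count ratio is 2 for charged and 1 for
  uncharged genes.

What the generators do **not** emulate: indel sequencing errors,
modification-driven reverse-transcription stops, base-quality
information, genome-wide background (each accession genome is just the
cluster plus flanks), and realistic phylogenetic structure among
accessions (units diverge star-like from prototypes). Passing tests
therefore demonstrate the correctness of the algorithms under controlled
conditions, not performance on raw sequencing data.

## Auxiliary scans

`scanHelitronSignals()` reports, on both strands, the 5'-terminal `TC`,
3'-terminal `CTRR` and the `CTAG` motif followed by T or C that are the
conserved terminal signals of rolling-circle (Helitron) transposons.
Interpretation is left to the caller: no window or strand convention for
a "terminal" occurrence is imposed, since none is standard.
`hairpinScan()` searches the 3'-terminal window (60 nt default)
exhaustively for inverted repeats (stem ≥ 6, loop 3–10, ≤ 1 mismatch),
the subterminal palindrome expected near a Helitron 3' end; brute force
is exact at this size. `inSilicoPcr()` reports all primer-site pairings
within a product-size cap, product size measured 5' end of the forward
site to 5' end of the reverse site inclusive (gel-equivalent length, both
primer footprints included); matching is exact by default because the
modelled PCR succeeded across accessions, implying conserved sites.

## Numerical choices and determinism

Every source of randomness flows through explicit seeds; generator
functions restore the caller's RNG state. Identity percentages are
reported to one decimal and compared to integer conventions by
round-half-up. NJ ties, greedy clustering order, traceback priorities
and group relabeling (by first appearance) are all deterministic, so the
pipeline's manifest (seed plus parameters) reproduces a run
bit-identically. Problem sizes used by the checked examples — read
depths of 20,000 per library for the error-free recovery analysis,
50 seeded panels for the unit-count recovery — were chosen so binomial
sampling error is well below the assertion margins.

## A worked example

```{r example, eval = FALSE}
panel <- makeClusterPanel(clusterSpec())
units <- lapply(names(panel$accessions), function(acc) {
  r <- extractClusterRegion(panel, acc)
  decomposeCluster(r$region, r$genes, accession = acc)
})
up <- buildUnitPanel(units)
callStructuralEvents(up)
```

`runPipeline(outDir, seed)` chains every stage on synthetic data and
writes per-stage outputs, a JSON report and a human-readable summary.
The package's functions (with `runPipeline()` as the orchestration
front-end) are the interface; `scripts/acceptance.R` recomputes the
headline quantities from a clean start.

## Known limitations

* Cluster calling needs annotations; there is no de-novo calling from
  raw sequence.
* Whole-cluster multiple alignments are out of scope; all comparisons
  are pairwise.
* The distance used for unit grouping is the alignment p-distance;
  model-based distances can be plugged in through the `distances`
  parameter of `groupUnits()` but none is shipped.
* Greedy identity clustering is order-dependent by construction; the
  package fixes the order rather than removing the dependence.
* The expression model assumes adapter-free reads and ignores
  modification-induced misincorporations, which in real tRNA-seq data
  bias coverage along the body.
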