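# cystra

Structure, variability and expression of tandemly repeated tRNA gene
clusters, modelled on the *Arabidopsis thaliana* tRNA-Cys-GCA system.

## What it is for

Plant genomes carry small clusters of near-identical tRNA genes — in
*A. thaliana*, a chromosome 5 array of ~420 bp tandem units each holding
one tRNA-Cys-GCA gene, plus two-gene mini-clusters elsewhere. Comparing
such clusters across accessions raises a chain of small but exacting
computational problems: delimiting clusters from annotations, cutting a
cluster into its repeating units, deciding whether length differences
between accessions are whole-unit gains/losses or partial deletions,
grouping corresponding units across genomes, counting mature tRNA
sequence variants, checking which variants still fold a canonical
cloverleaf, and — because the gene copies are nearly identical —
quantifying expression from small-RNA reads in a way that only credits a
specific gene copy when unprocessed precursor reads (retaining genomic
leader/trailer) demand it. `cystra` packages this chain for genome
biologists and anyone analysing multi-copy small-RNA loci, together with
seeded synthetic genomes and read libraries that make every stage
testable offline.

## The core methods

* **Identity statistic.** All comparisons use the percent identity of the
  optimal global alignment: affine-gap Needleman–Wunsch (Gotoh), match
  +5, mismatch −4, gap open 10, gap extend 0.5, end gaps free, with
  `identity = 100 · matches / alignment columns` (gap columns in the
  denominator). Verified against exhaustive enumeration and an
  independent affine-gap implementation.
* **Unit decomposition and events.** Units are anchored at gene starts
  (gene + downstream spacer). Accession units are matched to a reference
  accession greedily by identity; unmatched reference units are
  whole-unit deletions, surplus units insertions, and a length residual
  smaller than a unit signals a partial deletion with
  `size = unit length − residual`.
* **Unit grouping.** p-distances `(100 − identity)/100` feed a
  Saitou–Nei neighbor-joining tree; branches longer than 0.03 are cut
  and the remaining leaf components are the groups (the tree-cut form of
  the 97% identity convention).
* **Variant analysis.** Exact deduplication of mature bodies;
  USEARCH-style greedy centroid clustering at 97% identity; stem-mispair
  assessment that transfers the cloverleaf pairing (acceptor/D/
  anticodon/T stems) through an alignment, tolerating G·U wobble.
* **Expression.** Unique-read collapse → inclusive 55–110 nt filter →
  contamination matcher → Smith–Waterman best-hit assignment against
  mature (body+CCA) and precursor (leader+body+trailer) references, with
  gene-level assignment only for unique maxima and variant-level rescue
  for ties within one variant → trimmed-mean-of-M-values (TMM)
  normalization (verified against edgeR to 1e-6) → control vs deacylated
  contrast (`charged` when deacylated > control).
* **Auxiliary scans.** Helitron terminal signals (TC, CTRR, CTAG[TC]),
  exhaustive 3'-window hairpin search, and in-silico PCR with
  gel-equivalent product sizes.

## Worked example

```r
library(cystra)

panel <- makeClusterPanel(clusterSpec())          # 4 synthetic accessions
units <- lapply(names(panel$accessions), function(acc) {
  r <- extractClusterRegion(panel, acc)
  decomposeCluster(r$region, r$genes, accession = acc)
})
up <- buildUnitPanel(units)
up
#> UnitPanel: 4 accessions, 18 units in 7 groups; reference 'bigSix'
#>   colLike: groups [1 2 3 4]
#>   lerLike: groups [1 2 3 4 5]
#>   bigSix: groups [1 2 3 4 5 6]
#>   cviLike: groups [1 2 7]

callStructuralEvents(up)
#>   accession                kind affected_units size
#> 1   colLike whole_unit_deletion              5  420
#> 2   colLike whole_unit_deletion              6  420
#> 3   lerLike whole_unit_deletion              6  420
#> 4   cviLike    partial_deletion            3,4  167
#> 5   cviLike whole_unit_deletion              5  420
#> 6   cviLike whole_unit_deletion              6  420
```

Reading the output: the six-unit accession is the reference; the
four- and five-unit accessions differ from it only by whole 420 bp
units, while the Cvi-like accession additionally carries a 167 bp
deletion spanning the junction of units 3 and 4 (its truncated hybrid
unit is reported as a seventh group because it is no longer 97%
identical to any whole unit). In-silico PCR with the cluster-flanking
primers sizes the same panel at 2530 / 2950 / 3370 bp for 4 / 5 / 6
units — products stepping by exactly one unit length — and 2363 bp
(2530 − 167) for the deletion accession.

`runPipeline(outDir, seed = 1)` chains simulation, detection,
decomposition, grouping, variant analysis, expression quantification and
PCR, writing per-stage files, `report.json` and `summary.txt`; reruns
with the same seed are bit-identical.

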