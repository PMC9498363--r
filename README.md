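# nuptscan

Detection and characterization of organelle-to-nucleus DNA transfers
(intracellular gene transfer, IGT) in genome assemblies.

Plastid genomes continually shed DNA into the nucleus; the integrated
copies — NUPTs (nuclear plastid DNAs; NUMTs for mitochondrial donors) —
then diverge by mutation. Recent insertions are nearly identical to the
donor plastome, older ones less so, and how much of this content an
assembly contains depends on both the biology and on how well the assembly
resolved the repeat-rich regions where insertions concentrate. `nuptscan`
is for researchers who want to quantify that landscape reproducibly:
find the insertions, bin them by age and size, place them relative to
genes and transposable elements (TEs), profile their flanks, and compare
assemblies of the same taxon.

## What it computes

* **Homology search** — seed-and-extend local alignment of an organellar
  query against each nuclear chromosome, both strands: exact 11-mer seeds,
  gapped x-drop extension (match +2, mismatch −3, gap of length *L* costs
  5 + 2*L*, x-drop 20), banded global rescoring for match counts, and
  Karlin–Altschul significance *E* = *K m n* e^(−λ*S*) with λ = 0.625,
  *K* = 0.41, cutoff *E* ≤ 10⁻⁶. Externally computed 12-column tabular
  alignments can be imported instead.
* **Classification** — identity bins [80, 95) and ≥ 95 (older vs recent
  transfers); size classes < 100, 100–500, 500–1000, ≥ 1000 bp; overlap
  merging; per-chromosome counts and relative lengths; link-table export
  (length ≥ 100 bp, identity ≥ 80, highlight ≥ 95).
* **Genic context** — exact per-base partition of each chromosome into
  exon / intron / intergenic from a GFF3, per-region insertion counts,
  bases and TE content.
* **Flanks** — GC and TE content inside each insertion and in pooled
  flanking windows of 100/500/1000/2000 bp per side, with end-clipping and
  N-run flags.
* **Assembly comparison** — `igt_index`, the unioned bp of ≥ 95%-identity,
  ≥ 100 bp insertions per Mb of assembly, plus cell-wise deltas between
  versions.
* **Synthetic worlds** — simulated chromosomes with implanted plastome
  fragments of controlled identity, length and placement, gene/TE
  annotations and a ground-truth table, so the whole pipeline is testable
  offline.

## Worked example

```r
library(nuptscan)

w    <- build_world(implant_spec(seed = 42))      # 30 implants, known truth
hits <- nupt_search(w$plastome, w$chromosomes)    # E <= 1e-6, both strands
ins  <- merge_hits(hits)                          # union overlaps per bin

head(hits[, c("sid","sstart","send","strand","aln_len","identity","score","evalue")], 4)
#>    sid sstart  send strand aln_len identity score        evalue
#> 1 chr1  11106 11711      -     605 97.35537  1130 1.404684e-297
#> 2 chr1  15687 18227      +    2540 98.66142  4910  0.000000e+00
#> 3 chr1  20754 21645      -     891 97.30640  1662  0.000000e+00
#> 4 chr1  36980 39961      -    2981 97.14861  5537  0.000000e+00

subset(summarize_by_chromosome(ins, w$chrom_lens), id_bin == "hi95" & count > 0)
#>     sid id_bin size_class count total_len rel_len_pct
#> 1  chr1   hi95     ge1000     3      8175   2.7250000
#> 3  chr1   hi95   s100_500     6      1452   0.4840000
#> 4  chr1   hi95  s500_1000     8      6295   2.0983333
#> 9  chr2   hi95     ge1000     7     11765   3.9216667
#> 11 chr2   hi95   s100_500     4       988   0.3293333
#> 12 chr2   hi95  s500_1000     2      1869   0.6230000

igt_index(ins, sum(w$chrom_lens))
#> [1] 50906.67            # bp of recent insertions per Mb of assembly
```

Every hit lies on a simulated implant: the coordinates are 0-based
half-open nuclear spans, `identity` is percent matching columns of the
optimal alignment (all ≥ 95 here because the world implants recent
transfers), and the summary shows how counts skew to short insertions
while long ones dominate the transferred length. `region_summary()`,
`flank_table()` and `compare_versions()` continue from these objects; the
truth table `w$truth` gives the implanted ground truth for validation.

`run_all()` drives the same stages from a YAML config and writes
`hits.tsv`, `insertions.tsv`, `chrom_summary.tsv`, `region_summary.tsv`,
`flanks.tsv`, `links.tsv` and `report.json`; a thin command-line front end
is installed at `inst/scripts/nuptscan.R` (subcommands `run`, `scan`,
`simulate`).

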