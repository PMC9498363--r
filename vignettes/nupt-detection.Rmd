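---
title: "Detecting and characterizing organelle-to-nucleus DNA transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing organelle-to-nucleus DNA transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuptscan)
```

## The problem

Plastid and mitochondrial genomes continually shed DNA into the nucleus.
The plastome-derived copies (NUPTs) integrate, then decay by mutation, so
the nuclear genome carries a mixture of recent, nearly identical insertions
and older, diverged ones. Because these segments look organellar, assemblers
historically discarded or collapsed them; how much NUPT content an assembly
recovers therefore tracks both the biology of ongoing transfer and the
technical quality of the assembly, especially in the repeat-rich intergenic
regions where most insertions land. `nuptscan` implements the full
desk-scale workflow: find the insertions, age- and size-bin them, place them
relative to genes and transposable elements (TEs), profile their flanks, and
compare the resulting landscape across assembly versions.

## Detection model

Detection is local alignment of a single organellar query against each
nuclear chromosome, both strands, via seed-and-extend:

* exact k-mer seeds (`word_size = 11`, k-mers containing `N` excluded),
  skipping seeds already covered by a prior extension on the same diagonal;
* gapped x-drop extension outward from each seed with affine gaps: match
  $+2$, mismatch $-3$, a gap of length $L$ costing $5 + 2L$; extension stops
  when the running score falls more than `x_drop = 20` below its maximum;
* the clipped spans are then rescored by a banded global alignment with the
  same scoring scheme, which yields the match/mismatch/gap-column counts
  behind percent identity ($100 \cdot \mathrm{matches}/\mathrm{columns}$);
* significance is the Karlin–Altschul E-value
  $E = K\,m\,n\,e^{-\lambda S}$ with query length $m$, total subject length
  $n$, defaults $\lambda = 0.625$, $K = 0.41$, and cutoff
  $E \le 10^{-6}$.

The scoring scheme and $\lambda, K$ are package defaults chosen to mirror
classic megablast-style nucleotide search; only the E-value cutoff is a
fixed analysis convention. All are exposed through [search_params()].
Low-complexity masking is deliberately not implemented; on low-complexity
genomes counts will be more permissive than a masked search, and the
`max_pos_per_kmer` subsampling guard is the only repeat protection.

Two behaviors worth knowing about: the query is treated as linear (an
alignment crossing the circular origin is reported as two hits; rotate the
query if that matters), and hits sharing an identical subject span and
strand — typically the two inverted-repeat copies of a plastome hitting one
nuclear locus — are collapsed to the best-scoring one so nuclear bases are
not double-counted (`collapse_ir = FALSE` restores every copy). Like any
local aligner, an extension may absorb a few chance-matching bases beyond
the true insertion boundary; this shortens no insertion and perturbs
identity by well under a percentage point.

## Binning and summaries

Percent identity splits insertions into `mid80_95` ($[80, 95)$, older
transfers) and `hi95` ($\ge 95$, recent transfers); identity below 80 is
outside the analysis. Lengths split into `lt100`, `s100_500`, `s500_1000`,
`ge1000`. Interval edges are left-closed with 1000 bp in the top class; the
conventional phrasing of these bins leaves exact edge membership open, so
both edge sets are arguments with these defaults. Overlapping hits in the
same identity bin can be unioned into insertions (`merge_overlaps`, the
default) or kept per hit; relative length per chromosome is always computed
on the union of spans so no nuclear base counts twice. Link-table export
applies the display convention (length $\ge 100$ bp, identity $\ge 80$,
highlight at $\ge 95$) without affecting summaries.

## Genic context and flanks

From a gene/exon annotation the package derives a strict per-base partition
of each chromosome: exon, intron (gene bases not covered by any exon —
where isoforms disagree, exon wins), and intergenic (complement of merged
gene spans). The partition is asserted exactly at construction. Insertions
straddling a boundary have their bases split exactly; counts default to
intersect-style semantics (one count per region touched), with a
majority-region mode as the alternative since either reading of "number per
region" is defensible.

Flank profiles take windows of 100/500/1000/2000 bp on each side, clipped
at chromosome ends (and flagged when clipped). GC is `(G+C)/(A+C+G+T)` with
`N` excluded from the denominator; the two flanks are pooled into one GC
value per size (per-side values are also emitted), and a flank whose
longest `N` run exceeds half the window is flagged low-confidence. TE
content counts each annotated TE feature once per window touched, while TE
bases use self-merged intervals. Any TE interval file is accepted (GFF3 or
BED); the package is agnostic about which TE-annotation output produced it,
since structural TE classes are irrelevant to these statistics.

## Comparing assembly versions

The `igt_index` operationalizes the idea that recent NUPT content scores
assembly completeness: it is the unioned length of insertions with identity
$\ge 95$ and length $\ge 100$ bp per Mb of assembly. The thresholds mirror
the headline identity/length bin and are arguments, and the index is a
package-defined quantity, not an established standard. Its justifying
property — replacing implanted bases with `N` can never raise it — is
enforced by simulation tests. `compare_versions()` reports cell-wise deltas
of count, length and relative length per (chromosome x identity bin x size
class), with an optional chromosome name map between versions.

## What the simulator does and does not emulate

[build_world()] generates uniform-random chromosomes (0.36 GC) and a
uniform-random 30 kb "plastome" (0.37 GC), lays down non-overlapping
multi-exon genes and TE intervals, and writes mutated plastome fragments
over background bases (coordinates never shift). The reference world holds
30 implants — ten each in the three classes of at least 100 bp, with
lengths drawn from 120-450, 550-950 and 1050-3000 bp so that end-trimming
cannot flip a size class — at identity targets uniform in 96-100%,
emulating the empirically dominant recent-transfer fraction. Implants stay
200 bp apart and 4 kb from chromosome ends so the largest flank windows are
never clipped; placement can instead be constrained to exon/intron/
intergenic windows or biased toward TE neighborhoods.

Deliberately not emulated: real plastome gene content and codon structure,
TE sequence (intervals over random sequence suffice for interval
statistics), segmental duplications, and low-complexity sequence. Passing
tests on these worlds therefore demonstrate correctness of the alignment,
binning and interval arithmetic under known truth — not robustness to
repeat families or compositional bias in real assemblies.

## Numerical and design choices

* All internal coordinates are 0-based half-open; conversion to the 1-based
  inclusive conventions of GFF3, tabular alignment files and link tables
  happens only in the I/O layer, so boundary conversion is a single
  audited code path.
* Non-`ACGTN` characters in input FASTA become `N` with a warning rather
  than an error, since real assemblies contain IUPAC codes.
* Every seed is extended (no two-hit heuristic): desk-scale genomes make
  exhaustive extension affordable and simpler to verify. Determinism is
  absolute: equal inputs and parameters give byte-identical outputs, and
  `run_all()` stamps outputs with the seed and a hash of the effective
  configuration (output location and verbosity excluded).
* The per-hit scores are integers; ties during inverted-repeat collapsing
  break toward the lowest query coordinate for reproducibility.
* `mutate_to_identity()` uses exact substitution arithmetic
  (`round(L * (100 - t) / 100)` events), so identity-bin boundary cases are
  exact rather than stochastic; realized identity is recomputed by global
  realignment whenever indels are requested.
* Problem sizes in the test-suite worlds (two 300 kb chromosomes, 15-30 kb
  queries, 20 paired degradation worlds of 120 kb) were chosen as the
  smallest sizes at which random seed matches stay far below the E-value
  cutoff while whole-suite runs stay interactive.

## Known limitations

Ancient, heavily diverged insertions below 80% identity are invisible by
construction, and insertions shorter than the seed length or lacking any
exact 11-mer match to the query are missed. Counts are sensitive to the
absence of dust-style masking. The pipeline analyzes one organellar query
per run; mitogenome queries work identically, but nothing
mitochondrion-specific (e.g. shared plastome-mitogenome segments) is
modeled. Distinguishing biological insertion differences from
assembly-method differences is out of scope for the comparison module; it
reports deltas, not their cause.
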