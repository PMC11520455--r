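---
title: "Methods: synteny assembly, depth statistics and the clade simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny assembly, depth statistics and the clade simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CladeSynteny)
```

This vignette documents the models and procedures the package
implements, the parameters that matter, the numerical choices made at
points where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## The input model

The package operates downstream of a multi-genome alignment. A liftover
step projects a reference region onto each other genome and exports
pairwise alignments as 21-column PSL records — the atomic unit here.
PSL is 0-based half-open with negative-strand query block starts in
reverse-complement coordinates; `PslAlignments` stores records
bit-faithful to the file and converts only in accessors. Everything
else in the package lives on IRanges/GRanges, i.e. 1-based closed
coordinates, the native convention of the containers used; conversions
happen exactly once, at the format boundary. Emitted TSV tables are
1-based closed (GFF-like); BedGraph output is 0-based half-open as that
format requires.

GFF3 is read through rtracklayer and collapsed to one model per gene
(isoform sub-features unioned per type). The guide tree (newick, via
ape) fixes the track order of every plot: the left-to-right leaf order
of the tree as written, which puts sister taxa on adjacent tracks and
makes "links between adjacent tracks" meaningful.

## Fragment assembly and filtering

Liftover output fragments at every indel. Assembly reverses this:
records are grouped by (target sequence, strand), sorted by target
start, and chained while the target gap to the running chain end is at
most the **gap value** (default 200 bp, the package-wide default for a
typical gene-sized query; larger queries warrant larger gaps). Gaps are
measured on the target axis only: the upstream liftover is
target-ordered, and requiring query colinearity would break assembly
around small rearrangements. Overlapping and abutting records always
merge. The chain rule equals the transitive merge closure for intervals
on a line, which is what the test oracle exploits.

The **filtering percentage** (default 16) retains a fragment iff its
target-span extent is at least that percentage of the query length.
Both comparisons are inclusive ("minimal length to be included").
Fragment length means span extent, not aligned-base count: the
assembled object is a contiguous region of the target genome; the
aligned-base count remains available in the aggregates.

Per species, the longest retained fragment is **primary**, with ties
broken by larger aggregate matches and then smaller target start — the
paper-of-record for this pipeline leaves ties unspecified, and a total
order is required for reproducibility. Fragments overlapping any gene
the primary overlaps are **co-gene**; the rest are **secondary**,
labelled "(filtered)", and typically reflect paralogy. The optional
full-genes extension widens a fragment to the union of the spans of all
genes it overlaps, iterated to a fixpoint so the operation is
idempotent; alignment aggregates are deliberately untouched.

## Synteny links

For each adjacent pair of display tracks, pairwise alignment blocks are
restricted and clipped to both species' displayed fragments, then
merged transitively with the gap condition required **on both axes**.
Assembly's target-only rule is not symmetric under exchanging the
pair's query/target roles, and a link set should not depend on which
species happened to be the liftover query; the two-sided rule restores
that symmetry (verified by a test that transposes the PSL). Clipping to
the displayed fragments is the default and exposed as a flag, since a
case can be made for drawing links at full alignment extent.

## Synteny depth

Depth at a reference base is the number of alignment **blocks** covering
it — not the number of distinct species. Counting blocks is what makes
anciently duplicated genes exceed single-copy genes in depth (each copy
aligns to two orthologs per species), the signature the gene-class
summaries look for. Reference self-alignments are excluded: depth is
meant to measure conservation across species, and including paralogy of
the reference with itself would conflate the two signals.

Window summaries use non-overlapping 20-kb windows by default, with a
trailing partial window averaged over its true width. Feature-class
summaries assign each base exactly one class by the precedence
exon > 5'UTR > 3'UTR > intron > intergenic, where "exon" means
CDS-bearing exonic bases (disjoint from the UTR classes, which are
listed separately); overlapping genes are resolved by the same per-base
precedence, and per-gene summaries then sum the globally classified
bases within each gene span, so a base under two genes contributes to
both genes' summaries but to one class only. A trend line over the
window dots (e.g. a GAM smoother via `ggplot2::geom_smooth(method =
"mgcv::gam")`) is a plotting concern, not part of the numeric API.

## Paralog scores and parent/daughter calls

The alignment score is `matches + repMatches − misMatches − qNumInsert −
tNumInsert`, evaluated on records or on assembled-fragment aggregates;
because aggregates are member sums, the score is linear under merging.
"Normalised to the length of the paralog" is implemented as division by
the paralog's annotated gene length, reported per kb — the standard
reading of that phrase; both raw and normalised values are always
reported so either can be inspected. The parent call averages the
normalised score across partner species by default (configurable to
raw): normalisation removes the trivial advantage a longer paralog has
in raw score. Ties and paralogs without alignments return
"undetermined" with a reason rather than a guess.

## Duplication-size statistics

Events below 50 bp are excluded (mirroring the analysis this module
reproduces); the exclusion count is reported. Default size bins are 50,
100, 250, 500, 1000, 5000, ∞ bp — the reproduced figure does not print
its bin edges, so the bins are configurable and these defaults simply
span the plausible range log-ish. The sister-species comparison is a
standard paired t-test over per-bin counts. Degenerate inputs are
handled explicitly rather than crashing: identical vectors give t = 0,
p = 1; constant non-zero differences (zero variance) give t = ±Inf,
p = 0, flagged `degenerate`.

## The clade simulator

The generator works entirely at the coordinate/event level; no
nucleotide is ever materialised. Each gene copy carries a **homology
map** to its ancestral coordinates — matched intervals plus anchored
insertions, deletions implicit — and the exact pairwise alignment of two
copies is the intersection of their matched intervals, split wherever
either copy has an indel. That is precisely where a liftover breaks its
blocks, so assembling the emitted records under a gap value at least the
indel size reconstructs one fragment per ortholog by construction.
Substitutions accumulate as expected per-base divergence (branch length
× rate, with mild Gamma(40, 40) noise so leaves are not perfectly
clock-like); the divergence of a pair is the sum of the loads since
their lineages split, computed from per-node snapshots, and is turned
into mismatch counts deterministically. Pairs above a divergence
ceiling (default 0.35) are not emitted at all, emulating liftover
mapping failure on highly diverged sequence — this dropout is what
drives young, fast-evolving duplicates below single-copy depth.

Default study conditions: 5 species on the tree
`(((S1:1,S2:1):1,(S3:1,S4:1):1):1,S5:3)`, 100 genes of 2–6 exons
(80–300 bp) with 50–200 bp introns and 500–3500 bp intergenic gaps
(≈300 kb genomes), substitution rate 0.02/bp per unit branch length
(ortholog divergence ≈0.04–0.12 across the tree), 0.5 indels per copy
per unit length sized uniformly 10–150 bp, duplication rate 0.004 with
70% tandem placement and +0.12 daughter divergence, inversion rate
0.01, loss rate 0.003, and a 2% annotation-gap probability per gene in
non-reference leaves. These values were chosen once as a plausible
small-clade regime: enough fragmentation that assembly has work to do
(≈30% of single-copy queries are multi-fragment everywhere at gap 0,
all single-fragment by gap 150), and enough duplication/loss that every
downstream module sees its cases. Two generator choices are worth
making explicit:

* **Loss and annotation-gap events are drawn only from copies that are
  single-copy in their genome at the time.** Synteny-based
  missing-ortholog flagging is identifiable only when no retained
  paralog alignment covers the query; restricting the events keeps the
  ground truth unambiguous, which is what a perfect-precision test
  requires. Real data contain the ambiguous cases too — the detector
  still reports them, but no test claims it classifies them correctly.
* **Co-anchored insertions coalesce** into one event, so inter-fragment
  target gaps equal single indel sizes almost always. A deletion on one
  lineage overlapping an insertion on another can still compound into a
  larger gap; the re-assembly guarantee is therefore exercised at the
  top of the sweep grid (gap 1000 ≥ max indel 150), where compounding
  would require an implausible pile-up of events.

Epoch-specific experiments configure the generator as the analysis
demands: the depth-ordering experiment forces ancient duplications
(daughters nearly neutral, +0.02) and recent reference-branch
duplications (daughters +0.5, beyond the mapping ceiling, so they drop
out of the liftover); the parent/daughter experiment forces one recent
duplication at +0.15, diverged at least twice as far as the parent yet
still mappable. The golden fixture keeps the moderate default (+0.12)
so secondary alignments actually appear in plots and filtering tests.

What the simulator does **not** emulate, and hence what passing tests
cannot show about real data: nucleotide-level alignment error and
low-complexity artefacts; partial-gene duplication and gene fusion;
translocation between chromosomes (each species is one chromosome);
segmental duplications spanning several genes; intergenic alignment
(records are gene-anchored, so intergenic depth is zero by
construction); and annotation dialect quirks beyond plain GFF3.

## Problem sizes and numerical choices

The tests and the acceptance script run the golden clade (5 species,
100 genes, seed 42), 1000 random ≤8-record assembly instances against a
brute-force merge-closure oracle, and 50-replicate experiments at 24 and
12 genes — sizes chosen so the full ground truth is enumerable and the
whole suite stays desk-scale. Threshold comparisons are inclusive;
primary ties are broken deterministically; orthogroup plot colours are
assigned by hashing the orthogroup id, so figures are reproducible
across sessions. Degenerate inputs (empty PSL, empty annotation, a
species with no retained fragments, orthogroups absent from a species)
are legal and produce empty—but typed—results rather than errors.

## Known limitations

Query-side chaining (`gap-axis query` or `both`) is not implemented;
the target-only rule is the one the upstream liftover semantics
justify, and the links module already provides the symmetric two-sided
variant. Whole-copy inversion is the only rearrangement class inside a
gene. The detector reports, but cannot resolve, missing orthologs whose
syntenic interval is covered by a paralog's alignment. Scores compare
paralog pairs; families of three or more copies must be compared
pairwise.
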