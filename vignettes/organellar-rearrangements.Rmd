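---
title: "Detecting recombination-driven instability in organellar genomes"
author: "orgRecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination-driven instability in organellar genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgRecomb)
```

## The biological problem

Plant mitochondrial genomes are circular, repeat-rich and recombinogenic.
Recombination between the two copies of a *direct* repeat on the circle can
loop out a subgenomic circle; if that circle replicates autonomously, the
regions it carries change copy number relative to the rest of the genome
("substoichiometric shifting"). Repeats fall into functional size classes:
large repeats (> 500 bp) recombine frequently and reversibly,
intermediate-size repeats (50–500 bp) recombine rarely — unless the
machinery that suppresses or resolves ectopic recombination (branch
migration factors, mismatch surveillance) is compromised, as in several
Arabidopsis recombination mutants. The chloroplast genome adds a wrinkle:
its two large inverted-repeat copies interconvert the genome between two
isomers ("flip-flop"), a normal feature that a rearrangement scan must
ignore.

Three read-level signals diagnose this biology in paired-end sequencing
data, and the package implements all three against a simulated or real
library:

1. **Coverage stoichiometry** (`binCoverage()`, `compareProfiles()`):
   per-kilobase depth, normalized per million library reads, compared
   between a sample and a control on a log2 scale. Regions amplified or
   depleted by subgenome replication appear as runs of flagged bins whose
   boundaries coincide with the copies of a repeat pair.
2. **Soft-clip junctions** (`detectJunctions()` and its parts): a read that
   crosses the junction of a rearranged molecule aligns partially, leaving
   a soft clip; remapping the clip locates the partner locus. Events are
   binned to 1 kb and counted by supporting reads.
3. **Crossover configurations** (`classifySpanningPairs()`,
   `relativeAccumulation()`): around a direct repeat pair, read pairs
   anchored in the unique flanks distinguish the parental arrangements
   (1/1, 2/2) from the crossover products (1/2, 2/1) — the sequencing
   analog of qPCR with primers flanking each repeat copy.

## The simulated world

`buildMixture()` + `simulateReads()` generate libraries with complete
ground truth, so every stage of the pipeline is testable without external
data. The generator emulates:

* a master circular genome (any sequence; test worlds are uniform random
  circles with planted exact repeat pairs);
* recombination products derived from it — loop-out circles and their
  remainder circles (direct repeats, via `predictProducts()`),
  inverted-segment isomers (inverted repeats, via `invertSegment()`), and
  arbitrary chimeric fusions — each at a chosen relative copy number
  (weight) per master-genome copy;
* a 2 × 150 bp paired-end run: fragments drawn proportional to
  weight × molecule length, starts uniform on each circle, lengths
  normal(400, 50) redrawn into [read length, 3 × mean], one forward and
  one reverse-complement read per fragment, i.i.d. substitution errors
  (default 0.002/base), constant Q40 qualities.

The number of fragments is `round(depth × total_weighted_length /
(2 × read_length))`. Because fragments are allocated proportionally, this
makes the *master's* expected fold coverage equal `depth` regardless of how
many subgenomes are present.

The generator deliberately does **not** emulate: indels (the junction
filter discards indel-containing records, so simulating them adds nothing
testable), sequencing-machine error profiles, GC or position bias, optical
duplicates, or nuclear genome contamination (including nuclear copies of
organellar DNA). A green test therefore establishes correctness of the
pipeline's logic on substitution-only, bias-free data — not robustness to
every artifact of real libraries. With real data the alignment can come
from any external aligner through `readSam()`.

## The micro-aligner

Small organellar genomes do not need a production aligner, but the
pipeline needs deterministic, circular-aware placements. `alignRead()`
seeds on exact 31-mers against the doubled genome sequence and extends
without gaps in both directions while the running mismatch rate stays
≤ 4%; unextendable read ends become soft clips, blocks never end on a
mismatch, and placements shorter than 30 aligned bases are unmapped.
The best score (aligned length − 2 × mismatches) wins; among ties the
longer block, then the leftmost, then the plus strand; *exact* ties
(reads inside repeat copies) are resolved uniformly at random from the
session RNG and reported `is_unique = FALSE` / MAPQ 0. Random tie-breaking
keeps coverage unbiased across repeat copies; uniqueness gates junction
anchors and crossover counting.

One consequence worth knowing: at a junction, extension can run a few
bases past the true breakpoint on chance matches (≈ ¼ per base, bounded by
the mismatch-rate rule), so clip boundaries carry a few base pairs of
fuzz. At the pipeline's 1-kb event resolution this moves an event by at
most one bin, and all boundary-matching logic (region annotation,
isomerization filtering, truth matching in tests) uses a ± 1 bin
tolerance for exactly this reason.

## Numerical and design choices

* **Binning.** Bin *b* covers positions (b−1)·1000+1 … b·1000
  (`positionToBin()` = ceiling(pos/1000)); the last bin may be short and
  its mean depth uses its true width.
* **Normalization.** `normalized_depth = mean_depth × 1e6 / totalReads`.
  In real whole-plant libraries the organellar fraction is small, so
  "per million total reads" leaves unchanged regions comparable between
  samples. A purely organellar *simulated* library breaks that premise —
  an amplified subgenome inflates the library itself — so `runPipeline()`
  normalizes both libraries by a fixed nominal library size (10^6 by
  default, `nominalLibrarySize = NULL` to use true read counts for real
  whole-library data).
* **Pseudocount.** Log2 ratios add the normalized-depth equivalent of a
  single 150-bp read per bin to numerator and denominator, so empty bins
  stay finite; with tens of reads per bin it is negligible.
* **Flag threshold.** |log2| ≥ 1 (two-fold) by default; observed
  stoichiometry changes run from ~2-fold to > 20-fold, so two-fold is the
  sensitive end, and the threshold is a parameter.
* **Clip filter.** Soft clip ≥ 20 nt and no I/D/H anywhere in the CIGAR.
  Both clips of a doubly-clipped read are processed independently.
  Clip remapping is strict: the entire clip must align end-to-end within
  the mismatch bound at a unique position, or the clip is dropped (and
  counted) — the equivalent of remapping clips with an end-to-end aligner
  and discarding partial or ambiguous placements.
* **Event identity.** Events are keyed by (anchor bin, clip bin,
  orientation) with the bin pair canonicalised so anchor ≤ clip: the two
  read orientations across one junction merge into a single event.
  Orientation is read off the clip's remap strand (the stored read is
  always reference-forward over the anchor, so a "+" clip placement means
  a same-strand fusion).
* **Detection envelope.** A crossover junction across a repeat of length
  r is visible to soft-clip analysis only if one read can span the repeat
  plus a minimum anchor (30) and a minimum clip (20):
  r ≤ 150 − 30 − 20 = 100 bp with default parameters. A 60-bp repeat is
  detectable; 127-bp and larger are not — their products still register
  through coverage stoichiometry and spanning read pairs, which is why the
  three signals are complementary.
* **Flip-flop invisibility.** For an *exact* large inverted repeat, a read
  crossing an isomer junction is a perfect contiguous reverse-complement
  match to the master genome, so the isomer produces *no* soft-clip signal
  at all (short reads cannot distinguish the two isomers without spanning
  an entire repeat copy); in addition, any anchor lying wholly inside a
  repeat longer than the read is non-unique and is excluded. The
  isomerization filter (`filterIsomerization()`) therefore matters for
  real data — near-identical repeats, permissive external aligners, reads
  assigned across IR copies — and is specified at binned resolution: an
  opposite-strand event whose bins lie within one bin of corresponding
  boundaries (inner/inner or outer/outer) of a large (> 500 bp) inverted
  pair is flagged and excluded. Tests verify both the filter's contract on
  constructed events and the seamlessness of simulated isomers.
* **Events per genome copy.** Total supporting reads of retained events ÷
  mean per-base depth (mean of the per-bin mean depths). This
  operationalizes "rearranged molecules per genome copy"; it is isolated
  in `eventsPerGenomeCopy()` so an alternative normalization can be
  swapped in.
* **Crossover flanks.** Flanks default to two read lengths (300 bp): a
  mate must lie wholly inside a flank, and a flank of exactly one read
  length would admit a single placement (measure zero). The count
  normalizer is the informative-fragment total N (assay-local, like qPCR
  normalization against co-amplified references); the ½ continuity
  correction keeps log2 ratios finite for products absent from one sample,
  at the cost of shrinking extreme ratios toward zero by up to ~1 log2
  unit at small N.
* **Configs in JSON.** Pipeline configurations are JSON
  (`readRunConfig()`), matching the manifest format and avoiding an extra
  dependency.
* **Repeats.** "Repeat pair" means *exact, maximal, non-overlapping*
  copies ≥ the search threshold (≥ 20 bp hard floor against microhomology
  explosion; 50 bp default, the conventional lower edge of the
  intermediate class). Planted repeats in random test genomes may extend
  by a few chance-matching bases — the maximal repeat contains the planted
  one. Mismatch-tolerant repeat families are out of scope.

## Limitations

* Ungapped alignment only: reads over indel-bearing alleles soft-clip or
  go unmapped. Consistent with the junction filter, but real indel
  polymorphism against a reference will inflate clip counts.
* No nuclear-genome awareness: with real data, reads from nuclear
  insertions of organellar DNA will map onto the organellar reference;
  filter against the nuclear genome upstream.
* Junction resolution is the kilobase bin, by design; base-pair breakpoint
  assembly and junction-microhomology scoring are out of scope.
* Crossover quantification covers direct repeats; the inverted-repeat case
  has a different flank geometry and is not quantified (its product is the
  genome isomer, detectable as such).
* Statistical testing of per-bin changes is not performed; flagged regions
  are threshold runs, matching how such scans are read in practice.
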