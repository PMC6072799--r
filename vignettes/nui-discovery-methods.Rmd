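---
title: "Methods: assembly-anchored discovery of non-reference unique insertions"
author: "nuiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly-anchored discovery of non-reference unique insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A non-reference unique insertion (NUI) is a breakpoint-resolved insertion,
relative to a reference genome, whose inserted sequence contains at least
50 bp that is non-repetitive and absent from the reference set (core
assembly plus alternative loci and patches). Short-read pipelines detect
such events poorly: the inserted sequence has nowhere to align, so the
evidence is scattered across unmapped reads, clipped alignments and
discordant pairs. `nuiscan` therefore works assembly-first: reads that
fail against the reference are re-anchored on the individual's own diploid
de novo assembly (two pseudo-haplotypes), the assembled sequence around
each read cluster is excised with long flanking anchors, and the anchors
are realigned to the reference so that the insertion and its breakpoints
can be read off directly.

The package implements the full chain — extraction, stringent
re-acceptance, clustering, anchoring, breakpoint computation, the NUI
definition filters, cross-sample merging, ARMD and repeat analysis,
orthogonal annotation, optical-map validation, and population statistics —
as composable functions plus two orchestration entry points
(`run_sample()`, `run_cohort()`).

## Coordinates

All internal coordinates are 1-based and closed, the native convention of
IRanges/Biostrings and of SAM positions. BED and BEDPE input (0-based
half-open) is converted at the boundary by `read_bed()`/`read_blacklist()`.
Using the host ecosystem's convention end to end removes an entire class
of off-by-one translations between modules; the only conversions live in
two input functions.

## Filter banks and their thresholds

Stage 1 (`select_poorly_aligned()`) selects a pair when any of the
following fires, always carrying both mates: either mate unmapped;
absolute insert size outside the library bounds; orientation other than
forward–reverse inward; per-read alignment score
$-2\,\mathrm{mm} - 3\,\mathrm{indel} - 5\,\mathrm{clipseg} -
0.5\,\mathrm{clipbase} - 4\,\mathrm{improper} \le -80$ (forty mismatches
alone reach the threshold); or more than 40 clipped bases (soft plus hard,
primary alignment). Insert-size bounds are estimated as mean ± 3 SD of the
proper-pair distribution from at most the first 100,000 proper pairs
(`estimate_insert_bounds()`); the 3-SD window mirrors common aligner
practice and is overridable. The first 23 bases of mate 1 (16 bp droplet
barcode + 7 bp low-accuracy oligo) are trimmed, and a pair is dropped when
either mate has under 70% of bases at Phred 30.

Stage 2 (`accept_stringent_realignment()`) requires, against a
pseudo-haplotype, all of: mate-1 score ≥ 90, mate-2 score ≥ 113 (mate 1 is
shorter after trimming), forward–reverse inward orientation, insert size
within bounds, both mapping qualities ≥ 30. Pairs that satisfy the same
criteria against the reference realignment are removed first
(`discard_reference_concordant()`): a pair the reference still explains
carries no insertion signal.

Clusters are maximal runs of 8–100× coverage from accepted pairs only;
positions above 100× are treated as non-cluster positions, since such
pile-ups indicate collapsed repeats rather than insertion support. Cluster
spans extend 7 kb per side (or to the contig end) into anchors; extended
intervals merging under a 200 bp gap become one anchored contig, and
contigs with more than 10 ambiguous bases are dropped.

## Breakpoint geometry

Each anchored contig end is seeded and extended against the reference;
`select_best_anchor()` ranks candidates by alignment length then identity
and rejects anchors that hit more than five loci unless the winner spans
at least 3500 bp. With a left anchor ending at reference position
$b_L$ and a right anchor starting at $b_R$, the reference overlap is
$\max(0,\,b_L - b_R + 1)$. Calls are rejected when that overlap exceeds
800 bp (such calls validate poorly against optical maps), when the
inserted sequence is shorter than 50 bp, or when the contig base just past
either anchor is an N. When the overlap $w$ is positive — the signature of
an insertion whose two ends are homologous, collapsing to one copy on the
reference — the reported breakpoint-to-breakpoint sequence includes one
copy of the $w$ shared bases at each end, matching the genetics of the
pre-deletion allele: an Alu-recombination-mediated deletion (ARMD) leaves
a single chimeric Alu on the deleted (reference) haplotype, while the
insertion allele carries two complete Alu ends whose shared segment is
exactly the overlap. Calls from the two pseudo-haplotypes merge as
homozygous when breakpoints agree within (strictly less than) 10 bp on
both sides; cross-sample merging is single-linkage under "one identical
breakpoint, or both breakpoints within (inclusive) 50 bp" — single-linkage
because the rule is a pairwise trigger and its closure is order
independent. The cluster representative is the member with the most unique
bases (ties: smaller coordinate, then smallest sample id), which makes the
catalog deterministic.

## Masking and the 50-unique-base rule

Interspersed-repeat annotation is an *input* (a RepeatMasker-style table
or equivalent); the package does not search repeat libraries, except for a
small k-mer-seeded matcher used to annotate simulated sequences
(`annotate_repeats()`). Low-complexity masking is computed internally by a
symmetric DUST implementation (`dust_mask()`): an interval with $k$
triplets and triplet counts $c_t$ scores $\sum_t c_t(c_t-1)/2 \,/\,(k-1)$,
and the mask is the union of all "perfect" intervals — score above
threshold/10 (default threshold 20) and at least the score of every
subinterval — no longer than the 64-base window. Runs of N are never
scored. The implementation enumerates intervals with incremental counts
and a dynamic program for the subinterval maxima; the test suite checks it
against an independent brute-force oracle that rescores every interval
from scratch. Unique bases are the sequence length minus the union of
repeat and DUST intervals; records under 50 unique bases are dropped.

## Alignment screens

The identity/coverage screens (known-reference at 95%/100%, translocation
at 95%/100%, primate presence and external reciprocal overlap at 95%/95%,
contaminants at 90%/90%) run over a pluggable alignment contract whose
default is a gapless seed-and-extend aligner: exact seeds at fixed stride
(batched through a `PDict` so one Aho–Corasick pass per target finds every
diagonal), then the maximal-scoring local segment on each diagonal
(match +1, mismatch −3), trimming poorly matching termini the way a local
aligner would. Identity is matches over segment columns; coverage is
segment length over query length. This gapless model is exact for the
indel-free synthetic fixtures and keeps the pipeline self-contained and
deterministic; production data with indel-divergent sequence would
substitute an external aligner emitting the same hit records. The EST
screen differs deliberately: database entries are short, so query coverage
is not required — well-matching regions of at least 30 bp (a floor chosen
to exclude spurious matches, configurable) are extracted and then
discarded if they also align to the reference.

## ARMD analysis

Among catalog entries, a flank family is assigned only when a TE interval
on the reference annotation *contains* the breakpoint. The taxonomy is
Alu/Alu, Alu/LINE (symmetric), LINE/LINE, OtherTE (any other combination
with at least one TE flank), NonTE; flanks inside simple or low-complexity
repeats count as non-TE. ARMD candidates are Alu/Alu entries with at least
10 bp of homologous overlap whose two flanking Alu features coincide or
intersect — i.e. the reference carries a single chimeric Alu. Each
candidate's chimera breakpoint maps to an Alu consensus position $p$
through the feature's consensus coordinates, and because the true
recombination point is ambiguous across the homology, each candidate adds
$1/w$ to every consensus position in $[p-w+1,\,p]$ — weight flows down
from the breakpoint, a literal reading of "subtracting the overlap from
the breakpoint position"; the direction is configurable for sensitivity
analysis. Ranges clipped at the consensus edge renormalise so each
candidate always contributes total mass 1. The consensus length defaults
to 312 bp. Hotspots are not algorithmically specified in the source
analyses (they were read off a figure), so the package makes the rule
explicit: maximal runs of positions above the mean per-position frequency,
discarding runs shorter than 10 positions.

## Optical-map validation

Only calls longer than 2 kb are evaluable (smaller events drown in
label-distance sizing error). A call is excluded when a zero-coverage map
region or any non-insertion SV call lies within 10 kb — a size change
between two labels cannot be attributed when variants stack. Precision is
supported / (supported + unsupported); a call is supported when an
insertion-type optical call lies within a window of its locus. The
matching window is not specified by the validation design, so it defaults
to the same 10 kb as the exclusion radius, configurable.

## Population statistics

`fisher_2x2()` reports the conditional maximum-likelihood odds ratio (the
estimate consistent with the exact test) alongside the sample
cross-product ratio, because the two differ in the third decimal on
real tables and consumers should see both. ANOVA and Tukey HSD use the
classical decomposition via `stats::aov`/`TukeyHSD`; the Tukey–Kramer
correction applies automatically for unbalanced populations (the bundled
cohort is 5/3/4/3/2). PCA runs on the column-centred, unscaled binary
matrix — occurrences share one scale, so variance weighting is left off by
default (a `scale.` flag exists) — after removing occurrence counts of 1
and 2 (genotype ambiguity) and of $n$ (no variance). All of these are
oracle-tested against direct-formula implementations.

## The synthetic cohort

`sim_cohort()` emulates the study design: 17 individuals from five
populations (5 AFR / 3 AMR / 4 EAS / 3 EUR / 2 SAS), 60× total coverage of
151 bp pairs with ~350 ± 50 bp inserts, a 14% ARMD fraction, 10–40 bp
homologies, and population-structured carrier frequencies so the
occurrence matrix has block structure. Genome size and insertion count are
desk-scale: by default two 150 kb chromosomes with 12 insertions plus four
filter decoys (a translocated reference copy, a low-complexity tract, a
blacklisted locus, an alt-patch duplicate). Every event is encoded as a
point insertion (position $q$, inserted string $S$); an ARMD pre-deletion
allele is exactly the reference plus
$S = \text{Alu}_\text{tail} + \text{interstitial} + \text{Alu}_\text{head}
+ \text{homology}$ inserted at the chimera breakpoint, so the anchor
overlap emerges from sequence content rather than bookkeeping. Events sit
on a coarse grid (≥ ~15 kb apart) so that 7 kb anchors of neighbouring
events cannot merge and a fragment spans at most one event; one clean
insertion is always drawn above 2 kb so the optical-validation stratum is
never empty. Junction bases are chosen to differ from their reference
neighbours, making breakpoints unambiguous and recovery exact at zero
jitter.

Read alignments are *derived*, not computed: placements follow from the
known event structure (reads inside an absent insertion are unmapped,
partial overlaps are soft-clipped, junction-spanning reads on a carrier
haplotype map cleanly), and sequencing errors enter the score and
mismatch model only. Base-call qualities are uniform except for a
configurable fraction of low-quality pairs. What passing tests show,
therefore, is that the pipeline's logic is correct under its stated
assumptions; they do not exercise alignment ambiguity in long repeats,
indel errors, assembly mis-joins, or barcode-aware phasing — all properties
of real aligners and assemblers that are outside this package's scope.

## Problem sizes

The test suite runs a three-sample cohort (two 120 kb chromosomes, five
insertions plus four decoys, 40×) end to end, a three-sample jittered
cohort for merge-tolerance behaviour, and two-sample micro-cohorts for
generator properties. The acceptance script simulates a four-sample, six-
insertion cohort at 50×. These sizes keep full runs in the tens of seconds
per sample while leaving every pipeline stage non-trivially populated
(thousands of selected pairs, clusters on both haplotypes of every
carrier).

## Known limitations

* The default anchor aligner and hit screens are gapless; indel-divergent
  anchors require an external aligner behind the same contract.
* Reverse-orientation contigs are assumed pre-oriented (the simulator
  emits forward contigs); production use would reverse-complement
  contigs whose anchors align to the minus strand first.
* Translocation and inversion breakpoints are detected only negatively
  (rejected), never called.
* The homozygous/heterozygous distinction inherits the assembly's phasing;
  the occurrence matrix is recoded to presence/absence before statistics
  precisely because homozygous calls are the least reliable stratum.
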