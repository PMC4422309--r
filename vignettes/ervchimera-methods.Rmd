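---
title: "Detecting ERV/LTR-anchored chimeric transcription: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ERV/LTR-anchored chimeric transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long terminal repeats (LTRs) of endogenous retroviruses — ERV9/LTR12 in
particular — retain U3 promoter and enhancer sequence and can initiate
transcription that runs from the repeat into adjacent unique sequence.
Such *chimeric* transcription is invisible to annotation-based
quantification: the informative reads sit half in repeat sequence (where
mapping is ambiguous) and half in unique flank. `ervchimera` detects it
from directional paired-end RNA-seq by exploiting the pair structure: if
one mate looks like LTR U3 consensus and its partner maps uniquely
elsewhere, the partner pinpoints transcribed sequence adjacent to a repeat
copy.

## The detection model

The pipeline makes three assumptions explicit:

1. **Consensus recognizability.** Genomic LTR copies have diverged from
   their family consensus, but a 30 bp read prefix still matches the
   consensus within 2 mismatches for most copies (at 5% per-base
   divergence the binomial probability is ≈ 0.81). The scan is ungapped
   over every offset of every consensus on both strands; a union of hits
   over families is kept, since downstream only needs hit/no-hit per mate.
2. **Discordance as evidence.** A pair with *exactly one*
   consensus-anchored mate is informative. Pairs where both mates anchor
   lie entirely inside repeat sequence (uninformative about flanks); pairs
   where neither anchors are ordinary transcription.
3. **Unique adjacency.** Free mates are mapped full length; only *unique*
   placements (best beats every alternative location by
   `min_unique_gap = 2` mismatches) count. Clusters of such alignments
   (single-linkage, `merge_gap = 2000` bp — the same semantics as
   `bedtools merge -d 2000`) become chimeric positions when (a) some mate
   contributes a contiguous uniquely aligned block of `min_unique_bp = 40`
   bases that does not overlap any allowed-family repeat body, (b) an
   allowed-family repeat (defaults `LTR12*`, `ERV9*`) lies within
   `repeat_link_window = 1000` bp, and (c) at least `min_support_pairs = 1`
   distinct pairs support the cluster.

Two genuinely open readings were settled as follows. The 2 kb merge step is
implemented as a gap-merge distance, not fixed genomic tiling, because the
operation is described in terms of merging alignments; gap-merge is also
idempotent, which tiling is not. The 40 bp rule is enforced per mate as a
single contiguous block rather than summed across mates: the quantity is
meant to guarantee that *one* stretch of sequence is unambiguously
non-repetitive, which a sum over fragments does not.

The caller deliberately does **not** attribute a position to a single
"causal" repeat when several are linked; all linked repeats are reported
with distances.

### The aligners

Both alignment stages are authored in C++ (Rcpp), as short-read inner
loops should be. The genomic mapper is seed-and-extend with exact 12-mer
seeds at every 12 bp plus the final window: any contiguous placement with
up to `genomic_max_mismatches + min_unique_gap = 4` mismatches disrupts at
most 4 of the ≥ 5 seed windows of a ≥ 60 bp read, so every placement
relevant to calling or uniqueness is provably discovered — the mapper and
the exhaustive oracle agree exactly on contiguous mode, and the test suite
asserts this on a thousand randomized reads.

Split (single-junction) placements are sought only when no contiguous
placement fits the budget: candidate diagonal pairs with a gap in
`[min_intron, max_intron] = [30, 500000]` bp are scored by total
mismatches, preferring canonical junction motifs at equal counts. Because
anchors may be as short as `min_anchor = 8` bp (below the main seed
length), terminal 8-mer mini-seeds discover the short-side diagonal;
mutation-free junction reads are then always recoverable, while a read
carrying a mutation inside both terminal seeds may be missed — the
heuristic's only blind spot, quantified in the tests (≥ 95% of simulated
junction-spanning reads recover the exact truth junction). Canonical means
GT..AG *or* CT..AC on the genome plus strand: under the dUTP protocol the
aligned-read strand is not the transcript strand, so the motif, not the
alignment, decides junction polarity (as splice-aware mappers do).
Uniqueness of a split placement compares distinct diagonal pairs, not ±1
shifts of the split point within one pair — otherwise every junction read
would count as ambiguous against its own jitter.

An external-alignment bypass (`read_sam()`) accepts SAM produced by any
splice-aware mapper in place of `map_genomic()`; uniqueness is then taken
from mapping quality (≥ 30).

### Coordinates

Internally everything is 1-based closed `GRanges`/`IRanges`, the
Bioconductor convention; BED and BedGraph are converted from/to their
0-based half-open on-disk form at the I/O boundary, RepeatMasker `.out`
(1-based inclusive) and SAM (1-based) map directly. Keeping the single
ecosystem-native convention removes the off-by-one surface entirely.

## Coverage, patches, loci

Strand-specific coverage uses mate-1 alignments only by default (the
forward-read convention of browser-style tracks); each aligned block
increments the transcript strand implied by alignment strand × library
orientation. Total depth equals total aligned bases exactly — a
conservation law asserted on every test input.

Patch segmentation formalizes what figures of such loci show informally:
per strand, maximal runs with depth ≥ `min_cov = 2` are taken, runs with
gaps ≤ `max_gap = 10000` bp merged (bridging introns and dips), and
patches shorter than 200 bp dropped. Patches of either strand within
`join_gap = 50000` bp chain into a *locus*; a locus is bidirectional iff
both strands contribute. These four thresholds are analysis choices, not
part of the detection method, and are exposed in the configuration.

One practical caveat the tests make explicit: because runs are merged
*before* the width filter, scattered background pileups can glue into
spurious patches when `min_cov` sits near the background depth. A polarity
analysis should set `min_cov` above the noise floor — e.g. with ~0.23×
per-strand background the locus-level checks use `min_cov = 4`, under
which background runs remain isolated and sub-width while genuine
transcripts (≥ 15×) are untouched.

## Regulatory integration

Chromatin state follows the standard two-mark rule: H3K4me3 (alone or with
H3K27ac) ⇒ promoter; H3K27ac with H3K4me3 depletion ⇒ enhancer; neither ⇒
none. Peak *presence* within ±1 kb of the target decides; signal strength
is carried for reporting only, since no principled signal threshold exists
without a matched input. Promoter-state segments (e.g. HMM chromatin-state
output) are consumed as given, never recomputed. CAGE clusters are counted
per strand within ±1 kb; clusters on both strands make an element
TSS-bidirectional. Cross-sample comparison pools positions from ≥ 2
samples and gap-merges them with the same 2 kb semantics as calling, so a
"shared locus" means the same thing in both analyses.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults define the study conditions used throughout
the tests: a 2 Mb genome in 2 chromosomes; 12 copies each of an LTR12-like
(400 bp), Alu-like (300 bp) and MaLR-like (350 bp) family planted
non-overlapping at 5% per-base substitution divergence (confidence =
realized identity); 8 active LTR12-like elements, one transcript each
(5–50 kb exonic extent, 0–4 GT..AG junctions, genomic span ≤ 100 kb), a
quarter of them also firing the opposite strand; 200,000 dUTP-style 2×76 bp
pairs (fragments 250 ± 40 bp), 20% of them uniform genomic background; and
matched H3K4me3/H3K27ac peaks, promoter segments and CAGE clusters at
active elements only, plus 5 enhancer-only decoy peaks placed away from
all elements. Canonical splice motifs are written into the genome at
simulated introns so a motif-aware mapper can recover them; the patched
genome is the reference for everything downstream.

Three simulator design choices deserve justification:

* **Active-element separation.** Active elements are chosen greedily
  subject to a minimum pairwise distance (default 160 kb ≈ 2× maximum
  transcript reach + locus join gap), so planted loci are spatially
  distinct and locus-level truth — in particular uni- versus bidirectional
  — is identifiable. When the planted copies cannot accommodate the
  requested number, the threshold is halved with a warning rather than
  failing.
* **Uniform expression.** All active transcripts get equal expression:
  no expression model is part of the method being validated, and uniform
  weights make support counts interpretable.
* **Background is signal-like.** Background pairs are real genomic
  fragments, so background mates falling inside *any* LTR12-like copy
  anchor to the consensus exactly as real off-target transcription would.
  Consequently inactive copies with adjacent background accumulate genuine
  (if shallow) chimeric evidence and are called at
  `min_support_pairs = 1`. Truth evaluation therefore scores a call as
  correct when it sits at *any* planted element (precision), while
  sensitivity is computed over transcriptionally active elements only.
  This mirrors real-data behavior — the method reports any
  consensus-matching copy with adjacent transcription evidence — and the
  support distribution in the run report is the tool for tightening.

What the simulator does **not** model: indel divergence of repeat copies,
sequencing errors and quality effects, expression gradients, nested or
fragmented repeats, and multi-sample biological variation. Passing tests
therefore demonstrate correctness of the *procedure* under clean
conditions, not robustness to every artifact of real libraries; the
external-SAM bypass exists precisely so real data can be mapped with a
production aligner.

## Numerical and degenerate-input choices

* Ambiguity codes other than N are collapsed to N on input; N never
  matches anything during alignment, including another N.
* Mates shorter than the 30 bp prefix are scanned whole; reads shorter
  than twice `min_anchor` are mapped contiguous-only.
* Ties in split placement at equal mismatches prefer canonical motifs,
  then the smallest split point — a deterministic rule shared by mapper
  and oracle.
* Zero-variance input to the correlation is an error, never NaN; with
  |r| = 1 the p-value is reported as 0 (the t statistic diverges).
* An empty position set is written as a comment-only BED; precision with
  zero calls is reported as 0 with an explicit `precision_defined = FALSE`
  flag.
* All randomness flows from a single integer seed; stage seeds are small
  fixed offsets from it. Reruns are byte-identical, including the
  pipeline manifest (config snapshot, record counts, per-file md5).

## Problem sizes used by the tests

The test suite validates modules on 200–300 kb genomes with 8,000–50,000
read pairs, runs the full default conditions (2 Mb / 200,000 pairs / seed
1) once end-to-end for recovery, and checks oracle equivalence on 1,000
randomized reads per alignment mode against 3–20 kb references; these
sizes keep a full run comfortably on a laptop while still exercising every
code path at the method's native parameter values.

## Known limitations

* Two-block (single-junction) split alignments only; at 76 bp, reads
  spanning two junctions are rare and are simply not split-mapped.
* The consensus scan approximates a quality-blind, ungapped aligner; no
  indels, no quality-aware backtracking.
* Scale factors computed by `compute_scale_factor()` are geometric-mean
  normalization — a documented stand-in; externally computed depth factors
  are consumed as data where available (as in the packaged library table).
* The promoter/enhancer rule is presence-based; no signal thresholds, no
  input normalization.
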