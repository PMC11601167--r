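---
title: "Calling non-reference TE insertions from long reads: methods and design"
author: "teilr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling non-reference TE insertions from long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The detection model

A non-reference TE insertion (TEI) is a mobile-element copy present in the
sequenced individual but absent from the reference. Against the reference,
long reads betray a TEI in exactly two ways, and `teilr` uses both jointly:

* a read that bridges the insertion aligns with a large CIGAR `I`
  operation; the inserted query bases are a (noisy) copy of the element;
* a read that enters the insertion but ends inside it is soft-clipped at
  the junction; the clipped tail is a partial element copy.

Both footprints share one reference coordinate — the insertion point —
so per-read evidence is reduced to `(position, candidate sequence,
phasing tag)` and positions are clustered per contig. The caller assumes
the input is a coordinate-sorted, indexed BAM/CRAM of *aligned* reads;
it detects only sequence that is absent from the reference, so reference
TE polymorphisms (elements present in the reference but missing from the
individual) are out of reach by construction, as are tandem-repeat
expansions (no library entry will match) and insertions whose candidate
sequences are shorter than the evidence thresholds.

Supplementary alignments are ignored: the sequence that matters for
classification lives in the soft-clipped bases of the primary record,
and split-read pairing via `SA` tags would add bookkeeping without new
sequence. Hard clips carry no bases at all and are only counted.

# Coordinates

Internally everything is 0-based half-open; an evidence or call
"position" is the 0-based insertion point, i.e. the coordinate of the
first reference base to the right of the junction. A CIGAR `I` op after
*r* reference-consuming bases of a read starting at 0-based *s* yields
position *s + r*; a leading soft clip yields the read's reference start
and a trailing one its reference end, which is why all three footprints
of one event agree. The VCF writer is the single place where 1-based
coordinates appear (`POS = position + 1`).

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `minSupportingReads` | 3 | reads | same-family matches needed to report a cluster |
| `clusterEps` | 100 | bp | DBSCAN neighbourhood radius |
| `clusterMinPoints` | = `minSupportingReads` | positions | DBSCAN core-point threshold |
| `minInsertionLen` | 100 | bp | smallest `I` op kept as evidence |
| `minClipLen` | 150 | bp | smallest soft clip kept as evidence |
| `minMapq` | 10 | — | read mapping-quality floor |
| `matchFraction` | 0.10 | fraction | min aligned fraction of a candidate |
| `matchWindowBp` | 50 | bp | evaluation-only truth-matching window |

Rationale for the values that were genuinely open choices:

* **Event-size floors (100/150 bp).** The shortest family of interest,
  Alu at ~300 bp (often 5′-truncated), must stay detectable while
  ordinary indel and alignment noise is suppressed. Clips get a slightly
  higher floor because clipped tails arise from many benign causes
  (adapter remnants, reference gaps); 150 bp still leaves half of a
  truncated Alu.
* **`clusterEps` 100 bp.** Long-read breakpoint jitter plus alignment
  ambiguity at the junction rarely exceeds a few tens of bp; 100 bp
  absorbs it while keeping nearby independent sites separate. The
  core-point threshold is deliberately tied to `minSupportingReads` so a
  single sensitivity knob (`--sr` on the CLI) moves both; a separate
  `--eps` exists because distance and count are conceptually different
  controls.
* **`minMapq` 10.** Excludes reads with essentially arbitrary placement
  in repeats — exactly where false TEI clusters would otherwise
  accumulate — without discarding the bulk of long reads.
* **`matchFraction`.** The 10 % rule is interpreted against the
  *candidate* sequence length (the "original insertion or split read"),
  not the library consensus: a full-length read-through of a truncated
  element should pass even though it covers little of the consensus.

# TE classification choices

Realignment is an external contract: any local aligner that reports
target name, query-aligned span and strand can back it. The default is
minimap2 with the `map-ont` preset — its seed/chain settings are the
more sensitive option for short (300 bp), error-rich candidate
segments, which is where Alu detection is decided — and the package
falls back to an internal Smith–Waterman (match 2, mismatch −4, gap
open 4, extend 2, reporting threshold 40) when minimap2 is absent, so
the full pipeline works, hermetically, in tests. All clusters' candidates
are batched into one aligner invocation; results are split back per
cluster, and correctness is (and is tested to be) invariant to batching.

Per candidate only the best hit votes (highest score, ties towards the
longer aligned span, then the lexicographically smaller target name — a
total order, hence deterministic). A cluster's family is decided by
per-family *distinct-read* support; the spec-level ambiguity of "three
reads match a TE" versus "three reads match the *same* TE" is resolved
towards the stricter, precision-favouring reading: the winning family
alone must reach `minSupportingReads`. Mixed-family ties break by
cumulative aligned length, then name. An optional two-column
name→family map lets a library of many subfamily consensi (AluYa5,
AluYb8, …) vote as one family; the default is the identity.

# Clustering

DBSCAN is specialised to one dimension over the sorted positions:
neighbourhood sizes come from two binary searches, consecutive core
points within ε chain into clusters, and border points attach to the
nearest core (ties to the leftmost) — a deterministic refinement of the
visit-order-dependent border assignment of textbook DBSCAN. The labels
are property-tested for equivalence against an independent brute-force
O(n²) implementation (full distance matrix, BFS expansion) over
thousands of random instances, and the package relies on the standard
consequences: every cluster has ≥ `minPoints` members and adjacent
member gaps ≤ ε.

# Refinement and genotyping

The consensus position is the *lower median* of the supporting members'
positions — always an observed breakpoint, deterministic for even
counts, robust to a stray mis-anchored clip. `insertLen` is the lower
median of the supporting members' sequence lengths; clips truncate the
element, so for calls supported mainly by clips this underestimates the
true inserted length (the VCF records it as `SVLEN` with that caveat).

Genotyping is a haplotype tally, not a likelihood model. With phasing
tags (`HP`) on the supporting reads: ≥ 80 % on one haplotype ⇒ phased
heterozygote on that haplotype; both haplotypes represented ⇒ homozygous
variant. Without tags: heterozygote by default, upgraded to homozygous
when supporting reads are ≥ 80 % of the local MAPQ-passing depth at the
consensus position. Zero local depth (possible when the region's reads
all failed filters) yields `./.` but keeps the call. The two 0.8
thresholds are declared conventions of this package, both configurable
at the function level; on clean simulated diploid data the resulting
genotype concordance with truth zygosity is ≥ 0.9 (tested).

# The simulator: what it emulates, what it does not

The benchmark generator mirrors the evaluation design of
simulation-based TEI-caller studies at desk scale: a seeded random
genome (default 5 Mb), full-length TE insertions planted at
uniform-random positions with ≥ 1 kb mutual spacing and distance from
contig ends (default 60 Alu, 60 L1, 30 HERV, 30 SVA, homozygous), a
diploid pair of haplotypes to exercise haplotype-aware genotyping, and
reads at 20× with truncated-normal lengths (mean 8 kb, sd 3 kb, min
1 kb — a PacBio-CLR-era length scale) and per-base errors of 6 %
mismatch, 3 % insertion, 3 % deletion, approximating PacBio RS II
chemistry. A `truncation` of planted elements is deliberately *not*
applied by default: the reference benchmark plants full-length copies.

Two deliberate departures from realism, and their consequences:

* **Synthetic TE consensi.** `syntheticTELibrary()` generates seeded
  random sequences at the families' canonical lengths (with poly-A
  tails) rather than real Alu/L1/SVA/HERV consensi. Real consensi are
  homologous to thousands of reference TE copies, which is what makes
  real-data TEI calling hard (mis-mapped reads, reference TE clips);
  random consensi in a random genome remove that difficulty entirely.
  Passing benchmarks therefore demonstrate the pipeline's mechanics —
  evidence, clustering, realignment, filtering, genotyping — not
  robustness to repeat-induced mapping ambiguity.
* **Direct-BAM alignment.** Instead of re-aligning simulated reads,
  each read's *generative* alignment to the un-inserted reference is
  written with an exact CIGAR (planted insertions as `I` ops, junction
  overhangs as soft clips, error indels as 1 bp ops). This makes tests
  hermetic and breakpoints exact up to error noise; a real aligner adds
  breakpoint jitter and occasional mis-placement that the direct mode
  does not model. A FASTQ is always derivable for use with an external
  aligner.

In the error-free limit with direct-BAM alignment the pipeline is
closed-form: every spanning read yields an exact-length `I` op at the
truth position, every junction read an exact clip, so sensitivity and
precision are 1.0 for every family in the library — asserted exactly in
the acceptance suite.

# Numerical and degenerate-input conventions

* Evidence, clusters and calls are totally ordered (contig, position,
  read id, kind), making every stage's output order-deterministic and
  independent of input read order.
* `dbscan1d` requires sorted input and errors otherwise; empty inputs
  yield empty outputs everywhere (an empty BAM gives a header-only VCF).
* Sequence-less records are skipped and counted, never fatal; missing
  indexes and unknown contigs are fatal with remediation hints.
* All simulation stages derive their seeds from `SimConfig@seed` by
  fixed offsets and force their arguments before seeding, so nested
  calls are reproducible and byte-identical per seed.
* Greedy truth matching in the evaluator is one-to-one by increasing
  distance with deterministic tie-breaks; a duplicate call on a matched
  truth record is a false positive.

# Problem sizes in the shipped checks

The test suite and acceptance script size their simulations so a full
run stays comfortable on a single CPU: the reference benchmark uses the
5 Mb genome above (~14,000 reads, ~3 minutes), the clean-limit check a
1.5 Mb genome with 24 insertions, and unit tests 0.1–1 Mb genomes.
These sizes are the package's reference conditions, chosen once; the
per-family counts (60/60/30/30) put binomial sampling error at roughly
±2–3 % (1 sd) on sensitivities near 0.97.

# Known limitations

* No insertion-sequence assembly or polishing: calls carry symbolic
  ALT alleles and a length estimate, not a reconstructed element.
* No target-site-duplication or poly-A measurement, no subfamily
  assignment, no transduction detection.
* Heterozygous events at low per-haplotype coverage can fall below the
  3-read same-family threshold, particularly short noisy Alu
  candidates; lowering `--sr` trades precision for recall.
* Reference TE polymorphisms and de-novo-assembly input are out of
  scope.
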