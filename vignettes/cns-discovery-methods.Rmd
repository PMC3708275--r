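---
title: "Methods: conserved non-coding sequence discovery with cnspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved non-coding sequence discovery with cnspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conserved non-coding sequences (CNSs) are islands of non-coding DNA that
diverge more slowly than functionless sequence between related species; many
act as cis-regulatory elements. In plants, non-coding sequence turns over
quickly, so CNSs are short (tens of bp) and are only credibly identified when
(a) the two genomes compared sit in a suitable divergence window, (b) the
comparison is anchored on syntenic orthologous (or homeologous) gene pairs,
and (c) candidate similarities are required to be mutually consistent in
position, order and orientation relative to the anchoring genes. `cnspipe`
implements that whole procedure as a tested pipeline over two FASTA genomes
with BED12 gene models.

## Pipeline stages and their parameters

1. **Repeat masking.** A whole-genome self-comparison (seed word 15, expect
   < 0.001 over the squared genome length) counts, per position, the number of
   distinct self-alignment hits covering it; each unordered pair of aligned
   loci counts once and the trivial self-identity alignment is excluded, so a
   sequence present in k copies reaches coverage k − 1. Positions covered by
   **50 or more** hits become `N`. Masking is represented directly in the
   sequence, so an externally masked genome can skip this stage
   (`premasked = TRUE`).

2. **Co-annotation.** Each genome is searched with the partner genome's
   spliced CDS set (word 20, expect < 0.001). Hits from one source gene
   separated by **less than 1 kb** merge transitively; merged regions with
   less than **100 bp** of hit sequence or less than **40%** hit coverage of
   the merged span are discarded. Survivors overlapping an annotated
   transcription unit become missed exons of that gene (tie-break: larger
   overlap, then leftmost gene); intergenic survivors become new genes named
   `organism_chromosome_start_stop_strand` (strand = orientation of the
   majority of member-hit bp) and join the working annotation, where they can
   anchor synteny and CNS discovery like any official gene. The stage is
   idempotent: re-running it on the augmented annotation adds nothing.

3. **Synteny.** All-vs-all CDS comparison scores anchor pairs; each pair's
   *cscore* is its score divided by the best cross-genome score involving
   either gene, and only pairs with cscore **strictly above 0.5** survive.
   Within-genome homologs separated by at most **20 intervening genes**
   collapse into tandem clusters represented by their 5'-most member (after
   CNS discovery the member with the most CNSs is retained). Anchors chain
   into blocks when successive anchors advance by at most **20 gene-order
   indices** on both genomes, collinearly (same or inverted); chains shorter
   than **4 anchors** are dropped. Blocks are then selected greedily by
   descending score under a ploidy **quota** `p:q` (e.g. `1:2` against a
   genome with a retained whole-genome duplication): no gene-order interval
   may be covered by more selected blocks than its quota (coverage is counted
   over the runs of consecutive member indices of a block, so a single
   far-flung anchor legally absorbed by a chain does not claim the whole
   intervening span). Greedy selection is
   a deliberate simplification of exact integer programming: on desk-scale
   inputs the tested contract is constraint satisfaction, and the test suite
   compares greedy against exhaustive selection on small instances.

4. **Gene-space alignment.** For every selected gene pair, windows reaching
   **12 kb** beyond each transcription unit (clipped at chromosome ends) are
   cut from the masked genomes; every annotated CDS exon inside a window —
   from any gene, official or co-annotated — is additionally masked. The
   windows are compared with a seeded local aligner: word 7, match +1,
   mismatch −2, gap of length L costs 5 + 2L, DUST-style low-complexity
   stretches excluded from seeding, both subject strands. `N` never aligns.
   Hits are converted to bits with the Karlin–Altschul ungapped constants for
   +1/−2 scoring (λ = 1.33, K = 0.621), under which a perfect gapless 15 bp
   match scores 29.5 bits (1 d.p.); hits below that threshold are discarded,
   so the 15/15 exact match is the faintest acceptable signal. Because
   29.5 is the *rounded* value of `bit_score(15)` = 29.4695…, the default
   threshold is stored as the exact quantity — a literal `>= 29.5` comparison
   would wrongly discard the boundary case the threshold is named after.

5. **Geometric filtering.** Surviving hits of a pair are rectangles in the
   (query × subject) coordinate plane and pass a fixed cascade, each removal
   recorded with its stage: orientation consistency with the gene pair →
   intron consistency (intronic on one side only is removed) → iterative
   overlap resolution (while any two rectangles intersect on both axes, the
   least significant by expect value is removed; ties by lower bit score,
   then smaller query start) → crossing removal (a hit crossing **three or
   more** others, counted simultaneously by midpoints, is removed) →
   collinearity enforcement (while any crossing remains, the conflicting hit
   with the lowest bit score is removed) → the **bow-tie** filter. The
   bow-tie is an expanding band around the block diagonal centred on the two
   gene midpoints: at signed query distance d the tolerated subject offset is
   `w0 + slope * |d|`, with defaults w0 = 200 bp and slope = 0.5, represented
   as a hexagon and tested by ray casting on the hit's midpoint. The original
   method names the bow-tie but not its numbers, so both parameters are
   configuration keys; the defaults reproduce the intended behaviour
   (discrepancies tolerated increasingly far from the gene, full 12 kb
   reach). The large-genome option doubles the slope and raises the larger
   genome's pad to **30 kb**, accommodating transposon-inflated spacing.

6. **Assignment and classification.** Hits surviving in several overlapping
   windows are deduplicated by coordinates and assigned to the eligible gene
   pair with the fewest intervening non-syntenic genes (**at most three**,
   checked on both genomes), ties broken by the smaller total boundary-to-
   boundary bp separation summed over both genomes. Candidates that are
   really unannotated genes are reclassified: CNSs **over 18 bp** with a
   six-frame translated hit to a supplied protein set at expect < 0.01
   covering more than 90% of the CNS, and CNSs with a nucleotide hit (word 7,
   expect < 0.001) to a supplied RNA set, leave the CNS list. Each remaining
   CNS gets exactly one positional class with precedence UTR (overlap with an
   annotated UTR exon of either member) → intron (inside the transcription
   unit) → proximal (**< 1 kb** from the unit boundary, any overlap counts) →
   distal, sided 5'/3' by the query gene's strand. A pair is a **Bigfoot**
   gene when at least four flanking CNSs spread over at least 4 kb of
   non-coding 5'+3' space with no gap — CNS-to-CNS or CNS-to-exon —
   exceeding 1 kb.

7. **Downstream utilities.** `pan_intersect()` intersects CNS lists from
   several comparisons on their shared reference-genome coordinates
   (half-open, ≥ 1 bp overlap; associative and commutative).
   `probe_relaxed()` rescans a target window with a CNS sequence at the bit
   score of a perfect 13 bp match (≈ 25.6 bits), the relaxed cutoff used to
   ask whether a lineage-specific CNS was deleted or merely diverged below
   the standard threshold. The enrichment module counts non-overlapping
   IUPAC motif matches (greedy left-to-right; `N` matches nothing) in CNSs
   versus non-conserved non-coding control sequence taken within 15 kb of
   the gene excluding CDS, CNS and masked residues, and tests 2×2 tables
   with a two-tailed chi-squared test (Yates correction when an expected
   cell is below 5; Bonferroni across a motif set at 0.005). Gene-group term
   enrichment uses two-sided Fisher tests with Benjamini–Hochberg correction
   flagged at 0.001, excluding co-annotated genes from group and universe.

## The synthetic data generator

`generate_pair()` builds two annotated genomes with a complete planted ground
truth. Under the default configuration — the conditions all end-to-end
validation uses — there are 50 collinear ortholog pairs on one chromosome,
6 kb intergenic spacing, three-exon genes (200 bp exons, 150 bp introns,
100 bp UTRs), four planted 30 bp CNSs per gene split between the 5' and 3'
flanks at offsets up to ~2.6 kb with ±50 bp positional jitter between the
genomes, one 300 bp transposon family at 60 copies per genome (above the 50×
masking threshold), two tandem gene duplicates, two genes hidden from the
query annotation to exercise co-annotation, and no inversions (inverted
multi-gene segments are available via `inversion_blocks`).

Generator semantics worth stating explicitly:

* **Planted identity is exact.** A CNS at identity *i* receives exactly
  `floor((1 - i) * len + 0.5)` substitutions (each to a different base) at
  distinct random positions, so the truth table's identity column is the
  realized identity, not an expectation. Indels are applied to planted CNSs
  only when `cns_indel_rate > 0`: a 30 bp CNS at 85% identity scores right at
  the acceptance boundary (30 − 3·5 = 15 raw), and uncontrolled indels would
  make the planted truth ill-defined with respect to the threshold. Gapped
  alignment is exercised instead by the orthologous CDS divergence (5%
  substitutions + 2% single-bp indels by default) and by dedicated alignment
  tests.
* **Background is decontaminated.** Intergenic sequence, introns and UTRs are
  independent random sequence in the two genomes, then screened: every
  ortholog pair's window pair is scanned with the pipeline's own aligner at
  raw score ≥ 14 (one unit stricter than the raw-15 acceptance threshold) and
  any cross-genome similarity not overlapping a planted CNS is resampled
  until none remains. Without this step, chance 15 bp identities between
  ~25 kb random windows are expected at a rate of roughly one per two window
  pairs; they satisfy the similarity contract, so counting them as false
  positives would be a fixture artifact. Decontamination makes the planted
  CNS list the complete cross-genome homology ground truth, so recall and
  precision are well defined.
* **Tandem-carrying genes get upstream-only CNSs**, because the duplicate is
  inserted immediately downstream and would otherwise shift the 3' CNS
  spacing between the genomes beyond what the bow-tie tolerates.
* Planted repeats are treated as known homology during decontamination:
  always masked in the screen and never resampled. With copy numbers below
  the masking threshold the pipeline will genuinely report cross-genome
  repeat matches; precision against the planted truth is only guaranteed at
  or above 50 copies.

What the generator does *not* emulate: realistic base composition or codon
structure, rate heterogeneity along sequences, selection, segmental
duplications other than the planted tandems, assembly gaps, or annotation
errors beyond whole hidden genes. Passing the recovery tests therefore shows
the machinery is correct under its stated assumptions, not that real-genome
CNS counts would be reproduced; real comparisons also depend on divergence
depth and annotation quality.

## Numerical choices and edge cases

* Coordinates are 0-based half-open (BED convention) everywhere, including
  the tabular outputs; touching intervals do not overlap.
* Alignment is seeded by exact words, extended ungapped with an X-drop of 12,
  and gap-extended (Gotoh, X-drop 20) once the ungapped score reaches raw 11
  (~22 bits, the conventional gap trigger). Alignment tie-breaks prefer the
  shorter extension; equal-score endpoint differences are possible but
  scores are exact, and the test suite checks best-score equality against a
  heuristics-free full-matrix Smith–Waterman reference restricted to
  alignments containing an exact seed word.
* Expect values use E = K·m·n·e^(−λ·raw) with the search space m·n equal to
  the product of window lengths (per-comparison totals for the genome-wide
  stages); only their relative order matters downstream (overlap resolution).
* DUST filtering is the symmetric triplet-duplication score over 64 bp
  windows at threshold 20, applied to seeding only.
* The protein reclassification filter aligns six-frame translations with
  BLOSUM62 (gap 11/1) and the standard gapped Karlin–Altschul constants for
  that matrix (λ = 0.267, K = 0.041); coverage is measured over the CNS, per
  the stated >90% rule.
* Ties in the geometric cascade are fully specified (expect, then bit score,
  then query start), making every stage a pure function; reruns are
  byte-identical, which the tests assert.
* When several pairs' windows contain the same hit, the assignment considers
  the pairs in which the hit survived filtering — a hit judged non-syntenic
  for a pair is not assignable to it.

## Problem sizes used by tests and the acceptance script

End-to-end validation runs the default 50-gene generator (~350 kb per
genome; one full pipeline run takes a few seconds), once at full identity
(recall and precision are then exactly 1.0 against the planted truth) and
over 20 seeds at 85% identity for the mean-recall estimate. Oracle
comparisons use 200 random window pairs of 80–200 bp against the exhaustive
seeded Smith–Waterman reference, a ~10 kb toy genome with an N-flanked
52-copy repeat against the exact-match coverage oracle, and 1,000 random
candidate sets of up to 8 rectangles against literal simulations of the
four geometric filters. These sizes were chosen so the entire validation
is reproducible on a laptop in a few minutes while still exercising every
stage at realistic per-gene scale.

## Known limitations

* Quota selection is greedy, not optimal; pathological block configurations
  can be selected suboptimally (never infeasibly).
* The bow-tie geometry (w0, slope) is a parameterized reconstruction; other
  shapes satisfying "increasing tolerance with distance" are conceivable and
  the defaults matter near the 12 kb window edges.
* E-values inherit ungapped Karlin–Altschul constants also for gapped hits,
  as is conventional for this scoring scheme at these score ranges.
* The maize-style contig order/orientation correction that the large-genome
  option of the original method additionally triggers is out of scope here;
  `large_genome` affects pad and bow-tie slope only.
* Homeologous (self) comparisons analyze each unordered gene pair once and
  exclude self-identity anchors; nested duplications within a genome are
  subject to the same quota machinery but have not been exercised beyond
  two-copy fixtures.
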