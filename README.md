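# cnspipe

Automated discovery of **conserved non-coding sequences (CNSs)** between two
annotated genomes. CNSs are short islands of non-coding DNA that diverge more
slowly than functionless sequence between related species — candidate
cis-regulatory elements. In plants they are small (tens of bp) and credible
only when anchored on syntenic gene pairs and required to be mutually
consistent in position, order and orientation, which is what this package
automates, end to end:

1. **Repeat masking** — whole-genome self-alignment coverage; any position
   covered by ≥ 50 distinct self-hits becomes `N`.
2. **Co-annotation** — the partner genome's CDS set recovers genes missed by
   the official annotation (hits merged across gaps < 1 kb; kept when ≥ 100 bp
   and ≥ 40% hit coverage of the merged span); intergenic survivors become
   new genes named `organism_chromosome_start_stop_strand`.
3. **Synteny** — CDS anchor pairs filtered at cscore > 0.5 (score divided by
   the best score of either gene), tandem duplicates within ≤ 20 intervening
   genes collapsed, anchors chained (gap ≤ 20 gene indices, ≥ 4 anchors per
   block) and blocks selected greedily under a ploidy quota `p:q`.
4. **Gene-space alignment** — per gene pair, windows reaching 12 kb beyond
   the transcription units (30 kb for the larger genome in `large_genome`
   mode), all CDS masked, aligned with a sensitive seeded local aligner
   (word 7, +1/−2, gap 5 + 2L, DUST seed filtering). Hits are scored in
   Karlin–Altschul bits (λ = 1.33, K = 0.621); anything below the bit score
   of a perfect 15 bp match — 29.5 bits at one decimal — is discarded.
5. **Geometric filtering** — hits are rectangles in the (query × subject)
   plane and pass, in order: orientation consistency, intron consistency,
   iterative overlap resolution by expect value, removal of hits crossing
   ≥ 3 others, iterative collinearity enforcement by bit score, and a
   **bow-tie** polygon centred on the gene midpoints whose tolerated offset
   grows with distance from the genes.
6. **Assignment & classification** — each CNS goes to the gene pair with the
   fewest intervening non-syntenic genes (≤ 3; ties by total bp separation),
   is optionally reclassified against protein/RNA reference sets, and gets
   one of seven positional classes (5′/3′ distal, proximal, UTR, intron).
   Gene pairs with ≥ 4 flanking CNSs over ≥ 4 kb of non-coding space and at
   least one CNS per kb are flagged **Bigfoot**.

Downstream helpers intersect CNS lists across comparisons on a shared
reference genome (pan-species CNSs), probe CNS fate at a relaxed 13/13
cutoff, and compute motif enrichment (two-tailed chi-squared against
non-conserved non-coding control sequence) and gene-set term enrichment
(Fisher exact, Benjamini–Hochberg).

A synthetic genome-pair generator (`generate_pair()`) plants CNSs, tandem
duplicates, a high-copy repeat family, annotation-hidden genes and optional
inversions with an exact ground-truth table, so the whole pipeline is
testable without downloads. See the methods vignette
(`vignettes/cns-discovery-methods.Rmd`) for the model, parameter rationale
and generator semantics.

## Worked example

```r
library(cnspipe)

cfg  <- fixture_config(n_genes = 12, seed = 7)   # planted ground truth
pair <- generate_pair(cfg)
res  <- run_pipeline(pair$genome_q, pair$ann_q, pair$genome_s, pair$ann_s,
                     cns_config(), verbose = FALSE)

unlist(res$log)
#>  masked_bp_q  masked_bp_s  new_genes_q  new_genes_s      anchors
#>        18000        18000            2            0           12
#>        pairs       blocks   candidates      removed         live
#>           12            1          108            0          108
#>          cns reclassified_protein reclassified_rna
#>           40            0            0

head(res$cns[, c("cns_id", "query_start", "query_end", "subject_start",
                 "position_class", "bit_score")], 3)
#>     cns_id query_start query_end subject_start  position_class bit_score
#> 1 cns00001        6464      6495          6735   3prime_distal  60.16965
#> 2 cns00002        7492      7523          7714 3prime_proximal  60.16965
#> 3 cns00003       10461     10491         10650   5prime_distal  58.25087

evaluate_recovery(res$cns, pair$truth)
#>    recall precision
#>         1         1
```

Reading the log: the 60-copy planted repeat family was masked (18 kb per
genome), the two genes hidden from the query annotation were recovered by
co-annotation (`new_genes_q = 2`) and went on to anchor syntenic pairs — all
12 ortholog pairs are found in one collinear block — and all 40 planted CNSs
(4 per non-hidden gene, 30 bp, 100% identity) pass the 29.5-bit threshold
and the full filter cascade: recall and precision against the planted truth
are both 1. `res$audit` holds the per-candidate filter trail, `res$gene_list`
the per-gene summary (syntenic partner, tandem cluster, CNS count, Bigfoot
flag); `write_outputs()` emits both tables as TSV.

Real genomes go in the same way: `read_genome_fasta()` + `read_gene_bed()`
(BED12, thick span = CDS), then `run_pipeline()`, or from a shell via the
thin CLI in `inst/scripts/cns_pipeline.R` (`run-all`, `mask`,
`make-fixtures`, `enrich`). Within-genome (homeologous) comparisons use
`run_homeologous()`.

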