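#' Extract the paired gene spaces of a syntenic gene pair
#'
#' For each gene of the pair, extracts the window starting \code{pad} bp
#' upstream of the annotated transcription start and ending \code{pad} bp past
#' the end of transcription, clipped at the chromosome ends, from the
#' repeat-masked genome. Within the window every annotated protein-coding
#' region (CDS exon of any gene, official or co-annotated) is additionally
#' masked to N, so only non-coding sequence can align.
#'
#' @param pair one-row data.frame with q_gene and s_gene.
#' @param genome_q,genome_s masked [genome_seq()] objects.
#' @param ann_q,ann_s matching annotations.
#' @param pad_q,pad_s upstream/downstream reach in bp (12 kb default; the
#'   large-genome configuration raises the larger genome's pad to 30 kb).
#' @return list(q = list(chrom, start, end, seq), s = ...) with 0-based
#'   half-open window coordinates and CDS-masked sequence.
#' @export
extract_gene_space <- function(pair, genome_q, genome_s, ann_q, ann_s,
                               pad_q = 12000, pad_s = 12000) {
  list(q = gene_space_window(pair$q_gene, genome_q, ann_q, pad_q),
       s = gene_space_window(pair$s_gene, genome_s, ann_s, pad_s))
}

gene_space_window <- function(gene_id, genome, ann, pad) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id)
  n <- nchar(genome$seqs[[g$chrom]])
  ws <- max(0L, g$start - as.integer(pad))
  we <- min(n, g$end + as.integer(pad))
  if (we <= ws) stop("empty gene-space window for ", gene_id)
  s <- substring(genome$seqs[[g$chrom]], ws + 1L, we)
  # mask every CDS exon overlapping the window
  cds <- ann$cds[ann$cds$gene_id %in%
                   ann$genes$gene_id[ann$genes$chrom == g$chrom], , drop = FALSE]
  cds <- cds[cds$start < we & cds$end > ws, , drop = FALSE]
  if (nrow(cds)) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(cds))) {
      a <- max(cds$start[i], ws) - ws + 1L
      b <- min(cds$end[i], we) - ws
      v[a:b] <- "N"
    }
    s <- paste(v, collapse = "")
  }
  list(gene_id = gene_id, chrom = g$chrom, start = ws, end = we,
       gene_start = g$start, gene_end = g$end, strand = g$strand, seq = s)
}

#' Align two gene-space windows
#'
#' Sensitive seeded local alignment (word 7, +1/-2, gap 5+2L, DUST seed
#' filtering) of the query window against both strands of the subject window.
#' Returns every hit with raw score, bit score and expect value (search space
#' = product of the window lengths).
#'
#' @param window_q,window_s windows from [extract_gene_space()].
#' @param scheme a [scoring_scheme()].
#' @param min_raw minimum raw score to report (callers usually pass the raw
#'   equivalent of the bit threshold).
#' @return data.frame of hits in genome coordinates: qstart, qend, sstart,
#'   send, strand, raw, bit_score, expect.
#' @export
align_gene_space <- function(window_q, window_s, scheme = scoring_scheme(),
                             min_raw = 1) {
  h <- seed_hits(setNames(window_q$seq, "q"), setNames(window_s$seq, "s"),
                 scheme, min_raw = min_raw, both_strands = TRUE,
                 dust = scheme$dust)
  data.frame(qstart = h$qstart + window_q$start,
             qend = h$qend + window_q$start,
             sstart = h$sstart + window_s$start,
             send = h$send + window_s$start,
             strand = ifelse(h$strand > 0, "forward", "reverse"),
             raw = h$raw,
             bit_score = bit_score(h$raw, scheme),
             expect = expect_value(h$raw, nchar(window_q$seq),
                                   nchar(window_s$seq), scheme),
             stringsAsFactors = FALSE)
}

#' Apply the bit-score acceptance threshold
#'
#' Keeps hits whose bit score is at least \code{min_bits}. The default is the
#' bit score of a perfect gapless 15 bp match (29.5 at one decimal place), so
#' the boundary case -- a 15/15 exact match -- is kept and anything weaker is
#' discarded.
#'
#' @param hits data.frame with a bit_score column.
#' @param min_bits inclusive bit-score threshold.
#' @param scheme scoring scheme (supplies the default threshold).
#' @export
threshold_filter <- function(hits, min_bits = NULL, scheme = scoring_scheme()) {
  if (is.null(min_bits)) min_bits <- bit_score(15, scheme)
  hits[hits$bit_score >= min_bits, , drop = FALSE]
}
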