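#' Map a partner genome's CDS set onto a genome
#'
#' Local-alignment hits of each spliced partner CDS against the (masked)
#' genome at word size 20 and the given expect cutoff. This is the raw
#' material for co-annotation: regions of the genome similar to genes the
#' official annotation may have missed.
#'
#' @param partner_cds named character vector of spliced CDS sequences from the
#'   partner genome.
#' @param genome the (repeat-masked) target [genome_seq()].
#' @param word seed word size.
#' @param max_expect expect cutoff (search space: total CDS length x genome
#'   length).
#' @param scheme scoring scheme for extension.
#' @return data.frame of hits: source_gene, chrom, start, end, strand, raw.
#' @export
find_cds_hits <- function(partner_cds, genome, word = 20, max_expect = 1e-3,
                          scheme = scoring_scheme()) {
  stopifnot(length(partner_cds) > 0)
  scheme$word <- as.integer(word)
  m <- sum(nchar(partner_cds)); n <- sum(as.numeric(chrom_lengths(genome)))
  min_raw <- max(word, min_raw_for_expect(max_expect, m, n, scheme))
  h <- seed_hits(partner_cds, genome$seqs, scheme, min_raw = min_raw,
                 both_strands = TRUE, dust = FALSE)
  data.frame(source_gene = h$qname, chrom = h$sname,
             start = h$sstart, end = h$send,
             strand = ifelse(h$strand > 0, "+", "-"), raw = h$raw,
             stringsAsFactors = FALSE)
}

#' Merge nearby CDS hits into candidate regions
#'
#' Hits from the same source gene on the same chromosome separated by less
#' than \code{max_gap} bp are chained transitively into one candidate region
#' spanning the 5'-most hit start to the 3'-most hit end.
#'
#' @param hits output of [find_cds_hits()].
#' @param max_gap merge hits whose gap is strictly less than this many bp.
#' @return data.frame of candidate regions: source_gene, chrom, start, end,
#'   strand (orientation of the majority of member hit bp), n_hits,
#'   total_hit_length (union of member hit bp).
#' @export
merge_cds_hits <- function(hits, max_gap = 1000) {
  out <- list()
  if (nrow(hits) == 0)
    return(data.frame(source_gene = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_hits = integer(), total_hit_length = integer()))
  for (key in unique(paste(hits$source_gene, hits$chrom, sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1]]
    h <- hits[hits$source_gene == part[1] & hits$chrom == part[2], , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1] - cummax_end(h$end)[-nrow(h)] >= max_gap)))
    for (g in unique(grp)) {
      m <- h[grp == g, , drop = FALSE]
      plus <- sum((m$end - m$start)[m$strand == "+"])
      minus <- sum((m$end - m$start)[m$strand == "-"])
      out[[length(out) + 1L]] <- data.frame(
        source_gene = part[1], chrom = part[2],
        start = min(m$start), end = max(m$end),
        strand = if (plus >= minus) "+" else "-",
        n_hits = nrow(m),
        total_hit_length = interval_union_length(m$start, m$end),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

cummax_end <- function(e) cummax(e)

interval_union_length <- function(s, e) {
  r <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
  sum(IRanges::width(r))
}

#' Filter co-annotation candidate regions
#'
#' A region is kept when its merged hits total at least \code{min_length} bp
#' and cover at least \code{min_coverage} of the merged span (5'-most hit
#' start to 3'-most hit end); everything else is discarded.
#'
#' @param regions output of [merge_cds_hits()].
#' @param min_length minimum total hit length (bp).
#' @param min_coverage minimum hit coverage of the merged span.
#' @export
filter_candidates <- function(regions, min_length = 100, min_coverage = 0.4) {
  keep <- regions$total_hit_length >= min_length &
    regions$total_hit_length / (regions$end - regions$start) >= min_coverage
  regions[keep, , drop = FALSE]
}

#' Classify candidate regions as missed exons or new genes
#'
#' A candidate overlapping an annotated gene's transcription unit is assigned
#' to that gene as missed exon(s) (ties broken by larger overlap, then by
#' leftmost gene). Intergenic candidates become new genes named
#' \code{organism_chromosome_start_stop_strand} and are appended to the
#' working annotation with \code{origin = "coannotated"} (their merged hit
#' intervals, clipped to the span, serve as CDS exons).
#'
#' @param regions kept candidates (see [filter_candidates()]).
#' @param hits the underlying hits (for member CDS exon intervals).
#' @param ann the genome's current [gene_annotation()].
#' @param genome_id organism label used in new gene names.
#' @return list with \code{annotation} (augmented), \code{new_genes} and
#'   \code{missed_exons} data.frames.
#' @export
classify_candidates <- function(regions, hits, ann, genome_id) {
  new_genes <- list(); missed <- list()
  genes <- ann$genes
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    ov <- genes$chrom == r$chrom & genes$start < r$end & genes$end > r$start
    if (any(ov)) {
      cand <- genes[ov, , drop = FALSE]
      ovlen <- pmin(cand$end, r$end) - pmax(cand$start, r$start)
      cand <- cand[order(-ovlen, cand$start), , drop = FALSE]
      missed[[length(missed) + 1L]] <- data.frame(
        gene_id = cand$gene_id[1], chrom = r$chrom,
        start = r$start, end = r$end, source_gene = r$source_gene,
        stringsAsFactors = FALSE)
    } else {
      name <- paste(genome_id, r$chrom, r$start, r$end, r$strand, sep = "_")
      new_genes[[length(new_genes) + 1L]] <- data.frame(
        gene_id = name, chrom = r$chrom, start = r$start, end = r$end,
        strand = r$strand, origin = "coannotated", source_gene = r$source_gene,
        stringsAsFactors = FALSE)
    }
  }
  new_genes <- if (length(new_genes)) do.call(rbind, new_genes) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), origin = character(),
               source_gene = character())
  missed <- if (length(missed)) do.call(rbind, missed) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), source_gene = character())
  new_genes <- new_genes[!duplicated(new_genes$gene_id), , drop = FALSE]

  ann2 <- ann
  if (nrow(new_genes)) {
    ann2$genes <- rbind(ann2$genes, new_genes[, c("gene_id", "chrom", "start",
                                                  "end", "strand", "origin")])
    # member hit intervals (clipped to the span, merged) become CDS exons
    for (k in seq_len(nrow(new_genes))) {
      ng <- new_genes[k, ]
      h <- hits[hits$source_gene == ng$source_gene & hits$chrom == ng$chrom &
                  hits$start < ng$end & hits$end > ng$start, , drop = FALSE]
      r <- IRanges::reduce(IRanges::IRanges(pmax(h$start, ng$start) + 1L,
                                            pmin(h$end, ng$end)))
      ann2$cds <- rbind(ann2$cds, data.frame(
        gene_id = ng$gene_id, start = IRanges::start(r) - 1L,
        end = IRanges::end(r)))
    }
  }
  # missed exons extend the owner gene's CDS set (clipped to the gene span)
  if (nrow(missed)) {
    for (k in seq_len(nrow(missed))) {
      me <- missed[k, ]
      g <- ann2$genes[ann2$genes$gene_id == me$gene_id, ]
      old <- ann2$cds[ann2$cds$gene_id == me$gene_id, , drop = FALSE]
      add <- IRanges::IRanges(max(me$start, g$start) + 1L, min(me$end, g$end))
      r <- IRanges::reduce(c(IRanges::IRanges(old$start + 1L, old$end), add))
      ann2$cds <- ann2$cds[ann2$cds$gene_id != me$gene_id, , drop = FALSE]
      ann2$cds <- rbind(ann2$cds, data.frame(
        gene_id = me$gene_id, start = IRanges::start(r) - 1L,
        end = IRanges::end(r)))
    }
  }
  validate_annotation(ann2)
  list(annotation = ann2, new_genes = new_genes, missed_exons = missed)
}

#' Co-annotate a genome with the partner genome's CDS set
#'
#' Full co-annotation stage: map the partner CDS set, merge nearby hits,
#' apply the length/coverage filters and classify the survivors. New genes
#' become available as potential syntenic anchors downstream; a second run
#' with the augmented annotation adds no further new genes from the same hits.
#'
#' @param genome masked target [genome_seq()].
#' @param ann the genome's [gene_annotation()].
#' @param partner_cds spliced CDS set of the partner genome.
#' @param word,max_expect,merge_gap,min_length,min_coverage stage parameters.
#' @param scheme scoring scheme.
#' @return list(annotation, new_genes, missed_exons, hits, regions).
#' @export
coannotate <- function(genome, ann, partner_cds, word = 20, max_expect = 1e-3,
                       merge_gap = 1000, min_length = 100, min_coverage = 0.4,
                       scheme = scoring_scheme()) {
  hits <- find_cds_hits(partner_cds, genome, word, max_expect, scheme)
  regions <- merge_cds_hits(hits, merge_gap)
  kept <- filter_candidates(regions, min_length, min_coverage)
  res <- classify_candidates(kept, hits, ann, genome$genome_id)
  c(res, list(hits = hits, regions = regions, kept = kept))
}
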