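#' Reclassify CNSs that are unannotated protein fragments
#'
#' Every CNS longer than 18 bp is compared, in all six reading frames, against
#' a reference protein set. A translated local-alignment hit with expect below
#' \code{max_expect} covering more than \code{min_coverage} of the CNS
#' reclassifies it as a missed gene/gene fragment and removes it from the CNS
#' list. CNSs of 18 bp or shorter skip this filter.
#'
#' @param cns data.frame with \code{sequence} (query-side nucleotides).
#' @param protein_seqs named character vector of protein sequences (any
#'   reference proteome); NULL disables the filter.
#' @param max_expect expect cutoff.
#' @param min_coverage required fraction of the CNS covered by the hit
#'   (strict).
#' @param min_len CNSs at or below this length are not tested.
#' @return list(cns = surviving records, reclassified = removed records).
#' @export
protein_filter <- function(cns, protein_seqs, max_expect = 0.01,
                           min_coverage = 0.9, min_len = 18L) {
  if (is.null(protein_seqs) || length(protein_seqs) == 0 || nrow(cns) == 0)
    return(list(cns = cns, reclassified = cns[0, , drop = FALSE]))
  # gapped BLOSUM62 Karlin-Altschul constants (gap 11/1)
  lambda <- 0.267; kconst <- 0.041
  total_aa <- sum(nchar(protein_seqs))
  subj <- Biostrings::AAStringSet(protein_seqs)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  hit <- logical(nrow(cns))
  for (i in seq_len(nrow(cns))) {
    s <- cns$sequence[i]
    len <- nchar(s)
    if (len <= min_len) next
    frames <- six_frame_peptides(s)
    for (pep in frames) {
      if (nchar(pep) < 4) next
      pw <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep(pep, length(subj))), subj,
        type = "local", substitutionMatrix = mat,
        gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(pw)
      best <- which.max(sc)
      ev <- kconst * nchar(pep) * total_aa * exp(-lambda * sc[best])
      cover <- 3 * Biostrings::nchar(Biostrings::pattern(pw[best])) / len
      if (ev < max_expect && cover > min_coverage) { hit[i] <- TRUE; break }
    }
  }
  list(cns = cns[!hit, , drop = FALSE], reclassified = cns[hit, , drop = FALSE])
}

six_frame_peptides <- function(s) {
  out <- character(0)
  for (seq in c(s, revcomp(s))) {
    for (f in 0:2) {
      sub <- substring(seq, f + 1, nchar(seq))
      sub <- substring(sub, 1, 3 * (nchar(sub) %/% 3))
      if (nchar(sub) < 3) next
      pep <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X")))
      out <- c(out, pep)
    }
  }
  # split at stops/ambiguities; local alignment handles the fragments
  unlist(strsplit(out, "[*X]+"))
}

#' Reclassify CNSs matching known non-coding RNAs
#'
#' Nucleotide comparison (word 7) of each CNS against a reference RNA set; a
#' hit with expect below the cutoff reclassifies the CNS as RNA and removes
#' it.
#'
#' @param cns data.frame with \code{sequence}.
#' @param rna_seqs named character vector of RNA (DNA-alphabet) sequences;
#'   NULL or empty disables the filter.
#' @param max_expect expect cutoff.
#' @param scheme scoring scheme.
#' @return list(cns, reclassified).
#' @export
rna_filter <- function(cns, rna_seqs, max_expect = 1e-3,
                       scheme = scoring_scheme()) {
  if (is.null(rna_seqs) || length(rna_seqs) == 0 || nrow(cns) == 0)
    return(list(cns = cns, reclassified = cns[0, , drop = FALSE]))
  total <- sum(nchar(rna_seqs))
  hit <- logical(nrow(cns))
  for (i in seq_len(nrow(cns))) {
    min_raw <- min_raw_for_expect(max_expect, nchar(cns$sequence[i]), total, scheme)
    h <- seed_hits(setNames(cns$sequence[i], "c"), rna_seqs, scheme,
                   min_raw = max(scheme$word, min_raw), both_strands = TRUE,
                   dust = FALSE)
    hit[i] <- nrow(h) > 0
  }
  list(cns = cns[!hit, , drop = FALSE], reclassified = cns[hit, , drop = FALSE])
}

#' Assign a CNS to a gene pair
#'
#' Among the candidate pairs whose gene-space windows contained the hit, pairs
#' separated from the CNS by more than \code{max_intervening} non-syntenic
#' genes (on either genome) are ineligible. Among the eligible pairs the
#' assignment minimizes the intervening non-syntenic gene count, breaking ties
#' by the smaller total base-pair separation (query-side plus subject-side,
#' boundary to boundary). Returns NA when no pair is eligible; such CNSs are
#' dropped.
#'
#' @param cns_row one CNS record (qstart/qend/sstart/send in genome
#'   coordinates, query_chrom, subject_chrom).
#' @param pairs candidate pair table (q_gene, s_gene, pair_id).
#' @param ann_q,ann_s annotations.
#' @param syntenic_q,syntenic_s character vectors of gene ids that are
#'   syntenic (members of selected blocks or their tandem clusters).
#' @param max_intervening maximum tolerated non-syntenic intervening genes.
#' @return the chosen pair_id or NA.
#' @export
assign_to_pair <- function(cns_row, pairs, ann_q, ann_s,
                           syntenic_q, syntenic_s, max_intervening = 3L) {
  if (nrow(pairs) == 0) return(NA_character_)
  n_int <- integer(nrow(pairs)); dist <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    nq <- intervening_nonsyntenic(ann_q, pairs$q_gene[k],
                                  cns_row$qstart, cns_row$qend, syntenic_q)
    ns <- intervening_nonsyntenic(ann_s, pairs$s_gene[k],
                                  cns_row$sstart, cns_row$send, syntenic_s)
    n_int[k] <- max(nq, ns)
    dist[k] <- gene_distance(ann_q, pairs$q_gene[k], cns_row$qstart, cns_row$qend) +
      gene_distance(ann_s, pairs$s_gene[k], cns_row$sstart, cns_row$send)
  }
  ok <- n_int <= max_intervening
  if (!any(ok)) return(NA_character_)
  o <- order(n_int, dist)
  o <- o[ok[o]]
  pairs$pair_id[o[1]]
}

# genes strictly between the CNS and the gene that are not syntenic
intervening_nonsyntenic <- function(ann, gene_id, s, e, syntenic) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  lo <- min(e, g$start); hi <- max(s, g$end)
  if (lo >= hi) return(0L)
  between <- ann$genes$chrom == g$chrom & ann$genes$gene_id != gene_id &
    ann$genes$start >= lo & ann$genes$end <= hi
  sum(between & !(ann$genes$gene_id %in% syntenic))
}

gene_distance <- function(ann, gene_id, s, e) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  max(0, g$start - e, s - g$end)
}

#' Classify the position of a CNS relative to its gene pair
#'
#' Precedence: overlap with an annotated UTR exon of either member gives
#' 5'UTR/3'UTR; otherwise inside the transcription unit gives intron;
#' otherwise any part within \code{proximal_dist} bp of the transcription-unit
#' boundary gives proximal, further away distal. The 5'/3' side follows the
#' strand of the assigned query-side gene.
#'
#' @param cns_row one CNS record in genome coordinates.
#' @param q_gene,s_gene the assigned pair's gene ids.
#' @param ann_q,ann_s annotations.
#' @param proximal_dist proximal/distal boundary (bp).
#' @return one of "5prime_distal", "5prime_proximal", "5prime_UTR", "intron",
#'   "3prime_UTR", "3prime_proximal", "3prime_distal".
#' @export
classify_position <- function(cns_row, q_gene, s_gene, ann_q, ann_s,
                              proximal_dist = 1000L) {
  gq <- ann_q$genes[ann_q$genes$gene_id == q_gene, ]
  overlaps <- function(utr, s, e) utr$start < e & utr$end > s
  utr_q <- ann_q$utr[ann_q$utr$gene_id == q_gene, , drop = FALSE]
  utr_s <- ann_s$utr[ann_s$utr$gene_id == s_gene, , drop = FALSE]
  side_q <- utr_q$side[overlaps(utr_q, cns_row$qstart, cns_row$qend)]
  side_s <- utr_s$side[overlaps(utr_s, cns_row$sstart, cns_row$send)]
  side <- c(side_q, side_s)
  if (length(side)) return(paste0(side[1], "_UTR"))
  if (cns_row$qstart < gq$end && cns_row$qend > gq$start) return("intron")
  left <- cns_row$qend <= gq$start
  d <- if (left) gq$start - cns_row$qend else cns_row$qstart - gq$end
  five <- (gq$strand == "+") == left
  paste0(if (five) "5prime" else "3prime",
         if (d < proximal_dist) "_proximal" else "_distal")
}

#' Per-pair CNS summary and Bigfoot call
#'
#' Summarizes the CNSs assigned to one gene pair: count, per-class counts,
#' the total non-coding 5' + 3' span from the furthest CNS to the
#' transcription unit on each side, and the Bigfoot call.
#'
#' @param cns assigned CNS records of one pair (query-side coordinates and
#'   position_class).
#' @param tu_start,tu_end query gene transcription-unit span.
#' @param min_cns,min_span,max_gap Bigfoot parameters: at least \code{min_cns}
#'   flanking (5'/3') CNSs spread over at least \code{min_span} bp of
#'   non-coding space with no gap (CNS-to-CNS or CNS-to-exon) exceeding
#'   \code{max_gap}.
#' @return list(cns_count, class_counts, noncoding_span_bp, bigfoot).
#' @export
summarize_pair_cns <- function(cns, tu_start, tu_end,
                               min_cns = 4L, min_span = 4000L, max_gap = 1000L) {
  classes <- c("5prime_distal", "5prime_proximal", "5prime_UTR", "intron",
               "3prime_UTR", "3prime_proximal", "3prime_distal")
  cc <- table(factor(cns$position_class, levels = classes))
  flank <- cns[grepl("proximal|distal", cns$position_class), , drop = FALSE]
  up <- flank[flank$qend <= tu_start, , drop = FALSE]
  down <- flank[flank$qstart >= tu_end, , drop = FALSE]
  span <- (if (nrow(up)) tu_start - min(up$qstart) else 0) +
    (if (nrow(down)) max(down$qend) - tu_end else 0)
  gaps_ok <- function(side, anchor, upstream) {
    if (nrow(side) == 0) return(TRUE)
    side <- side[order(side$qstart), , drop = FALSE]
    gaps <- if (upstream) c(side$qstart[-1], anchor) - side$qend
            else side$qstart - c(anchor, side$qend[-nrow(side)])
    all(gaps <= max_gap)
  }
  ok_gaps <- gaps_ok(up, tu_start, TRUE) && gaps_ok(down, tu_end, FALSE)
  bigfoot <- nrow(flank) >= min_cns && span >= min_span && ok_gaps
  list(cns_count = nrow(cns), class_counts = as.integer(cc),
       class_names = classes, noncoding_span_bp = span, bigfoot = bigfoot)
}

#' Bigfoot call from summary quantities
#'
#' TRUE iff the pair has at least \code{min_cns} flanking CNSs, at least
#' \code{min_span} bp of non-coding 5'+3' space, and at least one CNS per
#' \code{max_gap} of that space (no gap between consecutive CNSs, or between
#' the nearest CNS and the exon, exceeds \code{max_gap}).
#'
#' @param cns_count number of flanking CNSs.
#' @param noncoding_span_bp total non-coding 5'+3' span (bp).
#' @param gaps numeric vector of consecutive gaps (CNS-to-CNS and CNS-to-exon).
#' @param min_cns,min_span,max_gap thresholds.
#' @export
call_bigfoot <- function(cns_count, noncoding_span_bp, gaps,
                         min_cns = 4L, min_span = 4000L, max_gap = 1000L) {
  cns_count >= min_cns && noncoding_span_bp >= min_span && all(gaps <= max_gap)
}

#' Intersect CNS lists on a shared reference genome
#'
#' A reference-coordinate interval enters the pan-species set iff every input
#' list contains a CNS overlapping it (half-open overlap of at least 1 bp);
#' the emitted interval is the intersection. Associative and commutative over
#' the input lists.
#'
#' @param cns_lists list of CNS data.frames sharing the reference genome on
#'   the query side (each must carry attribute \code{query_genome}).
#' @return data.frame chrom, start, end of pan CNS intervals.
#' @export
pan_intersect <- function(cns_lists) {
  stopifnot(length(cns_lists) >= 2)
  ids <- vapply(cns_lists, function(x) attr(x, "query_genome") %||% NA_character_,
                character(1))
  if (length(unique(ids)) != 1 || any(is.na(ids)))
    stop("all CNS lists must share the same reference (query) genome")
  as_ranges <- function(x) {
    split(IRanges::IRanges(x$query_start + 1L, x$query_end), x$query_chrom)
  }
  cur <- as_ranges(cns_lists[[1]])
  for (k in seq_along(cns_lists)[-1]) {
    nxt <- as_ranges(cns_lists[[k]])
    chroms <- intersect(names(cur), names(nxt))
    cur <- lapply(setNames(chroms, chroms), function(ch)
      IRanges::intersect(IRanges::reduce(cur[[ch]]), IRanges::reduce(nxt[[ch]])))
    cur <- cur[vapply(cur, length, integer(1)) > 0]
  }
  if (length(cur) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  out <- do.call(rbind, lapply(names(cur), function(ch)
    data.frame(chrom = ch, start = IRanges::start(cur[[ch]]) - 1L,
               end = IRanges::end(cur[[ch]]), stringsAsFactors = FALSE)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probe a target window with a CNS sequence at a relaxed cutoff
#'
#' Local alignment of the CNS sequence against a target window accepting hits
#' at the bit score of a perfect \code{min_exact} bp match (13 by default,
#' about 25.6 bits, versus the standard 15/15 at 29.5 bits). Lowering
#' \code{min_exact} never shrinks the hit set.
#'
#' @param cns_sequence CNS nucleotides (>= min_exact bp).
#' @param target_window target sequence string.
#' @param min_exact perfect-match length defining the acceptance bit score.
#' @param scheme scoring scheme.
#' @return hit data.frame (qstart, qend, sstart, send, strand, raw, bit_score).
#' @export
probe_relaxed <- function(cns_sequence, target_window, min_exact = 13L,
                          scheme = scoring_scheme()) {
  stopifnot(nchar(cns_sequence) >= min_exact)
  min_raw <- ceiling(raw_for_bits(bit_score(min_exact, scheme), scheme) - 1e-9)
  h <- seed_hits(setNames(cns_sequence, "cns"),
                 setNames(target_window, "target"), scheme,
                 min_raw = min_raw, both_strands = TRUE, dust = scheme$dust)
  h$bit_score <- bit_score(h$raw, scheme)
  h
}
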