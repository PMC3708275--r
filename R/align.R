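#' Seeded local alignment between sequence sets
#'
#' Finds local alignment hits (HSPs) of every query sequence against every
#' subject sequence: exact word seeds, ungapped X-drop extension, then affine
#' gapped extension once the ungapped score reaches the gap trigger. \code{N}
#' never aligns, so hits cannot overlap masked sequence. Subject coordinates of
#' reverse-strand hits are reported on the forward strand.
#'
#' @param query_seqs,subject_seqs named character vectors of sequences.
#' @param scheme a [scoring_scheme()]; \code{scheme$word} sets the seed size.
#' @param min_raw minimum raw score to report.
#' @param both_strands also search the reverse complement of the subjects.
#' @param self self-comparison mode: the identity alignment is excluded and
#'   each unordered pair of loci is counted once (used for repeat coverage).
#' @param dust override \code{scheme$dust} for seed-level low-complexity
#'   filtering of the query.
#' @return data.frame with columns qname, sname, strand (+1/-1), qstart, qend,
#'   sstart, send (0-based half-open), raw.
#' @export
seed_hits <- function(query_seqs, subject_seqs, scheme = scoring_scheme(),
                      min_raw = 1, both_strands = TRUE, self = FALSE,
                      dust = scheme$dust) {
  stopifnot(length(query_seqs) > 0, length(subject_seqs) > 0)
  qmask <- NULL
  if (isTRUE(dust)) {
    qmask <- lapply(unname(query_seqs), cpp_dust_mask,
                    window = scheme$dust_window,
                    threshold = scheme$dust_threshold)
  }
  h <- cpp_map_hits(unname(query_seqs), unname(subject_seqs),
                    scheme$word, scheme$match, scheme$mismatch,
                    scheme$gap_open, scheme$gap_extend,
                    min_raw, scheme$gap_trigger_raw,
                    scheme$xdrop_ungapped, scheme$xdrop_gapped,
                    both_strands, self, qmask)
  h$qname <- names(query_seqs)[h$query]
  h$sname <- names(subject_seqs)[h$subject]
  h$query <- NULL; h$subject <- NULL
  h[, c("qname", "sname", "strand", "qstart", "qend", "sstart", "send", "raw")]
}

#' DUST-style low-complexity intervals of a sequence
#'
#' Simplified symmetric-DUST scoring over sliding windows: a window is flagged
#' when ten times its triplet duplication score per triplet exceeds the
#' threshold. Used to exclude low-complexity stretches from alignment seeding.
#'
#' @param seq a sequence string.
#' @param window window size in bp.
#' @param threshold DUST score threshold (20 mirrors the common default).
#' @return logical vector, TRUE at flagged positions.
#' @export
dust_mask <- function(seq, window = 64, threshold = 20) {
  cpp_dust_mask(seq, window, threshold)
}

#' Exhaustive seeded Smith-Waterman reference scores
#'
#' Full-matrix affine local alignment restricted to alignments containing an
#' exact seed word: for every exact w-mer match the optimal score of an
#' alignment through it. Exponentially slower than [seed_hits()] but free of
#' heuristics; intended as an independent reference on small inputs.
#'
#' @param query,subject sequence strings (forward strand).
#' @param scheme a [scoring_scheme()].
#' @return data.frame with qpos, spos (0-based seed starts) and best score.
#' @export
sw_seeded_oracle <- function(query, subject, scheme = scoring_scheme()) {
  cpp_sw_seeded_oracle(query, subject, scheme$word, scheme$match,
                       scheme$mismatch, scheme$gap_open, scheme$gap_extend)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
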