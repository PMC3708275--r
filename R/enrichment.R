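#' Non-conserved non-coding control sequences for one gene
#'
#' The motif-enrichment background: all residues within \code{reach} bp up and
#' downstream of the gene's transcription unit that are not CDS, not CNS and
#' not masked, concatenated in genomic order. The control never overlaps any
#' CNS interval.
#'
#' @param gene_id gene of interest.
#' @param genome masked [genome_seq()].
#' @param ann the genome's annotation.
#' @param cns_intervals data.frame (chrom, start, end) of CNS locations on
#'   this genome.
#' @param reach flank size in bp (15 kb default).
#' @return a single character string (possibly empty).
#' @export
control_sequences <- function(gene_id, genome, ann, cns_intervals,
                              reach = 15000L) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id)
  n <- nchar(genome$seqs[[g$chrom]])
  ws <- max(0L, g$start - as.integer(reach))
  we <- min(n, g$end + as.integer(reach))
  keep <- IRanges::IRanges(ws + 1L, we)
  drop <- IRanges::IRanges()
  cds <- ann$cds[ann$cds$gene_id %in%
                   ann$genes$gene_id[ann$genes$chrom == g$chrom], , drop = FALSE]
  if (nrow(cds))
    drop <- c(drop, IRanges::IRanges(cds$start + 1L, cds$end))
  ci <- cns_intervals[cns_intervals$chrom == g$chrom, , drop = FALSE]
  if (nrow(ci))
    drop <- c(drop, IRanges::IRanges(ci$start + 1L, ci$end))
  free <- IRanges::setdiff(keep, IRanges::reduce(drop))
  if (length(free) == 0) return("")
  pieces <- substring(genome$seqs[[g$chrom]],
                      IRanges::start(free), IRanges::end(free))
  out <- paste(pieces, collapse = "")
  gsub("N", "", out, fixed = TRUE) # masked residues are excluded
}

#' Count non-overlapping motif occurrences
#'
#' Left-to-right greedy count of non-overlapping matches of an
#' IUPAC-degenerate pattern on the given strand. \code{N} in the scanned
#' sequence matches nothing, so concatenating sequences with an N spacer of at
#' least the pattern length adds counts exactly.
#'
#' @param pattern IUPAC nucleotide pattern (e.g. G-box \code{"CACGTG"}).
#' @param sequences character vector of sequences to scan.
#' @return integer total count.
#' @export
count_motif <- function(pattern, sequences) {
  stopifnot(nzchar(pattern))
  total <- 0L
  plen <- nchar(pattern)
  for (s in sequences) {
    if (nchar(s) < plen) next
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(s),
                                  fixed = c(pattern = FALSE, subject = TRUE))
    st <- Biostrings::start(m)
    if (length(st) == 0) next
    st <- sort(st)
    last_end <- -1L
    for (p in st) {
      if (p > last_end) { total <- total + 1L; last_end <- p + plen - 1L }
    }
  }
  total
}

#' Motif enrichment in foreground vs background sequence
#'
#' Builds the 2x2 table (motif occurrences vs remaining scanning opportunity,
#' foreground vs background) and applies a two-tailed chi-squared test with
#' one degree of freedom. Yates continuity correction is used when any
#' expected cell is below 5; both statistics are reported. Fold enrichment is
#' the ratio of per-residue occurrence rates.
#'
#' @param pattern IUPAC motif.
#' @param fg_seqs,bg_seqs foreground (CNS) and background (control) sequences.
#' @return one-row data.frame: item, count_fg, total_fg, count_bg, total_bg,
#'   fold, chisq, chisq_corrected, p_value.
#' @export
motif_enrichment <- function(pattern, fg_seqs, bg_seqs) {
  total_fg <- sum(nchar(fg_seqs)); total_bg <- sum(nchar(bg_seqs))
  stopifnot(total_fg > 0, total_bg > 0)
  count_fg <- count_motif(pattern, fg_seqs)
  count_bg <- count_motif(pattern, bg_seqs)
  tab <- matrix(c(count_fg, total_fg - count_fg,
                  count_bg, total_bg - count_bg), nrow = 2, byrow = TRUE)
  fold <- if (count_bg > 0) (count_fg / total_fg) / (count_bg / total_bg)
          else NA_real_
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_correction <- any(expected < 5)
  raw <- suppressWarnings(chisq.test(tab, correct = FALSE))
  cor <- suppressWarnings(chisq.test(tab, correct = TRUE))
  pick <- if (use_correction) cor else raw
  data.frame(item = pattern, count_fg = count_fg, total_fg = total_fg,
             count_bg = count_bg, total_bg = total_bg, fold = fold,
             chisq = unname(raw$statistic),
             chisq_corrected = unname(cor$statistic),
             p_value = unname(pick$p.value),
             stringsAsFactors = FALSE)
}

#' Scan a motif set against CNS and control sequence
#'
#' Convenience wrapper around [motif_enrichment()] with Bonferroni correction
#' across the motif set (significance at corrected p below \code{alpha}).
#'
#' @param motifs data.frame with columns name, pattern.
#' @param fg_seqs,bg_seqs sequences as in [motif_enrichment()].
#' @param alpha significance cutoff on the Bonferroni-corrected p-value.
#' @export
motif_enrichment_set <- function(motifs, fg_seqs, bg_seqs, alpha = 0.005) {
  res <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    r <- motif_enrichment(motifs$pattern[i], fg_seqs, bg_seqs)
    r$item <- motifs$name[i]
    r
  }))
  res$corrected_p <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$corrected_p < alpha
  res
}

#' Annotation-term enrichment of a gene group
#'
#' Per term, a two-sided Fisher's exact test on (in group vs not) x (has term
#' vs not) over the gene universe, Benjamini-Hochberg corrected, flagged at
#' corrected p below \code{alpha}. Co-annotated genes must be excluded from
#' both group and universe by the caller (the pipeline does this).
#'
#' @param gene_group character vector, subset of \code{universe}.
#' @param universe character vector of all genes considered.
#' @param gene_to_terms data.frame (gene, term).
#' @param alpha significance cutoff on the corrected p-value.
#' @return data.frame: item, count_fg, total_fg, count_bg, total_bg, fold,
#'   p_value, corrected_p, significant.
#' @export
term_enrichment <- function(gene_group, universe, gene_to_terms,
                            alpha = 0.001) {
  if (length(gene_group) == 0) stop("empty gene group")
  stopifnot(all(gene_group %in% universe))
  g2t <- gene_to_terms[gene_to_terms$gene %in% universe, , drop = FALSE]
  terms <- unique(g2t$term)
  n_in <- length(gene_group); n_out <- length(universe) - n_in
  out <- lapply(terms, function(tm) {
    with_term <- unique(g2t$gene[g2t$term == tm])
    a <- sum(gene_group %in% with_term)          # in group, has term
    b <- n_in - a                                # in group, no term
    c_ <- sum(!(with_term %in% gene_group))      # out of group, has term
    d <- n_out - c_
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2), alternative = "two.sided")$p.value
    fold <- if (c_ > 0 && n_out > 0) (a / n_in) / (c_ / n_out) else NA_real_
    data.frame(item = tm, count_fg = a, total_fg = n_in,
               count_bg = c_, total_bg = n_out, fold = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$corrected_p <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$corrected_p < alpha
  res[order(res$p_value), , drop = FALSE]
}

#' Transcription-factor association by CNS-count bin
#'
#' For gene-pair bins defined by CNS count, compares the fraction of genes in
#' the transcription-factor set against the genome-wide fraction with a
#' two-tailed chi-squared test (bin vs rest of genome).
#'
#' @param bins named list of character vectors (bin label -> query gene ids).
#' @param tf_genes character vector of transcription-factor gene ids.
#' @param universe all query genes considered.
#' @return data.frame per bin: item, count_fg (TFs in bin), total_fg,
#'   tf_fraction, genome_fraction, fold, chisq, p_value.
#' @export
tf_association <- function(bins, tf_genes, universe) {
  genome_frac <- mean(universe %in% tf_genes)
  out <- lapply(names(bins), function(nm) {
    genes <- bins[[nm]]
    a <- sum(genes %in% tf_genes); n <- length(genes)
    rest <- setdiff(universe, genes)
    c_ <- sum(rest %in% tf_genes); m <- length(rest)
    tab <- matrix(c(a, n - a, c_, m - c_), nrow = 2, byrow = TRUE)
    ct <- suppressWarnings(chisq.test(tab, correct = any(outer(rowSums(tab),
      colSums(tab)) / sum(tab) < 5)))
    data.frame(item = nm, count_fg = a, total_fg = n,
               tf_fraction = if (n > 0) a / n else NA_real_,
               genome_fraction = genome_frac,
               fold = if (genome_frac > 0 && n > 0) (a / n) / genome_frac else NA_real_,
               chisq = unname(ct$statistic), p_value = unname(ct$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a motif set file
#'
#' Two-column whitespace-separated text: name, IUPAC pattern.
#'
#' @param path file path.
#' @export
read_motifs <- function(path) {
  x <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(x[, 1:2], c("name", "pattern"))
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (gene, term), compatible with GO-association flat exports.
#'
#' @param path file path.
#' @export
read_gene_terms <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(x[, 1:2], c("gene", "term"))
}
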