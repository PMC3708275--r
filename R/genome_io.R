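#' Genome sequence container
#'
#' A light container for a genome: a short label and a named set of
#' chromosome sequences over the alphabet \code{A,C,G,T,N}. Lowercase input is
#' uppercased and any other symbol is mapped to \code{N}. Masked positions are
#' represented directly as \code{N} in the sequence, so applying a mask is
#' idempotent.
#'
#' @param genome_id short genome label, e.g. \code{"Os"}.
#' @param seqs named character vector of chromosome sequences.
#' @return An object of class \code{"genome_seq"}.
#' @export
genome_seq <- function(genome_id, seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- vapply(seqs, normalize_nt, character(1))
  structure(list(genome_id = genome_id, seqs = seqs), class = "genome_seq")
}

normalize_nt <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq <", x$genome_id, ">: ", length(x$seqs), " chromosome(s), ",
      sum(nchar(x$seqs)), " bp total\n", sep = "")
  invisible(x)
}

#' @rdname genome_seq
#' @param genome a \code{genome_seq}.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome$seqs, nchar, integer(1))
}

#' Positions currently masked (N) in a genome
#'
#' @param genome a [genome_seq()].
#' @return named list of 0-based positions per chromosome.
#' @export
masked_positions <- function(genome) {
  lapply(genome$seqs, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] == "N") - 1L
  })
}

#' Apply a positional mask to a genome
#'
#' Replaces the given 0-based positions with \code{N}. Idempotent; positions
#' outside the chromosome bounds are an error.
#'
#' @param genome a [genome_seq()].
#' @param mask named list (chromosome -> 0-based integer positions).
#' @export
apply_mask <- function(genome, mask) {
  for (chrom in names(mask)) {
    if (!chrom %in% names(genome$seqs)) stop("unknown chromosome: ", chrom)
    pos <- mask[[chrom]]
    if (length(pos) == 0) next
    n <- nchar(genome$seqs[[chrom]])
    if (any(pos < 0) || any(pos >= n)) stop("mask positions out of bounds on ", chrom)
    s <- strsplit(genome$seqs[[chrom]], "", fixed = TRUE)[[1]]
    s[pos + 1L] <- "N"
    genome$seqs[[chrom]] <- paste(s, collapse = "")
  }
  genome
}

#' Read a genome from FASTA
#'
#' Each record becomes one chromosome. Lowercase is normalized to uppercase
#' and non-ACGTN symbols become \code{N}. Duplicate record names and empty
#' files are errors.
#'
#' @param path FASTA file.
#' @param genome_id genome label; defaults to the file name without extension.
#' @return a [genome_seq()].
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  genome_seq(genome_id, setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#'
#' @param genome a [genome_seq()].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Gene annotation container
#'
#' Holds stranded gene models with 0-based half-open coordinates (BED
#' convention): a `genes` table (gene_id, chrom, start, end, strand, origin),
#' a `cds` exon table and a `utr` exon table tagged 5'/3'. All sub-intervals
#' must lie within the gene span; CDS exons must be pairwise disjoint; UTR
#' side tags must be consistent with strand.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand and
#'   optionally origin (\code{"official"} or \code{"coannotated"}).
#' @param cds data.frame with columns gene_id, start, end.
#' @param utr data.frame with columns gene_id, start, end, side
#'   (\code{"5prime"}/\code{"3prime"}); may be empty.
#' @return object of class \code{"gene_annotation"}.
#' @export
gene_annotation <- function(genes, cds, utr = NULL) {
  if (is.null(genes$origin)) genes$origin <- "official"
  if (is.null(utr))
    utr <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), side = character())
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  utr <- as.data.frame(utr, stringsAsFactors = FALSE)
  ann <- structure(list(genes = genes, cds = cds, utr = utr),
                   class = "gene_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  if (any(g$end <= g$start)) stop("gene end <= start")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  span <- split(g[, c("start", "end", "strand")], g$gene_id)
  for (tab in list(ann$cds, ann$utr)) {
    if (nrow(tab) == 0) next
    if (any(tab$end <= tab$start)) stop("exon end <= start")
    bad <- !tab$gene_id %in% g$gene_id
    if (any(bad)) stop("exon for unknown gene: ", tab$gene_id[which(bad)[1]])
    for (i in seq_len(nrow(tab))) {
      sp <- span[[tab$gene_id[i]]]
      if (tab$start[i] < sp$start || tab$end[i] > sp$end)
        stop("exon outside gene span for ", tab$gene_id[i])
    }
  }
  # CDS exons pairwise disjoint within a gene
  if (nrow(ann$cds) > 0) {
    for (gid in unique(ann$cds$gene_id)) {
      e <- ann$cds[ann$cds$gene_id == gid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        stop("overlapping CDS exons in ", gid)
    }
  }
  invisible(ann)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation: ", nrow(x$genes), " genes (",
      sum(x$genes$origin == "coannotated"), " co-annotated), ",
      nrow(x$cds), " CDS exons, ", nrow(x$utr), " UTR exons\n", sep = "")
  invisible(x)
}

#' Read gene models from BED12
#'
#' Blocks are the transcribed exons; the thick span marks the CDS. UTR exons
#' are derived as the parts of blocks outside the thick span and tagged 5'/3'
#' according to strand. A gene whose thick span equals its full span has no
#' UTR exons.
#'
#' @param path BED12 file.
#' @return a [gene_annotation()].
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) stop("empty BED file: ", path)
  genes <- data.frame(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    origin = "official",
    stringsAsFactors = FALSE)
  if (any(genes$strand == "*")) stop("BED rows must carry a strand")
  thick <- gr$thick
  blocks <- rtracklayer::blocks(gr)
  cds_list <- list(); utr_list <- list()
  for (i in seq_along(gr)) {
    gid <- genes$gene_id[i]
    b <- blocks[[i]]
    bs <- GenomicRanges::start(b) - 1L; be <- GenomicRanges::end(b)
    if (any(bs < genes$start[i]) || any(be > genes$end[i]))
      stop("blocks outside gene span for ", gid)
    ts <- GenomicRanges::start(thick)[i] - 1L; te <- GenomicRanges::end(thick)[i]
    for (k in seq_along(bs)) {
      cs <- max(bs[k], ts); ce <- min(be[k], te)
      if (ce > cs)
        cds_list[[length(cds_list) + 1L]] <-
          data.frame(gene_id = gid, start = cs, end = ce)
      if (bs[k] < ts) {   # block part left of the CDS
        side <- if (genes$strand[i] == "+") "5prime" else "3prime"
        utr_list[[length(utr_list) + 1L]] <-
          data.frame(gene_id = gid, start = bs[k], end = min(be[k], ts), side = side)
      }
      if (be[k] > te) {   # block part right of the CDS
        side <- if (genes$strand[i] == "+") "3prime" else "5prime"
        utr_list[[length(utr_list) + 1L]] <-
          data.frame(gene_id = gid, start = max(bs[k], te), end = be[k], side = side)
      }
    }
  }
  cds <- if (length(cds_list)) do.call(rbind, cds_list) else
    data.frame(gene_id = character(), start = integer(), end = integer())
  utr <- if (length(utr_list)) do.call(rbind, utr_list) else NULL
  gene_annotation(genes, cds, utr)
}

#' Write gene models to BED12
#'
#' Inverse of [read_gene_bed()]: blocks are the merged CDS+UTR exons and the
#' thick span covers the CDS extent.
#'
#' @param ann a [gene_annotation()].
#' @param path output file.
#' @export
write_gene_bed <- function(ann, path) {
  lines <- character(nrow(ann$genes))
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    ex <- rbind(ann$cds[ann$cds$gene_id == g$gene_id, c("start", "end")],
                ann$utr[ann$utr$gene_id == g$gene_id, c("start", "end")])
    if (nrow(ex) == 0) ex <- data.frame(start = g$start, end = g$end)
    ex <- ex[order(ex$start), , drop = FALSE]
    # merge touching/overlapping exon pieces into BED blocks
    ms <- ex$start[1]; me <- ex$end[1]; bs <- integer(); be <- integer()
    for (k in seq_len(nrow(ex))[-1]) {
      if (ex$start[k] <= me) me <- max(me, ex$end[k])
      else { bs <- c(bs, ms); be <- c(be, me); ms <- ex$start[k]; me <- ex$end[k] }
    }
    bs <- c(bs, ms); be <- c(be, me)
    cds_g <- ann$cds[ann$cds$gene_id == g$gene_id, , drop = FALSE]
    ts <- if (nrow(cds_g)) min(cds_g$start) else g$start
    te <- if (nrow(cds_g)) max(cds_g$end) else g$start
    lines[i] <- paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                      ts, te, 0L, length(bs),
                      paste0(paste(be - bs, collapse = ","), ","),
                      paste0(paste(bs - g$start, collapse = ","), ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# intron intervals (0-based half-open) of one gene: gaps between its exons
gene_introns <- function(ann, gene_id) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  ex <- rbind(ann$cds[ann$cds$gene_id == gene_id, c("start", "end")],
              ann$utr[ann$utr$gene_id == gene_id, c("start", "end")])
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  ex <- ex[order(ex$start), , drop = FALSE]
  st <- integer(); en <- integer(); cur <- ex$end[1]
  for (k in seq_len(nrow(ex))[-1]) {
    if (ex$start[k] > cur) { st <- c(st, cur); en <- c(en, ex$start[k]) }
    cur <- max(cur, ex$end[k])
  }
  data.frame(start = st, end = en)
}

# spliced CDS sequences (strand-aware) as a named character vector
cds_sequences <- function(genome, ann) {
  out <- character(0)
  if (nrow(ann$cds) == 0) return(out)
  for (gid in unique(ann$genes$gene_id)) {
    e <- ann$cds[ann$cds$gene_id == gid, , drop = FALSE]
    if (nrow(e) == 0) next
    g <- ann$genes[ann$genes$gene_id == gid, ]
    e <- e[order(e$start), , drop = FALSE]
    s <- paste(substring(genome$seqs[[g$chrom]], e$start + 1L, e$end),
               collapse = "")
    if (g$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    out[gid] <- s
  }
  out
}

# ---------------------------------------------------------------------------
# Pipeline tabular outputs
# ---------------------------------------------------------------------------

#' Write the pipeline's gene list and CNS list
#'
#' Emits two TSV files: \code{<prefix>_genes.tsv} (one row per query gene:
#' syntenic partner or NA, local duplicate cluster members, CNS count, Bigfoot
#' flag) and \code{<prefix>_cns.tsv} (one row per CNS with both genomic
#' locations, assigned gene pair, positional class, bit score and sequence).
#' The \code{gevo_url} column is a placeholder kept for format fidelity with
#' the original outputs. Both files round-trip losslessly through
#' [read_gene_list()] / [read_cns_list()].
#'
#' @param gene_list data.frame as produced by the pipeline.
#' @param cns data.frame of CNS records.
#' @param path_prefix output path prefix.
#' @return character vector of the two file paths.
#' @export
write_outputs <- function(gene_list, cns, path_prefix) {
  gpath <- paste0(path_prefix, "_genes.tsv")
  cpath <- paste0(path_prefix, "_cns.tsv")
  gl <- gene_list[, c("query_gene", "syntelog", "local_duplicate_cluster",
                      "cns_count", "bigfoot", "gevo_url")]
  write.table(gl, gpath, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  cl <- cns[, c("cns_id", "query_chrom", "query_start", "query_end",
                "subject_chrom", "subject_start", "subject_end",
                "assigned_gene_pair", "position_class", "bit_score",
                "sequence", "gevo_url")]
  write.table(cl, cpath, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(c(genes = gpath, cns = cpath))
}

#' @rdname write_outputs
#' @param path a file written by [write_outputs()].
#' @export
read_gene_list <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("query_gene", "syntelog", "local_duplicate_cluster", "gevo_url"))
    x[[col]] <- as.character(x[[col]])
  x
}

#' @rdname write_outputs
#' @export
read_cns_list <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("cns_id", "query_chrom", "subject_chrom", "assigned_gene_pair",
                "position_class", "sequence", "gevo_url"))
    x[[col]] <- as.character(x[[col]])
  x
}
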