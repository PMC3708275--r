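#' Self-alignment coverage of a genome
#'
#' Counts, for every base-pair position, the number of distinct self-alignment
#' hits covering it, from a whole-genome self-comparison at word size 15 and
#' the given expect cutoff. Each unordered pair of aligned loci contributes one
#' hit to both loci; the trivial identity alignment of a chromosome against
#' itself is excluded (otherwise unique sequence would never stay unmasked).
#' A sequence present k times therefore reaches coverage k - 1 at each copy.
#'
#' @param genome a [genome_seq()].
#' @param word seed word size for the self-search.
#' @param max_expect expect-value cutoff for counting a hit (search space =
#'   total genome length squared).
#' @param scheme scoring scheme for extension (word is overridden).
#' @return named list of integer coverage vectors, one per chromosome.
#' @export
self_hit_coverage <- function(genome, word = 15, max_expect = 1e-3,
                              scheme = scoring_scheme()) {
  scheme$word <- as.integer(word)
  lens <- chrom_lengths(genome)
  total <- sum(as.numeric(lens))
  if (total == 0) stop("empty genome")
  min_raw <- max(word, min_raw_for_expect(max_expect, total, total, scheme))
  h <- seed_hits(genome$seqs, genome$seqs, scheme, min_raw = min_raw,
                 both_strands = TRUE, self = TRUE, dust = FALSE)
  cov <- lapply(lens, function(n) integer(n))
  bump <- function(cov, chrom, s, e) { # 0-based half-open interval
    d <- cov[[chrom]]
    d[(s + 1L):e] <- d[(s + 1L):e] + 1L
    cov[[chrom]] <- d
    cov
  }
  for (i in seq_len(nrow(h))) {
    cov <- bump(cov, h$qname[i], h$qstart[i], h$qend[i])
    cov <- bump(cov, h$sname[i], h$sstart[i], h$send[i])
  }
  cov
}

#' Mask positions covered by too many self-alignment hits
#'
#' Replaces with \code{N} every position whose self-alignment coverage is at
#' or above the threshold (50 by default: sequence occurring in 50 or more
#' copies genome-wide). All other positions are unchanged. Raising the
#' threshold never masks additional positions.
#'
#' @param genome a [genome_seq()].
#' @param coverage output of [self_hit_coverage()].
#' @param threshold minimum hit count for masking (inclusive).
#' @return the masked [genome_seq()].
#' @export
mask_repeats <- function(genome, coverage, threshold = 50) {
  if (!identical(sort(names(coverage)), sort(names(genome$seqs))))
    stop("coverage does not match genome chromosomes")
  for (chrom in names(coverage)) {
    if (length(coverage[[chrom]]) != nchar(genome$seqs[[chrom]]))
      stop("coverage length mismatch on ", chrom)
    pos <- which(coverage[[chrom]] >= threshold) - 1L
    if (length(pos))
      genome <- apply_mask(genome, setNames(list(pos), chrom))
  }
  genome
}

#' Repeat-mask a genome by 50x self-coverage
#'
#' Convenience wrapper: [self_hit_coverage()] followed by [mask_repeats()].
#' A genome already masked by an external tool can simply skip this stage.
#'
#' @inheritParams self_hit_coverage
#' @inheritParams mask_repeats
#' @export
mask_genome <- function(genome, word = 15, max_expect = 1e-3, threshold = 50,
                        scheme = scoring_scheme()) {
  mask_repeats(genome, self_hit_coverage(genome, word, max_expect, scheme),
               threshold)
}
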