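#' Local alignment scoring scheme
#'
#' Bundles the nucleotide scoring parameters used by the gene-space CNS search
#' and the Karlin-Altschul constants that convert raw scores to bit scores.
#' The defaults reproduce the classic bl2seq settings for sensitive
#' nucleotide comparison: word size 7, match +1, mismatch -2, gap open 5,
#' gap extend 2, DUST low-complexity filtering of seed words. A gap of length
#' L costs \code{gap_open + L * gap_extend}.
#'
#' The Karlin-Altschul constants default to the standard ungapped values for
#' +1/-2 nucleotide scoring (lambda = 1.33 per raw-score unit, K = 0.621), under
#' which a perfect 15 bp match scores 29.5 bits (1 d.p.) -- the acceptance
#' threshold used throughout.
#'
#' @param word seed word size (exact-match length required to trigger an
#'   alignment).
#' @param match,mismatch per-base match reward and mismatch penalty.
#' @param gap_open,gap_extend affine gap parameters.
#' @param lambda,k Karlin-Altschul parameters.
#' @param dust logical; exclude DUST-flagged low-complexity query stretches
#'   from seeding.
#' @param dust_window,dust_threshold DUST window size (bp) and score threshold.
#' @param xdrop_ungapped,xdrop_gapped X-drop termination bounds (raw score
#'   units) for the ungapped and gapped extension phases.
#' @param gap_trigger_raw ungapped raw score required before gapped extension
#'   is attempted (approximately 22 bits under the default constants, the
#'   conventional gap trigger).
#' @return An object of class \code{"scoring_scheme"}.
#' @export
scoring_scheme <- function(word = 7, match = 1, mismatch = -2,
                           gap_open = 5, gap_extend = 2,
                           lambda = 1.33, k = 0.621,
                           dust = TRUE, dust_window = 64, dust_threshold = 20,
                           xdrop_ungapped = 12, xdrop_gapped = 20,
                           gap_trigger_raw = 11) {
  stopifnot(word >= 1, match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0,
            lambda > 0, k > 0)
  structure(list(word = as.integer(word), match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, k = k,
                 dust = isTRUE(dust), dust_window = as.integer(dust_window),
                 dust_threshold = dust_threshold,
                 xdrop_ungapped = xdrop_ungapped, xdrop_gapped = xdrop_gapped,
                 gap_trigger_raw = gap_trigger_raw),
            class = "scoring_scheme")
}

#' Convert a raw alignment score to bits
#'
#' \code{bits = (lambda * raw - ln K) / ln 2}. Under the default scheme a
#' perfect gapless 15 bp match (raw 15) scores 29.5 bits at one decimal place.
#'
#' @param raw raw alignment score(s).
#' @param scheme a [scoring_scheme()].
#' @return numeric bit score(s).
#' @export
bit_score <- function(raw, scheme = scoring_scheme()) {
  (scheme$lambda * raw - log(scheme$k)) / log(2)
}

#' Raw score equivalent of a bit score
#'
#' Inverse of [bit_score()]; used to translate bit-score thresholds into raw
#' score cutoffs for the aligner.
#'
#' @inheritParams bit_score
#' @param bits bit score(s).
#' @export
raw_for_bits <- function(bits, scheme = scoring_scheme()) {
  (bits * log(2) + log(scheme$k)) / scheme$lambda
}

#' Karlin-Altschul expect value
#'
#' \code{E = K * m * n * exp(-lambda * raw)} with search space \code{m * n}.
#'
#' @inheritParams bit_score
#' @param m,n effective query and subject search lengths (bp).
#' @export
expect_value <- function(raw, m, n, scheme = scoring_scheme()) {
  scheme$k * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * raw)
}

# smallest integer raw score whose expect value is below the cutoff
min_raw_for_expect <- function(max_expect, m, n, scheme) {
  ceiling((log(scheme$k * as.numeric(m) * as.numeric(n)) - log(max_expect)) /
            scheme$lambda)
}
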