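# Independent reference implementations used to cross-check the package's
# algorithms. Deliberately naive: exhaustive enumeration / literal simulation.

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rcomp <- function(s) chartr("ACGTN", "TGCAN",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))

plant <- function(host, guest, at) {   # 1-based position
  substr(host, at, at + nchar(guest) - 1L) <- guest
  host
}

rand_clean <- function(n) {   # random sequence with no DUST-flagged stretch
  repeat {
    s <- rseq(n)
    if (!any(cnspipe::dust_mask(s))) return(s)
  }
}

# -- exact-match self-coverage oracle ----------------------------------------
# Counts, per position, maximal exact self-matches of length >= min_len,
# one count per unordered pair of loci, identity excluded. Intended for toy
# genomes whose repeat copies are flanked by N so that every alignment is an
# exact match.
oracle_exact_coverage <- function(seqs, word = 15, min_len = 15) {
  # concatenate with N spacers; track per-chromosome offsets
  gap <- strrep("N", word + 5)
  cat_seq <- paste(seqs, collapse = gap)
  offs <- cumsum(c(0, head(nchar(seqs) + nchar(gap), -1)))
  names(offs) <- names(seqs)
  n <- nchar(cat_seq)
  chars <- strsplit(cat_seq, "")[[1]]

  collect <- function(s2, tag) {
    # all maximal exact matches between cat_seq and s2 (forward orientation
    # of s2 within the function; caller maps coordinates)
    c2 <- strsplit(s2, "")[[1]]
    words <- substring(cat_seq, seq_len(n - word + 1),
                       seq_len(n - word + 1) + word - 1)
    words2 <- substring(s2, seq_len(nchar(s2) - word + 1),
                        seq_len(nchar(s2) - word + 1) + word - 1)
    ok <- !grepl("N", words, fixed = TRUE)
    idx <- split(which(ok), words[ok])
    out <- NULL
    seen <- character(0)
    for (j in which(!grepl("N", words2, fixed = TRUE))) {
      for (i in idx[[words2[j]]]) {
        # extend to a maximal exact match
        a <- i; b <- j
        while (a > 1 && b > 1 && chars[a - 1] == c2[b - 1] &&
               chars[a - 1] != "N") { a <- a - 1; b <- b - 1 }
        len <- word
        while (a + len <= n && b + len <= nchar(s2) &&
               chars[a + len] == c2[b + len] && chars[a + len] != "N")
          len <- len + 1
        len <- len + 0
        # recompute true maximal length from the left-extended anchor
        l2 <- 0
        while (a + l2 <= n && b + l2 <= nchar(s2) &&
               chars[a + l2] == c2[b + l2] && chars[a + l2] != "N")
          l2 <- l2 + 1
        key <- paste(tag, a, b, l2)
        if (key %in% seen) next
        seen <- c(seen, key)
        out <- rbind(out, data.frame(a = a, b = b, len = l2, tag = tag))
      }
    }
    out
  }

  fw <- collect(cat_seq, "fw")
  rv <- collect(rcomp(cat_seq), "rv")
  cov <- integer(n)
  bump <- function(a, len) {
    cov[a:(a + len - 1)] <<- cov[a:(a + len - 1)] + 1L
  }
  if (!is.null(fw)) for (r in seq_len(nrow(fw))) {
    if (fw$len[r] < min_len) next
    a <- fw$a[r]; b <- fw$b[r]
    if (a >= b) next               # unordered pairs once; identity excluded
    bump(a, fw$len[r]); bump(b, fw$len[r])
  }
  if (!is.null(rv)) for (r in seq_len(nrow(rv))) {
    if (rv$len[r] < min_len) next
    a <- rv$a[r]
    b_f <- n - (rv$b[r] + rv$len[r] - 1) + 1   # map RC coords to forward
    if (a > b_f) next
    bump(a, rv$len[r]); bump(b_f, rv$len[r])
  }
  # split back into chromosomes
  lapply(setNames(names(seqs), names(seqs)), function(ch) {
    cov[(offs[ch] + 1):(offs[ch] + nchar(seqs[ch]))]
  })
}

# -- geometric filter oracles -------------------------------------------------

oracle_rect_intersect <- function(d, i, j) {
  d$qstart[i] < d$qend[j] && d$qstart[j] < d$qend[i] &&
    d$sstart[i] < d$send[j] && d$sstart[j] < d$send[i]
}

# literal simulation: repeatedly remove the conflicted candidate with the
# largest expect (ties: lower bit, then smaller qstart)
oracle_overlap_resolution <- function(d) {
  alive <- rep(TRUE, nrow(d))
  repeat {
    conf <- rep(FALSE, nrow(d))
    iv <- which(alive)
    for (i in iv) for (j in iv) if (i < j && oracle_rect_intersect(d, i, j)) {
      conf[i] <- TRUE; conf[j] <- TRUE
    }
    if (!any(conf)) break
    cand <- which(conf)
    o <- cand[order(-d$expect[cand], d$bit_score[cand], d$qstart[cand])]
    alive[o[1]] <- FALSE
  }
  alive
}

oracle_crossings <- function(d, idx, orientation = "same") {
  qm <- (d$qstart[idx] + d$qend[idx]) / 2
  sm <- (d$sstart[idx] + d$send[idx]) / 2
  if (orientation == "inverted") sm <- -sm
  sapply(seq_along(idx), function(a)
    sum(sapply(seq_along(idx), function(b)
      a != b && ((qm[a] < qm[b]) != (sm[a] < sm[b])))))
}

oracle_collinearity <- function(d, orientation = "same") {
  alive <- rep(TRUE, nrow(d))
  repeat {
    iv <- which(alive)
    if (length(iv) < 2) break
    nc <- oracle_crossings(d, iv, orientation)
    if (all(nc == 0)) break
    cand <- iv[nc > 0]
    o <- cand[order(d$bit_score[cand], -d$expect[cand], d$qstart[cand])]
    alive[o[1]] <- FALSE
  }
  alive
}

# analytic bow-tie membership (band form of the hexagon)
oracle_in_bowtie <- function(px, py, cx, cy, extent, w0, slope,
                             orientation = "same") {
  sgn <- if (orientation == "inverted") -1 else 1
  dx <- px - cx; dy <- py - cy
  abs(dy - sgn * dx) < w0 + slope * abs(dx) & abs(dx) < extent
}

# -- statistics oracles -------------------------------------------------------

# two-sided Fisher p: sum of hypergeometric point masses <= that of the table
oracle_fisher2 <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p0 <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

oracle_chisq <- function(tab, correct = FALSE) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (correct) sum((abs(tab - E) - 0.5)^2 / E) else sum((tab - E)^2 / E)
}

# greedy non-overlapping motif count by explicit placement enumeration
oracle_motif_count <- function(pattern, s) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  pat <- strsplit(toupper(pattern), "")[[1]]
  sv <- strsplit(s, "")[[1]]
  plen <- length(pat)
  hits <- integer(0)
  for (i in seq_len(max(0, length(sv) - plen + 1))) {
    win <- sv[i:(i + plen - 1)]
    if (all(mapply(function(b, p) b %in% strsplit(iupac[[p]], "")[[1]],
                   win, pat)))
      hits <- c(hits, i)
  }
  cnt <- 0L; last_end <- 0L
  for (h in hits) if (h > last_end) { cnt <- cnt + 1L; last_end <- h + plen - 1L }
  cnt
}

# random candidate sets for the geometric filter property tests
random_candidates <- function(n, span = 10000) {
  qs <- sort(sample(span, n))
  d <- data.frame(
    qstart = qs, qend = qs + sample(15:60, n, TRUE),
    sstart = sample(span, n), strand = "forward")
  d$send <- d$sstart + sample(15:60, n, TRUE)
  d$raw <- sample(15:40, n, TRUE)
  d$bit_score <- bit_score(d$raw)
  d$expect <- expect_value(d$raw, span, span)
  d$status <- "live"; d$reason <- NA_character_
  d
}
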