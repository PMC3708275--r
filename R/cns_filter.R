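#' Geometric filter cascade for candidate CNSs
#'
#' Candidate hits of one syntenic gene pair are treated as rectangles in the
#' (query coordinate x subject coordinate) plane and reduced to a mutually
#' syntenic set by the fixed cascade: orientation consistency, intron
#' consistency, iterative overlap resolution, crossing removal, collinearity
#' enforcement and the bow-tie polygon. Every stage is a pure function of its
#' input given the tie-break rules, and each removed candidate records the
#' stage that removed it. The final set has zero crossing pairs and zero
#' intersecting rectangles.
#'
#' @name cns_filter
NULL

new_candidates <- function(hits) {
  hits$status <- "live"
  hits$reason <- NA_character_
  hits
}

#' Orientation filter
#'
#' A hit must be in the same orientation as the syntenic gene pair: forward
#' hits are kept when the two genes are on like strands, reverse hits when
#' they are on opposite strands; everything else is removed.
#'
#' @param cands candidate data.frame (columns strand, status, reason).
#' @param strand_q,strand_s strands of the query and subject genes.
#' @export
orientation_filter <- function(cands, strand_q, strand_s) {
  expected <- if (strand_q == strand_s) "forward" else "reverse"
  i <- cands$status == "live" & cands$strand != expected
  cands$status[i] <- "removed"; cands$reason[i] <- "orientation"
  cands
}

#' Intron consistency filter
#'
#' A hit lying within an intron of one gene of the pair but not within an
#' intron of the other is removed.
#'
#' @param cands candidate data.frame.
#' @param introns_q,introns_s intron interval data.frames (start, end) of the
#'   query and subject genes in genome coordinates.
#' @export
intron_consistency_filter <- function(cands, introns_q, introns_s) {
  inside <- function(s, e, iv) {
    if (nrow(iv) == 0) return(rep(FALSE, length(s)))
    vapply(seq_along(s), function(k)
      any(iv$start <= s[k] & iv$end >= e[k]), logical(1))
  }
  in_q <- inside(cands$qstart, cands$qend, introns_q)
  in_s <- inside(cands$sstart, cands$send, introns_s)
  i <- cands$status == "live" & xor(in_q, in_s)
  cands$status[i] <- "removed"; cands$reason[i] <- "intron_mismatch"
  cands
}

rect_intersects <- function(c1, c2) {
  c1$qstart < c2$qend & c2$qstart < c1$qend &
    c1$sstart < c2$send & c2$sstart < c1$send
}

#' Iterative overlap resolution
#'
#' While any two live rectangles intersect (overlap on both axes), the
#' candidate with the least significant expect value among those in conflict
#' is removed (ties: lower bit score, then smaller query start).
#'
#' @param cands candidate data.frame.
#' @export
resolve_overlaps <- function(cands) {
  repeat {
    live <- which(cands$status == "live")
    if (length(live) < 2) break
    conflicted <- rep(FALSE, length(live))
    for (a in seq_along(live)) {
      for (b in seq_along(live)) {
        if (a >= b) next
        if (rect_intersects(cands[live[a], ], cands[live[b], ])) {
          conflicted[a] <- TRUE; conflicted[b] <- TRUE
        }
      }
    }
    if (!any(conflicted)) break
    cf <- live[conflicted]
    o <- order(-cands$expect[cf], cands$bit_score[cf], cands$qstart[cf])
    drop <- cf[o[1]]
    cands$status[drop] <- "removed"; cands$reason[drop] <- "overlap"
  }
  cands
}

crossing_matrix <- function(cands, idx, orientation) {
  qm <- (cands$qstart[idx] + cands$qend[idx]) / 2
  sm <- (cands$sstart[idx] + cands$send[idx]) / 2
  if (orientation == "inverted") sm <- -sm
  n <- length(idx)
  m <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    m[a, b] <- (qm[a] < qm[b]) != (sm[a] < sm[b])
  }
  m
}

#' Crossing filter
#'
#' Hits crossing three or more other live hits (counted simultaneously on the
#' stage's input set, midpoint comparison, subject axis reflected for inverted
#' blocks) are removed.
#'
#' @param cands candidate data.frame.
#' @param orientation block orientation, "same" or "inverted".
#' @param max_crossings removal threshold (inclusive).
#' @export
crossing_filter <- function(cands, orientation = "same", max_crossings = 3L) {
  live <- which(cands$status == "live")
  if (length(live) < 2) return(cands)
  m <- crossing_matrix(cands, live, orientation)
  nc <- rowSums(m)
  drop <- live[nc >= max_crossings]
  cands$status[drop] <- "removed"; cands$reason[drop] <- "crossing"
  cands
}

#' Collinearity enforcement
#'
#' While any crossing pair remains among live hits, the conflicting hit with
#' the lowest bit score (ties: larger expect, then smaller query start) is
#' removed, until all remaining hits appear in the same order in both genomes.
#'
#' @inheritParams crossing_filter
#' @export
enforce_collinearity <- function(cands, orientation = "same") {
  repeat {
    live <- which(cands$status == "live")
    if (length(live) < 2) break
    m <- crossing_matrix(cands, live, orientation)
    nc <- rowSums(m)
    if (!any(nc > 0)) break
    cf <- live[nc > 0]
    o <- order(cands$bit_score[cf], -cands$expect[cf], cands$qstart[cf])
    drop <- cf[o[1]]
    cands$status[drop] <- "removed"; cands$reason[drop] <- "order"
  }
  cands
}

#' Bow-tie polygon vertices
#'
#' The syntenic tolerance region around a gene pair: an expanding band (two
#' wedges meeting at a knot of half-width \code{w0} at the center) around the
#' block diagonal, represented as a hexagon. At signed query-axis distance d
#' from the center the tolerated subject offset is \code{w0 + slope * |d|}.
#'
#' @param center_q,center_s gene midpoints (query and subject genome
#'   coordinates).
#' @param extent polygon reach along the query axis (pad + gene-space length).
#' @param w0 half-width at the center (bp).
#' @param slope tolerance growth per bp of query distance (doubled in
#'   large-genome mode).
#' @param orientation "same" (+1 diagonal) or "inverted" (-1).
#' @return matrix with columns x, y (6 vertices).
#' @export
bowtie_polygon <- function(center_q, center_s, extent, w0 = 200, slope = 0.5,
                           orientation = "same") {
  if (extent <= 0) stop("degenerate bow-tie polygon: extent must be positive")
  if (w0 <= 0) stop("degenerate bow-tie polygon: w0 must be positive")
  sgn <- if (orientation == "inverted") -1 else 1
  wE <- w0 + slope * extent
  x <- c(center_q - extent, center_q, center_q + extent,
         center_q + extent, center_q, center_q - extent)
  y <- c(center_s - sgn * extent - wE, center_s - w0, center_s + sgn * extent - wE,
         center_s + sgn * extent + wE, center_s + w0, center_s - sgn * extent + wE)
  cbind(x = x, y = y)
}

#' Ray-casting point-in-polygon test
#'
#' @param px,py point coordinates (vectorized).
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
        xint <- (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1]
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

#' Bow-tie syntenic filter
#'
#' A hit is kept when its representative point (query midpoint, subject
#' midpoint) lies inside the bow-tie polygon centered on the gene-pair
#' midpoints; increasing positional discrepancies are tolerated further from
#' the genes.
#'
#' @param cands candidate data.frame.
#' @param poly polygon from [bowtie_polygon()].
#' @export
bowtie_filter <- function(cands, poly) {
  live <- which(cands$status == "live")
  if (length(live) == 0) return(cands)
  qm <- (cands$qstart[live] + cands$qend[live]) / 2
  sm <- (cands$sstart[live] + cands$send[live]) / 2
  ok <- point_in_polygon(qm, sm, poly)
  drop <- live[!ok]
  cands$status[drop] <- "removed"; cands$reason[drop] <- "bowtie"
  cands
}

#' Run the full filter cascade for one gene pair
#'
#' Applies the six stages in the fixed order orientation, intron, overlap,
#' crossing, order, bow-tie, recording the removal reason per candidate.
#'
#' @param hits hit data.frame from [align_gene_space()] after
#'   [threshold_filter()].
#' @param window_q,window_s the pair's gene-space windows.
#' @param ann_q,ann_s annotations (for strands and introns).
#' @param orientation block orientation ("same"/"inverted").
#' @param w0,slope bow-tie parameters.
#' @return the candidate data.frame with status/reason columns (the audit
#'   trail); live rows are the surviving CNS candidates.
#' @export
cns_filter_cascade <- function(hits, window_q, window_s, ann_q, ann_s,
                               orientation = "same", w0 = 200, slope = 0.5) {
  cands <- new_candidates(hits)
  cands <- orientation_filter(cands, window_q$strand, window_s$strand)
  cands <- intron_consistency_filter(
    cands,
    gene_introns(ann_q, window_q$gene_id),
    gene_introns(ann_s, window_s$gene_id))
  cands <- resolve_overlaps(cands)
  cands <- crossing_filter(cands, orientation)
  cands <- enforce_collinearity(cands, orientation)
  center_q <- (window_q$gene_start + window_q$gene_end) / 2
  center_s <- (window_s$gene_start + window_s$gene_end) / 2
  extent <- max(center_q - window_q$start, window_q$end - center_q)
  poly <- bowtie_polygon(center_q, center_s, extent, w0, slope, orientation)
  bowtie_filter(cands, poly)
}
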