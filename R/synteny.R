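#' Score CDS anchor pairs between two genomes
#'
#' All-vs-all local alignment of the spliced CDS sets (word size 20 by
#' default), keeping the best raw score per gene pair over both strands. The
#' cscore of a pair is its score divided by the best cross-genome score
#' involving either gene; pairs with cscore at or below the cutoff are
#' dropped (strictly greater than 0.5 survives).
#'
#' @param cds_q,cds_s named spliced CDS sets of the two genomes.
#' @param word anchor seed word size.
#' @param max_expect expect cutoff for anchor hits.
#' @param cscore_min cscore cutoff (strict).
#' @param scheme scoring scheme.
#' @param exclude_self drop pairs of identical gene ids (self-comparison runs).
#' @return data.frame: q_gene, s_gene, raw, cscore.
#' @export
score_anchors <- function(cds_q, cds_s, word = 20, max_expect = 1e-3,
                          cscore_min = 0.5, scheme = scoring_scheme(),
                          exclude_self = FALSE) {
  scheme$word <- as.integer(word)
  m <- sum(nchar(cds_q)); n <- sum(nchar(cds_s))
  min_raw <- max(word, min_raw_for_expect(max_expect, m, n, scheme))
  h <- seed_hits(cds_q, cds_s, scheme, min_raw = min_raw,
                 both_strands = TRUE, dust = FALSE)
  if (exclude_self) h <- h[h$qname != h$sname, , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(q_gene = character(), s_gene = character(),
                      raw = numeric(), cscore = numeric()))
  key <- paste(h$qname, h$sname, sep = "\r")
  raw <- tapply(h$raw, key, max)
  pr <- do.call(rbind, strsplit(names(raw), "\r", fixed = TRUE))
  a <- data.frame(q_gene = pr[, 1], s_gene = pr[, 2],
                  raw = as.numeric(raw), stringsAsFactors = FALSE)
  best_q <- tapply(a$raw, a$q_gene, max)
  best_s <- tapply(a$raw, a$s_gene, max)
  a$cscore <- a$raw / pmax(best_q[a$q_gene], best_s[a$s_gene])
  a[a$cscore > cscore_min, , drop = FALSE]
}

# gene order indices per chromosome (0-based rank by start)
gene_order <- function(ann) {
  g <- ann$genes
  g$order <- NA_integer_
  for (chrom in unique(g$chrom)) {
    i <- which(g$chrom == chrom)
    g$order[i[order(g$start[i])]] <- seq_along(i) - 1L
  }
  g[, c("gene_id", "chrom", "order", "start", "end")]
}

#' Cluster local duplicate genes
#'
#' Homologous genes on the same chromosome of one genome separated by no more
#' than \code{n_max} intervening genes are clustered transitively into a
#' single tandem group; one representative per cluster (the 5'-most member by
#' default) enters syntenic chaining. After CNS discovery the representative
#' can be re-chosen as the member with the most CNSs
#' ([reselect_representatives()]).
#'
#' @param pairs_within data.frame of within-genome homologous pairs
#'   (columns q_gene, s_gene), e.g. from [score_anchors()] of a CDS set
#'   against itself with \code{exclude_self = TRUE}.
#' @param ann the genome's [gene_annotation()].
#' @param n_max maximum intervening genes between successive cluster members.
#' @return data.frame: gene_id, cluster, representative (logical).
#' @export
collapse_tandems <- function(pairs_within, ann, n_max = 20) {
  ord <- gene_order(ann)
  idx <- setNames(seq_len(nrow(ord)), ord$gene_id)
  parent <- seq_len(nrow(ord))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (k in seq_len(nrow(pairs_within))) {
    a <- idx[[pairs_within$q_gene[k]]]; b <- idx[[pairs_within$s_gene[k]]]
    if (is.null(a) || is.null(b)) next
    if (ord$chrom[a] != ord$chrom[b]) next
    if (abs(ord$order[a] - ord$order[b]) - 1L > n_max) next
    union2(a, b)
  }
  root <- vapply(seq_len(nrow(ord)), find, integer(1))
  out <- data.frame(gene_id = ord$gene_id, chrom = ord$chrom,
                    order = ord$order, cluster = root,
                    stringsAsFactors = FALSE)
  out$representative <- FALSE
  for (cl in unique(out$cluster)) {
    i <- which(out$cluster == cl)
    out$representative[i[which.min(out$order[i])]] <- TRUE
  }
  # relabel clusters compactly, singletons included
  out$cluster <- match(out$cluster, unique(out$cluster))
  out
}

#' Re-choose tandem representatives by CNS count
#'
#' After CNS discovery, the retained copy of each tandem cluster is the member
#' with the most CNSs (ties broken toward the 5'-most member).
#'
#' @param clusters output of [collapse_tandems()].
#' @param cns_counts named integer vector (gene id -> CNS count); missing
#'   genes count 0.
#' @export
reselect_representatives <- function(clusters, cns_counts) {
  cnt <- cns_counts[clusters$gene_id]
  cnt[is.na(cnt)] <- 0L
  clusters$representative <- FALSE
  for (cl in unique(clusters$cluster)) {
    i <- which(clusters$cluster == cl)
    j <- i[order(-cnt[i], clusters$order[i])][1]
    clusters$representative[j] <- TRUE
  }
  clusters
}

#' Chain anchors into syntenic blocks
#'
#' Iteratively extracts maximal-scoring collinear chains of anchor pairs:
#' successive anchors must advance by at most \code{d_max} gene-order indices
#' on both genomes, increasing on the query and either increasing (same
#' orientation) or decreasing (inverted) on the subject. Chains shorter than
#' \code{min_size} anchors are dropped. Chaining depends only on gene order,
#' so it is invariant under chromosome relabeling and coordinate translation.
#'
#' @param anchors data.frame with q_gene, s_gene, raw (scores), plus gene
#'   order columns q_chrom, q_idx, s_chrom, s_idx.
#' @param d_max maximum gene-order gap for extending a chain.
#' @param min_size minimum anchors per block.
#' @return data.frame of anchors with block and orientation columns
#'   (anchors not in any block are omitted).
#' @export
chain_anchors <- function(anchors, d_max = 20, min_size = 4) {
  if (nrow(anchors) == 0) {
    anchors$block <- integer(); anchors$orientation <- character()
    return(anchors)
  }
  a <- anchors
  a$.id <- seq_len(nrow(a))
  live <- rep(TRUE, nrow(a))
  blocks <- list(); bid <- 0L

  best_chain <- function(av, inverted) {
    # DP over anchors sorted by query order; O(n^2), desk-scale instances
    sv <- if (inverted) -av$s_idx else av$s_idx
    o <- order(av$q_idx, sv)
    av <- av[o, , drop = FALSE]; sv <- sv[o]
    n <- nrow(av)
    dp <- av$raw; prev <- rep(NA_integer_, n); cnt <- rep(1L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (av$q_chrom[j] != av$q_chrom[i] || av$s_chrom[j] != av$s_chrom[i]) next
        dq <- av$q_idx[i] - av$q_idx[j]; ds <- sv[i] - sv[j]
        if (dq < 1 || dq > d_max || ds < 1 || ds > d_max) next
        if (dp[j] + av$raw[i] > dp[i]) {
          dp[i] <- dp[j] + av$raw[i]; prev[i] <- j; cnt[i] <- cnt[j] + 1L
        }
      }
    }
    i <- which.max(dp)
    chain <- integer(0)
    while (!is.na(i)) { chain <- c(av$.id[i], chain); i <- prev[i] }
    list(score = max(dp), size = length(chain), members = chain)
  }

  repeat {
    av <- a[live, , drop = FALSE]
    if (nrow(av) < min_size) break
    cand <- list(best_chain(av, FALSE), best_chain(av, TRUE))
    sizes <- vapply(cand, `[[`, integer(1), "size")
    scores <- vapply(cand, `[[`, numeric(1), "score")
    ok <- sizes >= min_size
    if (!any(ok)) break
    pick <- which(ok)[which.max(scores[ok])]
    bid <- bid + 1L
    mem <- cand[[pick]]$members
    blocks[[bid]] <- data.frame(.id = mem, block = bid,
                                orientation = if (pick == 1) "same" else "inverted")
    live[mem] <- FALSE
  }
  if (length(blocks) == 0) {
    out <- a[0, , drop = FALSE]; out$block <- integer(); out$orientation <- character()
    out$.id <- NULL
    return(out)
  }
  bl <- do.call(rbind, blocks)
  out <- merge(a, bl, by = ".id")
  out <- out[order(out$block, out$q_idx), , drop = FALSE]
  out$.id <- NULL
  rownames(out) <- NULL
  out
}

#' Enforce ploidy quotas on syntenic blocks
#'
#' Greedy selection of blocks by descending score such that no query
#' gene-order interval is covered by more than \code{quota_q} selected blocks
#' and no subject interval by more than \code{quota_s}. Blocks violating the
#' quota against already-selected blocks are removed (this is where
#' contaminating out-of-ploidy blocks drop out). Greedy selection may be
#' suboptimal but always satisfies the quota constraints.
#'
#' @param chained output of [chain_anchors()].
#' @param quota_q,quota_s maximum coverage multiplicities (>= 1).
#' @return the chained data.frame restricted to selected blocks.
#' @export
enforce_quota <- function(chained, quota_q = 1L, quota_s = 1L) {
  if (quota_q < 1 || quota_s < 1) stop("quotas must be >= 1")
  if (nrow(chained) == 0) return(chained)
  per <- split(chained, chained$block)
  scores <- vapply(per, function(b) sum(b$raw), numeric(1))
  ord <- order(-scores, as.integer(names(per)))
  # coverage is counted over the gene-order indices between consecutive block
  # members (so an isolated outlier anchor does not claim the whole span)
  member_idx <- function(b, side) {
    chrom <- b[[paste0(side, "_chrom")]][1]
    idx <- sort(unique(b[[paste0(side, "_idx")]]))
    runs <- split(idx, cumsum(c(1L, diff(idx) > 1L)))
    paste0(chrom, ":", unlist(lapply(runs, function(r) seq(min(r), max(r)))))
  }
  qcov <- integer(0); scov <- integer(0)
  keep <- integer(0)
  for (i in ord) {
    b <- per[[i]]
    qi <- member_idx(b, "q"); si <- member_idx(b, "s")
    if (length(qcov) && any(qcov[qi] >= quota_q, na.rm = TRUE)) next
    if (length(scov) && any(scov[si] >= quota_s, na.rm = TRUE)) next
    for (k in qi) qcov[k] <- if (is.na(qcov[k])) 1L else qcov[k] + 1L
    for (k in si) scov[k] <- if (is.na(scov[k])) 1L else scov[k] + 1L
    keep <- c(keep, b$block[1])
  }
  chained[chained$block %in% keep, , drop = FALSE]
}

#' Find syntenic gene pairs between two annotated genomes
#'
#' Orchestrates the synteny stage: CDS anchor scoring with the cscore filter,
#' tandem-duplicate collapsing on both genomes, chain formation and quota
#' enforcement. For a self-comparison (both genomes identical), self pairs are
#' excluded and each unordered pair is used once (upper triangle by gene
#' order), so homeologous blocks are reported a single time.
#'
#' @param genome_q,genome_s masked [genome_seq()] objects.
#' @param ann_q,ann_s matching [gene_annotation()] objects (co-annotated
#'   genes included).
#' @param word,max_expect,cscore_min anchor scoring parameters.
#' @param tandem_nmax tandem collapsing distance (intervening genes).
#' @param d_max,min_size chaining parameters.
#' @param quota string "p:q" or integer vector c(p, q).
#' @param scheme scoring scheme.
#' @return list(pairs, blocks, anchors, clusters_q, clusters_s).
#' @export
find_synteny <- function(genome_q, ann_q, genome_s, ann_s,
                         word = 20, max_expect = 1e-3, cscore_min = 0.5,
                         tandem_nmax = 20, d_max = 20, min_size = 4,
                         quota = "1:1", scheme = scoring_scheme()) {
  qt <- parse_quota(quota)
  self_cmp <- identical(genome_q$genome_id, genome_s$genome_id)
  cds_q <- cds_sequences(genome_q, ann_q)
  cds_s <- cds_sequences(genome_s, ann_s)
  anchors <- score_anchors(cds_q, cds_s, word, max_expect, cscore_min, scheme,
                           exclude_self = self_cmp)

  # within-genome homology for tandem clustering
  w_q <- score_anchors(cds_q, cds_q, word, max_expect, cscore_min, scheme,
                       exclude_self = TRUE)
  w_s <- if (self_cmp) w_q else
    score_anchors(cds_s, cds_s, word, max_expect, cscore_min, scheme,
                  exclude_self = TRUE)
  cl_q <- collapse_tandems(w_q, ann_q, tandem_nmax)
  cl_s <- if (self_cmp) cl_q else collapse_tandems(w_s, ann_s, tandem_nmax)

  rep_q <- cl_q$gene_id[cl_q$representative]
  rep_s <- cl_s$gene_id[cl_s$representative]
  anchors <- anchors[anchors$q_gene %in% rep_q & anchors$s_gene %in% rep_s, ,
                     drop = FALSE]

  ord_q <- gene_order(ann_q); ord_s <- gene_order(ann_s)
  # order indices among representatives only (clusters act as single genes)
  oq <- ord_q[ord_q$gene_id %in% rep_q, ]; os <- ord_s[ord_s$gene_id %in% rep_s, ]
  oq <- do.call(rbind, lapply(split(oq, oq$chrom), function(d) {
    d$idx <- rank(d$order) - 1L; d }))
  os <- do.call(rbind, lapply(split(os, os$chrom), function(d) {
    d$idx <- rank(d$order) - 1L; d }))
  anchors$q_chrom <- oq$chrom[match(anchors$q_gene, oq$gene_id)]
  anchors$q_idx <- oq$idx[match(anchors$q_gene, oq$gene_id)]
  anchors$s_chrom <- os$chrom[match(anchors$s_gene, os$gene_id)]
  anchors$s_idx <- os$idx[match(anchors$s_gene, os$gene_id)]

  if (self_cmp) {
    pos_q <- ord_q$start[match(anchors$q_gene, ord_q$gene_id)]
    pos_s <- ord_s$start[match(anchors$s_gene, ord_s$gene_id)]
    keep <- (anchors$q_chrom < anchors$s_chrom) |
      (anchors$q_chrom == anchors$s_chrom & pos_q < pos_s)
    anchors <- anchors[keep, , drop = FALSE]
  }

  chained <- chain_anchors(anchors, d_max, min_size)
  selected <- enforce_quota(chained, qt[1], qt[2])
  pairs <- selected[, c("q_gene", "s_gene", "block", "orientation", "raw")]
  pairs$pair_id <- paste(pairs$q_gene, pairs$s_gene, sep = "~")
  rownames(pairs) <- NULL
  list(pairs = pairs, blocks = selected, anchors = anchors,
       clusters_q = cl_q, clusters_s = cl_s)
}

parse_quota <- function(quota) {
  if (is.character(quota)) {
    parts <- suppressWarnings(as.integer(strsplit(quota, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || any(is.na(parts))) stop("quota must look like '1:2'")
    parts
  } else {
    as.integer(quota)
  }
}
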