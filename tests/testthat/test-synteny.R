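scheme <- scoring_scheme()

test_that("cscore is score over the best score of either gene, strictly > 0.5", {
  set.seed(401)
  a <- rseq(600)
  cds_q <- c(q1 = a)
  # s1: full-length copy (the best hit); s2 shares 250 bp (cscore ~ 0.42,
  # dropped); s3 shares 400 bp (cscore ~ 0.67, kept)
  cds_s <- c(s1 = a,
             s2 = paste0(substring(a, 1, 250), rseq(350)),
             s3 = paste0(substring(a, 1, 400), rseq(200)))
  res <- score_anchors(cds_q, cds_s, scheme = scheme)
  expect_true("s1" %in% res$s_gene)
  expect_equal(res$cscore[res$s_gene == "s1"], 1.0)
  expect_false("s2" %in% res$s_gene)
  expect_true("s3" %in% res$s_gene)
  expect_equal(res$cscore[res$s_gene == "s3"],
               res$raw[res$s_gene == "s3"] / res$raw[res$s_gene == "s1"])
})

test_that("tandem clustering respects the intervening-gene cutoff", {
  mk_ann <- function(n, chrom = "c1") {
    gene_annotation(
      data.frame(gene_id = paste0("g", seq_len(n)), chrom = chrom,
                 start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
                 strand = "+", origin = "official"),
      data.frame(gene_id = paste0("g", seq_len(n)),
                 start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L))
  }
  ann <- mk_ann(30)
  pairs <- data.frame(q_gene = "g1", s_gene = "g2")     # adjacent homologs
  cl <- collapse_tandems(pairs, ann, n_max = 20)
  expect_equal(cl$cluster[cl$gene_id == "g1"], cl$cluster[cl$gene_id == "g2"])
  expect_equal(sum(cl$representative[cl$gene_id %in% c("g1", "g2")]), 1)
  expect_true(cl$representative[cl$gene_id == "g1"])    # 5'-most member

  # 21 intervening genes: separate clusters (boundary at 20)
  far <- data.frame(q_gene = "g1", s_gene = "g23")      # 21 genes between
  cl2 <- collapse_tandems(far, ann, n_max = 20)
  expect_false(cl2$cluster[cl2$gene_id == "g1"] ==
                 cl2$cluster[cl2$gene_id == "g23"])
  edge <- data.frame(q_gene = "g1", s_gene = "g22")     # exactly 20 between
  cl3 <- collapse_tandems(edge, ann, n_max = 20)
  expect_equal(cl3$cluster[cl3$gene_id == "g1"], cl3$cluster[cl3$gene_id == "g22"])

  # transitivity across a chain of gaps
  chain <- data.frame(q_gene = c("g1", "g7", "g13"), s_gene = c("g7", "g13", "g19"))
  cl4 <- collapse_tandems(chain, ann, n_max = 20)
  expect_equal(length(unique(cl4$cluster[cl4$gene_id %in%
                                           c("g1", "g7", "g13", "g19")])), 1)
})

test_that("representatives are re-chosen by CNS count after discovery", {
  ann <- gene_annotation(
    data.frame(gene_id = c("a", "b"), chrom = "c1", start = c(0L, 1000L),
               end = c(500L, 1500L), strand = "+", origin = "official"),
    data.frame(gene_id = c("a", "b"), start = c(0L, 1000L),
               end = c(500L, 1500L)))
  cl <- collapse_tandems(data.frame(q_gene = "a", s_gene = "b"), ann)
  expect_true(cl$representative[cl$gene_id == "a"])
  cl2 <- reselect_representatives(cl, c(a = 1L, b = 5L))
  expect_true(cl2$representative[cl2$gene_id == "b"])
  expect_false(cl2$representative[cl2$gene_id == "a"])
})

mk_anchors <- function(qi, si, raw = 100, q_chrom = "c1", s_chrom = "d1") {
  data.frame(q_gene = paste0("q", seq_along(qi)),
             s_gene = paste0("s", seq_along(qi)),
             raw = rep_len(raw, length(qi)), q_chrom = q_chrom, q_idx = qi,
             s_chrom = s_chrom, s_idx = si, stringsAsFactors = FALSE)
}

test_that("chaining finds collinear runs and honours min_size and Dm", {
  b <- chain_anchors(mk_anchors(1:5, 11:15))
  expect_equal(nrow(b), 5)
  expect_equal(unique(b$block), 1L)
  expect_equal(unique(b$orientation), "same")

  expect_equal(nrow(chain_anchors(mk_anchors(1:3, 1:3))), 0)  # < min_size

  two <- chain_anchors(mk_anchors(c(1:5, 31:35), c(1:5, 31:35)))
  expect_equal(length(unique(two$block)), 2)    # 25-index gap breaks the chain

  inv <- chain_anchors(mk_anchors(1:5, 20:16))
  expect_equal(unique(inv$orientation), "inverted")
  expect_equal(nrow(inv), 5)
})

test_that("chaining is invariant under relabeling and index translation", {
  a1 <- mk_anchors(1:6, 3:8)
  a2 <- mk_anchors(1:6 + 100, 3:8 + 250, q_chrom = "zz", s_chrom = "yy")
  b1 <- chain_anchors(a1); b2 <- chain_anchors(a2)
  expect_equal(b1$q_gene, b2$q_gene)
  expect_equal(b1$orientation, b2$orientation)
})

test_that("quota enforcement keeps the best block per covered region", {
  # two blocks overlapping on the query, scores 90 vs 40, quota 1:1
  a <- rbind(cbind(mk_anchors(1:4, 1:4, raw = 90 / 4), block = 1L,
                   orientation = "same"),
             cbind(mk_anchors(2:5, 11:14, raw = 10), block = 2L,
                   orientation = "same"))
  sel <- enforce_quota(a, 1, 1)
  expect_equal(unique(sel$block), 1L)
  # quota 1:2: one query region matched by two subject-disjoint blocks
  sel2 <- enforce_quota(a, 2, 1)
  expect_setequal(unique(sel2$block), c(1L, 2L))
  # no overlaps anywhere: all blocks kept regardless of quota
  b <- rbind(cbind(mk_anchors(1:4, 1:4), block = 1L, orientation = "same"),
             cbind(mk_anchors(21:24, 21:24), block = 2L, orientation = "same"))
  expect_setequal(unique(enforce_quota(b, 1, 1)$block), c(1L, 2L))
  expect_error(enforce_quota(a, 0, 1), "quotas")
})

test_that("greedy quota selection satisfies constraints on random instances", {
  set.seed(402)
  for (trial in 1:50) {
    n_blocks <- sample(2:6, 1)
    blocks <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      q0 <- sample(1:20, 1); s0 <- sample(1:20, 1); len <- sample(4:6, 1)
      cbind(mk_anchors(q0:(q0 + len - 1), s0:(s0 + len - 1),
                       raw = sample(10:100, 1)),
            block = b, orientation = "same")
    }))
    blocks$q_gene <- paste0(blocks$q_gene, "_", blocks$block)
    blocks$s_gene <- paste0(blocks$s_gene, "_", blocks$block)
    qq <- sample(1:2, 1); qs <- sample(1:2, 1)
    sel <- enforce_quota(blocks, qq, qs)
    if (nrow(sel) == 0) next
    # verify coverage multiplicity constraint directly
    info <- split(sel, sel$block)
    covq <- integer(100); covs <- integer(100)
    for (b in info) {
      covq[min(b$q_idx):max(b$q_idx)] <- covq[min(b$q_idx):max(b$q_idx)] + 1L
      covs[min(b$s_idx):max(b$s_idx)] <- covs[min(b$s_idx):max(b$s_idx)] + 1L
    }
    expect_lte(max(covq), qq)
    expect_lte(max(covs), qs)
  }
})

test_that("greedy quota selection matches exhaustive search on small instances", {
  set.seed(403)
  n_better <- 0
  for (trial in 1:30) {
    n_blocks <- sample(2:4, 1)
    blocks <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      q0 <- sample(1:10, 1); s0 <- sample(1:10, 1)
      cbind(mk_anchors(q0:(q0 + 3), s0:(s0 + 3), raw = sample(10:100, 1)),
            block = b, orientation = "same")
    }))
    blocks$q_gene <- paste0(blocks$q_gene, "_", blocks$block)
    sel <- enforce_quota(blocks, 1, 1)
    got <- sum(sel$raw)
    # exhaustive optimal selection under the same constraints
    per <- split(blocks, blocks$block)
    feasible_score <- function(subset) {
      covq <- integer(40); covs <- integer(40)
      for (b in per[subset]) {
        rq <- min(b$q_idx):max(b$q_idx); rs <- min(b$s_idx):max(b$s_idx)
        covq[rq] <- covq[rq] + 1L; covs[rs] <- covs[rs] + 1L
      }
      if (max(covq) > 1 || max(covs) > 1) return(-Inf)
      sum(vapply(per[subset], function(b) sum(b$raw), numeric(1)))
    }
    best <- 0
    for (k in seq_len(n_blocks))
      for (cmb in utils::combn(n_blocks, k, simplify = FALSE))
        best <- max(best, feasible_score(cmb))
    expect_lte(got, best)      # greedy never beats the optimum
    if (got < best) n_better <- n_better + 1
  }
  # greedy is allowed to be suboptimal, but must usually find the optimum here
  expect_lte(n_better, 10)
})

test_that("full synteny on a generated fixture pairs every visible ortholog", {
  p <- generate_pair(fixture_config(n_genes = 8, n_tandems = 1,
                                    n_hidden_genes = 0,
                                    transposon_copy_number = 0, seed = 404))
  syn <- find_synteny(p$genome_q, p$ann_q, p$genome_s, p$ann_s, scheme = scheme)
  expect_equal(nrow(syn$pairs), 8)
  expect_true(all(p$truth$ortholog$q_gene %in% syn$pairs$q_gene))
  # every emitted pair belongs to exactly one block
  expect_equal(anyDuplicated(syn$pairs$pair_id), 0)
  # tandem copy collapsed: not an anchor
  expect_false(any(grepl("_td", syn$pairs$q_gene)))
})

test_that("inverted segments come out as inverted blocks", {
  # the inverted run is one gene longer than min_size + 1 because the
  # iterative greedy chain may absorb a single run anchor into the flanking
  # same-orientation chain (its subject order still increases across the run)
  p <- generate_pair(fixture_config(n_genes = 14, n_tandems = 0,
                                    n_hidden_genes = 0, inversion_blocks = 1,
                                    inversion_size = 6,
                                    transposon_copy_number = 0, seed = 405))
  syn <- find_synteny(p$genome_q, p$ann_q, p$genome_s, p$ann_s, scheme = scheme)
  expect_true("inverted" %in% syn$pairs$orientation)
  expect_true("same" %in% syn$pairs$orientation)
  expect_gte(nrow(syn$pairs), 12)
  inv_pairs <- syn$pairs[syn$pairs$orientation == "inverted", ]
  expect_gte(nrow(inv_pairs), 4)
  # inverted pairs relate genes whose strands disagree between the genomes
  sq <- p$ann_q$genes$strand[match(inv_pairs$q_gene, p$ann_q$genes$gene_id)]
  ss <- p$ann_s$genes$strand[match(inv_pairs$s_gene, p$ann_s$genes$gene_id)]
  expect_true(all(sq != ss))
})
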