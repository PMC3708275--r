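scheme <- scoring_scheme()

mk_cns <- function(seqs) {
  data.frame(cns_id = sprintf("c%02d", seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("protein filter reclassifies coding fragments above 18 bp only", {
  set.seed(701)
  # a protein and a CNS that is a verbatim in-frame fragment of its CDS
  aa <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  codons <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT", H="CAT",
              I="ATT", K="AAA", L="CTG", M="ATG", N="AAT", P="CCT", Q="CAA",
              R="CGT", S="TCT", T="ACT", V="GTT", W="TGG", Y="TAT")
  cds <- paste(codons[strsplit(aa, "")[[1]]], collapse = "")
  frag60 <- substring(cds, 4, 63)          # in-frame 60 bp fragment
  cns <- mk_cns(c(frag60, rseq(60), substring(cds, 4, 21)))
  res <- protein_filter(cns, c(prot1 = aa))
  expect_equal(res$reclassified$cns_id, "c01")   # coding fragment removed
  expect_true("c02" %in% res$cns$cns_id)         # random 60-mer stays
  expect_true("c03" %in% res$cns$cns_id)         # 18 bp: not tested at all

  # significant but low-coverage hit stays a CNS (>90% coverage required)
  half_coding <- paste0(substring(cds, 4, 33), rseq(31))  # ~48% of 61 bp
  res2 <- protein_filter(mk_cns(half_coding), c(prot1 = aa))
  expect_equal(nrow(res2$reclassified), 0)
})

test_that("RNA filter reclassifies matches and honours the expect cutoff", {
  set.seed(702)
  rna <- c(mir1 = rseq(120))
  hit_cns <- substring(rna[["mir1"]], 40, 79)     # 40 bp exact subsequence
  cns <- mk_cns(c(hit_cns, rseq(40)))
  res <- rna_filter(cns, rna, scheme = scheme)
  expect_equal(res$reclassified$cns_id, "c01")
  expect_equal(res$cns$cns_id, "c02")
  # empty RNA set: everything stays
  res2 <- rna_filter(cns, NULL, scheme = scheme)
  expect_equal(nrow(res2$reclassified), 0)
})

two_gene_ann <- function(prefix, starts, strands = "+") {
  n <- length(starts)
  gene_annotation(
    data.frame(gene_id = paste0(prefix, seq_len(n)), chrom = "chr1",
               start = starts, end = starts + 2000L,
               strand = rep_len(strands, n), origin = "official"),
    data.frame(gene_id = paste0(prefix, seq_len(n)), start = starts + 200L,
               end = starts + 1800L))
}

test_that("CNS assignment prefers fewer intervening genes, then distance", {
  ann_q <- two_gene_ann("q", c(10000L, 40000L, 32000L))
  ann_s <- two_gene_ann("s", c(10000L, 40000L, 32000L))
  pairs <- data.frame(q_gene = c("q1", "q2"), s_gene = c("s1", "s2"),
                      pair_id = c("q1~s1", "q2~s2"), stringsAsFactors = FALSE)
  syn_q <- c("q1", "q2"); syn_s <- c("s1", "s2")
  # CNS between q1 and q2; q3/s3 (non-syntenic) sits between it and q2
  cns <- data.frame(qstart = 30000L, qend = 30030L, sstart = 30000L,
                    send = 30030L, query_chrom = "chr1", subject_chrom = "chr1")
  got <- assign_to_pair(cns, pairs, ann_q, ann_s, syn_q, syn_s)
  expect_equal(got, "q1~s1")   # 0 intervening non-syntenic vs 1

  # equal intervening counts: smaller total bp separation wins
  ann_q2 <- two_gene_ann("q", c(10000L, 40000L))
  ann_s2 <- two_gene_ann("s", c(10000L, 40000L))
  cns2 <- data.frame(qstart = 30000L, qend = 30030L, sstart = 30000L,
                     send = 30030L, query_chrom = "chr1", subject_chrom = "chr1")
  got2 <- assign_to_pair(cns2, pairs, ann_q2, ann_s2, syn_q, syn_s)
  expect_equal(got2, "q2~s2")  # 2 x 10,000 bp < 2 x 18,000 bp

  # more than three intervening non-syntenic genes: unassigned
  ann_q3 <- two_gene_ann("q", c(10000L, 15000L, 18000L, 21000L, 24000L, 27000L))
  ann_s3 <- two_gene_ann("s", c(10000L, 50000L, 53000L, 56000L, 59000L, 62000L))
  one <- data.frame(q_gene = "q1", s_gene = "s1", pair_id = "q1~s1")
  cns3 <- data.frame(qstart = 30000L, qend = 30030L, sstart = 30000L,
                     send = 30030L, query_chrom = "chr1", subject_chrom = "chr1")
  got3 <- assign_to_pair(cns3, one, ann_q3, ann_s3, "q1", "s1")
  expect_true(is.na(got3))     # q2..q5 intervene on the query side
})

test_that("positional classification follows UTR > intron > proximal/distal", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 10000L,
                      end = 14000L, strand = "+", origin = "official")
  cds <- data.frame(gene_id = "g", start = c(10500L, 12000L),
                    end = c(11000L, 13500L))
  utr <- data.frame(gene_id = "g", start = c(10000L, 13500L),
                    end = c(10500L, 14000L), side = c("5prime", "3prime"))
  ann <- gene_annotation(genes, cds, utr)
  cls <- function(qs, qe, ss = qs, se = qe)
    classify_position(data.frame(qstart = qs, qend = qe, sstart = ss, send = se),
                      "g", "g", ann, ann)
  expect_equal(cls(9400L, 9430L), "5prime_proximal")   # 570 bp upstream
  expect_equal(cls(5000L, 5030L), "5prime_distal")     # 5 kb upstream
  expect_equal(cls(13600L, 13650L), "3prime_UTR")      # overlaps the 3' UTR
  expect_equal(cls(11200L, 11400L), "intron")
  expect_equal(cls(14200L, 14230L), "3prime_proximal")
  expect_equal(cls(16000L, 16030L), "3prime_distal")
  # UTR overlap of the subject member is enough
  got <- classify_position(
    data.frame(qstart = 9400L, qend = 9430L, sstart = 10100L, send = 10130L),
    "g", "g", ann, ann)
  expect_equal(got, "5prime_UTR")
  # minus strand flips sidedness
  ann_m <- ann; ann_m$genes$strand <- "-"
  utr_m <- utr; utr_m$side <- c("3prime", "5prime")
  ann_m <- gene_annotation(ann_m$genes, cds, utr_m)
  expect_equal(classify_position(
    data.frame(qstart = 9400L, qend = 9430L, sstart = 9400L, send = 9430L),
    "g", "g", ann_m, ann_m), "3prime_proximal")
})

test_that("Bigfoot needs four CNSs, 4 kb of space and one CNS per kb", {
  mk <- function(qstarts, len = 30L, class = "5prime_distal") {
    data.frame(qstart = qstarts, qend = qstarts + len,
               position_class = class, stringsAsFactors = FALSE)
  }
  tu <- c(20000L, 24000L)
  # 4 CNSs at 900 bp spacing spanning ~4.5 kb upstream: Bigfoot
  s1 <- summarize_pair_cns(mk(c(15970, 16970, 17970, 18970)), tu[1], tu[2])
  expect_true(s1$bigfoot)
  expect_gte(s1$noncoding_span_bp, 4000)
  # 3 CNSs spanning 6 kb: count fails
  expect_false(summarize_pair_cns(mk(c(14000, 16000, 19000)),
                                  tu[1], tu[2])$bigfoot)
  # 5 CNSs spanning 5 kb with a 2.2 kb gap: spacing fails
  expect_false(summarize_pair_cns(
    mk(c(15000, 15200, 17500, 18500, 19500)), tu[1], tu[2])$bigfoot)
  # direct clause check
  expect_true(call_bigfoot(4, 4500, c(900, 900, 900, 400)))
  expect_false(call_bigfoot(3, 6000, c(500, 500)))
  expect_false(call_bigfoot(5, 5000, c(2200, 300, 300, 300)))
  # class counts always partition the assigned set
  sm <- summarize_pair_cns(mk(c(15000, 16000, 25000), class =
    c("5prime_distal", "5prime_proximal", "3prime_distal")), tu[1], tu[2])
  expect_equal(sum(sm$class_counts), sm$cns_count)
})

pan_within <- function(a, b) {
  out <- pan_intersect(list(a, b))
  d <- data.frame(query_chrom = out$chrom, query_start = out$start,
                  query_end = out$end)
  attr(d, "query_genome") <- "Os"
  d
}

test_that("pan intersection keeps only intervals present in every list", {
  mk_list <- function(starts, ends, chrom = "chr1") {
    d <- data.frame(query_chrom = chrom, query_start = starts, query_end = ends)
    attr(d, "query_genome") <- "Os"
    d
  }
  l1 <- mk_list(c(100L, 500L, 900L), c(150L, 560L, 950L))
  l2 <- mk_list(c(120L, 480L), c(160L, 530L))
  l3 <- mk_list(c(90L, 510L), c(130L, 540L))
  pan <- pan_intersect(list(l1, l2, l3))
  expect_equal(nrow(pan), 2)
  expect_equal(pan$start, c(120L, 510L))   # intersection intervals
  expect_equal(pan$end, c(130L, 530L))
  # an interval in only 2 of 3 lists is excluded
  expect_false(any(pan$start >= 900))
  # touching half-open intervals do not overlap
  t1 <- mk_list(100L, 150L); t2 <- mk_list(150L, 200L)
  expect_equal(nrow(pan_intersect(list(t1, t2))), 0)
  # associativity / commutativity
  perm <- pan_intersect(list(l3, l1, l2))
  expect_equal(pan, perm)
  nest <- pan_intersect(list(pan_within(l1, l2), l3))
  expect_equal(pan, nest)
  # different reference genomes are an error
  bad <- l2; attr(bad, "query_genome") <- "Zm"
  expect_error(pan_intersect(list(l1, bad)), "reference")
})

test_that("relaxed probing finds 13/13 matches invisible at the default cutoff", {
  set.seed(703)
  cns <- rand_clean(35)
  target <- rseq(4000)
  target13 <- plant(target, substring(cns, 10, 22), 2001)   # 13 bp only
  h15 <- probe_relaxed(cns, target13, min_exact = 15, scheme = scheme)
  h13 <- probe_relaxed(cns, target13, min_exact = 13, scheme = scheme)
  expect_equal(nrow(h15[h15$sstart >= 1990 & h15$send <= 2025, ]), 0)
  expect_gte(nrow(h13[h13$sstart >= 1990 & h13$send <= 2025, ]), 1)
  # verbatim target: found at both cutoffs; relaxed never shrinks the hit set
  full <- plant(target, cns, 3001)
  expect_gte(nrow(probe_relaxed(cns, full, 15, scheme)), 1)
  for (trial in 1:10) {
    t2 <- plant(rseq(2000), substring(cns, 1, sample(13:35, 1)), 501)
    n15 <- nrow(probe_relaxed(cns, t2, 15, scheme))
    n13 <- nrow(probe_relaxed(cns, t2, 13, scheme))
    expect_gte(n13, n15)
  }
  # no shared 7-mer: no hit at any cutoff
  expect_equal(nrow(probe_relaxed(strrep("ACGTGCA", 3),
                                  strrep("T", 100), 13, scheme)), 0)
})
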