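test_that("control sequence excludes CDS, CNS and masked residues", {
  set.seed(801)
  g <- genome_seq("A", c(chr1 = rseq(40000)))
  ann <- gene_annotation(
    data.frame(gene_id = "g", chrom = "chr1", start = 18000L, end = 20000L,
               strand = "+", origin = "official"),
    data.frame(gene_id = "g", start = 18000L, end = 20000L))
  cns <- data.frame(chrom = "chr1", start = 17000L, end = 17100L)
  ctrl <- control_sequences("g", g, ann, cns, reach = 1000L)
  # 1 kb each flank minus the 100 bp CNS in the 5' flank
  expect_equal(nchar(ctrl), 2000 - 100)
  # the control never contains CNS residues (check by planting a marker)
  g2 <- g
  g2$seqs[["chr1"]] <- plant(g2$seqs[["chr1"]], strrep("A", 100), 17001)
  ctrl2 <- control_sequences("g", g2, ann, cns, reach = 1000L)
  expect_false(grepl(strrep("A", 60), ctrl2))
  # masked flank: empty control
  g3 <- g
  g3$seqs[["chr1"]] <- plant(g3$seqs[["chr1"]], strrep("N", 4600), 16501)
  ctrl3 <- control_sequences("g", g3, ann,
                             data.frame(chrom = character(), start = integer(),
                                        end = integer()), reach = 1000L)
  expect_equal(nchar(ctrl3), 0)
})

test_that("control subtraction matches an interval oracle on random layouts", {
  set.seed(802)
  for (trial in 1:20) {
    g <- genome_seq("A", c(chr1 = rseq(8000)))
    ann <- gene_annotation(
      data.frame(gene_id = "g", chrom = "chr1", start = 3000L, end = 4000L,
                 strand = "+", origin = "official"),
      data.frame(gene_id = "g", start = 3200L, end = 3800L))
    k <- sample(1:4, 1)
    st <- sort(sample(seq(1500L, 5400L, by = 120L), k))
    cns <- data.frame(chrom = "chr1", start = st, end = st + 60L)
    ctrl <- control_sequences("g", g, ann, cns, reach = 1500L)
    keep <- setdiff(1501:5500, c(3201:3800, unlist(Map(seq, st + 1L, st + 60L))))
    expect_equal(nchar(ctrl), length(keep))
  }
})

test_that("motif counting is greedy non-overlapping and N-safe", {
  expect_equal(count_motif("CACGTG", "CACGTG"), 1)
  expect_equal(count_motif("CACA", "CACACACA"), 2)
  expect_equal(count_motif("CACGTG", "TTTTTTTT"), 0)
  # degenerate IUPAC pattern
  expect_equal(count_motif("CAYGTG", "CACGTGCATGTG"), 2)
  # N splits sequences: counts add exactly
  set.seed(803)
  for (trial in 1:20) {
    s1 <- rseq(80); s2 <- rseq(80); pat <- c("CACGTG", "ACGTGGC", "AAACCCTAA",
                                             "CAYGTG")[sample(4, 1)]
    expect_equal(
      count_motif(pat, paste0(s1, strrep("N", nchar(pat)), s2)),
      count_motif(pat, s1) + count_motif(pat, s2))
  }
  # equals the brute-force all-placements oracle on short strings
  for (trial in 1:50) {
    s <- rseq(sample(20:100, 1))
    pat <- c("CACA", "CACGTG", "RYN", "AAACCCTAA")[sample(4, 1)]
    expect_equal(count_motif(pat, s), oracle_motif_count(pat, s))
  }
})

test_that("motif enrichment reproduces the textbook 2x2 chi-square", {
  # 30 hits / 10,000 bp vs 10 hits / 10,000 bp: fold 3
  fg <- paste0(strrep(paste0("CACGTG", strrep("T", 327)), 30), strrep("A", 10))
  bg <- strrep(paste0("CACGTG", strrep("T", 994)), 10)
  expect_equal(nchar(fg), 10000); expect_equal(nchar(bg), 10000)
  r <- motif_enrichment("CACGTG", fg, bg)
  expect_equal(r$count_fg, 30); expect_equal(r$count_bg, 10)
  expect_equal(r$fold, 3.0)
  expect_equal(round(r$chisq, 2), 10.02)
  expect_equal(round(r$chisq_corrected, 2), 9.04)
  tab <- matrix(c(30, 9970, 10, 9990), 2, byrow = TRUE)
  expect_equal(r$chisq, oracle_chisq(tab), tolerance = 1e-8)
  expect_equal(r$chisq_corrected, oracle_chisq(tab, TRUE), tolerance = 1e-8)

  # identical rates: fold 1, p ~ 1
  r2 <- motif_enrichment("CACGTG", bg, bg)
  expect_equal(r2$fold, 1.0)
  expect_gt(r2$p_value, 0.95)

  # doubling both amounts leaves fold unchanged
  r3 <- motif_enrichment("CACGTG", strrep(fg, 2), strrep(bg, 2))
  expect_equal(r3$fold, r$fold)
})

test_that("Fisher term enrichment equals the hypergeometric oracle", {
  # package p-values vs oracle over an exhaustive sweep of small tables
  for (m in c(4, 9, 17)) for (n2 in c(5, 13)) for (k in c(3, 8)) {
    if (k > m + n2) next
    for (a in max(0, k - n2):min(k, m)) {
      b <- m - a; c_ <- k - a; d <- n2 - c_
      expect_equal(fisher.test(matrix(c(a, b, c_, d), 2),
                               alternative = "two.sided")$p.value,
                   oracle_fisher2(a, b, c_, d), tolerance = 1e-9,
                   label = sprintf("table %d %d %d %d", a, b, c_, d))
    }
  }
  # a term confined to the group is flagged; a proportional one is not
  universe <- sprintf("g%02d", 1:20)
  group <- universe[1:5]
  g2t <- rbind(data.frame(gene = group, term = "GO:confined"),
               data.frame(gene = universe[seq(1, 20, 4)], term = "GO:even"))
  res <- term_enrichment(group, universe, g2t, alpha = 0.01)
  conf <- res[res$item == "GO:confined", ]
  expect_equal(conf$p_value, 1 / choose(20, 5), tolerance = 1e-9)
  expect_true(conf$corrected_p >= conf$p_value)
  expect_gt(res$p_value[res$item == "GO:even"], 0.5)
  # group == universe: every term has p = 1
  res2 <- term_enrichment(universe, universe, g2t)
  expect_true(all(res2$p_value == 1))
  expect_error(term_enrichment(character(0), universe, g2t), "empty")
})

test_that("TF association reports fold against the genome fraction", {
  universe <- sprintf("g%03d", 1:200)
  tf <- universe[1:10]                      # genome fraction 5%
  bins <- list(rich = universe[1:10],       # all TFs: fold 20
               flat = universe[c(1, 21:39)])  # 1/20 = genome fraction
  res <- tf_association(bins, tf, universe)
  expect_equal(res$fold[res$item == "rich"], 20)
  expect_equal(res$fold[res$item == "flat"], 1)
  expect_equal(res$genome_fraction, c(0.05, 0.05))
  # chi-square matches the direct formula on the same table
  a <- 10; n <- 10; c_ <- 0; m <- 190
  tab <- matrix(c(a, n - a, c_, m - c_), 2, byrow = TRUE)
  expect_equal(res$chisq[res$item == "rich"],
               oracle_chisq(tab, correct = any(outer(rowSums(tab),
                 colSums(tab)) / sum(tab) < 5)), tolerance = 1e-8)
})

test_that("motif sets get Bonferroni correction at the 0.005 cutoff", {
  set.seed(804)
  fg <- paste0(strrep("CACGTGTTTTTTTTTT", 50), rseq(200))
  bg <- rseq(3000)
  motifs <- data.frame(name = c("gbox", "telo"),
                       pattern = c("CACGTG", "AAACCCTAA"))
  res <- motif_enrichment_set(motifs, fg, bg, alpha = 0.005)
  expect_equal(res$corrected_p, pmin(1, res$p_value * 2))
  expect_true(res$significant[res$item == "gbox"])
})
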