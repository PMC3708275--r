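mk_cand <- function(qstart, qend, sstart, send, raw = 20,
                    strand = "forward") {
  d <- data.frame(qstart = qstart, qend = qend, sstart = sstart, send = send,
                  strand = strand, raw = raw, stringsAsFactors = FALSE)
  d$bit_score <- bit_score(d$raw)
  d$expect <- expect_value(d$raw, 25000, 25000)
  d$status <- "live"; d$reason <- NA_character_
  d
}

test_that("orientation filter keeps hits matching relative gene orientation", {
  d <- mk_cand(c(10, 50), c(30, 70), c(110, 150), c(130, 170),
               strand = c("forward", "reverse"))
  same <- orientation_filter(d, "+", "+")
  expect_equal(same$status, c("live", "removed"))
  expect_equal(same$reason[2], "orientation")
  opp <- orientation_filter(d, "+", "-")
  expect_equal(opp$status, c("removed", "live"))
})

test_that("intron consistency removes one-sided intronic hits", {
  iq <- data.frame(start = 100L, end = 200L)
  is <- data.frame(start = 1100L, end = 1200L)
  d <- mk_cand(c(120, 130, 400), c(150, 160, 430),
               c(1120, 1400, 1500), c(1150, 1430, 1530))
  out <- intron_consistency_filter(d, iq, is)
  expect_equal(out$status, c("live", "removed", "live"))  # both / q-only / none
  expect_equal(out$reason[2], "intron_mismatch")
})

test_that("overlap resolution matches the literal iterative oracle", {
  # boundary cases first
  d <- mk_cand(c(10, 100), c(40, 130), c(10, 100), c(40, 130))
  expect_true(all(resolve_overlaps(d)$status == "live"))  # disjoint

  d2 <- mk_cand(c(10, 20), c(40, 50), c(10, 20), c(40, 50), raw = c(21, 16))
  out2 <- resolve_overlaps(d2)
  expect_equal(out2$status, c("live", "removed"))         # lower bits removed
  expect_equal(out2$reason[2], "overlap")

  # chain A-B, B-C with A,C disjoint: only B removed
  d3 <- mk_cand(c(10, 25, 40), c(30, 45, 60), c(10, 25, 40), c(30, 45, 60),
                raw = c(30, 16, 25))
  out3 <- resolve_overlaps(d3)
  expect_equal(out3$status, c("live", "removed", "live"))

  # randomized equivalence with the oracle
  set.seed(601)
  for (trial in 1:300) {
    d <- random_candidates(sample(2:8, 1), span = 300)
    expect_identical(resolve_overlaps(d)$status == "live",
                     oracle_overlap_resolution(d))
  }
})

test_that("crossing filter removes hits crossing three or more others", {
  # 4 collinear + 1 strongly out of place
  d <- mk_cand(c(10, 100, 200, 300, 50), c(30, 120, 220, 320, 70),
               c(10, 100, 200, 300, 500), c(30, 120, 220, 320, 520))
  out <- crossing_filter(d, "same")
  expect_equal(out$status, c("live", "live", "live", "live", "removed"))
  expect_equal(out$reason[5], "crossing")

  # two mutually crossing hits: below the threshold, both stay
  d2 <- mk_cand(c(10, 100), c(30, 120), c(200, 50), c(220, 70))
  expect_true(all(crossing_filter(d2, "same")$status == "live"))

  # crossing counts match the oracle on random sets
  set.seed(602)
  for (trial in 1:200) {
    d <- random_candidates(sample(2:8, 1), span = 500)
    out <- crossing_filter(d, "same")
    nc <- oracle_crossings(d, seq_len(nrow(d)), "same")
    expect_identical(out$status == "removed", nc >= 3)
  }
})

test_that("collinearity enforcement equals the literal greedy simulation", {
  # two mutually crossing hits: lower bit score goes
  d <- mk_cand(c(10, 100), c(30, 120), c(200, 50), c(220, 70), raw = c(18, 16))
  out <- enforce_collinearity(d, "same")
  expect_equal(out$status, c("live", "removed"))
  expect_equal(out$reason[2], "order")

  set.seed(603)
  for (trial in 1:300) {
    d <- random_candidates(sample(2:8, 1), span = 500)
    out <- enforce_collinearity(d, "same")
    expect_identical(out$status == "live", oracle_collinearity(d, "same"))
    # terminal set has zero crossings
    live <- which(out$status == "live")
    if (length(live) > 1)
      expect_true(all(oracle_crossings(out, live, "same") == 0))
  }
  # inverted orientation: reflecting the subject axis twice is the identity
  for (trial in 1:50) {
    d <- random_candidates(sample(3:8, 1), span = 500)
    r1 <- enforce_collinearity(d, "inverted")
    d2 <- d
    d2$sstart <- -d$send; d2$send <- -d$sstart
    r2 <- enforce_collinearity(d2, "same")
    expect_identical(r1$status, r2$status)
  }
})

test_that("the bow-tie polygon matches its analytic band definition", {
  poly <- bowtie_polygon(10000, 20000, extent = 15000, w0 = 200, slope = 0.5,
                         orientation = "same")
  expect_equal(nrow(poly), 6)
  # center is interior (knot half-width w0 > 0)
  expect_true(point_in_polygon(10000, 20000, poly))
  # matched diagonal offsets stay inside; mirrored offsets fall outside
  expect_true(point_in_polygon(20000, 30000, poly))
  expect_false(point_in_polygon(20000, 10000, poly))
  expect_error(bowtie_polygon(0, 0, extent = 0), "degenerate")

  set.seed(604)
  for (orient in c("same", "inverted")) {
    poly <- bowtie_polygon(5000, 8000, extent = 12000, w0 = 200, slope = 0.5,
                           orientation = orient)
    px <- runif(500, -10000, 20000); py <- runif(500, -8000, 25000)
    got <- point_in_polygon(px, py, poly)
    want <- oracle_in_bowtie(px, py, 5000, 8000, 12000, 200, 0.5, orient)
    # points near the boundary are excluded from the comparison
    near <- abs(abs(py - 8000 - (if (orient == "same") 1 else -1) *
                      (px - 5000)) - (200 + 0.5 * abs(px - 5000))) < 2 |
      abs(abs(px - 5000) - 12000) < 2
    expect_identical(got[!near], want[!near])
  }
})

test_that("the full cascade applies stages in order and records reasons", {
  set.seed(605)
  gq <- genome_seq("A", c(chr1 = rseq(30000)))
  gs <- genome_seq("B", c(chr1 = rseq(30000)))
  ann1 <- gene_annotation(
    data.frame(gene_id = "g", chrom = "chr1", start = 14000L, end = 16000L,
               strand = "+", origin = "official"),
    data.frame(gene_id = "g", start = c(14000L, 15500L),
               end = c(14500L, 16000L)))
  wq <- gene_space_window("g", gq, ann1, 12000)
  ws <- gene_space_window("g", gs, ann1, 12000)
  # candidates: one clean, one wrong orientation, one bow-tie violator
  hits <- mk_cand(c(10000, 11000, 12000), c(10030, 11030, 12030),
                  c(10010, 11010, 26000), c(10040, 11040, 26030),
                  strand = c("forward", "reverse", "forward"))
  out <- cns_filter_cascade(hits, wq, ws, ann1, ann1, "same")
  expect_equal(out$status, c("live", "removed", "removed"))
  expect_equal(out$reason, c(NA, "orientation", "bowtie"))
  # pure function: identical rerun
  expect_identical(out, cns_filter_cascade(hits, wq, ws, ann1, ann1, "same"))
})
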