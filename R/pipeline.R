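#' Pipeline configuration
#'
#' All stage parameters with their standard defaults: self-search word 15 and
#' expect < 0.001 with the 50x masking threshold; co-annotation word 20,
#' expect < 0.001, merge gap < 1 kb, 100 bp / 40% candidate filters; anchor
#' word 20 with cscore > 0.5, tandem collapsing over <= 20 intervening genes,
#' chain gap 20 and minimum chain size 4 with a "1:1" quota; gene-space pad
#' 12 kb and the 29.5-bit (perfect 15 bp match) acceptance threshold; bow-tie
#' knot half-width 200 bp with slope 0.5. The large-genome option raises the
#' larger genome's pad to \code{pad_large} (30 kb) and doubles the bow-tie
#' slope, accommodating transposon-inflated spacing.
#'
#' @param word_self,expect_self,mask_threshold repeat-masking stage.
#' @param word_coann,expect_coann,merge_gap,min_candidate_len,min_candidate_cov
#'   co-annotation stage.
#' @param word_anchor,expect_anchor,cscore_min,tandem_nmax,dm,min_size,quota
#'   synteny stage.
#' @param pad,pad_large,min_bits CNS alignment stage (min_bits defaults to the
#'   bit score of a perfect 15 bp match).
#' @param bowtie_w0,bowtie_slope bow-tie filter geometry.
#' @param max_intervening,proximal_dist CNS assignment and classification.
#' @param protein_expect,protein_coverage,protein_min_len,rna_expect
#'   reclassification filters.
#' @param large_genome logical switch.
#' @param scheme a [scoring_scheme()] for the gene-space search.
#' @param seed seed recorded in outputs (the pipeline itself is
#'   deterministic).
#' @return list of class \code{"cns_config"}.
#' @export
cns_config <- function(word_self = 15, expect_self = 1e-3, mask_threshold = 50,
                       word_coann = 20, expect_coann = 1e-3, merge_gap = 1000,
                       min_candidate_len = 100, min_candidate_cov = 0.4,
                       word_anchor = 20, expect_anchor = 1e-3, cscore_min = 0.5,
                       tandem_nmax = 20, dm = 20, min_size = 4, quota = "1:1",
                       pad = 12000, pad_large = 30000, min_bits = NULL,
                       bowtie_w0 = 200, bowtie_slope = 0.5,
                       max_intervening = 3, proximal_dist = 1000,
                       protein_expect = 0.01, protein_coverage = 0.9,
                       protein_min_len = 18, rna_expect = 1e-3,
                       large_genome = FALSE, scheme = scoring_scheme(),
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$min_bits)) cfg$min_bits <- bit_score(15, scheme)
  structure(cfg, class = "cns_config")
}

#' Run the CNS discovery pipeline
#'
#' Executes the stages in order: repeat masking, co-annotation (each genome
#' against the partner's CDS set; new genes become available as syntenic
#' anchors), quota-constrained synteny, per-pair gene-space alignment and
#' geometric filtering, cross-pair deduplication, reclassification against
#' optional protein/RNA sets, assignment to gene pairs, positional
#' classification and Bigfoot calling. Identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param genome_q,genome_s [genome_seq()] objects (unmasked; masking is the
#'   first stage unless \code{premasked}).
#' @param ann_q,ann_s matching [gene_annotation()] objects.
#' @param config a [cns_config()].
#' @param protein_seqs,rna_seqs optional reference protein / RNA sets for the
#'   reclassification filters.
#' @param premasked skip the repeat-masking stage (genomes already carry N
#'   masks from an external tool).
#' @param verbose emit per-stage progress messages.
#' @return list with gene_list, cns (the CNS list), pairs, blocks, clusters_q,
#'   reclassified, audit (per-candidate filter trail), log (stage counts) and
#'   config.
#' @export
run_pipeline <- function(genome_q, ann_q, genome_s, ann_s,
                         config = cns_config(), protein_seqs = NULL,
                         rna_seqs = NULL, premasked = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message("[cnspipe] ", ...)
  log <- list()
  self_cmp <- identical(genome_q$genome_id, genome_s$genome_id)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  # -- masking ---------------------------------------------------------------
  if (!premasked) {
    say("masking repeats (>= ", config$mask_threshold, "x self-coverage)")
    mq <- stage("mask", mask_genome(genome_q, config$word_self,
                                    config$expect_self, config$mask_threshold,
                                    config$scheme))
    ms <- if (self_cmp) mq else
      stage("mask", mask_genome(genome_s, config$word_self, config$expect_self,
                                config$mask_threshold, config$scheme))
  } else {
    mq <- genome_q; ms <- genome_s
  }
  log$masked_bp_q <- sum(vapply(masked_positions(mq), length, integer(1)))
  log$masked_bp_s <- sum(vapply(masked_positions(ms), length, integer(1)))

  # -- co-annotation ---------------------------------------------------------
  say("co-annotating with the partner CDS sets")
  co_q <- stage("coannotate", coannotate(
    mq, ann_q, cds_sequences(ms, ann_s), config$word_coann,
    config$expect_coann, config$merge_gap, config$min_candidate_len,
    config$min_candidate_cov, config$scheme))
  co_s <- if (self_cmp) list(annotation = co_q$annotation,
                             new_genes = co_q$new_genes[0, ],
                             missed_exons = co_q$missed_exons[0, ])
  else stage("coannotate", coannotate(
    ms, ann_s, cds_sequences(mq, ann_q), config$word_coann,
    config$expect_coann, config$merge_gap, config$min_candidate_len,
    config$min_candidate_cov, config$scheme))
  ann_q2 <- co_q$annotation; ann_s2 <- co_s$annotation
  log$new_genes_q <- nrow(co_q$new_genes)
  log$new_genes_s <- nrow(co_s$new_genes)

  # -- synteny ---------------------------------------------------------------
  say("building syntenic blocks (quota ", paste(parse_quota(config$quota),
                                                collapse = ":"), ")")
  syn <- stage("synteny", find_synteny(
    mq, ann_q2, ms, ann_s2, config$word_anchor, config$expect_anchor,
    config$cscore_min, config$tandem_nmax, config$dm, config$min_size,
    config$quota, config$scheme))
  pairs <- syn$pairs
  log$anchors <- nrow(syn$anchors)
  log$pairs <- nrow(pairs)
  log$blocks <- length(unique(pairs$block))
  if (nrow(pairs) == 0) say("no syntenic pairs found")

  # -- per-pair CNS discovery ------------------------------------------------
  pad_q <- pad_s <- config$pad
  if (config$large_genome) {
    big_q <- sum(as.numeric(chrom_lengths(genome_q))) >=
      sum(as.numeric(chrom_lengths(genome_s)))
    if (big_q) pad_q <- config$pad_large else pad_s <- config$pad_large
  }
  slope <- config$bowtie_slope * (if (config$large_genome) 2 else 1)
  min_raw <- ceiling(raw_for_bits(config$min_bits, config$scheme) - 1e-9)
  say("aligning gene spaces (pad ", pad_q, "/", pad_s, " bp, >= ",
      round(config$min_bits, 1), " bits)")
  audit <- NULL
  cands_all <- NULL
  for (k in seq_len(nrow(pairs))) {
    pr <- pairs[k, ]
    ws <- stage("extract", extract_gene_space(pr, mq, ms, ann_q2, ann_s2,
                                              pad_q, pad_s))
    hits <- stage("align", align_gene_space(ws$q, ws$s, config$scheme,
                                            min_raw = min_raw))
    hits <- threshold_filter(hits, config$min_bits, config$scheme)
    if (nrow(hits) == 0) next
    cc <- stage("filter", cns_filter_cascade(
      hits, ws$q, ws$s, ann_q2, ann_s2, pr$orientation,
      config$bowtie_w0, slope))
    cc$pair_id <- pr$pair_id
    cc$query_chrom <- ws$q$chrom
    cc$subject_chrom <- ws$s$chrom
    audit <- rbind(audit, cc)
    cands_all <- rbind(cands_all, cc[cc$status == "live", , drop = FALSE])
  }
  log$candidates <- if (is.null(audit)) 0L else nrow(audit)
  log$removed <- if (is.null(audit)) 0L else sum(audit$status == "removed")
  log$live <- if (is.null(cands_all)) 0L else nrow(cands_all)

  empty_cns <- data.frame(
    cns_id = character(), query_chrom = character(), query_start = integer(),
    query_end = integer(), subject_chrom = character(),
    subject_start = integer(), subject_end = integer(),
    assigned_gene_pair = character(), position_class = character(),
    bit_score = numeric(), sequence = character(), gevo_url = character(),
    stringsAsFactors = FALSE)

  # -- dedupe across pairs and assign ---------------------------------------
  cns <- empty_cns
  reclassified <- list(protein = empty_cns, rna = empty_cns)
  if (!is.null(cands_all) && nrow(cands_all)) {
    key <- with(cands_all, paste(query_chrom, qstart, qend, subject_chrom,
                                 sstart, send, strand))
    say("assigning ", length(unique(key)), " unique CNS candidates to gene pairs")
    uniq <- cands_all[!duplicated(key), , drop = FALSE]
    ukey <- key[!duplicated(key)]
    syntenic_q <- syntenic_members(pairs$q_gene, syn$clusters_q)
    syntenic_s <- syntenic_members(pairs$s_gene, syn$clusters_s)
    assigned <- character(nrow(uniq))
    for (i in seq_len(nrow(uniq))) {
      cand_pairs <- pairs[pairs$pair_id %in% cands_all$pair_id[key == ukey[i]], ,
                          drop = FALSE]
      assigned[i] <- assign_to_pair(
        uniq[i, ], cand_pairs, ann_q2, ann_s2, syntenic_q, syntenic_s,
        config$max_intervening)
    }
    uniq$assigned_gene_pair <- assigned
    uniq <- uniq[!is.na(assigned), , drop = FALSE]
    if (nrow(uniq)) {
      uniq$sequence <- vapply(seq_len(nrow(uniq)), function(i)
        substring(genome_q$seqs[[uniq$query_chrom[i]]],
                  uniq$qstart[i] + 1L, uniq$qend[i]), character(1))
      # reclassification filters (protein, then RNA)
      pf <- protein_filter(uniq, protein_seqs, config$protein_expect,
                           config$protein_coverage, config$protein_min_len)
      rf <- rna_filter(pf$cns, rna_seqs, config$rna_expect, config$scheme)
      reclassified <- list(protein = pf$reclassified, rna = rf$reclassified)
      uniq <- rf$cns
    }
    if (nrow(uniq)) {
      uniq$position_class <- vapply(seq_len(nrow(uniq)), function(i) {
        pr <- pairs[pairs$pair_id == uniq$assigned_gene_pair[i], ][1, ]
        classify_position(uniq[i, ], pr$q_gene, pr$s_gene, ann_q2, ann_s2,
                          config$proximal_dist)
      }, character(1))
      uniq <- uniq[order(uniq$query_chrom, uniq$qstart, uniq$qend,
                         uniq$subject_chrom, uniq$sstart), , drop = FALSE]
      cns <- data.frame(
        cns_id = sprintf("cns%05d", seq_len(nrow(uniq))),
        query_chrom = uniq$query_chrom, query_start = uniq$qstart,
        query_end = uniq$qend, subject_chrom = uniq$subject_chrom,
        subject_start = uniq$sstart, subject_end = uniq$send,
        assigned_gene_pair = uniq$assigned_gene_pair,
        position_class = uniq$position_class,
        bit_score = uniq$bit_score, sequence = uniq$sequence,
        gevo_url = NA_character_, stringsAsFactors = FALSE)
    }
  }
  log$cns <- nrow(cns)
  log$reclassified_protein <- nrow(reclassified$protein)
  log$reclassified_rna <- nrow(reclassified$rna)
  say(nrow(cns), " CNSs retained")

  # -- tandem representative re-selection ------------------------------------
  counts_by_gene <- table(sub("~.*$", "", cns$assigned_gene_pair))
  clusters_q <- reselect_representatives(
    syn$clusters_q, setNames(as.integer(counts_by_gene), names(counts_by_gene)))

  # -- gene list and Bigfoot calls -------------------------------------------
  gene_list <- build_gene_list(ann_q2, pairs, cns, clusters_q)
  attr(cns, "query_genome") <- genome_q$genome_id
  attr(cns, "subject_genome") <- genome_s$genome_id

  list(gene_list = gene_list, cns = cns, pairs = pairs, blocks = syn$blocks,
       clusters_q = clusters_q, clusters_s = syn$clusters_s,
       coannotation = list(q = co_q[c("new_genes", "missed_exons")],
                           s = co_s[c("new_genes", "missed_exons")]),
       annotation_q = ann_q2, annotation_s = ann_s2,
       reclassified = reclassified, audit = audit, log = log, config = config)
}

# syntenic genes plus the members of their tandem clusters
syntenic_members <- function(genes, clusters) {
  cl <- clusters$cluster[match(genes, clusters$gene_id)]
  unique(c(genes, clusters$gene_id[clusters$cluster %in% cl[!is.na(cl)]]))
}

build_gene_list <- function(ann_q, pairs, cns, clusters_q) {
  genes <- ann_q$genes
  pair_of_gene <- split(pairs$pair_id, pairs$q_gene)
  syntelog_of <- split(pairs$s_gene, pairs$q_gene)
  cns_by_pair <- table(cns$assigned_gene_pair)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    prs <- pair_of_gene[[gid]]
    cnt <- if (is.null(prs)) 0L else sum(cns_by_pair[prs], na.rm = TRUE)
    cl <- clusters_q$cluster[clusters_q$gene_id == gid]
    members <- clusters_q$gene_id[clusters_q$cluster == cl]
    bf <- FALSE
    if (!is.null(prs) && cnt > 0) {
      g <- genes[i, ]
      for (p in prs) {
        sub <- cns[cns$assigned_gene_pair == p, , drop = FALSE]
        names(sub)[names(sub) == "query_start"] <- "qstart"
        names(sub)[names(sub) == "query_end"] <- "qend"
        sm <- summarize_pair_cns(sub, g$start, g$end)
        if (sm$bigfoot) bf <- TRUE
      }
    }
    data.frame(
      query_gene = gid,
      syntelog = if (is.null(syntelog_of[[gid]])) NA_character_
                 else paste(syntelog_of[[gid]], collapse = ","),
      local_duplicate_cluster = if (length(members) > 1)
        paste(members, collapse = ",") else NA_character_,
      cns_count = as.integer(cnt), bigfoot = bf, gevo_url = NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the pipeline within one genome (homeologous mode)
#'
#' Supplies the same genome as query and subject: self-identity anchors are
#' excluded and each unordered homeologous pair is analyzed once; otherwise
#' the pipeline is identical. Useful for CNSs retained between whole-genome
#' duplicates.
#'
#' @param genome a [genome_seq()].
#' @param ann its [gene_annotation()].
#' @inheritParams run_pipeline
#' @export
run_homeologous <- function(genome, ann, config = cns_config(),
                            protein_seqs = NULL, rna_seqs = NULL,
                            premasked = FALSE, verbose = TRUE) {
  run_pipeline(genome, ann, genome, ann, config, protein_seqs, rna_seqs,
               premasked, verbose)
}
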