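#' Configuration for the synthetic genome-pair generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' 50 collinear ortholog pairs, 4 planted 30 bp CNSs per gene at 100%
#' identity, one transposon family at 60 copies per genome (above the 50x
#' masking threshold), 2 tandem duplicates, 2 genes hidden from the query
#' annotation (to exercise co-annotation) and no inversions. Orthologous CDS
#' diverges by per-site substitution plus single-bp indels; planted CNSs
#' receive exactly \code{round((1 - cns_identity) * length)} substitutions so
#' their realized identity is the configured one, and carry indels only when
#' \code{cns_indel_rate > 0}. Intergenic background, introns and UTRs are
#' independent random sequence in the two genomes, decontaminated so that the
#' planted CNS list is the complete cross-genome homology ground truth (see
#' the methods vignette).
#'
#' @param n_genes number of ortholog pairs.
#' @param n_chrom chromosomes per genome (genes split evenly).
#' @param gene_spacing intergenic distance (bp) between transcription units.
#' @param n_cns_per_gene planted CNSs per gene (split between 5' and 3').
#' @param cns_len_range length range (bp) of planted CNSs.
#' @param cns_identity fraction of identical positions in each planted pair.
#' @param cns_indel_rate per-site single-bp indel rate applied to planted CNS
#'   copies (0 keeps the planted truth exactly at the configured identity).
#' @param cns_jitter_sd positional jitter (bp, sd) of the subject-side copy.
#' @param transposon_copy_number,transposon_length repeat family planted in
#'   both genomes.
#' @param n_tandems tandem gene duplicates planted in the query genome.
#' @param n_hidden_genes genes present in the query sequence but left out of
#'   its annotation.
#' @param inversion_blocks number of inverted multi-gene segments in the
#'   subject genome.
#' @param inversion_size genes per inverted segment.
#' @param gene_divergence,gene_indel_rate per-site substitution and indel
#'   rates applied to orthologous CDS.
#' @param utr5_len,utr3_len,cds_exon_len,n_cds_exons,intron_len gene geometry.
#' @param decontaminate scrub chance cross-genome similarity from
#'   non-functional sequence (raw-score 14 screen, one unit stricter than the
#'   pipeline's raw 15 acceptance), so that precision/recall against the
#'   planted truth are well defined.
#' @param pad gene-space reach used by the decontamination screen (should
#'   match the pipeline pad).
#' @param genome_ids labels of the two genomes.
#' @param seed RNG seed; regeneration with the same seed is bit-identical.
#' @return a list of class \code{"fixture_config"}.
#' @export
fixture_config <- function(n_genes = 50, n_chrom = 1, gene_spacing = 6000,
                           n_cns_per_gene = 4, cns_len_range = c(30, 30),
                           cns_identity = 1.0, cns_indel_rate = 0,
                           cns_jitter_sd = 50,
                           transposon_copy_number = 60, transposon_length = 300,
                           n_tandems = 2, n_hidden_genes = 2,
                           inversion_blocks = 0, inversion_size = 5,
                           gene_divergence = 0.05, gene_indel_rate = 0.02,
                           utr5_len = 100, utr3_len = 100, cds_exon_len = 200,
                           n_cds_exons = 3, intron_len = 150,
                           decontaminate = TRUE, pad = 12000,
                           genome_ids = c("A", "B"), seed = 1) {
  cfg <- as.list(environment())
  if (n_genes > 0 && gene_spacing / 2 - max(cns_len_range) - 400 < 160)
    stop("infeasible packing: gene_spacing too small for the CNS lengths")
  structure(cfg, class = "fixture_config")
}

rand_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_nt_clean <- function(n, window = 64, threshold = 20) {
  repeat {
    s <- rand_nt(n)
    if (!any(cpp_dust_mask(s, window, threshold))) return(s)
  }
}

# substitutions at rate `sub` (always to a different base) and single-bp
# indels at rate `indel`
mutate_seq <- function(seq, sub = 0, indel = 0) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (sub > 0) {
    hit <- runif(length(v)) < sub
    if (any(hit))
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  if (indel > 0) {
    out <- character(0)
    for (b in v) {
      r <- runif(1)
      if (r < indel / 2) next                                        # deletion
      if (r < indel) out <- c(out, sample(c("A", "C", "G", "T"), 1)) # insertion
      out <- c(out, b)
    }
    v <- out
  }
  paste(v, collapse = "")
}

# exactly n_sub substitutions at distinct random positions
substitute_exact <- function(seq, n_sub) {
  if (n_sub <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), n_sub)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

# gene segment layout in transcription order, with both genomes' sequences
make_gene_segments <- function(cfg) {
  segs <- list(list(type = "utr", side = "5prime", len = cfg$utr5_len))
  for (k in seq_len(cfg$n_cds_exons)) {
    segs <- c(segs, list(list(type = "cds", len = cfg$cds_exon_len)))
    if (k < cfg$n_cds_exons)
      segs <- c(segs, list(list(type = "intron", len = cfg$intron_len)))
  }
  segs <- c(segs, list(list(type = "utr", side = "3prime", len = cfg$utr3_len)))
  for (i in seq_along(segs)) {
    a <- rand_nt(segs[[i]]$len)
    segs[[i]]$seq_a <- a
    segs[[i]]$seq_b <- if (segs[[i]]$type == "cds")
      mutate_seq(a, cfg$gene_divergence, cfg$gene_indel_rate)
    else rand_nt(segs[[i]]$len)
  }
  segs
}

# one genome's copy of a gene: genomic sequence plus relative exon coordinates
# honouring strand (minus genes are reverse-complemented)
assemble_gene <- function(segs, which_seq, strand) {
  seqs <- vapply(segs, `[[`, character(1), which_seq)
  lens <- nchar(seqs)
  ends <- cumsum(lens); starts <- ends - lens
  total <- sum(lens)
  cds <- NULL; utr <- NULL
  for (i in seq_along(segs)) {
    s <- starts[i]; e <- ends[i]
    if (strand == "-") { tmp <- s; s <- total - e; e <- total - tmp }
    if (segs[[i]]$type == "cds")
      cds <- rbind(cds, data.frame(start = s, end = e))
    else if (segs[[i]]$type == "utr")
      utr <- rbind(utr, data.frame(start = s, end = e, side = segs[[i]]$side))
  }
  seq <- paste(seqs, collapse = "")
  if (strand == "-") seq <- revcomp(seq)
  list(seq = seq, len = total,
       cds = cds[order(cds$start), , drop = FALSE],
       utr = utr[order(utr$start), , drop = FALSE])
}

# sorted offsets with a minimum gap
sample_offsets <- function(k, lo, hi, min_gap) {
  if (k == 0) return(integer(0))
  if (hi - lo < (k - 1) * min_gap) stop("infeasible packing of planted CNSs")
  for (try in 1:200) {
    o <- sort(sample(lo:hi, k))
    if (k == 1 || all(diff(o) >= min_gap)) return(as.integer(o))
  }
  as.integer(round(seq(lo, hi, length.out = k)))
}

#' Generate a synthetic annotated genome pair with planted ground truth
#'
#' Builds two genomes in which orthologous genes are collinear (optionally
#' with inverted segments), each ortholog pair is flanked by planted CNSs at
#' the configured identity, a repeat family is present at the configured copy
#' number in both genomes, and tandem gene duplicates and annotation-hidden
#' genes are planted in the query genome. All remaining sequence is
#' independent random background. Regeneration with the same seed is
#' bit-identical.
#'
#' @param cfg a [fixture_config()].
#' @return list(genome_q, ann_q, genome_s, ann_s, truth); truth carries the
#'   planted CNS table (both-genome coordinates, length, realized percent
#'   identity), tandem clusters, transposon insertions, hidden genes, the
#'   ortholog map and the seed.
#' @export
generate_pair <- function(cfg = fixture_config()) {
  set.seed(cfg$seed)
  ids <- cfg$genome_ids
  L <- as.integer(cfg$gene_spacing)
  n <- cfg$n_genes

  empty_cns <- data.frame(cns_id = character(), gene = character(),
                          qchrom = character(), qstart = integer(),
                          qend = integer(), schrom = character(),
                          sstart = integer(), send = integer(),
                          length = integer(), identity = numeric(),
                          stringsAsFactors = FALSE)
  if (n == 0) {
    gq <- genome_seq(ids[1], c(chr1 = rand_nt(10000)))
    gs <- genome_seq(ids[2], c(chr1 = rand_nt(10000)))
    empty_ann <- gene_annotation(
      data.frame(gene_id = character(), chrom = character(), start = integer(),
                 end = integer(), strand = character(), origin = character()),
      data.frame(gene_id = character(), start = integer(), end = integer()))
    truth <- list(cns = empty_cns, tandems = data.frame(),
                  transposons = data.frame(), hidden = data.frame(),
                  hidden_cds = data.frame(), ortholog = data.frame(),
                  seed = cfg$seed)
    return(list(genome_q = gq, ann_q = empty_ann, genome_s = gs,
                ann_s = empty_ann, truth = truth))
  }

  chrom_of <- sort(rep(seq_len(cfg$n_chrom), length.out = n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  special_pool <- setdiff(seq_len(n), c(1, n))
  hidden <- sort(sample(special_pool,
                        min(cfg$n_hidden_genes, length(special_pool))))
  tandem <- sort(sample(setdiff(special_pool, hidden),
                        min(cfg$n_tandems,
                            length(setdiff(special_pool, hidden)))))
  tf_seq <- rand_nt_clean(cfg$transposon_length)

  genes <- lapply(seq_len(n), function(i) make_gene_segments(cfg))

  # planted CNS plan per gene: offsets from the transcription-unit boundary
  cns_plan <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (i %in% hidden) 0L else cfg$n_cns_per_gene
    if (k == 0) next
    # tandem duplicates are inserted just downstream of their gene, which
    # would shift 3' CNS spacing between the genomes; those genes get
    # upstream CNSs only so planted geometry stays comparable
    k_up <- if (i %in% tandem) k else ceiling(k / 2)
    k_down <- k - k_up
    len_choices <- seq(cfg$cns_len_range[1], cfg$cns_len_range[2])
    lens <- len_choices[sample.int(length(len_choices), k, replace = TRUE)]
    lmax <- max(lens)
    omax <- as.integer(L / 2 - lmax - 400)
    o_up <- sample_offsets(k_up, 150L, omax, lmax + 250L)
    o_down <- sample_offsets(k_down, 150L, omax, lmax + 250L)
    mk <- function(o, side, lenv) {
      if (length(o) == 0) return(NULL)
      jit <- pmin(100L, pmax(-100L,
        as.integer(round(rnorm(length(o), 0, cfg$cns_jitter_sd)))))
      data.frame(side = side, rank = seq_along(o), offset_a = o,
                 offset_b = pmax(120L, o + jit), len = lenv,
                 stringsAsFactors = FALSE)
    }
    plan <- rbind(mk(o_up, "up", lens[seq_len(k_up)]),
                  mk(o_down, "down", lens[k_up + seq_len(k_down)]))
    # substitution count rounds half away from zero so the planted identity
    # is deterministic (e.g. 30 bp at 0.85 -> 5 substitutions)
    n_sub <- as.integer(floor((1 - cfg$cns_identity) * plan$len + 0.5))
    plan$seq_a <- vapply(plan$len, rand_nt_clean, character(1))
    plan$seq_b <- vapply(seq_len(nrow(plan)), function(r) {
      s <- substitute_exact(plan$seq_a[r], n_sub[r])
      if (cfg$cns_indel_rate > 0) s <- mutate_seq(s, 0, cfg$cns_indel_rate)
      s
    }, character(1))
    plan$identity <- (plan$len - n_sub) / plan$len
    cns_plan[[i]] <- plan
  }

  # transposon copies per intergap: inserted as extra sequence at the gap
  # centre, so capacity is unconstrained and CNS geometry is untouched
  place_tf <- function(n_copies) {
    if (n_copies == 0) return(integer(n))
    idx <- sample(rep(seq_len(n), length.out = max(n_copies, n)))[seq_len(n_copies)]
    tabulate(idx, n)
  }
  tf_a <- place_tf(cfg$transposon_copy_number)
  tf_b <- place_tf(cfg$transposon_copy_number)

  build_genome <- function(which_seq, gid) {
    is_q <- which_seq == "seq_a"
    tf_tab <- if (is_q) tf_a else tf_b
    chrseqs <- character(0)
    genes_df <- NULL; cds_df <- NULL; utr_df <- NULL
    cns_rows <- NULL; tf_rows <- NULL; hidden_rows <- NULL
    hidden_cds <- NULL; tand_rows <- NULL
    for (ch in seq_len(cfg$n_chrom)) {
      chrom <- paste0("chr", ch)
      members <- which(chrom_of == ch)
      pieces <- list(); cursor <- 0L
      add <- function(s) {
        pieces[[length(pieces) + 1L]] <<- s
        cursor <<- cursor + nchar(s)
      }
      for (i in members) {
        # intergap before gene i: left piece (previous gene's 3' CNSs),
        # transposon copies inserted at the centre, right piece (gene i's
        # 5' CNSs, offsets measured from the transcription start)
        Lg <- if (is_q) L else L + sample(0:300, 1)
        left_len <- as.integer(Lg / 2); right_len <- Lg - left_len
        left <- strsplit(rand_nt(left_len), "", fixed = TRUE)[[1]]
        right <- strsplit(rand_nt(right_len), "", fixed = TRUE)[[1]]
        prev <- if (i > min(members)) i - 1L else NA_integer_
        if (!is.na(prev) && !is.null(cns_plan[[prev]])) {
          p <- cns_plan[[prev]]
          for (r in which(p$side == "down")) {
            o <- if (is_q) p$offset_a[r] else p$offset_b[r]
            s <- if (is_q) p$seq_a[r] else p$seq_b[r]
            left[(o + 1):(o + nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
            cns_rows <- rbind(cns_rows, data.frame(
              gene = prev, side = "down", rank = p$rank[r], chrom = chrom,
              start = cursor + o, end = cursor + o + nchar(s)))
          }
        }
        add(paste(left, collapse = ""))
        for (r in seq_len(tf_tab[i])) {
          add(rand_nt(60))
          tf_rows <- rbind(tf_rows, data.frame(
            chrom = chrom, start = cursor, end = cursor + nchar(tf_seq)))
          add(tf_seq)
        }
        up_rel <- NULL
        if (!is.null(cns_plan[[i]])) {
          p <- cns_plan[[i]]
          for (r in which(p$side == "up")) {
            o <- if (is_q) p$offset_a[r] else p$offset_b[r]
            s <- if (is_q) p$seq_a[r] else p$seq_b[r]
            rel <- right_len - o - nchar(s)
            right[(rel + 1):(rel + nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
            up_rel <- rbind(up_rel, data.frame(rank = p$rank[r], rel = rel,
                                               len = nchar(s)))
          }
        }
        right_at <- cursor
        add(paste(right, collapse = ""))
        for (r in seq_len(NROW(up_rel))) {
          cns_rows <- rbind(cns_rows, data.frame(
            gene = i, side = "up", rank = up_rel$rank[r], chrom = chrom,
            start = right_at + up_rel$rel[r],
            end = right_at + up_rel$rel[r] + up_rel$len[r]))
        }

        gm <- assemble_gene(genes[[i]], which_seq, strand[i])
        gstart <- cursor
        gene_id <- sprintf("%s_g%03d", gid, i)
        if (is_q && i %in% hidden) {
          hidden_rows <- rbind(hidden_rows, data.frame(
            gene = i, gene_id = gene_id, chrom = chrom, start = gstart,
            end = gstart + gm$len, strand = strand[i],
            stringsAsFactors = FALSE))
          hidden_cds <- rbind(hidden_cds, data.frame(
            gene_id = gene_id, chrom = chrom,
            start = gm$cds$start + gstart, end = gm$cds$end + gstart))
        } else {
          genes_df <- rbind(genes_df, data.frame(
            gene_id = gene_id, chrom = chrom, start = gstart,
            end = gstart + gm$len, strand = strand[i], origin = "official",
            stringsAsFactors = FALSE))
          cds_df <- rbind(cds_df, data.frame(
            gene_id = gene_id, start = gm$cds$start + gstart,
            end = gm$cds$end + gstart))
          if (nrow(gm$utr))
            utr_df <- rbind(utr_df, data.frame(
              gene_id = gene_id, start = gm$utr$start + gstart,
              end = gm$utr$end + gstart, side = gm$utr$side))
        }
        add(gm$seq)

        if (is_q && i %in% tandem) {
          add(rand_nt(300))
          td <- assemble_gene(genes[[i]], which_seq, strand[i])
          td_id <- paste0(gene_id, "_td")
          tstart <- cursor
          genes_df <- rbind(genes_df, data.frame(
            gene_id = td_id, chrom = chrom, start = tstart,
            end = tstart + td$len, strand = strand[i], origin = "official",
            stringsAsFactors = FALSE))
          cds_df <- rbind(cds_df, data.frame(
            gene_id = td_id, start = td$cds$start + tstart,
            end = td$cds$end + tstart))
          if (nrow(td$utr))
            utr_df <- rbind(utr_df, data.frame(
              gene_id = td_id, start = td$utr$start + tstart,
              end = td$utr$end + tstart, side = td$utr$side))
          tand_rows <- rbind(tand_rows, data.frame(
            gene = i, gene_id = gene_id, copy_id = td_id, chrom = chrom,
            start = tstart, end = tstart + td$len, stringsAsFactors = FALSE))
          add(td$seq)
        }
      }
      # trailing intergap hosts the last gene's 3' CNSs
      last <- max(members)
      tail_gap <- strsplit(rand_nt(L), "", fixed = TRUE)[[1]]
      if (!is.null(cns_plan[[last]])) {
        p <- cns_plan[[last]]
        for (r in which(p$side == "down")) {
          o <- if (is_q) p$offset_a[r] else p$offset_b[r]
          s <- if (is_q) p$seq_a[r] else p$seq_b[r]
          tail_gap[(o + 1):(o + nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
          cns_rows <- rbind(cns_rows, data.frame(
            gene = last, side = "down", rank = p$rank[r], chrom = chrom,
            start = cursor + o, end = cursor + o + nchar(s)))
        }
      }
      add(paste(tail_gap, collapse = ""))
      chrseqs[chrom] <- paste(unlist(pieces), collapse = "")
    }
    list(genome = genome_seq(gid, chrseqs),
         ann = gene_annotation(genes_df, cds_df, utr_df),
         cns = cns_rows, tf = tf_rows, hidden = hidden_rows,
         hidden_cds = hidden_cds, tandems = tand_rows)
  }

  qb <- build_genome("seq_a", ids[1])
  sb <- build_genome("seq_b", ids[2])

  if (cfg$inversion_blocks > 0)
    sb <- apply_inversions(sb, cfg, chrom_of, L)

  truth_cns <- empty_cns
  if (!is.null(qb$cns) && !is.null(sb$cns)) {
    m <- merge(qb$cns, sb$cns, by = c("gene", "side", "rank"),
               suffixes = c("_q", "_s"))
    m <- m[order(m$chrom_q, m$start_q), , drop = FALSE]
    ident <- unlist(lapply(seq_len(n), function(i) {
      p <- cns_plan[[i]]
      if (is.null(p)) return(NULL)
      setNames(p$identity, paste(i, p$side, p$rank))
    }))
    truth_cns <- data.frame(
      cns_id = sprintf("planted%04d", seq_len(nrow(m))),
      gene = sprintf("%s_g%03d", ids[1], m$gene),
      qchrom = m$chrom_q, qstart = m$start_q, qend = m$end_q,
      schrom = m$chrom_s, sstart = m$start_s, send = m$end_s,
      length = m$end_q - m$start_q,
      identity = unname(ident[paste(m$gene, m$side, m$rank)]),
      stringsAsFactors = FALSE)
  }

  truth <- list(
    cns = truth_cns,
    tandems = if (is.null(qb$tandems)) data.frame() else qb$tandems,
    transposons = {
      tf <- rbind(if (is.null(qb$tf)) NULL else cbind(qb$tf, genome = ids[1]),
                  if (is.null(sb$tf)) NULL else cbind(sb$tf, genome = ids[2]))
      if (is.null(tf)) data.frame(chrom = character(), start = integer(),
                                  end = integer(), genome = character())
      else tf
    },
    hidden = if (is.null(qb$hidden)) data.frame() else qb$hidden,
    hidden_cds = if (is.null(qb$hidden_cds)) data.frame() else qb$hidden_cds,
    ortholog = data.frame(
      q_gene = sprintf("%s_g%03d", ids[1], seq_len(n)),
      s_gene = sprintf("%s_g%03d", ids[2], seq_len(n)),
      hidden_q = seq_len(n) %in% hidden,
      stringsAsFactors = FALSE),
    seed = cfg$seed)

  out <- list(genome_q = qb$genome, ann_q = qb$ann,
              genome_s = sb$genome, ann_s = sb$ann, truth = truth)
  if (cfg$decontaminate) out <- decontaminate_pair(out, cfg)
  out
}

# invert `inversion_blocks` runs of consecutive genes in the subject build:
# reverse-complement the spanned region and mirror all feature coordinates
apply_inversions <- function(sb, cfg, chrom_of, L) {
  g <- sb$ann$genes
  used <- integer(0)
  for (b in seq_len(cfg$inversion_blocks)) {
    ord <- g[order(g$chrom, g$start), ]
    n <- nrow(ord)
    size <- min(cfg$inversion_size, n - 2)
    starts_ok <- which(vapply(seq_len(n - size + 1), function(i)
      all(ord$chrom[i:(i + size - 1)] == ord$chrom[i]) &&
        !any(seq(i, i + size - 1) %in% used), logical(1)))
    starts_ok <- setdiff(starts_ok, c(1))
    if (length(starts_ok) == 0) break
    i0 <- sample(starts_ok, 1)
    run <- i0:(i0 + size - 1)
    used <- c(used, run)
    chrom <- ord$chrom[i0]
    half <- as.integer(L / 2)
    rs <- ord$start[i0] - half
    re <- ord$end[run[length(run)]] + half
    clen <- nchar(sb$genome$seqs[[chrom]])
    rs <- max(0L, rs); re <- min(clen, re)
    # nudge boundaries off any feature interval
    feat <- rbind(
      data.frame(start = sb$cns$start[sb$cns$chrom == chrom],
                 end = sb$cns$end[sb$cns$chrom == chrom]),
      data.frame(start = sb$tf$start[sb$tf$chrom == chrom],
                 end = sb$tf$end[sb$tf$chrom == chrom]),
      data.frame(start = g$start[g$chrom == chrom],
                 end = g$end[g$chrom == chrom]))
    inside <- function(p) any(feat$start < p & feat$end > p)
    while (rs > 0 && inside(rs)) rs <- rs - 37L
    while (re < clen && inside(re)) re <- re + 37L
    # reverse-complement the region
    s <- sb$genome$seqs[[chrom]]
    mid <- revcomp(substring(s, rs + 1L, re))
    sb$genome$seqs[[chrom]] <- paste0(substring(s, 1L, rs), mid,
                                      substring(s, re + 1L, clen))
    mirror <- function(df) {
      if (is.null(df) || nrow(df) == 0) return(df)
      hit <- df$chrom == chrom & df$start >= rs & df$end <= re
      ns <- rs + (re - df$end[hit]); ne <- rs + (re - df$start[hit])
      df$start[hit] <- ns; df$end[hit] <- ne
      df
    }
    # genes need chrom lookup via the gene table
    gsel <- g$chrom == chrom & g$start >= rs & g$end <= re
    moved <- g$gene_id[gsel]
    ns <- rs + (re - g$end[gsel]); ne <- rs + (re - g$start[gsel])
    g$start[gsel] <- ns; g$end[gsel] <- ne
    g$strand[gsel] <- ifelse(g$strand[gsel] == "+", "-", "+")
    for (tab in c("cds", "utr")) {
      df <- sb$ann[[tab]]
      hit <- df$gene_id %in% moved
      ns <- rs + (re - df$end[hit]); ne <- rs + (re - df$start[hit])
      df$start[hit] <- ns; df$end[hit] <- ne
      sb$ann[[tab]] <- df
    }
    sb$cns <- mirror(sb$cns)
    sb$tf <- mirror(sb$tf)
  }
  sb$ann$genes <- g
  validate_annotation(sb$ann)
  sb
}

# scrub chance cross-genome similarity from non-functional sequence so the
# planted CNS list is the complete homology ground truth for the window pairs
# the pipeline will examine
decontaminate_pair <- function(pair, cfg, max_rounds = 20L) {
  scheme <- scoring_scheme()
  truth <- pair$truth
  orth <- truth$ortholog
  if (is.null(orth) || nrow(orth) == 0) return(pair)

  protected_q <- rbind(
    data.frame(chrom = pair$ann_q$genes$chrom[
      match(pair$ann_q$cds$gene_id, pair$ann_q$genes$gene_id)],
      start = pair$ann_q$cds$start, end = pair$ann_q$cds$end),
    if (nrow(truth$hidden_cds))
      truth$hidden_cds[, c("chrom", "start", "end")] else NULL,
    if (nrow(truth$cns))
      data.frame(chrom = truth$cns$qchrom, start = truth$cns$qstart,
                 end = truth$cns$qend) else NULL)
  protected_s <- rbind(
    data.frame(chrom = pair$ann_s$genes$chrom[
      match(pair$ann_s$cds$gene_id, pair$ann_s$genes$gene_id)],
      start = pair$ann_s$cds$start, end = pair$ann_s$cds$end),
    if (nrow(truth$cns))
      data.frame(chrom = truth$cns$schrom, start = truth$cns$sstart,
                 end = truth$cns$send) else NULL)

  # gene spans (hidden genes included) define the screening windows
  gene_span <- function(ann, hidden_tab, gid, hidden_id) {
    if (!is.na(hidden_id) && hidden_id %in% hidden_tab$gene_id) {
      h <- hidden_tab[hidden_tab$gene_id == hidden_id, ]
      return(list(chrom = h$chrom, start = h$start, end = h$end))
    }
    gg <- ann$genes[ann$genes$gene_id == gid, ]
    list(chrom = gg$chrom, start = gg$start, end = gg$end)
  }

  mask_iv_q <- rbind(
    data.frame(chrom = pair$ann_q$genes$chrom[
      match(pair$ann_q$cds$gene_id, pair$ann_q$genes$gene_id)],
      start = pair$ann_q$cds$start, end = pair$ann_q$cds$end),
    if (nrow(truth$hidden_cds))
      truth$hidden_cds[, c("chrom", "start", "end")] else NULL)
  mask_iv_s <- data.frame(chrom = pair$ann_s$genes$chrom[
    match(pair$ann_s$cds$gene_id, pair$ann_s$genes$gene_id)],
    start = pair$ann_s$cds$start, end = pair$ann_s$cds$end)
  # planted repeats are known homology, not chance background: always masked
  # during the screen and never resampled
  if (NROW(truth$transposons) > 0) {
    tf <- truth$transposons
    tf_q <- tf[tf$genome == pair$genome_q$genome_id, c("chrom", "start", "end")]
    tf_s <- tf[tf$genome == pair$genome_s$genome_id, c("chrom", "start", "end")]
    mask_iv_q <- rbind(mask_iv_q, tf_q)
    mask_iv_s <- rbind(mask_iv_s, tf_s)
    protected_q <- rbind(protected_q, tf_q)
    protected_s <- rbind(protected_s, tf_s)
  }

  # window coordinates per ortholog pair
  win <- lapply(seq_len(nrow(orth)), function(k) {
    spq <- gene_span(pair$ann_q, truth$hidden, orth$q_gene[k],
                     if (orth$hidden_q[k]) orth$q_gene[k] else NA)
    sps <- gene_span(pair$ann_s, data.frame(), orth$s_gene[k], NA)
    list(qchrom = spq$chrom,
         qs = max(0L, spq$start - cfg$pad),
         qe = spq$end + cfg$pad,
         schrom = sps$chrom,
         ss = max(0L, sps$start - cfg$pad),
         se = sps$end + cfg$pad)
  })

  overlaps_any <- function(chrom, s, e, iv) {
    if (NROW(iv) == 0) return(FALSE)
    any(iv$chrom == chrom & iv$start < e & iv$end > s)
  }

  # window extraction with window-local CDS/repeat masking
  masked_window <- function(genome, chrom, ws, we, iv) {
    we <- min(nchar(genome$seqs[[chrom]]), we)
    s <- substring(genome$seqs[[chrom]], ws + 1L, we)
    sub <- iv[iv$chrom == chrom & iv$start < we & iv$end > ws, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      a <- max(sub$start[r], ws) - ws + 1L
      b <- min(sub$end[r], we) - ws
      substr(s, a, b) <- strrep("N", b - a + 1L)
    }
    s
  }

  dirty <- rep(TRUE, nrow(orth))
  for (round in seq_len(max_rounds)) {
    if (!any(dirty)) break
    spurious <- NULL
    for (k in which(dirty)) {
      w <- win[[k]]
      wq <- masked_window(pair$genome_q, w$qchrom, w$qs, w$qe, mask_iv_q)
      ws <- masked_window(pair$genome_s, w$schrom, w$ss, w$se, mask_iv_s)
      h <- seed_hits(setNames(wq, "q"), setNames(ws, "s"), scheme,
                     min_raw = 14, both_strands = TRUE, dust = TRUE)
      if (nrow(h) == 0) next
      h$qchrom <- w$qchrom; h$schrom <- w$schrom
      h$qstart <- h$qstart + w$qs; h$qend <- h$qend + w$qs
      h$sstart <- h$sstart + w$ss; h$send <- h$send + w$ss
      spurious <- rbind(spurious, h)
    }
    if (!is.null(spurious) && nrow(spurious)) {
      tc <- truth$cns
      ov <- function(chrom, s, e, tchrom, ts, te) {
        if (length(ts) == 0) return(rep(FALSE, length(s)))
        vapply(seq_along(s), function(i)
          any(tchrom == chrom[i] & ts < e[i] & te > s[i]), logical(1))
      }
      ok <- ov(spurious$qchrom, spurious$qstart, spurious$qend,
               tc$qchrom, tc$qstart, tc$qend) &
        ov(spurious$schrom, spurious$sstart, spurious$send,
           tc$schrom, tc$sstart, tc$send)
      spurious <- spurious[!ok, , drop = FALSE]
    }
    if (is.null(spurious) || nrow(spurious) == 0) break

    # resample the offending background (subject side preferred) and mark
    # every window pair touching a resampled interval for re-screening
    resampled_q <- NULL; resampled_s <- NULL
    for (r in seq_len(nrow(spurious))) {
      hit <- spurious[r, ]
      done <- resample_free(pair, "genome_s", hit$schrom,
                            hit$sstart - 6L, hit$send + 6L, protected_s)
      if (!is.null(done)) {
        pair <- done
        resampled_s <- rbind(resampled_s, data.frame(
          chrom = hit$schrom, start = hit$sstart - 6L, end = hit$send + 6L))
        next
      }
      done <- resample_free(pair, "genome_q", hit$qchrom,
                            hit$qstart - 6L, hit$qend + 6L, protected_q)
      if (!is.null(done)) {
        pair <- done
        resampled_q <- rbind(resampled_q, data.frame(
          chrom = hit$qchrom, start = hit$qstart - 6L, end = hit$qend + 6L))
      }
    }
    dirty <- vapply(seq_len(nrow(orth)), function(k) {
      w <- win[[k]]
      overlaps_any(w$qchrom, w$qs, w$qe, resampled_q) ||
        overlaps_any(w$schrom, w$ss, w$se, resampled_s)
    }, logical(1))
  }
  pair
}

# replace the unprotected part of [s, e) with fresh random bases;
# NULL when every position is protected
resample_free <- function(pair, which_genome, chrom, s, e, protected) {
  gnm <- pair[[which_genome]]
  n <- nchar(gnm$seqs[[chrom]])
  s <- max(0L, s); e <- min(n, e)
  if (e <= s) return(NULL)
  keep <- IRanges::IRanges(s + 1L, e)
  pr <- protected[protected$chrom == chrom, , drop = FALSE]
  free <- if (nrow(pr))
    IRanges::setdiff(keep, IRanges::IRanges(pr$start + 1L, pr$end))
  else keep
  if (length(free) == 0 || sum(IRanges::width(free)) == 0) return(NULL)
  for (i in seq_along(free)) {
    a <- IRanges::start(free)[i]; b <- IRanges::end(free)[i]
    substr(gnm$seqs[[chrom]], a, b) <- rand_nt(b - a + 1L)
  }
  pair[[which_genome]] <- gnm
  pair
}

#' Score pipeline output against the planted truth
#'
#' Recall is the fraction of planted CNSs overlapped (query side, >= 1 bp) by
#' at least one reported CNS; precision is the fraction of reported CNSs
#' overlapping at least one planted CNS. With zero reported CNSs precision is
#' returned as 1.0 with attribute \code{zero_denominator = TRUE}.
#'
#' @param reported CNS data.frame with query_chrom, query_start, query_end.
#' @param truth the generator's truth list (or its \code{cns} table).
#' @param min_overlap minimum overlap in bp.
#' @return named numeric c(recall, precision).
#' @export
evaluate_recovery <- function(reported, truth, min_overlap = 1L) {
  tc <- if (is.data.frame(truth)) truth else truth$cns
  ov_count <- function(ac, as_, ae, bc, bs, be) {
    vapply(seq_along(as_), function(i) {
      w <- bc == ac[i]
      any(pmin(be[w], ae[i]) - pmax(bs[w], as_[i]) >= min_overlap)
    }, logical(1))
  }
  if (nrow(tc) == 0)
    return(c(recall = NA_real_, precision = NA_real_))
  if (is.null(reported) || nrow(reported) == 0) {
    out <- c(recall = 0, precision = 1)
    attr(out, "zero_denominator") <- TRUE
    return(out)
  }
  hit_t <- ov_count(tc$qchrom, tc$qstart, tc$qend,
                    reported$query_chrom, reported$query_start,
                    reported$query_end)
  hit_r <- ov_count(reported$query_chrom, reported$query_start,
                    reported$query_end, tc$qchrom, tc$qstart, tc$qend)
  c(recall = mean(hit_t), precision = mean(hit_r))
}

#' Merge a generated pair into one genome for homeologous analysis
#'
#' Concatenates the two genomes of [generate_pair()] into a single genome
#' (subject chromosomes renamed with a \code{_h} suffix) whose planted CNSs
#' now relate homeologous gene copies; used to exercise the within-genome
#' (homeologous) pipeline mode.
#'
#' @param cfg a [fixture_config()].
#' @return list(genome, ann, truth).
#' @export
generate_homeolog_fixture <- function(cfg = fixture_config()) {
  p <- generate_pair(cfg)
  rn <- function(x) paste0(x, "_h")
  seqs <- c(p$genome_q$seqs, setNames(p$genome_s$seqs, rn(names(p$genome_s$seqs))))
  genome <- genome_seq(p$genome_q$genome_id, seqs)
  gs <- p$ann_s$genes; gs$chrom <- rn(gs$chrom)
  ann <- gene_annotation(rbind(p$ann_q$genes, gs),
                         rbind(p$ann_q$cds, p$ann_s$cds),
                         rbind(p$ann_q$utr, p$ann_s$utr))
  truth <- p$truth
  if (nrow(truth$cns)) truth$cns$schrom <- rn(truth$cns$schrom)
  if (nrow(truth$transposons)) {
    sel <- truth$transposons$genome == p$genome_s$genome_id
    truth$transposons$chrom[sel] <- rn(truth$transposons$chrom[sel])
  }
  list(genome = genome, ann = ann, truth = truth)
}

#' Write a generated fixture to standard files
#'
#' FASTA and BED12 per genome plus the planted-CNS truth table as TSV.
#'
#' @param pair output of [generate_pair()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta_q = file.path(dir, paste0(pair$genome_q$genome_id, ".fa")),
    bed_q = file.path(dir, paste0(pair$genome_q$genome_id, ".bed")),
    fasta_s = file.path(dir, paste0(pair$genome_s$genome_id, ".fa")),
    bed_s = file.path(dir, paste0(pair$genome_s$genome_id, ".bed")),
    truth = file.path(dir, "truth_cns.tsv"))
  write_genome_fasta(pair$genome_q, paths["fasta_q"])
  write_gene_bed(pair$ann_q, paths["bed_q"])
  write_genome_fasta(pair$genome_s, paths["fasta_s"])
  write_gene_bed(pair$ann_s, paths["bed_s"])
  write.table(pair$truth$cns, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
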