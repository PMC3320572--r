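#' Configuration for the synthetic RNA-Seq simulator
#'
#' The simulator emulates the conditions the detection method was designed
#' for: multi-gene genomes with exon/intron structure, expressed transcripts
#' at log-normally varied abundance, fusion transcripts joining the exons of
#' two genes (inter-chromosomal, inverted, and same-strand cases),
#' strand-specific paired-end reads of unequal mate lengths (50x25 default)
#' from gel-selected inserts of 100-200 bp (normal, mean 150 sd 25), and
#' i.i.d. substitution errors.  The genome is uniform-random ACGT (no repeat
#' families).
#'
#' @param n_chroms,chrom_length number and length of chromosomes.
#' @param n_genes number of genes (placed round-robin across chromosomes,
#'   non-overlapping, random strand).
#' @param exons_per_gene,exon_length,intron_length,intergenic_gap
#'   length-2 vectors giving inclusive sampling ranges.
#' @param n_fusions number of fusion transcripts.
#' @param fusion_mix named weights over classes `inter_chromosomal`,
#'   `inverted`, `same_strand`.
#' @param fusion_five_prime_rank `"uniform"` draws the last retained 5' exon
#'   uniformly from ranks 1..(n-1); `"first"` always fuses after exon 1 (a
#'   positive control for the breakpoint-bias test).
#' @param expr_meanlog,expr_sdlog log-normal expression weights.
#' @param read_len_fwd,read_len_rev mate lengths (50/25 or 75/35 chemistry).
#' @param insert_mean,insert_sd insert-size model.
#' @param error_rate per-base substitution probability.
#' @param pairs_per_transcript,fusion_pairs_per_transcript expected read
#'   pairs per gene transcript (scaled by expression weight) and per fusion
#'   transcript.
#' @param seed master seed; downstream stages derive their own offsets so a
#'   config reproduces a dataset byte for byte.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(n_chroms = 2L, chrom_length = 60000L, n_genes = 16L,
                      exons_per_gene = c(3L, 6L),
                      exon_length = c(90L, 240L),
                      intron_length = c(150L, 600L),
                      intergenic_gap = c(400L, 1200L),
                      n_fusions = 6L,
                      fusion_mix = c(inter_chromosomal = 1/3,
                                     inverted = 1/3, same_strand = 1/3),
                      fusion_five_prime_rank = c("uniform", "first"),
                      expr_meanlog = log(20), expr_sdlog = 0.8,
                      read_len_fwd = 50L, read_len_rev = 25L,
                      insert_mean = 150, insert_sd = 25,
                      error_rate = 0,
                      pairs_per_transcript = 60,
                      fusion_pairs_per_transcript = 300,
                      seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_gap = as.integer(intergenic_gap),
              n_fusions = as.integer(n_fusions),
              fusion_mix = fusion_mix,
              fusion_five_prime_rank = match.arg(fusion_five_prime_rank),
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              read_len_fwd = as.integer(read_len_fwd),
              read_len_rev = as.integer(read_len_rev),
              insert_mean = insert_mean, insert_sd = insert_sd,
              error_rate = error_rate,
              pairs_per_transcript = pairs_per_transcript,
              fusion_pairs_per_transcript = fusion_pairs_per_transcript,
              seed = as.integer(seed))
  stopifnot(cfg$chrom_length > 0L, cfg$n_genes > 0L,
            all(cfg$exon_length > 0L), all(cfg$intron_length > 0L),
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$insert_mean >= cfg$read_len_fwd,
            all(names(cfg$fusion_mix) %in%
                  c("inter_chromosomal", "inverted", "same_strand")))
  structure(cfg, class = "SimConfig")
}

#' @noRd
.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' @noRd
.randomSeq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a genome and gene model
#'
#' Draws a uniform-random genome and places non-overlapping genes with
#' exon/intron structure per the configuration; deterministic under the
#' config seed.
#'
#' @param config a [simConfig()].
#' @return `list(model=, truth=)` where `truth$junctions` lists the true
#'   (adjacent-exon) splice junctions per gene.
#' @export
simulateReference <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  pos <- setNames(rep(1L, config$n_chroms), chroms)
  rows <- list()
  for (g in seq_len(config$n_genes)) {
    chrom <- chroms[(g - 1L) %% config$n_chroms + 1L]
    strand <- sample(c("+", "-"), 1L)
    k <- .runif_int(1L, config$exons_per_gene)
    elens <- .runif_int(k, config$exon_length)
    ilens <- if (k > 1L) .runif_int(k - 1L, config$intron_length) else
      integer(0)
    gap <- .runif_int(1L, config$intergenic_gap)
    start <- pos[chrom] + gap
    st <- start + cumsum(c(0L, head(elens, -1L) + ilens))
    en <- st + elens - 1L
    if (max(en) > config$chrom_length)
      stop("genes do not fit on ", chrom,
           "; increase chrom_length or reduce n_genes")
    pos[chrom] <- max(en)
    rows[[g]] <- data.frame(chrom = chrom,
                            start = st, end = en, strand = strand,
                            gene_id = sprintf("G%02d", g),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  genome <- Biostrings::DNAStringSet(setNames(
    vapply(chroms, function(ch) .randomSeq(config$chrom_length),
           character(1)), chroms))
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$gene_id <- tab$gene_id
  model <- GeneModel(gr, genome)
  ex <- model@exons
  jn <- list()
  for (g in model@genes$gene_id) {
    i <- which(ex$gene_id == g)
    i <- i[order(ex$rank[i])]
    if (length(i) > 1L) {
      jn[[g]] <- data.frame(
        gene_id = g,
        donor_exon_id = ex$exon_id[i[-length(i)]],
        acceptor_exon_id = ex$exon_id[i[-1L]],
        stringsAsFactors = FALSE)
    }
  }
  junctions <- if (length(jn)) do.call(rbind, jn) else
    data.frame(gene_id = character(0), donor_exon_id = character(0),
               acceptor_exon_id = character(0), stringsAsFactors = FALSE)
  rownames(junctions) <- NULL
  list(model = model, truth = list(junctions = junctions))
}

#' Simulate fusion transcripts
#'
#' Each fusion joins exons 1..r of a 5' gene to exons s..n of a 3' gene,
#' with the partner geometry drawn from the configured class mix.  Gene
#' pairs are drawn without replacement; the recorded truth includes the
#' class and (for same-strand fusions) the signed distance under the same
#' convention as [classifyFusion()].
#'
#' @param model a [GeneModel-class].
#' @param config a [simConfig()].
#' @param seed RNG seed (default: config seed + 1).
#' @return `data.frame` of fusion truth: `fusion_id`, `gene5`, `gene3`,
#'   `donor_exon_id`, `acceptor_exon_id`, `class`, `signed_distance`,
#'   `sequence`, `breakpoint_offset` (position of the last 5' base in the
#'   fusion transcript).
#' @export
simulateFusions <- function(model, config, seed = config$seed + 1L) {
  set.seed(seed)
  gt <- model@genes
  ex <- model@exons
  if (nrow(gt) < 2L) stop("need at least two genes to fuse")
  pairs <- expand.grid(g5 = gt$gene_id, g3 = gt$gene_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$g5 != pairs$g3, ]
  i5 <- match(pairs$g5, gt$gene_id); i3 <- match(pairs$g3, gt$gene_id)
  pairs$class <- ifelse(gt$chrom[i5] != gt$chrom[i3], "inter_chromosomal",
                        ifelse(gt$strand[i5] != gt$strand[i3], "inverted",
                               "same_strand"))
  # 5' genes need >= 2 exons (an intron must follow the fused exon);
  # 3' genes need >= 2 exons (we retain exons s..n with s >= 2)
  nex <- setNames(gt$n_exons, gt$gene_id)
  pairs <- pairs[nex[pairs$g5] >= 2L & nex[pairs$g3] >= 2L, ]
  mix <- config$fusion_mix / sum(config$fusion_mix)
  out <- list()
  for (f in seq_len(config$n_fusions)) {
    repeat {
      cls <- sample(names(mix), 1L, prob = mix)
      avail <- pairs[pairs$class == cls, , drop = FALSE]
      if (nrow(avail)) break
      if (!nrow(pairs)) stop("no eligible gene pairs left for fusions")
      mix <- mix[names(mix) %in% pairs$class]
      if (!length(mix)) stop("fusion class mix impossible for this model")
    }
    pick <- avail[sample(nrow(avail), 1L), ]
    pairs <- pairs[!(pairs$g5 == pick$g5 & pairs$g3 == pick$g3), ]
    n5 <- nex[[pick$g5]]; n3 <- nex[[pick$g3]]
    r <- if (config$fusion_five_prime_rank == "first") 1L else
      sample(seq_len(n5 - 1L), 1L)
    s <- if (n3 == 2L) 2L else sample(2:n3, 1L)
    i <- which(ex$gene_id == pick$g5)
    i <- i[order(ex$rank[i])][seq_len(r)]
    j <- which(ex$gene_id == pick$g3)
    j <- j[order(ex$rank[j])][s:n3]
    seq5 <- paste(exonSequence(model, ex$exon_id[i]), collapse = "")
    seq3 <- paste(exonSequence(model, ex$exon_id[j]), collapse = "")
    donor <- ex$exon_id[i[length(i)]]
    acceptor <- ex$exon_id[j[1L]]
    geom <- classifyFusion(donor, acceptor, model)
    out[[f]] <- data.frame(
      fusion_id = sprintf("F%02d", f),
      gene5 = pick$g5, gene3 = pick$g3,
      donor_exon_id = donor, acceptor_exon_id = acceptor,
      class = cls,
      signed_distance = geom$signed_distance,
      sequence = paste0(seq5, seq3),
      breakpoint_offset = nchar(seq5),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcript table for read simulation
#'
#' One spliced transcript per gene plus the supplied fusion transcripts,
#' with the transcript-coordinate offsets of every junction (last base of
#' the upstream exon) recorded for ground-truth bookkeeping.
#'
#' @param model a [GeneModel-class].
#' @param fusions fusion table from [simulateFusions()], or `NULL`.
#' @return `list(table=, junctions=)`: `table` has `transcript_id`,
#'   `sequence`, `is_fusion`, `fusion_id`; `junctions` maps transcript id to
#'   a `data.frame(offset, donor_exon_id, acceptor_exon_id, is_fusion)`.
#' @export
simTranscripts <- function(model, fusions = NULL) {
  ex <- model@exons
  rows <- list(); jn <- list()
  for (g in model@genes$gene_id) {
    i <- which(ex$gene_id == g)
    i <- i[order(ex$rank[i])]
    seqs <- exonSequence(model, ex$exon_id[i])
    rows[[g]] <- data.frame(transcript_id = g,
                            sequence = paste(seqs, collapse = ""),
                            is_fusion = FALSE, fusion_id = NA_character_,
                            stringsAsFactors = FALSE)
    if (length(i) > 1L) {
      off <- cumsum(nchar(seqs))
      jn[[g]] <- data.frame(offset = off[-length(off)],
                            donor_exon_id = ex$exon_id[i[-length(i)]],
                            acceptor_exon_id = ex$exon_id[i[-1L]],
                            is_fusion = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(fusions) && nrow(fusions)) {
    for (k in seq_len(nrow(fusions))) {
      id <- fusions$fusion_id[k]
      rows[[id]] <- data.frame(transcript_id = id,
                               sequence = fusions$sequence[k],
                               is_fusion = TRUE, fusion_id = id,
                               stringsAsFactors = FALSE)
      jn[[id]] <- data.frame(offset = fusions$breakpoint_offset[k],
                             donor_exon_id = fusions$donor_exon_id[k],
                             acceptor_exon_id = fusions$acceptor_exon_id[k],
                             is_fusion = TRUE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, junctions = jn)
}

#' @noRd
.mutate <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate strand-specific paired-end reads
#'
#' Fragments are drawn per transcript with Poisson pair counts at the given
#' expectations, insert sizes normal (truncated to the feasible range), the
#' forward mate reading the fragment 5' end in sense orientation and the
#' reverse mate the fragment 3' end reverse-complemented.  Substitution
#' errors are applied i.i.d. per base.  The per-pair truth records, for
#' fusion transcripts, whether each mate spans the breakpoint with at least
#' `anchor_len` bases on both sides (SPAN-capable) and whether the mates
#' fall on opposite sides of it (BRIDGE-capable).
#'
#' @param transcripts output of [simTranscripts()].
#' @param expected_pairs named numeric vector of expected pair counts per
#'   transcript id.
#' @param config a [simConfig()].
#' @param seed RNG seed (default: config seed + 2).
#' @param anchor_len anchor length used for the SPAN-capable flag.
#' @return `list(reads=, truth=)`: `reads` has `read_id`, `seq1`, `seq2`;
#'   `truth` adds `transcript_id`, `start`, `frag_len`, `span_fwd`,
#'   `span_rev`, `bridge`, `donor_exon_id`, `acceptor_exon_id`.
#' @export
simulateReads <- function(transcripts, expected_pairs, config,
                          seed = config$seed + 2L, anchor_len = 10L) {
  set.seed(seed)
  tab <- transcripts$table
  jn <- transcripts$junctions
  rl1 <- config$read_len_fwd; rl2 <- config$read_len_rev
  reads <- list(); truth <- list()
  for (t in seq_len(nrow(tab))) {
    id <- tab$transcript_id[t]
    lam <- expected_pairs[[id]]
    if (is.null(lam) || is.na(lam)) lam <- 0
    n <- rpois(1L, lam)
    txlen <- nchar(tab$sequence[t])
    minfrag <- max(rl1, rl2)
    if (n == 0L || txlen < minfrag) next
    L <- pmin(pmax(round(rnorm(n, config$insert_mean, config$insert_sd)),
                   minfrag), txlen)
    start <- floor(runif(n) * (txlen - L + 1)) + 1L
    s1 <- substr(rep(tab$sequence[t], n), start, start + rl1 - 1L)
    s2 <- .revcomp(substr(rep(tab$sequence[t], n),
                          start + L - rl2, start + L - 1L))
    rid <- sprintf("%s_p%04d", id, seq_len(n))
    span_fwd <- rep(FALSE, n); span_rev <- rep(FALSE, n)
    bridge <- rep(FALSE, n)
    dj <- NA_character_; aj <- NA_character_
    if (tab$is_fusion[t]) {
      o <- jn[[id]]$offset[jn[[id]]$is_fusion][1L]
      dj <- jn[[id]]$donor_exon_id[jn[[id]]$is_fusion][1L]
      aj <- jn[[id]]$acceptor_exon_id[jn[[id]]$is_fusion][1L]
      span_fwd <- (o - start + 1L >= anchor_len) &
        (start + rl1 - 1L - o >= anchor_len)
      rev_start <- start + L - rl2
      span_rev <- (o - rev_start + 1L >= anchor_len) &
        (rev_start + rl2 - 1L - o >= anchor_len)
      bridge <- (start + rl1 - 1L <= o) & (rev_start >= o + 1L)
    }
    reads[[id]] <- data.frame(read_id = rid, seq1 = s1, seq2 = s2,
                              stringsAsFactors = FALSE)
    truth[[id]] <- data.frame(read_id = rid, transcript_id = id,
                              start = start, frag_len = L,
                              span_fwd = span_fwd, span_rev = span_rev,
                              bridge = bridge,
                              donor_exon_id = dj, acceptor_exon_id = aj,
                              stringsAsFactors = FALSE)
  }
  emptyR <- data.frame(read_id = character(0), seq1 = character(0),
                       seq2 = character(0), stringsAsFactors = FALSE)
  rd <- if (length(reads)) do.call(rbind, reads) else emptyR
  # mutate after all fragments are drawn so the error rate perturbs bases
  # without changing which fragments a given seed samples
  rd$seq1 <- .mutate(rd$seq1, config$error_rate)
  rd$seq2 <- .mutate(rd$seq2, config$error_rate)
  list(reads = rd,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(read_id = character(0)))
}

#' Simulate a complete dataset
#'
#' Reference, fusions, transcripts and reads in one call; all randomness
#' flows from the config seed.  Gene transcripts receive log-normal
#' expression weights scaled to `pairs_per_transcript` expected pairs on
#' average; fusion transcripts receive `fusion_pairs_per_transcript`.
#'
#' @param config a [simConfig()].
#' @return list with `model`, `fusions`, `transcripts`, `reads`,
#'   `read_truth`, `truth` (junctions + fusions), `expected_pairs`,
#'   `config`.
#' @export
simulateDataset <- function(config) {
  ref <- simulateReference(config)
  fus <- if (config$n_fusions > 0L)
    simulateFusions(ref$model, config) else NULL
  tx <- simTranscripts(ref$model, fus)
  set.seed(config$seed + 3L)
  isfus <- tx$table$is_fusion
  w <- rlnorm(sum(!isfus), config$expr_meanlog, config$expr_sdlog)
  expected <- setNames(numeric(nrow(tx$table)), tx$table$transcript_id)
  expected[!isfus] <- config$pairs_per_transcript * w / mean(w)
  expected[isfus] <- config$fusion_pairs_per_transcript
  rd <- simulateReads(tx, expected, config)
  list(model = ref$model, fusions = fus, transcripts = tx,
       reads = rd$reads, read_truth = rd$truth,
       truth = list(junctions = ref$truth$junctions, fusions = fus),
       expected_pairs = expected, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes `genome.fa`, `model.gtf`, `reads_1.fq`, `reads_2.fq` and
#' `truth_*.tsv` under `dir` (plain text, uncompressed).
#'
#' @param sim output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimFixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genomeSeq(sim$model),
                              file.path(dir, "genome.fa"))
  exportGeneModelGtf(sim$model, file.path(dir, "model.gtf"))
  writeFastq <- function(ids, seqs, path) {
    q <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), path)
  }
  writeFastq(sim$reads$read_id, sim$reads$seq1,
             file.path(dir, "reads_1.fq"))
  writeFastq(sim$reads$read_id, sim$reads$seq2,
             file.path(dir, "reads_2.fq"))
  utils::write.table(sim$read_truth, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$fusions))
    utils::write.table(sim$fusions[setdiff(names(sim$fusions), "sequence")],
                       file.path(dir, "truth_fusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
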