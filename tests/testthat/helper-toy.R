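# Deterministic toy models and sequence helpers used across the suite.

toyBases <- c("A", "C", "G", "T")

toyRandomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(toyBases, n, replace = TRUE), collapse = "")
}

toyRevcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# Build a GeneModel from a list of genes, each a list with fields
# chrom, strand, and exon_seqs (sequences in transcription orientation).
# Exons are laid out left to right with `intron` bases between them; on the
# minus strand the first transcribed exon is placed rightmost.  Chromosome
# sequences are random with the exon slots overwritten, so exonic sequence
# is exactly as requested.
toyModel <- function(genes, intron = 40L, gap = 60L, seed = 99L) {
  set.seed(seed)
  chroms <- unique(vapply(genes, `[[`, character(1), "chrom"))
  cursor <- setNames(rep(0L, length(chroms)), chroms)  # last used base
  pieces <- setNames(vector("list", length(chroms)), chroms)
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    seqs <- g$exon_seqs                      # transcription order
    placed <- if (g$strand == "-") rev(lapply(seqs, toyRevcomp)) else
      as.list(seqs)                          # genomic left-to-right
    ch <- g$chrom
    start <- cursor[ch] + gap + 1L
    st <- integer(length(placed)); en <- integer(length(placed))
    pos <- start
    for (k in seq_along(placed)) {
      if (pos > start) {
        pieces[[ch]] <- c(pieces[[ch]], toyRandomSeq(intron))
        pos <- pos + intron
      } else {
        pieces[[ch]] <- c(pieces[[ch]], toyRandomSeq(gap))
      }
      st[k] <- pos
      en[k] <- pos + nchar(placed[[k]]) - 1L
      pieces[[ch]] <- c(pieces[[ch]], placed[[k]])
      pos <- en[k] + 1L
    }
    cursor[ch] <- pos - 1L
    rows[[gi]] <- data.frame(chrom = ch, start = st, end = en,
                             strand = g$strand,
                             gene_id = if (is.null(g$gene_id))
                               sprintf("T%02d", gi) else g$gene_id,
                             stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(setNames(
    vapply(chroms, function(ch)
      paste0(paste(pieces[[ch]], collapse = ""), toyRandomSeq(gap)),
      character(1)),
    chroms))
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$gene_id <- tab$gene_id
  GeneModel(gr, genome)
}

# A small fixed two-chromosome model reused by many tests: four genes,
# mixed strands, exon lengths comfortably above the anchor length.
toyFourGeneModel <- function() {
  set.seed(1234)
  toyModel(list(
    list(chrom = "chr1", strand = "+", gene_id = "GA",
         exon_seqs = c(toyRandomSeq(80), toyRandomSeq(70), toyRandomSeq(90))),
    list(chrom = "chr1", strand = "-", gene_id = "GB",
         exon_seqs = c(toyRandomSeq(75), toyRandomSeq(85))),
    list(chrom = "chr2", strand = "+", gene_id = "GC",
         exon_seqs = c(toyRandomSeq(60), toyRandomSeq(65), toyRandomSeq(70))),
    list(chrom = "chr2", strand = "-", gene_id = "GD",
         exon_seqs = c(toyRandomSeq(95), toyRandomSeq(55)))),
    seed = 77L)
}

# Shared cache so expensive simulated-pipeline runs happen once per session.
.toyCache <- new.env(parent = emptyenv())

# Larger simulated run exercising all fusion classes at guaranteed depth.
cachedScaleRun <- function() {
  if (is.null(.toyCache$scale)) {
    cfg <- simConfig(n_genes = 16L, n_fusions = 20L,
                     pairs_per_transcript = 40,
                     fusion_pairs_per_transcript = 300, seed = 11L)
    sim <- simulateDataset(cfg)
    elapsed <- system.time(res <- runPipeline(sim$model, sim$reads))
    .toyCache$scale <- list(sim = sim, res = res,
                            elapsed = elapsed[["elapsed"]])
  }
  .toyCache$scale
}

cachedSmallRun <- function() {
  if (is.null(.toyCache$small)) {
    cfg <- simConfig(n_genes = 8L, n_fusions = 3L,
                     pairs_per_transcript = 40,
                     fusion_pairs_per_transcript = 150, seed = 7L)
    sim <- simulateDataset(cfg)
    res <- runPipeline(sim$model, sim$reads)
    .toyCache$small <- list(sim = sim, res = res)
  }
  .toyCache$small
}
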