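#' Construct a GeneModel from exon ranges and a genome
#'
#' Low-level constructor used by [loadGeneModel()] and the simulator.
#' Overlapping transcripts of a gene are expected to be flattened already:
#' `exons` must contain one range per distinct (start, end) per gene.  Ranks
#' are (re)assigned in transcription order and exon identifiers are set to
#' `gene_id-rank`.
#'
#' @param exons [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @param genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(exons, genome) {
  if (is.null(exons$gene_id))
    stop("exons must carry a 'gene_id' metadata column")
  names(genome) <- sub("\\s.*$", "", names(genome))
  chr <- as.character(GenomicRanges::seqnames(exons))
  unknown <- setdiff(unique(chr), names(genome))
  if (length(unknown))
    stop("annotation references unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  if (length(exons) && any(GenomicRanges::width(exons) < 1L))
    stop("zero-length exon in annotation")

  # transcription-order ranks: ascending start on '+', descending on '-'
  st <- GenomicRanges::start(exons)
  strand <- as.character(GenomicRanges::strand(exons))
  key <- ifelse(strand == "-", -st, st)
  ord <- order(exons$gene_id, key)
  exons <- exons[ord]
  rk <- integer(length(exons))
  for (g in unique(exons$gene_id)) {
    i <- which(exons$gene_id == g)
    rk[i] <- seq_along(i)
  }
  exons$rank <- rk
  exons$exon_id <- paste0(exons$gene_id, "-", exons$rank)

  gsplit <- split(seq_along(exons), exons$gene_id)
  genes <- data.frame(
    gene_id = names(gsplit),
    chrom = vapply(gsplit, function(i)
      as.character(GenomicRanges::seqnames(exons))[i[1]], character(1)),
    strand = vapply(gsplit, function(i)
      as.character(GenomicRanges::strand(exons))[i[1]], character(1)),
    span_start = vapply(gsplit, function(i)
      min(GenomicRanges::start(exons)[i]), numeric(1)),
    span_end = vapply(gsplit, function(i)
      max(GenomicRanges::end(exons)[i]), numeric(1)),
    n_exons = lengths(gsplit),
    exonic_length = vapply(gsplit, function(i)
      sum(GenomicRanges::width(exons)[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  new("GeneModel", exons = exons, genes = genes, genome = genome)
}

#' Load a gene model from annotation and genome files
#'
#' Reads a genome FASTA and a GTF or BED12 annotation and returns a
#' [GeneModel-class].  GTF input uses the `exon` features grouped by
#' `gene_id`; overlapping transcripts of one gene are flattened to the set
#' of distinct (start, end) exons.  BED12 input treats each record as one
#' gene whose blocks are its exons.  Exon ranks follow transcription order
#' (reverse genomic order on the minus strand).
#'
#' @param annotation_path path to a `.gtf`/`.gff` or `.bed` (BED12) file.
#' @param genome_path path to a FASTA file.
#' @return A [GeneModel-class].
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' fa <- file.path(dir, "g.fa")
#' writeLines(c(">chr1", strrep("ACGT", 250)), fa)
#' gtf <- file.path(dir, "m.gtf")
#' writeLines(paste("chr1\tsim\texon", c("\t101\t200", "\t301\t400"),
#'                  '\t.\t+\t.\tgene_id "G1"; transcript_id "G1.1";',
#'                  sep = ""), gtf)
#' loadGeneModel(gtf, fa)
#' @export
loadGeneModel <- function(annotation_path, genome_path) {
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (grepl("\\.bed(\\.gz)?$", annotation_path, ignore.case = TRUE)) {
    rec <- rtracklayer::import(annotation_path, format = "BED")
    if (is.null(rec$blocks))
      stop("BED annotation must be BED12 (with block structure)")
    exl <- rec$blocks  # block ranges relative to record start
    n <- lengths(exl)
    gr <- GenomicRanges::GRanges(
      seqnames = rep(as.character(GenomicRanges::seqnames(rec)), n),
      ranges = IRanges::shift(unlist(exl),
                              rep(GenomicRanges::start(rec) - 1L, n)),
      strand = rep(as.character(GenomicRanges::strand(rec)), n))
    gr$gene_id <- rep(rec$name, n)
  } else {
    rec <- rtracklayer::import(annotation_path, format = "GTF")
    rec <- rec[rec$type == "exon"]
    if (!length(rec)) stop("no exon features in annotation")
    # flatten transcripts: distinct (chrom,start,end,strand) per gene
    key <- paste(rec$gene_id, GenomicRanges::seqnames(rec),
                 GenomicRanges::start(rec), GenomicRanges::end(rec),
                 GenomicRanges::strand(rec))
    rec <- rec[!duplicated(key)]
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rec),
                                 IRanges::ranges(rec),
                                 strand = GenomicRanges::strand(rec))
    gr$gene_id <- rec$gene_id
  }
  GeneModel(gr, genome)
}

#' Exon and transcript sequences in transcription orientation
#'
#' `exonSequence()` returns the genomic slice of each exon, reverse
#' complemented on the minus strand.  `transcriptSequence()` concatenates a
#' gene's exons in rank order (the spliced transcript).
#'
#' @param model a [GeneModel-class].
#' @param exon_id character vector of exon identifiers.
#' @param gene_id a single gene identifier.
#' @return Character vector of sequences.
#' @export
exonSequence <- function(model, exon_id) {
  ex <- model@exons
  i <- match(exon_id, ex$exon_id)
  if (anyNA(i)) stop("unknown exon_id: ",
                     paste(exon_id[is.na(i)], collapse = ", "))
  chr <- as.character(GenomicRanges::seqnames(ex))[i]
  seqs <- vapply(seq_along(i), function(k) {
    s <- Biostrings::subseq(model@genome[[chr[k]]],
                            GenomicRanges::start(ex)[i[k]],
                            GenomicRanges::end(ex)[i[k]])
    as.character(s)
  }, character(1))
  minus <- as.character(GenomicRanges::strand(ex))[i] == "-"
  if (any(minus)) seqs[minus] <- .revcomp(seqs[minus])
  seqs
}

#' @rdname exonSequence
#' @export
transcriptSequence <- function(model, gene_id) {
  ex <- model@exons
  i <- which(ex$gene_id == gene_id)
  if (!length(i)) stop("unknown gene_id: ", gene_id)
  i <- i[order(ex$rank[i])]
  paste(exonSequence(model, ex$exon_id[i]), collapse = "")
}

#' Build the exon-exon junction reference
#'
#' For every gene, every ordered exon pair (rank i, rank j) with i < j yields
#' one junction reference entry: the last `flank_len` bases of the donor
#' exon followed by the first `flank_len` bases of the acceptor exon
#' (truncated when an exon is shorter).  Adjacent pairs (j = i + 1) are the
#' annotated ("known") junctions; skipping pairs are "putative" exon
#' skips.  A gene with n exons contributes n(n-1)/2 entries.
#'
#' @param model a [GeneModel-class].
#' @param flank_len bases taken from each side of the junction.  A natural
#'   choice is `read_length - anchor_len`, so a read spanning the junction
#'   with at least one anchor length on the short side is fully contained.
#' @param max_rank_gap optional cap on `j - i` to bound the quadratic
#'   enumeration on genes with very many exons (`Inf` = no cap).
#' @return `data.frame` with columns `name`, `gene_id`, `donor_exon_id`,
#'   `acceptor_exon_id`, `class` (`known`/`putative`), `donor_flank`,
#'   `acceptor_flank`, `sequence`.
#' @export
buildJunctionReference <- function(model, flank_len = 40L,
                                   max_rank_gap = Inf) {
  stopifnot(flank_len >= 1L)
  ex <- model@exons
  out <- list()
  for (g in model@genes$gene_id) {
    i <- which(ex$gene_id == g)
    i <- i[order(ex$rank[i])]
    n <- length(i)
    if (n < 2L) next
    seqs <- exonSequence(model, ex$exon_id[i])
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- pairs[pairs[, 2] - pairs[, 1] <= max_rank_gap, , drop = FALSE]
    di <- pairs[, 1]; ai <- pairs[, 2]
    dseq <- substr(seqs[di], pmax(1L, nchar(seqs[di]) - flank_len + 1L),
                   nchar(seqs[di]))
    aseq <- substr(seqs[ai], 1L, pmin(nchar(seqs[ai]), flank_len))
    out[[g]] <- data.frame(
      name = paste0(ex$exon_id[i][di], "|", ex$exon_id[i][ai]),
      gene_id = g,
      donor_exon_id = ex$exon_id[i][di],
      acceptor_exon_id = ex$exon_id[i][ai],
      class = ifelse(ai - di == 1L, "known", "putative"),
      donor_flank = nchar(dseq),
      acceptor_flank = nchar(aseq),
      sequence = paste0(dseq, aseq),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(name = character(0), gene_id = character(0),
                      donor_exon_id = character(0),
                      acceptor_exon_id = character(0), class = character(0),
                      donor_flank = integer(0), acceptor_flank = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$name), , drop = FALSE]
}

#' Load or construct the filter reference
#'
#' The filter reference holds sequences whose confident hits disqualify a
#' read (homopolymers, rRNA/tRNA, repeats, adaptors, ...).
#' `loadFilterReference()` reads them from FASTA; an empty file yields a
#' warning and an empty set (the pipeline then proceeds without filtering).
#' `defaultFilterSet()` returns the built-in minimal set: the four
#' homopolymers at a configurable length.
#'
#' @param filter_path path to a FASTA file.
#' @param length homopolymer length for the default set.
#' @return A [Biostrings::DNAStringSet].
#' @export
loadFilterReference <- function(filter_path) {
  res <- tryCatch(Biostrings::readDNAStringSet(filter_path),
                  error = function(e) NULL)
  if (is.null(res) || length(res) == 0L) {
    warning("empty filter reference; proceeding without filtering")
    return(Biostrings::DNAStringSet())
  }
  res
}

#' @rdname loadFilterReference
#' @export
defaultFilterSet <- function(length = 50L) {
  s <- vapply(.BASES, function(b) strrep(b, length), character(1))
  Biostrings::DNAStringSet(setNames(s, paste0("poly", .BASES)))
}

#' Export a GeneModel
#'
#' `exportGeneModelBed()` writes one BED12 record per gene (blocks =
#' exons); `exportGeneModelGtf()` writes GTF exon features with one
#' transcript per gene.  Both round-trip through [loadGeneModel()].
#'
#' @param model a [GeneModel-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
exportGeneModelBed <- function(model, path) {
  ex <- model@exons
  gt <- model@genes
  recs <- GenomicRanges::GRanges(
    gt$chrom, IRanges::IRanges(gt$span_start, gt$span_end),
    strand = gt$strand)
  recs$name <- gt$gene_id
  blocks <- lapply(seq_len(nrow(gt)), function(k) {
    i <- which(ex$gene_id == gt$gene_id[k])
    i <- i[order(GenomicRanges::start(ex)[i])]
    IRanges::IRanges(GenomicRanges::start(ex)[i] - gt$span_start[k] + 1L,
                     GenomicRanges::end(ex)[i] - gt$span_start[k] + 1L)
  })
  recs$blocks <- IRanges::IRangesList(blocks)
  rtracklayer::export(recs, path, format = "BED")
  invisible(path)
}

#' @rdname exportGeneModelBed
#' @export
exportGeneModelGtf <- function(model, path) {
  ex <- model@exons
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(ex),
                               IRanges::ranges(ex),
                               strand = GenomicRanges::strand(ex))
  gr$source <- "sasrfuse"
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- paste0(ex$gene_id, ".1")
  gr$exon_number <- ex$rank
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}
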