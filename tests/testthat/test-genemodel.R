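test_that("GeneModel assigns transcription-order ranks and identifiers", {
  model <- toyFourGeneModel()
  ex <- exonRanges(model)
  gt <- geneTable(model)

  expect_setequal(gt$gene_id, c("GA", "GB", "GC", "GD"))
  expect_equal(gt$n_exons[match(c("GA", "GB", "GC", "GD"), gt$gene_id)],
               c(3L, 2L, 3L, 2L))
  expect_false(anyDuplicated(ex$exon_id) > 0)
  # plus strand: rank increases with genomic start
  ga <- ex[ex$gene_id == "GA"]
  expect_equal(order(GenomicRanges::start(ga)), order(ga$rank))
  # minus strand: rank decreases with genomic start
  gb <- ex[ex$gene_id == "GB"]
  expect_equal(order(GenomicRanges::start(gb)), rev(order(gb$rank)))
  expect_equal(ex$exon_id, paste0(ex$gene_id, "-", ex$rank))
})

test_that("GeneModel rejects inconsistent input", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  gr <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10),
                               strand = "+")
  gr$gene_id <- "G1"
  expect_error(GeneModel(gr, genome), "unknown chromosome")
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 9),
                                strand = "+")   # width zero
  gr2$gene_id <- "G1"
  expect_error(GeneModel(gr2, genome), "zero-length exon")
  gr3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10),
                                strand = "+")
  expect_error(GeneModel(gr3, genome), "gene_id")
})

test_that("exonSequence reverse-complements minus-strand exons", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTTTTGGGCCCAAAA"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3, 13), c(8, 16)),
                               strand = "-")
  gr$gene_id <- "G1"
  model <- GeneModel(gr, genome)
  # transcription order on '-' begins with the rightmost exon;
  # bases 13-16 are "GCCC", bases 3-8 are "AACGTT"
  expect_equal(exonSequence(model, "G1-1"), toyRevcomp("GCCC"))
  expect_equal(exonSequence(model, "G1-2"), toyRevcomp("AACGTT"))
  expect_equal(transcriptSequence(model, "G1"),
               paste0(toyRevcomp("GCCC"), toyRevcomp("AACGTT")))
  expect_error(exonSequence(model, "nope"), "unknown exon_id")
})

test_that("GTF and BED exports round-trip through loadGeneModel", {
  model <- toyFourGeneModel()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(genomeSeq(model), fa)

  gtf <- file.path(dir, "m.gtf")
  exportGeneModelGtf(model, gtf)
  m2 <- loadGeneModel(gtf, fa)
  expect_equal(geneTable(m2), geneTable(model))
  expect_equal(as.data.frame(exonRanges(m2)), as.data.frame(exonRanges(model)))

  bed <- file.path(dir, "m.bed")
  exportGeneModelBed(model, bed)
  m3 <- loadGeneModel(bed, fa)
  expect_equal(geneTable(m3), geneTable(model))
})

test_that("GTF loading flattens overlapping transcripts per gene", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 250)), fa)
  gtf <- file.path(dir, "m.gtf")
  attr1 <- 'gene_id "G1"; transcript_id "G1.1";'
  attr2 <- 'gene_id "G1"; transcript_id "G1.2";'
  writeLines(c(
    paste("chr1", "t", "exon", 101, 200, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "t", "exon", 301, 400, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "t", "exon", 101, 200, ".", "+", ".", attr2, sep = "\t"),
    paste("chr1", "t", "exon", 501, 600, ".", "+", ".", attr2, sep = "\t")),
    gtf)
  model <- loadGeneModel(gtf, fa)
  expect_equal(geneTable(model)$n_exons, 3L)
  expect_equal(exonRanges(model)$rank, 1:3)
})

test_that("junction reference enumerates ordered exon pairs with flanks", {
  model <- toyFourGeneModel()
  jref <- buildJunctionReference(model, flank_len = 20L)
  gt <- geneTable(model)
  expect_equal(nrow(jref),
               sum(gt$n_exons * (gt$n_exons - 1) / 2))
  ga <- jref[jref$gene_id == "GA", ]
  expect_setequal(ga$class[paste(ga$donor_exon_id, ga$acceptor_exon_id) %in%
                             c("GA-1 GA-2", "GA-2 GA-3")], "known")
  expect_equal(ga$class[ga$donor_exon_id == "GA-1" &
                          ga$acceptor_exon_id == "GA-3"], "putative")
  # entry sequence = donor 3' flank + acceptor 5' flank
  e12 <- ga[ga$name == "GA-1|GA-2", ]
  dseq <- exonSequence(model, "GA-1")
  aseq <- exonSequence(model, "GA-2")
  expect_equal(e12$sequence,
               paste0(substr(dseq, nchar(dseq) - 19L, nchar(dseq)),
                      substr(aseq, 1L, 20L)))
  # flanks truncate at short exons
  jshort <- buildJunctionReference(model, flank_len = 500L)
  expect_true(all(jshort$donor_flank <= 95L))
})

test_that("filter reference loading degrades gracefully", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.fa")
  file.create(empty)
  expect_warning(fs <- loadFilterReference(empty), "empty filter")
  expect_length(fs, 0L)
  expect_length(defaultFilterSet(30L), 4L)
  expect_equal(unname(nchar(as.character(defaultFilterSet(30L)))),
               rep(30L, 4))
})
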