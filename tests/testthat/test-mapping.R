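test_that("reference sets keep names and block cross-entry matches", {
  rs <- referenceSet(setNames(c(strrep("ACGT", 10), strrep("GGCA", 10)),
                              c("e1", "e2")), "exon")
  expect_equal(rs$names, c("e1", "e2"))
  expect_equal(rs$offsets, c(e1 = 1L, e2 = 66L))   # 40 + 25-N spacer
  # a probe overlapping the spacer never matches
  probe <- paste0(strrep("ACGT", 5), strrep("N", 5))
  expect_equal(nrow(mapReadSimple(rs, probe)), 0L)
})

test_that("simple mapping finds exact and near matches on both strands", {
  model <- toyFourGeneModel()
  rs <- referenceSet(genomeSeq(model), "genome")
  chr1 <- as.character(genomeSeq(model)[["chr1"]])
  read <- substr(chr1, 101, 140)
  a <- mapReadSimple(rs, read)
  expect_true(any(a$refname == "chr1" & a$pos == 101L & a$strand == "+"))
  # reverse-complemented read maps at the same locus on the minus strand
  b <- mapReadSimple(rs, toyRevcomp(read))
  expect_true(any(b$refname == "chr1" & b$pos == 101L & b$strand == "-"))
  # two mismatches pass the genome budget, three do not
  flip <- function(s, i) {
    substr(s, i, i) <- setdiff(toyBases, substr(s, i, i))[1]
    s
  }
  r2 <- flip(flip(read, 5), 15)
  expect_true(any(mapReadSimple(rs, r2)$pos == 101L))
  r3 <- flip(r2, 25)
  expect_false(any(mapReadSimple(rs, r3)$pos == 101L))
  expect_true(any(mapReadSimple(rs, r3, max_mismatches = 3L)$pos == 101L))
})

test_that("batch exact mapping agrees with the per-read mapper", {
  model <- toyFourGeneModel()
  rs <- referenceSet(genomeSeq(model), "genome")
  chr2 <- as.character(genomeSeq(model)[["chr2"]])
  reads <- c(r1 = substr(chr2, 61, 100),
             r2 = toyRevcomp(substr(chr2, 151, 190)),
             r3 = toyRandomSeq(40, seed = 3))
  batch <- sasrfuse:::.mapReadsExact(rs, unname(reads), names(reads), 1L)
  for (id in names(reads)) {
    single <- mapReadSimple(rs, reads[[id]], id, 1L, max_mismatches = 0L)
    got <- batch[batch$read_id == id, ]
    rownames(got) <- rownames(single) <- NULL
    got <- got[order(got$pos, got$strand), ]
    single <- single[order(single$pos, single$strand), ]
    rownames(got) <- rownames(single) <- NULL
    expect_equal(got, single)
  }
})

test_that("filter subtraction removes all alignments of filtered mates", {
  aln <- data.frame(read_id = c("a", "a", "b"), mate = c(1L, 1L, 1L),
                    refname = "x", pos = 1L, strand = "+", matches = 25L,
                    mismatches = 0L, score = 25L,
                    reference_class = "genome", stringsAsFactors = FALSE)
  fh <- data.frame(read_id = "a", mate = 1L, refname = "polyA", pos = 1L,
                   strand = "+", matches = 25L, mismatches = 0L,
                   score = 25L, reference_class = "filter",
                   stringsAsFactors = FALSE)
  out <- subtractFiltered(aln, fh)
  expect_equal(out$read_id, "b")
  # low-scoring filter hits are ignored; empty filter set is the identity
  fh$score <- 10L
  expect_equal(nrow(subtractFiltered(aln, fh)), 3L)
  expect_equal(subtractFiltered(aln, fh[0, ]), aln)
})

test_that("mate rescue searches downstream exons of the anchored gene", {
  model <- toyFourGeneModel()
  gt <- geneTable(model)
  ga <- gt[gt$gene_id == "GA", ]
  e3 <- exonSequence(model, "GA-3")
  read <- substr(e3, 11, 35)
  anchor1 <- exonRanges(model)[exonRanges(model)$exon_id == "GA-1"]
  resc <- rescueMate(model, "chr1", GenomicRanges::start(anchor1),
                     GenomicRanges::end(anchor1), read, "r1", 2L)
  expect_equal(resc$refname, "GA-3")
  expect_equal(resc$pos, 11L)
  expect_equal(resc$reference_class, "rescue")
  # up to six mismatches are tolerated
  flip <- function(s, i) {
    substr(s, i, i) <- setdiff(toyBases, substr(s, i, i))[1]
    s
  }
  r6 <- read
  for (i in c(2, 5, 8, 12, 15, 18)) r6 <- flip(r6, i)
  expect_equal(rescueMate(model, "chr1", GenomicRanges::start(anchor1),
                          GenomicRanges::end(anchor1), r6, "r", 2L)$refname,
               "GA-3")
  r7 <- flip(r6, 21)
  expect_null(rescueMate(model, "chr1", GenomicRanges::start(anchor1),
                         GenomicRanges::end(anchor1), r7, "r", 2L))
  # an anchor outside any gene cannot rescue
  expect_null(rescueMate(model, "chr1", 1, 5, read, "r", 2L))
})

test_that("pairing assigns confident PQV to unique placements", {
  model <- toyFourGeneModel()
  # concordant pair within GA: mate 1 in exon 1, mate 2 in exon 2,
  # transcript-space insert 150 despite the intervening intron
  tx <- transcriptSequence(model, "GA")
  frag <- substr(tx, 1, 150)
  ers <- referenceSet(setNames(exonSequence(model, exonRanges(model)$exon_id),
                               exonRanges(model)$exon_id), "exon")
  aln <- rbind(mapReadSimple(ers, substr(frag, 1, 40), "p1", 1L),
               mapReadSimple(ers, toyRevcomp(substr(frag, 126, 150)),
                             "p1", 2L))
  paired <- pairAndScore(aln, model)
  prim <- paired[paired$primary, ]
  expect_equal(nrow(prim), 1L)
  expect_true(prim$concordant)
  expect_equal(prim$insert, 150)
  expect_equal(prim$pqv, 40L)
  expect_equal(prim$gene_id_1, "GA")
})

test_that("ambiguous placements split the posterior and kill confidence", {
  # two genes with byte-identical exon sequences: every pair has two
  # equally good concordant placements
  set.seed(8)
  e1 <- toyRandomSeq(80); e2 <- toyRandomSeq(80)
  model <- toyModel(list(
    list(chrom = "chr1", strand = "+", gene_id = "R1",
         exon_seqs = c(e1, e2)),
    list(chrom = "chr2", strand = "+", gene_id = "R2",
         exon_seqs = c(e1, e2))),
    seed = 66L)
  ers <- referenceSet(setNames(exonSequence(model, exonRanges(model)$exon_id),
                               exonRanges(model)$exon_id), "exon")
  tx <- paste0(e1, e2)
  aln <- rbind(mapReadSimple(ers, substr(tx, 1, 30), "q", 1L),
               mapReadSimple(ers, toyRevcomp(substr(tx, 121, 150)), "q", 2L))
  paired <- pairAndScore(aln, model)
  expect_true(all(paired$pqv <= 10))
  expect_equal(sum(paired$primary), 1L)
})

test_that("discordant unique pairs stay confident (fusion bridges)", {
  model <- toyFourGeneModel()
  e_a <- exonSequence(model, "GA-1")
  e_c <- exonSequence(model, "GC-1")
  ers <- referenceSet(setNames(exonSequence(model, exonRanges(model)$exon_id),
                               exonRanges(model)$exon_id), "exon")
  aln <- rbind(mapReadSimple(ers, substr(e_a, 1, 40), "b1", 1L),
               mapReadSimple(ers, toyRevcomp(substr(e_c, 11, 35)), "b1", 2L))
  paired <- pairAndScore(aln, model)
  prim <- paired[paired$primary, ]
  expect_false(prim$concordant)
  expect_equal(prim$pqv, 40L)
  expect_equal(c(prim$gene_id_1, prim$gene_id_2), c("GA", "GC"))
})

test_that("RPKM follows the confident-pair formula", {
  model <- toyFourGeneModel()
  paired <- data.frame(read_id = c("a", "b", "c"),
                       gene_id_1 = c("GA", "GA", "GB"),
                       pqv = c(40L, 40L, 5L), primary = TRUE,
                       stringsAsFactors = FALSE)
  rpkm <- computeRpkm(model, paired)
  gt <- geneTable(model)
  len_ga <- gt$exonic_length[gt$gene_id == "GA"]
  expect_equal(rpkm[["GA"]], 2 * 1e9 / (2 * len_ga))
  expect_equal(rpkm[["GB"]], 0)   # below the confidence threshold
  expect_equal(rpkm[["GC"]], 0)
})
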