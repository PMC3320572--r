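simTestConfig <- function(...) {
  defaults <- list(n_chroms = 2L, chrom_length = 20000L, n_genes = 6L,
                   n_fusions = 2L, pairs_per_transcript = 10,
                   fusion_pairs_per_transcript = 25, seed = 5L)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

test_that("a configuration reproduces its dataset byte for byte", {
  cfg <- simTestConfig()
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$read_truth, b$read_truth)
  expect_identical(a$fusions, b$fusions)
  expect_identical(as.data.frame(exonRanges(a$model)),
                   as.data.frame(exonRanges(b$model)))
  # a different seed changes the data
  c2 <- simulateDataset(simTestConfig(seed = 6L))
  expect_false(identical(a$reads, c2$reads))
})

test_that("fusion transcripts splice donor prefix to acceptor suffix", {
  cfg <- simTestConfig()
  sim <- simulateDataset(cfg)
  ex <- exonRanges(sim$model)
  for (k in seq_len(nrow(sim$fusions))) {
    f <- sim$fusions[k, ]
    dr <- ex$rank[ex$exon_id == f$donor_exon_id]
    ar <- ex$rank[ex$exon_id == f$acceptor_exon_id]
    n5 <- sum(ex$gene_id == f$gene5)
    n3 <- sum(ex$gene_id == f$gene3)
    expect_lt(dr, n5)      # an intron must follow the fused 5' exon
    expect_gte(ar, 2L)     # the 3' partner loses at least its first exon
    # 5' side: exons 1..dr of gene5 in transcription order
    want5 <- paste(vapply(seq_len(dr), function(r)
      exonSequence(sim$model, paste0(f$gene5, "-", r)), character(1)),
      collapse = "")
    expect_equal(substr(f$sequence, 1, f$breakpoint_offset), want5)
    # 3' side: exons ar..n3 of gene3
    want3 <- paste(vapply(ar:n3, function(r)
      exonSequence(sim$model, paste0(f$gene3, "-", r)), character(1)),
      collapse = "")
    expect_equal(substr(f$sequence, f$breakpoint_offset + 1,
                        nchar(f$sequence)), want3)
    # class label matches the partner geometry
    geom <- classifyFusion(f$donor_exon_id, f$acceptor_exon_id, sim$model)
    expect_equal(f$class,
                 c("inter-chromosomal" = "inter_chromosomal",
                   "inverted" = "inverted",
                   "same-strand" = "same_strand")[[geom$classification]])
  }
  expect_false(anyDuplicated(paste(sim$fusions$gene5,
                                   sim$fusions$gene3)) > 0)
})

test_that("reads are cut from transcripts with faithful truth flags", {
  cfg <- simTestConfig()
  sim <- simulateDataset(cfg)
  tx <- setNames(sim$transcripts$table$sequence,
                 sim$transcripts$table$transcript_id)
  tr <- sim$read_truth
  rd <- sim$reads
  expect_equal(rd$read_id, tr$read_id)
  expect_true(all(nchar(rd$seq1) == cfg$read_len_fwd))
  expect_true(all(nchar(rd$seq2) == cfg$read_len_rev))
  # error-free reads are exact substrings (mate 2 reverse-complemented)
  idx <- sample(nrow(rd), min(30L, nrow(rd)))
  for (i in idx) {
    s <- tx[[tr$transcript_id[i]]]
    expect_equal(rd$seq1[i],
                 substr(s, tr$start[i], tr$start[i] + cfg$read_len_fwd - 1))
    re <- tr$start[i] + tr$frag_len[i] - 1
    expect_equal(rd$seq2[i],
                 toyRevcomp(substr(s, re - cfg$read_len_rev + 1, re)))
  }
  # span/bridge flags recomputed from the fragment geometry
  fus <- tr[grepl("^F", tr$transcript_id), ]
  expect_gt(nrow(fus), 0L)
  off <- setNames(sim$fusions$breakpoint_offset, sim$fusions$fusion_id)
  o <- off[fus$transcript_id]
  e1 <- fus$start + cfg$read_len_fwd - 1
  r0 <- fus$start + fus$frag_len - cfg$read_len_rev
  expect_equal(fus$span_fwd,
               unname(o - fus$start + 1 >= 10 & e1 - o >= 10))
  expect_equal(fus$bridge, unname(e1 <= o & r0 >= o + 1))
  # bridging pairs by construction cannot also span
  expect_false(any(fus$bridge & (fus$span_fwd | fus$span_rev)))
  # non-fusion reads never carry junction flags
  gen <- tr[!grepl("^F", tr$transcript_id), ]
  expect_false(any(gen$span_fwd | gen$span_rev | gen$bridge))
})

test_that("the first-exon mode fuses every 5' gene after exon 1", {
  sim <- simulateDataset(simTestConfig(fusion_five_prime_rank = "first"))
  ex <- exonRanges(sim$model)
  expect_true(all(ex$rank[match(sim$fusions$donor_exon_id,
                                ex$exon_id)] == 1L))
})

test_that("substitution errors perturb reads at roughly the set rate", {
  cfg0 <- simTestConfig()
  cfg1 <- simTestConfig(error_rate = 0.05)
  clean <- simulateDataset(cfg0)$reads
  noisy <- simulateDataset(cfg1)$reads
  expect_equal(clean$read_id, noisy$read_id)
  ham <- function(a, b) {
    mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
           a, b, USE.NAMES = FALSE)
  }
  d <- ham(clean$seq1, noisy$seq1)
  rate <- sum(d) / sum(nchar(clean$seq1))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("fixtures round-trip through the standard-format loaders", {
  sim <- simulateDataset(simTestConfig())
  dir <- withr::local_tempdir()
  writeSimFixture(sim, dir)
  for (f in c("genome.fa", "model.gtf", "reads_1.fq", "reads_2.fq",
              "truth_reads.tsv", "truth_fusions.tsv"))
    expect_true(file.exists(file.path(dir, f)))
  m2 <- loadGeneModel(file.path(dir, "model.gtf"),
                      file.path(dir, "genome.fa"))
  expect_equal(geneTable(m2), geneTable(sim$model))
  r1 <- readFastq(file.path(dir, "reads_1.fq"))
  expect_equal(unname(as.character(r1)), sim$reads$seq1)
  expect_equal(names(r1), sim$reads$read_id)
})
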