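# Minimal primary-pairing rows carrying just the columns the evidence
# accumulator consumes.
mkPair <- function(read_id, e1, e2, pqv = 40, gstart = 1,
                   amb1 = FALSE, amb2 = FALSE) {
  data.frame(read_id = read_id, exon_id_1 = e1, exon_id_2 = e2,
             pqv = pqv, primary = TRUE, ambiguous_1 = amb1,
             ambiguous_2 = amb2, gstart_1 = gstart,
             stringsAsFactors = FALSE)
}

mkSpan <- function(read_id, d, a, prefix = 12L, clip = 0L) {
  data.frame(read_id = read_id, donor_exon_id = d, acceptor_exon_id = a,
             prefix_len = prefix, suffix_len = 12L, clipped_left = clip,
             clipped_right = 0L, mismatches = 0L, stringsAsFactors = FALSE)
}

test_that("evidence accumulation builds SPAN and BRIDGE edges", {
  model <- toyFourGeneModel()
  span <- mkSpan("s1", "GA-2", "GC-1", prefix = 12L, clip = 3L)
  paired <- rbind(
    mkPair("b1", "GA-1", "GC-2", pqv = 20, gstart = 100),
    mkPair("b2", "GA-1", "GC-2", pqv = 10, gstart = 200),   # at threshold
    mkPair("b3", "GA-1", "GC-2", pqv = 11, gstart = 300),   # just above
    mkPair("b4", "GA-1", "GC-2", pqv = 40, gstart = 400, amb1 = TRUE),
    mkPair("b5", "GA-1", "GA-1", pqv = 40, gstart = 500))   # self pair
  g <- accumulateEvidence(span_hits = span, paired = paired, model = model)
  e <- g@edges
  expect_equal(sum(e$kind == "SPAN"), 1L)
  expect_equal(e$start_point[e$kind == "SPAN"], 15)  # prefix + left clip
  # pqv 10 is excluded (strict >), 11 included; ambiguous and self excluded
  expect_setequal(e$read_id[e$kind == "BRIDGE"], c("b1", "b3"))
})

test_that("bridge counting honors transcription-order compatibility", {
  model <- toyFourGeneModel()
  span <- mkSpan("s1", "GA-2", "GC-1")
  paired <- rbind(
    mkPair("b1", "GA-1", "GC-2", gstart = 100),  # upstream donor: compatible
    mkPair("b2", "GA-3", "GC-1", gstart = 200))  # downstream donor: not
  g <- accumulateEvidence(span_hits = span, paired = paired, model = model)
  cand <- g@candidates
  c21 <- cand[cand$donor_exon_id == "GA-2" & cand$acceptor_exon_id == "GC-1", ]
  expect_equal(c21$span_unique, 1L)
  expect_equal(c21$bridge_count, 1L)
  expect_equal(c21$bridge_unique, 1L)
  # the pure-bridge candidates exist but carry no SPAN evidence
  c31 <- cand[cand$donor_exon_id == "GA-3" & cand$acceptor_exon_id == "GC-1", ]
  expect_equal(c31$span_unique, 0L)
  expect_equal(c31$bridge_count, 2L)  # both bridges compatible here
})

test_that("unique start counting collapses PCR duplicates", {
  edges <- data.frame(
    kind = c("SPAN", "SPAN", "SPAN", "BRIDGE", "BRIDGE"),
    start_point = c(5, 5, 9, 100, 100), stringsAsFactors = FALSE)
  u <- countUniqueStarts(edges)
  expect_equal(u[["span_unique"]], 2L)
  expect_equal(u[["bridge_unique"]], 1L)
})

test_that("JCV matches the worked example and behaves monotonically", {
  # two near-certain bridges, lambda = 1e-4 * 100 * 100 / 1e3 = 1e-3
  expect_equal(computeJcv(c(40, 40), 100, 100, 1e3), 63L)
  expect_equal(computeJcv(numeric(0), 100, 100, 1e3), 0L)
  expect_equal(computeJcv(c(40, 40), 100, 100, 0), 0L)
  # more bridges -> more confidence
  j <- vapply(1:6, function(k) computeJcv(rep(40, k), 100, 100, 1e4),
              integer(1))
  expect_true(all(diff(j) >= 0))
  expect_equal(j[5], 100L)  # five strong bridges at low expression saturate
  # higher expression inflates the null and deflates the score
  expect_lt(computeJcv(c(40, 40), 2000, 2000, 1e4),
            computeJcv(c(40, 40), 100, 100, 1e4))
  # weaker placement confidence reduces effective evidence
  expect_lt(computeJcv(c(3, 3), 100, 100, 1e3),
            computeJcv(c(40, 40), 100, 100, 1e3))
})

test_that("scoreJcv fills candidates, using compatibility when modeled", {
  model <- toyFourGeneModel()
  span <- mkSpan("s1", "GA-2", "GC-1")
  paired <- mkPair("b1", "GA-1", "GC-2", gstart = 100)
  g <- accumulateEvidence(span_hits = span, paired = paired, model = model)
  counts <- c("GA-2" = 50, "GC-1" = 50, "GA-1" = 50, "GC-2" = 50)
  # exact-pair scoring sees no bridge on the SPAN candidate
  s0 <- scoreJcv(g, counts, total_pairs = 1e3)
  c0 <- s0@candidates
  expect_equal(c0$jcv[c0$donor_exon_id == "GA-2"], 0L)
  # compatibility-based scoring credits the upstream bridge
  s1 <- scoreJcv(g, counts, total_pairs = 1e3, model = model)
  c1 <- s1@candidates
  expect_gt(c1$jcv[c1$donor_exon_id == "GA-2"], 0L)
  expect_true(all(!is.na(c1$jcv)))
})

test_that("calling applies per-class unique-evidence thresholds", {
  model <- toyFourGeneModel()
  span <- rbind(
    mkSpan("j1", "GA-1", "GA-2", prefix = 12L),
    mkSpan("j2", "GA-1", "GA-3", prefix = 14L),
    mkSpan("f1", "GB-1", "GD-1", prefix = 11L),
    mkSpan("f2", "GB-1", "GD-1", prefix = 16L),
    mkSpan("f3", "GA-1", "GC-1", prefix = 13L))
  paired <- rbind(
    mkPair("p1", "GA-1", "GA-2", gstart = 10),
    mkPair("p2", "GA-1", "GA-3", gstart = 20),
    mkPair("p3", "GB-1", "GD-1", gstart = 30),
    mkPair("p4", "GB-1", "GD-1", gstart = 40),
    mkPair("p5", "GA-1", "GC-1", gstart = 50))
  g <- accumulateEvidence(span_hits = span, paired = paired, model = model)
  calls <- callJunctions(g, model)
  # both same-gene junctions pass 1+1 and share a donor -> alternative splice
  expect_equal(nrow(calls$junctions), 2L)
  expect_true(all(calls$junctions$alt_splice))
  # only the 2-SPAN/2-BRIDGE inter-gene candidate is a fusion at defaults
  expect_equal(nrow(calls$fusions), 1L)
  expect_equal(calls$fusions$donor_exon_id, "GB-1")
  expect_equal(calls$fusions$classification, "inter-chromosomal")
  # relaxed thresholds admit the singleton candidate too (nesting)
  relaxed <- callJunctions(g, model, fusion_min = c(1L, 1L))
  expect_gt(nrow(relaxed$fusions), 1L)
  expect_true(all(paste(calls$fusions$donor_exon_id,
                        calls$fusions$acceptor_exon_id) %in%
                    paste(relaxed$fusions$donor_exon_id,
                          relaxed$fusions$acceptor_exon_id)))
  # an impossible JCV floor removes everything
  scored <- scoreJcv(g, c("GB-1" = 10, "GD-1" = 10), 1e3, model = model)
  none <- callJunctions(scored, model, jcv_min = 101L)
  expect_equal(nrow(none$fusions), 0L)
  expect_equal(nrow(none$junctions), 0L)
})

test_that("fusion classification covers the three geometric classes", {
  model <- toyFourGeneModel()
  cls <- classifyFusion(c("GA-1", "GA-1"), c("GC-1", "GB-1"), model)
  expect_equal(cls$classification, c("inter-chromosomal", "inverted"))
  expect_true(all(is.na(cls$signed_distance)))
  expect_true(all(is.na(cls$in_frame)))
  expect_error(classifyFusion("GA-9", "GC-1", model), "unknown exon")

  # same-strand distances: plus-strand genes laid left to right
  set.seed(31)
  plus <- toyModel(list(
    list(chrom = "chr1", strand = "+", gene_id = "S1",
         exon_seqs = c(toyRandomSeq(60), toyRandomSeq(60))),
    list(chrom = "chr1", strand = "+", gene_id = "S2",
         exon_seqs = c(toyRandomSeq(60), toyRandomSeq(60)))),
    seed = 12L)
  fwd <- classifyFusion("S1-2", "S2-1", plus)
  expect_equal(fwd$classification, "same-strand")
  expect_gt(fwd$signed_distance, 0)
  expect_lt(classifyFusion("S2-1", "S1-2", plus)$signed_distance, 0)

  # on the minus strand the sign flips with transcription direction:
  # the gene laid further right is transcriptionally upstream
  minus <- toyModel(list(
    list(chrom = "chr1", strand = "-", gene_id = "M1",
         exon_seqs = c(toyRandomSeq(60), toyRandomSeq(60))),
    list(chrom = "chr1", strand = "-", gene_id = "M2",
         exon_seqs = c(toyRandomSeq(60), toyRandomSeq(60)))),
    seed = 13L)
  rev_call <- classifyFusion("M1-2", "M2-1", minus)
  expect_equal(rev_call$classification, "same-strand")
  expect_lt(rev_call$signed_distance, 0)
  expect_gt(classifyFusion("M2-2", "M1-1", minus)$signed_distance, 0)
})
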