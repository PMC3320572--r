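# End-to-end orchestration: references -> map -> filter-subtract -> rescue
# -> pair -> spliced-read search on admitted reads -> evidence -> calls.

# Map one mate group against the non-filter reference sets: batch
# exact-match first, then per-read approximate fallback (class mismatch
# budgets) only for reads with no exact hit anywhere.
#' @noRd
.mapMateGroup <- function(refsets, sequences, read_ids, mate) {
  aln <- list()
  for (rs in refsets) {
    a <- .mapReadsExact(rs, sequences, read_ids, mate)
    if (nrow(a)) aln[[length(aln) + 1L]] <- a
  }
  hit <- if (length(aln))
    read_ids %in% unlist(lapply(aln, `[[`, "read_id")) else
      rep(FALSE, length(read_ids))
  for (r in which(!hit)) {
    for (rs in refsets) {
      a <- mapReadSimple(rs, sequences[r], read_ids[r], mate)
      if (nrow(a)) aln[[length(aln) + 1L]] <- a
    }
  }
  if (!length(aln)) return(.emptyAlignmentFrame())
  out <- do.call(rbind, aln)
  rownames(out) <- NULL
  out
}

#' Run the full fusion-discovery pipeline
#'
#' Executes the stages in order: reference construction (genome, exon-exon
#' junction, exon, filter), read mapping (batch exact plus approximate
#' fallback within the class mismatch budgets), filter subtraction, mate
#' rescue, pairing with pairing quality values, the suffix-array spliced
#' read search on admitted reads, evidence accumulation, junction confidence
#' scoring, and junction/fusion calling at the unique-evidence thresholds.
#'
#' Defaults reproduce the reference operating point: decamer anchors, at
#' most 2 extension mismatches, at most 10 clipped bases, PQV > 10
#' confidence, 1-SPAN-1-BRIDGE same-gene junction calls and 2-SPAN-2-BRIDGE
#' fusion calls.
#'
#' @param model a [GeneModel-class].
#' @param reads `data.frame` with `read_id`, `seq1` (forward mate), `seq2`
#'   (reverse mate, reverse-complement orientation).
#' @param filter_seqs filter reference ([Biostrings::DNAStringSet]; default
#'   homopolymers); zero length disables filtering.
#' @param anchor_len,min_len,max_len suffix-array index geometry.
#' @param max_mismatches,max_clip spliced-search budgets.
#' @param insert_mean,insert_sd insert-size model for pairing.
#' @param bridge_pqv_min pairing-quality confidence threshold (strict `>`).
#' @param same_gene_min,fusion_min unique-evidence call thresholds
#'   `(span_min, bridge_min)`.
#' @param jcv_min optional junction-confidence floor on the call sets.
#' @param flank_len junction-reference flank (default: forward read length
#'   minus `anchor_len`, so every contained read spans with both anchors).
#' @param run_sasr set `FALSE` to skip the spliced-read search stage.
#' @param verbose emit per-stage progress messages.
#' @return list with `paired` (candidate pairings), `graph`
#'   ([JunctionGraph-class]), `junctions` and `fusions` (call tables),
#'   `span_hits` (spliced-read hits), `rpkm`, `junction_ref`, `stats`
#'   (per-stage accounting), `params`.
#' @export
runPipeline <- function(model, reads,
                        filter_seqs = defaultFilterSet(),
                        anchor_len = 10L, min_len = 10L, max_len = 38L,
                        max_mismatches = 2L, max_clip = 10L,
                        insert_mean = 150, insert_sd = 25,
                        bridge_pqv_min = 10,
                        same_gene_min = c(1L, 1L), fusion_min = c(2L, 2L),
                        jcv_min = NULL, flank_len = NULL,
                        run_sasr = TRUE, verbose = FALSE) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "seq1", "seq2") %in% names(reads)))
  if (anyDuplicated(reads$read_id))
    stop("read_id values must be unique")
  say <- function(...) if (verbose) message("[sasrfuse] ", ...)
  fwd_len <- if (nrow(reads)) max(nchar(reads$seq1)) else 50L
  if (is.null(flank_len))
    flank_len <- max(fwd_len - anchor_len, anchor_len)

  say("building references (flank ", flank_len, ")")
  jref <- buildJunctionReference(model, flank_len = flank_len)
  ex <- model@exons
  refsets <- list(
    genome = referenceSet(genomeSeq(model), "genome"),
    junction = referenceSet(setNames(jref$sequence, jref$name), "junction",
                            meta = jref),
    exon = referenceSet(setNames(exonSequence(model, ex$exon_id),
                                 ex$exon_id), "exon"))
  filter_rs <- if (length(filter_seqs))
    referenceSet(filter_seqs, "filter") else NULL

  say("mapping ", nrow(reads), " read pairs")
  aln <- rbind(.mapMateGroup(refsets, reads$seq1, reads$read_id, 1L),
               .mapMateGroup(refsets, reads$seq2, reads$read_id, 2L))
  n_mapped <- length(unique(paste(aln$read_id, aln$mate)))

  filtered_keys <- character(0)
  if (!is.null(filter_rs)) {
    fhits <- rbind(.mapReadsExact(filter_rs, reads$seq1, reads$read_id, 1L),
                   .mapReadsExact(filter_rs, reads$seq2, reads$read_id, 2L))
    fhits <- fhits[fhits$score >= 20, , drop = FALSE]
    filtered_keys <- unique(paste(fhits$read_id, fhits$mate))
    aln <- subtractFiltered(aln, fhits)
  }

  # mate rescue: one mate confidently placed, the other unaligned
  say("rescuing half-mapped pairs")
  n_rescued <- 0L
  if (nrow(aln)) {
    proj <- .projectAlignments(aln, model, jref)
    proj <- proj[!is.na(proj$chrom), , drop = FALSE]
    has1 <- reads$read_id %in% proj$read_id[proj$mate == 1L]
    has2 <- reads$read_id %in% proj$read_id[proj$mate == 2L]
    half <- which(xor(has1, has2))
    for (r in half) {
      anchored_mate <- if (has1[r]) 1L else 2L
      other_mate <- 3L - anchored_mate
      okey <- paste(reads$read_id[r], other_mate)
      if (okey %in% filtered_keys) next
      p <- proj[proj$read_id == reads$read_id[r] &
                  proj$mate == anchored_mate, , drop = FALSE]
      p <- p[which.max(p$score), , drop = FALSE]
      seq_other <- if (other_mate == 1L) reads$seq1[r] else reads$seq2[r]
      resc <- rescueMate(model, p$chrom, p$gstart, p$gend, seq_other,
                         read_id = reads$read_id[r], mate = other_mate)
      if (!is.null(resc)) {
        aln <- rbind(aln, resc)
        n_rescued <- n_rescued + 1L
      }
    }
  }

  say("pairing")
  paired <- pairAndScore(aln, model, junction_meta = jref,
                         insert_mean = insert_mean, insert_sd = insert_sd)
  has_pairs <- nrow(paired) > 0L && "primary" %in% names(paired)
  primary <- if (has_pairs)
    paired[paired$primary, , drop = FALSE] else paired
  confident <- if (has_pairs)
    primary[primary$pqv > bridge_pqv_min, , drop = FALSE] else primary
  total_pairs <- nrow(confident)
  mispair_rate <- if (has_pairs && nrow(primary))
    max(mean(!primary$concordant), 1e-4) else 1e-4

  exon_counts <- if (total_pairs) {
    tb <- table(c(confident$exon_id_1, confident$exon_id_2))
    setNames(as.numeric(tb), names(tb))
  } else setNames(numeric(0), character(0))

  # junction-reference SPAN evidence from confident spliced mates
  junction_spans <- NULL
  if (total_pairs) {
    js <- list()
    for (m in c("1", "2")) {
      sp <- confident[confident[[paste0("spliced_", m)]], , drop = FALSE]
      if (nrow(sp))
        js[[m]] <- data.frame(
          donor_exon_id = sp[[paste0("span_donor_", m)]],
          acceptor_exon_id = sp[[paste0("span_acceptor_", m)]],
          read_id = sp$read_id,
          start_point = sp[[paste0("pos_", m)]],
          pqv = sp$pqv, stringsAsFactors = FALSE)
    }
    if (length(js)) junction_spans <- do.call(rbind, js)
  }

  # spliced-read search on admitted reads (unplaced or low-confidence)
  span_hits <- NULL
  n_admitted <- 0L
  if (run_sasr && nrow(reads)) {
    best_pqv <- setNames(rep(NA_real_, nrow(reads)), reads$read_id)
    if (has_pairs && nrow(primary))
      best_pqv[primary$read_id] <- primary$pqv
    say("building spliced-read index")
    sidx <- buildSasrIndex(model, min_len = min_len, max_len = max_len,
                           anchor_len = anchor_len)
    hits <- list()
    for (r in seq_len(nrow(reads))) {
      for (m in 1:2) {
        if (paste(reads$read_id[r], m) %in% filtered_keys) next
        s <- if (m == 1L) reads$seq1[r] else reads$seq2[r]
        if (!admitRead(s, pqv = best_pqv[[reads$read_id[r]]],
                       admit_pqv_max = bridge_pqv_min,
                       anchor_len = anchor_len)) next
        n_admitted <- n_admitted + 1L
        h <- sasrMapRead(sidx, s, read_id = reads$read_id[r],
                         max_mismatches = max_mismatches,
                         max_clip = max_clip)
        u <- resolveUniqueJunction(h, sidx)
        if (!is.null(u)) hits[[length(hits) + 1L]] <- u
      }
    }
    say(n_admitted, " reads admitted, ", length(hits), " spliced hits")
    if (length(hits)) span_hits <- do.call(rbind, hits)
  }

  say("accumulating evidence")
  graph <- accumulateEvidence(span_hits = span_hits, paired = paired,
                              model = model,
                              junction_spans = junction_spans,
                              bridge_pqv_min = bridge_pqv_min)
  graph <- scoreJcv(graph, exon_counts, total_pairs,
                    mispair_rate = mispair_rate, model = model)
  calls <- callJunctions(graph, model, same_gene_min = same_gene_min,
                         fusion_min = fusion_min, jcv_min = jcv_min)
  rpkm <- computeRpkm(model, paired, pqv_threshold = bridge_pqv_min)

  stats <- list(
    n_pairs = nrow(reads),
    n_mapped_mates = n_mapped,
    n_filtered_mates = length(filtered_keys),
    n_rescued = n_rescued,
    n_paired = if (has_pairs) nrow(primary) else 0L,
    n_confident_pairs = total_pairs,
    mispair_rate = mispair_rate,
    n_admitted = n_admitted,
    n_sasr_spans = if (is.null(span_hits)) 0L else nrow(span_hits),
    n_junction_spans = if (is.null(junction_spans)) 0L else
      nrow(junction_spans),
    n_candidates = nrow(graph@candidates),
    n_junction_calls = nrow(calls$junctions),
    n_fusion_calls = nrow(calls$fusions))
  say("done: ", stats$n_fusion_calls, " fusions, ",
      stats$n_junction_calls, " junctions")

  list(paired = paired, graph = graph,
       junctions = calls$junctions, fusions = calls$fusions,
       span_hits = span_hits, rpkm = rpkm, junction_ref = jref,
       stats = stats,
       params = list(anchor_len = anchor_len, min_len = min_len,
                     max_len = max_len, max_mismatches = max_mismatches,
                     max_clip = max_clip, insert_mean = insert_mean,
                     insert_sd = insert_sd, bridge_pqv_min = bridge_pqv_min,
                     same_gene_min = same_gene_min, fusion_min = fusion_min,
                     jcv_min = jcv_min, flank_len = flank_len))
}
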