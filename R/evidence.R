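#' Accumulate SPAN and BRIDGE evidence into a junction graph
#'
#' Builds the sparse directed exon graph.  SPAN edges come from (a)
#' spliced-read hits discovered by [sasrMapRead()] (including same-gene
#' junctions) and (b) reads confidently mapped across a junction-reference
#' entry; BRIDGE edges come from primary read pairings with
#' `pqv > bridge_pqv_min` (strict) whose mates fall in two different exons,
#' the forward (5') mate defining the donor side.  A pair whose exon
#' assignment is ambiguous across overlapping gene annotations contributes
#' no edge.  Each edge records a start point (fragment position) so PCR
#' duplicates collapse in the unique-start counts.
#'
#' Candidate junctions are keyed by exact exon pair; SPAN counts are exact,
#' while a BRIDGE edge is counted for every candidate whose junction lies
#' between its mates in transcription order (the fragment of a pair whose
#' forward mate stops one exon short of the breakpoint still crosses it).
#'
#' @param span_hits `data.frame` of spliced hits (columns of
#'   [sasrMapRead()] output), or `NULL`.
#' @param paired output of [pairAndScore()], or `NULL`.
#' @param model a [GeneModel-class].
#' @param junction_spans optional `data.frame` of junction-reference SPAN
#'   evidence with columns `donor_exon_id`, `acceptor_exon_id`, `read_id`,
#'   `start_point`, `pqv`.
#' @param bridge_pqv_min bridge confidence threshold (default 10, strict
#'   `>`).
#' @return A [JunctionGraph-class].
#' @export
accumulateEvidence <- function(span_hits = NULL, paired = NULL, model,
                               junction_spans = NULL,
                               bridge_pqv_min = 10) {
  edges <- list()
  if (!is.null(span_hits) && nrow(span_hits)) {
    edges[[length(edges) + 1L]] <- data.frame(
      donor_exon_id = span_hits$donor_exon_id,
      acceptor_exon_id = span_hits$acceptor_exon_id,
      kind = "SPAN",
      read_id = span_hits$read_id,
      start_point = span_hits$prefix_len + span_hits$clipped_left,
      pqv = 40,
      stringsAsFactors = FALSE)
  }
  if (!is.null(junction_spans) && nrow(junction_spans)) {
    edges[[length(edges) + 1L]] <- data.frame(
      donor_exon_id = junction_spans$donor_exon_id,
      acceptor_exon_id = junction_spans$acceptor_exon_id,
      kind = "SPAN",
      read_id = junction_spans$read_id,
      start_point = junction_spans$start_point,
      pqv = junction_spans$pqv,
      stringsAsFactors = FALSE)
  }
  if (!is.null(paired) && nrow(paired) && "primary" %in% names(paired)) {
    b <- paired[paired$primary & paired$pqv > bridge_pqv_min &
                  !paired$ambiguous_1 & !paired$ambiguous_2 &
                  !is.na(paired$exon_id_1) & !is.na(paired$exon_id_2) &
                  paired$exon_id_1 != paired$exon_id_2, , drop = FALSE]
    if (nrow(b)) {
      edges[[length(edges) + 1L]] <- data.frame(
        donor_exon_id = b$exon_id_1,
        acceptor_exon_id = b$exon_id_2,
        kind = "BRIDGE",
        read_id = b$read_id,
        start_point = b$gstart_1,
        pqv = b$pqv,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(donor_exon_id = character(0),
               acceptor_exon_id = character(0), kind = character(0),
               read_id = character(0), start_point = numeric(0),
               pqv = numeric(0), stringsAsFactors = FALSE)
  edges <- edges[edges$donor_exon_id != edges$acceptor_exon_id, ,
                 drop = FALSE]
  edges <- edges[order(edges$donor_exon_id, edges$acceptor_exon_id,
                       edges$kind, edges$start_point), , drop = FALSE]
  rownames(edges) <- NULL

  new("JunctionGraph", edges = edges,
      candidates = .candidatesFromEdges(edges, model))
}

# Aggregate an edge table into the candidate-junction table (exact-pair
# SPAN stats, compatibility-based BRIDGE stats).
#' @noRd
.candidatesFromEdges <- function(edges, model) {
  ex <- model@exons
  gene_of <- function(eid) ex$gene_id[match(eid, ex$exon_id)]
  key <- paste(edges$donor_exon_id, edges$acceptor_exon_id, sep = "\r")
  byk <- split(seq_len(nrow(edges)), key)
  cand <- do.call(rbind, lapply(byk, function(i) {
    e <- edges[i, , drop = FALSE]
    sp <- e[e$kind == "SPAN", , drop = FALSE]
    data.frame(donor_exon_id = e$donor_exon_id[1],
               acceptor_exon_id = e$acceptor_exon_id[1],
               donor_gene = gene_of(e$donor_exon_id[1]),
               acceptor_gene = gene_of(e$acceptor_exon_id[1]),
               span_count = nrow(sp),
               bridge_count = 0L,
               span_unique = length(unique(sp$start_point)),
               bridge_unique = 0L,
               jcv = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cand)) {
    # a bridge pair supports every candidate junction lying between its
    # mates in transcription order: forward mate in or upstream of the
    # donor exon, reverse mate in or downstream of the acceptor exon
    compat <- .bridgeCompatibility(edges, cand, model)
    cand$bridge_count <- lengths(compat)
    cand$bridge_unique <- vapply(compat, function(i)
      length(unique(edges$start_point[i])), integer(1))
  }
  if (is.null(cand)) {
    cand <- data.frame(donor_exon_id = character(0),
                       acceptor_exon_id = character(0),
                       donor_gene = character(0),
                       acceptor_gene = character(0),
                       span_count = integer(0), bridge_count = integer(0),
                       span_unique = integer(0), bridge_unique = integer(0),
                       jcv = integer(0), stringsAsFactors = FALSE)
  }
  cand$same_gene <- !is.na(cand$donor_gene) & !is.na(cand$acceptor_gene) &
    cand$donor_gene == cand$acceptor_gene
  cand <- cand[order(cand$donor_exon_id, cand$acceptor_exon_id), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# Indices of BRIDGE edges supporting each candidate: the bridge's donor
# exon must be in the candidate's donor gene at rank <= the candidate donor
# rank, and its acceptor exon in the acceptor gene at rank >= the candidate
# acceptor rank.
#' @noRd
.bridgeCompatibility <- function(edges, cand, model) {
  ex <- model@exons
  bi <- which(edges$kind == "BRIDGE")
  di <- match(edges$donor_exon_id[bi], ex$exon_id)
  ai <- match(edges$acceptor_exon_id[bi], ex$exon_id)
  dg <- ex$gene_id[di]; dr <- ex$rank[di]
  ag <- ex$gene_id[ai]; ar <- ex$rank[ai]
  cdi <- match(cand$donor_exon_id, ex$exon_id)
  cai <- match(cand$acceptor_exon_id, ex$exon_id)
  lapply(seq_len(nrow(cand)), function(k) {
    bi[!is.na(dg) & !is.na(ag) &
         dg == ex$gene_id[cdi[k]] & dr <= ex$rank[cdi[k]] &
         ag == ex$gene_id[cai[k]] & ar >= ex$rank[cai[k]]]
  })
}

#' Count unique evidence start points
#'
#' Distinct `start_point` values per evidence kind for one candidate's
#' edges; duplicates (PCR towers) collapse to one.
#'
#' @param edges edge `data.frame` for a single candidate.
#' @return `c(span_unique=, bridge_unique=)`.
#' @export
countUniqueStarts <- function(edges) {
  c(span_unique = length(unique(
      edges$start_point[edges$kind == "SPAN"])),
    bridge_unique = length(unique(
      edges$start_point[edges$kind == "BRIDGE"])))
}

#' Junction confidence value (JCV)
#'
#' Scores the quantity and quality of BRIDGE evidence against an error
#' expectation metric: the null hypothesis that the bridges arise from
#' random mispairing between two (possibly highly expressed) exons.
#' Effective evidence is `k_eff = sum(1 - 10^(-pqv/10))` over the bridge
#' edges; the null bridge rate is
#' `lambda = max(1e-6, mispair_rate * r_x * r_y / total_pairs)` where `r_x`,
#' `r_y` are the confident read counts of the two exons; the null tail
#' probability `P(Poisson(lambda) >= k_eff)` (regularized upper incomplete
#' gamma in `k_eff`) is phred-scaled and clamped to 0..100.  The original
#' formula was not published; this reconstruction preserves the documented
#' behavior (0-100 range, mass at 0 and 100, expression-driven null).
#'
#' @param bridge_pqv numeric vector of bridge-edge PQVs (empty = no
#'   bridges, JCV 0).
#' @param reads_x,reads_y confident read counts on the donor and acceptor
#'   exons.
#' @param total_pairs total confident read pairs in the library.
#' @param mispair_rate estimated fraction of pairs that mispair at random
#'   (default 1e-4; the pipeline estimates it from inter-gene discordant
#'   pairs when possible).
#' @return Integer JCV in 0..100.
#' @export
computeJcv <- function(bridge_pqv, reads_x, reads_y, total_pairs,
                       mispair_rate = 1e-4) {
  if (!length(bridge_pqv) || total_pairs <= 0) return(0L)
  k_eff <- sum(1 - 10^(-bridge_pqv / 10))
  if (k_eff <= 0) return(0L)
  lambda <- max(1e-6, mispair_rate * reads_x * reads_y / total_pairs)
  p_null <- pgamma(lambda, shape = k_eff)  # P(Poisson(lambda) >= k_eff)
  as.integer(max(0L, min(100L, round(-10 * log10(max(p_null, 1e-300))))))
}

#' Score all candidates of a junction graph with JCV
#'
#' @param graph a [JunctionGraph-class].
#' @param exon_counts named numeric vector: confident reads per exon id
#'   (missing exons count 0).
#' @param total_pairs total confident pairs.
#' @param mispair_rate see [computeJcv()].
#' @param model optional [GeneModel-class]; when given, each candidate's
#'   bridge evidence is gathered by transcription-order compatibility (as in
#'   [accumulateEvidence()]) instead of by exact exon pair.
#' @return The graph with the candidates' `jcv` column filled in.
#' @export
scoreJcv <- function(graph, exon_counts, total_pairs, mispair_rate = 1e-4,
                     model = NULL) {
  cand <- graph@candidates
  edges <- graph@edges
  cnt <- function(eid) {
    v <- exon_counts[eid]
    ifelse(is.na(v), 0, v)
  }
  compat <- if (!is.null(model))
    .bridgeCompatibility(edges, cand, model) else NULL
  key <- paste(edges$donor_exon_id, edges$acceptor_exon_id, sep = "\r")
  for (i in seq_len(nrow(cand))) {
    k <- paste(cand$donor_exon_id[i], cand$acceptor_exon_id[i], sep = "\r")
    bq <- if (is.null(compat))
      edges$pqv[key == k & edges$kind == "BRIDGE"] else
        edges$pqv[compat[[i]]]
    cand$jcv[i] <- computeJcv(bq, cnt(cand$donor_exon_id[i]),
                              cnt(cand$acceptor_exon_id[i]),
                              total_pairs, mispair_rate)
  }
  new("JunctionGraph", edges = edges, candidates = cand)
}

#' Call junctions and fusions at unique-evidence thresholds
#'
#' A same-gene candidate is called when it has at least `same_gene_min[1]`
#' unique-start SPAN and `same_gene_min[2]` unique-start BRIDGE evidences
#' (default 1 and 1); an inter-gene candidate is called as a fusion at
#' `fusion_min` (default 2 and 2).  An optional JCV filter applies
#' afterwards.  Called same-gene junctions sharing a donor (or acceptor)
#' with at least one other call are flagged as alternative splices.
#'
#' @param graph a scored [JunctionGraph-class].
#' @param model a [GeneModel-class] (for fusion classification).
#' @param same_gene_min,fusion_min length-2 integer vectors
#'   `(span_min, bridge_min)`.
#' @param jcv_min optional minimum JCV applied to both call sets.
#' @return `list(junctions=, fusions=)`; fusions carry the columns of
#'   [classifyFusion()].
#' @export
callJunctions <- function(graph, model, same_gene_min = c(1L, 1L),
                          fusion_min = c(2L, 2L), jcv_min = NULL) {
  cand <- graph@candidates
  pass <- function(x, thr) x$span_unique >= thr[1] & x$bridge_unique >= thr[2]
  jn <- cand[cand$same_gene & pass(cand, same_gene_min), , drop = FALSE]
  fu <- cand[!cand$same_gene & pass(cand, fusion_min), , drop = FALSE]
  if (!is.null(jcv_min)) {
    jn <- jn[!is.na(jn$jcv) & jn$jcv >= jcv_min, , drop = FALSE]
    fu <- fu[!is.na(fu$jcv) & fu$jcv >= jcv_min, , drop = FALSE]
  }
  if (nrow(jn)) {
    jn$alt_splice <- ave(seq_len(nrow(jn)), jn$donor_exon_id,
                         FUN = length) > 1 |
      ave(seq_len(nrow(jn)), jn$acceptor_exon_id, FUN = length) > 1
  } else jn$alt_splice <- logical(0)
  if (nrow(fu)) {
    fu <- cbind(fu, classifyFusion(fu$donor_exon_id, fu$acceptor_exon_id,
                                   model))
  } else {
    fu <- cbind(fu, data.frame(five_prime_gene = character(0),
                               three_prime_gene = character(0),
                               classification = character(0),
                               signed_distance = numeric(0),
                               in_frame = logical(0)))
  }
  rownames(jn) <- rownames(fu) <- NULL
  list(junctions = jn, fusions = fu)
}

#' Classify a fusion candidate by partner geometry
#'
#' Inter-chromosomal when the partner genes lie on different chromosomes;
#' inverted when on the same chromosome but opposite strands; same-strand
#' otherwise, with a signed genomic distance from the donor exon's 3'
#' boundary to the acceptor exon's 5' boundary measured in transcription
#' direction -- negative when the acceptor partner lies upstream of the
#' donor in expected transcription order (fusions in the reverse of
#' transcription order print negative distances).  Reading-frame status
#' would require CDS annotation, which the flattened exon model does not
#' retain, so `in_frame` is reported as `NA`.
#'
#' @param donor_exon_id,acceptor_exon_id character vectors (recycled
#'   together) naming the fused exons.
#' @param model a [GeneModel-class].
#' @return `data.frame` with `five_prime_gene`, `three_prime_gene`,
#'   `classification`, `signed_distance` (NA unless same-strand),
#'   `in_frame` (NA).
#' @export
classifyFusion <- function(donor_exon_id, acceptor_exon_id, model) {
  ex <- model@exons
  di <- match(donor_exon_id, ex$exon_id)
  ai <- match(acceptor_exon_id, ex$exon_id)
  if (anyNA(di) || anyNA(ai)) stop("unknown exon id in fusion candidate")
  chr <- as.character(GenomicRanges::seqnames(ex))
  str <- as.character(GenomicRanges::strand(ex))
  donor3 <- ifelse(str[di] == "-", GenomicRanges::start(ex)[di],
                   GenomicRanges::end(ex)[di])
  acc5 <- ifelse(str[ai] == "-", GenomicRanges::end(ex)[ai],
                 GenomicRanges::start(ex)[ai])
  classification <- ifelse(
    chr[di] != chr[ai], "inter-chromosomal",
    ifelse(str[di] != str[ai], "inverted", "same-strand"))
  signed <- ifelse(classification == "same-strand",
                   (acc5 - donor3) * ifelse(str[di] == "-", -1, 1),
                   NA_real_)
  data.frame(five_prime_gene = ex$gene_id[di],
             three_prime_gene = ex$gene_id[ai],
             classification = classification,
             signed_distance = signed,
             in_frame = NA,
             stringsAsFactors = FALSE)
}
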