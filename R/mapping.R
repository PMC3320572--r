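# Simplified four-reference mapping stage feeding the evidence graph.
# Alignments here are full-read, substitution-only placements with a
# per-reference-class mismatch budget (genome/junction 2, exon 3); the
# pairing step assigns a phred-scaled pairing quality value (PQV, 0-40).
# This stage is deliberately modest: it is adequate for annotated-exon
# transcriptome references and synthetic data, and users with real data can
# supply their own alignments to the evidence stage instead.

.CLASS_CAP <- c(genome = 2L, junction = 2L, exon = 3L, filter = 2L,
                rescue = 6L)

#' Bundle reference sequences for the simple mapper
#'
#' Concatenates the entries with 25-N spacers into one searchable subject
#' (exact matches can never cross a spacer) and records entry offsets so
#' hits map back to individual entries.
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector).
#' @param class one of `"genome"`, `"junction"`, `"exon"`, `"filter"`; sets
#'   the default mismatch budget (genome/junction 2, exon 3).
#' @param meta optional `data.frame` of per-entry metadata (row order =
#'   entry order); the junction reference passes its donor/acceptor table.
#' @return A `ReferenceSet` (list with subject, offsets, widths, names,
#'   class, cap, meta).
#' @export
referenceSet <- function(seqs, class = c("genome", "junction", "exon",
                                         "filter"),
                         meta = NULL) {
  class <- match.arg(class)
  nm <- names(seqs)
  seqs <- as.character(seqs)   # as.character() drops names; restore them
  names(seqs) <- nm
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("ref", seq_along(seqs))
  spacer <- strrep("N", 25L)
  subject <- Biostrings::DNAString(paste(seqs, collapse = spacer))
  widths <- nchar(seqs)
  offsets <- if (length(seqs)) {
    setNames(cumsum(c(1L, head(widths + 25L, -1L))), names(seqs))
  } else integer(0)
  structure(list(subject = subject, offsets = offsets, widths = widths,
                 names = names(seqs), class = class,
                 cap = .CLASS_CAP[[class]], meta = meta),
            class = "ReferenceSet")
}

# Turn match start positions in the concatenated subject into alignment
# records, dropping matches that are not fully inside one entry.
#' @noRd
.matchesToRecords <- function(refset, starts, w, read_id, mate, strand,
                              mismatches = NULL, sequence = NULL) {
  if (!length(starts)) return(.emptyAlignmentFrame())
  e <- findInterval(starts, refset$offsets)
  ok <- e >= 1L & starts + w - 1L <= refset$offsets[e] + refset$widths[e] - 1L
  starts <- starts[ok]; e <- e[ok]
  if (!length(starts)) return(.emptyAlignmentFrame())
  if (is.null(mismatches)) {
    mismatches <- vapply(starts, function(s) {
      ref <- as.character(Biostrings::subseq(refset$subject, s, s + w - 1L))
      .countMismatch(ref, sequence)
    }, integer(1))
  } else {
    mismatches <- rep_len(mismatches, length(starts))
  }
  data.frame(read_id = read_id, mate = mate,
             refname = refset$names[e],
             pos = starts - refset$offsets[e] + 1L,
             strand = strand,
             matches = w - mismatches, mismatches = mismatches,
             score = (w - mismatches) - 2L * mismatches,
             reference_class = refset$class, stringsAsFactors = FALSE)
}

#' Align one read against a reference set
#'
#' Full-length, substitution-only alignment of the read (both orientations)
#' with at most the class mismatch budget; scored match = +1,
#' mismatch = -2.  For minus-strand records `pos` refers to the leftmost
#' base of the reverse-complemented read on the reference.
#'
#' @param refset a [referenceSet()].
#' @param sequence read sequence.
#' @param read_id,mate identifiers carried into the output.
#' @param max_mismatches override of the class mismatch budget.
#' @return `data.frame` of alignment records (zero rows when unmapped).
#' @export
mapReadSimple <- function(refset, sequence, read_id = "read", mate = 1L,
                          max_mismatches = NULL) {
  cap <- if (is.null(max_mismatches)) refset$cap else as.integer(max_mismatches)
  w <- nchar(sequence)
  if (!length(refset$names) || w < 1L) return(.emptyAlignmentFrame())
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(sequence),
                                  refset$subject, max.mismatch = cap)
  rcseq <- .revcomp(sequence)
  rev <- Biostrings::matchPattern(Biostrings::DNAString(rcseq),
                                  refset$subject, max.mismatch = cap)
  out <- rbind(
    .matchesToRecords(refset, Biostrings::start(fwd), w, read_id, mate,
                      "+", sequence = sequence),
    .matchesToRecords(refset, Biostrings::start(rev), w, read_id, mate,
                      "-", sequence = rcseq))
  out <- out[out$mismatches <= cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Batch exact-match path: all reads of one mate group against one reference
# set via PDict (grouped by read width).  Error-free reads take this path;
# unseeded reads fall back to mapReadSimple() in the pipeline.
#' @noRd
.mapReadsExact <- function(refset, sequences, read_ids, mate) {
  if (!length(sequences) || !length(refset$names))
    return(.emptyAlignmentFrame())
  res <- list()
  for (or in c("+", "-")) {
    seqs <- if (or == "+") sequences else .revcomp(sequences)
    for (w in unique(nchar(seqs))) {
      idx <- which(nchar(seqs) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
      m <- Biostrings::matchPDict(pd, refset$subject)
      starts <- Biostrings::startIndex(m)
      hit <- which(lengths(starts) > 0L)
      for (h in hit) {
        res[[length(res) + 1L]] <- .matchesToRecords(
          refset, starts[[h]], w, read_ids[idx[h]], mate, or,
          mismatches = 0L)
      }
    }
  }
  if (!length(res)) return(.emptyAlignmentFrame())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Remove reads that hit the filter reference confidently
#'
#' Any read with a filter-class alignment scoring at least `score_min`
#' has *all* of its alignments removed (keyed by read id and mate).  The
#' operation is idempotent and the identity when no filter hits are given.
#'
#' @param alignments alignment `data.frame`.
#' @param filter_hits filter-class alignment `data.frame`.
#' @param score_min minimum alignment score for a filter hit to count as
#'   confident (default 20; a 25-base exact hit scores 25).
#' @return The surviving alignments.
#' @export
subtractFiltered <- function(alignments, filter_hits, score_min = 20) {
  if (is.null(filter_hits) || nrow(filter_hits) == 0L) return(alignments)
  bad <- filter_hits[filter_hits$score >= score_min, , drop = FALSE]
  if (!nrow(bad)) return(alignments)
  key <- paste(alignments$read_id, alignments$mate)
  badkey <- unique(paste(bad$read_id, bad$mate))
  out <- alignments[!(key %in% badkey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best gapless placement of a read along one sequence (both orientations);
# returns c(pos, mismatches, sense) or NULL.
#' @noRd
.slideBest <- function(read, target, max_mismatches) {
  w <- nchar(read); m <- nchar(target)
  if (w > m) return(NULL)
  traw <- charToRaw(target)
  best <- NULL
  for (sense in c(1L, 0L)) {
    rraw <- charToRaw(if (sense == 1L) read else .revcomp(read))
    for (p in seq_len(m - w + 1L)) {
      mm <- sum(traw[p:(p + w - 1L)] != rraw)
      if (mm <= max_mismatches && (is.null(best) || mm < best[2L]))
        best <- c(p, mm, sense)
    }
  }
  best
}

#' Rescue an unaligned mate within its partner's gene
#'
#' When one mate is confidently anchored inside a gene and the other is
#' unaligned, the unaligned mate is searched against the downstream exons
#' (transcription order) of that gene, allowing up to six mismatches.  The
#' best placement is returned as an exon-space alignment record
#' (`reference_class = "rescue"`, `refname` = exon id, `pos` = offset in the
#' exon's transcription-orientation sequence).
#'
#' @param model a [GeneModel-class].
#' @param anchored_chrom,anchored_start,anchored_end genomic interval of the
#'   anchored mate's alignment.
#' @param sequence the unaligned mate's sequence.
#' @param read_id,mate identifiers for the output record.
#' @param max_mismatches substitution budget (default 6).
#' @return One-row alignment `data.frame`, or `NULL` when the anchor is not
#'   inside a unique gene or no placement fits the budget.
#' @export
rescueMate <- function(model, anchored_chrom, anchored_start, anchored_end,
                       sequence, read_id = "read", mate = 2L,
                       max_mismatches = 6L) {
  gt <- model@genes
  g <- which(gt$chrom == anchored_chrom &
               gt$span_start <= anchored_start &
               gt$span_end >= anchored_end)
  if (length(g) != 1L) return(NULL)
  gene <- gt$gene_id[g]
  ex <- model@exons
  i <- which(ex$gene_id == gene)
  i <- i[order(ex$rank[i])]
  # first exon at or downstream (transcription order) of the anchor
  if (gt$strand[g] == "+") {
    dn <- GenomicRanges::end(ex)[i] >= anchored_start
  } else {
    dn <- GenomicRanges::start(ex)[i] <= anchored_end
  }
  if (!any(dn)) return(NULL)
  cand <- i[seq(from = which(dn)[1L], to = length(i))]
  best <- NULL; best_exon <- NA_character_
  for (k in cand) {
    hit <- .slideBest(sequence, exonSequence(model, ex$exon_id[k]),
                      max_mismatches)
    if (!is.null(hit) && (is.null(best) || hit[2L] < best[2L])) {
      best <- hit; best_exon <- ex$exon_id[k]
    }
  }
  if (is.null(best)) return(NULL)
  w <- nchar(sequence); mm <- best[2L]
  data.frame(read_id = read_id, mate = mate, refname = best_exon,
             pos = as.integer(best[1L]),
             strand = if (best[3L] == 1L) "+" else "-",
             matches = w - mm, mismatches = as.integer(mm),
             score = (w - mm) - 2L * mm,
             reference_class = "rescue", stringsAsFactors = FALSE)
}

# ---- projection of alignments to genomic + transcript coordinates ----

#' @noRd
.txCumBefore <- function(model) {
  ex <- model@exons
  out <- numeric(length(ex))
  for (g in unique(ex$gene_id)) {
    i <- which(ex$gene_id == g)
    i <- i[order(ex$rank[i])]
    w <- GenomicRanges::width(ex)[i]
    out[i] <- cumsum(c(0, head(w, -1)))
  }
  out
}

# Annotate alignment records with genomic interval, gene/exon assignment,
# transcript coordinates and junction-span information.
#' @noRd
.projectAlignments <- function(alignments, model, junction_meta = NULL) {
  n <- nrow(alignments)
  ex <- model@exons
  exon_strand <- as.character(GenomicRanges::strand(ex))
  exon_start <- GenomicRanges::start(ex)
  exon_end <- GenomicRanges::end(ex)
  exon_chr <- as.character(GenomicRanges::seqnames(ex))
  exon_ids <- ex$exon_id
  exon_gene <- ex$gene_id
  cumbefore <- .txCumBefore(model)

  chrom <- rep(NA_character_, n); gstart <- rep(NA_real_, n)
  gend <- rep(NA_real_, n); gstrand <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n); exon_id <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n); tx_start <- rep(NA_real_, n)
  tx_end <- rep(NA_real_, n); spliced <- rep(FALSE, n)
  span_donor <- rep(NA_character_, n); span_acceptor <- rep(NA_character_, n)

  if (n) {
    w <- alignments$matches + alignments$mismatches
    cls <- alignments$reference_class
    astrand <- alignments$strand

    # exon-space placement (rows r at exon indices e, position p in the
    # exon's transcription-orientation sequence), vectorized
    fillExon <- function(r, e, p) {
      exon_id[r] <<- exon_ids[e]
      gene_id[r] <<- exon_gene[e]
      chrom[r] <<- exon_chr[e]
      tx_start[r] <<- cumbefore[e] + p
      tx_end[r] <<- cumbefore[e] + p + w[r] - 1
      plus <- exon_strand[e] == "+"
      gstart[r] <<- ifelse(plus, exon_start[e] + p - 1,
                           exon_end[e] - p + 2 - w[r])
      gend[r] <<- gstart[r] + w[r] - 1
      gstrand[r] <<- ifelse(plus == (astrand[r] == "+"), "+", "-")
    }

    # genome-space records: assign the gene/exon with the largest overlap;
    # overlap with more than one gene marks the record ambiguous
    gi <- which(cls == "genome")
    if (length(gi)) {
      chrom[gi] <- alignments$refname[gi]
      gstart[gi] <- alignments$pos[gi]
      gend[gi] <- alignments$pos[gi] + w[gi] - 1
      gstrand[gi] <- astrand[gi]
      qry <- GenomicRanges::GRanges(chrom[gi],
                                    IRanges::IRanges(gstart[gi], gend[gi]))
      ov <- GenomicRanges::findOverlaps(qry, ex, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      if (length(qh)) {
        ovw <- GenomicRanges::width(IRanges::pintersect(
          IRanges::ranges(qry)[qh], IRanges::ranges(ex)[sh]))
        ngene <- vapply(split(exon_gene[sh], qh), function(g)
          length(unique(g)), integer(1))
        amb_q <- as.integer(names(ngene))[ngene > 1L]
        ambiguous[gi[amb_q]] <- TRUE
        o <- order(qh, -ovw)
        keep <- !duplicated(qh[o]) & !(qh[o] %in% amb_q)
        q <- qh[o][keep]; b <- sh[o][keep]
        r <- gi[q]
        gene_id[r] <- exon_gene[b]
        exon_id[r] <- exon_ids[b]
        # transcript coordinates only when fully exonic
        full <- gstart[r] >= exon_start[b] & gend[r] <= exon_end[b]
        rf <- r[full]; bf <- b[full]
        p <- ifelse(exon_strand[bf] == "+", gstart[rf] - exon_start[bf] + 1,
                    exon_end[bf] - gend[rf] + 1)
        tx_start[rf] <- cumbefore[bf] + p
        tx_end[rf] <- tx_start[rf] + w[rf] - 1
      }
    }

    # exon-space records (exon reference and rescued mates)
    ei <- which(cls %in% c("exon", "rescue"))
    if (length(ei)) {
      eidx <- match(alignments$refname[ei], exon_ids)
      ok <- !is.na(eidx)
      if (any(ok)) fillExon(ei[ok], eidx[ok], alignments$pos[ei][ok])
    }

    # junction-space records: inside the donor flank, inside the acceptor
    # flank, or spanning the junction
    ji <- which(cls == "junction")
    if (length(ji) && !is.null(junction_meta)) {
      mi <- match(alignments$refname[ji], junction_meta$name)
      ok <- !is.na(mi)
      ji <- ji[ok]; mi <- mi[ok]
      if (length(ji)) {
        d <- junction_meta$donor_exon_id[mi]
        a <- junction_meta$acceptor_exon_id[mi]
        df <- junction_meta$donor_flank[mi]
        didx <- match(d, exon_ids); aidx <- match(a, exon_ids)
        dlen <- exon_end[didx] - exon_start[didx] + 1L
        s <- alignments$pos[ji]; e <- s + w[ji] - 1L
        ind <- e <= df                    # fully inside the donor flank
        ina <- s > df                     # fully inside the acceptor flank
        isp <- !ind & !ina                # spans the junction
        if (any(ind)) fillExon(ji[ind], didx[ind], (dlen - df + s)[ind])
        if (any(ina)) fillExon(ji[ina], aidx[ina], (s - df)[ina])
        if (any(isp)) {
          r <- ji[isp]; b <- didx[isp]
          spliced[r] <- TRUE
          span_donor[r] <- d[isp]
          span_acceptor[r] <- a[isp]
          exon_id[r] <- exon_ids[b]
          gene_id[r] <- exon_gene[b]
          chrom[r] <- exon_chr[b]
          # donor-side segment genomic interval
          p <- (dlen - df + s)[isp]
          dw <- (df - s + 1L)[isp]
          plus <- exon_strand[b] == "+"
          gstart[r] <- ifelse(plus, exon_start[b] + p - 1,
                              exon_end[b] - p + 2 - dw)
          gend[r] <- gstart[r] + dw - 1
          gstrand[r] <- ifelse(plus == (astrand[r] == "+"), "+", "-")
          tx_start[r] <- cumbefore[b] + p
          tx_end[r] <- tx_start[r] + w[r] - 1
        }
      }
    }
  }

  cbind(alignments, data.frame(
    chrom = chrom, gstart = gstart, gend = gend, gstrand = gstrand,
    gene_id = gene_id, exon_id = exon_id, ambiguous = ambiguous,
    tx_start = tx_start, tx_end = tx_end, spliced = spliced,
    span_donor = span_donor, span_acceptor = span_acceptor,
    stringsAsFactors = FALSE))
}

#' Pair mate alignments and assign pairing quality values
#'
#' Enumerates joint placements of the two mates of each read pair and scores
#' them with a posterior over candidates: candidate weight
#' `w = 10^(score_sum/10) * density`, where `density` is a normal
#' insert-size likelihood for concordant placements (both mates in one gene,
#' in transcript coordinates, or same chromosome in forward/reverse
#' orientation in genomic coordinates) and a small constant prior for
#' discordant placements (e.g. mates on two genes -- the geometry of a
#' fusion bridge).  The pairing quality value is
#' `PQV = round(-10*log10(1 - p))` from the candidate posterior `p`, capped
#' at 40; the best candidate of each pair is flagged `primary`.
#'
#' The exact pairing formula of the original pipeline was not published;
#' this reconstruction preserves its observable behavior (0-40 phred scale,
#' confidence semantics, `PQV > 10` as the confidence threshold).
#'
#' @param alignments alignment `data.frame` covering both mates (classes
#'   genome/junction/exon/rescue), e.g. rows from [mapReadSimple()].
#' @param model a [GeneModel-class] used to project alignments.
#' @param junction_meta junction reference table
#'   ([buildJunctionReference()]) when junction-class alignments are
#'   present.
#' @param insert_mean,insert_sd insert-size model (defaults 150/25, matching
#'   a 100-200 bp gel-selected library).
#' @param disc_prior constant density assigned to a discordant joint
#'   placement (default 1e-6; concordant placements at the modal insert
#'   score about 0.016).
#' @param pqv_cap maximum PQV (default 40).
#' @param max_candidates per-mate cap on alignments entering the
#'   enumeration (best-scoring kept).
#' @return `data.frame` with one row per candidate joint placement:
#'   projected coordinates of both mates (suffixes `_1`, `_2`), `insert`,
#'   `concordant`, `posterior`, `pqv`, `primary`.
#' @export
pairAndScore <- function(alignments, model, junction_meta = NULL,
                         insert_mean = 150, insert_sd = 25,
                         disc_prior = 1e-6, pqv_cap = 40L,
                         max_candidates = 20L) {
  proj <- .projectAlignments(alignments, model, junction_meta)
  # the same physical placement can surface through several reference
  # classes (e.g. genome and exon); keep one record per genomic locus so
  # duplicates cannot split the pairing posterior
  if (nrow(proj)) {
    prio <- match(proj$reference_class,
                  c("genome", "junction", "exon", "rescue"))
    proj <- proj[order(proj$read_id, proj$mate, prio, -proj$score), ,
                 drop = FALSE]
    lockey <- paste(proj$read_id, proj$mate, proj$chrom, proj$gstart,
                    proj$gend, proj$gstrand)
    proj <- proj[is.na(proj$chrom) | !duplicated(lockey), , drop = FALSE]
  }
  keep <- c("refname", "pos", "strand", "score", "reference_class",
            "chrom", "gstart", "gend", "gstrand", "gene_id", "exon_id",
            "ambiguous", "tx_start", "tx_end", "spliced",
            "span_donor", "span_acceptor")
  res <- list()
  byread <- split(seq_len(nrow(proj)), proj$read_id)
  for (id in names(byread)) {
    rows <- proj[byread[[id]], , drop = FALSE]
    m1 <- rows[rows$mate == 1L, , drop = FALSE]
    m2 <- rows[rows$mate == 2L, , drop = FALSE]
    if (!nrow(m1) || !nrow(m2)) next
    m1 <- head(m1[order(-m1$score), , drop = FALSE], max_candidates)
    m2 <- head(m2[order(-m2$score), , drop = FALSE], max_candidates)
    grid <- expand.grid(i = seq_len(nrow(m1)), j = seq_len(nrow(m2)))
    a <- m1[grid$i, , drop = FALSE]; b <- m2[grid$j, , drop = FALSE]
    insert <- rep(NA_real_, nrow(grid))
    dens <- numeric(nrow(grid))
    sameGene <- !is.na(a$gene_id) & !is.na(b$gene_id) &
      a$gene_id == b$gene_id & !is.na(a$tx_start) & !is.na(b$tx_start)
    insert[sameGene] <- pmax(a$tx_end, b$tx_end)[sameGene] -
      pmin(a$tx_start, b$tx_start)[sameGene] + 1
    genomic <- !sameGene & !is.na(a$chrom) & !is.na(b$chrom) &
      a$chrom == b$chrom & a$gstrand != b$gstrand
    if (any(genomic)) {
      plusFirst <- ifelse(a$gstrand == "+",
                          a$gstart <= b$gstart, b$gstart <= a$gstart)
      genomic <- genomic & plusFirst
      insert[genomic] <- pmax(a$gend, b$gend)[genomic] -
        pmin(a$gstart, b$gstart)[genomic] + 1
    }
    concordant <- sameGene | genomic
    dens[concordant] <- dnorm(insert[concordant], insert_mean, insert_sd)
    dens <- pmax(dens, disc_prior)
    wgt <- 10^((a$score + b$score) / 10) * dens
    post <- wgt / sum(wgt)
    pqv <- pmin(as.integer(pqv_cap),
                as.integer(round(-10 * log10(pmax(1e-4, 1 - post)))))
    prim <- seq_along(post) == which.max(post)
    one <- data.frame(read_id = id, stringsAsFactors = FALSE)
    one <- cbind(one, setNames(a[keep], paste0(keep, "_1")),
                 setNames(b[keep], paste0(keep, "_2")))
    one$insert <- insert
    one$concordant <- concordant
    one$posterior <- post
    one$pqv <- pqv
    one$primary <- prim
    res[[length(res) + 1L]] <- one
  }
  if (!length(res)) {
    return(data.frame(read_id = character(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene expression as RPKM from confident pairs
#'
#' `RPKM(g) = pairs_in_g * 1e9 / (total_confident_pairs * exonic_length(g))`
#' counting only primary pairings with `pqv > pqv_threshold`; a pair is
#' attributed to the gene of its forward mate.
#'
#' @param model a [GeneModel-class].
#' @param paired output of [pairAndScore()].
#' @param pqv_threshold confidence threshold (strict `>`, default 10).
#' @return Named numeric vector over all genes (0 where unexpressed).
#' @export
computeRpkm <- function(model, paired, pqv_threshold = 10) {
  gt <- model@genes
  rpkm <- setNames(numeric(nrow(gt)), gt$gene_id)
  if (!nrow(paired) || !"primary" %in% names(paired)) return(rpkm)
  conf <- paired[paired$primary & paired$pqv > pqv_threshold, , drop = FALSE]
  total <- nrow(conf)
  if (!total) return(rpkm)
  cnt <- table(conf$gene_id_1[!is.na(conf$gene_id_1)])
  i <- match(names(cnt), gt$gene_id)
  ok <- !is.na(i)
  rpkm[i[ok]] <- as.numeric(cnt[ok]) * 1e9 /
    (total * gt$exonic_length[i[ok]])
  rpkm
}
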