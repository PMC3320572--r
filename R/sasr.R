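#' Map one read across a putative exon-exon breakpoint
#'
#' The core spliced-read search.  Clip totals c = 0, 1, ..., `max_clip` are
#' tried in order; each total is split over the two read ends (smaller left
#' clip first).  For each effective read the leading decamer is searched in
#' the donor table and the terminal decamer in the acceptor table; matches
#' are extended (anchor exact, up to `max_mismatches` substitutions per
#' extension region) and every (donor, acceptor) pair whose covered lengths
#' sum to the effective read length is emitted.  The search stops at the
#' first clip total that yields at least one hit.
#'
#' Every emitted hit satisfies `prefix_len + suffix_len =
#' nchar(sequence) - clipped_left - clipped_right` with both sides at least
#' the anchor length.
#'
#' @param index a [SasrIndex-class].
#' @param sequence read sequence (base space).
#' @param read_id identifier carried through to the output.
#' @param max_mismatches substitution budget per extension region
#'   (default 2).
#' @param max_clip total clipping budget over both read ends (default 10).
#' @return `data.frame` with columns `read_id`, `donor_exon_id`,
#'   `acceptor_exon_id`, `prefix_len`, `suffix_len`, `clipped_left`,
#'   `clipped_right`, `mismatches`, ordered by (donor, acceptor,
#'   prefix_len); zero rows when the read provides no junction evidence.
#' @export
sasrMapRead <- function(index, sequence, read_id = "read",
                        max_mismatches = 2L, max_clip = 10L) {
  anchor <- index@anchor_len
  n <- nchar(sequence)
  empty <- data.frame(read_id = character(0), donor_exon_id = character(0),
                      acceptor_exon_id = character(0),
                      prefix_len = integer(0), suffix_len = integer(0),
                      clipped_left = integer(0), clipped_right = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  hits <- list()
  for (cl in 0:max_clip) {
    L <- n - cl
    if (L < 2L * anchor) break
    for (left in 0:cl) {
      right <- cl - left
      eff <- substr(sequence, 1L + left, n - right)

      donors <- searchAnchor(index, substr(eff, 1L, anchor), "donor")
      donors <- donors[donors$length <= L - anchor, , drop = FALSE]
      dcov <- list()
      for (i in seq_len(nrow(donors))) {
        em <- extendMatch(index, donors[i, ], eff, "donor", max_mismatches)
        if (em$covered)
          dcov[[length(dcov) + 1L]] <- c(donors$exon_index[i],
                                         donors$length[i], em$mismatches)
      }
      if (!length(dcov)) next

      acceptors <- searchAnchor(index, substr(eff, L - anchor + 1L, L),
                                "acceptor")
      acceptors <- acceptors[acceptors$length <= L - anchor, , drop = FALSE]
      acov <- list()
      for (i in seq_len(nrow(acceptors))) {
        em <- extendMatch(index, acceptors[i, ], eff, "acceptor",
                          max_mismatches)
        if (em$covered)
          acov[[length(acov) + 1L]] <- c(acceptors$exon_index[i],
                                         acceptors$length[i], em$mismatches)
      }
      if (!length(acov)) next

      dmat <- do.call(rbind, dcov)
      amat <- do.call(rbind, acov)
      for (i in seq_len(nrow(dmat))) {
        p <- dmat[i, 2]
        j <- which(amat[, 2] == L - p)
        for (jj in j) {
          hits[[length(hits) + 1L]] <- data.frame(
            read_id = read_id,
            donor_exon_id = index@exon_ids[dmat[i, 1]],
            acceptor_exon_id = index@exon_ids[amat[jj, 1]],
            prefix_len = as.integer(p),
            suffix_len = as.integer(L - p),
            clipped_left = left, clipped_right = right,
            mismatches = as.integer(dmat[i, 3] + amat[jj, 3]),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) break  # first productive clip total wins
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[c("donor_exon_id", "acceptor_exon_id",
                               "prefix_len", "clipped_left")]), ,
             drop = FALSE]
  out <- out[order(out$donor_exon_id, out$acceptor_exon_id,
                   out$prefix_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Admission filter for the spliced-read search
#'
#' Only reads without a confident placement are candidates for fusion
#' splicing: a read is admitted when it is unmapped or its pairing quality
#' does not exceed `admit_pqv_max`, it is long enough to carry two anchors,
#' and its base composition passes a complexity check (Shannon entropy of
#' base frequencies, in bits).  The criteria reconstruct the intent of the
#' original admission rule; the exact original definition was not published.
#'
#' @param sequence read sequence.
#' @param pqv pairing quality of the read's confident placement, or `NA`
#'   when unmapped.
#' @param admit_pqv_max highest PQV still considered "not confidently
#'   placed" (default 10, the confidence threshold used throughout).
#' @param anchor_len anchor length of the index the read will be searched
#'   against.
#' @param min_entropy minimum base-composition entropy in bits (default 1;
#'   homopolymers score 0, random ACGT about 2).
#' @return `TRUE` when the read should enter the spliced-read search.
#' @export
admitRead <- function(sequence, pqv = NA_real_, admit_pqv_max = 10,
                      anchor_len = 10L, min_entropy = 1.0) {
  if (!is.na(pqv) && pqv > admit_pqv_max) return(FALSE)
  if (nchar(sequence) < 2L * anchor_len) return(FALSE)
  .seqEntropy(sequence) >= min_entropy
}

#' Resolve whether a read's hits name a unique junction
#'
#' Exons sharing an identical boundary coordinate (overlapping annotation)
#' are collapsed: hits agreeing after collapsing the donor 3' and acceptor
#' 5' coordinates count as one junction.  If all hits agree, the
#' first hit (in the deterministic output order of [sasrMapRead()]) is
#' returned; otherwise the read is ambiguous and discarded.
#'
#' @param hits output of [sasrMapRead()] for one read.
#' @param index the [SasrIndex-class] the hits came from.
#' @return A one-row `data.frame`, or `NULL` when the evidence is ambiguous
#'   or empty.
#' @export
resolveUniqueJunction <- function(hits, index) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  dk <- index@donor_boundary[match(hits$donor_exon_id, index@exon_ids)]
  ak <- index@acceptor_boundary[match(hits$acceptor_exon_id,
                                      index@exon_ids)]
  if (length(unique(paste(dk, ak))) != 1L) return(NULL)
  hits[1L, , drop = FALSE]
}
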