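#' Build the spliced-read suffix index over exon ends
#'
#' For every exon of length L >= `min_len`, the donor table stores the 3'
#' suffixes of lengths `min_len` .. min(L, `max_len`) and the acceptor table
#' the reversed 5' prefixes of the same lengths, both sorted
#' lexicographically (A < C < G < T).  Entries are (exon index, length)
#' pairs; the leading `anchor_len` characters of each key are additionally
#' encoded base-4 so anchor lookups reduce to an integer range search.
#' Entries whose key contains a non-ACGT symbol are excluded (they can never
#' anchor-match).
#'
#' @param model a [GeneModel-class].
#' @param min_len,max_len stored suffix/prefix length bounds.  With the
#'   classic 50-bp forward reads the useful range is 10 through
#'   `read_length - anchor_len` = 40 (we default `max_len` to 38, the
#'   historical operating point; both bounds are configurable).
#' @param anchor_len exact-match anchor length (default 10, the "decamer").
#' @return A [SasrIndex-class].
#' @export
buildSasrIndex <- function(model, min_len = 10L, max_len = 38L,
                           anchor_len = 10L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  anchor_len <- as.integer(anchor_len)
  stopifnot(min_len >= anchor_len, max_len >= min_len)
  ex <- model@exons
  exon_ids <- ex$exon_id
  if (length(exon_ids)) {
    seqs <- exonSequence(model, exon_ids)
    chr <- as.character(GenomicRanges::seqnames(ex))
    str <- as.character(GenomicRanges::strand(ex))
    d3 <- ifelse(str == "-", GenomicRanges::start(ex),
                 GenomicRanges::end(ex))
    a5 <- ifelse(str == "-", GenomicRanges::end(ex),
                 GenomicRanges::start(ex))
    donor_boundary <- paste(chr, str, d3, sep = ":")
    acceptor_boundary <- paste(chr, str, a5, sep = ":")
  } else {
    seqs <- character(0)
    donor_boundary <- acceptor_boundary <- character(0)
  }

  buildTable <- function(side) {
    lens <- nchar(seqs)
    n_entry <- pmax(0L, pmin(lens, max_len) - min_len + 1L)
    idx <- rep(seq_along(seqs), n_entry)
    L <- unlist(lapply(n_entry, function(k)
      if (k > 0L) seq(min_len, length.out = k) else integer(0)))
    if (!length(idx)) {
      return(data.frame(exon_index = integer(0), length = integer(0),
                        anchor_code = numeric(0)))
    }
    keys <- if (side == "donor") {
      substring(seqs[idx], lens[idx] - L + 1L, lens[idx])
    } else {
      .strrev(substring(seqs[idx], 1L, L))
    }
    ok <- !grepl("[^ACGT]", keys)
    idx <- idx[ok]; L <- L[ok]; keys <- keys[ok]
    code <- as.numeric(.encodeAnchor(substr(keys, 1L, anchor_len),
                                     anchor_len))
    ord <- order(keys, idx, method = "radix")
    data.frame(exon_index = idx[ord], length = as.integer(L[ord]),
               anchor_code = code[ord])
  }

  new("SasrIndex", exon_ids = exon_ids, exon_gene = ex$gene_id,
      exon_seqs = seqs,
      donor_boundary = donor_boundary,
      acceptor_boundary = acceptor_boundary,
      donor_table = buildTable("donor"),
      acceptor_table = buildTable("acceptor"),
      min_len = min_len, max_len = max_len, anchor_len = anchor_len)
}

#' Materialize the key strings of a suffix table
#'
#' Keys are stored compactly as (exon index, length) pairs; this
#' reconstructs the sorted key strings (donor: exon 3' suffixes; acceptor:
#' reversed exon 5' prefixes).  Mostly useful for inspection and for
#' verifying table sortedness.
#'
#' @param index a [SasrIndex-class].
#' @param side `"donor"` or `"acceptor"`.
#' @return Character vector of keys in table order.
#' @export
sasrKeys <- function(index, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  tab <- if (side == "donor") index@donor_table else index@acceptor_table
  if (!nrow(tab)) return(character(0))
  seqs <- index@exon_seqs[tab$exon_index]
  if (side == "donor") {
    substring(seqs, nchar(seqs) - tab$length + 1L, nchar(seqs))
  } else {
    .strrev(substring(seqs, 1L, tab$length))
  }
}

#' Binary anchor search in a suffix table
#'
#' Returns every entry whose key begins with the given anchor, matched with
#' zero mismatches.  For the donor side the anchor is the read's leading
#' decamer; for the acceptor side pass the read's *terminal* decamer -- it
#' is reversed internally to match the reversed-prefix keys (so the returned
#' exon prefixes *end* with the anchor).  Anchors containing non-ACGT
#' symbols yield an empty result.
#'
#' @param index a [SasrIndex-class].
#' @param anchor a string of exactly `anchor_len` bases.
#' @param side `"donor"` or `"acceptor"`.
#' @return The matching slice of the suffix table (`data.frame` with
#'   `exon_index`, `length`, `anchor_code`), zero rows when absent.
#' @export
searchAnchor <- function(index, anchor, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  k <- index@anchor_len
  if (nchar(anchor) != k)
    stop("anchor must have length ", k)
  if (side == "acceptor") anchor <- .strrev(anchor)
  code <- .encodeAnchor(anchor, k)
  tab <- if (side == "donor") index@donor_table else index@acceptor_table
  if (is.na(code) || !nrow(tab)) return(tab[0, , drop = FALSE])
  lo <- findInterval(code - 0.5, tab$anchor_code) + 1L
  hi <- findInterval(code + 0.5, tab$anchor_code)
  if (lo > hi) return(tab[0, , drop = FALSE])
  res <- tab[lo:hi, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extend an anchor match across the stored exon end
#'
#' Checks whether a read end covers an entire stored suffix/prefix: the
#' anchor region must match exactly and the extension region may carry at
#' most `max_mismatches` substitutions.  Donor entries are compared against
#' the read prefix of length `entry$length`; acceptor entries against the
#' read suffix of the same length.
#'
#' @param index a [SasrIndex-class].
#' @param entry one row of a suffix table (or a list with `exon_index` and
#'   `length`).
#' @param read the (possibly clipped) read sequence.
#' @param side `"donor"` or `"acceptor"`.
#' @param max_mismatches substitution budget in the extension region
#'   (default 2).
#' @return `list(covered=, map_len=, mismatches=)`; `map_len` equals the
#'   entry length when covered and 0 otherwise; `mismatches` counts
#'   extension-region substitutions (NA when the entry is longer than the
#'   read).
#' @export
extendMatch <- function(index, entry, read,
                        side = c("donor", "acceptor"),
                        max_mismatches = 2L) {
  side <- match.arg(side)
  L <- as.integer(entry$length)
  n <- nchar(read)
  if (L > n) return(list(covered = FALSE, map_len = 0L,
                         mismatches = NA_integer_))
  k <- index@anchor_len
  seq <- index@exon_seqs[entry$exon_index]
  if (side == "donor") {
    exon_str <- substr(seq, nchar(seq) - L + 1L, nchar(seq))
    read_str <- substr(read, 1L, L)
    anchor_ok <- substr(exon_str, 1L, k) == substr(read_str, 1L, k)
    mm <- if (L > k) .countMismatch(substr(exon_str, k + 1L, L),
                                    substr(read_str, k + 1L, L)) else 0L
  } else {
    exon_str <- substr(seq, 1L, L)
    read_str <- substr(read, n - L + 1L, n)
    anchor_ok <- substr(exon_str, L - k + 1L, L) ==
      substr(read_str, L - k + 1L, L)
    mm <- if (L > k) .countMismatch(substr(exon_str, 1L, L - k),
                                    substr(read_str, 1L, L - k)) else 0L
  }
  covered <- anchor_ok && mm <= max_mismatches
  list(covered = covered, map_len = if (covered) L else 0L,
       mismatches = as.integer(mm))
}

#' Anchor-block size histogram of a suffix table
#'
#' Partitions the table into maximal runs of entries sharing the same
#' leading anchor and tabulates run sizes.  The sum of size x count equals
#' the table length.  Large blocks flag low-complexity or repeated exon
#' ends whose anchors retrieve many candidates.
#'
#' @param index a [SasrIndex-class].
#' @param side `"donor"` or `"acceptor"`.
#' @return Named integer vector: counts indexed by block size (empty for an
#'   empty index).
#' @export
blockHistogram <- function(index, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  tab <- if (side == "donor") index@donor_table else index@acceptor_table
  if (!nrow(tab)) return(setNames(integer(0), character(0)))
  runs <- rle(tab$anchor_code)$lengths
  tb <- table(runs)
  setNames(as.integer(tb), names(tb))
}
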