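# Independent test oracles.  These deliberately share no code with the
# package: plain substring comparisons and closed-form mathematics only.

# Brute-force spliced-read oracle: enumerate every exon pair, every split
# position and every clip assignment within the same budgets as the
# implementation, using direct string comparison.  Mirrors the documented
# semantics (anchor-exact decamers, per-side extension mismatch budget,
# stop at the first productive clip total, dedupe on
# donor/acceptor/prefix/clipped_left).
oracleSasr <- function(model, sequence, read_id = "read",
                       min_len = 10L, max_len = 38L, anchor_len = 10L,
                       max_mismatches = 2L, max_clip = 10L) {
  ex <- model@exons
  eids <- ex$exon_id
  eseq <- exonSequence(model, eids)
  elen <- nchar(eseq)
  nmm <- function(a, b) {
    sum(strsplit(a, "", fixed = TRUE)[[1]] !=
          strsplit(b, "", fixed = TRUE)[[1]])
  }
  n <- nchar(sequence)
  rows <- list()
  for (cl in 0:max_clip) {
    L <- n - cl
    if (L < 2L * anchor_len) break
    found_at_this_total <- FALSE
    for (left in 0:cl) {
      right <- cl - left
      eff <- substr(sequence, 1L + left, n - right)
      for (p in seq_len(L)) {
        s <- L - p
        if (p < max(min_len, anchor_len) || s < max(min_len, anchor_len))
          next
        if (p > max_len || s > max_len) next
        prefix <- substr(eff, 1L, p)
        suffix <- substr(eff, p + 1L, L)
        for (di in seq_along(eids)) {
          if (elen[di] < p) next
          dref <- substr(eseq[di], elen[di] - p + 1L, elen[di])
          if (substr(dref, 1L, anchor_len) !=
              substr(prefix, 1L, anchor_len)) next
          dmm <- if (p > anchor_len)
            nmm(substr(dref, anchor_len + 1L, p),
                substr(prefix, anchor_len + 1L, p)) else 0L
          if (dmm > max_mismatches) next
          for (ai in seq_along(eids)) {
            if (elen[ai] < s) next
            aref <- substr(eseq[ai], 1L, s)
            if (substr(aref, s - anchor_len + 1L, s) !=
                substr(suffix, s - anchor_len + 1L, s)) next
            amm <- if (s > anchor_len)
              nmm(substr(aref, 1L, s - anchor_len),
                  substr(suffix, 1L, s - anchor_len)) else 0L
            if (amm > max_mismatches) next
            rows[[length(rows) + 1L]] <- data.frame(
              read_id = read_id, donor_exon_id = eids[di],
              acceptor_exon_id = eids[ai],
              prefix_len = p, suffix_len = s,
              clipped_left = left, clipped_right = right,
              mismatches = dmm + amm, stringsAsFactors = FALSE)
            found_at_this_total <- TRUE
          }
        }
      }
    }
    if (found_at_this_total) break
  }
  if (!length(rows)) {
    return(data.frame(read_id = character(0), donor_exon_id = character(0),
                      acceptor_exon_id = character(0),
                      prefix_len = integer(0), suffix_len = integer(0),
                      clipped_left = integer(0), clipped_right = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("donor_exon_id", "acceptor_exon_id",
                               "prefix_len", "clipped_left")]), ,
             drop = FALSE]
  out <- out[order(out$donor_exon_id, out$acceptor_exon_id,
                   out$prefix_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Linear-scan oracle for the anchor search: enumerate the side's table
# entries by direct substring reconstruction and string comparison.
oracleAnchorScan <- function(model, anchor, side,
                             min_len = 10L, max_len = 38L,
                             anchor_len = 10L) {
  ex <- model@exons
  eids <- ex$exon_id
  eseq <- exonSequence(model, eids)
  elen <- nchar(eseq)
  hits <- list()
  for (i in seq_along(eids)) {
    lmax <- min(elen[i], max_len)
    if (lmax < min_len) next
    for (l in min_len:lmax) {
      key <- if (side == "donor") {
        substr(eseq[i], elen[i] - l + 1L, elen[i] - l + anchor_len)
      } else {
        # acceptor entries are reversed prefixes; their leading decamer is
        # the reverse of the prefix's trailing decamer
        paste(rev(strsplit(substr(eseq[i], l - anchor_len + 1L, l), "",
                           fixed = TRUE)[[1]]), collapse = "")
      }
      qry <- if (side == "donor") anchor else
        paste(rev(strsplit(anchor, "", fixed = TRUE)[[1]]), collapse = "")
      if (key == qry)
        hits[[length(hits) + 1L]] <- data.frame(exon_index = i, length = l)
    }
  }
  if (!length(hits))
    return(data.frame(exon_index = integer(0), length = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$exon_index, out$length), , drop = FALSE]
}

# Irwin-Hall distribution: closed-form P(mean of n uniforms < x), via
# P(sum < t) with t = n * x.  Alternating-sum form; fine in double
# precision for n <= ~30.
irwinHallMeanCdf <- function(x, n) {
  t <- n * x
  if (t <= 0) return(0)
  if (t >= n) return(1)
  k <- 0:floor(t)
  sum((-1)^k * choose(n, k) * (t - k)^n) / factorial(n)
}
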