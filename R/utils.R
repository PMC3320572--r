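# Internal string helpers.  Alphabet is A < C < G < T throughout; anchors are
# encoded base-4 so a sorted suffix table can be range-searched with
# findInterval() instead of locale-dependent string comparison.

.BASES <- c("A", "C", "G", "T")

#' @noRd
.encodeAnchor <- function(x, k) {
  if (length(x) == 0L) return(integer(0))
  chars <- strsplit(x, "", fixed = TRUE)
  pow <- 4^((k - 1L):0L)
  vapply(chars, function(ch) {
    if (length(ch) != k) return(NA_integer_)
    v <- match(ch, .BASES) - 1L
    if (anyNA(v)) return(NA_integer_)
    as.integer(sum(v * pow))
  }, integer(1))
}

#' @noRd
.strrev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Reverse complement; the scalar short-read path avoids the cost of
# constructing a DNAStringSet for every read.
#' @noRd
.revcomp <- function(x) {
  if (length(x) == 1L && !is.na(x) && nchar(x) <= 200L)
    return(.strrev(chartr("ACGTacgtN", "TGCAtgcaN", x)))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Mismatch count between equal-length strings (byte-wise).
#' @noRd
.countMismatch <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Shannon entropy (bits) of the base composition of a read; low-complexity
# reads (homopolymers and near-homopolymers) score close to zero.
#' @noRd
.seqEntropy <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  p <- table(ch) / length(ch)
  -sum(p * log2(p))
}

#' @noRd
.emptyAlignmentFrame <- function() {
  data.frame(read_id = character(0), mate = integer(0),
             refname = character(0), pos = integer(0),
             strand = character(0), matches = integer(0),
             mismatches = integer(0), score = integer(0),
             reference_class = character(0), stringsAsFactors = FALSE)
}
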