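#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats dnorm pgamma runif rnorm rpois rlnorm sd setNames rbinom
#' @importFrom utils head
NULL

#' GeneModel: genome plus annotated exon structure
#'
#' Container for a genome (as a [Biostrings::DNAStringSet]) and its gene
#' annotation flattened to one exon set per gene.  Exons are stored as a
#' [GenomicRanges::GRanges] (1-based, closed intervals) carrying
#' `exon_id`, `gene_id` and `rank` metadata columns, where `rank` is the
#' 1-based exon order in transcription direction (reverse genomic order on
#' the minus strand).  Exon identifiers follow the `gene-rank` convention
#' (e.g. `"G01-2"` for the second exon of gene `G01`).
#'
#' @slot exons [GenomicRanges::GRanges] of exons with metadata columns
#'   `exon_id`, `gene_id`, `rank`.
#' @slot genes `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `span_start`, `span_end` (distance between the start of the
#'   first exon and the end of the last exon defines gene length),
#'   `n_exons`, `exonic_length`.
#' @slot genome [Biostrings::DNAStringSet] of chromosome sequences.
#'
#' @seealso [loadGeneModel()], [exonSequence()], [buildJunctionReference()]
#' @export
setClass("GeneModel",
         representation(exons = "GRanges", genes = "data.frame",
                        genome = "DNAStringSet"))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msg <- character(0)
  if (anyDuplicated(object@genes$gene_id))
    msg <- c(msg, "gene_ids must be unique")
  if (anyDuplicated(ex$exon_id))
    msg <- c(msg, "exon_ids must be unique")
  if (length(ex)) {
    chr <- as.character(GenomicRanges::seqnames(ex))
    bad <- !(chr %in% names(object@genome))
    if (any(bad))
      msg <- c(msg, paste0("exon on unknown chromosome: ",
                           paste(unique(chr[bad]), collapse = ", ")))
    if (!any(bad)) {
      lens <- Biostrings::width(object@genome)[match(chr, names(object@genome))]
      if (any(GenomicRanges::end(ex) > lens) ||
          any(GenomicRanges::start(ex) < 1L))
        msg <- c(msg, "exon coordinates outside chromosome bounds")
    }
    if (any(GenomicRanges::width(ex) < 1L))
      msg <- c(msg, "zero-length exon")
    if (any(ex$rank < 1L))
      msg <- c(msg, "exon rank must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' SasrIndex: suffix-array tables over exon ends
#'
#' The spliced-read aligner's search structure: two lexicographically sorted
#' tables of exon-end substrings.  The donor table holds, for every exon,
#' the suffixes of its 3' end (lengths `min_len` through `max_len`, in
#' transcription orientation); the acceptor table holds the *reversed*
#' prefixes of each exon's 5' start, so that a read's terminal decamer can be
#' binary-searched after reversal.  Each entry is stored compactly as an
#' (exon index, length) pair; key strings are materialized on demand by
#' [sasrKeys()].  A precomputed base-4 code of each key's leading
#' `anchor_len` characters supports O(log n) exact-anchor range lookup.
#'
#' @slot exon_ids,exon_gene character vectors parallel to the exon list.
#' @slot exon_seqs exon sequences in transcription orientation.
#' @slot donor_boundary,acceptor_boundary collapse keys
#'   (`chrom:strand:coordinate` of the 3' end / 5' start) used to merge
#'   exons that share a boundary across overlapping annotation.
#' @slot donor_table,acceptor_table `data.frame`s with columns
#'   `exon_index`, `length`, `anchor_code`, sorted by full key string.
#' @slot min_len,max_len,anchor_len stored length bounds and the exact-match
#'   anchor length (default 10).
#'
#' @seealso [buildSasrIndex()], [searchAnchor()], [sasrMapRead()]
#' @export
setClass("SasrIndex",
         representation(exon_ids = "character", exon_gene = "character",
                        exon_seqs = "character",
                        donor_boundary = "character",
                        acceptor_boundary = "character",
                        donor_table = "data.frame",
                        acceptor_table = "data.frame",
                        min_len = "integer", max_len = "integer",
                        anchor_len = "integer"))

setValidity("SasrIndex", function(object) {
  msg <- character(0)
  if (object@min_len < object@anchor_len)
    msg <- c(msg, "min_len must be >= anchor_len")
  if (object@max_len < object@min_len)
    msg <- c(msg, "max_len must be >= min_len")
  for (side in c("donor_table", "acceptor_table")) {
    tab <- slot(object, side)
    if (!all(c("exon_index", "length", "anchor_code") %in% names(tab)))
      msg <- c(msg, paste(side, "missing required columns"))
    else if (nrow(tab) && is.unsorted(tab$anchor_code))
      msg <- c(msg, paste(side, "anchor codes not sorted"))
  }
  if (length(msg)) msg else TRUE
})

#' JunctionGraph: sparse directed graph of junction evidence
#'
#' Exons are nodes; SPAN (breakpoint-spanning read) and BRIDGE (mate-pair)
#' evidences are two kinds of directed edges from a donor exon to an
#' acceptor exon.  Aggregated per-candidate counts, unique start points and
#' the junction confidence value (JCV) live in the `candidates` table.
#'
#' @slot edges `data.frame` with columns `donor_exon_id`,
#'   `acceptor_exon_id`, `kind` (`"SPAN"`/`"BRIDGE"`), `read_id`,
#'   `start_point`, `pqv`.
#' @slot candidates `data.frame` with one row per observed (donor, acceptor)
#'   exon pair: evidence counts, unique-start counts, `same_gene`, `jcv`.
#'
#' @seealso [accumulateEvidence()], [scoreJcv()], [callJunctions()]
#' @export
setClass("JunctionGraph",
         representation(edges = "data.frame", candidates = "data.frame"))

#' BiasResult: parametric bootstrap test of 5' breakpoint bias
#'
#' Result of testing whether fusion breakpoints fall closer to the 5' end of
#' the 5' partner genes than expected under a uniform-within-gene null.
#'
#' @slot n_genes number of fusion loci.
#' @slot observed_mean mean normalized breakpoint location (fraction of gene
#'   length, measured from the transcription start).
#' @slot sim_mean,sim_sd grand mean and standard deviation of the simulated
#'   per-set means.
#' @slot n_sims number of simulated sets.
#' @slot p_value fraction of simulated set means strictly below the observed
#'   mean.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot sim_means the simulated set means (empty unless requested).
#'
#' @seealso [bootstrapBiasTest()], [inferBreakpoint()]
#' @export
setClass("BiasResult",
         representation(n_genes = "integer", observed_mean = "numeric",
                        sim_mean = "numeric", sim_sd = "numeric",
                        n_sims = "integer", p_value = "numeric",
                        seed = "integer", sim_means = "numeric"))

setValidity("BiasResult", function(object) {
  if (object@p_value < 0 || object@p_value > 1)
    "p_value must be in [0, 1]"
  else TRUE
})

## ---- accessors ----

#' Accessors for package classes
#'
#' `exonRanges()` returns the exon [GenomicRanges::GRanges] of a
#' [GeneModel-class]; `geneTable()` its per-gene summary `data.frame`;
#' `genomeSeq()` its genome.  `candidates()` and `evidenceEdges()` return
#' the candidate and edge tables of a [JunctionGraph-class].
#'
#' @param x a `GeneModel` or `JunctionGraph` object.
#' @return See description.
#' @name accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setGeneric("evidenceEdges", function(x) standardGeneric("evidenceEdges"))

#' @rdname accessors
setMethod("exonRanges", "GeneModel", function(x) x@exons)

#' @rdname accessors
setMethod("geneTable", "GeneModel", function(x) x@genes)

#' @rdname accessors
setMethod("genomeSeq", "GeneModel", function(x) x@genome)

#' @rdname accessors
setMethod("candidates", "JunctionGraph", function(x) x@candidates)

#' @rdname accessors
setMethod("evidenceEdges", "JunctionGraph", function(x) x@edges)

## ---- show methods ----

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel with", nrow(object@genes), "gene(s),",
      length(object@exons), "exon(s) on",
      length(object@genome), "sequence(s)\n")
})

setMethod("show", "SasrIndex", function(object) {
  cat("SasrIndex over", length(object@exon_ids), "exon(s): ",
      nrow(object@donor_table), "donor /",
      nrow(object@acceptor_table), "acceptor entries",
      sprintf("(lengths %d..%d, anchor %d)\n",
              object@min_len, object@max_len, object@anchor_len))
})

setMethod("show", "JunctionGraph", function(object) {
  cs <- object@candidates
  cat("JunctionGraph:", nrow(object@edges), "evidence edge(s) on",
      nrow(cs), "candidate junction(s)",
      sprintf("(%d same-gene, %d inter-gene)\n",
              sum(cs$same_gene), sum(!cs$same_gene)))
})

setMethod("show", "BiasResult", function(object) {
  cat(sprintf(
    "Breakpoint-bias bootstrap: n_genes=%d, observed mean=%.4f\n",
    object@n_genes, object@observed_mean))
  cat(sprintf("  null (uniform within gene): mean=%.4f sd=%.4f over %d sets\n",
              object@sim_mean, object@sim_sd, object@n_sims))
  cat(sprintf("  p-value (sets with mean < observed): %.3g\n",
              object@p_value))
})
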