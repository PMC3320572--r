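#' Infer a fusion breakpoint location within the 5' partner gene
#'
#' The genomic breakpoint is modeled at the midpoint of the intron that
#' follows the last retained exon of the 5' gene (transcription order;
#' mirrored on the minus strand).  The location is normalized by gene
#' length -- the distance between the start of the first exon and the end of
#' the last exon -- measured from the transcription start, giving a fraction
#' in \[0, 1\].
#'
#' @param model a [GeneModel-class].
#' @param gene_id the 5' partner gene.
#' @param fused_exon_rank rank of the last retained exon; must be smaller
#'   than the gene's exon count (an intron must follow).
#' @return One-row `data.frame`: `gene_id`, `fused_exon_rank`, `breakpoint`
#'   (genomic coordinate, possibly half-integer), `normalized_location`.
#' @examples
#' # a two-exon gene with exons at 101-200 and 301-400 fused after exon 1
#' # puts the breakpoint at 250, i.e. 0.5 of the 300-base gene span
#' @export
inferBreakpoint <- function(model, gene_id, fused_exon_rank) {
  ex <- model@exons
  gt <- model@genes
  g <- match(gene_id, gt$gene_id)
  if (is.na(g)) stop("unknown gene_id: ", gene_id)
  i <- which(ex$gene_id == gene_id)
  n <- length(i)
  if (fused_exon_rank >= n)
    stop("no intron follows exon rank ", fused_exon_rank, " of ", gene_id)
  e1 <- i[match(fused_exon_rank, ex$rank[i])]
  e2 <- i[match(fused_exon_rank + 1L, ex$rank[i])]
  # genomically left/right exon around the following intron
  left_end <- min(GenomicRanges::end(ex)[c(e1, e2)])
  right_start <- max(GenomicRanges::start(ex)[c(e1, e2)])
  bp <- (left_end + right_start - 1) / 2
  len <- gt$span_end[g] - gt$span_start[g] + 1
  norm <- if (gt$strand[g] == "+") {
    (bp - (gt$span_start[g] - 1)) / len
  } else {
    (gt$span_end[g] - bp) / len
  }
  data.frame(gene_id = gene_id, fused_exon_rank = fused_exon_rank,
             breakpoint = bp, normalized_location = norm,
             stringsAsFactors = FALSE)
}

#' Parametric bootstrap test for 5' breakpoint bias
#'
#' Tests whether fusion breakpoints fall closer to the 5' end of their 5'
#' partner genes than a uniform-within-gene null allows.  `n_sims` sets of
#' `n_genes` independent uniform(0, 1) normalized locations are drawn; the
#' p-value is the fraction of simulated set means strictly below the
#' observed mean.  Either supply the observed loci (rows from
#' [inferBreakpoint()]) or the observed mean and gene count directly.
#'
#' For `n_genes` genes the null set mean has expectation 0.5 and standard
#' deviation `1/sqrt(12 * n_genes)`; the simulated summary converges there.
#'
#' @param loci `data.frame` with a `normalized_location` column, or `NULL`.
#' @param observed_mean,n_genes alternative direct specification.
#' @param n_sims number of simulated sets (default 100000).
#' @param seed optional RNG seed, recorded in the result.
#' @param keep_sims keep the simulated set means in the returned object.
#' @return A [BiasResult-class].
#' @export
bootstrapBiasTest <- function(loci = NULL, observed_mean = NULL,
                              n_genes = NULL, n_sims = 100000L,
                              seed = NULL, keep_sims = FALSE) {
  if (!is.null(loci)) {
    observed_mean <- mean(loci$normalized_location)
    n_genes <- nrow(loci)
  }
  if (is.null(observed_mean) || is.null(n_genes))
    stop("supply either loci or both observed_mean and n_genes")
  n_genes <- as.integer(n_genes)
  n_sims <- as.integer(n_sims)
  stopifnot(n_genes >= 1L, n_sims >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sim_means <- colMeans(matrix(runif(n_sims * n_genes), nrow = n_genes))
  new("BiasResult",
      n_genes = n_genes,
      observed_mean = observed_mean,
      sim_mean = mean(sim_means),
      sim_sd = sd(sim_means),
      n_sims = n_sims,
      p_value = mean(sim_means < observed_mean),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      sim_means = if (keep_sims) sim_means else numeric(0))
}

#' Histogram of breakpoint intron ranks for fusion calls
#'
#' For the 5' partner the breakpoint intron is the one *following* the fused
#' exon (rank = the fused exon's rank); for the 3' partner it is the intron
#' *preceding* the first retained exon (rank = that exon's rank minus one;
#' a 3' partner fused at its first exon counts as rank 0, upstream of the
#' gene body).
#'
#' @param fusions `data.frame` with `donor_exon_id` and `acceptor_exon_id`
#'   columns (e.g. the fusion calls of [callJunctions()]).
#' @param model a [GeneModel-class].
#' @return `list(five_prime=, three_prime=)` of named integer count vectors
#'   indexed by intron rank (empty lists of counts for no calls).
#' @export
intronPositionHistogram <- function(fusions, model) {
  empty <- setNames(integer(0), character(0))
  if (is.null(fusions) || nrow(fusions) == 0L)
    return(list(five_prime = empty, three_prime = empty))
  ex <- model@exons
  r5 <- ex$rank[match(fusions$donor_exon_id, ex$exon_id)]
  r3 <- ex$rank[match(fusions$acceptor_exon_id, ex$exon_id)] - 1L
  tab <- function(x) {
    t <- table(x)
    setNames(as.integer(t), names(t))
  }
  list(five_prime = tab(r5), three_prime = tab(r3))
}

#' Breakpoint-bias test over a set of fusion calls
#'
#' Convenience wrapper: maps each fusion call to the midpoint of the intron
#' following its 5' fused exon (calls fusing the last exon of the 5' gene
#' are dropped with a message -- no intron follows) and runs
#' [bootstrapBiasTest()].
#'
#' @inheritParams intronPositionHistogram
#' @inheritParams bootstrapBiasTest
#' @return A [BiasResult-class], or `NULL` when no usable loci remain.
#' @export
fusionBiasTest <- function(fusions, model, n_sims = 100000L, seed = NULL) {
  if (is.null(fusions) || nrow(fusions) == 0L) return(NULL)
  ex <- model@exons
  loci <- list()
  for (i in seq_len(nrow(fusions))) {
    eidx <- match(fusions$donor_exon_id[i], ex$exon_id)
    g <- ex$gene_id[eidx]
    rk <- ex$rank[eidx]
    n <- sum(ex$gene_id == g)
    if (rk >= n) {
      message("skipping ", fusions$donor_exon_id[i],
              ": last exon fused, no following intron")
      next
    }
    loci[[length(loci) + 1L]] <- inferBreakpoint(model, g, rk)
  }
  if (!length(loci)) return(NULL)
  bootstrapBiasTest(do.call(rbind, loci), n_sims = n_sims, seed = seed)
}
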