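---
title: "Methods: suffix-array spliced-read alignment and fusion calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suffix-array spliced-read alignment and fusion calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasrfuse)
```

# Overview

`sasrfuse` detects splice junctions and gene fusions from strand-specific
paired-end RNA-Seq against an annotated gene model. The method rests on two
kinds of evidence for a candidate exon-exon junction:

* **SPAN** — a single read whose alignment crosses the junction, found
  either by the suffix-array spliced-read aligner (SASR) or by confident
  placement on a precomputed junction reference;
* **BRIDGE** — a read pair whose mates land in two different exons such
  that the fragment must cross the junction between them.

Evidence accumulates in a sparse directed exon graph; candidates are called
at unique-evidence thresholds (defaults: 1 SPAN + 1 BRIDGE for same-gene
junctions, 2 + 2 for inter-gene fusions), optionally filtered by a junction
confidence value (JCV).

# The gene model

A `GeneModel` flattens annotation to one exon chain per gene: overlapping
transcript structures are reduced (`GenomicRanges::reduce`) and exons are
ranked in transcription order, so rank 1 is the 5'-most exon on either
strand and `exon_id = <gene>-<rank>`. Coordinates are 1-based inclusive
throughout, the native convention of the Bioconductor containers used here.

Because the model does not retain CDS annotation, reading-frame status of a
fusion cannot be determined; `classifyFusion()` reports `in_frame = NA` by
design rather than guessing.

# SASR: suffix-array spliced-read alignment

The index holds, for every exon, its 3' suffixes (the donor table) and its
**reversed** 5' prefixes (the acceptor table), for lengths 10-38. Each
entry is keyed by its leading decamer encoded as a base-4 integer; the
tables are sorted by key so a decamer anchor resolves to a contiguous block
by binary range search (`findInterval`).

A read is tested at every prefix/suffix split with at least 10 bases on
each side:

1. the prefix's leading decamer must match a donor entry **exactly** (the
   anchor tolerates no mismatches);
2. the remainder of the prefix is extended against the entry with at most
   2 mismatches; the suffix side is matched symmetrically against the
   acceptor table (anchored at its trailing decamer);
3. the map-length sum rule holds by construction: prefix length + suffix
   length equals the effective (unclipped) read length.

Reads that fail to map whole may be clipped from either end, up to 10 bases
total. Clip totals are explored in increasing order (0, 1, 2, ...) with all
left/right assignments at each total, and the search **stops at the first
productive total** — a read is never clipped more than necessary. Within a
clip total, hits are deduplicated on (donor, acceptor, prefix length, left
clip). This "clip outside, then split" order is a design choice: clipped
bases never participate in the anchor or extension.

Only reads that are unplaced or ambiguously placed by ordinary mapping
(pairing quality <= 10, see below), at least 20 nt long and not
low-complexity are admitted to SASR; a read whose hits disagree on the
junction is discarded (`resolveUniqueJunction`).

# Four-reference mapping and pairing quality

Each mate is mapped against up to four reference sets — genome, exon-exon
junction reference (flanks sized so any contained read keeps a full anchor
on both sides), exon set, and a filter set (adapters, homopolymers).
Entries are concatenated with 25-N spacers so matches cannot cross entry
boundaries. Exact placements are found in batch (`Biostrings::PDict`);
reads with no exact hit anywhere fall back to a per-read approximate scan.
Mates whose best filter hit scores >= 20 are removed outright. A mate whose
partner maps but which maps nowhere itself is rescued by a bounded
mismatch scan over the downstream exons of the anchored gene.

All placements of a pair are projected to genomic coordinates and
combined into candidate pairings. Each candidate is weighted by

```
w = 10^(score_sum / 10) * max(dnorm(insert, 150, 25), 1e-6)
```

where `score = matches - 2 * mismatches`; the discordant prior `1e-6`
keeps genuinely discordant (fusion-bridging) pairs alive. The posterior
`p = w / sum(w)` over candidates gives the **pairing quality value**

```
PQV = min(40, round(-10 * log10(max(1e-4, 1 - p))))
```

so a unique placement scores 40 and two equal placements score 3.
Confident evidence requires PQV strictly greater than 10. The PQV and JCV
formulas are reconstructions: the published description fixes their ranges
and qualitative behavior but not the exact algebra, and the forms above
were chosen to reproduce that documented behavior.

# Evidence accumulation and the JCV

SPAN counting is exact by exon pair. BRIDGE counting uses
transcription-order **compatibility**: a bridge with forward mate in exon
`d` and reverse mate in exon `a` supports every candidate `(X, Y)` with
`gene(d) = gene(X)`, `rank(d) <= rank(X)`, `gene(a) = gene(Y)`,
`rank(a) >= rank(Y)` — the fragment crosses any junction lying between its
mates. This prevents one fusion's bridges from scattering over adjacent
exon pairs. Candidates supported only by bridges have zero SPAN evidence
and therefore can never be called on bridges alone. Unique fragment start
points, not raw read counts, feed the thresholds, collapsing PCR
duplicates.

The JCV scores bridge evidence against an expression-driven null: with
effective evidence `k_eff = sum(1 - 10^(-PQV/10))` and null rate
`lambda = max(1e-6, mispair_rate * r_x * r_y / total_pairs)` (the `r` are
confident read counts on the two exons, `mispair_rate` is estimated from
observed discordant pairs), the tail probability `P(Poisson(lambda) >=
k_eff)` is phred-scaled and clamped to 0-100. Highly expressed exon pairs
need more bridges to reach the same JCV.

# Breakpoint-bias test

For a called fusion the genomic breakpoint is modeled at the midpoint of
the intron following the last retained 5'-partner exon, normalized by gene
span from the transcription start. Under the null that breakpoints fall
uniformly within genes, the mean of `n` normalized locations has
expectation 0.5 and standard deviation `1/sqrt(12 n)`. The parametric
bootstrap (`bootstrapBiasTest`) draws 100,000 sets and reports the
fraction of simulated set means **strictly below** the observed mean; the
closed-form Irwin-Hall distribution provides an independent cross-check in
the test suite.

# The simulator

`simulateDataset()` generates a uniform-random multi-chromosome genome,
non-overlapping genes with exon/intron structure, log-normal expression,
fusion transcripts joining exons `1..r` of a 5' gene to `s..n` of a 3'
gene across all three geometric classes, and strand-specific paired-end
reads (50/25 nt mates, inserts ~ N(150, 25), optional substitution
errors). Per-pair ground truth records whether each mate could span the
breakpoint (>= 10 nt on both sides) and whether the pair bridges it. The
simulator's scope is validation of the detection machinery: it has no
repeat families, sequencing-quality model, indels, or alternative
isoforms, so it bounds sensitivity claims to idealized inputs.

# Command-line interface

`inst/scripts/sasrfuse.R` exposes `simulate`, `index`, `map`, `sasr`,
`run`, `call` and `biastest` subcommands. Outputs are plain TSV/JSON (plus
FASTA/GTF/BED for references) rather than BAM: the pipeline consumes its
own alignment tables internally, and text outputs keep the tool free of
any dependence on external alignment-format libraries. `call` re-applies
thresholds to a stored edge table without re-mapping.

# Worked example

```{r example, eval = FALSE}
cfg <- simConfig(n_genes = 8, n_fusions = 3,
                 pairs_per_transcript = 40,
                 fusion_pairs_per_transcript = 150, seed = 7)
sim <- simulateDataset(cfg)
res <- runPipeline(sim$model, sim$reads)
res$fusions[, c("donor_exon_id", "acceptor_exon_id",
                "span_unique", "bridge_unique", "classification")]
fusionBiasTest(res$fusions, sim$model, seed = 1)
```
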