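---
title: "Methods: poly(A)-tag APA analysis in patseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A)-tag APA analysis in patseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patseqr)
```

## The analysis model

Poly(A)-tag (PAT) sequencing reads each end at a transcript's
cleavage-and-polyadenylation junction, so a mapped tag, reduced to the
genomic position of its 3'-most aligned base, marks one cleavage event at
single-nucleotide resolution. `patseqr` works entirely downstream of
mapping and makes the following assumptions explicit:

1. **Internal priming.** Reverse transcription can prime on genomic
   A-tracts rather than genuine poly(A) tails. A tag is discarded when the
   sense-strand sequence in the 10 nt downstream of its cleavage
   coordinate contains a run of 8 or more A residues, or when the tag
   itself lies inside such a run (`flag_internal_priming()`). This is the
   post-hoc equivalent of masking A8 regions before mapping, which is the
   natural formulation when the pipeline starts from already-mapped tags.
2. **Sites and clusters.** Tags sharing a (chromosome, strand, coordinate)
   form a poly(A) site (PAS). Cleavage is microheterogeneous, so PASs
   within 24 nt of one another are chained into one poly(A)-site cluster
   (PAC) by single linkage: a new cluster starts only when the gap to the
   previous sorted PAS exceeds 24 nt, which means a cluster's span can
   legitimately exceed 24 nt through chaining. Dataset-level support
   filters retain PASs with >= 8 tags and PACs with >= 20 tags. We cluster
   the filtered PAS list (the "master list"); a switch (`use_filtered`)
   exposes the alternative order because the method description leaves it
   ambiguous.
3. **Gene and region context.** Because annotated 3'UTRs systematically
   end upstream of true cleavage sites, 3'UTRs are extended 200 nt
   downstream before assignment; `extension_sweep()` reproduces the
   empirical calibration of that number (counting assignable tags at
   100-400 nt extensions and stopping when the gain drops below 1%, a
   tolerance we chose since "ceased to increase" needs an operational
   definition). Items are labeled `3UTR`, `CDS`, `INTRON`, `5UTR`,
   `AMBIGUOUS` (several genes, or conflicting isoform labels within one
   gene) or `INTERGENIC`. A PAC is labeled by its representative
   coordinate — the highest-count member PAS, ties broken toward the
   3'-most member — because a single deterministic position per cluster
   makes region labels reproducible; the representative definition itself
   is our choice, as is labeling by representative rather than by a vote
   over the span.
4. **Usage statistics.** Relative usage of a PAC in a sample is its tag
   count divided by the gene's total PAC tags in that sample; only
   multi-PAC genes are informative. Between-tissue differences are means
   over replicates, aggregated per region into boxplot summaries. The
   per-gene dissimilarity (`polya_metric()`) is the total-variation
   distance, `0.5 * sum(|a - b|)`, which is 0 for identical usage and 1
   for disjoint support and satisfies the metric axioms.
5. **Differential usage.** Calls use a two-sided conditional exact
   (Fisher) test on the replicate-summed 2x2 table (PAC tags vs the
   gene's other tags, group A vs group B), BH adjustment within each
   comparison, and an adjusted p < 0.05 rule. A negative-binomial
   exon-usage GLM would model replicate overdispersion directly; we
   deliberately keep the stage self-contained and instead require the
   usage-difference sign to agree in every between-group replicate
   pairing. The guard is our overdispersion hedge: pooled counts can reach
   significance on the strength of one replicate, and the sign condition
   is what rejects those calls. The cost is conservatism for weak but
   consistent shifts.
6. **Nucleotide composition.** For one tissue, PAS counts are normalized
   per replicate to tags per million over all PASs and averaged; PASs
   with a mean of >= 2 normalized tags (we read the cutoff as applying to
   the replicate mean, as written), assigned to a gene and a concrete
   region, contribute a sense-strand window of 201 nt. Windows that would
   cross a chromosome end are dropped rather than padded. The N6A8
   control (`internal_priming_profile()`) profiles every maximal >= 8-A
   run preceded by at least 6 nt, anchored at the first A of the run —
   the pseudo-cleavage position an internally primed read would produce;
   the anchor choice is ours and is exposed as a parameter.
7. **Expression.** Gene expression is the count of tags in the extended
   gene span, transformed by + 1, quantile normalization, then log2, in
   that order, before Pearson correlation.

### Window coordinates

Window positions are labeled `-100..-1, +1..+101` with the cleavage base
at `+1` and no position 0, following the plant-polyadenylation convention
that the cleavage dinucleotide straddles -1/+1. A 201-nt window therefore
runs to +101 downstream; all signal landmarks discussed here (-20 NUE,
-1/+1 YA) are unaffected by where the downstream edge is labeled.

### Quantile-normalization ties

Ties within a column receive the mean of the rank-range means. Two
textbook properties — identical column multisets after normalization, and
idempotence — hold exactly only for tie-free columns: a tied group
collapses to a single value other columns need not contain. The tests
check oracle equivalence on tied matrices and the two properties on
tie-free ones.

## The synthetic-data generator

`simulate_genome()` / `simulate_tags()` generate the study conditions the
package is validated under: a toy genome of `n_genes` (default 50) genes
with 5'UTR - CDS - intron - CDS - 3'UTR structure on alternating strands,
three tissues x three replicates, ~100 tags per gene per sample, 1-4
PACs per gene with non-primary clusters drawn from a configurable region
mix, and a planted usage shift of Delta = 0.4 in the second tissue for
30% of multi-PAC genes (the shifted cluster loses Delta to the canonical
3'UTR cluster, mirroring the intronic-site depletion seen in root
tissue). Defaults worth noting:

- **Signal architecture.** Sites in 3'UTRs, introns and 5'UTRs carry a
  U-rich far-upstream element (-100..-31, U = 0.4), an A-rich NUE across
  -30..-15 (A = 0.8), a U-rich stretch (-10..-2, U = 0.7) and YA at
  -1/+1; CDS sites carry an (A+G)-rich composition (-40..+10) instead.
  The NUE is a flat window at least as wide as the cleavage jitter
  support on purpose: observed PAS coordinates are jittered by up to
  ±5 nt, so a flat window keeps the observed A frequency at -20 equal to
  the planted value, making motif recovery a sharp test instead of a
  smeared one. The YA dinucleotide cannot be protected the same way — it
  is a property of the exact cleavage base — so jitter dilutes it and
  recovery tests assert elevation over background, not the planted 0.9.
- **Cleavage jitter** is discrete, symmetric and bounded (±5 nt,
  sd 1.5), keeping each true cluster inside one 24-nt window.
- **Tag counts** are negative binomial (size 10) around a per-gene
  expression level drawn once per gene from a log-normal (sdlog 1). The
  log-normal dynamic range is what makes replicate correlations
  meaningful (~0.9, matching the 0.85-0.92 range reported for real
  replicate libraries); tests that state an exact per-gene depth set
  `expr_sdlog = 0`. The within-gene overdispersion value is our choice —
  the study data do not characterize it.
- **Internal priming.** 2% of tags are re-assigned to designated A8
  tracts written into the first few 3'UTRs and CDSs, placed >= 50 nt
  away from any planted cluster so that artifact and signal do not
  overlap and the flagging confusion matrix is well defined.
- **Background** composition is uniform over A/C/G/T so that signal
  recovery is not confounded by base bias; accidental A8 runs in the
  background (expected at ~1.5e-5 per position) are genuine N6A8 control
  sites, not errors.

What the generator does **not** emulate: sequencing error and adapter
artifacts (the pipeline starts from mapped tags), rRNA contamination,
isoform-specific annotation complexity (one isoform per gene), GC bias,
and the 100-fold larger scale of a real experiment. Passing tests
therefore demonstrate algorithmic correctness and statistical behavior
under controlled truth, not robustness to mapping artifacts.

## Numerical and design choices

- Internal coordinates are 1-based closed (the Bioconductor convention);
  BED is read/written 0-based half-open, GFF3 1-based closed, and both
  boundary conversions are covered by round-trip tests.
- Gene placement is strictly non-overlapping with 500-nt intergenic
  gaps; a fixed `chromosome_length` that cannot hold its genes is an
  explicit placement-overflow error.
- A 3'UTR extension colliding with a downstream same-strand gene is
  truncated at that gene's start, so no position is claimed by two genes
  through extensions alone.
- Degenerate inputs: empty tag sets error in `extension_sweep()`; a
  replicate with zero PAS tags errors in normalization; region classes
  with no retained sites yield explicitly flagged empty profiles;
  zero-variance columns yield flagged `NA` correlations.
- Multi-isoform region conflicts resolve to `AMBIGUOUS` rather than a
  precedence order, because the source material reports an ambiguous
  category without defining precedence.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at desk scale,
chosen to make every stochastic check sharp while the whole suite runs in
about a minute: 50 genes / 9 samples (~45,000 tags) for end-to-end runs,
700 genes / 3 replicates (~125,000 tags, > 4,000 retained 3'UTR PASs)
for motif recovery, 100 genes x 200 tags/gene for the power and type-I
simulations, 1,000 random instances for the clustering oracle, and
10,000 tags/gene for the law-of-large-numbers usage check.

## Known limitations

- The exact test ignores replicate overdispersion; the sign-consistency
  guard is a pragmatic hedge, not a dispersion model.
- PAC region labels depend only on the representative coordinate; a
  cluster straddling a region boundary carries one label.
- The internal-priming filter scans the tag's sense strand only.
- The A-tail read extractor uses a greedy run definition
  (>= 8 A, <= 1 mismatch by default); the underlying study does not
  specify its definition, so the parameters are exposed.
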