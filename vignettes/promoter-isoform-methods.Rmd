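---
title: "Promoter-isoform resolution regulatory analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-isoform resolution regulatory analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `promiso`, the
parameters that matter, the design choices made where several
reasonable options existed, and what the synthetic-data tests do and do
not demonstrate about real data.

## Promoter-isoform model

A *promoter-isoform* is the group of a gene's transcripts sharing a
strand-aware transcription start site (the interval start on `+`, the
interval end on `-`; all coordinates are 0-based half-open internally,
converted exactly once at the GTF/VCF boundary). Promoters are ranked
1..k in transcription direction, so rank 1 is the 5′-most promoter and
"non-5′" means rank > 1.

The grouping key is the TSS coordinate alone, not the full first exon:
transcripts with identical starts but different first-exon ends share a
promoter. This matches how the promoters are quantified — by the union
of their members' first-intron junctions — which such transcripts
contribute to jointly. When a promoter has several member transcripts
we label it with the lexicographically smallest `transcript_id` rather
than an arbitrary pick, so output tables are reproducible run to run.

**Identifiability.** Junction-based quantification fails when a
promoter's first-intron junction cannot be told apart from splicing
inside another isoform. A promoter is `internal` when any edge (donor
or acceptor) of any member's first-intron junction coincides with a
non-first intron edge of another transcript of the same gene;
single-exon-only promoters have no junctions at all. Both are flagged
non-quantifiable. The comparison is within-gene only: cross-gene
coordinate coincidences are not treated as ambiguity, since the rule
models isoform-versus-isoform confusability. Promoters whose TSS
coincides across *overlapping genes* are likewise kept per-gene rather
than merged; merging them would require a gene-model authority the
input annotation does not provide.

**Quantification.** A promoter's count in a sample is the sum of
junction reads over its first-intron junction set. A junction claimed
by two retained promoters (possible after TSS-based grouping) is
counted for *neither* and reported, preserving the unique-read
contract; affected promoters keep a zero row. Junction table rows
matching no promoter are tallied as unassigned. The differential
analysis uses uniquely identifiable promoters only; the
enhancer-linking stage includes `internal` promoters as well (their
promoter activity is still informative even if their counts absorb
read-through), via `quantify_promoters(exclude_nonunique = FALSE)`.

## Normalization and detection

Counts are normalized with trimmed-mean-of-M-values scaling (reference
sample: upper-quartile fraction closest to the mean; trims M = 0.30,
A = 0.05; inverse-binomial precision weights — the canonical recipe,
computed by edgeR and cross-checked in the tests against an
independently coded trimming oracle at 1e-6), with factors rescaled to
geometric mean 1, and expressed as CPM against factor-adjusted library
sizes. Detection filters: genes and OCRs need ≥ 1 CPM in ≥ 20% of
samples; promoter-isoforms ≥ 2 CPM in strictly more than 40%. The
sample universe for the promoter filter is the full input matrix by
default; a caller can pass any sample subset instead. CPM uses a 0.5
pseudo-count only inside log transforms, never for filtering or
activity rules.

The *major promoter* of a gene is the promoter-isoform with the highest
mean CPM (mean, not median: with modest per-region sample counts the
mean is the lower-variance summary and keeps ties rare), ties breaking
toward the smaller rank; a `samples` argument yields per-region major
promoters.

## Differential engine

Each feature is fit by weighted least squares on `log2(CPM + 0.5)` with
the contrast group, the donor as a fixed blocking factor, and any
requested covariates. Precision weights follow an inverse mean–variance
trend: a LOWESS curve of residual sqrt-SD against mean log2-CPM from an
initial unweighted fit, evaluated at each observation's fitted value,
weighted as trend^-4. This is a deliberate, documented simplification
of a mixed-model/voom pipeline: with donors as a fixed blocking factor
the downstream statistics (log2FC, p) behave equivalently at this
design scale, and the engine stays dependency-free and fast. It does
not estimate random-effect variance components, so designs with many
repeated measures per donor and strong donor-by-region interactions
would be better served by a mixed model.

Covariates collinear with the design are dropped with a warning; a
collinear *group* term is an error. Zero-variance features get p = 1,
log2FC = 0. P-values are BH-adjusted within contrast; the
region-specificity call re-pools p-values across all supplied contrasts
("global FDR") before requiring a feature to win *every* pairwise
comparison against the other regions with the fold change in its
favor.

**Storey's π1** estimates the proportion of non-null tests:
π0(λ) = #{p > λ}/((1−λ)n) on the grid λ = 0.05..0.95 (step 0.05),
smoothed by a cubic smoothing spline (df = 3), evaluated at the largest
λ, clamped to [0, 1]; π1 = 1 − π0. With fewer than 5 usable grid
points the fixed-λ = 0.5 estimate is used. The π1 matrix over region
pairs is a dissimilarity: ~0 for exchangeable regions, approaching 1
when most features differ.

**Isoform-specific differential calls** select promoter-isoforms with
FDR < 0.05 whose parent gene is either not nominally significant
(p > 0.1) or has the opposite fold-change sign (strict inequality; a
zero gene log2FC counts as neither sign). Both p-values must come from
this engine so the gene and isoform tests are comparable. Promoters
without a parent-gene row are skipped and counted, never called.

## Activity-by-contact links

Per region, a promoter is *active* iff CPM > 1 in ≥ 20% of that
region's samples (the per-region reading; a caller can pool samples
instead) **and** an open-chromatin peak lies within 1 kb of its TSS.
Element activity is the mean ATAC CPM across the region's samples —
accessibility only, matching the package's input set; no H3K27ac
geometric mean is implemented. Elements overlapping any promoter window
are `promoter_proximal`, the rest `distal`.

Contact comes from a binned intra-chromosomal map. Observed bin pairs
are returned as stored; absent or zero pairs fall back to a power law

C(d) = C100 · ((d + res) / (10^5 + res))^(−γ)

scaled so the fallback equals the map's mean contact at a 100 kb
reference distance (C100 = 1 on an empty map). γ defaults to 1 and is a
configuration parameter — the fallback and its default are this
package's plumbing choices, not values taken from any particular
dataset. Same-bin queries return a self-contact convention value (the
maximum of the map's largest count and the fallback at distance zero)
so the diagonal dominates; trans-chromosomal queries return 0 with a
warning, and Hi-C matrix normalization (ICE/KR) is out of scope — maps
are consumed as already normalized.

ABC scores normalize activity × contact over *all* candidate elements
within ± 5 Mb of the TSS — including the promoter's own proximal
elements, the canonical normalization — and links at or above 0.02 are
emitted with their kind flag. Cross-region sharing statistics use the
link identity (element_id, promoter_id) on a shared element universe,
so peaks must be merged across regions before scoring if region-private
peak sets exist; score correlations are Spearman over links present in
both regions. Gene-level link tables collapse promoter links per
(element, gene) by maximum ABC.

## Fine-mapping

SNPs (1-based input positions) with PIP > 0.01 are intersected with
link elements (distal only by default). ABC-Max keeps, per SNP and
region, the link with maximal ABC; ties break by smaller TSS distance,
then lexicographic promoter id, making assignment deterministic and
order-invariant. Per-region application mirrors region-resolved target
maps — one SNP may nominate different genes in different regions — and
a global-max mode is available behind `per_region = FALSE`. Genes
aggregate to promoter classes 5′ / non-5′ / both. Closest genes
minimize TSS distance with deterministic tie reporting; lead-SNP
windows flank GWAS hits by 10 kb, merge overlaps, and keep the lowest
p-value. Priority scores are consumed as a per-gene table with rank
percentiles computed over all scored genes. Score comparisons between
non-5′ targets, 5′ targets, and closest genes use the one-tailed
rank-sum (unpaired) mode because these gene sets have unequal sizes;
`wilcoxon_one_tailed()` requires the paired/unpaired choice explicitly
so a signed-rank test is never silently applied to unpaired sets.

## Validation operators

Fisher enrichment is the exact hypergeometric upper tail with the
sample odds ratio (infinite when b·c = 0). The Wilcoxon implementation
uses the exact null up to n = 25 without ties and the
continuity-and-tie-corrected normal approximation otherwise; zero
differences are dropped by default with Pratt's zero-inclusive variant
behind a flag. Spearman is the Pearson correlation of mid-ranks.
External link validation flanks elements by 500 bp, expands reference
variants with LD proxies at r² > 0.8 (proxies inherit the lead's target
gene), counts a link as validated when an intersecting variant targets
the link's gene, divides by links whose flanked element intersects any
reference position, evaluates 5′ and non-5′ links separately, and
compares each region against the pooled others by one-tailed Fisher.

## Synthetic data: what it emulates, and what it does not

The generator defines the package's reference study conditions: 50
genes on one chromosome (200 kb spacing), 1–3 promoters per gene 6 kb
apart (so each TSS owns a 5 kb contact bin), 3 regions × 4 donors × 2
replicates, negative-binomial junction counts (dispersion 0.1, a
typical bulk overdispersion) with lognormal donor effects (SD 0.2) and
library factors (SD 0.25). Planted structure: 20% of genes switch one
low-share promoter by log2FC 2 in one region with the gene total held
constant (the compensating promoters move oppositely — the classic
two-isoform switch); 20% of multi-promoter genes have a rank-2 major
promoter at triple the rank-1 weight; 10% carry an internal promoter
and 8% are single-exon. Each gene has 3 distal enhancers on distinct
5 kb contact bins (20–60 kb from the TSS); 30% of genes get one planted
loop (designated enhancer × designated promoter, non-5′ for ~60% of
multi-promoter loop genes) boosted 10-fold over the power-law baseline.
Causal SNPs (30% of 40) land in loop enhancers — preferentially non-5′
ones, whose genes also receive a +2 SD priority-score shift — and the
rest in intergenic background, with some PIPs below the 1% threshold to
exercise the filter.

Giving every gene several exchangeable enhancers makes the no-loop
null meaningful: with the contact multiplier at 1 the designated
enhancer should rank first among the gene's distal links at roughly the
uniform share 1/3, which is exactly what the null acceptance test
checks.

Real data differ in ways the generator deliberately omits: GC and
mappability bias, correlated peak/expression noise, LD structure,
trans contacts, annotation errors, and cell-type mixtures. Passing the
recovery tests therefore demonstrates the *algorithms* are correct and
well-calibrated at realistic noise levels, not that any particular
biological dataset will reach the same sensitivity.

A separate constructed scenario (`sim_isoform_case()`) checks the
discriminating behavior the isoform resolution exists for: a SNP inside
an enhancer looped only to a gene's rank-3 promoter, with a decoy
gene's TSS much nearer, must be assigned to the true gene as
non-5′ and flagged not-closest — a gene-level closest-gene assignment
gets this case wrong by construction.

## Numerical choices and degenerate inputs

* Tie-breaks are everywhere deterministic (rank, then position, then
  lexicographic id) so identical inputs give byte-identical outputs;
  the pipeline manifest hashes every stage table to verify this.
* The π0 spline falls back to the fixed-λ estimator rather than
  erroring on short grids; π1 is always clamped to [0, 1].
* BH adjustment is monotone, capped at 1, and never below the raw
  p-value; note that re-applying BH to an already-adjusted vector is
  *not* an identity in general (tied adjusted groups can be lifted by a
  second pass), so the package treats adjusted vectors as terminal.
* An all-zero contingency table, an empty p-value vector, an empty
  reference set, a zero-library sample, and a region without samples
  are errors; a constant vector in Spearman and an empty Jaccard union
  return NA / 0 with a warning.
* Problem sizes in the tests and the acceptance script (50-gene
  bundles, 5,000-p-value calibration with 100 replicates, 20-seed null
  and discriminating-case loops) were chosen as the smallest designs at
  which the planted effects are comfortably identifiable; they run in a
  few minutes on a single CPU.

## Known limitations

* The differential engine is fixed-effects only (see above).
* Activity uses ATAC alone; no H3K27ac or geometric-mean variant.
* Contact maps are intra-chromosomal and consumed as normalized.
* Statistical fine-mapping itself (PIP computation), LD estimation,
  heritability partitioning, and pathway enrichment are out of scope;
  their outputs are consumed as inputs where relevant.
* The closest-gene baseline uses promoter TSSs from the supplied
  annotation only; unannotated genes are invisible to it.
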