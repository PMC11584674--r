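# promiso

Gene regulation analysis at **promoter-isoform resolution**. Most genes
have several alternative transcription start sites; the transcripts
sharing one TSS form a *promoter-isoform*, and these — not whole genes —
are the units that enhancers contact and that disease-associated
regulatory variants perturb. `promiso` implements an end-to-end pipeline
for tissue-region panels of RNA-seq splice-junction counts, ATAC-seq
open-chromatin peaks, and Hi-C contacts:

1. **Annotation** — group transcript models by strand-aware TSS into
   ranked promoter-isoforms (rank 1 = 5′-most), classify which are
   uniquely identifiable from junction reads (promoters whose
   first-intron junction edges coincide with non-first introns of other
   isoforms are `internal` and not quantifiable), and attach
   promoter-proximal open-chromatin peaks (TSS ± 1 kb).
2. **Quantification** — promoter-isoform expression as the sum of reads
   over its unique first-intron junctions; TMM normalization and CPM;
   detection filters (genes/OCRs: ≥ 1 CPM in ≥ 20% of samples;
   promoter-isoforms: ≥ 2 CPM in > 40%); major-promoter calls
   (a gene's major promoter may be non-5′).
3. **Differential statistics** — per-feature weighted least squares on
   log2(CPM + 0.5) with donor blocking and mean–variance precision
   weights; BH FDR; Storey's π1 as a pairwise region dissimilarity;
   region-specificity calls (significantly higher in *all* pairwise
   comparisons at global FDR); and promoter-isoform-specific
   differential calls (isoform FDR < 0.05 while the parent gene is null,
   nominal p > 0.1, or changes in the opposite direction).
4. **Enhancer–promoter links** — the activity-by-contact (ABC) model per
   region and per promoter-isoform:
   `ABC(e, p) = A(e) · C(e, p) / Σ_e′ A(e′) · C(e′, p)` over all
   candidate elements within ± 5 Mb of the TSS, with ATAC CPM as
   activity, observed Hi-C contact with a power-law distance fallback,
   and a 0.02 score threshold; cross-region link sharing, uniqueness and
   Spearman score correlations.
5. **Fine-mapping** — ABC-Max assignment of fine-mapped GWAS variants
   (PIP > 1%) to the promoter-isoform with the maximal ABC score among
   links whose enhancer contains the variant; 5′ / non-5′ / both
   promoter-type classification, closest-gene context, 10 kb lead-SNP
   windows, and priority-score comparisons.
6. **Validation operators** — one-tailed Fisher enrichment, one-tailed
   Wilcoxon tests, tie-aware Spearman, basepair Jaccard, and external
   link validation with 500 bp flanks and LD proxies (r² > 0.8).
7. **Synthetic data** — a seeded generator with planted ground truth
   (region-switching promoters, non-5′ major promoters, enhancer loops,
   causal SNPs) so every stage is testable end-to-end.

Everything is tidyverse-native: functions take tibbles, return tibbles,
and chain with the pipe; fitted containers have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(promiso)
library(dplyr)

# seeded synthetic inputs with planted truth
bundle <- simulate_bundle(sim_config(seed = 1))
res <- run_pipeline(bundle)

res$promoters |> count(class)
#> # A tibble: 3 × 2
#>   class                n
#>   <chr>            <int>
#> 1 internal             2
#> 2 single_exon_only     2
#> 3 unique             109

res$major_calls |> summarise(frac_non5_major = mean(!is_5prime))
#> # A tibble: 1 × 1
#>   frac_non5_major
#>             <dbl>
#> 1           0.125

truth_report(res, bundle$truth)
#> # A tibble: 5 × 3
#>   metric                     value     n
#>   <chr>                      <dbl> <int>
#> 1 switching_sensitivity       1       10
#> 2 switching_precision         1       47
#> 3 loop_recovery               1       15
#> 4 causal_assignment_accuracy  1       12
#> 5 nonfive_major_accuracy      1        6
```

The 113 promoters group 333 exon records into ranked promoter-isoforms;
109 are uniquely identifiable from junction reads. `truth_report()`
shows that at the default planted effect sizes the pipeline recovers
every region-switching promoter (isoform significant while the gene is
null or discordant), ranks every planted enhancer loop first at
ABC ≥ 0.02, and assigns every planted causal SNP to its true gene with
the correct 5′/non-5′ promoter type. 12.5% of genes have a non-5′ major
promoter, matching the generator's plant.

Single pieces compose just as well, e.g. a pairwise region
dissimilarity heatmap:

```r
pi1 <- pairwise_dissimilarity(res$expr_gene, bundle$meta)
autoplot(pi1)
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/annotation.R` | promoter grouping, identifiability, OCR assignment |
| `R/quant.R` | junction quantification, TMM/CPM, filters, major promoters |
| `R/diffstats.R` | WLS differential engine, BH, Storey π1, specificity |
| `R/abc.R` | activity, contact model, ABC scores, link sharing |
| `R/finemap.R` | SNP overlap, ABC-Max, closest gene, lead windows |
| `R/validation.R` | Fisher/Wilcoxon/Spearman/Jaccard, link validation |
| `R/synthdata.R` | generator, planted truth, recovery report |
| `R/io.R`, `R/pipeline.R` | GTF/TSV/BED readers and writers, orchestration |
| `vignettes/promoter-isoform-methods.Rmd` | model and design notes |
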