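# chipislands

Differential H3K4me3 epigenomics for postmortem brain specimens whose RNA
is too degraded for transcriptome profiling.

Long postmortem intervals fragment RNA (RIN values below ~7) and rule out
expression studies on a large share of archived brain tissue, but the
promoter-associated histone modification H3K4me3 remains detectable by ChIP
for up to about 72 h. `chipislands` implements the downstream analysis that
turns per-sample extended-fragment ChIP-seq tags into biological
conclusions under that design:

* **Island calling.** The genome is scored in fixed windows (200 bp
  default). With `N` tags on an effective genome of length `L`, the window
  background is Poisson with rate `lambda = N * w / L`. Windows whose count
  `k` has tail `P(X >= k; lambda) < p_w` are *eligible*, eligible windows
  separated by at most a gap `g` (600 bp default) are chained into an
  island, and each island's significance is the Poisson tail of its total
  tag count against `lambda` scaled to its span. Benjamini–Hochberg
  correction across islands is applied per sample and islands with
  `FDR < 1e-10` are kept.
* **Normalization** by random downsampling of every library to the tag
  count of the smallest sample, before any interval is called.
* **Merged regions**: the transitive closure of island overlap across
  samples, spanning from the most upstream member start to the most
  downstream member end, with per-sample presence, group Venn partitions
  (exclusive/shared active regions), per-chromosome counts and pairwise
  overlap QC.
* **Annotation** of regions (by strand-aware midpoint) into proximal
  (0–1 kb) / distal (1–3 kb) promoters, 5'UTR / exon / intron / 3'UTR,
  proximal/distal downstream and distal intergenic, plus matched
  random-control peaks, and gene association within 10 kb.
* **Differential activity**: promoter (TSS ± 1 kb) and length-corrected
  gene-body tag densities per sample; group means; ratio on pseudocounted
  densities with a `>= 1.5`-fold **and** Welch `p < 0.05` filter.
* **Profiles**: strand-aware tag-density matrices over gene bodies
  (± 2 kb, meta-scaled), merged regions (± 5 kb) and promoters (± 1.5 kb),
  5-cluster k-means heatmap ordering, average plots, and the
  between-group scatter QC (Pearson r, OLS slope).
* **Motif frequency**: JASPAR-format PFMs scored as min–max-normalized
  log-odds on both strands of island sequences with 200 bp flanks,
  reported as average binding sites per interval.
* **ChIP-qPCR statistics**: percent input, fold over a gene-desert
  negative region, one-way ANOVA with Bonferroni post-hoc across
  postmortem intervals, and log-scale decay slopes per antibody.

Because studies of this kind rarely deposit raw reads, the package ships a
first-class synthetic-data generator (`simulate_genome()`,
`simulate_truth()`, `simulate_tags()`, `plant_motif_sites()`,
`simulate_qpcr()`) that plants known promoter enrichment, group fold
changes, motif occurrences and postmortem signal decay, together with a
machine-readable truth record, so every stage is testable end to end.

## Worked example

```r
library(chipislands)

gen   <- simulate_genome(n_chroms = 1, chrom_length = 2e6, n_genes = 80, seed = 1)
truth <- simulate_truth(gen$genes, n_enriched = 40, n_differential = 10,
                        enrichment_factor = 10, differential_fold = 3, seed = 1)
tags  <- simulate_tags(gen$layout, gen$genes, truth,
                       n_samples_per_group = 3, depth = 5e4)
truth <- attr(tags, "truth")

norm <- downsample_tags(tags, seed = 1)
norm[[1]]
#> tag_set 'A1' (group A): 49717 fragments

islands <- lapply(norm, function(ts)
  call_islands(bin_tags(ts, gen$layout, bin_size = 200),
               gap = 600, fdr_cutoff = 1e-10))
names(islands) <- sapply(norm, `[[`, "sample_id")
groups <- setNames(sapply(norm, `[[`, "group"), names(islands))
head(islands$A1, 3)
#>   chrom  start    end tag_count    score             p           fdr
#> 1  chr1  42000  44000       324 146.2118 6.140291e-147 8.987153e-146
#> 2  chr1  76000  78400       332 130.7885 1.627268e-131 1.587819e-130
#> 3  chr1 176400 179200       360 132.3880 4.093007e-133 4.251446e-132

merged <- merge_regions(islands, groups)
merged
#> merged_regions: 39 regions across 6 samples (A/B)
group_venn(merged)
#> exclusive_A exclusive_B      shared
#>           0           0          39

round(feature_pie(annotate_regions(merged$regions, gen$genes)), 3)
#>   proximal_promoter     distal_promoter      five_prime_utr                exon
#>               0.538               0.000               0.436               0.000
#>              intron     three_prime_utr proximal_downstream   distal_downstream
#>               0.026               0.000               0.000               0.000
#>   distal_intergenic
#>               0.000

sig <- do.call(rbind, lapply(norm, quantify_signal, gen$genes, "promoter"))
dc  <- differential_call(sig, groups)
head(dc[, c("target_id", "mean_A", "mean_B", "ratio", "p", "passes_filter")], 4)
#>   target_id mean_A mean_B ratio        p passes_filter
#> 1  gene0024    172    496  2.87 3.95e-06          TRUE
#> 2  gene0077    180    490  2.72 7.86e-06          TRUE
#> 3  gene0065    174    491  2.82 2.01e-05          TRUE
#> 4  gene0031    182    481  2.64 4.82e-05          TRUE

sum(dc$passes_filter[match(truth$differential_genes, dc$target_id)])
#> [1] 10   # all 10 planted differential genes recovered
```

All 40 enriched promoters produce FDR-significant islands in every sample,
the merged regions sit almost entirely in proximal promoters and 5'UTRs
(the planted geometry), and the 1.5-fold + Welch filter recovers the ten
planted 3-fold genes with mean densities near the planted ratio.

The whole study — simulation, tracks, normalization, calling, merging,
annotation, differential, profiles, motif scan, qPCR statistics — also
runs as one call with a YAML-configurable parameter set:

```r
res <- run_pipeline(default_config(), "run1")
res$summary$differential_sensitivity
```

or from a shell via the thin wrapper
`Rscript inst/scripts/run_pipeline.R --config cfg.yaml --seed 1 --outdir run1`.

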