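# apaflow

Alternative polyadenylation (APA) analysis for 3'-end-enriched RNA-seq.

Most human genes carry more than one polyadenylation site (PAS); switching
between a proximal and a distal site changes the 3'UTR length of the
transcript, and tumors systematically favour the proximal site (3'UTR
shortening). `apaflow` implements the full analysis chain for detecting and
interpreting these switches from 3'-end-enriched libraries (QuantSeq
REV-style protocols, where each read is antisense to the transcript and its
5' terminus marks the cleavage locus):

1. **PolyA-site atlas** — cleavage-locus extraction from alignments,
   removal of internal-priming artefacts (a run of more than 6 consecutive
   As, or more than 8 As in any 10-nt window, in the ±10 nt around the
   locus), a polyadenylation-signal requirement (one of 18 hexamers
   starting in the \[-30, -10\] window upstream), ±5 nt clustering of
   cleavage signal, and greedy selection of dominant sites at least 125 nt
   apart.
2. **Annotation** — assignment of sites to genes with a downstream
   extension (5 kb, or half the intergenic gap when genes are closer than
   10 kb), location classification (3'UTR / exon / intron), and
   proximal/distal pair typing (same-exon, composite-exon, skipped-exon).
3. **Quantification** — abundance filters (presence in ≥25% of samples,
   ≥10 reads per tissue group, ≥5% of the gene's major site), the polyA
   site index

   `PSI = proximal / (proximal + distal)`      (higher PSI = shorter 3'UTR)

   per gene and sample, ΔPSI = PSI(tumor) − PSI(normal) over matched
   pairs, per-gene paired Wilcoxon switch tests under Benjamini–Hochberg
   FDR control, and PSI–expression Spearman correlation with a
   column-permutation empirical null.
4. **Indices** — polyadenylation-machinery activity (per-sample median
   z-scored expression over a machinery gene set), PSI-load (per-sample
   median PSI), PSI-load fold changes by driver-gene mutation status,
   read counting between proximal and distal sites, miRNA binding-site
   loss, mRNA–protein concordance contrasts, and PDUI→PSI conversion
   (PSI = 1 − PDUI).
5. **Prognostic modelling** — lasso Cox feature selection over gene PSI
   (covariates unpenalized), the prognosis index

   `PI_k = Σ_i β_i · χ_ik`

   (β = Cox log-hazard coefficient of gene i, χ = its PSI in sample k),
   leave-one-out cross-validation, median-split risk groups and the
   two-sided log-rank test.
6. **Synthetic data** — a generator that plants a genome, annotation,
   REV-protocol alignments, expression, mutation and survival tables with
   known ground truth, so every stage is testable without external data.

All user-facing functions take tibbles first and return tibbles; fitted
objects have `tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

```r
library(apaflow)

cfg <- apa_sim_config(n_genes = 40, n_decoys = 8)
gen <- generate_genome_annotation(cfg, seed = 3)
sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 12, depth = 200),
                      seed = 4)
run <- run_apa_pipeline(sim$alignments, gen$genome, gen$models,
                        sim$metadata)
run$atlas$log
#>                     events_in loci_removed_internal_priming
#>                        197328                            57
#>                      clusters            removed_no_hexamer
#>                            58                             0
#>               removed_spacing                     sites_out
#>                             0                            58
```

All 58 planted sites (40 genes, 18 of them with a proximal/distal pair)
come through the filters; the 8 A-rich decoy loci are removed as
internal-priming artefacts (57 removed raw loci = decoys plus their ±5 nt
jitter neighbours). The run summary reports the bookkeeping:

```r
print(run$summary, n = 8)
#> # A tibble: 21 × 4
#>   metric                numerator denominator value
#>   <chr>                     <dbl>       <dbl> <dbl>
#> 1 n_sites                      NA          NA    58
#> 2 n_genes                      NA          NA    40
#> 3 n_multi_site_genes           NA          NA    18
#> 4 pct_multi_site               18          40    45
#> 5 n_shortened                  NA          NA     8
#> 6 n_lengthened                 NA          NA     0
#> 7 n_switched                   NA          NA     8
#> 8 pct_switched_of_multi        8          18    44
```

45% of the genes are multi-site and 8 of the 18 testable genes are called
shortened at q < 0.05 — exactly the genes the generator planted with a
positive ΔPSI of 0.3. Downstream:

```r
sw <- run$switches                       # per-gene statistics
autoplot(sw)                             # delta-PSI vs -log10 q
load <- psi_load(run$psi)                # per-sample shortening index
```

Prognostic modelling, at a cohort scale (98 tumor samples, two genes
planted with non-zero Cox coefficients among 28 nulls):

```r
cfg2 <- apa_sim_config(n_genes = 30, multi_site_frac = 1,
                       n_prognostic = 2, prognostic_beta = 3,
                       psi_subject_sd = 0.2, n_decoys = 0)
gen2 <- generate_genome_annotation(cfg2, seed = 6)
sim2 <- simulate_reads(gen2$truth, apa_sim_design(n_pairs = 98, depth = 0),
                       seed = 7)
tum  <- subset(sim2$metadata, tissue == "tumor")$sample_id
cl   <- simulate_clinical(gen2$truth, sim2$psi_true, seed = 8,
                          sample_ids = tum)
psi2 <- sim2$psi_true[, c("gene_id", tum)]
sel  <- select_features_lasso(psi2, cl, seed = 9)
sel
#> [1] "G0001" "G0002"    # exactly the two planted prognostic genes

cv     <- loocv_prognostic_index(psi2, cl, genes = sel)
strata <- stratify_and_logrank(cv, cl)
glance(strata)
#> # A tibble: 1 × 6
#>   chisq        p    hr hr_lo hr_hi orientation
#>   <dbl>    <dbl> <dbl> <dbl> <dbl> <chr>
#> 1  14.1 0.000176 0.335 0.184 0.610 as-published
autoplot(strata)                         # Kaplan-Meier curves by risk group
```

The median split separates survival strongly (log-rank p = 1.8e-4). Note
the `as-published` label orientation calls samples with PI *above* the
median "low" risk, matching the source cohort's description; the reported
HR below 1 is the same separation seen from the inverted labelling —
use `orientation = "conventional"` for the usual convention.

## Vignette

`vignettes/apa-methods.Rmd` describes the model and the procedure in
detail: window and threshold conventions, tie-breaking rules, what the
synthetic generator does and does not emulate, and the design decisions
taken where the methodology was open.
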