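---
title: "Alternative polyadenylation analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alternative polyadenylation analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaflow)
```

# The problem

Cleavage and polyadenylation fix the 3' end of a transcript. When a gene
carries several polyadenylation sites (PAS), the choice between a proximal
and a distal site sets the 3'UTR length, and with it the complement of
miRNA binding sites and RNA-binding-protein docking regions the mature
transcript carries. Tumors shift usage toward proximal sites — global
3'UTR shortening — and the degree of shortening carries prognostic
information. `apaflow` detects polyA sites from 3'-end-enriched RNA-seq,
quantifies proximal usage per gene and sample, tests tumor--normal usage
switches, and builds usage-based prognostic models.

This vignette documents the models, the coordinate and threshold
conventions, the synthetic-data generator used to validate every stage,
and the decisions taken where the methodology was genuinely open.

# Coordinates and strand conventions

All internal coordinates are 0-based half-open on the genomic forward
strand; GTF I/O converts from and to 1-based inclusive at the boundary,
BED is native. Cleavage events live on the *transcript* strand. Window
offsets around a cleavage locus are expressed in transcript orientation —
offset 0 is the cleavage locus, negative offsets are upstream (5') — and
the sequence inside a window is read on the transcript strand, i.e.
reverse-complemented for minus-strand events.

For REV-protocol libraries the read is antisense to the transcript and
sequencing starts at the polyA junction, so the cleavage locus is the
terminal *aligned* base at the read's 5' end: the maximum genomic
coordinate of the aligned span for a minus-strand alignment, the minimum
for a plus-strand alignment. Soft-clipped bases never contribute to the
span. A forward-protocol mode (`protocol = "fwd"`) takes the read's 3'
terminus on its own strand instead.

# Atlas construction

The atlas stage runs in a fixed order; each step logs counters and removal
reasons so every filter is auditable.

1. **Extraction** collapses alignments to cleavage events, summing counts
   at identical (chromosome, transcript strand, position, sample).
2. **Internal priming.** Oligo-dT priming at genomic A-rich stretches
   fabricates cleavage signal. An event is removed iff the 21-nt window
   spanning offsets $[-10, +10]$ contains a run of $\ge 7$ consecutive As
   ("more than 6") or any 10-nt subwindow with $\ge 9$ As ("more than 8
   sparse As"). Windows truncated by a chromosome edge are evaluated on
   the available bases. This filter acts on *raw events*, because the
   artefact is positional.
3. **Clustering.** Cleavage is not nucleotide-exact, so pooled
   (across-sample) signal is clustered greedily: seed at the unassigned
   position with the highest pooled count, absorb all unassigned
   positions within $\pm 5$ nt, repeat. The absorption is one-pass (a
   position absorbed by a stronger seed can no longer seed); whether the
   radius should instead be applied iteratively to convergence is not
   specified by the protocol this follows, and one-pass is the
   implemented, documented choice. The cluster's per-sample counts are
   sums over members; the representative is the seed.
4. **Hexamer requirement.** A site is retained iff one of 18
   polyadenylation-signal hexamers (canonical AATAAA first; the catalogue
   is an argument and therefore configurable) starts at an offset
   $s \in [-30, -10]$. The annotated signal is chosen by catalogue
   priority, then by the most site-proximal offset. The criterion is
   applied to *cluster representatives*, not raw events: jittered members
   of a true site should not be discarded one by one for missing a window
   they sit 3 nt away from. Roughly a fifth of true human polyA sites
   lack a canonical hexamer and are knowingly missed by this design.
5. **Spacing.** Dominant sites are selected greedily by descending pooled
   count, accepting a cluster only if its representative is $\ge 125$ nt
   from every accepted representative on the same chromosome and strand.

Tie-breaks everywhere are: higher count first, then the 5'-most position
in transcript orientation. This makes every stage deterministic.

# Gene assignment and pair typing

Because 3'UTR annotation is incomplete, each gene is extended past its
annotated 3' end by 5 kb, or by half the intergenic gap when the nearest
downstream gene begins closer than 10 kb; the neighbour search ignores
strand by default (configurable to same-strand-only), and extensions clip
at chromosome bounds. A site is assigned to a gene when it falls inside
the extended span on the matching strand; among several candidates the
nearest annotated 3' end wins, then the smaller gene id.

Location classes follow the precedence 3'UTR > exon > intron >
downstream-extension; in summary tables the downstream-extension sites are
pooled with the 3'UTR bucket, since they are putative unannotated 3'UTR.

For genes with more than two retained sites, the proximal/distal pair is
the 5'-most and 3'-most site in transcript orientation — the pairing that
matches the PSI definition's two-term denominator. Pairs are typed by
splice architecture:

* **same-exon** — some single transcript has one exon containing both
  sites;
* **skipped-exon** — the proximal site lies in an exon that is fully
  spliced out (intronic) in a transcript containing the distal site;
* **composite-exon** — the proximal site lies in an exon extending past a
  5' splice donor used by a distal-containing transcript.

Precedence is same > skipped > composite. Annotated isoforms do not always
determine a class; pairs matching no rule are labelled composite-exon and
flagged `unclassified` rather than silently forced. Both the location and
the pair-type logic are verified exactly against a brute-force per-base
oracle on 1,000 randomized gene models in the test suite.

# Quantification and switch testing

Site-level counts pass three abundance filters, in order and with logged
reasons: presence (non-zero in $\ge 25\%$ of samples), group count
($\ge 10$ summed reads in the tumor group *and* in the non-involved
group — the conservative reading of "in either"), and minor fraction
($\ge 5\%$ of the gene's best-supported surviving site).

The polyA site index for gene $g$ in sample $s$ is

$$\mathrm{PSI}_{gs} = \frac{\text{proximal reads}}{\text{proximal reads} + \text{distal reads}},$$

missing when the denominator is zero; higher PSI means shorter 3'UTR
usage. $\Delta\mathrm{PSI} = \mathrm{PSI}_{tumor} - \mathrm{PSI}_{normal}$
over subject-matched pairs, so positive values are shortening; the
per-gene summary is the median over complete pairs.

Switches are tested per gene with a two-sided paired Wilcoxon signed-rank
on the matched PSI values (exact when ties permit, normal approximation
otherwise; all-zero differences give $p = 1$ by convention), requiring at
least 10 complete pairs, with Benjamini--Hochberg adjustment across tested
genes. A gene is *shortened* when $q < 0.05$ and its median
$\Delta\mathrm{PSI} > 0$, *lengthened* for the negative direction,
*unchanged* otherwise. A paired rank test on PSI was chosen as a defined,
dependency-light replacement for exon-level negative-binomial differential
usage machinery; the negative-binomial GLM route is explicitly out of
scope. Calibration is checked empirically: on a 70% null / 30% planted
($|\Delta\mathrm{PSI}| = 0.3$, 20 pairs, ~200 reads per gene and sample)
cohort the suite requires sensitivity $\ge 0.8$ and empirical FDR
$\le 0.10$ at $q < 0.05$, and on an all-null cohort per-gene p-values that
pass a Kolmogorov--Smirnov uniformity check.

Gene-wise PSI--expression association uses Spearman correlation over
shared samples ($\ge 10$). The cohort-level statistic — the number of
genes with $\rho$ beyond a threshold (default $\rho > 0.1$, one-sided; an
absolute-value mode exists because "beyond 0.1" is ambiguous) — gets an
empirical p-value by shuffling the *columns* of the PSI matrix jointly
across genes, preserving gene--gene correlation, which is the natural
reading of shuffling the APA matrix; a per-gene independent shuffle is
available as an option. The add-one (permutation-inclusive) convention
$p = (1 + \#\{S_{perm} \ge S_{obs}\})/(B + 1)$ avoids zero p-values.

# Indices

* **PA machinery activity** — per machinery gene, expression z-scored
  across samples (constant genes get $z = 0$); per sample, the median z
  over the set. The gene list is data, not code: pass the catalogue
  (e.g., CPSF/CSTF-pathway members) as an argument.
* **PSI-load** — the per-sample median of defined PSI values, a global
  shortening index; the mean is a config alternative. The median was
  chosen for robustness and because group-level summaries of the load are
  themselves medians.
* **Mutation fold change** — per driver gene,
  $FC = \mathrm{median}(\text{load} \mid \text{mutated}) / \mathrm{median}(\text{load} \mid \text{wildtype})$
  with a two-sided Wilcoxon rank-sum p and BH correction; flagged when
  $q < 0.1$ and $|FC - 1| > 0.1$. Whether the published FC gate meant
  $FC > 1.1$ or $|\log FC| > \log 1.1$ is ambiguous; $|FC - 1| > 0.1$ is
  implemented and documented.
* **Interval counting** — reads between the proximal and distal site are
  counted under any-overlap semantics by default (full containment as an
  option); the same any-overlap rule counts miRNA binding sites lost in a
  shortened region.
* **PDUI conversion** — external distal-usage matrices convert by
  $\mathrm{PSI} = 1 - \mathrm{PDUI}$, preserving missingness and
  rejecting out-of-range values with coordinates.

# Prognostic modelling

Feature selection is a single multivariate L1-penalized Cox fit over all
gene PSI columns with clinical covariates (age, sex, race, stage) included
unpenalized; the penalty is chosen by 5-fold cross-validated partial
likelihood (seeded) and the selected genes are those with non-zero
coefficients. The phrase "lasso regression for each gene" in the protocol
this follows is read as describing per-gene *coefficients* of one joint
model — only a joint model can yield genes associated *independently*
with survival — and a univariate per-gene screen is provided as an
alternative mode.

The selected genes enter an unpenalized multivariate Cox model (Breslow
ties) with the covariates; the prognosis index of sample $k$ is

$$\mathrm{PI}_k = \sum_{i=1}^{m} \beta_i \chi_{ik}$$

over the *gene* terms only ($\beta_i$ the fitted log-hazard coefficient,
$\chi_{ik}$ the sample's PSI). The suite asserts this identity to
$10^{-12}$. Leave-one-out cross-validation refits the model without each
sample and scores it with the held-out fit. Risk groups split at the
median PI; the published labelling ("PI greater than the median are
categorized as low-risk") likely inverts the usual convention but is
followed verbatim as the `as-published` default, with a `conventional`
orientation switch — the labelling only swaps group names, not the
log-rank statistic. The two-group log-rank test is checked against a
hand-computed hypergeometric-formula oracle, and the null distribution of
the median-split p-value is checked for uniformity over 200 simulated
cohorts.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions used by the acceptance checks:

* 200 genes on one synthetic chromosome, one gene per 4-kb slot;
* 46% of genes multi-site, matching the published cohort's stringent
  atlas; 44% of multi-site genes carry a planted switch, 88% of switches
  are shortenings (the published 3,119 : 412 split), with
  $|\Delta\mathrm{PSI}| = 0.3$;
* normal-tissue baseline PSI uniform on $[0.2, 0.8]$ so most planted
  shifts are representable without clipping (clipping, when it occurs, is
  recorded in the truth table);
* subject-level PSI jitter with SD 0.05 — samples vary around the planted
  tissue mean, giving the rank-based tests something to rank;
* pair architectures mixed 50/29/21 same/composite/skipped-exon,
  following the published proximal-enhanced breakdown;
* 40 internal-priming decoys: A-free upstream windows (so no hexamer can
  match) with an 8-base A-run immediately downstream of the locus;
* every planted site carries AATAAA at offset $-25$ inside an A-free
  41-nt context, so true sites always survive both filters — site
  recovery then measures the pipeline, not the generator's luck;
* read depth ~200 per gene and sample (Poisson), cleavage jitter
  truncated normal within $\pm 5$ nt, read length 80, REV orientation.

Per-gene sequencing depth is not pinned down by the source protocol
(which reports only a per-sample total), so it is a free design parameter;
200 reads/gene/sample keeps the binomial error of PSI near 0.03 while the
whole default cohort (200 genes x 40 samples) simulates and analyses in
about a minute on one core — these are also the problem sizes the test
suite and the acceptance script use.

Survival simulation draws exponential event times under a Cox model whose
linear predictor is $\sum_g \beta_g (\mathrm{PSI}_{gs} - 0.5)$ plus
optional covariate effects, with administrative censoring at a fixed
horizon; covariate marginals default to a realistic lung-cancer
case-series mix (median age ~65, ~28% male, ~47% AA, stage I-heavy,
mostly ever-smokers) and carry no survival effect unless requested.
Expression is coupled to PSI through a Gaussian copula on ranks — the
latent Pearson correlation $2\sin(\pi\rho/6)$ yields the target Spearman
$\rho$ — and per-gene mRNA--protein correlations rise monotonically with
median PSI through a configurable affine map plus noise.

What the generator does **not** emulate: sequencing errors and quality
scores, PCR duplicates and UMIs, isoform-level expression structure,
overlapping genes, multi-chromosome genomes, batch effects, or
covariate-linked APA. Passing tests therefore demonstrate the correctness
and calibration of the *analysis machinery* under the planted statistical
structure — not robustness to every artefact of real libraries, where
mapping quality, annotation error and expression covariation add noise
the generator does not model.

# Numerical and degenerate-input conventions

* Percentages in summaries round half-up to integers (45.7% prints 46),
  matching printed-cohort arithmetic; undefined fractions report `NA`,
  never 0.
* Zero-denominator PSI is missing, not 0; pairs with a missing member are
  excluded from $\Delta\mathrm{PSI}$.
* All-zero paired differences give $p = 1$; constant vectors skip
  correlation; a constant PI refuses to split.
* Empty inputs (no events, header-only matrices, zero-depth samples)
  produce empty, well-typed outputs rather than errors wherever the
  operation is meaningful.
* Windows truncated by chromosome edges are evaluated on the available
  bases.

# Known limitations

* Sites whose polyadenylation signal is non-canonical (UGUA- or
  downstream-element-driven, ~20% of true sites) are filtered out by
  design.
* Pair typing uses annotated isoforms only; no novel-transcript assembly.
* The switch test is a rank test on PSI, not a count-level GLM; very low
  depths lose power earlier than a count model would.
* Covariate-adjusted usage comparison is offered only as a
  clearly-labelled approximation (`adjust_delta_psi_covariates()`, a
  per-gene linear model of delta-PSI on covariates); the published
  multivariate form — model structure, per-gene versus pooled — is
  underspecified, so no exact reproduction is attempted.
* The published 21-gene/12-gene signatures are cohort-specific and not
  reproducible without the cohort; the deliverable is the machinery.
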