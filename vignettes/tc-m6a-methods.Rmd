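---
title: "Calling tissue-conserved m6A sites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue-conserved m6A sites: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcm6a)
```

This vignette is the package's account of its statistics: what the
tissue-conserved (TC) m6A caller actually tests, what the synthetic study
generator does and does not emulate, and the choices made where the design
was genuinely open.

## The sharing test

The central object is a boolean detection matrix `D` (catalog sites x
samples), built by intersecting QC-filtered MeRIP-seq peaks with a
single-base background catalog. The question "is site *i* shared across
samples more than chance would allow?" needs a null for the row sums of `D`
that respects the enormous variation in per-sample peak counts.

**Null model.** `permutation_null()` redraws, per replicate, each sample's
detected-site set uniformly without replacement from the catalog, keeping
that sample's detection count `k_j` fixed (column margins preserved,
site identities destroyed). Per-site sample counts are pooled over all
sites and replicates into one tally vector. Under this null the count of
site *i* is Poisson-binomial with `p_j = k_j / N`, which
`site_pvalues(mode = "analytic")` evaluates exactly by convolution; the
empirical and analytic routes are cross-checked against each other in the
test suite. Pooling counts across sites is an exchangeability assumption —
all sites are interchangeable under the null — and is what makes 1,000
replicates informative at catalog scale. The per-site exact alternative is
the analytic mode.

**P-values and multiplicity.** Empirical p-values use the +1 pseudo-count
convention, `p = (1 + #null >= obs) / (1 + total)`, so `p > 0` always
(required downstream by the step-up adjustment). Adjustment is
Benjamini-Yekutieli, valid under the arbitrary dependence created by
shared peaks and clustered sites. Observed counts of 0 give `p = 1`.

**Classification.** Per dataset, a site is *significantly shared* when
`q < 0.01` and it is detected in every tissue of that dataset. **TC** means
significantly shared in both datasets (hence seen in all tissues overall);
**infrequent** means detected in 1-3 distinct tissue types pooled across
both datasets (and not TC); **shared** is reserved for sites below the q
threshold in both datasets that miss full tissue coverage; everything else
is background. Precedence is TC > infrequent > shared > background: a site
significant in only one dataset with broad tissue coverage falls through to
background, because single-panel significance is not evidence of
conservation.

## What the generator emulates

`simulation_config()` defaults define the study conditions; they are not
free dials. The design mirrors a two-dataset (`A`/`B`), six-tissue panel
with two samples per tissue per dataset — 24 samples, 12 per dataset.
With one sample per tissue a conserved site detected at the realistic
per-sample rate of 0.98 would reach *all* tissues of both datasets only
`0.98^12 = 0.785` of the time, so no caller could reach high sensitivity;
two samples per tissue make tissue coverage robust to single dropouts,
which is also why multi-donor panels work in practice.

Key defaults and their origin:

* `p_detect_conserved = 0.98` — the "detected in nearly all samples" mode
  of the bimodal sharing structure.
* Class mix 10% conserved / 15% tissue-specific / 15% infrequent / 60%
  background over ~2,000 catalog sites; ~5% of the planted TC class in the
  catalog matches the reported scale of TC discovery.
* Region placement: conserved sites 70/28/2 over 3'UTR/CDS/5'UTR,
  everything else 53/41/6 — the reported regional distributions of TC and
  background sites.
* Conserved sites are laid down in clusters (2-4 sites within +/-100 bp of
  an anchor, so pairwise within +/-200 bp) on ~20% of genes, giving 4-5 TC
  sites per host gene, near the reported 4.29.
* Methylation levels are gamma draws (positive support): shape 8, rate 2
  (mean 4) for conserved; shape 2, rate 2 (mean 1) otherwise. No
  methylation distribution is prescribed anywhere; the gamma family is the
  simplest positive-support choice with separate mean and spread.
* Conserved methylation is a **per-host-gene set-point**: all conserved
  sites of a gene share one high-distribution draw, observed per sample
  with ~10% log-normal noise. This is what lets site-level methylation and
  gene-level expression share a driver.
* Expression: `log2 FPKM = basal + expr_coupling x (gene methylation) +
  noise`, `expr_coupling = -0.5`, basal sd 1.05, per-sample noise sd 0.4
  (0.2 for conserved-hosting genes, which is what makes their
  cross-tissue CV lower by construction). The basal sd was calibrated on a
  fixed 40-replicate panel so that the pooled Spearman correlation between
  TC-site methylation and host-gene expression is -0.50, the coupling the
  generator is required to realize; a closed-form bivariate-normal sizing
  got close but rank attenuation on the gamma/log-normal mixture required
  the empirical step.
* Reader binding: the focal RBP covers each conserved site with probability
  0.825 (the reported fraction of TC sites engaged by decay readers). Each
  targeted peak is clipped at neighbouring conserved sites and the focal
  RBP's background peaks avoid conserved sites entirely, so the covered
  fraction is exactly Bernoulli; the binding-center offset spans +/-21 bp,
  giving a ~9 bp mean center distance, at the low end of the reported
  8.8-13.4 bp range.
* Infrequent sites carry 1-3 home tissues (weights 0.75/0.17/0.08) with
  home detection probability 0.5; tissue-specific sites detect at 0.75 at
  home and 0.02 elsewhere. These were sized so that ~82-84% of
  infrequent-labelled sites appear in fewer than five samples, the
  reported share. Closed-form sizing initially ignored *peak
  cross-coverage* — a peak covering one site also covers catalog sites
  within its span, inflating sample counts — and was corrected after
  accounting for it.
* A 160 bp exclusion zone separates conserved sites from all other-class
  placements. Peaks extend at most 150 bp from their site, so a conserved
  site's peak can never cover a differently-labelled site; without this,
  background sites inside conserved clusters are detected everywhere and
  are — correctly, per the method's definition, but uselessly for
  benchmarking — called TC.
* Attribution tracks are strictly non-positive off the planted segments
  (-64..-15 and -98..-91) and positive on them, with sub-threshold noise.

**What it does not emulate:** read-level data (no FASTQ, no alignment, no
coverage profiles), donor structure (samples are independent given class —
matching the independence the shuffle null assumes), isoform diversity
(one transcript per gene in generated annotation, though the region
annotator handles multi-isoform input), peak-calling artefacts beyond the
four planted QC violations, and any sequence signal beyond the forced
RGACW context. Passing tests therefore validate the *statistics* —
calibration, recovery, enrichment machinery — not robustness to alignment
or peak-calling pathologies.

## Numerical and procedural choices

* **Enrichment ratio.** Counts-per-library-size normalization; any
  per-million constant cancels in the IP/input ratio. Multi-peak overlaps
  resolve to the smallest-FDR peak (tie: larger IP ratio). "Detectable
  expression" for peak QC is FPKM > 0 in the peak's own sample.
* **Region labels.** Multi-isoform conflicts resolve to the longest
  transcript (summed exon length, ties by id) of the host gene —
  deterministic and testable. "Distal downstream" is treated as
  intergenic; exclusion is by exon membership only. Exonic sites on
  CDS-less transcripts count as generic exon.
* **Neighbor windows** are genomic distances on the same transcript, not
  spliced distances; at +/-200 bp the two differ only across introns, and
  the clustered structure of interest is intra-exonic.
* **Two-cluster stratification.** An optimal 1-D 2-means partition is
  always a threshold partition, so the within-cluster SSE objective is
  minimised exactly by a prefix-sum scan over the n-1 sorted splits —
  deterministic, initialization-free, and identical to converged Lloyd
  iterations wherever those reach the global optimum (percentile-initialized
  Lloyd demonstrably does not on small unstructured inputs).
* **Rank-sum tests** use exact enumeration when both groups together hold
  at most 12 untied values, otherwise the normal approximation with tie and
  continuity corrections. Two identical constant groups give p = 1.
* **zFPKM** centers log2(FPKM + 0.01) at the kernel-density mode
  (Silverman bandwidth) and scales by the half-normal spread of the
  expressed peak; activity means median z > -3 across tissues. "Consistent
  expression" of an RBP is a cross-tissue CV ceiling (default 1.0) — no
  test or threshold is prescribed, so it is exposed as configuration, as is
  the binding-assignment rule (interval overlap by default; a center-window
  mode is provided because mean center distances are reported without an
  assignment rule).
* **ROI segmentation.** "Positive" is strictly > 0; zeros are gap
  material. Runs merge across gaps <= 3 *before* the length > 5 filter, the
  more permissive of the two orders (both are consistent with the reported
  segments); padding with non-positive values never changes the output.
* **Integrated gradients** use midpoint quadrature and central finite
  differences with a relative step of 1e-4, so any deterministic scorer
  works without autodiff; completeness holds to ~1% at 200 steps for
  smooth scorers and exactly for linear ones.
* **Stability null.** The "random model" behind the cosine/SD contrasts is
  a within-tissue permutation of site labels: it preserves each tissue's
  value distribution and destroys only the cross-tissue coupling of sites,
  which is exactly the structure being claimed.

## Problem sizes

The test suite and acceptance script run the default study (~2,000 sites,
24 samples, 1,000 permutation replicates per dataset; the TC call itself
takes under a second) plus oracle sweeps (10,000 random tracks, 1,000
random p-vectors, exhaustive small Fisher tables). The Spearman coupling is
estimated by pooling (site, sample) pairs over 12 replicate studies in the
tests and 32 in the acceptance script: one study's ~170 TC sites in ~35
host genes leave a sampling SE near 0.2 on rho, and host genes — not
pairs — are the effective unit.

## Limitations

Calibration of the permutation p-values relies on the exchangeability of
sites under the null; real catalogs have covariates (expression,
mappability) that could be modelled with stratified nulls. Donor sharing
across tissues induces correlations the null ignores, in the same way the
sample-shuffle it implements does. The infrequent class is defined by
observed tissue counts, so at low detection rates it mixes genuinely
restricted sites with under-sampled ones — visible in the synthetic truth
tables as background-class sites labelled infrequent. The generator's
uniform-random sequences carry no motif structure beyond the forced site
contexts, so sequence-model benchmarks beyond motif matching are out of
scope.
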