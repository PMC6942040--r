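---
title: "Detecting fine-scale population structure with ipclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fine-scale population structure with ipclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipclust)
```

## The problem

Cohorts assembled from many neighbouring populations are differentiated
at fixation-index (F~ST~) scales of 0.001--0.01 -- an order of magnitude
below the continental scale (~0.1) that a single PCA resolves easily.
One global decomposition spends its leading components on the largest
divergences and on atypical individuals, and the fine structure stays
invisible. `ipclust` instead applies PCA *iteratively*: whenever a
subset of samples shows evidence of internal structure it is split, and
each child is re-analysed on its own, where previously hidden contrasts
become leading components. The recursion needs principled stopping
rules, and those rules are the heart of the method.

## The model and its stopping rules

Dosages count copies of the A1 allele. Within a node, SNPs monomorphic
in that node are dropped and each remaining column is standardized by
its drift scale, $(g - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$. The
$n \times n$ covariance $XX'/m$ is eigendecomposed exactly (sample
counts here are far below SNP counts, so the sample-side decomposition
is cheap).

**Spectrum gap.** Under homogeneity the spectrum is bulk-only and its
leading log~10~ gaps are tiny (empirically ~0.004 for 200 samples and
10,000 SNPs); $k$ separable subgroups add roughly $k-1$ spiked
eigenvalues. The statistic
$\max_i(\log_{10}\lambda_i - \log_{10}\lambda_{i+1})$ over the leading
10 eigenvalues therefore separates "structured" from "noise" nodes.
The decision threshold is the main resolution dial: 0.18 (the default)
keeps only strong, well-separated structure; 0.03 pursues fine
structure. Both ends produce the same picture for strongly diverged
groups; the fine end additionally resolves groups whose spikes barely
clear the bulk edge $(1+\sqrt{n/m})^2$. For a pair of groups of size
$n_g$ at divergence $F$ the spike sits near $1 + 2 n_g F$, which is why
fine-scale detection profits from both more samples and more SNPs.

**Rotation peeling.** Outliers distort mixture fits, so they are peeled
first: the cloud of the first three PC scores is rotated over a fixed
grid (10-degree steps within each coordinate plane) and every axis
projection is scanned for an internal gap exceeding `gap_factor` (3)
times the projection's IQR. Because a balanced bimodal projection has
an IQR spanning both modes, this criterion reacts only to minorities
(below ~25% of the node) and isolated points -- which is its intended
role; balanced splits are the mixture's job. The grid makes the
procedure deterministic.

**Mixture splitting.** A two-component Gaussian mixture with
unrestricted covariances is fitted to the top three PC scores (mclust;
deterministic model-based hierarchical initialisation, EM refinement)
and its MAP partition proposed -- but only when BIC prefers two
components, which on a single Gaussian cloud happens in well under 10%
of cases.

**F~ST~ gate.** PCA and mixtures will happily split noise if asked.
Every proposed split must therefore show average Hudson F~ST~ of at
least `min_fst` = 8e-4 between its two largest children. Hudson's
estimator is unbiased around zero (values may be negative; they are
kept, and fall below any positive gate), so a random split of a
panmictic node measures ~0 ± 0.002 and is rejected. Singleton peels
carry no frequency information and skip the gate; they surface later as
outlier groups. `min_in_group` (default 20) bars small nodes from
further splitting, and terminal groups under 5 members are reported as
outlier groups rather than populations.

Group numbering is deterministic: children are ordered by smallest
member index, terminals numbered depth-first, accepted groups before
outlier groups. The whole engine is deterministic given data and
parameters.

## Quality control

`run_qc()` applies, in this order: founders only; autosomes only
(codes 1--22); greedy windowed LD pruning (window 50 SNPs, step 5,
prune pairs with genotype $r^2 > 0.2$, removing the smaller-MAF member,
map-later on ties); Hardy--Weinberg exact test (remove $p < 0.001$;
two-sided conditional enumeration); sample call-rate (remove missing
fraction $> 0.05$); SNP missingness (remove $> 0.02$); MAF (remove
$< 0.05$). Boundary conventions are strict inequalities throughout, and
LD pruning precedes the distributional filters deliberately -- the
protocol is the one this kind of chip-data analysis uses before PCA.
Statistics are recomputed after every step, so a SNP can, for example,
pass the MAF filter only because a low-call-rate sample was removed
first; the per-step report telescopes exactly. Remaining gaps are
imputed with the per-SNP modal genotype (ties to the smaller dosage,
for determinism) -- adequate for common variants feeding a PCA, not for
rare-variant work.

## Discriminator SNPs and the uniqueness test

For each unordered pair of accepted groups, per-SNP Hudson ratios
$N/D$ are ranked and the top tail selected with the ascending
nearest-rank rule: cutoff at rank $\lceil 0.999\, m\rceil$, selection
of everything at or above it. Tie-free, that is exactly
$m - \lceil 0.999\,m\rceil + 1$ SNPs (139 of 138,111); ties at the
cutoff enlarge the selection; SNPs monomorphic across the pair rank
below everything. The selected lists are written in a
chromosome/position/id/alleles layout directly usable by annotation
tools.

The uniqueness test relabels the pooled pair at random (sizes
preserved), recomputes the top list, and compares it with the observed
list via a bootstrap Jaccard/Tanimoto test: the observed index is
tested two-sidedly against its expectation under independent membership
with the observed marginals,
$E = \pi_A\pi_B/(\pi_A+\pi_B-\pi_A\pi_B)$, with the null built from
multinomial redraws of the four membership cells and add-one smoothing.
The *maximum* p across rounds is reported.

A caveat worth stating plainly: with exact-binomial within-group
genotypes (as our simulator produces), permuting labels destroys the
allele-frequency signal entirely, so permuted top lists share
essentially no SNPs with the observed list and the similarity test has
nothing to reject -- the maximum p is large for structured and
panmictic pairs alike. In real data, within-group departures from
Hardy--Weinberg proportions and other variance heterogeneity inflate
some SNPs' F~ST~ under *every* labelling and can couple observed and
permuted lists, making very small maxima attainable. The per-round
p-values and the observed list are returned so users can inspect the
full distribution rather than the maximum alone.

## The synthetic cohort generator

Populations are simulated under the Balding--Nichols model: a branch
with parameter $F$ draws each SNP's frequency from
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ (mean $p$, variance
$Fp(1-p)$), ancestral frequencies uniform on (0.05, 0.95) so fixtures
are not dominated by post-QC MAF loss. Divergence accumulates along
branches, and two leaves' expected pairwise Hudson F~ST~ is about half
the summed divergence on their paths from the common ancestor -- the
generator and the estimator cross-validate each other in the tests.
Admixed individuals draw genotypes from $p = Q^\top p_{\text{sources}}$
with per-individual mixing proportions. Genotypes are conditionally
independent given frequencies: no linkage disequilibrium is simulated,
so LD-pruning behaviour is exercised with explicitly planted duplicate
columns instead, and nothing here validates haplotype-scale methods.
Truth labels ride along in `population_label` purely for reporting.

`western_africa_like()` fixes the study conditions used throughout the
tests: 20,000 SNPs; one endogamous population (n = 60) at branch
divergence 0.28, i.e. pairwise F~ST~ ≈ 0.14 against everything; six
sedentary populations (n = 75 each) in two regional clades with
pairwise F~ST~ 0.004--0.01; two diaspora groups (n = 50 each) of mixed
local ancestry plus a Uniform(0.05, 0.15) per-individual dose of an
out-group at continental divergence (branch 0.29, the European--West
African scale); and five singleton outliers from five distinct distant
populations (branch 0.30--0.50), so each lands in its own terminal
group of size 1. The two diaspora groups are drawn from the same
admixture law and are expected to merge with each other -- the claim
under test is their separation from the unadmixed clusters, not from
one another.

## Numerical choices and edge cases

* Eigenvalues are clipped at zero; rank-deficient nodes simply carry
  trailing zeros. Component signs are fixed by making the
  largest-magnitude score positive.
* EigenFit excludes non-positive eigenvalues and pads spectra shorter
  than 10 with their smallest positive value.
* `percentile_select()` subtracts 1e-9 before `ceiling()` so that
  `percentile * m` landing a hair above an exact integer cannot shift
  the rank.
* Zero-variance dosage pairs score $r^2 = 0$ (no evidence of LD);
  $r^2$ uses pairwise-complete observations.
* Hudson components require more than one chromosome per group; group
  allele counts are twice the non-missing genotype counts, so
  missingness shrinks the correction terms per SNP.
* The HWE exact test enumerates heterozygote counts of matching parity
  in log space; the "no more probable than observed" comparison uses a
  1e-7 relative tolerance, the standard guard against ties lost to
  floating point.
* The BED codec packs four samples per byte, low bits first
  (00 two copies of A1, 10 one, 11 none, 01 missing); only SNP-major
  files are accepted and individual-major files raise an explicit
  error.

## Problem sizes and what the tests show

The validation suite runs at deliberately desk-sized conditions: FST
recovery on 20 replicates of 10,000 SNPs and 50+50 diploids per scale;
cluster recovery on five populations of 100 at pairwise F~ST~ 0.01 with
10,000 SNPs (adjusted Rand index ≥ 0.95 against truth; in practice 1.0);
homogeneity control on 20 cohorts of 200; and the Western-Africa-like
cohort at both threshold extremes, where the threshold behaves
monotonically (more groups at 0.03 than at 0.18). Passing these shows
the estimator, the stopping rules and their interaction behave as
designed under the generator's assumptions -- independent SNPs, exact
HWE within populations, no genotyping batch structure. Real chip data
violate all three in places; the QC protocol removes the worst of it,
but group counts on real cohorts should be read alongside the per-node
splitting history (`fit$nodes`) rather than taken as the single truth.

## Known limitations

* No covariate adjustment of the PCA, and no alternative split
  schedules: the engine always tries rotation peeling first, then the
  mixture.
* Hudson's is the only F~ST~ estimator (by design; alternatives would
  change the `min_fst` calibration).
* The permutation uniqueness test inherits the power caveat described
  above.
* The simulator produces no LD and no genotyping error; it validates
  frequency-scale behaviour only.
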