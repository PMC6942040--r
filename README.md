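# ipclust

Fine-scale population structure from SNP genotypes by iterative PCA
clustering.

Large genotyping cohorts often mix many closely related populations —
differentiated at pairwise F<sub>ST</sub> of 0.001–0.01 — together with
strongly diverged or admixed groups and a handful of atypical
individuals. A single PCA of such data resolves only the coarsest
structure. `ipclust` detects the fine structure by splitting the sample
set *recursively*: each subset gets its own PCA, so components that were
buried under larger-scale variation become leading components of the
subset, and splitting continues until several stopping rules say the
remaining variation is noise.

The package is aimed at population and statistical geneticists working
with diploid SNP data in PLINK binary format who want label-free
stratification, the SNPs that drive it, and a fully simulated test bed.

## The method

For the samples of a node, genotype dosages (copies of the A1 allele)
are column-standardized to `(g − 2p̂) / sqrt(2 p̂ (1 − p̂))` and the
sample covariance is eigendecomposed. Splitting is governed by:

* **Spectrum gap ("EigenFit")** — the largest consecutive gap of
  log<sub>10</sub> eigenvalues among the leading ten. A flat (Marchenko–
  Pastur-like) spectrum scores near 0; detectable structure opens a
  gap. Nodes below a threshold (0.03–0.18; default 0.18) become leaves.
* **Rotation peeling** — the 3-D cloud of the first three PC scores is
  rotated over a fixed angular grid and each axis projection is scanned
  for an internal gap wider than 3× its interquartile range; the widest
  such gap splits off outliers and minority groups.
* **Gaussian-mixture splitting** — when no gap is found, a
  two-component Gaussian mixture (unrestricted covariances) is fitted to
  the top three PC scores and its MAP partition is used, but only when
  BIC prefers two components over one.
* **F<sub>ST</sub> gate** — a proposed split is accepted only if the
  average Hudson F<sub>ST</sub> between its two largest children,

      Fst = mean(N) / mean(D),
      N = (p1 − p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1),
      D = p1(1−p2) + p2(1−p1),

  (ratio of per-SNP averages, monomorphic SNPs excluded) reaches
  `min_fst` (default 8e-4). Terminal groups with fewer than five
  members are reported as outlier groups.

Upstream, `run_qc()` applies the standard pre-PCA protocol in order:
founders only, autosomes only, LD pruning (window 50, step 5,
r² > 0.2), Hardy–Weinberg exact test (p < 0.001), sample call rate
(> 5% missing), SNP missingness (> 2%), MAF (< 0.05), then modal
imputation. Downstream, `top_fst_snps()` ranks SNPs by per-SNP Hudson
F<sub>ST</sub> between a pair of inferred groups and keeps the top 0.1%
(nearest-rank rule), and `permutation_uniqueness()` assesses those
discriminator sets against label permutations with a bootstrap
Jaccard/Tanimoto similarity test.

A Balding–Nichols simulator (`population_tree_spec()`,
`simulate_tree()`, `sample_genotypes()`) generates hierarchically
structured cohorts with admixture, missingness and planted QC
violations; `western_africa_like()` is a ready-made preset with one
strongly diverged population (F<sub>ST</sub> ≈ 0.14 against the rest),
six close populations, two admixed diaspora groups and five singleton
outliers.

## Worked example

```r
library(ipclust)

x <- western_africa_like(seed = 5)        # 615 samples x 20,000 SNPs
fit <- ipclust(x, threshold = 0.03, min_in_group = 20)
print(fit)
#> Iterative PCA clustering (threshold = 0.03 , min_in_group = 20 , min_fst = 8e-04 )
#>    615 samples -> 8 accepted groups, 5 outlier groups
#>   accepted group sizes: 60 75 93 75 75 75 82 75
#>   outlier samples: 5

table(fit$assignment$group, x$samples$population_label)[1:3, c("DIV", "ADM1", "A1")]
#>     DIV ADM1 A1
#>   1  60    0  0
#>   2   0    0 75
#>   3   0   46  0
```

Group 1 is exactly the diverged population, group 2 one of the close
sedentary populations, group 3 admixed diaspora individuals only; the
five planted outlier individuals each end in their own outlier group.
Pairwise divergence and discriminator SNPs for the accepted groups:

```r
keep <- !fit$assignment$outlier
pairwise_group_fst(x[keep, ], fit$assignment$group[keep])  # 8 x 8 matrix
disc <- all_pair_discriminators(x, fit$assignment)
nrow(disc$summary)     # 28 pairs = choose(8, 2)
```

`run_pipeline(list(bed_prefix = ..., out_dir = ...))` chains QC,
clustering and discriminators on PLINK input and writes TSV/JSON
artifacts for every stage.

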