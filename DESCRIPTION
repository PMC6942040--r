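Package: ipclust
Title: Fine-Scale Population Structure by Iterative PCA Clustering of SNP
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects fine-scale population stratification in diploid SNP
    genotype data by iteratively splitting samples in principal-component
    space, with outlier peeling by three-dimensional rotation, two-component
    Gaussian mixture splitting, and stopping rules based on the eigenvalue
    spectrum, minimum group size, and the average Hudson fixation index
    between proposed subgroups.  Includes a PLINK BED/BIM/FAM reader and
    writer, the standard genotype quality-control protocol (founder,
    autosome, linkage-disequilibrium, Hardy-Weinberg, call-rate, and
    minor-allele-frequency filters), per-SNP Hudson FST components with
    ratio-of-averages aggregation, identification of top-FST discriminator
    SNPs between inferred groups with a permutation Jaccard uniqueness test,
    and a Balding-Nichols simulator of hierarchically structured populations
    with admixture for fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
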