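test_that("founder filter keeps exactly the samples with unknown parents", {
  x <- tiny_dataset(n = 6, m = 4)
  x$samples$father_id <- c("0", "F9", "0", "0", "0", "0")
  x$samples$mother_id <- c("0", "M9", "0", "M9", "0", "0")
  res <- filter_founders(x)
  # both the trio child and the one-parent-known sample are removed
  expect_identical(res$removed, c("I02", "I04"))
  expect_identical(n_samples(res$data), 4L)
  # all-founder dataset is unchanged
  res2 <- filter_founders(res$data)
  expect_identical(res2$data$samples, res$data$samples)
  expect_length(res2$removed, 0)
})

test_that("autosome filter drops sex, mitochondrial and unknown codes", {
  x <- tiny_dataset(n = 4, m = 5)
  x$variants$chromosome <- c(1L, 23L, 26L, 0L, 22L)
  res <- filter_autosomes(x)
  expect_identical(res$data$variants$id, c("s001", "s005"))
  expect_identical(res$removed, c("s002", "s003", "s004"))
  expect_identical(filter_autosomes(res$data)$removed, character(0))
})

test_that("genotype r-squared matches the Pearson formula", {
  x <- c(0, 1, 2, 0, 2)
  expect_equal(genotype_r2(x, x), 1)
  expect_equal(genotype_r2(x, 2 - x), 1)        # allele flip
  y <- c(0, 1, 1, 0, 2)
  # hand arithmetic: cov = 0.75, var x = 1, var y = 0.7 (population
  # denominators cancel) -> r2 = 0.5625 / 0.7
  expect_equal(genotype_r2(x, y), 0.5625 / 0.7)
  expect_equal(genotype_r2(rep(1, 5), x), 0)    # zero variance
  # pairwise-complete: missing entries are dropped from both vectors
  xm <- x; xm[5] <- NA
  expect_equal(genotype_r2(xm, y),
               stats::cor(x[1:4], y[1:4])^2)
})

test_that("LD pruning leaves no surviving pair above the threshold", {
  # planted: s2 duplicates s1 (r2 = 1); s4 correlated with s3
  set.seed(7)
  n <- 60
  base <- matrix(sample(0:2, n * 5, replace = TRUE, prob = c(.3, .4, .3)),
                 n, 5)
  base[, 2] <- base[, 1]
  flip <- sample(n, 12)
  base[, 4] <- base[, 3]
  base[flip, 4] <- sample(0:2, 12, replace = TRUE)
  x <- tiny_dataset(n = n, m = 5)
  x$dosages <- base
  storage.mode(x$dosages) <- "integer"
  stopifnot(genotype_r2(base[, 3], base[, 4]) > 0.2)
  res <- ld_prune(x, qc_params(ld_window = 5, ld_step = 2))
  surv <- res$data$dosages
  # oracle: exhaustive pairwise check on the surviving panel
  for (i in seq_len(ncol(surv) - 1)) {
    for (j in seq(i + 1, ncol(surv))) {
      expect_lte(genotype_r2(surv[, i], surv[, j]), 0.2)
    }
  }
  expect_identical(ncol(surv), 3L)
  # identical pair: MAF ties, so the later SNP in map order is removed
  expect_true("s002" %in% res$removed)
})

test_that("LD pruning is a no-op below threshold and needs sorted input", {
  x <- tiny_dataset(n = 80, m = 10, seed = 2)
  res <- ld_prune(x, qc_params())
  expect_length(res$removed, 0)
  bad <- x
  bad$variants$position <- rev(bad$variants$position)
  expect_error(ld_prune(bad), "sorted")
})

test_that("HWE exact p-values agree with full enumeration", {
  expect_equal(hwe_exact_p(10, 0, 0), 1)           # monomorphic
  expect_lt(hwe_exact_p(0, 100, 0), 1e-20)         # extreme het excess
  expect_equal(hwe_exact_p(3, 5, 2), hwe_oracle(3, 5, 2))
  set.seed(1)
  for (r in 1:20) {
    counts <- as.vector(stats::rmultinom(1, 40, c(.25, .5, .25)))
    expect_equal(hwe_exact_p(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]))
  }
})

test_that("HWE filter removes exactly the planted violating SNP", {
  x <- clean_background(n = 100, m = 12, seed = 3)
  x$dosages[, 5] <- 1L                            # all heterozygotes
  res <- hwe_filter(x, 0.001)
  expect_identical(res$removed, x$variants$id[5])
  empty <- hwe_filter(x[, integer(0)], 0.001)
  expect_identical(n_variants(empty$data), 0L)
})

test_that("call-rate and missingness filters use strict boundaries", {
  x <- tiny_dataset(n = 20, m = 100, seed = 5)
  x$dosages[1, 1:6] <- NA_integer_                # 6% missing sample
  x$dosages[2, 1:5] <- NA_integer_                # exactly 5%
  res <- sample_call_rate_filter(x, 0.05)
  expect_identical(res$removed, "I01")
  expect_true("I02" %in% res$data$samples$individual_id)

  y <- tiny_dataset(n = 100, m = 8, seed = 6)
  y$dosages[1:3, 1] <- NA_integer_                # 3% missing SNP
  y$dosages[1:2, 2] <- NA_integer_                # exactly 2%
  res2 <- snp_missingness_filter(y, 0.02)
  expect_identical(res2$removed, "s001")
  expect_true("s002" %in% res2$data$variants$id)
})

test_that("MAF filter removes strictly below the cutoff", {
  x <- tiny_dataset(n = 10, m = 4, seed = 7)
  x$dosages[, 1] <- 0L                            # monomorphic, MAF 0
  x$dosages[, 2] <- c(1L, rep(0L, 9))             # MAF 0.05 exactly
  x$dosages[, 3] <- c(0L, 0L, 1L, 2L, rep(0L, 6)) # MAF 3/20
  res <- maf_filter(x, 0.05)
  expect_identical(res$removed, "s001")
  expect_setequal(res$data$variants$id, c("s002", "s003", "s004"))
  # the spec-style 4-sample column: MAF 3/8, retained
  expect_equal(minor_allele_freq_of(c(0, 0, 1, 2)), 0.375)
})

test_that("modal imputation fills every gap deterministically", {
  x <- tiny_dataset(n = 4, m = 3)
  x$dosages <- matrix(c(0L, 0L, 1L, NA,           # mode 0
                        2L, 2L, 1L, 1L,           # complete
                        0L, 0L, 1L, 1L), 4, 3)    # tie -> smaller dosage
  x$dosages[4, 3] <- NA
  y <- impute_most_frequent(x)
  expect_identical(y$dosages[4, 1], 0L)
  expect_identical(y$dosages[, 2], c(2L, 2L, 1L, 1L))
  expect_identical(y$dosages[4, 3], 0L)           # tie broken downward
  allmiss <- x
  allmiss$dosages[, 1] <- NA_integer_
  expect_error(impute_most_frequent(allmiss), "no observed genotypes")
})

test_that("run_qc removes nothing from a clean dataset and telescopes", {
  x <- clean_background(n = 120, m = 20, seed = 8)
  qc <- run_qc(x)
  expect_true(all(qc$report$n_removed == 0))
  expect_identical(n_samples(qc$data), 120L)
  expect_identical(n_variants(qc$data), 20L)
  # telescoping: after-counts of step k equal before-counts of step k+1
  k <- nrow(qc$report)
  expect_identical(qc$report$samples_after[-k], qc$report$samples_before[-1])
  expect_identical(qc$report$snps_after[-k], qc$report$snps_before[-1])
})

test_that("run_qc removes exactly one planted violation per step", {
  x <- qc_violation_fixture(seed = 2)
  pl <- attr(x, "planted")
  qc <- run_qc(x)
  expect_identical(qc$removed$founders, pl$nonfounders)
  expect_identical(qc$removed$autosomes, pl$nonautosomal_snps)
  expect_identical(qc$removed$ld_prune, pl$duplicate_snps)
  expect_identical(qc$removed$hwe, pl$hwe_snps)
  expect_identical(qc$removed$sample_call_rate, pl$low_call_samples)
  expect_identical(qc$removed$snp_missingness, pl$high_missing_snps)
  expect_identical(qc$removed$maf, pl$low_maf_snps)
  expect_false(anyNA(qc$data$dosages))            # imputation applied
})

test_that("a SNP can pass MAF only because samples were removed first", {
  # 21 samples, 4 non-founders homozygous major at the focal SNP; the
  # minor allele count of 2 gives MAF 2/42 < 0.05 before removal but
  # 2/34 >= 0.05 after the founder filter
  x <- clean_background(n = 21, m = 5, seed = 9)
  x$samples$father_id[1:4] <- "X"
  focal <- c(rep(0L, 15), 1L, 1L, rep(0L, 4))
  x$dosages <- cbind(x$dosages, focal)
  x$variants <- rbind(x$variants,
                      data.frame(chromosome = 22L, id = "focal",
                                 position = 1e6L, allele1 = "A",
                                 allele2 = "G"))
  expect_lt(minor_allele_freq_of(x$dosages[, 6]), 0.05)
  qc <- run_qc(x)
  expect_true("focal" %in% qc$data$variants$id)
})

test_that("each QC filter is idempotent", {
  x <- tiny_dataset(n = 40, m = 30, seed = 10, missing = 0.03)
  x$samples$father_id[3] <- "X"
  x$variants$chromosome[30] <- 23L   # last variant: map stays sorted
  for (f in list(filter_founders, filter_autosomes,
                 function(d) hwe_filter(d, 0.001),
                 function(d) sample_call_rate_filter(d, 0.05),
                 function(d) snp_missingness_filter(d, 0.02),
                 function(d) maf_filter(d, 0.05),
                 function(d) ld_prune(d, qc_params()))) {
    once <- f(x)$data
    twice <- f(once)
    expect_length(twice$removed, 0)
    expect_identical(twice$data$dosages, once$dosages)
  }
})
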