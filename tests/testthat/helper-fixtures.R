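# Shared fixture builders and independent oracles.

# A small genotype_dataset with random dosages (optionally with missing
# entries), all founders, variants on one chromosome in map order.
tiny_dataset <- function(n = 8, m = 6, seed = 1, missing = 0) {
  set.seed(seed)
  D <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing > 0) {
    D[sample(length(D), ceiling(missing * length(D)))] <- NA_integer_
  }
  genotype_dataset(
    D,
    data.frame(family_id = sprintf("F%02d", seq_len(n)),
               individual_id = sprintf("I%02d", seq_len(n)),
               father_id = "0", mother_id = "0",
               sex = rep(1:2, length.out = n),
               stringsAsFactors = FALSE),
    data.frame(chromosome = 1L, id = sprintf("s%03d", seq_len(m)),
               position = seq_len(m) * 100L, allele1 = "A", allele2 = "G",
               stringsAsFactors = FALSE)
  )
}

# Two populations diverged from a shared ancestor with Balding-Nichols
# parameter F each (expected pairwise Hudson FST ~ F); returns a dosage
# matrix with the first n_per rows from population 1.
bn_pair <- function(F, n_per, m, seed) {
  set.seed(seed)
  p <- stats::runif(m, 0.05, 0.95)
  p1 <- balding_nichols_freq(p, F)
  p2 <- balding_nichols_freq(p, F)
  g1 <- matrix(stats::rbinom(n_per * m, 2, rep(p1, each = n_per)), n_per)
  g2 <- matrix(stats::rbinom(n_per * m, 2, rep(p2, each = n_per)), n_per)
  rbind(g1, g2)
}

# One panmictic population as a dosage matrix.
bn_single <- function(n, m, seed, F = 0.01) {
  set.seed(seed)
  p <- stats::runif(m, 0.05, 0.95)
  pk <- balding_nichols_freq(p, F)
  matrix(stats::rbinom(n * m, 2, rep(pk, each = n)), n)
}

# Brute-force oracle for the Hardy-Weinberg exact test: enumerate every
# genotype configuration compatible with the observed allele counts and
# sum the conditional probabilities of configurations no more probable
# than the observed one.  Independent of the package implementation.
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  hets <- 0:min(na, 2 * n - na)
  hets <- hets[(na - hets) %% 2 == 0]
  w <- vapply(hets, function(h) {
    h1 <- (na - h) / 2
    h2 <- n - h1 - h
    if (h2 < 0) return(0)
    exp(lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
          h * log(2))
  }, numeric(1))
  prob <- w / sum(w)
  obs <- prob[match(n_het, hets)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# The Western-Africa-like fixture and its two reference fits, computed
# once per test run (several acceptance checks share them).
wal_cache <- new.env()
wal_fit <- function() {
  if (is.null(wal_cache$val)) {
    x <- western_africa_like(seed = 106)
    wal_cache$val <- list(
      x = x,
      fine = ipclust(x, threshold = 0.03, min_in_group = 20),
      coarse = ipclust(x, threshold = 0.18, min_in_group = 20))
  }
  wal_cache$val
}

# Minor allele frequency of a single dosage vector.
minor_allele_freq_of <- function(v) {
  f <- mean(v, na.rm = TRUE) / 2
  min(f, 1 - f)
}

# A dataset whose background passes all filters deterministically:
# HWE-exact genotype counts per SNP, one SNP per chromosome (so LD
# pruning never compares a pair), common MAF, no missingness.
clean_background <- function(n, m, seed = 1, p = 0.3) {
  set.seed(seed)
  D <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    n_hom1 <- round(n * p^2)
    n_het <- round(n * 2 * p * (1 - p))
    pool <- c(rep(2L, n_hom1), rep(1L, n_het),
              rep(0L, n - n_hom1 - n_het))
    D[, j] <- sample(pool)
  }
  genotype_dataset(
    D,
    data.frame(family_id = sprintf("F%02d", seq_len(n)),
               individual_id = sprintf("I%02d", seq_len(n)),
               father_id = "0", mother_id = "0",
               sex = rep(1:2, length.out = n),
               stringsAsFactors = FALSE),
    data.frame(chromosome = seq_len(m) %% 22L + 1L,
               id = sprintf("s%03d", seq_len(m)),
               position = seq_len(m) * 100L, allele1 = "A", allele2 = "G",
               stringsAsFactors = FALSE)[order(seq_len(m) %% 22L + 1L), ]
  )
}
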