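#' Balding-Nichols population allele frequencies
#'
#' Draws population frequencies around an ancestral frequency `p` from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`; `F` is the expected fixation index of the drawn
#' population against its ancestor.  Vectorised over `p`.
#'
#' @param p ancestral allele frequencies in `(0, 1)`.
#' @param F divergence parameter in `(0, 1)`.
#' @return drawn frequencies, same length as `p`.
#' @export
balding_nichols_freq <- function(p, F) {
  if (any(F <= 0 | F >= 1)) stop("F must lie in (0, 1)")
  if (any(p <= 0 | p >= 1)) stop("ancestral frequencies must lie in (0, 1)")
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Specify a hierarchy of diverging populations
#'
#' A population tree is a nested list: internal nodes are
#' `list(F = <branch divergence>, children = list(...))` and leaves are
#' `list(F = <branch divergence>, name = "POP", n = <diploid sample
#' size>)`.  `F` is the Balding-Nichols parameter of the branch leading
#' into the node; the root has no branch.  Under this model the expected
#' pairwise Hudson FST between two leaves is approximately half the sum
#' of the divergence accumulated along their two paths from the common
#' ancestor (exact for small `F`).
#'
#' @param tree the nested list described above.
#' @param n_snps number of SNPs to simulate.
#' @param freq_range range of the uniform ancestral allele-frequency law
#'   (default `c(0.05, 0.95)`, which keeps most SNPs common enough to
#'   survive a MAF filter).
#' @param seed integer seed; the blueprint is fully deterministic per
#'   seed.
#' @return a list of class `population_tree_spec`.
#' @export
population_tree_spec <- function(tree, n_snps, freq_range = c(0.05, 0.95),
                                 seed = 1L) {
  stopifnot(n_snps >= 1, length(freq_range) == 2,
            freq_range[1] > 0, freq_range[2] < 1,
            freq_range[1] < freq_range[2])
  check_node <- function(node) {
    if (!is.null(node$children)) {
      lapply(node$children, function(ch) {
        if (is.null(ch$F) || ch$F <= 0 || ch$F >= 1) {
          stop("every branch needs F in (0, 1)")
        }
        check_node(ch)
      })
    } else if (!identical(node$root, TRUE)) {
      if (is.null(node$name)) stop("leaf populations need a name")
      if (is.null(node$n) || node$n < 2) {
        stop("leaf populations need n >= 2 diploid samples")
      }
    }
    invisible(NULL)
  }
  check_node(c(tree, list(root = TRUE)))
  structure(list(tree = tree, n_snps = as.integer(n_snps),
                 freq_range = freq_range, seed = as.integer(seed)),
            class = "population_tree_spec")
}

#' Simulate leaf-population allele frequencies along a tree
#'
#' Frequencies evolve from a Uniform ancestral draw down every branch by
#' repeated Balding-Nichols sampling; divergence accumulates with path
#' length.
#'
#' @param spec a [population_tree_spec()].
#' @return `n_snps x n_leaves` matrix of allele frequencies, columns
#'   named by leaf population.
#' @export
simulate_tree <- function(spec) {
  stopifnot(inherits(spec, "population_tree_spec"))
  set.seed(spec$seed)
  p0 <- stats::runif(spec$n_snps, spec$freq_range[1], spec$freq_range[2])
  freqs <- list()
  descend <- function(node, p) {
    if (!is.null(node$F)) {
      p <- balding_nichols_freq(pmin(pmax(p, 1e-6), 1 - 1e-6), node$F)
    }
    if (is.null(node$children)) {
      freqs[[node$name]] <<- p
    } else {
      for (ch in node$children) descend(ch, p)
    }
  }
  descend(spec$tree, p0)
  do.call(cbind, freqs)
}

#' Sizes of the leaf populations of a tree spec
#' @param spec a [population_tree_spec()].
#' @return named integer vector of diploid sample sizes per leaf.
#' @export
leaf_sizes <- function(spec) {
  out <- integer()
  walk <- function(node) {
    if (is.null(node$children)) {
      out[node$name] <<- as.integer(node$n)
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(spec$tree)
  out
}

#' Specify admixed sample groups
#'
#' @param groups list of `list(name, n, Q)` entries.  `Q` is either a
#'   simplex vector of mixing proportions over the source populations
#'   (columns of the frequency table) or an `n x K` matrix giving
#'   per-individual proportions; rows must sum to one.
#' @return list of class `admixture_spec`.
#' @export
admixture_spec <- function(groups) {
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n) || is.null(g$Q)) {
      stop("each admixed group needs name, n and Q")
    }
    Q <- if (is.matrix(g$Q)) g$Q else matrix(g$Q, nrow = 1)
    if (any(abs(rowSums(Q) - 1) > 1e-8)) {
      stop("mixing proportions must sum to 1")
    }
  }
  structure(list(groups = groups), class = "admixture_spec")
}

#' Specify missingness and planted QC violations
#'
#' Planted violations give the QC test-bed known ground truth: SNPs
#' forced out of Hardy-Weinberg proportions (all heterozygous), low-MAF
#' SNPs, duplicated adjacent SNPs (perfect LD pairs), low-call-rate
#' samples, and non-founder samples (parent ids filled in).
#'
#' @param missing_rate fraction of genotypes set missing uniformly at
#'   random, in `[0, 1)`.
#' @param n_hwe_snps,n_low_maf_snps,n_duplicate_snps counts of planted
#'   variant-level violations.
#' @param low_maf target minor allele frequency of planted low-MAF SNPs.
#' @param n_low_call_samples count of planted low-call-rate samples.
#' @param low_call_missing missing fraction given to those samples.
#' @param n_nonfounders count of samples turned into non-founders.
#' @param n_nonautosomal_snps count of SNPs moved to the X chromosome
#'   (always the last variants, so the map stays position-sorted).
#' @param n_high_missing_snps count of SNPs given `snp_missing`
#'   missingness.
#' @param snp_missing missing fraction of those SNPs.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(missing_rate = 0, n_hwe_snps = 0L,
                       n_low_maf_snps = 0L, low_maf = 0.01,
                       n_duplicate_snps = 0L, n_low_call_samples = 0L,
                       low_call_missing = 0.10, n_nonfounders = 0L,
                       n_nonautosomal_snps = 0L, n_high_missing_snps = 0L,
                       snp_missing = 0.05) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            low_call_missing > 0, low_call_missing < 1,
            low_maf >= 0, low_maf < 0.05,
            snp_missing > 0, snp_missing < 1)
  structure(list(missing_rate = missing_rate,
                 n_hwe_snps = as.integer(n_hwe_snps),
                 n_low_maf_snps = as.integer(n_low_maf_snps),
                 low_maf = low_maf,
                 n_duplicate_snps = as.integer(n_duplicate_snps),
                 n_low_call_samples = as.integer(n_low_call_samples),
                 low_call_missing = low_call_missing,
                 n_nonfounders = as.integer(n_nonfounders),
                 n_nonautosomal_snps = as.integer(n_nonautosomal_snps),
                 n_high_missing_snps = as.integer(n_high_missing_snps),
                 snp_missing = snp_missing),
            class = "noise_spec")
}

#' Sample diploid genotypes from population frequencies
#'
#' Unadmixed individuals draw `Binomial(2, p_pop)` genotypes per SNP;
#' admixed individuals use their mixture frequency `p = Q %*% p_sources`.
#' Uniform missingness is applied afterwards, planted QC violations
#' last.  Truth labels are stored in `population_label` (and the planted
#' identifiers in the `"planted"` attribute); the clustering engine never
#' reads them.
#'
#' @param freqs `n_snps x K` matrix of population allele frequencies.
#' @param sizes named integer vector of diploid sample sizes for the
#'   unadmixed populations (names must match columns of `freqs`; use 0 to
#'   simulate a source population without sampling it).
#' @param admixture optional [admixture_spec()].
#' @param noise optional [noise_spec()].
#' @param seed integer seed.
#' @return a [genotype_dataset()] with truth labels and a `"planted"`
#'   attribute listing planted violation identifiers.
#' @export
sample_genotypes <- function(freqs, sizes, admixture = NULL, noise = NULL,
                             seed = 1L) {
  set.seed(as.integer(seed))
  m <- nrow(freqs)
  pops <- colnames(freqs)
  if (is.null(pops)) stop("freqs must have column names")
  sizes <- sizes[sizes > 0]
  if (length(sizes) && !all(names(sizes) %in% pops)) {
    stop("sizes names must match freq columns")
  }

  blocks <- list()
  labels <- character()
  for (pop in names(sizes)) {
    nk <- sizes[[pop]]
    g <- matrix(stats::rbinom(nk * m, 2L, rep(freqs[, pop], each = nk)),
                nrow = nk)
    blocks[[length(blocks) + 1L]] <- g
    labels <- c(labels, rep(pop, nk))
  }
  if (!is.null(admixture)) {
    stopifnot(inherits(admixture, "admixture_spec"))
    for (grp in admixture$groups) {
      Q <- grp$Q
      if (!is.matrix(Q)) {
        Q <- matrix(rep(Q, grp$n), nrow = grp$n, byrow = TRUE)
      }
      if (ncol(Q) != ncol(freqs)) {
        stop("Q must have one column per source population")
      }
      p_eff <- Q %*% t(freqs)                   # n x m individual freqs
      g <- matrix(stats::rbinom(grp$n * m, 2L, pmin(pmax(p_eff, 0), 1)),
                  nrow = grp$n)
      blocks[[length(blocks) + 1L]] <- g
      labels <- c(labels, rep(grp$name, grp$n))
    }
  }
  if (!length(blocks)) stop("no samples requested")
  D <- do.call(rbind, blocks)
  n <- nrow(D)

  planted <- list(hwe_snps = character(), low_maf_snps = character(),
                  duplicate_snps = character(),
                  low_call_samples = character(),
                  nonfounders = character(),
                  nonautosomal_snps = character(),
                  high_missing_snps = character())

  variants <- data.frame(
    chromosome = rep(1:22, length.out = m)[order(rep(1:22,
                                                     length.out = m))],
    id = sprintf("snp%06d", seq_len(m)),
    position = integer(m), allele1 = "A", allele2 = "G",
    stringsAsFactors = FALSE
  )
  # positions increase within each chromosome
  variants$position <- stats::ave(seq_len(m), variants$chromosome,
                                  FUN = seq_along) * 1000L
  samples <- data.frame(
    family_id = sprintf("F%04d", seq_len(n)),
    individual_id = sprintf("ind%04d", seq_len(n)),
    father_id = "0", mother_id = "0", sex = rep(c(1L, 2L), length.out = n),
    population_label = labels, stringsAsFactors = FALSE
  )

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (noise$missing_rate > 0) {
      drop <- stats::runif(length(D)) < noise$missing_rate
      D[drop] <- NA_integer_
    }
    planted_cols <- integer()
    take_cols <- function(k) {
      free <- setdiff(seq_len(m), planted_cols)
      if (length(free) < k) stop("not enough SNPs to plant violations")
      picked <- sort(sample(free, k))
      planted_cols <<- c(planted_cols, picked)
      picked
    }
    if (noise$n_hwe_snps > 0) {
      js <- take_cols(noise$n_hwe_snps)
      D[, js] <- 1L                       # all-heterozygote: HWE p ~ 0
      planted$hwe_snps <- variants$id[js]
    }
    if (noise$n_low_maf_snps > 0) {
      js <- take_cols(noise$n_low_maf_snps)
      for (j in js) {
        D[, j] <- stats::rbinom(n, 2L, noise$low_maf)
        if (minor_allele_freq(D[, j, drop = FALSE]) >= 0.05) {
          D[, j] <- 0L
          D[1, j] <- 1L
        }
      }
      planted$low_maf_snps <- variants$id[js]
    }
    if (noise$n_duplicate_snps > 0) {
      for (k in seq_len(noise$n_duplicate_snps)) {
        # copy a column into its next map neighbour -> an r2 = 1 pair;
        # the copy (larger MAF-tie index) is the one LD pruning removes
        free <- setdiff(seq_len(m - 1L), planted_cols)
        free <- free[!(free + 1L) %in% planted_cols]
        free <- free[variants$chromosome[free] ==
                       variants$chromosome[free + 1L]]
        if (!length(free)) stop("not enough SNPs to plant duplicates")
        j <- sample(free, 1L)
        planted_cols <- c(planted_cols, j, j + 1L)
        D[, j + 1L] <- D[, j]
        planted$duplicate_snps <-
          c(planted$duplicate_snps, variants$id[j + 1L])
      }
    }
    if (noise$n_nonautosomal_snps > 0) {
      # last variants: reassigning them to X keeps the map sorted
      js <- seq(m - noise$n_nonautosomal_snps + 1L, m)
      if (any(js %in% planted_cols)) stop("planting collision at map end")
      planted_cols <- c(planted_cols, js)
      variants$chromosome[js] <- 23L
      planted$nonautosomal_snps <- variants$id[js]
    }
    if (noise$n_high_missing_snps > 0) {
      js <- take_cols(noise$n_high_missing_snps)
      for (j in js) {
        rows <- sample(n, ceiling(noise$snp_missing * n))
        D[rows, j] <- NA_integer_
      }
      planted$high_missing_snps <- variants$id[js]
    }
    if (noise$n_low_call_samples > 0) {
      rows <- sort(sample(n, noise$n_low_call_samples))
      for (r in rows) {
        js <- sample(m, ceiling(noise$low_call_missing * m))
        D[r, js] <- NA_integer_
      }
      planted$low_call_samples <- samples$individual_id[rows]
    }
    if (noise$n_nonfounders > 0) {
      rows <- sort(sample(setdiff(seq_len(n), match(
        planted$low_call_samples, samples$individual_id)),
        noise$n_nonfounders))
      samples$father_id[rows] <- "9998"
      samples$mother_id[rows] <- "9999"
      planted$nonfounders <- samples$individual_id[rows]
    }
  }

  out <- genotype_dataset(D, samples, variants)
  attr(out, "planted") <- planted
  out
}

#' Fixture with exactly one planted violation per QC step
#'
#' Builds a dataset whose background is guaranteed to pass every filter
#' -- each background SNP has genotype counts fixed at their
#' Hardy-Weinberg expectation (permuted across samples, so pairwise LD
#' is pure noise) with common allele frequencies and no missingness --
#' and plants exactly one violation for each of the seven QC steps: a
#' non-founder sample, an X-chromosome SNP, a duplicated (r-squared = 1)
#' SNP pair, an all-heterozygote SNP, a low-call-rate sample, a
#' high-missingness SNP and a low-MAF SNP.
#'
#' @param seed integer seed (arranges genotypes; all planted outcomes
#'   are deterministic).
#' @param n,m diploid sample and SNP counts (defaults 200 and 200).
#' @return a [genotype_dataset()]; the `"planted"` attribute names the
#'   violation of each step.
#' @export
qc_violation_fixture <- function(seed = 1L, n = 200L, m = 200L) {
  stopifnot(n >= 50, m >= 30)
  set.seed(as.integer(seed))
  p <- stats::runif(m, 0.2, 0.5)
  D <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    n_hom1 <- round(n * p[j]^2)
    n_het <- round(n * 2 * p[j] * (1 - p[j]))
    pool <- c(rep(2L, n_hom1), rep(1L, n_het),
              rep(0L, n - n_hom1 - n_het))
    D[, j] <- sample(pool)
  }
  variants <- data.frame(
    chromosome = sort(rep(1:22, length.out = m)),
    id = sprintf("snp%06d", seq_len(m)),
    position = 0L, allele1 = "A", allele2 = "G",
    stringsAsFactors = FALSE)
  variants$position <- stats::ave(seq_len(m), variants$chromosome,
                                  FUN = seq_along) * 1000L
  samples <- data.frame(
    family_id = sprintf("F%04d", seq_len(n)),
    individual_id = sprintf("ind%04d", seq_len(n)),
    father_id = "0", mother_id = "0",
    sex = rep(c(1L, 2L), length.out = n),
    population_label = "SIM", stringsAsFactors = FALSE)

  # one planted violation per QC step, on reserved low-index columns
  # (chromosome 1) plus the last column for the autosome filter
  planted <- list()
  samples$father_id[4L] <- "9998"
  samples$mother_id[4L] <- "9999"
  planted$nonfounders <- samples$individual_id[4L]
  variants$chromosome[m] <- 23L
  planted$nonautosomal_snps <- variants$id[m]
  D[, 2L] <- D[, 1L]                    # duplicate pair on chr 1
  planted$duplicate_snps <- variants$id[2L]
  D[, 3L] <- 1L                         # all heterozygotes: HWE p ~ 0
  planted$hwe_snps <- variants$id[3L]
  D[, 4L] <- 0L                         # one heterozygote: MAF << 0.05
  D[5L, 4L] <- 1L
  planted$low_maf_snps <- variants$id[4L]
  D[sample(n, ceiling(0.05 * n)), 5L] <- NA_integer_
  planted$high_missing_snps <- variants$id[5L]
  low_call <- 9L
  # keep the planted columns out of the low-call sample's missing set so
  # their outcomes stay deterministic
  D[low_call, sample(setdiff(seq_len(m), c(1:5, m)),
                     ceiling(0.10 * m))] <- NA_integer_
  planted$low_call_samples <- samples$individual_id[low_call]

  out <- genotype_dataset(D, samples, variants)
  attr(out, "planted") <- planted
  out
}

#' Preset: a Western-Africa-like structured cohort
#'
#' Emulates the statistical structure of a large multi-population West
#' African cohort: one strongly diverged endogamous population (pairwise
#' FST about 0.14 against everything else), six closely related
#' sedentary populations in two regional clades (pairwise FST roughly
#' 0.002-0.01), two diaspora groups of mainly local ancestry carrying
#' 5-15 percent out-group admixture (out-group at continental divergence,
#' branch F = 0.29), and five singleton outlier individuals each drawn
#' from its own distant population.  No linkage disequilibrium is
#' simulated.
#'
#' @param seed integer seed; output is fully deterministic per seed.
#' @param n_snps number of SNPs (default 20000).
#' @return a [genotype_dataset()] of 615 samples with truth labels:
#'   populations `DIV` (n = 60), `A1 A2 A3 B1 B2 B3` (n = 75 each),
#'   admixed `ADM1`/`ADM2` (n = 50 each) and outliers `OUT1`-`OUT5`
#'   (n = 1 each).
#' @export
western_africa_like <- function(seed = 1L, n_snps = 20000L) {
  tree <- list(children = list(
    list(F = 0.28, name = "DIV", n = 60L),
    list(F = 0.29, name = "EURO", n = 0L),      # admixture source only
    list(F = 0.004, children = list(
      list(F = 0.004, name = "A1", n = 75L),
      list(F = 0.005, name = "A2", n = 75L),
      list(F = 0.006, name = "A3", n = 75L)
    )),
    list(F = 0.004, children = list(
      list(F = 0.004, name = "B1", n = 75L),
      list(F = 0.005, name = "B2", n = 75L),
      list(F = 0.006, name = "B3", n = 75L)
    )),
    list(F = 0.30, name = "OUT1", n = 1L),
    list(F = 0.35, name = "OUT2", n = 1L),
    list(F = 0.40, name = "OUT3", n = 1L),
    list(F = 0.45, name = "OUT4", n = 1L),
    list(F = 0.50, name = "OUT5", n = 1L)
  ))
  # leaf n = 1 is below the population_tree_spec floor of 2, so declare
  # the outlier leaves with n = 2 and sample one individual from each.
  spec_tree <- tree
  for (i in seq_along(spec_tree$children)) {
    if (!is.null(spec_tree$children[[i]]$n) &&
        spec_tree$children[[i]]$n < 2) {
      spec_tree$children[[i]]$n <- 2L
    }
  }
  spec <- population_tree_spec(spec_tree, n_snps = n_snps, seed = seed)
  freqs <- simulate_tree(spec)

  sizes <- leaf_sizes(spec)
  sizes[c("OUT1", "OUT2", "OUT3", "OUT4", "OUT5")] <- 1L
  sizes["EURO"] <- 0L

  locals <- c("A1", "A2", "A3", "B1", "B2", "B3")
  set.seed(seed + 1L)
  adm_groups <- lapply(c("ADM1", "ADM2"), function(nm) {
    n <- 50L
    q_out <- stats::runif(n, 0.05, 0.15)   # per-individual out-group dose
    # local ancestry spread over all six sedentary populations
    w <- matrix(stats::rgamma(n * length(locals), shape = 2), nrow = n)
    w <- w / rowSums(w)
    Q <- matrix(0, nrow = n, ncol = ncol(freqs),
                dimnames = list(NULL, colnames(freqs)))
    Q[, locals] <- w * (1 - q_out)
    Q[, "EURO"] <- q_out
    list(name = nm, n = n, Q = Q)
  })

  sample_genotypes(freqs, sizes, admixture = admixture_spec(adm_groups),
                   seed = seed + 2L)
}
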