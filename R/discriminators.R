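#' Top-percentile FST discriminator SNPs for a group pair
#'
#' Ranks SNPs by their per-SNP Hudson ratio `N/D` between two groups and
#' selects the top tail by the ascending nearest-rank percentile rule:
#' the cutoff is the value at rank `ceiling(percentile * m)` and every
#' SNP at or above it is selected.  With tie-free values this yields
#' exactly `m - ceiling(percentile * m) + 1` SNPs; ties spanning the
#' cutoff can enlarge or (by collapsing distinct values) shrink the
#' list.  SNPs monomorphic across both groups (`D = 0`) rank below all
#' polymorphic SNPs.
#'
#' @param x a [genotype_dataset()] or dosage matrix.
#' @param g1,g2 sample indices of the two groups (each >= 2 samples).
#' @param percentile selection percentile in `(0, 1)` (default 0.999,
#'   the top 0.1 percent).
#' @return list of class `discriminator_result`: `snp_ids`, `fst`
#'   (per-SNP values of the selected SNPs), `cutoff`, `set_size`, `m`
#'   (number of ranked SNPs) and `pair`.
#' @export
top_fst_snps <- function(x, g1, g2, percentile = 0.999) {
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must lie strictly between 0 and 1")
  }
  comp <- fst_components(x, g1, g2)
  ratio <- ifelse(!is.na(comp$D) & comp$D > 0, comp$N / comp$D, -Inf)
  if (!any(is.finite(ratio))) stop("all SNPs monomorphic across the pair")
  ps <- percentile_select(ratio, percentile)
  sel <- ps$selected
  cutoff <- ps$cutoff
  m <- length(ratio)
  structure(list(snp_ids = comp$id[sel], fst = ratio[sel],
                 cutoff = cutoff, set_size = length(sel), m = m,
                 pair = c(deparse(substitute(g1)),
                          deparse(substitute(g2)))),
            class = "discriminator_result")
}

#' Nearest-rank top-percentile selection
#'
#' The cutoff is the value at rank `ceiling(percentile * m)` of the
#' ascending sort of `values` (`m = length(values)`); everything at or
#' above the cutoff is selected.  With tie-free values this picks
#' exactly `m - ceiling(percentile * m) + 1` elements; ties at the
#' cutoff enlarge the selection.  `-Inf` entries (used to rank
#' monomorphic SNPs below everything) are never selected: if the cutoff
#' falls among them, all finite values are selected instead.
#'
#' @param values numeric vector to rank (may contain `-Inf`).
#' @param percentile selection percentile in `(0, 1)`.
#' @return `list(selected, cutoff)`: integer indices of the selected
#'   elements and the cutoff value.
#' @export
percentile_select <- function(values, percentile) {
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must lie strictly between 0 and 1")
  }
  m <- length(values)
  if (m == 0) stop("no values to select from")
  # small epsilon guards against e.g. 0.999 * m landing just above the
  # integer it equals mathematically
  r <- ceiling(percentile * m - 1e-9)
  cutoff <- sort(values)[r]
  if (!is.finite(cutoff)) {
    sel <- which(is.finite(values))
  } else {
    sel <- which(values >= cutoff)
  }
  list(selected = sel, cutoff = cutoff)
}

#' Jaccard/Tanimoto index of two sets
#'
#' @param a,b vectors interpreted as sets.
#' @return `|intersect| / |union|`, defined as 0 when both sets are
#'   empty.
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Bootstrap test of Jaccard similarity against independence
#'
#' Tests whether the observed Jaccard index of two subsets of a common
#' universe departs from its expectation under independent membership
#' with the observed marginals, `E = piA piB / (piA + piB - piA piB)`
#' with `pi = |set| / m`.  The null distribution is built from `B`
#' resamples of independently re-drawn membership indicators with the
#' observed marginals (a multinomial draw over the four membership
#' cells); the two-sided p-value is the add-one-smoothed fraction of
#' null statistics at least as far from `E` as the observed index.
#'
#' @param a,b the two sets (vectors of identifiers).
#' @param m size of the common universe (`m >= |union|`).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return p-value in `(0, 1]`; an empty union returns 1 by convention.
#' @export
jaccard_test_p <- function(a, b, m, B = 1000L, seed = NULL) {
  a <- unique(a)
  b <- unique(b)
  if (m < length(union(a, b))) stop("universe smaller than the union")
  if (length(a) == 0 && length(b) == 0) return(1)
  piA <- length(a) / m
  piB <- length(b) / m
  expect <- piA * piB / (piA + piB - piA * piB)
  obs <- jaccard_index(a, b)
  probs <- c(piA * piB, piA * (1 - piB), (1 - piA) * piB,
             (1 - piA) * (1 - piB))
  draw <- with_seed(seed, stats::rmultinom(B, m, probs))
  both <- draw[1, ]
  un <- both + draw[2, ] + draw[3, ]
  jb <- ifelse(un > 0, both / un, 0)
  (1 + sum(abs(jb - expect) >= abs(obs - expect) - 1e-12)) / (B + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`;
# the caller's RNG state is untouched when seed is given.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv())
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Permutation uniqueness test of a discriminator set
#'
#' Assesses whether the top-FST SNP set of a group pair could arise from
#' an arbitrary relabelling of its individuals.  For each permutation
#' round the pooled samples of the pair are relabelled at random
#' (without replacement, preserving group sizes), the top-FST set is
#' recomputed, and the observed set is compared to the permuted set with
#' [jaccard_test_p()].  The maximum p-value across rounds is reported:
#' it is small only when every permuted set overlaps the observed set
#' beyond chance.
#'
#' @param x a [genotype_dataset()] or dosage matrix.
#' @param g1,g2 sample indices of the two groups.
#' @param percentile selection percentile (default 0.999).
#' @param n_permutations number of label permutations (default 10000).
#' @param B bootstrap resamples inside each Jaccard test (default 1000).
#' @param seed integer seed; results are deterministic per seed.
#' @return `list(max_p, p_values, observed)`.
#' @export
permutation_uniqueness <- function(x, g1, g2, percentile = 0.999,
                                   n_permutations = 10000L, B = 1000L,
                                   seed = 1L) {
  observed <- top_fst_snps(x, g1, g2, percentile)
  pooled <- c(g1, g2)
  n1 <- length(g1)
  p_values <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(r) {
      perm <- sample(pooled)
      set_r <- top_fst_snps(x, perm[seq_len(n1)], perm[-seq_len(n1)],
                            percentile)
      jaccard_test_p(observed$snp_ids, set_r$snp_ids, m = observed$m,
                     B = B)
    }, numeric(1))
  })
  list(max_p = max(p_values), p_values = p_values, observed = observed)
}

#' Discriminator SNP sets for all accepted group pairs
#'
#' Enumerates every unordered pair of accepted (non-outlier) groups of a
#' cluster assignment -- `k` groups give `k (k - 1) / 2` pairs -- and
#' computes each pair's top-FST SNP set, optionally followed by the
#' permutation uniqueness test.
#'
#' @param x a [genotype_dataset()].
#' @param assignment assignment data frame (from [ipclust()] or
#'   [read_assignment()]).
#' @param percentile selection percentile (default 0.999).
#' @param n_permutations permutation rounds for the uniqueness test; 0
#'   (the default) skips the test.
#' @param B bootstrap resamples per Jaccard test.
#' @param seed integer seed for the uniqueness tests.
#' @return `list(summary, results)`: a data frame with one row per pair
#'   (`group_i`, `group_j`, `set_size`, `cutoff`, `max_p`) and the list
#'   of `discriminator_result` objects.
#' @export
all_pair_discriminators <- function(x, assignment, percentile = 0.999,
                                    n_permutations = 0L, B = 1000L,
                                    seed = 1L) {
  acc <- assignment[!assignment$outlier, ]
  groups <- split(match(paste(acc$family_id, acc$individual_id),
                        paste(x$samples$family_id,
                              x$samples$individual_id)),
                  acc$group)
  ids <- names(groups)
  k <- length(groups)
  if (k < 2) stop("need at least two accepted groups")
  summary <- NULL
  results <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      res <- top_fst_snps(x, groups[[i]], groups[[j]], percentile)
      res$pair <- c(ids[i], ids[j])
      max_p <- NA_real_
      if (n_permutations > 0) {
        max_p <- permutation_uniqueness(
          x, groups[[i]], groups[[j]], percentile,
          n_permutations = n_permutations, B = B,
          seed = seed + 1000L * i + j)$max_p
      }
      res$max_p <- max_p
      results[[paste(ids[i], ids[j], sep = "-")]] <- res
      summary <- rbind(summary, data.frame(
        group_i = ids[i], group_j = ids[j], set_size = res$set_size,
        cutoff = res$cutoff, max_p = max_p, stringsAsFactors = FALSE))
    }
  }
  list(summary = summary, results = results)
}

#' Write discriminator SNPs as a VEP-ready TSV
#'
#' One row per selected SNP with chromosome, position, identifier and
#' alleles, directly usable as input to variant annotation tools.
#'
#' @param result a `discriminator_result` from [top_fst_snps()].
#' @param x the [genotype_dataset()] the result was computed from.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_discriminators <- function(result, x, path) {
  v <- x$variants[match(result$snp_ids, x$variants$id), ]
  out <- data.frame(chromosome = v$chromosome, position = v$position,
                    id = v$id, allele1 = v$allele1, allele2 = v$allele2,
                    fst = result$fst, stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
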