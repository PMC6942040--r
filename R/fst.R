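#' Hudson FST numerator and denominator
#'
#' Per-SNP components of Hudson's FST estimator in the
#' ratio-of-averages form: `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) -
#' p2(1-p2)/(n2-1)` and `D = p1(1-p2) + p2(1-p1)`, where `p1`, `p2` are
#' sample allele frequencies and `n1`, `n2` counted chromosomes.  All
#' arguments vectorise over SNPs.
#'
#' @param p1,p2 sample allele frequencies in `[0, 1]`.
#' @param n1,n2 numbers of chromosomes sampled (must exceed 1).
#' @return `list(N, D)` of per-SNP components.
#' @references Bhatia G, Patterson N, Sankararaman S, Price AL (2013).
#'   Estimating and interpreting FST: the impact of rare variants.
#'   Genome Research 23(9):1514-1521.
#' @export
hudson_components <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) {
    stop("Hudson components need more than one chromosome per group")
  }
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  list(N = N, D = D)
}

#' Per-SNP Hudson components between two sample groups
#'
#' Frequencies and chromosome counts are computed per SNP from
#' non-missing genotypes (`n = 2 x` non-missing samples).  SNPs where
#' either group retains at most one chromosome get `NA` components and
#' are ignored by [average_fst()].
#'
#' @param x a [genotype_dataset()] or a dosage matrix.
#' @param g1,g2 sample (row) indices of the two groups, each of size >= 2.
#' @return data frame with columns `id`, `p1`, `n1`, `p2`, `n2`, `N`, `D`.
#' @export
fst_components <- function(x, g1, g2) {
  D <- if (inherits(x, "genotype_dataset")) x$dosages else x
  ids <- if (inherits(x, "genotype_dataset")) x$variants$id else
    as.character(seq_len(ncol(D)))
  if (length(g1) < 2 || length(g2) < 2) {
    stop("both groups need at least two samples")
  }
  d1 <- D[g1, , drop = FALSE]
  d2 <- D[g2, , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  ok <- n1 > 1 & n2 > 1
  N <- Dh <- rep(NA_real_, ncol(D))
  if (any(ok)) {
    comp <- hudson_components(p1[ok], n1[ok], p2[ok], n2[ok])
    N[ok] <- comp$N
    Dh[ok] <- comp$D
  }
  data.frame(id = ids, p1 = p1, n1 = n1, p2 = p2, n2 = n2, N = N, D = Dh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average Hudson FST (ratio of averages)
#'
#' Aggregates per-SNP components as mean(N) / mean(D) over SNPs with
#' `D > 0`; SNPs monomorphic across both groups (`D = 0`) carry no
#' information and are excluded.  Values can be slightly negative at zero
#' divergence: the per-SNP corrections make the estimator unbiased, so
#' negative values are retained, not clamped.
#'
#' @param N,D per-SNP numerators and denominators, or a data frame from
#'   [fst_components()] as the first argument.
#' @return the aggregate FST estimate (unitless).
#' @export
average_fst <- function(N, D = NULL) {
  if (is.data.frame(N)) {
    D <- N$D
    N <- N$N
  }
  use <- !is.na(D) & !is.na(N) & D > 0
  if (!any(use)) stop("all SNPs are monomorphic; FST undefined")
  mean(N[use]) / mean(D[use])
}

#' Pairwise FST matrix over sample groups
#'
#' @param x a [genotype_dataset()] or dosage matrix.
#' @param groups a factor or vector of group labels, one per sample, or a
#'   named list of sample index vectors.  Every group must have at least
#'   two samples.
#' @return a symmetric matrix of average Hudson FST values with zero
#'   diagonal, dimnames the group labels.
#' @export
pairwise_group_fst <- function(x, groups) {
  if (!is.list(groups)) {
    f <- factor(groups)
    groups <- split(seq_along(f), f)
  }
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("groups of size one cannot enter FST: ",
         paste(names(groups)[sizes < 2], collapse = ", "))
  }
  k <- length(groups)
  out <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      est <- average_fst(fst_components(x, groups[[i]], groups[[j]]))
      out[i, j] <- out[j, i] <- est
    }
  }
  out
}
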