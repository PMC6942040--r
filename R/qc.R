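#' Quality-control parameters
#'
#' Defaults follow the standard stringent pre-PCA protocol: LD pruning in
#' sliding windows of 50 SNPs advanced by 5 with r-squared above 0.2
#' removed, Hardy-Weinberg exact p below 0.001 removed, samples with more
#' than 5 percent missing genotypes removed, SNPs with more than 2 percent
#' missing removed, and SNPs with minor allele frequency below 0.05
#' removed.
#'
#' @param ld_window,ld_step window size and step (SNP counts) for LD
#'   pruning.
#' @param ld_r2_max maximum tolerated pairwise genotype r-squared.
#' @param hwe_p_min variants with exact HWE p-value strictly below this
#'   are removed.
#' @param sample_max_missing samples with missing fraction strictly above
#'   this are removed.
#' @param snp_max_missing variants with missing fraction strictly above
#'   this are removed.
#' @param maf_min variants with minor allele frequency strictly below
#'   this are removed.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(ld_window = 50L, ld_step = 5L, ld_r2_max = 0.2,
                      hwe_p_min = 0.001, sample_max_missing = 0.05,
                      snp_max_missing = 0.02, maf_min = 0.05) {
  stopifnot(ld_step <= ld_window, ld_window >= 2,
            ld_r2_max >= 0, ld_r2_max <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            sample_max_missing >= 0, sample_max_missing <= 1,
            snp_max_missing >= 0, snp_max_missing <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max,
                 hwe_p_min = hwe_p_min,
                 sample_max_missing = sample_max_missing,
                 snp_max_missing = snp_max_missing, maf_min = maf_min),
            class = "qc_params")
}

#' Individual QC filters
#'
#' Each filter returns `list(data = <filtered dataset>, removed =
#' <identifiers removed>)`.  Removal conventions: call-rate and
#' missingness filters remove strictly-greater-than fractions, the MAF
#' filter removes strictly-less-than frequencies, and the HWE filter
#' removes strictly-less-than p-values.
#'
#' @param x a [genotype_dataset()].
#' @return `list(data, removed)`.
#' @name qc_filters
NULL

#' @describeIn qc_filters keep only founders (both parent ids `"0"`).
#' @export
filter_founders <- function(x) {
  keep <- is_founder(x)
  if (!any(keep)) warning("no founders left after filtering")
  list(data = x[keep, ], removed = x$samples$individual_id[!keep])
}

#' @describeIn qc_filters keep only autosomal variants (chromosomes 1-22).
#' @export
filter_autosomes <- function(x) {
  keep <- x$variants$chromosome %in% 1:22
  list(data = x[, keep], removed = x$variants$id[!keep])
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of two dosage vectors over their
#' pairwise-complete entries.  A pair where either vector has zero
#' variance on the complete subset scores 0 (no evidence of LD).
#'
#' @param x,y dosage vectors of equal length (`NA` = missing).
#' @return r-squared in `[0, 1]`.
#' @export
genotype_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  sx <- stats::sd(x[ok])
  sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `ld_window` SNPs along each chromosome in steps of
#' `ld_step`.  Within a window, while any retained pair has r-squared
#' above `ld_r2_max`, the worst pair is broken by removing its
#' smaller-MAF member (ties: the later SNP in map order).  After pruning,
#' no retained pair within any window exceeds the threshold.
#'
#' @param x a [genotype_dataset()] with variants sorted by (chromosome,
#'   position).
#' @param params a [qc_params()].
#' @return `list(data, removed)`.
#' @export
ld_prune <- function(x, params = qc_params()) {
  v <- x$variants
  ord <- order(v$chromosome, v$position)
  if (!identical(ord, seq_len(nrow(v)))) {
    stop("variants must be sorted by (chromosome, position) before LD ",
         "pruning")
  }
  m <- n_variants(x)
  keep <- rep(TRUE, m)
  maf <- minor_allele_freq(x$dosages)
  for (chr in unique(v$chromosome)) {
    idx <- which(v$chromosome == chr)
    nv <- length(idx)
    if (nv < 2) next
    starts <- seq(1L, nv, by = params$ld_step)
    for (s in starts) {
      win <- idx[s:min(s + params$ld_window - 1L, nv)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        stats::cor(x$dosages[, win, drop = FALSE],
                   use = "pairwise.complete.obs")^2
      )
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      alive <- rep(TRUE, length(win))
      repeat {
        r2a <- r2[alive, alive, drop = FALSE]
        if (!length(r2a) || max(r2a) <= params$ld_r2_max) break
        w <- which(alive)
        worst <- which(r2[w, w, drop = FALSE] == max(r2a),
                       arr.ind = TRUE)[1, ]
        i <- w[worst[1]]; j <- w[worst[2]]
        vi <- win[i]; vj <- win[j]
        # drop the smaller-MAF SNP; equal MAF -> the later one in map order
        drop_j <- maf[vj] < maf[vi] ||
          (maf[vj] == maf[vi] && vj > vi)
        drop <- if (drop_j) j else i
        alive[drop] <- FALSE
        keep[win[drop]] <- FALSE
      }
      if (s + params$ld_window - 1L >= nv) break
    }
  }
  list(data = x[, keep], removed = v$id[!keep])
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value conditional on the observed allele counts:
#' the sum of probabilities of all heterozygote configurations no more
#' probable than the observed one (the standard SNP exact-test
#' convention).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (allele-1 homozygotes,
#'   heterozygotes, allele-2 homozygotes).
#' @return exact p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("negative genotype count")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("no genotypes")
  na <- 2L * n_hom1 + n_het     # allele-1 count
  nb <- 2L * n_hom2 + n_het
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(h) up to a constant: n! 2^h / (n_hom_rare! h! n_hom_common!)
  logp <- lfactorial(n) + hets * log(2) -
    lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial((na + nb - rare - hets) / 2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' @describeIn qc_filters remove variants with exact HWE p below `p_min`.
#' @param p_min HWE p-value cutoff.
#' @export
hwe_filter <- function(x, p_min = 0.001) {
  m <- n_variants(x)
  if (m == 0) return(list(data = x, removed = character()))
  p <- vapply(seq_len(m), function(j) {
    d <- x$dosages[, j]
    hwe_exact_p(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                sum(d == 0, na.rm = TRUE))
  }, numeric(1))
  keep <- p >= p_min
  list(data = x[, keep], removed = x$variants$id[!keep])
}

#' @describeIn qc_filters remove samples whose missing-genotype fraction
#'   exceeds `max_missing`.
#' @param max_missing maximum tolerated missing fraction.
#' @export
sample_call_rate_filter <- function(x, max_missing = 0.05) {
  frac <- rowMeans(is.na(x$dosages))
  if (n_variants(x) == 0) frac <- rep(0, n_samples(x))
  keep <- frac <= max_missing
  list(data = x[keep, ], removed = x$samples$individual_id[!keep])
}

#' @describeIn qc_filters remove variants whose missing-genotype fraction
#'   exceeds `max_missing`.
#' @export
snp_missingness_filter <- function(x, max_missing = 0.02) {
  frac <- colMeans(is.na(x$dosages))
  keep <- frac <= max_missing
  list(data = x[, keep], removed = x$variants$id[!keep])
}

#' @describeIn qc_filters remove variants with minor allele frequency
#'   below `maf_min`.
#' @param maf_min minimum minor allele frequency retained.
#' @export
maf_filter <- function(x, maf_min = 0.05) {
  maf <- minor_allele_freq(x$dosages)
  maf[is.nan(maf)] <- 0
  keep <- maf >= maf_min
  list(data = x[, keep], removed = x$variants$id[!keep])
}

#' Single imputation by the per-SNP modal genotype
#'
#' Replaces every missing entry by the most frequent non-missing dosage
#' of its SNP; ties between modes resolve to the smaller dosage, so the
#' result is deterministic.
#'
#' @param x a [genotype_dataset()].
#' @return a complete (no-`NA`) `genotype_dataset`.
#' @export
impute_most_frequent <- function(x) {
  D <- x$dosages
  miss_col <- which(colSums(is.na(D)) > 0)
  for (j in miss_col) {
    d <- D[, j]
    obs <- d[!is.na(d)]
    if (!length(obs)) {
      stop("variant ", x$variants$id[j], " has no observed genotypes; ",
           "remove it before imputation")
    }
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode <- which(counts == max(counts))[1] - 1L  # smallest modal dosage
    d[is.na(d)] <- mode
    D[, j] <- d
  }
  genotype_dataset(D, x$samples, x$variants)
}

#' Run the full QC protocol
#'
#' Applies, in order: founder filter, autosome filter, LD pruning, HWE
#' filter, sample call-rate filter, SNP missingness filter and MAF
#' filter, recomputing all statistics after each step; remaining missing
#' genotypes are then imputed by the per-SNP mode.  The report telescopes:
#' the after-counts of each step are the before-counts of the next.
#'
#' @param x a [genotype_dataset()].
#' @param params a [qc_params()].
#' @param impute impute remaining missing genotypes after filtering
#'   (default `TRUE`).
#' @return `list(data, report, removed)` where `report` is a data frame
#'   with one row per step (step, samples_before, samples_after,
#'   snps_before, snps_after, n_removed) and `removed` is a named list of
#'   the identifiers removed at each step.
#' @export
run_qc <- function(x, params = qc_params(), impute = TRUE) {
  steps <- list(
    founders = function(d) filter_founders(d),
    autosomes = function(d) filter_autosomes(d),
    ld_prune = function(d) ld_prune(d, params),
    hwe = function(d) hwe_filter(d, params$hwe_p_min),
    sample_call_rate = function(d)
      sample_call_rate_filter(d, params$sample_max_missing),
    snp_missingness = function(d)
      snp_missingness_filter(d, params$snp_max_missing),
    maf = function(d) maf_filter(d, params$maf_min)
  )
  report <- data.frame(step = names(steps), samples_before = NA_integer_,
                       samples_after = NA_integer_,
                       snps_before = NA_integer_, snps_after = NA_integer_,
                       n_removed = NA_integer_, stringsAsFactors = FALSE)
  removed <- vector("list", length(steps))
  names(removed) <- names(steps)
  cur <- x
  for (k in seq_along(steps)) {
    report$samples_before[k] <- n_samples(cur)
    report$snps_before[k] <- n_variants(cur)
    res <- steps[[k]](cur)
    cur <- res$data
    removed[[k]] <- res$removed
    report$samples_after[k] <- n_samples(cur)
    report$snps_after[k] <- n_variants(cur)
    report$n_removed[k] <- length(res$removed)
  }
  if (impute && anyNA(cur$dosages)) {
    cur <- impute_most_frequent(cur)
  }
  list(data = cur, report = report, removed = removed)
}

#' Write a QC report as TSV
#' @param report the report data frame from [run_qc()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
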