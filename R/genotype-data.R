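#' In-memory SNP genotype dataset
#'
#' Bundles sample metadata, variant metadata and a dosage matrix into a
#' single object shared by every stage of the pipeline.  Dosages count
#' copies of `allele1` (the PLINK A1 allele as recorded in the BIM file),
#' so each entry is 0, 1, 2 or `NA` for a missing genotype call.
#'
#' @param dosages integer matrix, one row per sample and one column per
#'   variant; entries in `{0, 1, 2, NA}`.
#' @param samples data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` (1 = male, 2 = female, 0 = unknown)
#'   and optionally `population_label` (reporting only, never used by the
#'   clustering engine).
#' @param variants data frame with columns `chromosome` (PLINK numeric
#'   codes: 1-22 autosomes, 23 = X, 24 = Y, 25 = XY, 26 = MT, 0 =
#'   unknown), `id`, `position` (1-based bp), `allele1` (the counted
#'   allele) and `allele2`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, samples, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(samples$population_label)) {
    samples$population_label <- NA_character_
  }
  x <- structure(
    list(dosages = dosages, samples = samples, variants = variants),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(x)
  x
}

validate_genotype_dataset <- function(x) {
  need_s <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  need_v <- c("chromosome", "id", "position", "allele1", "allele2")
  if (!all(need_s %in% names(x$samples))) {
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  }
  if (!all(need_v %in% names(x$variants))) {
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  }
  if (nrow(x$dosages) != nrow(x$samples)) {
    stop("dosage rows (", nrow(x$dosages), ") != number of samples (",
         nrow(x$samples), ")")
  }
  if (ncol(x$dosages) != nrow(x$variants)) {
    stop("dosage columns (", ncol(x$dosages), ") != number of variants (",
         nrow(x$variants), ")")
  }
  bad <- x$dosages[!is.na(x$dosages)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(x$variants$id)) {
    stop("variant identifiers must be unique")
  }
  key <- paste(x$samples$family_id, x$samples$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(family_id, individual_id) pairs must be unique")
  }
  if (nrow(x$variants) && any(x$variants$position <= 0)) {
    stop("variant positions must be positive")
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", n_samples(x), "samples x", n_variants(x),
      "variants\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  chr <- sort(unique(x$variants$chromosome))
  if (length(chr)) {
    cat("  chromosomes:", paste(chr, collapse = " "), "\n")
  }
  if (any(!is.na(x$samples$population_label))) {
    cat("  population labels:",
        paste(utils::head(sort(unique(stats::na.omit(
          x$samples$population_label))), 10), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of samples / variants in a dataset
#' @param x a [genotype_dataset()].
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype dataset
#'
#' `i` indexes samples (rows), `j` indexes variants (columns); both follow
#' usual R indexing (integer, logical or negative indices).
#'
#' @param x a [genotype_dataset()].
#' @param i,j sample and variant indices; missing keeps all.
#' @param ... ignored.
#' @return a `genotype_dataset`.
#' @export
`[.genotype_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  genotype_dataset(
    x$dosages[i, j, drop = FALSE],
    x$samples[i, , drop = FALSE],
    x$variants[j, , drop = FALSE]
  )
}

#' Founder status of each sample
#'
#' A founder has both parent identifiers unknown (`"0"`).
#'
#' @param x a [genotype_dataset()].
#' @return logical vector, one entry per sample.
#' @export
is_founder <- function(x) {
  x$samples$father_id == "0" & x$samples$mother_id == "0"
}

# Per-variant allele-1 sample frequency over non-missing genotypes.
allele1_freq <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

# Per-variant minor allele frequency; NaN (all missing) propagates.
minor_allele_freq <- function(dosages) {
  f <- allele1_freq(dosages)
  pmin(f, 1 - f)
}
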