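#' End-to-end structure-detection pipeline
#'
#' Runs quality control, iterative PCA clustering and pairwise
#' discriminator identification on a PLINK dataset, writing every
#' stage's artifacts into an output directory: the filtered dataset
#' (`qc.bed/.bim/.fam`), `qc_report.tsv`, `assignment.tsv`,
#' `tree.json`, `fst_matrix.tsv` and `discriminators.tsv` (plus one
#' per-pair SNP list under `discriminators/`).  Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config a list (or path to a JSON file) with entries
#'   `bed_prefix` (input path stem), `out_dir`, optional `qc`
#'   (arguments for [qc_params()]), `ipclust` (arguments for
#'   [ipclust_params()]), `discriminators` (list with `percentile`,
#'   `n_permutations`, `B`), and flags `skip_qc`,
#'   `skip_discriminators`.
#' @return a run report: `list(qc_report, assignment, fit, fst_matrix,
#'   discriminators, group_summary)`, invisibly writing all artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$bed_prefix) || is.null(config$out_dir)) {
    stop("config needs bed_prefix and out_dir")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  x <- read_plink(config$bed_prefix)

  qc_report <- NULL
  if (!isTRUE(config$skip_qc)) {
    qp <- do.call(qc_params, as.list(config$qc))
    qc <- run_qc(x, qp)
    x <- qc$data
    qc_report <- qc$report
    write_qc_report(qc_report, file.path(config$out_dir, "qc_report.tsv"))
    write_plink(x, file.path(config$out_dir, "qc"))
  } else if (anyNA(x$dosages)) {
    x <- impute_most_frequent(x)
  }

  ip <- do.call(ipclust_params, as.list(config$ipclust))
  fit <- ipclust(x, params = ip)
  write_assignment(fit$assignment, file.path(config$out_dir,
                                             "assignment.tsv"))
  write_tree_json(fit, file.path(config$out_dir, "tree.json"))

  fst_matrix <- NULL
  disc <- NULL
  if (!isTRUE(config$skip_discriminators) && fit$n_groups >= 2) {
    acc <- fit$assignment[!fit$assignment$outlier, ]
    idx <- split(which(!fit$assignment$outlier),
                 acc$group)
    fst_matrix <- pairwise_group_fst(x, idx)
    utils::write.table(
      data.frame(group = rownames(fst_matrix), fst_matrix,
                 check.names = FALSE),
      file.path(config$out_dir, "fst_matrix.tsv"), quote = FALSE,
      sep = "\t", row.names = FALSE)
    dc <- config$discriminators
    disc <- all_pair_discriminators(
      x, fit$assignment,
      percentile = dc$percentile %||% 0.999,
      n_permutations = dc$n_permutations %||% 0L,
      B = dc$B %||% 1000L, seed = ip$seed)
    utils::write.table(disc$summary,
                       file.path(config$out_dir, "discriminators.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    ddir <- file.path(config$out_dir, "discriminators")
    dir.create(ddir, showWarnings = FALSE)
    for (nm in names(disc$results)) {
      write_discriminators(disc$results[[nm]], x,
                           file.path(ddir, paste0(nm, ".tsv")))
    }
  }

  group_summary <- crosstab_report(fit$assignment,
                                   x$samples$population_label)
  invisible(list(qc_report = qc_report, assignment = fit$assignment,
                 fit = fit, fst_matrix = fst_matrix,
                 discriminators = disc, group_summary = group_summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a cluster assignment with reference labels
#'
#' Builds the contingency table of inferred groups against truth (or
#' self-identified) labels, the adjusted Rand index, and each group's
#' majority label.  Reporting only: labels never influence clustering.
#'
#' @param assignment assignment data frame (from [ipclust()]).
#' @param labels vector of reference labels, one per sample in
#'   assignment order.
#' @return `list(table, ari, majority)`.
#' @export
crosstab_report <- function(assignment, labels) {
  if (is.null(labels) || all(is.na(labels))) {
    return(list(table = NULL, ari = NA_real_, majority = NULL))
  }
  tab <- table(group = assignment$group, label = labels)
  ari <- adjusted_rand_index(assignment$group, labels)
  majority <- apply(tab, 1, function(r) colnames(tab)[which.max(r)])
  list(table = tab, ari = ari, majority = majority)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions,
#' about 0 for independent ones.
#'
#' @param a,b partition labels of the same samples.
#' @return the index, in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  total <- choose2(length(a))
  expected <- sum_i * sum_j / total
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) {
    # degenerate margins (e.g. all-singleton partitions): identical
    # partitions still score 1, anything else 0
    return(as.numeric(sum_ij == maxi))
  }
  (sum_ij - expected) / (maxi - expected)
}
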