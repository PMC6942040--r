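#' Standardize a dosage matrix for PCA
#'
#' Drops SNPs monomorphic within the node (allele frequency 0 or 1),
#' mean-centers each remaining column and divides it by
#' `sqrt(2 p (1 - p))`, with `p` the column allele frequency, so every
#' SNP contributes on the same drift scale.
#'
#' @param dosages complete (no `NA`) dosage matrix with at least two
#'   rows.
#' @return a real matrix with zero column means; the `"kept"` attribute
#'   gives the retained column indices.
#' @export
standardize_genotypes <- function(dosages) {
  if (anyNA(dosages)) stop("impute missing genotypes before standardizing")
  if (nrow(dosages) < 2) stop("need at least two samples")
  p <- colMeans(dosages) / 2
  keep <- which(p > 0 & p < 1)
  X <- dosages[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  attr(X, "kept") <- keep
  X
}

#' Principal components of a standardized genotype matrix
#'
#' Eigendecomposition of the sample-side covariance `X X' / m` (`m` =
#' number of SNPs).  Scores are scaled so that `S S' = X X'` up to rank
#' `k`; each component's sign is fixed by making its largest-magnitude
#' score positive.
#'
#' @param X standardized matrix from [standardize_genotypes()].
#' @param k number of score columns returned.
#' @return `list(values, scores)`: all `n` eigenvalues (descending,
#'   clipped at zero) and the `n x k` score matrix.
#' @export
pc_decompose <- function(X, k = 3L) {
  n <- nrow(X)
  if (n < 3) stop("need at least three samples for PCA")
  m <- ncol(X)
  C <- tcrossprod(X) / m
  e <- eigen(C, symmetric = TRUE)
  values <- pmax(e$values, 0)
  k <- min(k, n)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] * sqrt(values[j] * m)
  }
  list(values = values, scores = scores)
}

#' EigenFit statistic of an eigenvalue spectrum
#'
#' The largest consecutive gap of log10 eigenvalues among the leading
#' `n_eigs` components: `max_i (log10 lambda_i - log10 lambda_{i+1})`.
#' A flat spectrum scores 0; strong low-dimensional structure opens a
#' large leading gap.  Non-positive eigenvalues are excluded before
#' taking logs; if fewer than `n_eigs` remain, the spectrum is padded
#' with its smallest positive value.
#'
#' @param values eigenvalues in descending order.
#' @param n_eigs number of leading eigenvalues examined (default 10).
#' @return the gap statistic (unitless, >= 0).
#' @export
eigenfit <- function(values, n_eigs = 10L) {
  pos <- values[values > 0]
  if (length(pos) < 2) return(0)
  if (length(pos) < n_eigs) {
    pos <- c(pos, rep(min(pos), n_eigs - length(pos)))
  }
  lv <- log10(pos[seq_len(n_eigs)])
  max(lv[-length(lv)] - lv[-1])
}

#' Gap-based splitting by rotation of the first three PCs
#'
#' Rotates the 3-D cloud of PC scores over a fixed angular grid (10
#' degree increments within each pair of coordinate planes) and scans
#' every axis of every rotation for an internal gap in the sorted
#' projection larger than `gap_factor` times that projection's
#' interquartile range.  The widest qualifying gap (relative to its IQR)
#' splits the samples in two.  Because the IQR of a balanced bimodal
#' projection spans the two modes, this criterion reacts to minority
#' groups and outliers; balanced splits are left to [mixture_split()].
#'
#' @param scores an `n x 3` matrix of PC scores.
#' @param gap_factor multiple of the IQR a gap must exceed (default 3).
#' @return `list(part1, part2)` of row indices, or `NULL` when no
#'   qualifying gap exists (including all `n < 4`).
#' @export
rubik_split <- function(scores, gap_factor = 3) {
  n <- nrow(scores)
  if (n < 4 || ncol(scores) < 3) return(NULL)
  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  angles <- seq(0, 80, by = 10) * pi / 180
  best <- NULL
  for (pl in planes) {
    for (a in angles) {
      R <- scores
      ca <- cos(a); sa <- sin(a)
      R[, pl[1]] <- ca * scores[, pl[1]] - sa * scores[, pl[2]]
      R[, pl[2]] <- sa * scores[, pl[1]] + ca * scores[, pl[2]]
      for (ax in 1:3) {
        v <- R[, ax]
        o <- order(v)
        sv <- v[o]
        gaps <- diff(sv)
        iqr <- stats::IQR(sv)
        if (iqr <= 0) next
        qual <- which(gaps > gap_factor * iqr)
        if (!length(qual)) next
        g <- qual[which.max(gaps[qual])]
        score <- gaps[g] / iqr
        if (is.null(best) || score > best$score) {
          best <- list(score = score, left = o[seq_len(g)],
                       right = o[seq((g + 1), n)])
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(part1 = sort(best$left), part2 = sort(best$right))
}

#' Two-component Gaussian mixture splitting of PC scores
#'
#' Fits one- and two-component Gaussian mixtures with unrestricted
#' covariances (model-based EM, deterministic hierarchical
#' initialisation) and returns the two-component maximum-a-posteriori
#' partition when BIC prefers it; otherwise reports no separation.
#'
#' @param scores `n x d` matrix of PC scores.
#' @return `list(part1, part2)` of row indices, or `NULL` when a single
#'   component fits better (or the fit degenerates).
#' @importFrom mclust Mclust mclustBIC
#' @export
mixture_split <- function(scores) {
  n <- nrow(scores)
  if (n < 4) return(NULL)
  fit <- tryCatch(
    Mclust(scores, G = 1:2, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$G < 2) return(NULL)
  cl <- fit$classification
  if (length(unique(cl)) < 2) return(NULL)
  list(part1 = which(cl == 1), part2 = which(cl == 2))
}

#' Iterative PCA clustering parameters
#'
#' @param threshold EigenFit stop value; splitting is only attempted at
#'   nodes whose spectrum gap reaches it.  The useful range is about
#'   0.03 (fine resolution, more groups) to 0.18 (coarse resolution);
#'   values outside it are accepted with a warning.
#' @param min_in_group nodes smaller than this are never split further
#'   (range 5-20 recommended).
#' @param min_fst minimum average Hudson FST between the two largest
#'   proposed children for a split to be accepted.
#' @param n_pcs_cluster number of leading PCs used for splitting (>= 3).
#' @param n_eigs_fit number of leading eigenvalues entering EigenFit.
#' @param outlier_size terminal groups smaller than this are reported as
#'   outlier groups.
#' @param gap_factor rotation-split gap criterion, see [rubik_split()].
#' @param seed integer seed recorded with the fit (the engine itself is
#'   deterministic).
#' @return list of class `ipclust_params`.
#' @export
ipclust_params <- function(threshold = 0.18, min_in_group = 20L,
                           min_fst = 0.0008, n_pcs_cluster = 3L,
                           n_eigs_fit = 10L, outlier_size = 5L,
                           gap_factor = 3, seed = 1L) {
  if (threshold < 0.03 || threshold > 0.18) {
    warning("threshold ", threshold, " is outside the recommended range ",
            "[0.03, 0.18]")
  }
  stopifnot(min_fst >= 0, n_pcs_cluster >= 3, min_in_group >= 2,
            n_eigs_fit >= 2, outlier_size >= 1)
  structure(list(threshold = threshold,
                 min_in_group = as.integer(min_in_group),
                 min_fst = min_fst,
                 n_pcs_cluster = as.integer(n_pcs_cluster),
                 n_eigs_fit = as.integer(n_eigs_fit),
                 outlier_size = as.integer(outlier_size),
                 gap_factor = gap_factor, seed = as.integer(seed)),
            class = "ipclust_params")
}

#' Iterative PCA clustering of SNP genotypes
#'
#' Recursively partitions the samples of a QC'd, imputed genotype
#' dataset.  At each node the dosages are standardized, the sample
#' covariance eigendecomposed, and the EigenFit spectrum-gap statistic
#' computed; nodes whose gap falls below `threshold` become leaves.
#' Otherwise a split is proposed, first by rotation-based gap search in
#' the top three PCs ([rubik_split()], which peels outliers and minority
#' groups), then by two-component Gaussian mixture modelling
#' ([mixture_split()]).  A proposed split is accepted only when the
#' average Hudson FST between its two largest children reaches
#' `min_fst` (singleton peels skip the FST gate); accepted children of
#' size at least `min_in_group` are recursed into.  Terminal groups
#' smaller than `outlier_size` (default 5) are reported as outlier
#' groups.  The procedure is deterministic for fixed data and
#' parameters.
#'
#' @param x a [genotype_dataset()] without missing genotypes (run
#'   [run_qc()] first), or a complete dosage matrix.
#' @param threshold,min_in_group,min_fst,seed see [ipclust_params()].
#' @param params a full [ipclust_params()] object; overrides the
#'   individual arguments.
#' @return an object of class `ipclust` with components
#'   \describe{
#'     \item{assignment}{data frame: `family_id`, `individual_id`,
#'       `group`, `outlier`, `node_path`; accepted groups are numbered
#'       1..k in depth-first order, outlier groups continue k+1..}
#'     \item{nodes}{data frame of the splitting history: one row per
#'       node with its size, depth, EigenFit value, split method,
#'       inter-child FST and status (`split`, `leaf` or `outlier`).}
#'     \item{scores}{the top-3 PC scores of the root decomposition (for
#'       plotting).}
#'     \item{params}{the parameters used.}
#'   }
#' @examples
#' \donttest{
#' spec <- population_tree_spec(
#'   list(children = list(list(F = 0.05, name = "P1", n = 30),
#'                        list(F = 0.05, name = "P2", n = 30))),
#'   n_snps = 2000, seed = 7)
#' x <- sample_genotypes(simulate_tree(spec), leaf_sizes(spec), seed = 7)
#' fit <- ipclust(x, threshold = 0.03, min_in_group = 10)
#' table(fit$assignment$group, x$samples$population_label)
#' }
#' @export
ipclust <- function(x, threshold = 0.18, min_in_group = 20L,
                    min_fst = 0.0008, seed = 1L, params = NULL) {
  if (is.null(params)) {
    params <- ipclust_params(threshold = threshold,
                             min_in_group = min_in_group,
                             min_fst = min_fst, seed = seed)
  }
  stopifnot(inherits(params, "ipclust_params"))
  dataset <- inherits(x, "genotype_dataset")
  D <- if (dataset) x$dosages else as.matrix(x)
  if (anyNA(D)) {
    stop("dataset contains missing genotypes; run run_qc() or ",
         "impute_most_frequent() first")
  }
  n <- nrow(D)

  nodes <- list()
  terminal <- list()   # list of list(members, path)
  root_scores <- NULL

  note_node <- function(path, members, depth, ef, method, fst, status) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      node_path = path, size = length(members), depth = depth,
      eigenfit = ef, split_method = method, inter_child_fst = fst,
      status = status, stringsAsFactors = FALSE)
  }

  recurse <- function(members, path, depth) {
    size <- length(members)
    if (size < params$min_in_group) {
      note_node(path, members, depth, NA_real_, "none", NA_real_, "leaf")
      terminal[[length(terminal) + 1L]] <<- list(members = members,
                                                 path = path)
      return(invisible(NULL))
    }
    X <- standardize_genotypes(D[members, , drop = FALSE])
    if (ncol(X) == 0) {
      note_node(path, members, depth, 0, "none", NA_real_, "leaf")
      terminal[[length(terminal) + 1L]] <<- list(members = members,
                                                 path = path)
      return(invisible(NULL))
    }
    pc <- pc_decompose(X, k = max(3L, params$n_pcs_cluster))
    if (depth == 0L) root_scores <<- pc$scores[, 1:3, drop = FALSE]
    ef <- eigenfit(pc$values, params$n_eigs_fit)
    if (ef < params$threshold) {
      note_node(path, members, depth, ef, "none", NA_real_, "leaf")
      terminal[[length(terminal) + 1L]] <<- list(members = members,
                                                 path = path)
      return(invisible(NULL))
    }

    gate <- function(parts) {
      # accept unless the two largest children show FST below min_fst;
      # singleton peels carry no frequency information and pass.
      sizes <- vapply(parts, length, integer(1))
      ord <- order(sizes, decreasing = TRUE)
      g1 <- parts[[ord[1]]]; g2 <- parts[[ord[2]]]
      if (length(g2) < 2) return(list(ok = TRUE, fst = NA_real_))
      est <- tryCatch(
        average_fst(fst_components(D, members[g1], members[g2])),
        error = function(e) NA_real_)
      list(ok = !is.na(est) && est >= params$min_fst, fst = est)
    }

    parts <- rubik_split(pc$scores[, 1:3, drop = FALSE],
                         params$gap_factor)
    method <- "rubik"
    verdict <- if (is.null(parts)) NULL else gate(parts)
    if (is.null(parts) || !verdict$ok) {
      if (size >= 2L * params$min_in_group) {
        parts2 <- mixture_split(
          pc$scores[, seq_len(params$n_pcs_cluster), drop = FALSE])
        verdict2 <- if (is.null(parts2)) NULL else gate(parts2)
        if (!is.null(parts2) && verdict2$ok) {
          parts <- parts2
          verdict <- verdict2
          method <- "mixture"
        } else {
          parts <- NULL
        }
      } else {
        parts <- NULL
      }
    }
    if (is.null(parts)) {
      note_node(path, members, depth, ef, "none", NA_real_, "leaf")
      terminal[[length(terminal) + 1L]] <<- list(members = members,
                                                 path = path)
      return(invisible(NULL))
    }

    note_node(path, members, depth, ef, method, verdict$fst, "split")
    # deterministic child order: by smallest member index
    first <- vapply(parts, function(p) min(members[p]), numeric(1))
    parts <- parts[order(first)]
    for (ci in seq_along(parts)) {
      recurse(members[parts[[ci]]], paste0(path, "/", ci), depth + 1L)
    }
    invisible(NULL)
  }

  recurse(seq_len(n), "0", 0L)

  node_tab <- do.call(rbind, nodes)
  sizes <- vapply(terminal, function(t) length(t$members), integer(1))
  is_out <- sizes < params$outlier_size
  node_tab$status[match(vapply(terminal, `[[`, "", "path"),
                        node_tab$node_path)] <-
    ifelse(is_out, "outlier", "leaf")

  group_id <- integer(length(terminal))
  group_id[!is_out] <- seq_len(sum(!is_out))
  group_id[is_out] <- sum(!is_out) + seq_len(sum(is_out))

  group <- integer(n)
  outlier <- logical(n)
  node_path <- character(n)
  for (t in seq_along(terminal)) {
    idx <- terminal[[t]]$members
    group[idx] <- group_id[t]
    outlier[idx] <- is_out[t]
    node_path[idx] <- terminal[[t]]$path
  }

  assignment <- data.frame(
    family_id = if (dataset) x$samples$family_id else
      sprintf("F%04d", seq_len(n)),
    individual_id = if (dataset) x$samples$individual_id else
      sprintf("ind%04d", seq_len(n)),
    group = group, outlier = outlier, node_path = node_path,
    stringsAsFactors = FALSE
  )

  structure(list(assignment = assignment, nodes = node_tab,
                 scores = root_scores, params = params,
                 n_groups = sum(!is_out), n_outlier_groups = sum(is_out),
                 call = match.call()),
            class = "ipclust")
}

#' @export
print.ipclust <- function(x, ...) {
  cat("Iterative PCA clustering (threshold =", x$params$threshold,
      ", min_in_group =", x$params$min_in_group,
      ", min_fst =", x$params$min_fst, ")\n")
  cat("  ", nrow(x$assignment), "samples ->", x$n_groups,
      "accepted groups,", x$n_outlier_groups, "outlier groups\n")
  acc <- table(x$assignment$group[!x$assignment$outlier])
  if (length(acc)) {
    cat("  accepted group sizes:", paste(as.integer(acc), collapse = " "),
        "\n")
  }
  if (x$n_outlier_groups) {
    cat("  outlier samples:", sum(x$assignment$outlier), "\n")
  }
  invisible(x)
}

#' @export
summary.ipclust <- function(object, ...) {
  tab <- table(group = object$assignment$group,
               outlier = object$assignment$outlier)
  out <- list(params = object$params, nodes = object$nodes,
              group_sizes = table(object$assignment$group),
              n_groups = object$n_groups,
              n_outlier_groups = object$n_outlier_groups)
  class(out) <- "summary.ipclust"
  out
}

#' @export
print.summary.ipclust <- function(x, ...) {
  cat("Iterative PCA clustering:", x$n_groups, "accepted groups,",
      x$n_outlier_groups, "outlier groups\n\nSplitting history:\n")
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Plot an iterative PCA clustering
#'
#' Scatter of the root principal-component scores coloured by final
#' group; outlier samples are drawn as crosses.
#'
#' @param x an [ipclust()] fit.
#' @param dims which two PCs to draw (default `c(1, 2)`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ipclust <- function(x, dims = c(1, 2), ...) {
  s <- x$scores
  if (is.null(s)) stop("no scores recorded (root was not decomposed)")
  grp <- x$assignment$group
  pch <- ifelse(x$assignment$outlier, 4L, 19L)
  graphics::plot(s[, dims[1]], s[, dims[2]],
                 col = grp %% 8 + 1, pch = pch,
                 xlab = paste0("PC", dims[1]),
                 ylab = paste0("PC", dims[2]), ...)
  invisible(x)
}

#' @export
as.data.frame.ipclust <- function(x, ...) x$assignment

#' Export an ipclust tree as JSON
#'
#' @param fit an [ipclust()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(fit, path) {
  jsonlite::write_json(
    list(params = unclass(fit$params), nodes = fit$nodes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
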