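test_that("standardization centers, scales and drops monomorphic SNPs", {
  D <- cbind(c(0L, 1L, 2L), c(1L, 1L, 1L), c(2L, 2L, 2L))
  X <- standardize_genotypes(D)
  # column (0,1,2): p = 0.5, scale sqrt(2 * 0.25)
  expect_equal(X[, 1], c(-1, 0, 1) / sqrt(0.5))
  expect_identical(attr(X, "kept"), c(1L, 2L))   # p = 1 column dropped
  expect_equal(colMeans(X), c(0, 0))
  expect_error(standardize_genotypes(cbind(c(0L, NA, 2L))), "impute")
})

test_that("node PCA agrees with a brute-force decomposition", {
  set.seed(31)
  X <- matrix(rnorm(20 * 50), 20, 50)
  X <- sweep(X, 2, colMeans(X))
  pc <- pc_decompose(X, k = 5)
  # oracle: singular values of X give the same spectrum
  sv <- svd(X)
  expect_equal(pc$values, c(sv$d^2 / 50, rep(0, 0))[1:20], tolerance = 1e-8)
  # eigenvalue sum equals the total variance of the standardized matrix
  expect_equal(sum(pc$values), sum(X^2) / 50)
  # scores reproduce sample inner products up to rank k
  G <- tcrossprod(X)
  Gk <- tcrossprod(pc$scores)
  full <- svd(X, nu = 5)
  Gk_oracle <- tcrossprod(full$u %*% diag(full$d[1:5]))
  expect_equal(Gk, Gk_oracle, tolerance = 1e-8)
})

test_that("PC1 separates two mean-shifted point clouds", {
  set.seed(32)
  D <- rbind(matrix(rbinom(20 * 200, 2, 0.2), 20),
             matrix(rbinom(20 * 200, 2, 0.8), 20))
  pc <- pc_decompose(standardize_genotypes(D), k = 3)
  s1 <- pc$scores[1:20, 1]
  s2 <- pc$scores[21:40, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("EigenFit measures the largest log10 spectral gap", {
  expect_equal(eigenfit(rep(2, 12)), 0)
  expect_equal(eigenfit(c(100, rep(1, 11))), 2)
  # shorter spectra are padded with the smallest positive eigenvalue
  expect_equal(eigenfit(c(100, 1, 1)), 2)
  # non-positive eigenvalues are excluded before logs
  expect_equal(eigenfit(c(100, rep(1, 10), 0, -1e-12)), 2)
  # gaps below the leading n_eigs are ignored
  expect_equal(eigenfit(c(rep(2, 15), 1e-4), n_eigs = 10), 0)
})

test_that("rotation splitting peels minority clouds and outliers", {
  set.seed(33)
  # minority cloud at 10x the spread along a diagonal direction
  main <- matrix(rnorm(180 * 3), 180, 3)
  minority <- matrix(rnorm(20 * 3), 20, 3) + 10
  sc <- rbind(main, minority)
  sp <- rubik_split(sc)
  expect_false(is.null(sp))
  small <- if (length(sp$part1) < length(sp$part2)) sp$part1 else sp$part2
  expect_identical(small, 181:200)

  # single isotropic cloud: no separation
  expect_null(rubik_split(matrix(rnorm(200 * 3), 200, 3)))

  # one point at 20 sigma: singleton peeled
  sc2 <- matrix(rnorm(100 * 3), 100, 3)
  sc2[7, ] <- c(20, 0, 0)
  sp2 <- rubik_split(sc2)
  expect_false(is.null(sp2))
  small2 <- if (length(sp2$part1) < length(sp2$part2)) sp2$part1 else
    sp2$part2
  expect_identical(small2, 7L)

  expect_null(rubik_split(matrix(rnorm(9), 3, 3)))  # n < 4
})

test_that("mixture splitting recovers separated components, not noise", {
  set.seed(34)
  a <- matrix(rnorm(60 * 3), 60, 3)
  b <- matrix(rnorm(60 * 3), 60, 3) + 8
  sp <- mixture_split(rbind(a, b))
  expect_false(is.null(sp))
  got <- sort(unname(vapply(sp, length, integer(1))))
  expect_identical(got, c(60L, 60L))
  expect_true(identical(sort(sp$part1), 1:60) ||
                identical(sort(sp$part2), 1:60))

  # single Gaussian: BIC prefers one component in most replicates
  rejections <- sum(vapply(1:20, function(r) {
    set.seed(100 + r)
    is.null(mixture_split(matrix(rnorm(150 * 3), 150, 3)))
  }, logical(1)))
  expect_gte(rejections, 18)

  # deterministic: same input, same partition
  sp2 <- mixture_split(rbind(a, b))
  expect_identical(sp, sp2)
})

test_that("a homogeneous population yields a single group", {
  D <- bn_single(80, 3000, seed = 35)
  fit <- ipclust(D, threshold = 0.18, min_in_group = 10)
  expect_identical(fit$n_groups, 1L)
  expect_identical(fit$n_outlier_groups, 0L)
})

test_that("a two-population sample at F = 0.005 is split, panmixia is not", {
  D <- bn_pair(0.005, 60, 8000, seed = 36)
  fit <- ipclust(D, threshold = 0.03, min_in_group = 10)
  expect_identical(fit$n_groups, 2L)
  truth <- rep(1:2, each = 60)
  expect_equal(adjusted_rand_index(fit$assignment$group, truth), 1)
})

test_that("leaves partition the samples and the run is deterministic", {
  set.seed(37)
  spec <- population_tree_spec(
    list(children = list(
      list(F = 0.02, name = "P1", n = 40L),
      list(F = 0.02, children = list(
        list(F = 0.008, name = "P2", n = 40L),
        list(F = 0.008, name = "P3", n = 40L)
      ))
    )), n_snps = 4000, seed = 37)
  x <- sample_genotypes(simulate_tree(spec), leaf_sizes(spec), seed = 38)
  fit1 <- ipclust(x, threshold = 0.03, min_in_group = 10)
  fit2 <- ipclust(x, threshold = 0.03, min_in_group = 10)
  expect_identical(fit1$assignment, fit2$assignment)
  # every sample appears exactly once with a positive group id
  expect_identical(sort(unique(fit1$assignment$group)),
                   seq_len(max(fit1$assignment$group)))
  expect_identical(nrow(fit1$assignment), n_samples(x))
  # nested structure recovered at the fine threshold
  expect_gte(adjusted_rand_index(fit1$assignment$group,
                                 x$samples$population_label), 0.95)

  # threshold monotonicity: the coarse threshold finds at most as many
  # groups as the fine one
  fit_coarse <- ipclust(x, threshold = 0.18, min_in_group = 10)
  expect_lte(fit_coarse$n_groups, fit1$n_groups)

  # no accepted sibling pair below min_fst (splitting history contract)
  splits <- fit1$nodes[fit1$nodes$status == "split" &
                         !is.na(fit1$nodes$inter_child_fst), ]
  expect_true(all(splits$inter_child_fst >= fit1$params$min_fst))
})

test_that("small nodes become leaves and tiny terminal groups outliers", {
  D <- bn_single(15, 1000, seed = 39)
  fit <- ipclust(D, min_in_group = 20)        # root below min_in_group
  expect_identical(fit$n_groups, 1L)
  expect_identical(unique(fit$assignment$node_path), "0")

  # planted far-away singletons peel off as outlier groups
  D2 <- bn_single(60, 2000, seed = 40)
  div <- bn_single(3, 2000, seed = 41, F = 0.5)
  x <- rbind(D2, div)
  fit2 <- ipclust(x, threshold = 0.03, min_in_group = 10)
  asg <- fit2$assignment
  expect_true(all(asg$outlier[61:63]))
  expect_true(all(!asg$outlier[1:60]))
  out_sizes <- table(asg$group[asg$outlier])
  expect_true(all(out_sizes < 5))
})

test_that("adjusted Rand index matches the mclust reference", {
  set.seed(42)
  for (r in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("ipclust accessors and plot behave", {
  D <- bn_pair(0.05, 25, 2000, seed = 43)
  fit <- ipclust(D, threshold = 0.03, min_in_group = 10)
  expect_s3_class(fit, "ipclust")
  expect_output(print(fit), "accepted groups")
  expect_output(print(summary(fit)), "Splitting history")
  expect_identical(as.data.frame(fit), fit$assignment)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(ipclust(cbind(c(0L, NA, 1L, 2L))), "missing")
})
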