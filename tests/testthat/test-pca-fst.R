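test_that("normalization follows the shrunk-frequency convention", {
  # all-heterozygous column: p-hat = (1+4)/(2+8) = 0.5, centres to zeros, kept
  gm <- genotype_matrix(cbind(rep(1L, 4), c(0L, 1L, 2L, 1L)))
  x <- normalize_genotypes(gm)
  expect_identical(ncol(x), 2L)
  expect_equal(unname(x[, 1]), rep(0, 4))
  # explicit hand evaluation of column 2: s = 4, n = 4
  p <- (1 + 4) / (2 + 8)
  expect_equal(unname(x[, 2]), (c(0, 1, 2, 1) - 2 * p) / sqrt(p * (1 - p)))
  # allele-level fixed column is dropped with a notice
  gm2 <- genotype_matrix(cbind(rep(0L, 4), c(0L, 1L, 2L, 1L)))
  expect_message(x2 <- normalize_genotypes(gm2), "monomorphic")
  expect_identical(ncol(x2), 1L)
  # centring: column means ~ 0 under the MLE variant with no missing data
  gm3 <- random_genotypes(30, 20, seed = 2)
  x3 <- normalize_genotypes(gm3, shrink = FALSE)
  expect_equal(unname(colMeans(x3)), rep(0, ncol(x3)), tolerance = 1e-12)
  # row-wise operation: permutation equivariance
  perm <- sample(nrow(gm3$dosages))
  gm_p <- genotype_matrix(gm3$dosages[perm, ], snps = gm3$snps,
                          sample_ids = gm3$sample_ids[perm])
  expect_equal(unname(normalize_genotypes(gm_p)),
               unname(normalize_genotypes(gm3)[perm, ]))
  # missing entries centre to exactly zero
  d <- gm3$dosages; d[3, 5] <- NA
  gm_m <- genotype_matrix(d, snps = gm3$snps, sample_ids = gm3$sample_ids)
  expect_equal(unname(normalize_genotypes(gm_m)[3, 5]), 0)
})

test_that("run_pca matches an independent SVD and conserves variance", {
  set.seed(10)
  x <- matrix(rnorm(20 * 50), 20, 50)
  pca <- run_pca(x, 20)
  # oracle: eigen-decomposition of the explicit covariance matrix
  ev <- eigen(tcrossprod(x) / ncol(x), symmetric = TRUE)
  expect_equal(pca$eigenvalues, ev$values, tolerance = 1e-8)
  expect_equal(sum(pca$eigenvalues), sum(diag(tcrossprod(x) / ncol(x))))
  expect_true(all(diff(pca$eigenvalues) <= 1e-10))
  expect_true(all(pca$eigenvalues > -1e-10))
  # projections: orthogonal columns, norms tied to the eigenvalues
  g <- crossprod(pca$projections)
  expect_equal(g, diag(diag(g)), tolerance = 1e-6)
  expect_equal(diag(g) / ncol(x), pca$eigenvalues, tolerance = 1e-8)
  # rank-1 input: all but the first eigenvalue vanish
  r1 <- outer(rnorm(10), rnorm(30))
  p1 <- run_pca(r1, 5)
  expect_lt(max(p1$eigenvalues[-1]), 1e-10)
  expect_error(run_pca(x, 21), "k must lie")
})

test_that("fst_hudson reproduces hand-derived single-SNP values", {
  # fixed difference: p1 = 1, p2 = 0 -> estimate exactly 1
  gm <- genotype_matrix(matrix(c(2L, 2L, 0L, 0L), ncol = 1))
  lab <- label_set(gm$sample_ids, c(0L, 0L, 1L, 1L))
  est <- fst_hudson(gm, lab)
  expect_identical(est$fst_hat, 1)
  # symmetric heterozygote case: n_s = -1/6, d_s = 1/2 -> -1/3
  gm2 <- genotype_matrix(matrix(rep(1L, 4), ncol = 1))
  est2 <- fst_hudson(gm2, lab)
  expect_equal(est2$fst_hat, -1 / 3)
})

test_that("fst_hudson equals the brute-force per-SNP oracle", {
  set.seed(20)
  for (rep in 1:50) {
    m <- sample(6:20, 1)
    gm <- random_genotypes(m, sample(5:40, 1),
                           miss_rate = sample(c(0, 0.15), 1))
    n1 <- sample(2:(m - 2), 1)
    lab <- two_pop_labels(gm, max(2, n1))
    est <- fst_hudson(gm, lab)
    expect_equal(est$fst_hat, fst_brute(gm, lab), tolerance = 1e-12)
  }
})

test_that("fst_hudson is bounded by 1, negative in expectation under the null,
           and reports a finite jackknife SE", {
  set.seed(30)
  vals <- ses <- numeric(30)
  for (r in 1:30) {
    sim <- simulate_pair(sim_spec(0, 200, c(15, 15), seed = NULL))
    est <- fst_hudson(sim$genotypes, sim$labels)
    vals[r] <- est$fst_hat; ses[r] <- est$se
  }
  expect_true(all(vals <= 1))
  expect_lt(mean(vals), 0)          # finite-sample bias of the ratio of sums
  expect_true(all(is.finite(ses) & ses >= 0))
  # jackknife SE is a sane scale for the null spread
  expect_lt(abs(mean(vals)), 4 * mean(ses))
})

test_that("the BBP critical threshold follows 1/sqrt(N*M)", {
  expect_equal(fst_critical(500, 400), 2.2360679e-3, tolerance = 1e-7)
  expect_equal(fst_critical(5739, 400), 6.60e-4, tolerance = 1e-3)
  expect_equal(fst_critical(4 * 500, 400), fst_critical(500, 400) / 2)
  expect_error(fst_critical(0, 10), "n_snps")
})

test_that("the summed-ANOVA structure test matches a textbook ANOVA", {
  set.seed(40)
  x <- matrix(rnorm(12 * 30), 12, 30)
  gm <- random_genotypes(12, 30)
  lab <- two_pop_labels(gm, 6)
  pca <- run_pca(x, 4)
  rownames(pca$projections) <- gm$sample_ids
  st <- anova_structure_test(pca, lab, 4)
  g <- lab$labels[gm$sample_ids]
  for (k in 1:4)
    expect_equal(st$axis_stats[k], anova_f_oracle(pca$projections[, k], g))
  expect_equal(st$global_stat, sum(st$axis_stats))
  expect_identical(st$dof, 4L)
  expect_equal(st$p_value,
               pchisq(st$global_stat, 4, lower.tail = FALSE))
  # identical projections in both groups -> zero statistic, p = 1
  pca0 <- pca
  pca0$projections <- matrix(rep(seq_len(6), 2), 12, 4)
  rownames(pca0$projections) <- gm$sample_ids
  st0 <- anova_structure_test(pca0, lab, 4)
  expect_equal(st0$global_stat, 0)
  expect_equal(st0$p_value, 1)
})

test_that("the global chi-squared p-value is roughly uniform under the null", {
  set.seed(50)
  pvals <- vapply(1:300, function(r) {
    sim <- simulate_pair(sim_spec(0, 60, c(20, 20), seed = NULL))
    x <- suppressMessages(normalize_genotypes(sim$genotypes))
    pca <- run_pca(x, 5)
    anova_structure_test(pca, sim$labels, 5)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 0 & pvals <= 1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 1e-4)
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("pca_window_scan tiles the axis and localises a divergent block", {
  sim <- simulate_blocks(c(50, 50), c(0.08, 0), c(50, 50), seed = 60)
  scan <- pca_window_scan(sim$genotypes, sim$labels, 50, k_axes = 5)
  expect_identical(nrow(scan), 2L)
  expect_identical(scan$start, c(0L, 50L))
  expect_identical(scan$end, c(50L, 100L))
  expect_gt(scan$fst_hat[1], scan$fst_crit[1])
  expect_lt(scan$p_value[1], 0.01)
  expect_lt(scan$fst_hat[2], scan$fst_crit[2])
  # trailing partial window is dropped
  scan2 <- pca_window_scan(sim$genotypes, sim$labels, 30, k_axes = 3)
  expect_identical(nrow(scan2), 3L)
  # degenerate all-fixed window yields a flagged record, not an error
  d <- sim$genotypes$dosages
  d[, 51:100] <- 0L
  gm_deg <- genotype_matrix(d, snps = sim$genotypes$snps,
                            sample_ids = sim$genotypes$sample_ids)
  scan3 <- pca_window_scan(gm_deg, sim$labels, 50, k_axes = 5)
  expect_true(scan3$degenerate[2])
  expect_true(is.na(scan3$fst_hat[2]))
})
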