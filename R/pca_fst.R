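#' Normalize genotypes for PCA
#'
#' Per SNP the allele frequency is estimated with the shrunk form
#' `p-hat = (1 + sum of dosages) / (2 + 2 * n_called)` (the eigensoft
#' smartpca convention; set `shrink = FALSE` for the plain maximum-likelihood
#' frequency), each dosage is centred by `2 p-hat` and scaled by
#' `sqrt(p-hat (1 - p-hat))`, and missing entries are set to 0 after
#' centring (i.e. to the mean).  SNPs fixed at the allele level (all
#' non-missing dosages 0, or all 2) carry no variance and are dropped with a
#' notice; an all-heterozygous column is kept (it centres to zeros under the
#' shrunk frequency).
#'
#' @param gm a [genotype_matrix()].
#' @param shrink use the shrunk frequency estimate (default) or the MLE.
#' @return A numeric samples x SNPs matrix; dropped SNPs are absent.
#' @export
normalize_genotypes <- function(gm, shrink = TRUE) {
  d <- gm$dosages
  if (length(d) == 0L) stop("empty genotype matrix")
  st <- norm_stats(d, shrink = shrink)
  if (length(st$dropped))
    message(sprintf("normalize_genotypes: dropped %d monomorphic SNP(s)",
                    length(st$dropped)))
  apply_norm(d[, st$keep, drop = FALSE], st)
}

# frequency/scale statistics for normalization, computed on `d` (the training
# rows in leakage-free classifier paths).  keep = non-fixed SNP columns.
norm_stats <- function(d, shrink = TRUE) {
  x <- matrix(as.numeric(d), nrow = nrow(d))
  n_called <- colSums(!is.na(x))
  if (any(n_called == 0L)) stop("SNP with no non-missing calls")
  s <- colSums(x, na.rm = TRUE)
  p <- if (shrink) (1 + s) / (2 + 2 * n_called) else s / (2 * n_called)
  p_mle <- s / (2 * n_called)
  keep <- which(p_mle > 0 & p_mle < 1)
  dropped <- which(p_mle <= 0 | p_mle >= 1)
  list(p = p[keep], keep = keep, dropped = dropped, shrink = shrink)
}

# centre/scale columns of dosage matrix `d` (already restricted to st$keep)
apply_norm <- function(d, st) {
  x <- matrix(as.numeric(d), nrow = nrow(d), dimnames = dimnames(d))
  out <- sweep(x, 2, 2 * st$p)
  out <- sweep(out, 2, sqrt(st$p * (1 - st$p)), "/")
  out[is.na(out)] <- 0
  out
}

#' Principal components of a normalized genotype matrix
#'
#' Eigen-decomposes the M x M sample covariance `X X' / N` of the normalized
#' rows (computed via the SVD of `X`).  Projections are the sample
#' coordinates on the top axes, `U D` restricted to the first `k` columns.
#'
#' @param x numeric samples x SNPs matrix, e.g. from [normalize_genotypes()].
#' @param k number of axes to retain, at most `min(M, N)`.
#' @return An object of class `pca_result`: list with `eigenvalues` (all
#'   `min(M, N)` covariance eigenvalues, non-increasing), `projections`
#'   (M x k sample scores) and `n_axes = k`.
#' @export
run_pca <- function(x, k) {
  m <- nrow(x); n <- ncol(x)
  if (k < 1L || k > min(m, n)) stop("k must lie in 1..min(M, N)")
  if (!all(is.finite(x))) stop("normalized matrix must be finite")
  sv <- svd(x, nu = min(m, n), nv = 0)
  eig <- sv$d^2 / n
  proj <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(proj) <- rownames(x)
  structure(list(eigenvalues = eig, projections = proj, n_axes = as.integer(k)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d axes retained\n",
              nrow(x$projections), x$n_axes))
  cat("  top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Hudson/Reich ratio-of-sums F_ST estimator
#'
#' Per SNP, with sample allele frequencies `p1, p2` from allele counts over
#' `n1, n2` non-missing allele copies, the numerator is
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`; the estimate is the ratio of sums over SNPs.  It is
#' biased but asymptotically consistent for Wright's F_ST and may be negative
#' in finite samples.  The standard error is a delete-one-SNP jackknife of
#' the ratio.
#'
#' SNPs with a zero denominator, or with fewer than two non-missing calls in
#' either class, are excluded (reflected in `n_snps_used`).
#'
#' @param gm a [genotype_matrix()].
#' @param labels a [label_set()]; only labelled samples are used.
#' @return An object of class `fst_estimate`: list with `fst_hat`, `se`,
#'   `n_snps_used`, `n1`, `n2` (individuals per class).
#' @export
fst_hudson <- function(gm, labels) {
  lab <- align_labels(gm, labels)
  ids0 <- names(lab)[lab == 0L]; ids1 <- names(lab)[lab == 1L]
  if (length(ids0) < 2L || length(ids1) < 2L)
    stop("each class needs at least 2 individuals")
  d <- gm$dosages
  d0 <- d[ids0, , drop = FALSE]; d1 <- d[ids1, , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d0))          # allele copies per class
  n2 <- 2 * colSums(!is.na(d1))
  a1 <- colSums(d0, na.rm = TRUE); a2 <- colSums(d1, na.rm = TRUE)
  usable <- n1 >= 4 & n2 >= 4            # >=2 non-missing calls per class
  if (!any(usable))
    stop("no SNP has >=2 non-missing calls in both classes")
  p1 <- a1[usable] / n1[usable]; p2 <- a2[usable] / n2[usable]
  m1 <- n1[usable]; m2 <- n2[usable]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  num <- num[keep]; den <- den[keep]
  if (!length(num)) stop("all SNPs degenerate (zero denominator)")
  fst_hat <- sum(num) / sum(den)
  j <- length(num)
  if (j > 1L) {
    loo <- (sum(num) - num) / (sum(den) - den)
    se <- sqrt((j - 1) / j * sum((loo - mean(loo))^2))
  } else se <- 0
  structure(list(fst_hat = fst_hat, se = se, n_snps_used = j,
                 n1 = length(ids0), n2 = length(ids1)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("F_ST (ratio of sums): %.6g  (SE %.3g, %d SNPs, %d + %d individuals)\n",
              x$fst_hat, x$se, x$n_snps_used, x$n1, x$n2))
  invisible(x)
}

#' BBP critical F_ST threshold
#'
#' The Baik-Ben Arous-Peche phase-transition point for PCA detectability of
#' two equal-sized populations: below `1 / sqrt(n_snps * n_individuals)` the
#' leading sample eigenvector carries no population signal and structure is
#' conjectured undetectable by any unsupervised method.
#'
#' @param n_snps number of SNPs (N).
#' @param n_individuals total number of individuals (M).
#' @return The critical F_ST value.
#' @export
fst_critical <- function(n_snps, n_individuals) {
  if (n_snps < 1 || n_individuals < 2)
    stop("need n_snps >= 1 and n_individuals >= 2")
  1 / sqrt(n_snps * n_individuals)
}

#' Summed-ANOVA structure test over principal axes
#'
#' For each retained axis, the one-way ANOVA F statistic for the difference in
#' mean projection between the two labelled groups; the global statistic is
#' the sum over the first `k_axes` axes and is referred to a chi-squared
#' distribution with `k_axes` degrees of freedom (upper tail).
#'
#' @param pca a [run_pca()] result whose projection rows are the labelled
#'   samples in `labels`' order of appearance within the genotype matrix.
#' @param labels a [label_set()].
#' @param k_axes number of leading axes to sum over (default all retained).
#' @return An object of class `structure_test`: list with `axis_stats`,
#'   `global_stat`, `dof`, `p_value`.
#' @export
anova_structure_test <- function(pca, labels, k_axes = pca$n_axes) {
  if (k_axes < 1L || k_axes > pca$n_axes)
    stop("k_axes must lie in 1..n_axes")
  proj <- pca$projections
  lab <- labels$labels[rownames(proj)]
  if (any(is.na(lab))) stop("projection rows must all be labelled")
  g0 <- lab == 0L
  if (sum(g0) < 2L || sum(!g0) < 2L) stop("each class needs >= 2 members")
  m <- length(lab)
  axis_f <- vapply(seq_len(k_axes), function(k) {
    y <- proj[, k]
    mu <- mean(y)
    mu0 <- mean(y[g0]); mu1 <- mean(y[!g0])
    ssb <- sum(g0) * (mu0 - mu)^2 + sum(!g0) * (mu1 - mu)^2
    ssw <- sum((y[g0] - mu0)^2) + sum((y[!g0] - mu1)^2)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / 1) / (ssw / (m - 2))
  }, numeric(1))
  global <- sum(axis_f)
  structure(list(axis_stats = axis_f, global_stat = global,
                 dof = as.integer(k_axes),
                 p_value = stats::pchisq(global, df = k_axes,
                                         lower.tail = FALSE)),
            class = "structure_test")
}

#' @export
print.structure_test <- function(x, ...) {
  cat(sprintf("structure_test: global chi^2 = %.4g on %d axes, p = %.3g\n",
              x$global_stat, x$dof, x$p_value))
  invisible(x)
}

#' Sliding-window PCA / F_ST scan
#'
#' Partitions the SNP axis into non-overlapping windows of `window_size` SNPs
#' (a trailing partial window is dropped) and, per window, runs
#' normalization, PCA, the Hudson/Reich F_ST estimator and the summed-ANOVA
#' structure test on the labelled samples, recording the estimate against the
#' window's BBP critical value.  Windows in which every SNP is monomorphic in
#' the pooled sample yield a flagged degenerate row rather than an error.
#'
#' @param gm a [genotype_matrix()].
#' @param labels a [label_set()].
#' @param window_size SNPs per window.
#' @param k_axes principal axes for the structure test (default 10, capped by
#'   the window's rank).
#' @return An object of classes `pca_scan`/`data.frame`, one row per window:
#'   `start`, `end` (0-based, half-open), `fst_hat`, `fst_se`, `fst_crit`,
#'   `global_stat`, `dof`, `p_value`, `degenerate`.
#' @export
pca_window_scan <- function(gm, labels, window_size, k_axes = 10L) {
  window_size <- as.integer(window_size)
  n <- ncol(gm$dosages)
  if (window_size < 1L || window_size > n)
    stop("window_size must lie in 1..N")
  lab <- align_labels(gm, labels)
  sub_ids <- names(lab)
  m <- length(sub_ids)
  n_win <- n %/% window_size
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    start <- (w - 1L) * window_size
    win <- subset_window(gm, start, window_size)
    win$dosages <- win$dosages[sub_ids, , drop = FALSE]
    win$sample_ids <- sub_ids
    crit <- fst_critical(window_size, m)
    res <- tryCatch({
      st <- norm_stats(win$dosages)
      if (!length(st$keep)) stop("degenerate window")
      x <- apply_norm(win$dosages[, st$keep, drop = FALSE], st)
      k <- min(k_axes, nrow(x) - 2L, ncol(x))
      pca <- run_pca(x, k)
      fst <- fst_hudson(win, labels)
      test <- anova_structure_test(pca, labels, k)
      data.frame(start = start, end = start + window_size,
                 fst_hat = fst$fst_hat, fst_se = fst$se, fst_crit = crit,
                 global_stat = test$global_stat, dof = test$dof,
                 p_value = test$p_value, degenerate = FALSE)
    }, error = function(e) {
      if (!grepl("degenerate", conditionMessage(e)))
        stop(sprintf("window [%d, %d): %s", start, start + window_size,
                     conditionMessage(e)))
      data.frame(start = start, end = start + window_size,
                 fst_hat = NA_real_, fst_se = NA_real_, fst_crit = crit,
                 global_stat = NA_real_, dof = NA_integer_,
                 p_value = NA_real_, degenerate = TRUE)
    })
    rows[[w]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pca_scan", "data.frame")
  out
}

#' @export
print.pca_scan <- function(x, ...) {
  cat(sprintf("pca_scan: %d windows; %d with F_ST above the BBP threshold\n",
              nrow(x), sum(x$fst_hat > x$fst_crit, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.pca_scan <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  plot(mid, x$fst_hat, type = "b", pch = 16, xlab = "SNP index (window midpoint)",
       ylab = expression(hat(F)[ST]), ...)
  graphics::lines(mid, x$fst_crit, lty = 3)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
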