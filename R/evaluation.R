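#' Stratified train / hold-out split
#'
#' Splits the labelled samples into disjoint, exhaustive training and
#' hold-out sets, stratified by class, with the per-class training count
#' rounded toward the training side (`ceiling(fraction * n)`).
#'
#' @param labels a [label_set()].
#' @param train_fraction proportion of each class assigned to training.
#' @param seed optional integer seed.
#' @return A list with character vectors `train` and `holdout` of sample ids.
#' @export
holdout_split <- function(labels, train_fraction = 0.8, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  lab <- labels$labels
  train <- character(0)
  for (cls in c(0L, 1L)) {
    ids <- names(lab)[lab == cls]
    n_tr <- ceiling(train_fraction * length(ids))
    if (n_tr >= length(ids) || n_tr < 1L)
      stop(sprintf("class %d would be empty on one side of the split", cls))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = train, holdout = setdiff(names(lab), train))
}

#' Percent classification accuracy
#'
#' `100 * #matches / #total`; 100 is a perfect classifier and 50 is no better
#' than random on balanced classes.
#'
#' @param predicted,truth equal-length class vectors.
#' @return Accuracy in percent.
#' @export
accuracy_percent <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  100 * mean(predicted == truth)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the sorted unique scores (plus
#' sentinels), computing the true and false positive rates at each; tied
#' scores share one threshold step.  The area under the curve is computed by
#' the trapezoid rule and equals the probability that a random class-1 sample
#' outranks a random class-0 sample.
#'
#' @param scores per-sample class-1 probability or signed score.
#' @param truth 0/1 vector of true classes (both classes present).
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (descending, starting at `Inf`), `fpr`, `tpr` (non-decreasing, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present in truth")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; tr <- truth[ord]
  cum1 <- cumsum(tr == 1L); cum0 <- cumsum(tr == 0L)
  last <- cumsum(table(factor(sc, levels = thr))[as.character(thr)])
  tpr <- c(0, cum1[last] / n1)
  fpr <- c(0, cum0[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = unname(fpr),
                 tpr = unname(tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d threshold steps, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# leakage-free per-window feature preparation: imputation means and
# normalization statistics come from the training rows only
.window_features <- function(dos, train_ids, holdout_ids) {
  d_tr <- dos[train_ids, , drop = FALSE]
  mu <- colMeans(d_tr, na.rm = TRUE)
  mu[is.nan(mu)] <- 1                     # column unseen in training
  fill <- function(d) {
    x <- matrix(as.numeric(d), nrow = nrow(d), dimnames = dimnames(d))
    idx <- which(is.na(x), arr.ind = TRUE)
    if (nrow(idx)) x[idx] <- mu[idx[, 2]]
    x
  }
  st <- tryCatch(norm_stats(fill(d_tr)), error = function(e) NULL)
  if (is.null(st) || !length(st$keep)) return(NULL)
  list(train = apply_norm(fill(d_tr)[, st$keep, drop = FALSE], st),
       holdout = apply_norm(fill(dos[holdout_ids, , drop = FALSE])[, st$keep,
                                                                   drop = FALSE],
                            st))
}

#' Sliding-window classifier scan
#'
#' Partitions the SNP axis into non-overlapping windows and evaluates a
#' supervised classifier per window on one shared train/hold-out split (so
#' the accuracy spectra of different windows and methods are comparable).
#' Within each window, imputation and normalization statistics are computed
#' on the training samples only and applied to the hold-out samples -- the
#' hold-out set never influences training.
#'
#' @param gm a [genotype_matrix()].
#' @param labels a [label_set()].
#' @param window_size SNPs per window (trailing partial window dropped).
#' @param method `"ann"` (ensemble mean accuracy with a sigma band) or
#'   `"svm"` (single deterministic accuracy).
#' @param config an [ann_config()] for the ANN path.
#' @param cost soft-margin cost for the SVM path.
#' @param split optional shared split from [holdout_split()]; computed from
#'   `seed` when omitted.
#' @param train_fraction passed to [holdout_split()] when `split` is omitted.
#' @param seed master seed for the split and the per-window ensembles.
#' @param return_models attach per-window fitted models as an attribute.
#' @return An object of classes `window_scan`/`data.frame`: `start`, `end`
#'   (0-based half-open), `mean_acc` (percent), `sigma` (`NA` for SVM).
#'   Attributes: `method`, `split`, per-window hold-out `scores` (mean
#'   class-1 probability for ANN, signed score for SVM).
#' @export
classifier_window_scan <- function(gm, labels, window_size,
                                   method = c("ann", "svm"),
                                   config = ann_config(), cost = 1,
                                   split = NULL, train_fraction = 0.8,
                                   seed = NULL, return_models = FALSE) {
  method <- match.arg(method)
  window_size <- as.integer(window_size)
  n <- ncol(gm$dosages)
  if (window_size < 1L || window_size > n) stop("window_size must lie in 1..N")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(split)) split <- holdout_split(labels, train_fraction)
  lab <- align_labels(gm, labels)
  y_tr <- lab[split$train]; y_ho <- lab[split$holdout]
  n_win <- n %/% window_size
  win_seeds <- derive_seeds(NULL, n_win)
  acc <- sigma <- rep(NA_real_, n_win)
  starts <- (seq_len(n_win) - 1L) * window_size
  scores <- vector("list", n_win)
  models <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    dos <- gm$dosages[, starts[w] + seq_len(window_size), drop = FALSE]
    feats <- .window_features(dos, split$train, split$holdout)
    if (is.null(feats)) next                     # degenerate window: NA row
    if (method == "ann") {
      ens <- ann_ensemble(feats$train, y_tr, feats$holdout, y_ho,
                          config = config, seed = win_seeds[w])
      acc[w] <- ens$mean_accuracy
      sigma[w] <- ens$sigma
      scores[[w]] <- ens$per_sample_mean_probability
      if (return_models) models[[w]] <- ens
    } else {
      mod <- svm_train(feats$train, y_tr, C = cost)
      pred <- svm_predict(mod, feats$holdout)
      acc[w] <- accuracy_percent(pred$class, y_ho)
      scores[[w]] <- stats::setNames(pred$score, split$holdout)
      if (return_models) models[[w]] <- mod
    }
  }
  out <- data.frame(start = starts, end = starts + window_size,
                    mean_acc = acc, sigma = sigma)
  class(out) <- c("window_scan", "data.frame")
  attr(out, "method") <- method
  attr(out, "split") <- split
  attr(out, "scores") <- scores
  if (return_models) attr(out, "models") <- models
  out
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("window_scan (%s): %d windows, hold-out accuracy %.1f%%..%.1f%%\n",
              attr(x, "method"), nrow(x),
              min(x$mean_acc, na.rm = TRUE), max(x$mean_acc, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.window_scan <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  plot(mid, x$mean_acc, type = "b", pch = 16, ylim = c(30, 100),
       xlab = "SNP index (window midpoint)", ylab = "Hold-out accuracy (%)",
       ...)
  if (any(is.finite(x$sigma))) {
    graphics::arrows(mid, x$mean_acc - x$sigma, mid, x$mean_acc + x$sigma,
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}

#' Window-size convergence experiment
#'
#' Runs [classifier_window_scan()] at several window sizes on the same
#' train/hold-out split and, for each window of a larger size, compares its
#' accuracy with the best and the mean of its constituent smallest-size
#' windows.  On data where informative SNPs are confined to a narrow block
#' this shows whether enlarging the window drags accuracy toward the best or
#' the worst constituent rate.
#'
#' @param gm,labels,method,config,cost,train_fraction,seed as in
#'   [classifier_window_scan()].
#' @param sizes ascending window sizes; the first is the reference scale.
#' @return An object of class `convergence_result`: list with `scans` (one
#'   [classifier_window_scan()] result per size) and `comparison` (for each
#'   window of each larger size: `size`, `start`, `end`, `acc`, `sigma`,
#'   `best_sub`, `mean_sub` over the contained smallest-size windows).
#' @export
window_convergence_experiment <- function(gm, labels, sizes = c(20L, 50L, 100L),
                                          method = "ann",
                                          config = ann_config(), cost = 1,
                                          train_fraction = 0.8, seed = NULL) {
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be ascending")
  if (!is.null(seed)) set.seed(seed)
  split <- holdout_split(labels, train_fraction)
  scans <- lapply(sizes, function(sz)
    classifier_window_scan(gm, labels, sz, method = method, config = config,
                           cost = cost, split = split))
  names(scans) <- as.character(sizes)
  base <- scans[[1]]
  comp <- do.call(rbind, lapply(seq_along(sizes)[-1], function(k) {
    sc <- scans[[k]]
    sub <- lapply(seq_len(nrow(sc)), function(w) {
      inside <- base$start >= sc$start[w] & base$end <= sc$end[w]
      data.frame(size = sizes[k], start = sc$start[w], end = sc$end[w],
                 acc = sc$mean_acc[w], sigma = sc$sigma[w],
                 best_sub = max(base$mean_acc[inside], na.rm = TRUE),
                 mean_sub = mean(base$mean_acc[inside], na.rm = TRUE))
    })
    do.call(rbind, sub)
  }))
  structure(list(scans = scans, comparison = comp),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("convergence_result: window sizes %s\n",
              paste(names(x$scans), collapse = ", ")))
  print.data.frame(x$comparison, digits = 4)
  invisible(x)
}

#' Intra-population null-split homogeneity test
#'
#' Splits one population into two random disjoint subsets and runs both the
#' PCA/F_ST scan and the classifier scan against those arbitrary labels.  A
#' homogeneous population should classify at chance in every window; the
#' report flags any window whose hold-out accuracy exceeds 50 by more than 3
#' ensemble sigma, or whose structure-test p-value falls below a
#' Bonferroni-corrected level.
#'
#' @param gm a [genotype_matrix()].
#' @param n_a,n_b sizes of the two random subsets.
#' @param window_size SNPs per window.
#' @param k_axes principal axes for the structure test.
#' @param config an [ann_config()].
#' @param alpha family-wise level for the structure-test flag (Bonferroni
#'   across windows).
#' @param train_fraction,seed as in [classifier_window_scan()].
#' @return An object of class `null_split_report`: list with `labels`,
#'   `pca_scan`, `classifier_scan`, `flagged` (data frame of windows and the
#'   reason) and `alpha_per_window`.
#' @export
null_split_test <- function(gm, n_a, n_b, window_size = 50L, k_axes = 10L,
                            config = ann_config(), alpha = 0.01,
                            train_fraction = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- split_null(gm, n_a, n_b)
  pca <- pca_window_scan(gm, labels, window_size, k_axes = k_axes)
  cls <- classifier_window_scan(gm, labels, window_size, method = "ann",
                                config = config,
                                train_fraction = train_fraction)
  n_win <- nrow(pca)
  level <- alpha / n_win
  acc_flag <- !is.na(cls$mean_acc) &
    cls$mean_acc > 50 + 3 * pmax(cls$sigma, .Machine$double.eps)
  p_flag <- !is.na(pca$p_value) & pca$p_value < level
  flagged <- data.frame(start = pca$start, end = pca$end,
                        mean_acc = cls$mean_acc, sigma = cls$sigma,
                        p_value = pca$p_value,
                        accuracy_flag = acc_flag, pvalue_flag = p_flag)
  flagged <- flagged[acc_flag | p_flag, , drop = FALSE]
  structure(list(labels = labels, pca_scan = pca, classifier_scan = cls,
                 flagged = flagged, alpha_per_window = level),
            class = "null_split_report")
}

#' @export
print.null_split_report <- function(x, ...) {
  cat(sprintf(
    "null_split_report: %d windows, %d flagged (per-window alpha %.3g)\n",
    nrow(x$pca_scan), nrow(x$flagged), x$alpha_per_window))
  if (nrow(x$flagged)) print.data.frame(x$flagged, digits = 4)
  invisible(x)
}
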