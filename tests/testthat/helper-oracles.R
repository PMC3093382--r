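# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive each quantity by the most transparent route
# available (explicit loops, finite differences, projected gradient, rank
# statistics) so they share no code with the implementation they check.

# random minor-allele-coded genotype matrix (coded-allele frequency <= 0.5),
# optionally with missing calls
random_genotypes <- function(m, n, miss_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n, 0.05, 0.5)
  d <- matrix(rbinom(m * n, 2L, rep(p, each = m)), nrow = m)
  if (miss_rate > 0) {
    drop <- matrix(runif(m * n) < miss_rate, m, n)
    # keep at least one call per SNP
    for (j in seq_len(n)) if (all(drop[, j])) drop[1, j] <- FALSE
    d[drop] <- NA_integer_
  }
  # minor-allele coding must hold among the *observed* calls for PED
  # round-trips (the reader recomputes the minor allele from the file)
  flip <- colMeans(d, na.rm = TRUE) / 2 > 0.5
  d[, flip] <- 2L - d[, flip]
  genotype_matrix(d)
}

two_pop_labels <- function(gm, n1) {
  m <- length(gm$sample_ids)
  label_set(gm$sample_ids, rep(c(0L, 1L), c(n1, m - n1)))
}

# brute-force per-SNP Hudson/Reich ratio-of-sums oracle: explicit loops,
# scalar arithmetic only
fst_brute <- function(gm, labels) {
  lab <- labels$labels
  ids0 <- names(lab)[lab == 0L]
  ids1 <- names(lab)[lab == 1L]
  num_sum <- 0; den_sum <- 0
  for (j in seq_len(ncol(gm$dosages))) {
    g0 <- gm$dosages[ids0, j]; g0 <- g0[!is.na(g0)]
    g1 <- gm$dosages[ids1, j]; g1 <- g1[!is.na(g1)]
    if (length(g0) < 2 || length(g1) < 2) next
    n1 <- 2 * length(g0); n2 <- 2 * length(g1)
    p1 <- sum(g0) / n1; p2 <- sum(g1) / n2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (den == 0) next
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    num_sum <- num_sum + num
    den_sum <- den_sum + den
  }
  num_sum / den_sum
}

# central finite-difference gradient of the ANN training loss
fd_gradient <- function(params, x, y1hot, l2, h = 1e-5) {
  loss_at <- function(p) popsep:::.ann_loss_grad(p, x, y1hot, l2)$loss
  out <- params
  for (nm in c("W1", "b1", "W2", "b2")) {
    if (is.null(params[[nm]])) next
    g <- params[[nm]]
    for (i in seq_along(g)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g[i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

# brute-force QP solver for the augmented-bias linear SVM dual:
# min 0.5 a'Qa - e'a over the box [0, C]^n, by projected gradient with a
# conservative fixed step.  Independent of the coordinate-descent path.
svm_qp_oracle <- function(x, y, C, iters = 2e5) {
  s <- ifelse(y == 1L, 1, -1)
  xa <- cbind(as.matrix(x), 1)
  Q <- (s %o% s) * tcrossprod(xa)
  n <- nrow(Q)
  step <- 1 / max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  a <- numeric(n)
  for (it in seq_len(iters)) {
    g <- as.vector(Q %*% a) - 1
    a_new <- pmin(pmax(a - step * g, 0), C)
    if (max(abs(a_new - a)) < 1e-13) { a <- a_new; break }
    a <- a_new
  }
  w <- colSums(a * s * xa)
  list(weights = w[-length(w)], bias = w[length(w)], alpha = as.vector(a))
}

# Mann-Whitney U / (n1 * n0) computed from rank sums (midranks for ties)
auc_rank_oracle <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# textbook one-way ANOVA F via R's lm/anova machinery
anova_f_oracle <- function(y, g) {
  as.data.frame(anova(lm(y ~ factor(g))))[1, "F value"]
}
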