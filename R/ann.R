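#' Training configuration for the feed-forward network
#'
#' @param hidden number of hidden nodes H (>= 0).  `hidden = 0` degenerates
#'   to a direct linear map (multinomial logistic regression), the
#'   architecture used to demonstrate that a detected signal is linear.
#' @param reps ensemble repetitions (independent random restarts).
#' @param max_iter maximum full-batch gradient iterations per training.
#' @param tol relative loss-change convergence tolerance.
#' @param init_scale initial weights and biases are drawn from
#'   `Normal(0, init_scale / sqrt(fan_in))`.
#' @param l2 L2 penalty on weights (not biases); keeps the optimum finite on
#'   separable data.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden = 8L, reps = 10L, max_iter = 500L, tol = 1e-8,
                       init_scale = 1, l2 = 1e-4) {
  stopifnot(hidden >= 0L, reps >= 1L, max_iter >= 1L, tol > 0,
            init_scale > 0, l2 >= 0)
  structure(list(hidden = as.integer(hidden), reps = as.integer(reps),
                 max_iter = as.integer(max_iter), tol = tol,
                 init_scale = init_scale, l2 = l2),
            class = "ann_config")
}

# draw n_sub reproducible sub-seeds from one master seed (NULL = current RNG)
derive_seeds <- function(seed, n_sub) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n_sub)
}

.ann_init <- function(n_in, hidden, init_scale) {
  if (hidden > 0L) {
    list(W1 = matrix(stats::rnorm(n_in * hidden, 0, init_scale / sqrt(n_in)),
                     n_in, hidden),
         b1 = stats::rnorm(hidden, 0, init_scale / sqrt(n_in)),
         W2 = matrix(stats::rnorm(hidden * 2L, 0, init_scale / sqrt(hidden)),
                     hidden, 2L),
         b2 = stats::rnorm(2L, 0, init_scale / sqrt(hidden)))
  } else {
    list(W1 = NULL, b1 = NULL,
         W2 = matrix(stats::rnorm(n_in * 2L, 0, init_scale / sqrt(n_in)),
                     n_in, 2L),
         b2 = stats::rnorm(2L, 0, init_scale / sqrt(n_in)))
  }
}

.softmax <- function(o) {
  o <- o - apply(o, 1, max)
  e <- exp(o)
  e / rowSums(e)
}

# forward pass on a matrix of inputs; returns hidden activations and probs
.ann_forward_batch <- function(params, x) {
  if (!is.null(params$W1)) {
    a1 <- tanh(sweep(x %*% params$W1, 2, params$b1, "+"))
    o <- sweep(a1 %*% params$W2, 2, params$b2, "+")
  } else {
    a1 <- NULL
    o <- sweep(x %*% params$W2, 2, params$b2, "+")
  }
  list(a1 = a1, probs = .softmax(o))
}

# mean cross-entropy + L2 penalty, and its exact gradient (backprop)
.ann_loss_grad <- function(params, x, y1hot, l2) {
  n <- nrow(x)
  fw <- .ann_forward_batch(params, x)
  p <- pmax(fw$probs, 1e-300)
  loss <- -sum(y1hot * log(p)) / n +
    l2 / 2 * (sum(params$W2^2) + if (!is.null(params$W1)) sum(params$W1^2) else 0)
  d_o <- (fw$probs - y1hot) / n
  if (!is.null(params$W1)) {
    g_W2 <- crossprod(fw$a1, d_o) + l2 * params$W2
    g_b2 <- colSums(d_o)
    d_a1 <- d_o %*% t(params$W2)
    d_z1 <- d_a1 * (1 - fw$a1^2)
    g_W1 <- crossprod(x, d_z1) + l2 * params$W1
    g_b1 <- colSums(d_z1)
    grad <- list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2)
  } else {
    grad <- list(W1 = NULL, b1 = NULL,
                 W2 = crossprod(x, d_o) + l2 * params$W2, b2 = colSums(d_o))
  }
  list(loss = loss, grad = grad)
}

.ann_axpy <- function(params, grad, step) {
  out <- params
  for (nm in c("W1", "b1", "W2", "b2"))
    if (!is.null(params[[nm]])) out[[nm]] <- params[[nm]] - step * grad[[nm]]
  out
}

.ann_grad_sq <- function(grad) {
  s <- 0
  for (nm in c("W1", "b1", "W2", "b2"))
    if (!is.null(grad[[nm]])) s <- s + sum(grad[[nm]]^2)
  s
}

#' Forward pass of the three-layer network
#'
#' Hidden activations `h_j = tanh(sum_i w_ij x_i + b_j)`; output activations
#' are the identity of the affine combination `o_k = sum_j w_jk h_j + b_k`,
#' normalised to class probabilities with softmax.  With zero hidden nodes
#' the input feeds the output layer directly.
#'
#' @param params an `ann_net` object (or bare parameter list with `W1`, `b1`,
#'   `W2`, `b2`).
#' @param x input vector of length `n_in`, or a matrix with `n_in` columns.
#' @return Probability pair (class 0, class 1) summing to 1; a matrix of rows
#'   when `x` is a matrix.
#' @export
ann_forward <- function(params, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  n_in <- if (!is.null(params$W1)) nrow(params$W1) else nrow(params$W2)
  if (ncol(xm) != n_in)
    stop(sprintf("input has %d features, network expects %d", ncol(xm), n_in))
  p <- .ann_forward_batch(params, xm)$probs
  colnames(p) <- c("p0", "p1")
  if (vec) p[1, ] else p
}

#' Train the three-layer network
#'
#' Minimises the mean softmax cross-entropy (plus a small L2 penalty on the
#' weights) by full-batch gradient descent with a backtracking Armijo line
#' search.  Initial weights and biases are drawn from
#' `Normal(0, init_scale / sqrt(fan_in))`, so a seed determines the trained
#' network exactly.
#'
#' @param train_x numeric samples x features matrix (complete; impute and
#'   normalize upstream).
#' @param train_labels integer 0/1 vector, one per row of `train_x`.
#' @param config an [ann_config()].
#' @param seed optional integer seed for the random start.
#' @return An object of class `ann_net`: parameter list (`W1`, `b1`, `W2`,
#'   `b2`), `hidden`, `n_in`, `loss` (final), `loss_trace`, `iterations`,
#'   `converged`.
#' @export
ann_train <- function(train_x, train_labels, config = ann_config(),
                      seed = NULL) {
  train_x <- as.matrix(train_x)
  train_labels <- as.integer(train_labels)
  if (length(train_labels) != nrow(train_x))
    stop("one label per training row required")
  if (length(unique(train_labels)) < 2L)
    stop("training data must contain both classes")
  if (!all(is.finite(train_x))) stop("training inputs must be finite")
  if (!is.null(seed)) set.seed(seed)
  y1hot <- cbind(train_labels == 0L, train_labels == 1L) * 1
  params <- .ann_init(ncol(train_x), config$hidden, config$init_scale)
  lg <- .ann_loss_grad(params, train_x, y1hot, config$l2)
  if (!is.finite(lg$loss)) stop("non-finite loss at initialisation")
  step <- 1
  trace <- numeric(config$max_iter + 1L)
  trace[1] <- lg$loss
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    g2 <- .ann_grad_sq(lg$grad)
    if (g2 < 1e-20) { converged <- TRUE; it <- it - 1L; break }
    accepted <- FALSE
    for (bt in seq_len(40L)) {
      cand <- .ann_axpy(params, lg$grad, step)
      lg_new <- .ann_loss_grad(cand, train_x, y1hot, config$l2)
      if (is.finite(lg_new$loss) &&
          lg_new$loss <= lg$loss - 1e-4 * step * g2) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; it <- it - 1L; break }
    rel_drop <- (lg$loss - lg_new$loss) / max(1, abs(lg$loss))
    params <- cand
    lg <- lg_new
    trace[it + 1L] <- lg$loss
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite loss at iteration %d", it))
    step <- min(step * 2, 1e3)
    if (rel_drop < config$tol) { converged <- TRUE; break }
  }
  structure(c(params,
              list(hidden = config$hidden, n_in = ncol(train_x),
                   loss = lg$loss, loss_trace = trace[seq_len(it + 1L)],
                   iterations = it, converged = converged, config = config)),
            class = "ann_net")
}

#' @export
print.ann_net <- function(x, ...) {
  cat(sprintf(
    "ann_net: %d inputs -> %d hidden (tanh) -> 2 outputs (softmax)\n",
    x$n_in, x$hidden))
  cat(sprintf("  trained %d iterations, final loss %.6g (%s)\n",
              x$iterations, x$loss,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' @export
predict.ann_net <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- ann_forward(object, newdata)
  if (type == "prob") return(p)
  p1 <- if (is.null(dim(p))) p["p1"] else p[, "p1"]
  as.integer(p1 >= 0.5)
}

#' Random-restart ensemble of trained networks
#'
#' Trains `config$reps` networks from distinct random starting points, each
#' evaluated on the same hold-out set.  The spread of hold-out accuracies
#' across the ensemble supplies the confidence band on the classification,
#' and per-sample membership probabilities are averaged over the ensemble.
#'
#' @param train_x,train_labels training matrix and 0/1 labels.
#' @param holdout_x,holdout_labels hold-out matrix and 0/1 labels (disjoint
#'   samples from the training set).
#' @param config an [ann_config()].
#' @param seed optional master seed; per-repetition seeds are derived from it.
#' @return An object of class `ann_ensemble`: list with
#'   `per_repetition_accuracy` (percent), `mean_accuracy`, `sigma` (sample
#'   standard deviation; 0 with a warning when `reps < 2`),
#'   `per_sample_mean_probability` (named class-1 probabilities for the
#'   hold-out samples), and `models`.
#' @export
ann_ensemble <- function(train_x, train_labels, holdout_x, holdout_labels,
                         config = ann_config(), seed = NULL) {
  holdout_x <- as.matrix(holdout_x)
  holdout_labels <- as.integer(holdout_labels)
  seeds <- derive_seeds(seed, config$reps)
  acc <- numeric(config$reps)
  p1 <- matrix(0, nrow(holdout_x), config$reps)
  models <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    net <- ann_train(train_x, train_labels, config, seed = seeds[r])
    probs <- ann_forward(net, holdout_x)
    p1[, r] <- probs[, "p1"]
    acc[r] <- accuracy_percent(as.integer(probs[, "p1"] >= 0.5), holdout_labels)
    models[[r]] <- net
  }
  sigma <- if (config$reps < 2L) {
    warning("reps < 2: ensemble sigma reported as 0")
    0
  } else stats::sd(acc)
  mp <- rowMeans(p1)
  names(mp) <- rownames(holdout_x)
  structure(list(per_repetition_accuracy = acc, mean_accuracy = mean(acc),
                 sigma = sigma, per_sample_mean_probability = mp,
                 models = models),
            class = "ann_ensemble")
}

#' @export
print.ann_ensemble <- function(x, ...) {
  cat(sprintf("ann_ensemble: %d repetitions, hold-out accuracy %.1f%% +/- %.2f\n",
              length(x$per_repetition_accuracy), x$mean_accuracy, x$sigma))
  invisible(x)
}
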