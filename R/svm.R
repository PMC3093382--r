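#' Train a linear soft-margin support vector machine
#'
#' Finds the hyperplane that places as many points as possible into their
#' pre-defined class while maximising the margin: minimises
#' `1/2 ||w||^2 + C * sum(hinge losses)`.  The bias is handled by feature
#' augmentation (a constant-1 coordinate, penalised with the weights) and the
#' dual is solved by coordinate descent over the box `0 <= alpha_i <= C` in a
#' fixed sample order, so training is fully deterministic: rerunning on
#' identical input yields a bit-identical model.
#'
#' @param train_x numeric samples x features matrix.
#' @param train_labels integer 0/1 vector.
#' @param C soft-margin cost (> 0).
#' @param tol convergence tolerance on the spread of projected gradients over
#'   one sweep.
#' @param max_sweeps sweep cap; exceeding it raises an error reporting the
#'   final duality gap.
#' @return An object of class `linear_svm`: list with `weights`, `bias`,
#'   `C`, `margin_width = 2 / ||weights||`, `alpha`, `sweeps`,
#'   `dual_objective_trace` (monotonically non-increasing values of the dual
#'   minimisation objective, one per sweep) and `objective` (primal value).
#' @export
svm_train <- function(train_x, train_labels, C = 1, tol = 1e-8,
                      max_sweeps = 20000L) {
  x <- as.matrix(train_x)
  y <- as.integer(train_labels)
  if (length(y) != nrow(x)) stop("one label per training row required")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (C <= 0) stop("C must be positive")
  s <- ifelse(y == 1L, 1, -1)
  xa <- cbind(x, 1)                       # augmented bias coordinate
  n <- nrow(xa); p <- ncol(xa)
  qii <- rowSums(xa^2)
  alpha <- numeric(n)
  w <- numeric(p)
  trace <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    pg_max <- -Inf; pg_min <- Inf
    for (i in seq_len(n)) {
      g <- s[i] * sum(w * xa[i, ]) - 1
      pg <- g
      if (alpha[i] == 0) pg <- min(g, 0)
      else if (alpha[i] == C) pg <- max(g, 0)
      pg_max <- max(pg_max, pg); pg_min <- min(pg_min, pg)
      if (abs(pg) > 1e-14) {
        a_new <- min(max(alpha[i] - g / qii[i], 0), C)
        if (a_new != alpha[i]) {
          w <- w + (a_new - alpha[i]) * s[i] * xa[i, ]
          alpha[i] <- a_new
        }
      }
    }
    trace <- c(trace, 0.5 * sum(w^2) - sum(alpha))
    if (pg_max - pg_min < tol) { converged <- TRUE; break }
  }
  margins <- s * as.vector(xa %*% w)
  primal <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - margins))
  dual <- sum(alpha) - 0.5 * sum(w^2)
  if (!converged)
    stop(sprintf("dual coordinate descent did not converge in %d sweeps (duality gap %.3g)",
                 max_sweeps, primal - dual))
  weights <- w[-p]
  structure(list(weights = weights, bias = w[p], C = C,
                 margin_width = 2 / sqrt(sum(weights^2)),
                 alpha = alpha, sweeps = sweep,
                 dual_objective_trace = trace, objective = primal,
                 duality_gap = primal - dual),
            class = "linear_svm")
}

#' Classify with a linear SVM
#'
#' The signed score is `w . x + bias`; class 1 when the score is positive,
#' class 0 when negative, with ties on the hyperplane (score exactly 0)
#' assigned to class 1 by convention.
#'
#' @param model a [svm_train()] result.
#' @param x feature vector, or matrix with one sample per row.
#' @return A list with `class` (0/1) and `score` (signed distance times
#'   `||w||`), vectors when `x` is a matrix.
#' @export
svm_predict <- function(model, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(xm) != length(model$weights))
    stop(sprintf("input has %d features, model expects %d",
                 ncol(xm), length(model$weights)))
  score <- as.vector(xm %*% model$weights + model$bias)
  cls <- as.integer(score >= 0)
  if (vec) list(class = cls[1], score = score[1])
  else list(class = cls, score = score)
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  out <- svm_predict(object, newdata)
  if (type == "class") out$class else out$score
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, C = %g, margin width %.4g, %d sweeps\n",
              length(x$weights), x$C, x$margin_width, x$sweeps))
  invisible(x)
}
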