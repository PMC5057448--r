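#' Conditioning mask for a category
#'
#' The HLR trains each category's logistic model only on the time points
#' where *all* of its hypernyms (direct parents, hence by closure all
#' ancestors) are present — the "siblings" policy: the negative examples are
#' time points where the category's siblings are present but the category is
#' not. Root categories are unconditioned (all TRs).
#'
#' @param labels A hierarchy-closed [label_timecourse()].
#' @param tax A [taxonomy()].
#' @param cat Category id.
#' @return Logical vector, one entry per TR.
#' @export
conditioning_mask <- function(labels, tax, cat) {
  stopifnot(inherits(labels, "label_timecourse"), inherits(tax, "taxonomy"))
  if (!cat %in% tax$nodes$id) stop("unknown category id: ", cat)
  ps <- parents_of(tax, cat)
  if (length(ps) == 0) return(rep(TRUE, nrow(labels$values)))
  missing <- setdiff(ps, labels$categories)
  if (length(missing) > 0) stop("labels lack parent column(s): ", paste(missing, collapse = ", "))
  rowSums(labels$values[, ps, drop = FALSE] == 1L) == length(ps)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
logit <- function(p) log(p / (1 - p))

# mean Bernoulli log-loss with clipping
mean_logloss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

laplace_rate <- function(n_pos, n) (n_pos + 1) / (n + 2)

new_conditional_model <- function(category, weights, bias, p0, eta = 0,
                                  n_cond = 0L, n_pos = 0L, degenerate = FALSE,
                                  flip = NULL) {
  structure(
    list(category = category, weights = weights, bias = bias, p0 = p0,
         eta = eta, n_cond = as.integer(n_cond), n_pos = as.integer(n_pos),
         degenerate = degenerate, flip = flip),
    class = "conditional_model"
  )
}

#' @export
print.conditional_model <- function(x, ...) {
  cat("<conditional_model> ", x$category, ": ", length(x$weights), " weights, p0 = ",
      signif(x$p0, 3), ", eta = ", signif(x$eta, 3),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

degenerate_model <- function(category, p, n_feat, n_cond = 0L, n_pos = 0L) {
  new_conditional_model(category, numeric(n_feat), logit(p), p,
                        n_cond = n_cond, n_pos = n_pos, degenerate = TRUE)
}

# Assign contiguous 4-TR blocks of the row sequence to n_splits groups,
# uniformly at random (seeded). Returns an integer group per row.
block_split_groups <- function(n_rows, n_splits, block = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- ceiling(seq_len(n_rows) / block)
  nb <- max(blocks)
  grp <- sample(rep_len(seq_len(n_splits), nb))
  grp[blocks]
}

#' Fit a conditional logistic model by gradient descent with early stopping
#'
#' Restricted to the conditioned (masked) rows, the data are split into 90%
#' gradient-descent and 10% early-stopping sets, block-wise in blocks of 4
#' TRs to limit autocorrelation leakage. Full-batch gradient descent on the
#' logistic log-loss starts from zero weights and a bias producing the
#' empirical conditional prior; descent stops when the early-stopping loss
#' has not improved for `patience` consecutive evaluations (checked every
#' iteration). The fit is repeated with `n_restarts` disjoint early-stopping
#' sets and the resulting weights and biases are averaged.
#'
#' @param features A [build_lagged_features()] result (or numeric matrix).
#' @param y Binary response vector (length = number of TRs).
#' @param mask Logical conditioning mask; combined with the feature validity
#'   mask.
#' @param seed Integer seed; the split assignment is the only randomness.
#' @param learning_rate Step size on the mean-log-loss gradient (default 0.1,
#'   i.e. 0.1/n on the summed gradient).
#' @param max_iter Iteration cap (default 500).
#' @param patience Consecutive non-improving early-stopping evaluations
#'   before termination (default 10).
#' @param n_restarts Number of disjoint early-stopping splits (default 3).
#' @param min_samples,min_pos Minimum conditioned TRs / positives to attempt
#'   a fit; below these a degenerate prior model is returned.
#' @return A `conditional_model`.
#' @export
fit_conditional_earlystop <- function(features, y, mask = NULL, seed = 1,
                                      learning_rate = 0.1, max_iter = 500,
                                      patience = 10, n_restarts = 3,
                                      min_samples = 10, min_pos = 3) {
  d <- masked_design(features, y, mask)
  p0 <- laplace_rate(sum(d$y), length(d$y))
  if (is_degenerate_case(d$y, min_samples, min_pos)) {
    return(degenerate_model("", p0, ncol(d$X), length(d$y), sum(d$y)))
  }
  X <- d$X; yy <- d$y
  grp <- block_split_groups(nrow(X), n_splits = 10L, seed = seed)
  restart_fits <- lapply(seq_len(n_restarts), function(r) {
    va <- grp == r
    gd_logistic(X[!va, , drop = FALSE], yy[!va], X[va, , drop = FALSE], yy[va],
                p0 = p0, learning_rate = learning_rate, max_iter = max_iter,
                patience = patience)
  })
  w <- Reduce(`+`, lapply(restart_fits, `[[`, "w")) / n_restarts
  b <- mean(vapply(restart_fits, `[[`, numeric(1), "b"))
  names(w) <- colnames(X)
  new_conditional_model("", w, b, p0, n_cond = length(yy), n_pos = sum(yy))
}

masked_design <- function(features, y, mask) {
  if (inherits(features, "feature_matrix")) {
    valid <- features$valid
    X <- features$values
  } else {
    X <- as.matrix(features)
    valid <- rep(TRUE, nrow(X))
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  stopifnot(length(y) == nrow(X), length(mask) == nrow(X))
  rows <- which(mask & valid)
  list(X = X[rows, , drop = FALSE], y = as.numeric(y[rows]), rows = rows)
}

is_degenerate_case <- function(y, min_samples, min_pos) {
  length(y) < min_samples || sum(y) < min_pos || sum(1 - y) < 1
}

# Full-batch GD with early stopping; returns the best-validation iterate.
gd_logistic <- function(Xtr, ytr, Xva, yva, p0, learning_rate, max_iter, patience) {
  w <- numeric(ncol(Xtr))
  b <- logit(p0)
  best <- list(w = w, b = b)
  best_loss <- mean_logloss(sigmoid(drop(Xva %*% w) + b), yva)
  bad <- 0L
  n <- nrow(Xtr)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- sigmoid(drop(Xtr %*% w) + b)
    err <- p - ytr
    w <- w - learning_rate * drop(crossprod(Xtr, err)) / n
    b <- b - learning_rate * mean(err)
    loss <- mean_logloss(sigmoid(drop(Xva %*% w) + b), yva)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- list(w = w, b = b)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  best
}

#' Fit a conditional logistic model with an L2 penalty
#'
#' The alternative to early stopping: penalized likelihood
#' `sum log-loss + lambda/2 ||w||^2` (intercept unpenalized), with the
#' penalty chosen over a wide grid (default `10^(-6) .. 10^4`). For each of
#' `n_boot` block-wise 90/10 splits the model is fit on 90% and the log-loss
#' evaluated on 10%; the median of the per-split best penalties is used to
#' refit on all conditioned rows.
#'
#' @inheritParams fit_conditional_earlystop
#' @param lambda_grid Penalty grid (default `10^seq(-6, 4)`).
#' @param n_boot Number of selection splits (default 3).
#' @return A `conditional_model`.
#' @export
fit_conditional_l2 <- function(features, y, mask = NULL, seed = 1,
                               lambda_grid = 10^seq(-6, 4), n_boot = 3,
                               min_samples = 10, min_pos = 3) {
  d <- masked_design(features, y, mask)
  p0 <- laplace_rate(sum(d$y), length(d$y))
  if (is_degenerate_case(d$y, min_samples, min_pos)) {
    return(degenerate_model("", p0, ncol(d$X), length(d$y), sum(d$y)))
  }
  X <- d$X; yy <- d$y
  grp <- block_split_groups(nrow(X), n_splits = 10L, seed = seed)
  best_lam <- vapply(seq_len(n_boot), function(r) {
    va <- grp == r
    losses <- vapply(lambda_grid, function(lam) {
      fit <- ridge_logistic(X[!va, , drop = FALSE], yy[!va], lam, p0)
      mean_logloss(sigmoid(drop(X[va, , drop = FALSE] %*% fit$w) + fit$b), yy[va])
    }, numeric(1))
    lambda_grid[which.min(losses)]
  }, numeric(1))
  lam <- stats::median(best_lam)
  fit <- ridge_logistic(X, yy, lam, p0)
  w <- fit$w
  names(w) <- colnames(X)
  m <- new_conditional_model("", w, fit$b, p0, n_cond = length(yy), n_pos = sum(yy))
  m$lambda <- lam
  m
}

# L2-penalized logistic regression via L-BFGS-B (intercept unpenalized).
ridge_logistic <- function(X, y, lambda, p0, maxit = 200) {
  p <- ncol(X)
  obj <- function(theta) {
    w <- theta[-1]; b <- theta[1]
    z <- drop(X %*% w) + b
    sum(log1p(exp(-abs(z))) + pmax(z, 0) - y * z) + lambda / 2 * sum(w^2)
  }
  grad <- function(theta) {
    w <- theta[-1]; b <- theta[1]
    err <- sigmoid(drop(X %*% w) + b) - y
    c(sum(err), drop(crossprod(X, err)) + lambda * w)
  }
  fit <- stats::optim(c(logit(p0), numeric(p)), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(w = fit$par[-1], b = fit$par[1])
}

#' Smooth a conditional model's output toward its prior
#'
#' To limit overfitting, the raw logistic output is shrunk toward the
#' conditional prior under a beta-prior argument:
#' `P* = (P + eta * p0) / (1 + eta)`. The scaling `eta` is grid-searched
#' (`{0} U logspace(-3, 3, 25)`) to maximize the Bernoulli log-likelihood of
#' a held-out segment of about one minute of estimation data (30 TRs at
#' TR = 2 s), restricted to the category's conditioning mask.
#'
#' @param model A `conditional_model`.
#' @param features Features for the held-out segment (matrix or
#'   `feature_matrix`).
#' @param y Held-out binary responses.
#' @param mask Conditioning mask on the held-out rows.
#' @param eta_grid Candidate values (default `c(0, 10^seq(-3, 3, length.out = 25))`).
#' @return The model with `eta` set.
#' @export
fit_smoothing_eta <- function(model, features, y, mask = NULL,
                              eta_grid = c(0, 10^seq(-3, 3, length.out = 25))) {
  stopifnot(inherits(model, "conditional_model"))
  d <- masked_design(features, y, mask)
  if (length(d$y) == 0) {
    warning("empty held-out conditioning mask for '", model$category,
            "'; eta set to 0")
    model$eta <- 0
    return(model)
  }
  p_raw <- sigmoid(drop(d$X %*% model$weights) + model$bias)
  ll <- vapply(eta_grid, function(eta) {
    ps <- (p_raw + eta * model$p0) / (1 + eta)
    -mean_logloss(ps, d$y)
  }, numeric(1))
  model$eta <- eta_grid[which.max(ll)]
  model
}

#' Predict conditional category probabilities
#'
#' Applies the smoothed logistic map
#' `P* = (sigmoid(w . x + b) + eta * p0) / (1 + eta)` to every valid TR;
#' TRs with invalid lags fall back to the conditional prior `p0`.
#'
#' @param model A `conditional_model`.
#' @param features A `feature_matrix` or numeric matrix with matching width.
#' @return Numeric probability vector, one entry per TR.
#' @export
predict_conditional <- function(model, features) {
  stopifnot(inherits(model, "conditional_model"))
  if (inherits(features, "feature_matrix")) {
    X <- features$values
    valid <- features$valid
  } else {
    X <- as.matrix(features)
    valid <- rep(TRUE, nrow(X))
  }
  if (ncol(X) != length(model$weights)) {
    stop("feature width (", ncol(X), ") does not match model (", length(model$weights), ")")
  }
  out <- rep(model$p0, nrow(X))
  if (any(valid)) {
    z <- drop(X[valid, , drop = FALSE] %*% model$weights) + model$bias
    out[valid] <- (sigmoid(z) + model$eta * model$p0) / (1 + model$eta)
  }
  out
}

# log P(observed y | x) under the 2x2 flip matrix:
# P(obs=1 | x) = G[1,2] (1-s) + G[2,2] s, s = sigmoid(w.x + b)
noisy_loglik <- function(theta, X, y, G, eps = 1e-12) {
  s <- sigmoid(drop(X %*% theta[-1]) + theta[1])
  p1 <- G[1, 2] * (1 - s) + G[2, 2] * s
  p1 <- pmin(pmax(p1, eps), 1 - eps)
  sum(y * log(p1) + (1 - y) * log(1 - p1))
}

noisy_loglik_grad <- function(theta, X, y, G, eps = 1e-12) {
  s <- sigmoid(drop(X %*% theta[-1]) + theta[1])
  p1 <- pmin(pmax(G[1, 2] * (1 - s) + G[2, 2] * s, eps), 1 - eps)
  # d p1 / dz = (G[2,2] - G[1,2]) s (1 - s)
  dz <- (G[2, 2] - G[1, 2]) * s * (1 - s) * (y / p1 - (1 - y) / (1 - p1))
  c(sum(dz), drop(crossprod(X, dz)))
}

#' Label-noise-robust conditional logistic regression
#'
#' Jointly estimates the logistic weights and a 2x2 label-flipping
#' probability matrix (row = true label 0/1, column = observed label 0/1;
#' rows sum to one) under the noisy-label likelihood
#' `P(obs = 1 | x) = G01 (1 - s) + G11 s`. Estimation alternates gradient
#' updates of the weights under the current flip matrix with
#' expected-count (EM) updates of the flip matrix, until the flip matrix
#' changes by less than `tol` or `max_rounds` rounds elapse. The flip
#' off-diagonals are initialized at `init_flip` (0.1 by default), and the
#' weights start either at zero or from a warm-start model.
#'
#' @inheritParams fit_conditional_earlystop
#' @param init_flip Initial label-error probability (off-diagonals of the
#'   flip matrix).
#' @param warm_start Optional `conditional_model` whose weights/bias seed the
#'   optimization (the "second condition": initialize from a plain fit).
#' @param max_rounds,tol Alternation cap and flip-matrix convergence
#'   tolerance.
#' @return A list with `model` (a `conditional_model` carrying the flip
#'   matrix), `flip` (the 2x2 matrix) and `converged`.
#' @export
fit_label_noise <- function(features, y, mask = NULL, init_flip = 0.1,
                            warm_start = NULL, max_rounds = 200, tol = 1e-6,
                            min_samples = 10, min_pos = 3) {
  d <- masked_design(features, y, mask)
  p0 <- laplace_rate(sum(d$y), length(d$y))
  if (is_degenerate_case(d$y, min_samples, min_pos)) {
    m <- degenerate_model("", p0, ncol(d$X), length(d$y), sum(d$y))
    m$flip <- diag(2)
    return(list(model = m, flip = diag(2), converged = TRUE))
  }
  X <- d$X; yy <- d$y
  G <- matrix(c(1 - init_flip, init_flip, init_flip, 1 - init_flip), 2, byrow = TRUE)
  theta <- if (!is.null(warm_start)) c(warm_start$bias, warm_start$weights)
           else c(logit(p0), numeric(ncol(X)))
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    fit <- stats::optim(theta, fn = function(t) -noisy_loglik(t, X, yy, G),
                        gr = function(t) -noisy_loglik_grad(t, X, yy, G),
                        method = "L-BFGS-B", control = list(maxit = 50))
    theta <- fit$par
    s <- sigmoid(drop(X %*% theta[-1]) + theta[1])
    # posterior that the true label is 1 given the observed label
    denom1 <- G[1, 2] * (1 - s) + G[2, 2] * s
    denom0 <- G[1, 1] * (1 - s) + G[2, 1] * s
    r <- ifelse(yy == 1, G[2, 2] * s / pmax(denom1, 1e-12),
                         G[2, 1] * s / pmax(denom0, 1e-12))
    n1 <- sum(r); n0 <- sum(1 - r)
    Gnew <- rbind(
      c(sum((1 - r) * (yy == 0)), sum((1 - r) * (yy == 1))) / max(n0, 1e-12),
      c(sum(r * (yy == 0)), sum(r * (yy == 1))) / max(n1, 1e-12)
    )
    delta <- max(abs(Gnew - G))
    G <- Gnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("label-noise fit did not converge; returning last iterate")
  w <- theta[-1]
  names(w) <- colnames(X)
  m <- new_conditional_model("", w, theta[1], p0,
                             n_cond = length(yy), n_pos = sum(yy), flip = G)
  list(model = m, flip = G, converged = converged)
}
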