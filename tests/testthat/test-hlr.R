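test_that("conditioning masks are the conjunction of all parent columns", {
  m <- matrix(0L, 10, 3, dimnames = list(NULL, chain_tax$nodes$id))
  m[c(4, 5, 10), "motor_vehicle.n.01"] <- 1L
  lab <- label_timecourse(m)
  mask <- conditioning_mask(lab, chain_tax, "car.n.01")
  expect_equal(which(mask), c(4, 5, 10))
  expect_true(all(conditioning_mask(lab, chain_tax, "motor_vehicle.n.01")))

  md <- matrix(rbinom(40, 1, 0.5), 10, 4, dimnames = list(NULL, diamond_tax$nodes$id))
  labd <- label_timecourse(md)
  expect_equal(conditioning_mask(labd, diamond_tax, "d"),
               md[, "b"] == 1 & md[, "c"] == 1)
  expect_error(conditioning_mask(lab, chain_tax, "nope"), "unknown")
})

test_that("early-stopping fitter separates a separable toy and respects max_iter", {
  toy <- separable_toy(200, mu = 1, sd = 0.5, seed = 0)
  test <- separable_toy(200, mu = 1, sd = 0.5, seed = 99)
  m <- fit_conditional_earlystop(toy$X, toy$y, seed = 0)
  p <- predict_conditional(m, test$X)
  expect_equal(roc_auc(p, test$y), 1.0)

  # zero iterations: prediction is exactly the prior
  m0 <- fit_conditional_earlystop(toy$X, toy$y, seed = 0, max_iter = 0)
  expect_equal(unique(predict_conditional(m0, toy$X)), m0$p0, tolerance = 1e-12)
  expect_equal(unname(m0$weights), c(0, 0))
})

test_that("labels independent of features yield near-prior predictions", {
  set.seed(3)
  X <- matrix(rnorm(500 * 4), 500, 4)
  y <- rbinom(500, 1, 0.3)
  m <- fit_conditional_earlystop(X, y, seed = 1)
  expect_lt(sqrt(sum(m$weights^2)), 0.5)
  expect_lt(abs(mean(predict_conditional(m, X)) - m$p0), 0.05)
})

test_that("degenerate data fall back to a prior model", {
  X <- matrix(rnorm(40), 20, 2)
  m <- fit_conditional_earlystop(X, rep(0, 20))
  expect_true(m$degenerate)
  expect_equal(m$p0, 1 / 22)   # Laplace-smoothed empirical rate
  expect_equal(unname(m$weights), c(0, 0))
  m2 <- fit_conditional_earlystop(X[1:4, ], c(1, 1, 1, 0))  # < min_samples
  expect_true(m2$degenerate)
})

test_that("L2 fitter matches early stopping on held-out toys and has a ridge limit", {
  toy <- separable_toy(300, mu = 1, sd = 0.5, seed = 1)
  test <- separable_toy(300, mu = 1, sd = 0.5, seed = 98)
  ml2 <- fit_conditional_l2(toy$X, toy$y, seed = 1)
  expect_equal(roc_auc(predict_conditional(ml2, test$X), test$y), 1.0)
  expect_lt(ml2$lambda, 1e2)

  # infinite regularization: weights ~ 0, predictions ~ empirical rate
  mbig <- fit_conditional_l2(toy$X, toy$y, seed = 1, lambda_grid = 1e12)
  expect_lt(sqrt(sum(mbig$weights^2)), 1e-4)
  expect_equal(mean(predict_conditional(mbig, toy$X)), mean(toy$y),
               tolerance = 0.01)

  mes <- fit_conditional_earlystop(toy$X, toy$y, seed = 1)
  expect_gt(cor(predict_conditional(mes, test$X),
                predict_conditional(ml2, test$X)), 0.95)
})

test_that("prior smoothing follows P* = (P + eta p0) / (1 + eta)", {
  m <- hlrdecode:::new_conditional_model("x", c(0, 0), hlrdecode:::logit(0.6), 0.2)
  shrink <- function(eta) (0.6 + eta * 0.2) / (1 + eta)
  m$eta <- 1
  expect_equal(predict_conditional(m, matrix(0, 1, 2)), shrink(1))  # = 0.4
  expect_equal(shrink(1), 0.4)
  m$eta <- 0
  expect_equal(predict_conditional(m, matrix(0, 1, 2)), 0.6)
  m$eta <- 1e9
  expect_equal(predict_conditional(m, matrix(0, 1, 2)), 0.2, tolerance = 1e-6)

  # grid search picks an eta that helps a miscalibrated model
  set.seed(5)
  Xh <- matrix(rnorm(60), 30, 2)
  yh <- rbinom(30, 1, 0.2)
  over <- hlrdecode:::new_conditional_model("x", c(3, -3), 0, 0.2)
  fitted <- fit_smoothing_eta(over, Xh, yh)
  expect_gt(fitted$eta, 0)
  expect_warning(fit_smoothing_eta(over, Xh, yh, mask = rep(FALSE, 30)), "empty")
})

test_that("conditional predictions match a scalar sigmoid oracle", {
  w <- c(0.7, -1.2); b <- 0.3
  m <- hlrdecode:::new_conditional_model("x", w, b, 0.5)
  X <- matrix(c(0.1, -0.5, 2, 0.3, -1, 0.8), 3, 2)
  oracle <- vapply(1:3, function(i) 1 / (1 + exp(-(sum(w * X[i, ]) + b))),
                   numeric(1))
  expect_equal(predict_conditional(m, X), oracle, tolerance = 1e-12)
  # monotone in the projection
  ord <- order(X %*% w)
  expect_equal(order(predict_conditional(m, X)), ord)
  expect_error(predict_conditional(m, matrix(0, 2, 3)), "width")
})

test_that("label-noise likelihood with identity flip equals the plain likelihood", {
  toy <- separable_toy(50, seed = 2)
  theta <- c(0.2, rnorm(2))
  ll_noisy <- hlrdecode:::noisy_loglik(theta, toy$X, toy$y, diag(2))
  p <- plogis(drop(toy$X %*% theta[-1]) + theta[1])
  ll_plain <- sum(toy$y * log(p) + (1 - toy$y) * log(1 - p))
  expect_equal(ll_noisy, ll_plain, tolerance = 1e-9)
})

test_that("label-noise fitter converges toward identity on clean labels", {
  set.seed(1)
  n <- 800
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X %*% c(2, -1.5, 1)))
  fit <- suppressWarnings(fit_label_noise(X, y))
  expect_lt(fit$flip[1, 2], 0.01)
  expect_lt(fit$flip[2, 1], 0.01)
  expect_equal(rowSums(fit$flip), c(1, 1), tolerance = 1e-9)
})

test_that("label-noise fitter recovers a planted 10% flip rate", {
  est <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 2000
    X <- matrix(rnorm(n * 5), n, 5)
    y <- rbinom(n, 1, plogis(drop(X %*% c(1.5, -1, 0.8, 0, 0.5)) - 0.2))
    yn <- ifelse(runif(n) < 0.1, 1 - y, y)
    fit <- suppressWarnings(fit_label_noise(X, yn))
    mean(c(fit$flip[1, 2], fit$flip[2, 1]))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.1), 0.03)

  # warm starting from a plain fit is supported and also recovers the rate
  set.seed(10)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X %*% c(1.5, -1, 1)))
  yn <- ifelse(runif(n) < 0.1, 1 - y, y)
  warm <- fit_conditional_earlystop(X, yn, seed = 1)
  fit <- suppressWarnings(fit_label_noise(X, yn, warm_start = warm))
  expect_lt(abs(mean(c(fit$flip[1, 2], fit$flip[2, 1])) - 0.1), 0.05)
})
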