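# Brute-force Mann-Whitney oracle: (concordant + half ties) / (n1 * n0).
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("roc_auc matches the pairwise-counting oracle", {
  expect_equal(roc_auc(c(0.2, 0.5, 0.5, 0.9), c(0, 0, 1, 1)), 0.875)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(10, 3, 2, 1), c(0, 0, 1, 1)), 0.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)  # all ties
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "single class")

  set.seed(20)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(runif(n), 1))  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels),
                 auc_pairwise_oracle(scores, labels))
  }
})

test_that("block shuffling preserves counts and autocorrelation structure", {
  set.seed(21)
  y <- as.integer(rbinom(100, 1, 0.4))
  sh <- block_shuffle(y, block = 4, n = 50, seed = 5)
  expect_length(sh, 50)
  expect_true(all(vapply(sh, sum, numeric(1)) == sum(y)))
  expect_identical(block_shuffle(y, 4, 10, seed = 9),
                   block_shuffle(y, 4, 10, seed = 9))

  # persistent labels keep most of their lag-1 autocorrelation under shuffling
  yp <- simulate_labels(make_toy_taxonomy(1), 400, persistence = 0.95,
                        seed = 3)$values[, 1]
  ac <- function(v) cor(v[-1], v[-length(v)])
  sh <- block_shuffle(yp, block = 4, n = 100, seed = 1)
  ac_sh <- mean(vapply(sh, ac, numeric(1)))
  # within a 4-TR block 3 of 4 lag-1 pairs are preserved
  expect_gt(ac_sh, 0.5 * ac(yp))
})

test_that("symmetric beta fit matches the variance-moment identity", {
  # uniform null: var 1/12 -> alpha = 1
  set.seed(22)
  u <- runif(20000)
  nb <- fit_null_beta(u)
  expect_equal(nb$alpha, 1, tolerance = 0.05)
  expect_equal(nb$alpha / (nb$alpha + nb$beta), 0.5)  # mean exactly 1/2

  draws <- rbeta(1000, 20, 20)
  nb2 <- fit_null_beta(draws)
  expect_equal(nb2$alpha, 20, tolerance = 20 * 0.15)

  nb0 <- fit_null_beta(rep(0.5, 200))
  expect_equal(nb0$var, 0)
})

test_that("beta-null p-values match the shuffle tail", {
  nb <- list(alpha = 30, beta = 30)
  expect_equal(auc_pvalue(0.5, nb), 0.5)
  expect_equal(auc_pvalue(1.0, nb), 0)

  set.seed(23)
  nulls <- rbeta(1000, 30, 30)
  fitted <- fit_null_beta(nulls)
  at <- unname(quantile(nulls, 0.95))
  expect_lt(abs(auc_pvalue(at, fitted) - mean(nulls >= at)), 0.02)

  point <- fit_null_beta(rep(0.5, 200))
  expect_equal(auc_pvalue(0.7, point), 0)
  expect_equal(auc_pvalue(0.5, point), 1)
})

test_that("BH rejections match brute-force step-up", {
  step_up_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * q / m)
    out <- rep(FALSE, m)
    if (length(ks) > 0) out[o[seq_len(max(ks))]] <- TRUE
    out
  }
  expect_equal(bh_fdr(c(0.001, 0.008, 0.039, 0.041), q = 0.05),
               rep(TRUE, 4))
  expect_equal(bh_fdr(rep(1, 5), q = 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(0.005, q = 0.01), TRUE)
  expect_error(bh_fdr(numeric(0)), "empty")

  set.seed(24)
  for (rep in 1:30) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.2), 1)
    expect_equal(bh_fdr(p, q), step_up_oracle(p, q))
  }
})

test_that("category evaluation applies the occurrence filter and null machinery", {
  Tn <- 120
  set.seed(25)
  m <- cbind(common = rbinom(Tn, 1, 0.4), rare = 0L, full = 1L)
  m[c(10, 50), "rare"] <- 1L   # 2 occurrences: excluded
  m[7, "full"] <- 0L
  lab <- label_timecourse(m)
  dec <- structure(
    list(values = cbind(common = as.numeric(m[, "common"]),
                        rare = runif(Tn), full = runif(Tn)),
         categories = c("common", "rare", "full"), valid = rep(TRUE, Tn)),
    class = "decoded_matrix")
  ev <- evaluate_categories(dec, lab, shuffles = 300, seed = 1)
  expect_false("rare" %in% ev$category)      # < 3 occurrences
  row <- ev[ev$category == "common", ]
  expect_equal(row$auc, 1.0)                 # decoded == labels
  expect_lt(row$p, 1e-4)
  expect_true(row$q_reject)

  # constant decoded scores: all ties -> AUC 0.5, not significant
  dec$values[, "common"] <- 0.4
  ev2 <- evaluate_categories(dec, lab, shuffles = 300, seed = 1)
  expect_equal(ev2$auc[ev2$category == "common"], 0.5)
  expect_false(ev2$q_reject[ev2$category == "common"])
})

test_that("conditional AUC restricts to hypernym-present time points", {
  Tn <- 60
  set.seed(26)
  mv <- rep(1L, Tn)  # parent always present -> cauc == auc
  car <- rbinom(Tn, 1, 0.5)
  m <- cbind("motor_vehicle.n.01" = mv, "car.n.01" = car,
             "station_wagon.n.01" = 0L)
  m[c(3, 9), "station_wagon.n.01"] <- 1L
  m[c(3, 9), "car.n.01"] <- 1L
  lab <- label_timecourse(m)
  s <- matrix(runif(Tn * 3), Tn, 3, dimnames = list(NULL, colnames(m)))
  dec <- structure(list(values = s, categories = colnames(m),
                        valid = rep(TRUE, Tn)), class = "decoded_matrix")
  ca <- conditional_auc(dec, lab, chain_tax, "car.n.01")
  expect_true(ca$defined)
  expect_equal(ca$cauc, roc_auc(s[, "car.n.01"], m[, "car.n.01"]))

  # 2 conditional positives -> undefined
  sw <- conditional_auc(dec, lab, chain_tax, "station_wagon.n.01")
  expect_false(sw$defined)
  expect_true(is.na(sw$cauc))
})

test_that("a category separable from siblings but not strangers has cauc > auc", {
  # response space toy: sibling categories grouped, the target overlaps a
  # distant category, so conditioning on the parent helps
  tax <- taxonomy(c("root", "grp", "target", "sibling", "stranger"),
                  rbind(c("root", "grp"), c("grp", "target"),
                        c("grp", "sibling"), c("root", "stranger")))
  set.seed(27)
  Tn <- 300
  state <- sample(c("target", "sibling", "stranger"), Tn, replace = TRUE)
  m <- matrix(0L, Tn, 5, dimnames = list(NULL, tax$nodes$id))
  m[, "root"] <- 1L
  m[state == "target", "target"] <- 1L
  m[state == "sibling", "sibling"] <- 1L
  m[state != "stranger", "grp"] <- 1L
  m[state == "stranger", "stranger"] <- 1L
  lab <- label_timecourse(m)
  # decoded target score: high for target, low for sibling, high for stranger
  s_target <- ifelse(state == "target", rnorm(Tn, 2),
                     ifelse(state == "sibling", rnorm(Tn, -2), rnorm(Tn, 2)))
  s <- matrix(0.5, Tn, 5, dimnames = list(NULL, tax$nodes$id))
  s[, "target"] <- plogis(s_target)
  dec <- structure(list(values = s, categories = colnames(s),
                        valid = rep(TRUE, Tn)), class = "decoded_matrix")
  auc <- roc_auc(s[, "target"], m[, "target"])
  ca <- conditional_auc(dec, lab, tax, "target")
  expect_true(ca$defined)
  expect_gt(ca$cauc, auc)
  expect_gt(ca$cauc, 0.95)

  # and the edge test flags grp -> target
  et <- edge_inconsistency_test(dec, lab, tax, n_boot = 400, seed = 2)
  flagged <- et[et$child == "target", ]
  expect_true(flagged$q_reject)
  # identical seed gives identical p-values
  et2 <- edge_inconsistency_test(dec, lab, tax, n_boot = 400, seed = 2)
  expect_equal(et$p, et2$p)
})

test_that("edge test stays silent when decoding is perfect", {
  Tn <- 200
  set.seed(28)
  mv <- rbinom(Tn, 1, 0.6)
  car <- ifelse(mv == 1, rbinom(Tn, 1, 0.5), 0L)
  m <- cbind("motor_vehicle.n.01" = mv, "car.n.01" = as.integer(car),
             "station_wagon.n.01" = 0L)
  lab <- label_timecourse(m)
  s <- matrix(0, Tn, 3, dimnames = list(NULL, colnames(m)))
  s[, "motor_vehicle.n.01"] <- mv
  s[, "car.n.01"] <- car
  dec <- structure(list(values = s, categories = colnames(m),
                        valid = rep(TRUE, Tn)), class = "decoded_matrix")
  et <- edge_inconsistency_test(dec, lab, chain_tax, n_boot = 300, seed = 3)
  expect_false(any(et$q_reject))
})

test_that("timepoint log likelihood ratios follow the printed formula", {
  m <- cbind(a = c(1L, 0L), b = c(0L, 1L))
  lab <- label_timecourse(m)
  dec <- structure(list(values = cbind(a = c(0.9, 0.5), b = c(0.5, 0.5)),
                        categories = c("a", "b"), valid = c(TRUE, TRUE)),
                   class = "decoded_matrix")
  priors <- c(a = 0.5, b = 0.5)
  llr <- timepoint_llr(dec, lab, priors)
  expect_equal(llr$llr[1], log(0.9 / 0.5) + log(0.5 / 0.5))  # = log(1.8)
  expect_equal(llr$llr[2], 0)                                 # theta == prior

  # theta == labels exactly (clipped): LLR is the -log prior mass, >= 0
  dec2 <- structure(list(values = cbind(a = c(1, 0), b = c(0, 1)),
                         categories = c("a", "b"), valid = c(TRUE, TRUE)),
                    class = "decoded_matrix")
  llr2 <- timepoint_llr(dec2, lab, priors)
  expect_true(all(llr2$llr >= 0))
  expect_equal(llr2$llr[1], -log(0.5) - log(0.5), tolerance = 1e-4)
})

test_that("LLR permutation null flags informative timepoints reproducibly", {
  # constant decoded output: shuffling is a no-op, nothing significant
  m <- cbind(a = rbinom(60, 1, 0.4))
  lab <- label_timecourse(m)
  dec <- structure(list(values = cbind(a = rep(0.4, 60)), categories = "a",
                        valid = rep(TRUE, 60)), class = "decoded_matrix")
  out <- llr_shuffle_null(dec, lab, c(a = 0.4), n = 200, seed = 1)
  expect_false(any(out$significant))

  # strongly correct decoding across many categories: most TRs significant
  set.seed(29)
  Y <- matrix(rbinom(200 * 8, 1, 0.5), 200, 8,
              dimnames = list(NULL, paste0("c", 1:8)))
  dec2 <- structure(list(values = ifelse(Y == 1, 0.95, 0.05),
                         categories = colnames(Y), valid = rep(TRUE, 200)),
                    class = "decoded_matrix")
  lab2 <- label_timecourse(Y)
  priors <- stats::setNames(rep(0.5, 8), colnames(Y))
  out2 <- llr_shuffle_null(dec2, lab2, priors, n = 500, seed = 2)
  expect_gt(mean(out2$significant), 0.5)
  out3 <- llr_shuffle_null(dec2, lab2, priors, n = 500, seed = 2)
  expect_identical(out2$significant, out3$significant)
})
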