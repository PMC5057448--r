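test_that("marginals are products of conditionals along the closure", {
  probs <- list("motor_vehicle.n.01" = 0.8, "car.n.01" = 0.5,
                "station_wagon.n.01" = 0.9)
  model <- manual_hlr(chain_tax, probs)
  d <- decode(model, feature_stub(3))
  expect_equal(unique(d$values[, "car.n.01"]), 0.8 * 0.5)          # 0.4
  expect_equal(unique(d$values[, "motor_vehicle.n.01"]), 0.8)      # root = own
  expect_equal(unique(d$values[, "station_wagon.n.01"]), 0.8 * 0.5 * 0.9)
})

test_that("decode matches exhaustive joint enumeration on small hierarchies", {
  set.seed(11)
  taxa <- list(
    chain_tax,
    diamond_tax,
    taxonomy(c("r", "x", "y"), rbind(c("r", "x"), c("r", "y"))),
    taxonomy("solo", NULL)
  )
  for (tax in taxa) {
    for (rep in 1:5) {
      probs <- as.list(stats::setNames(runif(nrow(tax$nodes), 0.05, 0.95),
                                       tax$order))
      model <- manual_hlr(tax, probs)
      d <- decode(model, feature_stub(2))
      oracle <- enumeration_marginals(tax, probs)
      expect_equal(d$values[1, names(oracle)], oracle, tolerance = 1e-10)
    }
  }
})

test_that("decoded probabilities never exceed any hypernym's", {
  set.seed(12)
  for (rep in 1:100) {
    depth <- sample(2:4, 1)
    tax <- make_toy_taxonomy(depth, sample(2:3, 1))
    nf <- 3
    models <- lapply(tax$order, function(cat) {
      hlrdecode:::new_conditional_model(
        cat, rnorm(nf), rnorm(1), runif(1, 0.05, 0.95),
        eta = sample(c(0, runif(1, 0, 2)), 1))
    })
    names(models) <- tax$order
    model <- structure(
      list(taxonomy = tax, voxel_ids = paste0("v", 1:nf), delays = 1L,
           models = models, P0 = NULL, method = "earlystop", seed = 0),
      class = "hlr_model")
    feat <- feature_stub(4, nf)
    feat$values <- matrix(rnorm(4 * nf), 4, nf)
    d <- decode(model, feat)
    for (e in seq_len(nrow(tax$edges))) {
      expect_true(all(d$values[, tax$edges$child[e]] <=
                        d$values[, tax$edges$parent[e]] + 1e-12))
    }
  }
})

test_that("a fitted chain decoder conditions each child on its parent", {
  set.seed(13)
  Tn <- 300
  mv <- rbinom(Tn, 1, 0.6)
  car <- ifelse(mv == 1, rbinom(Tn, 1, 0.5), 0)
  sw <- ifelse(car == 1, rbinom(Tn, 1, 0.5), 0)
  m <- cbind("motor_vehicle.n.01" = mv, "car.n.01" = car,
             "station_wagon.n.01" = sw)
  lab <- label_timecourse(m)
  feat <- feature_stub(Tn, 4)
  feat$values <- matrix(rnorm(Tn * 4), Tn, 4)
  colnames(feat$values) <- paste0("v", 1:4)
  model <- fit_hlr(lab, feat, chain_tax, seed = 2)
  expect_named(model$models, chain_tax$order)
  # the car model saw only motor-vehicle-present TRs (minus the eta holdout)
  holdout <- seq_len(Tn) > Tn - 30
  expect_equal(model$models[["car.n.01"]]$n_cond, sum(mv == 1 & !holdout))
  # marginal priors respect the hierarchy
  expect_true(model$P0["car.n.01"] <= model$P0["motor_vehicle.n.01"])
  expect_true(model$P0["station_wagon.n.01"] <= model$P0["car.n.01"])
})

test_that("never-present categories get degenerate Laplace-prior models", {
  Tn <- 100
  m <- cbind("motor_vehicle.n.01" = rbinom(Tn, 1, 0.5),
             "car.n.01" = 0L, "station_wagon.n.01" = 0L)
  lab <- label_timecourse(m)
  feat <- feature_stub(Tn, 2)
  feat$values <- matrix(rnorm(Tn * 2), Tn, 2)
  colnames(feat$values) <- c("v1", "v2")
  model <- fit_hlr(lab, feat, chain_tax, seed = 3)
  car <- model$models[["car.n.01"]]
  expect_true(car$degenerate)
  expect_equal(car$p0, 1 / (car$n_cond + 2))
})

test_that("serialization round-trips decoded probabilities to 1e-12", {
  bundle <- ref_small
  trf <- build_lagged_features(preprocess_bold(bundle$train$bold))
  model <- fit_hlr(bundle$train$labels, trf, bundle$taxonomy, seed = 7)
  d1 <- decode(model, trf)
  path <- withr::local_tempfile(fileext = ".json")
  write_hlr(model, path)
  back <- read_hlr(path)
  d2 <- decode(back, trf)
  expect_equal(d2$values, d1$values, tolerance = 1e-12)
})

test_that("tidy and glance summarize a fitted decoder", {
  bundle <- ref_small
  trf <- build_lagged_features(preprocess_bold(bundle$train$bold))
  model <- fit_hlr(bundle$train$labels, trf, bundle$taxonomy, seed = 7)
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 7)
  expect_true(all(c("category", "p0", "eta", "weight_norm", "degenerate")
                  %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_categories, 7)
  expect_equal(gl$n_features, ncol(trf$values))
})

test_that("fitted weights recover planted voxel tuning at high SNR", {
  cfg <- sim_config(seed = 21, depth = 1, T_train = 600, T_val = 50,
                    n_voxels = 40, n_signal_voxels = 20, noise_sd = 0.1,
                    n_repeats = 1, drift_amplitude = 0)
  bundle <- simulate_dataset(cfg)
  trf <- build_lagged_features(preprocess_bold(bundle$train$bold))
  model <- fit_hlr(bundle$train$labels, trf, bundle$taxonomy, seed = 21)
  root <- bundle$taxonomy$roots
  w <- model$models[[root]]$weights
  # mid-delay weights against the planted tuning column for the root
  mid <- w[grepl("\\+3$", names(w))]
  expect_gt(cor(mid, bundle$W[, root]), 0.8)
})
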