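# Shared fixtures, built in code once per test run.

# The canonical 3-node chain: motor vehicle -> car -> station wagon.
chain_tax <- taxonomy(
  c("motor_vehicle.n.01", "car.n.01", "station_wagon.n.01"),
  rbind(c("motor_vehicle.n.01", "car.n.01"),
        c("car.n.01", "station_wagon.n.01"))
)

# Diamond DAG: a -> b, a -> c, b -> d, c -> d.
diamond_tax <- taxonomy(
  c("a", "b", "c", "d"),
  rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d"))
)

# Build an hlr_model by hand from per-category constant conditional
# probabilities (weights zero, bias = logit(p)), for decode() oracles.
manual_hlr <- function(tax, cond_probs, n_feat = 2) {
  models <- lapply(tax$order, function(cat) {
    m <- hlrdecode:::new_conditional_model(
      cat, numeric(n_feat), hlrdecode:::logit(cond_probs[[cat]]), cond_probs[[cat]]
    )
    m
  })
  names(models) <- tax$order
  structure(
    list(taxonomy = tax, voxel_ids = paste0("v", seq_len(n_feat)), delays = 1L,
         models = models, P0 = unlist(cond_probs), method = "earlystop", seed = 0),
    class = "hlr_model"
  )
}

feature_stub <- function(Tn, n_feat = 2) {
  structure(
    list(values = matrix(0, Tn, n_feat), valid = rep(TRUE, Tn),
         delays = 1L, voxel_ids = paste0("v", seq_len(n_feat)),
         runs = tibble::tibble(start = 0L, length = Tn)),
    class = "feature_matrix"
  )
}

# Exhaustive-enumeration oracle: marginal P(category present) from the
# conditional probability of each node given all parents present, summing the
# joint over every binary label configuration (child forced absent when any
# parent is absent).
enumeration_marginals <- function(tax, cond_probs) {
  nodes <- tax$order
  n <- length(nodes)
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(configs) <- nodes
  marg <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(nrow(configs))) {
    s <- configs[i, ]
    p <- 1
    for (v in nodes) {
      ps <- tax$edges$parent[tax$edges$child == v]
      if (length(ps) == 0 || all(s[ps] == 1)) {
        p <- p * if (s[v] == 1) cond_probs[[v]] else 1 - cond_probs[[v]]
      } else if (s[v] == 1) {
        p <- 0
      }
      if (p == 0) break
    }
    marg[s == 1] <- marg[s == 1] + p
  }
  marg
}

# Separable two-voxel toy for the conditional fitters: class means at
# (+mu, +mu) and (-mu, -mu) with unit-ish noise.
separable_toy <- function(n = 200, mu = 1, sd = 0.5, seed = 0) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  X <- cbind(rnorm(n, ifelse(y == 1, mu, -mu), sd),
             rnorm(n, ifelse(y == 1, mu, -mu), sd))
  colnames(X) <- c("v1", "v2")
  list(X = X, y = y)
}

# One small simulated estimation/validation bundle shared across tests.
ref_small <- local({
  cfg <- sim_config(seed = 42, T_train = 400, T_val = 200, n_repeats = 3,
                    n_voxels = 48, n_signal_voxels = 16)
  simulate_dataset(cfg)
})
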