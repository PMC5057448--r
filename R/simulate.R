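#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' reference study conditions at desk scale: a 7-node balanced taxonomy
#' (depth 3, branching 2), 600 training TRs and 270 validation TRs with the
#' validation stimulus repeated 10 times and averaged, 64 category-tuned
#' signal voxels among 256 total, responses lagged 2-4 TRs behind the
#' stimulus with kernel (0.5, 1.0, 0.5), unit response gain and Gaussian
#' measurement noise of sd 0.3, slow sinusoidal drift (period 67 TRs, about
#' 134 s at TR = 2 s, so a 120-s median filter attenuates it), and
#' persistent scene-like labels (two-state Markov stay probability 0.9).
#'
#' @param depth,branching Balanced-tree taxonomy shape (used when `tax` is
#'   `NULL`).
#' @param tax Optional explicit [taxonomy()].
#' @param T_train,T_val Training / validation TR counts.
#' @param n_repeats Validation repeats to simulate (default 10).
#' @param n_voxels,n_signal_voxels Total and category-tuned voxel counts.
#' @param tr_seconds TR in seconds (default 2).
#' @param delays Response lags in TRs (default `c(2, 3, 4)`).
#' @param kernel Lag kernel weights over `delays` (default `c(0.5, 1, 0.5)`,
#'   a crude hemodynamic-response stand-in the decoder is never told about).
#' @param gain Response gain (0 gives label-independent responses).
#' @param noise_sd Measurement noise standard deviation.
#' @param drift_amplitude,drift_period_trs Sinusoidal drift parameters.
#' @param tuning_sparsity Probability that a signal voxel is *not* also
#'   weakly tuned to any given non-primary category (default 0.9).
#' @param persistence Per-category two-state Markov stay probability in
#'   (0, 1) (default 0.9).
#' @param seed Master seed; fixes every draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(depth = 3, branching = 2, tax = NULL,
                       T_train = 600, T_val = 270, n_repeats = 10,
                       n_voxels = 256, n_signal_voxels = 64,
                       tr_seconds = 2, delays = c(2, 3, 4),
                       kernel = c(0.5, 1, 0.5), gain = 1, noise_sd = 0.3,
                       drift_amplitude = 0.5, drift_period_trs = 67,
                       tuning_sparsity = 0.9, persistence = 0.9, seed = 0) {
  stopifnot(T_train > 0, T_val > 0, n_repeats >= 1, n_voxels >= 1,
            n_signal_voxels <= n_voxels, persistence > 0, persistence < 1,
            length(kernel) == length(delays), gain >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a balanced toy taxonomy
#'
#' A balanced tree of the given depth and branching factor with
#' synset-style synthetic ids (`"sim000.n.01"` etc.), deterministic for a
#' given shape.
#'
#' @param depth Number of levels (1 = a single root).
#' @param branching Children per node.
#' @param seed Unused for the balanced tree (kept so the generator API is
#'   uniformly seeded).
#' @return A [taxonomy()] with `branching^depth - 1` nodes for binary
#'   branching (generally `sum(branching^(0:(depth-1)))`).
#' @export
make_toy_taxonomy <- function(depth, branching = 2, seed = 0) {
  stopifnot(depth >= 1, branching >= 1)
  n_per_level <- branching^(0:(depth - 1))
  total <- sum(n_per_level)
  ids <- sprintf("sim%03d.n.01", seq_len(total) - 1L)
  edges <- NULL
  offset <- 0L
  for (lev in seq_len(depth - 1)) {
    parents <- ids[offset + seq_len(n_per_level[lev])]
    child_off <- offset + n_per_level[lev]
    for (i in seq_along(parents)) {
      kids <- ids[child_off + (i - 1L) * branching + seq_len(branching)]
      edges <- rbind(edges, cbind(parents[i], kids))
    }
    offset <- child_off
  }
  taxonomy(ids, edges)
}

taxonomy_leaves <- function(tax) setdiff(tax$nodes$id, tax$edges$parent)

#' Simulate a hierarchy-closed label time course
#'
#' Leaf categories follow independent two-state Markov chains with stay
#' probability `persistence` (so scene-like presence runs of mean length
#' `1/(1 - persistence)` TRs); ancestor categories are then set by hypernym
#' closure. The output always passes [validate_closure()].
#'
#' @param tax A [taxonomy()].
#' @param T Number of TRs.
#' @param persistence Stay probability in (0, 1).
#' @param seed Integer seed.
#' @param tr_seconds TR in seconds.
#' @return A hierarchy-closed [label_timecourse()] covering every taxonomy
#'   node.
#' @export
simulate_labels <- function(tax, T, persistence = 0.9, seed = 0, tr_seconds = 2) {
  stopifnot(inherits(tax, "taxonomy"), T >= 1)
  leaves <- taxonomy_leaves(tax)
  set.seed(seed)
  m <- matrix(0L, T, length(leaves), dimnames = list(NULL, leaves))
  for (j in seq_along(leaves)) {
    x <- integer(T)
    x[1] <- stats::rbinom(1, 1, 0.5)
    stay <- stats::runif(T - 1) < persistence
    for (t in seq_len(T - 1)) {
      x[t + 1] <- if (stay[t]) x[t] else 1L - x[t]
    }
    m[, j] <- x
  }
  propagate_labels(label_timecourse(m, tr_seconds = tr_seconds), tax)
}

# Planted voxel-by-category tuning: each signal voxel gets a primary
# category (round-robin over the taxonomy order) with weight ~ N(1, 0.2),
# plus weak secondary tunings with probability 1 - sparsity.
make_tuning <- function(tax, n_voxels, n_signal, sparsity) {
  cats <- tax$order
  W <- matrix(0, n_voxels, length(cats), dimnames = list(NULL, cats))
  if (n_signal > 0) {
    primary <- rep_len(seq_along(cats), n_signal)
    W[cbind(seq_len(n_signal), primary)] <- stats::rnorm(n_signal, 1, 0.2)
    extra <- matrix(stats::runif(n_signal * length(cats)) > sparsity,
                    n_signal, length(cats))
    extra[cbind(seq_len(n_signal), primary)] <- FALSE
    W[seq_len(n_signal), ][extra] <- stats::rnorm(sum(extra), 0, 0.3)
  }
  W
}

#' Simulate lagged, category-tuned BOLD responses
#'
#' Signal voxel `v` responds to the categories it is tuned to with a fixed
#' lag kernel: the stimulus at TR `t` adds
#' `gain * W[v, c] * label[t, c] * kernel[d]` to the response at `t + d`
#' for each delay `d` (within the run), emulating the slow hemodynamic
#' response the decoder's lagged features must deconvolve. Slow sinusoidal
#' drift and i.i.d. Gaussian noise are added on top; across repeats the
#' signal and drift are identical and only the noise is redrawn.
#'
#' @param labels A [label_timecourse()] (the stimulus).
#' @param config A [sim_config()].
#' @param n_repeats Number of repeats to generate (default 1).
#' @param W Optional pre-built tuning matrix (rows = voxels, columns =
#'   taxonomy-ordered categories); built from `config` when `NULL`.
#' @param seed Seed for tuning/noise draws (default `config$seed`).
#' @return A list with `repeats` (list of [bold_runs()]) and `W` (the
#'   planted tuning matrix, ground truth for recovery tests).
#' @export
simulate_bold <- function(labels, config, n_repeats = 1, W = NULL,
                          seed = config$seed) {
  stopifnot(inherits(labels, "label_timecourse"), inherits(config, "sim_config"))
  set.seed(seed)
  nv <- config$n_voxels
  if (is.null(W)) {
    W <- make_tuning(
      tax_of_labels(labels, config), nv, config$n_signal_voxels,
      config$tuning_sparsity
    )
  }
  cats <- colnames(W)
  stopifnot(all(cats %in% labels$categories))
  Tn <- nrow(labels$values)
  L <- labels$values[, cats, drop = FALSE]
  drive <- L %*% t(W) * config$gain  # time x voxel stimulus drive
  signal <- matrix(0, Tn, nv)
  off <- 0L
  for (r in seq_len(nrow(labels$runs))) {
    len <- labels$runs$length[r]
    for (di in seq_along(config$delays)) {
      d <- config$delays[di]
      src <- seq_len(len - d)
      signal[off + src + d, ] <- signal[off + src + d, ] +
        config$kernel[di] * drive[off + src, , drop = FALSE]
    }
    off <- off + len
  }
  drift <- config$drift_amplitude *
    sin(2 * pi * seq_len(Tn) / config$drift_period_trs)
  base <- signal + drift
  repeats <- lapply(seq_len(n_repeats), function(i) {
    noise <- matrix(stats::rnorm(Tn * nv, 0, config$noise_sd), Tn, nv)
    m <- base + noise
    runs <- split_by_runs(m, labels$runs)
    bold_runs(runs, tr_seconds = labels$tr_seconds)
  })
  list(repeats = repeats, W = W)
}

split_by_runs <- function(m, runs) {
  lapply(seq_len(nrow(runs)), function(r) {
    m[runs$start[r] + seq_len(runs$length[r]), , drop = FALSE]
  })
}

tax_of_labels <- function(labels, config) {
  if (!is.null(config$tax)) config$tax
  else make_toy_taxonomy(config$depth, config$branching, config$seed)
}

#' Simulate a complete estimation + validation dataset
#'
#' Draws a taxonomy (unless given), disjoint training and validation label
#' streams, one training BOLD pass, and `n_repeats` validation passes
#' sharing the validation labels (noise redrawn per repeat), with the
#' planted tuning matrix as ground truth. When `out` is given, the bundle
#' is written to disk in the formats the rest of the pipeline reads
#' (taxonomy JSON, label TSVs + sidecars, BOLD TSVs, ground-truth JSON and
#' a manifest recording the seed).
#'
#' @param config A [sim_config()].
#' @param out Optional output directory.
#' @return A list with `taxonomy`, `train` (list of `labels`, `bold`),
#'   `val` (list of `labels`, `repeats`), `W`, and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), out = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tax <- tax_of_labels(NULL, config)
  train_labels <- simulate_labels(tax, config$T_train, config$persistence,
                                  seed = config$seed + 1,
                                  tr_seconds = config$tr_seconds)
  val_labels <- simulate_labels(tax, config$T_val, config$persistence,
                                seed = config$seed + 2,
                                tr_seconds = config$tr_seconds)
  set.seed(config$seed + 3)
  W <- make_tuning(tax, config$n_voxels, config$n_signal_voxels,
                   config$tuning_sparsity)
  train <- simulate_bold(train_labels, config, n_repeats = 1, W = W,
                         seed = config$seed + 4)
  val <- simulate_bold(val_labels, config, n_repeats = config$n_repeats, W = W,
                       seed = config$seed + 5)
  bundle <- list(
    taxonomy = tax,
    train = list(labels = train_labels, bold = train$repeats[[1]]),
    val = list(labels = val_labels, repeats = val$repeats),
    W = W,
    config = config
  )
  if (!is.null(out)) write_sim_bundle(bundle, out)
  bundle
}

write_sim_bundle <- function(bundle, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_taxonomy(bundle$taxonomy, file.path(out, "taxonomy.json"))
  write_labels(bundle$train$labels, file.path(out, "train_labels.tsv"))
  write_labels(bundle$val$labels, file.path(out, "val_labels.tsv"))
  write_bold(bundle$train$bold, file.path(out, "train_bold.tsv"))
  for (i in seq_along(bundle$val$repeats)) {
    write_bold(bundle$val$repeats[[i]],
               file.path(out, sprintf("val_bold_rep%02d.tsv", i)))
  }
  jsonlite::write_json(
    list(W = as.data.frame(bundle$W)),
    file.path(out, "ground_truth_synthetic.json"), digits = NA
  )
  cfg <- unclass(bundle$config)
  cfg$tax <- NULL
  jsonlite::write_json(
    list(config = cfg, n_repeats = length(bundle$val$repeats)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out)
}
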