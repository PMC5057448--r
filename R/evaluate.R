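#' Area under the ROC curve
#'
#' Rank-statistic AUC: with average ranks, ties count one half, which equals
#' the trapezoidal area under the threshold-swept ROC curve and the
#' Mann-Whitney pairwise probability that a random positive outranks a
#' random negative. Constant scores give all ties, hence 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  if (n1 == 0 || n0 == 0) stop("AUC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permute a label time course in contiguous blocks
#'
#' Partitions the time axis into consecutive blocks of `block` TRs (the last
#' block may be shorter) and permutes the block order uniformly. Block
#' shuffling preserves the number of positives exactly and approximately
#' preserves the within-block autocorrelation, destroying only the alignment
#' with the decoded scores — the appropriate permutation null for
#' autocorrelated natural-movie labels.
#'
#' @param labels Binary vector.
#' @param block Block length in TRs (default 4).
#' @param n Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @return A list of `n` shuffled vectors.
#' @export
block_shuffle <- function(labels, block = 4, n = 1000, seed = 1) {
  stopifnot(block >= 1)
  Tn <- length(labels)
  idx <- split(seq_len(Tn), ceiling(seq_len(Tn) / block))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ord <- unlist(idx[sample(length(idx))], use.names = FALSE)
    labels[ord]
  })
}

#' Fit a symmetric beta distribution to a permutation-null AUC sample
#'
#' The chance distribution of the AUC is centered at 0.5, so the beta fit is
#' constrained symmetric (`alpha = beta`, mean exactly 0.5) and the shape is
#' set by matching the null variance: `var(Beta(a, a)) = 1/(4(2a + 1))`,
#' hence `a = 1/(8 var) - 1/2`, clipped below at 1.
#'
#' @param null_aucs Numeric vector of null AUCs (at least 100 recommended).
#' @return A list with `alpha`, `beta` (equal) and `var`; zero-variance
#'   input returns `alpha = Inf` (a point null at 0.5).
#' @export
fit_null_beta <- function(null_aucs) {
  stopifnot(length(null_aucs) >= 2, all(is.finite(null_aucs)))
  v <- stats::var(null_aucs)
  if (v < .Machine$double.eps) {
    return(list(alpha = Inf, beta = Inf, var = 0))
  }
  a <- max(1, 1 / (8 * v) - 0.5)
  list(alpha = a, beta = a, var = v)
}

#' Upper-tail p-value of an AUC under the fitted beta null
#'
#' @param auc Observed AUC.
#' @param null_beta A [fit_null_beta()] result.
#' @return `P(X >= auc)` under `Beta(alpha, alpha)`; for the degenerate
#'   point null, an indicator of `auc <= 0.5`.
#' @export
auc_pvalue <- function(auc, null_beta) {
  if (!is.finite(null_beta$alpha)) return(as.numeric(auc <= 0.5))
  stats::pbeta(auc, null_beta$alpha, null_beta$beta, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Rejects every hypothesis whose BH-adjusted p-value is at most `q`,
#' equivalent to the step-up rule: reject all `p <= p_(k*)` with
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.01).
#' @return Logical rejection vector aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.01) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Per-category decoding evaluation
#'
#' For every category that appears in at least `min_occurrence` validation
#' TRs (and is absent in at least one), computes the AUC of the decoded
#' probabilities against the actual labels, a block-shuffle permutation null
#' (labels shuffled in blocks, AUC recomputed), a symmetric beta fit to the
#' null, the upper-tail p-value, and a Benjamini-Hochberg rejection flag
#' across all tested categories.
#'
#' @param decoded A `decoded_matrix` from [decode()].
#' @param labels The validation [label_timecourse()] (hierarchy-closed).
#' @param min_occurrence Minimum positive TRs to evaluate a category
#'   (default 3).
#' @param shuffles Number of block shuffles (default 1000).
#' @param block Shuffle block length in TRs (default 4).
#' @param q FDR level (default 0.01).
#' @param seed Integer seed for the shuffles.
#' @return A tibble with one row per tested category: `category`, `n_pos`,
#'   `auc`, `null_alpha`, `null_mean`, `p`, `q_reject`.
#' @export
evaluate_categories <- function(decoded, labels, min_occurrence = 3,
                                shuffles = 1000, block = 4, q = 0.01, seed = 1) {
  stopifnot(inherits(decoded, "decoded_matrix"), inherits(labels, "label_timecourse"))
  common <- intersect(decoded$categories, labels$categories)
  if (length(common) == 0) stop("decoded and label categories do not overlap")
  rows <- which(decoded$valid)
  res <- purrr::map_dfr(seq_along(common), function(i) {
    cat_id <- common[i]
    y <- labels$values[rows, cat_id]
    s <- decoded$values[rows, cat_id]
    n_pos <- sum(y)
    if (n_pos < min_occurrence || n_pos == length(y)) return(NULL)
    auc <- roc_auc(s, y)
    nulls <- vapply(block_shuffle(y, block = block, n = shuffles,
                                  seed = seed + i),
                    function(yp) roc_auc(s, yp), numeric(1))
    nb <- fit_null_beta(nulls)
    tibble::tibble(
      category = cat_id, n_pos = n_pos, auc = auc,
      null_alpha = nb$alpha, null_mean = mean(nulls),
      p = auc_pvalue(auc, nb)
    )
  })
  if (nrow(res) == 0) stop("no category passes the occurrence filter")
  res$q_reject <- bh_fdr(res$p, q = q)
  res
}

#' Conditional AUC: separability from sibling categories
#'
#' The AUC recomputed using only the validation TRs where all of the
#' category's hypernyms are present, so the negatives are the category's
#' siblings. A high cAUC with a lower total AUC indicates a category that is
#' easier to tell apart from its siblings than from unrelated categories —
#' evidence that the taxonomy grouping is not reflected in the responses.
#' The statistic is undefined (conditional entropy too low) when the
#' conditioned subset has fewer than `min_pos` positives or `min_neg`
#' negatives.
#'
#' @param decoded A `decoded_matrix`.
#' @param labels Validation [label_timecourse()] (hierarchy-closed).
#' @param tax A [taxonomy()].
#' @param cat Category id.
#' @param min_pos,min_neg Minimum conditioned positives / negatives
#'   (default 3 each).
#' @return A list with `cauc` (NA when undefined) and `defined`.
#' @export
conditional_auc <- function(decoded, labels, tax, cat, min_pos = 3, min_neg = 3) {
  stopifnot(inherits(decoded, "decoded_matrix"))
  if (!cat %in% tax$nodes$id) stop("unknown category id: ", cat)
  cmask <- conditioning_mask(labels, tax, cat)
  rows <- which(cmask & decoded$valid)
  y <- labels$values[rows, cat]
  if (sum(y) < min_pos || sum(1 - y) < min_neg) {
    return(list(cauc = NA_real_, defined = FALSE))
  }
  list(cauc = roc_auc(decoded$values[rows, cat], y), defined = TRUE)
}

#' Test taxonomy edges for inconsistency with the decoded responses
#'
#' For each hypernym edge whose child has a defined conditional AUC, tests
#' whether the child's cAUC is significantly *higher* than its overall AUC
#' (the signature of a taxonomy grouping not reflected in the brain
#' responses). Significance uses a moving-block bootstrap over validation
#' TRs: blocks of `block` TRs are resampled with replacement, cAUC - AUC is
#' recomputed per resample, the p-value is the fraction of resamples with a
#' non-positive difference, and Benjamini-Hochberg is applied across edges.
#'
#' @inheritParams evaluate_categories
#' @param tax A [taxonomy()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param min_pos,min_neg Conditional sample thresholds (default 3).
#' @return A tibble with one row per testable edge: `parent`, `child`,
#'   `auc`, `cauc`, `delta` (cauc - auc), `p`, `q_reject`.
#' @export
edge_inconsistency_test <- function(decoded, labels, tax, n_boot = 1000,
                                    block = 4, q = 0.01, seed = 1,
                                    min_pos = 3, min_neg = 3) {
  stopifnot(inherits(decoded, "decoded_matrix"), inherits(tax, "taxonomy"))
  rows <- which(decoded$valid)
  Tn <- length(rows)
  nb <- ceiling(Tn / block)
  set.seed(seed)
  # shared resample index sets so edges see the same bootstrap draws
  resamples <- lapply(seq_len(n_boot), function(i) {
    starts <- sample(seq_len(max(Tn - block + 1, 1)), nb, replace = TRUE)
    idx <- as.vector(outer(0:(block - 1), starts, `+`))
    rows[idx[idx <= Tn][seq_len(Tn)]]
  })
  res <- purrr::map_dfr(seq_len(nrow(tax$edges)), function(e) {
    child <- tax$edges$child[e]
    parent <- tax$edges$parent[e]
    if (!child %in% decoded$categories || !child %in% labels$categories) return(NULL)
    ca <- conditional_auc(decoded, labels, tax, child,
                          min_pos = min_pos, min_neg = min_neg)
    if (!ca$defined) return(NULL)
    y_all <- labels$values[rows, child]
    s_all <- decoded$values[rows, child]
    if (sum(y_all) == 0 || sum(y_all) == length(y_all)) return(NULL)
    auc <- roc_auc(s_all, y_all)
    cmask_full <- conditioning_mask(labels, tax, child) & decoded$valid
    deltas <- vapply(resamples, function(rs) {
      y <- labels$values[rs, child]
      s <- decoded$values[rs, child]
      cm <- cmask_full[rs]
      if (sum(y) == 0 || sum(y) == length(y)) return(NA_real_)
      yc <- y[cm]; sc <- s[cm]
      if (sum(yc) < 1 || sum(1 - yc) < 1) return(NA_real_)
      roc_auc(sc, yc) - roc_auc(s, y)
    }, numeric(1))
    deltas <- deltas[is.finite(deltas)]
    if (length(deltas) < n_boot / 2) return(NULL)
    tibble::tibble(parent = parent, child = child, auc = auc, cauc = ca$cauc,
                   delta = ca$cauc - auc, p = mean(deltas <= 0))
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(parent = character(), child = character(),
                          auc = numeric(), cauc = numeric(), delta = numeric(),
                          p = numeric(), q_reject = logical()))
  }
  res$q_reject <- bh_fdr(res$p, q = q)
  res
}

#' Per-timepoint log likelihood ratio of the decoded labels
#'
#' At each TR, the log likelihood of the actual binary label vector under
#' the decoded probabilities, relative to its likelihood under the constant
#' training-set priors (natural log):
#' `LLR(t) = sum_c [ s log(theta/p0) + (1 - s) log((1-theta)/(1-p0)) ]`,
#' with probabilities clipped to `[1e-6, 1 - 1e-6]`. Zero means the decoder
#' does exactly as well as guessing from the priors.
#'
#' @param decoded A `decoded_matrix`.
#' @param labels Validation [label_timecourse()].
#' @param priors Named numeric vector of marginal training priors in (0,1)
#'   (e.g. `model$P0`).
#' @return A tibble with `tr` (0-based), `valid`, `llr`.
#' @export
timepoint_llr <- function(decoded, labels, priors) {
  stopifnot(inherits(decoded, "decoded_matrix"), inherits(labels, "label_timecourse"))
  cats <- intersect(decoded$categories, intersect(labels$categories, names(priors)))
  if (length(cats) == 0) stop("no common categories between decoded, labels and priors")
  stopifnot(all(priors[cats] > 0 & priors[cats] < 1))
  th <- pmin(pmax(decoded$values[, cats, drop = FALSE], 1e-6), 1 - 1e-6)
  s <- labels$values[, cats, drop = FALSE]
  p0 <- matrix(priors[cats], nrow(th), length(cats), byrow = TRUE)
  llr <- rowSums(s * log(th / p0) + (1 - s) * log((1 - th) / (1 - p0)))
  tibble::tibble(tr = seq_len(nrow(th)) - 1L, valid = decoded$valid, llr = llr)
}

#' Permutation significance of the per-timepoint likelihood ratio
#'
#' Independently permutes each category's decoded probability time course
#' across TRs, recomputes the per-TR log likelihood ratio for each shuffle,
#' and flags TRs whose observed LLR exceeds the shuffled values at
#' `alpha` (uncorrected).
#'
#' @inheritParams timepoint_llr
#' @param n Number of shuffles (default 10000).
#' @param alpha Per-TR significance level (default 0.01).
#' @param seed Integer seed.
#' @return The [timepoint_llr()] tibble with extra columns `p` and
#'   `significant`.
#' @export
llr_shuffle_null <- function(decoded, labels, priors, n = 10000, alpha = 0.01,
                             seed = 1) {
  base <- timepoint_llr(decoded, labels, priors)
  cats <- intersect(decoded$categories, intersect(labels$categories, names(priors)))
  th <- pmin(pmax(decoded$values[, cats, drop = FALSE], 1e-6), 1 - 1e-6)
  s <- labels$values[, cats, drop = FALSE]
  Tn <- nrow(th)
  # per-category contribution vectors for present / absent labels
  lp <- log(sweep(th, 2, priors[cats], "/"))
  ln <- log(sweep(1 - th, 2, 1 - priors[cats], "/"))
  set.seed(seed)
  count_ge <- numeric(Tn)
  for (i in seq_len(n)) {
    llr_i <- numeric(Tn)
    for (j in seq_along(cats)) {
      perm <- sample.int(Tn)
      llr_i <- llr_i + ifelse(s[, j] == 1L, lp[perm, j], ln[perm, j])
    }
    count_ge <- count_ge + (llr_i >= base$llr)
  }
  base$p <- count_ge / n
  base$significant <- base$p < alpha & base$valid
  base
}
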