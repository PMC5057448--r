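#' Score voxels by cross-validated encoding-model prediction
#'
#' An encoding model predicts each voxel's response as a weighted sum of the
#' binary category labels at the hemodynamic delays (the reverse direction of
#' the decoder): the response at TR `t` is regressed on labels at
#' `t - d` for each delay `d`. Per fold, a contiguous segment of the time
#' axis is held out, ridge regression is fit on the remainder (the ridge
#' penalty is chosen per voxel on an inner contiguous split of the training
#' segment), and the held-out segment is scored by the Pearson correlation
#' between predicted and observed responses. Scores are averaged over folds.
#'
#' @param labels A hierarchy-closed [label_timecourse()] aligned to `bold`.
#' @param bold A preprocessed [bold_runs()].
#' @param n_folds Number of contiguous cross-validation folds (default 50).
#' @param ridge_grid Ridge penalties to search (default `10^seq(-2, 4)`).
#' @param delays TR delays for the lagged label design (default `c(2,3,4)`).
#' @return A tibble with `voxel`, `score` (mean over folds) and a list
#'   column `fold_scores`, sorted in the input voxel order.
#' @export
fit_encoding_scores <- function(labels, bold, n_folds = 50,
                                ridge_grid = 10^seq(-2, 4), delays = c(2, 3, 4)) {
  stopifnot(inherits(labels, "label_timecourse"), inherits(bold, "bold_runs"))
  if (n_folds < 2) stop("n_folds must be at least 2")
  Y <- do.call(rbind, bold$runs)
  Tn <- nrow(Y)
  if (Tn != nrow(labels$values)) stop("labels and BOLD are misaligned in length")

  # lagged label design: X[t, (d,c)] = label[t - d, c], within-run
  X <- lagged_label_design(labels, delays)
  valid <- attr(X, "valid")
  X <- X[valid, , drop = FALSE]
  Y <- Y[valid, , drop = FALSE]
  n <- nrow(X)
  if (n < 2 * n_folds) stop("too few valid TRs (", n, ") for ", n_folds, " folds")

  fold_id <- as.integer(cut(seq_len(n), breaks = n_folds, labels = FALSE))
  nv <- ncol(Y)
  fold_scores <- matrix(NA_real_, n_folds, nv)
  warned <- FALSE
  for (f in seq_len(n_folds)) {
    test <- fold_id == f
    Xtr <- X[!test, , drop = FALSE]; Ytr <- Y[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE];  Yte <- Y[test, , drop = FALSE]
    W <- ridge_multiresponse(Xtr, Ytr, ridge_grid)
    pred <- cbind(1, Xte) %*% W
    for (v in seq_len(nv)) {
      if (stats::sd(Yte[, v]) < .Machine$double.eps^0.5 ||
          stats::sd(pred[, v]) < .Machine$double.eps^0.5) {
        fold_scores[f, v] <- 0
        if (!warned) {
          warning("constant held-out or predicted response in some fold(s); score set to 0")
          warned <- TRUE
        }
      } else {
        fold_scores[f, v] <- stats::cor(pred[, v], Yte[, v])
      }
    }
  }
  tibble::tibble(
    voxel = bold$voxel_ids,
    score = colMeans(fold_scores),
    fold_scores = lapply(seq_len(nv), function(v) fold_scores[, v])
  )
}

lagged_label_design <- function(labels, delays) {
  L <- labels$values
  Tn <- nrow(L)
  nc <- ncol(L)
  delays <- as.integer(delays)
  X <- matrix(0, Tn, nc * length(delays))
  colnames(X) <- unlist(lapply(delays, function(d) paste0(labels$categories, "-", d)))
  valid <- logical(Tn)
  off <- 0L
  for (r in seq_len(nrow(labels$runs))) {
    len <- labels$runs$length[r]
    rows <- off + seq_len(len)
    ok <- seq_len(len) > max(delays)
    for (di in seq_along(delays)) {
      d <- delays[di]
      src <- rows[which(ok)] - d
      X[rows[which(ok)], (di - 1L) * nc + seq_len(nc)] <- L[src, , drop = FALSE]
    }
    valid[rows[ok]] <- TRUE
    off <- off + len
  }
  attr(X, "valid") <- valid
  X
}

# Multi-response ridge with per-response lambda chosen on an inner contiguous
# 20% split of the training rows. Returns (p+1) x V weights incl. intercept.
ridge_multiresponse <- function(X, Y, lambda_grid) {
  n <- nrow(X)
  n_in <- max(1L, floor(0.2 * n))
  tr <- seq_len(n - n_in)
  va <- (n - n_in + 1L):n
  fit_all <- function(rows, lam) {
    Xc <- X[rows, , drop = FALSE]
    mx <- colMeans(Xc); my <- colMeans(Y[rows, , drop = FALSE])
    Xc <- sweep(Xc, 2, mx)
    Yc <- sweep(Y[rows, , drop = FALSE], 2, my)
    sv <- svd(Xc)
    keep <- sv$d > max(sv$d) * 1e-12
    U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]; d <- sv$d[keep]
    UtY <- crossprod(U, Yc)
    lapply(lam, function(l) {
      B <- V %*% (UtY * (d / (d^2 + l)))
      rbind(my - drop(crossprod(mx, B)), B)  # intercept row first
    })
  }
  Ws <- fit_all(tr, lambda_grid)
  Xva <- cbind(1, X[va, , drop = FALSE])
  err <- vapply(Ws, function(W) colMeans((Xva %*% W - Y[va, , drop = FALSE])^2),
                numeric(ncol(Y)))
  if (is.null(dim(err))) err <- matrix(err, nrow = ncol(Y))
  best <- apply(err, 1, which.min)
  Wfull <- fit_all(seq_len(n), lambda_grid[sort(unique(best))])
  lam_pos <- match(best, sort(unique(best)))
  out <- matrix(0, ncol(X) + 1L, ncol(Y))
  for (i in seq_along(Wfull)) {
    cols <- which(lam_pos == i)
    out[, cols] <- Wfull[[i]][, cols, drop = FALSE]
  }
  out
}

#' Select the top-scoring voxels
#'
#' Keeps the `k` voxels with the highest mean encoding score (ties broken by
#' voxel id so the selection is deterministic); returns all voxels with a
#' warning when `k` exceeds the voxel count.
#'
#' @param scores Tibble from [fit_encoding_scores()] (columns `voxel`, `score`).
#' @param k Number of voxels to keep (default 5000).
#' @return Character vector of selected voxel ids, best first.
#' @export
select_voxels <- function(scores, k = 5000) {
  if (nrow(scores) == 0) stop("empty score list")
  stopifnot(k >= 1)
  ord <- order(-scores$score, scores$voxel)
  if (k > nrow(scores)) {
    warning("k = ", k, " exceeds the number of voxels (", nrow(scores), "); keeping all")
    k <- nrow(scores)
  }
  scores$voxel[ord][seq_len(k)]
}
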