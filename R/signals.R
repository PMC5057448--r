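#' BOLD runs container
#'
#' One or more (time x voxel) response matrices sharing a voxel ordering.
#' Runs are kept separate so that detrending, z-scoring and lagging never
#' cross a scan boundary.
#'
#' @param runs A matrix or list of matrices (rows = TRs, columns = voxels).
#' @param tr_seconds Sampling interval in seconds.
#' @param voxel_ids Optional voxel names; defaults to `v0001`, `v0002`, ...
#' @return An object of class `bold_runs`.
#' @export
bold_runs <- function(runs, tr_seconds = 2, voxel_ids = NULL) {
  if (is.matrix(runs) || is.data.frame(runs)) runs <- list(as.matrix(runs))
  runs <- lapply(runs, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    r
  })
  nv <- unique(vapply(runs, ncol, integer(1)))
  if (length(nv) != 1) stop("all runs must share the voxel count")
  if (!all(vapply(runs, function(r) all(is.finite(r)), logical(1)))) {
    stop("non-finite values in BOLD data")
  }
  if (is.null(voxel_ids)) {
    voxel_ids <- colnames(runs[[1]])
    if (is.null(voxel_ids)) voxel_ids <- sprintf("v%04d", seq_len(nv))
  }
  stopifnot(length(voxel_ids) == nv, tr_seconds > 0)
  runs <- lapply(runs, function(r) { colnames(r) <- voxel_ids; r })
  structure(
    list(runs = runs, tr_seconds = as.numeric(tr_seconds),
         voxel_ids = as.character(voxel_ids)),
    class = "bold_runs"
  )
}

#' @export
print.bold_runs <- function(x, ...) {
  cat("<bold_runs> ", length(x$runs), " run(s) of ",
      paste(vapply(x$runs, nrow, integer(1)), collapse = "/"), " TRs x ",
      length(x$voxel_ids), " voxels, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

run_starts <- function(bold) {
  lens <- vapply(bold$runs, nrow, integer(1))
  cumsum(c(0L, lens[-length(lens)]))
}

# Window length in TRs: round(window/tr), forced odd by +1.
median_window_trs <- function(tr_seconds, window_seconds) {
  k <- round(window_seconds / tr_seconds)
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}

#' Remove slow response drift with a running-median filter
#'
#' Subtracts, per voxel, the running median computed in a window of
#' `window_seconds` (default 120 s, the standard slow-drift cutoff for
#' movie-watching BOLD data). The window length in TRs is
#' `round(window/tr)`, forced odd by adding one; series edges are handled by
#' reflection so the filter is defined everywhere.
#'
#' @param run A (time x voxel) matrix (a single scan; never concatenate runs).
#' @param tr_seconds TR in seconds.
#' @param window_seconds Filter window in seconds; must exceed `2 * tr_seconds`.
#' @return Matrix of the same shape, drift removed.
#' @export
detrend_median <- function(run, tr_seconds, window_seconds = 120) {
  run <- as.matrix(run)
  if (!all(is.finite(run))) stop("non-finite values in input")
  if (window_seconds <= 2 * tr_seconds) {
    stop("window_seconds must exceed 2 * tr_seconds")
  }
  k <- median_window_trs(tr_seconds, window_seconds)
  n <- nrow(run)
  half <- (k - 1L) %/% 2L
  pad <- min(half, n - 1L)
  idx <- c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))  # reflection
  kk <- min(k, length(idx))
  if (kk %% 2L == 0L) kk <- kk - 1L
  out <- run
  for (j in seq_len(ncol(run))) {
    med <- stats::runmed(run[idx, j], k = kk, endrule = "median")
    out[, j] <- run[, j] - med[pad + seq_len(n)]
  }
  out
}

#' Standardize each voxel to zero mean and unit variance
#'
#' Within-run z-scoring: the per-voxel mean is subtracted and the residual
#' scaled to unit variance. Constant voxels map to all-zero columns with a
#' warning, since they carry no signal.
#'
#' @param run A (time x voxel) matrix.
#' @return Matrix of the same shape.
#' @export
standardize <- function(run) {
  run <- as.matrix(run)
  if (!all(is.finite(run))) stop("non-finite values in input")
  mu <- colMeans(run)
  ctr <- sweep(run, 2, mu)
  sd <- apply(ctr, 2, stats::sd)
  const <- sd < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sum(const), " constant voxel(s) mapped to zero")
    sd[const] <- 1
    ctr[, const] <- 0
  }
  sweep(ctr, 2, sd, "/")
}

#' Average repeated presentations of the same stimulus
#'
#' Element-wise mean across repeats; with i.i.d. measurement noise of
#' standard deviation `s`, the residual noise shrinks to about `s/sqrt(n)`.
#'
#' @param repeats List of equally-shaped (time x voxel) matrices, or a list
#'   of [bold_runs()] with matching structure.
#' @return A single matrix (or `bold_runs`) of the common shape.
#' @export
average_repeats <- function(repeats) {
  if (length(repeats) == 0) stop("need at least one repeat")
  if (inherits(repeats[[1]], "bold_runs")) {
    base <- repeats[[1]]
    avg <- lapply(seq_along(base$runs), function(i) {
      average_repeats(lapply(repeats, function(b) b$runs[[i]]))
    })
    return(bold_runs(avg, tr_seconds = base$tr_seconds, voxel_ids = base$voxel_ids))
  }
  dims <- lapply(repeats, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("repeat shape mismatch")
  }
  Reduce(`+`, lapply(repeats, as.matrix)) / length(repeats)
}

#' Build the lagged feature matrix the decoder consumes
#'
#' To decode the stimulus at TR `t` the model uses voxel responses at
#' `t + d` for each delay `d` (default 2, 3 and 4 TRs, i.e. 4-8 s at
#' TR = 2 s), which lets the regression learn a filter that deconvolves the
#' slow hemodynamic response. Lags never cross run boundaries: rows whose
#' largest lag falls outside the run are masked invalid. Column layout is
#' delay-major, voxel-minor: `(d=2,v1..vV), (d=3,v1..vV), (d=4,v1..vV)`,
#' named `<voxel>+<d>`.
#'
#' @param bold A [bold_runs()] (already detrended/standardized).
#' @param delays Positive integer TR offsets, default `c(2, 3, 4)`.
#' @return An object of class `feature_matrix`: list with `values`
#'   (time x voxel*delay, invalid rows `NA`), `valid` (logical per TR),
#'   `delays`, `voxel_ids`, `runs` (tibble of start/length, 0-based).
#' @export
build_lagged_features <- function(bold, delays = c(2, 3, 4)) {
  stopifnot(inherits(bold, "bold_runs"))
  if (length(delays) == 0) stop("delays must be non-empty")
  delays <- as.integer(delays)
  if (any(delays <= 0)) stop("delays must be positive integers")
  nv <- length(bold$voxel_ids)
  lens <- vapply(bold$runs, nrow, integer(1))
  total <- sum(lens)
  p <- nv * length(delays)
  vals <- matrix(NA_real_, total, p)
  colnames(vals) <- unlist(lapply(delays, function(d) paste0(bold$voxel_ids, "+", d)))
  valid <- logical(total)
  offset <- 0L
  for (r in seq_along(bold$runs)) {
    Tn <- lens[r]
    run <- bold$runs[[r]]
    ok <- seq_len(Tn) + max(delays) <= Tn  # 0-based t valid iff t + max(d) <= Tn-1
    for (di in seq_along(delays)) {
      d <- delays[di]
      rows <- which(ok)
      vals[offset + rows, (di - 1L) * nv + seq_len(nv)] <- run[rows + d, , drop = FALSE]
    }
    valid[offset + which(ok)] <- TRUE
    offset <- offset + Tn
  }
  structure(
    list(values = vals, valid = valid, delays = delays,
         voxel_ids = bold$voxel_ids,
         runs = tibble::tibble(start = run_starts(bold), length = lens)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " TRs x ", ncol(x$values),
      " features (", length(x$voxel_ids), " voxels x delays ",
      paste(x$delays, collapse = ","), "), ", sum(x$valid), " valid rows\n", sep = "")
  invisible(x)
}

#' Subset a feature matrix to a set of voxels
#'
#' @param features A [build_lagged_features()] result.
#' @param voxel_ids Voxels to keep, in the order given.
#' @return A `feature_matrix` restricted to those voxels.
#' @export
subset_voxels <- function(features, voxel_ids) {
  stopifnot(inherits(features, "feature_matrix"))
  missing <- setdiff(voxel_ids, features$voxel_ids)
  if (length(missing) > 0) stop("unknown voxel id(s): ", paste(missing, collapse = ", "))
  cols <- unlist(lapply(features$delays, function(d) paste0(voxel_ids, "+", d)))
  structure(
    list(values = features$values[, cols, drop = FALSE], valid = features$valid,
         delays = features$delays, voxel_ids = voxel_ids, runs = features$runs),
    class = "feature_matrix"
  )
}

#' Preprocess BOLD runs: detrend then standardize, per run
#'
#' @param bold A [bold_runs()].
#' @param window_seconds Median-filter window (default 120 s); `NULL` skips
#'   detrending.
#' @return A [bold_runs()] with each run detrended and z-scored.
#' @export
preprocess_bold <- function(bold, window_seconds = 120) {
  stopifnot(inherits(bold, "bold_runs"))
  runs <- lapply(bold$runs, function(r) {
    if (!is.null(window_seconds)) r <- detrend_median(r, bold$tr_seconds, window_seconds)
    standardize(r)
  })
  bold_runs(runs, tr_seconds = bold$tr_seconds, voxel_ids = bold$voxel_ids)
}

#' Read / write BOLD data
#'
#' Plain TSV (rows = TRs, one column per voxel) is the first-class format
#' for toy and simulated data. 4D NIfTI volumes are supported when the
#' `RNifti` package is available: voxels are taken either from a supplied
#' integer index list (into the flattened x,y,z grid) or all voxels in
#' file order.
#'
#' @param path `.tsv`/`.txt` or `.nii`/`.nii.gz` file.
#' @param tr_seconds TR in seconds (TSV only; NIfTI reads it from the header
#'   when present).
#' @param voxel_index Optional 1-based indices into the flattened spatial
#'   grid (NIfTI only).
#' @return A single-run [bold_runs()].
#' @export
read_bold <- function(path, tr_seconds = 2, voxel_index = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package")
    }
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4) stop("expected a 4D NIfTI volume: ", path)
    m <- t(matrix(img, nrow = prod(d[1:3]), ncol = d[4]))
    if (!is.null(voxel_index)) m <- m[, voxel_index, drop = FALSE]
    tr <- tryCatch(RNifti::pixdim(img)[4], error = function(e) tr_seconds)
    if (!is.finite(tr) || tr <= 0) tr <- tr_seconds
    return(bold_runs(m, tr_seconds = tr))
  }
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  bold_runs(m, tr_seconds = tr_seconds, voxel_ids = colnames(m))
}

#' @rdname read_bold
#' @param bold A single-run [bold_runs()] or matrix.
#' @export
write_bold <- function(bold, path) {
  m <- if (inherits(bold, "bold_runs")) {
    if (length(bold$runs) != 1) stop("write_bold() writes one run per file")
    bold$runs[[1]]
  } else as.matrix(bold)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
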