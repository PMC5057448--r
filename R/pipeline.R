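#' Pipeline run configuration
#'
#' Validated bag of paths and settings for [run_pipeline()]. Defaults are
#' the reference analysis settings: 5000 voxels, delays 2-4 TRs, 4-TR
#' shuffle blocks, 1000 shuffles, FDR level 0.01.
#'
#' @param taxonomy,train_labels,train_bold,val_labels Paths to the taxonomy
#'   JSON, label TSVs and training BOLD table.
#' @param val_bold Character vector of validation BOLD paths (repeats are
#'   preprocessed, then averaged).
#' @param out Output directory.
#' @param k Number of voxels to keep (default 5000; capped at the voxel
#'   count with a warning).
#' @param n_folds Encoding-model cross-validation folds (default 50).
#' @param delays Feature delays in TRs (default `c(2, 3, 4)`).
#' @param method Conditional fitter: `"earlystop"`, `"l2"` or `"labelnoise"`.
#' @param window_seconds Median-filter detrend window (default 120 s);
#'   `NULL` skips detrending.
#' @param shuffles,block,q,min_occurrence Evaluation settings.
#' @param llr_shuffles Timepoint-LLR permutation count (default 10000).
#' @param tr_seconds TR in seconds used when the label sidecar is absent.
#' @param seed Master seed for every stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(taxonomy, train_labels, train_bold, val_labels, val_bold,
                       out, k = 5000, n_folds = 50, delays = c(2, 3, 4),
                       method = c("earlystop", "l2", "labelnoise"),
                       window_seconds = 120, shuffles = 1000, block = 4,
                       q = 0.01, min_occurrence = 3, llr_shuffles = 10000,
                       tr_seconds = 2, seed = 1) {
  method <- match.arg(method)
  stopifnot(k >= 1, n_folds >= 2, all(delays > 0), shuffles >= 1, block >= 1,
            q > 0, q < 1, min_occurrence >= 1, llr_shuffles >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Keys must match [run_config()] arguments exactly; unrecognized keys are
#' rejected.
#'
#' @param path JSON file.
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dots <- list(...)
  doc[names(dots)] <- dots
  known <- setdiff(names(formals(run_config)), "...")
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0) {
    stop("unrecognized config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, doc)
}

stage_stop <- function(stage, ...) stop("[", stage, "] ", ..., call. = FALSE)

#' Run the full decoding pipeline
#'
#' Executes preprocess -> voxel selection -> HLR fit -> decode -> evaluate
#' on files named in the configuration, writing into `config$out`:
#' `eval.csv` (per-category AUC/null/p/FDR + conditional AUC + edge test),
#' `llr.tsv` (per-TR log likelihood ratio and significance), `probs.tsv`
#' (decoded probabilities), `model.json` (the serialized decoder),
#' `voxels.json` (selected voxels and scores) and `manifest.json`
#' (settings + seed). Re-running with the same configuration and seed
#' reproduces every output.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results (`model`, `decoded`,
#'   `eval`, `edges`, `llr`, `voxels`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  # stage 0: validate inputs
  paths <- c(config$taxonomy, config$train_labels, config$train_bold,
             config$val_labels, config$val_bold)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stage_stop("validate", "missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  say("[load] reading taxonomy and labels")
  tax <- tryCatch(read_taxonomy(config$taxonomy),
                  error = function(e) stage_stop("load", conditionMessage(e)))
  train_labels <- propagate_labels(read_labels(config$train_labels), tax)
  val_labels <- propagate_labels(read_labels(config$val_labels), tax)

  say("[preprocess] detrending and standardizing BOLD runs")
  prep <- function(path) {
    b <- read_bold(path, tr_seconds = config$tr_seconds)
    preprocess_bold(b, window_seconds = config$window_seconds)
  }
  train_bold <- tryCatch(prep(config$train_bold),
                         error = function(e) stage_stop("preprocess", conditionMessage(e)))
  val_reps <- lapply(config$val_bold, prep)
  val_bold <- average_repeats(val_reps)

  say("[select-voxels] scoring ", length(train_bold$voxel_ids),
      " voxels over ", config$n_folds, " folds")
  scores <- tryCatch(
    fit_encoding_scores(train_labels, train_bold, n_folds = config$n_folds,
                        delays = config$delays),
    error = function(e) stage_stop("select-voxels", conditionMessage(e)))
  voxels <- select_voxels(scores, k = config$k)
  jsonlite::write_json(
    list(voxels = voxels,
         scores = scores[match(voxels, scores$voxel), c("voxel", "score")]),
    file.path(config$out, "voxels.json"), auto_unbox = TRUE, digits = NA)

  say("[fit] fitting conditional models (", config$method, ")")
  train_feat <- subset_voxels(build_lagged_features(train_bold, config$delays), voxels)
  model <- tryCatch(
    fit_hlr(train_labels, train_feat, tax, method = config$method,
            seed = config$seed),
    error = function(e) stage_stop("fit", conditionMessage(e)))
  write_hlr(model, file.path(config$out, "model.json"))

  say("[decode] decoding validation data")
  val_feat <- subset_voxels(build_lagged_features(val_bold, config$delays), voxels)
  decoded <- decode(model, val_feat)
  write_decoded(decoded, file.path(config$out, "probs.tsv"))

  say("[evaluate] ROC/AUC, edge consistency, timepoint LLR")
  ev <- tryCatch(
    evaluate_categories(decoded, val_labels, min_occurrence = config$min_occurrence,
                        shuffles = config$shuffles, block = config$block,
                        q = config$q, seed = config$seed),
    error = function(e) stage_stop("evaluate", conditionMessage(e)))
  cauc <- purrr::map_dfr(ev$category, function(cat) {
    ca <- conditional_auc(decoded, val_labels, tax, cat)
    tibble::tibble(category = cat, cauc = ca$cauc, cauc_defined = ca$defined)
  })
  ev <- dplyr::left_join(ev, cauc, by = "category")
  edges <- edge_inconsistency_test(decoded, val_labels, tax,
                                   n_boot = config$shuffles, block = config$block,
                                   q = config$q, seed = config$seed)
  edge_cols <- dplyr::select(edges, category = "child", edge_parent = "parent",
                             edge_p = "p", edge_reject = "q_reject")
  ev <- dplyr::left_join(ev, edge_cols, by = "category",
                         relationship = "one-to-many")
  utils::write.csv(ev, file.path(config$out, "eval.csv"), row.names = FALSE)

  llr <- llr_shuffle_null(decoded, val_labels, model$P0, n = config$llr_shuffles,
                          seed = config$seed)
  utils::write.table(llr, file.path(config$out, "llr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- unclass(config)
  manifest$elapsed_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[done] outputs in ", config$out)
  invisible(list(model = model, decoded = decoded, eval = ev, edges = edges,
                 llr = llr, voxels = voxels))
}

#' Summarize pipeline outputs
#'
#' Prints the per-category AUC table sorted by AUC, the list of taxonomy
#' edges flagged as inconsistent, and the fraction of significantly decoded
#' time points.
#'
#' @param out Pipeline output directory (containing `eval.csv` and
#'   `llr.tsv`).
#' @return Invisibly, the evaluation tibble.
#' @export
report <- function(out) {
  eval_path <- file.path(out, "eval.csv")
  if (!file.exists(eval_path)) stop("no eval.csv in ", out)
  ev <- tibble::as_tibble(utils::read.csv(eval_path))
  needed <- c("category", "n_pos", "auc", "p", "q_reject")
  if (!all(needed %in% names(ev))) {
    stop("malformed eval.csv: expected columns ", paste(needed, collapse = ", "))
  }
  ev <- dplyr::arrange(ev, dplyr::desc(.data$auc))
  cat("Per-category decoding performance (best first):\n")
  print(as.data.frame(ev[, intersect(c("category", "n_pos", "auc", "p",
                                       "q_reject", "cauc"), names(ev))]),
        row.names = FALSE, digits = 3)
  sig <- ev$category[ev$q_reject %in% TRUE]
  if (length(sig) == 0) {
    cat("\nno categories significant at the configured FDR level\n")
  } else {
    cat("\n", length(sig), " categories significant: ",
        paste(sig, collapse = ", "), "\n", sep = "")
  }
  if ("edge_reject" %in% names(ev) && any(ev$edge_reject %in% TRUE)) {
    bad <- ev[ev$edge_reject %in% TRUE, ]
    cat("taxonomy edges inconsistent with responses:\n")
    for (i in seq_len(nrow(bad))) {
      cat("  ", bad$edge_parent[i], "->", bad$category[i], "\n")
    }
  } else {
    cat("no taxonomy edges flagged as inconsistent\n")
  }
  llr_path <- file.path(out, "llr.tsv")
  if (file.exists(llr_path)) {
    llr <- utils::read.delim(llr_path)
    cat(sprintf("fraction of significantly decoded time points: %.3f\n",
                mean(llr$significant %in% c(TRUE, "TRUE"))))
  }
  invisible(ev)
}
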