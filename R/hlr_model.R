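#' Fit the full hierarchical logistic regression decoder
#'
#' Fits one conditional logistic model per taxonomy category, each trained
#' only on the TRs where all of the category's hypernyms are present, then
#' assembles them into a single decoder whose marginal category
#' probabilities are products of conditionals along the ancestor closure.
#' Categories with too few conditioned TRs (or too few positives) get a
#' degenerate prior model. A trailing held-out segment of the estimation
#' data (about one minute) is excluded from all conditional fits and used to
#' set each category's prior-smoothing `eta`.
#'
#' @param labels A hierarchy-closed [label_timecourse()] for the estimation
#'   data (run [propagate_labels()] first).
#' @param features A [build_lagged_features()] result aligned to `labels`.
#' @param tax A [taxonomy()] covering all label columns.
#' @param method `"earlystop"` (gradient descent with early stopping,
#'   default), `"l2"` (penalized likelihood) or `"labelnoise"`.
#' @param seed Integer seed driving every split.
#' @param eta_holdout_trs TRs held out from the end of the estimation set
#'   for smoothing estimation (default 30, one minute at TR = 2 s).
#' @param min_samples,min_pos Thresholds below which a category gets a
#'   degenerate prior model (defaults 10 conditioned TRs, 3 positives).
#' @param ... Passed to the per-category fitter
#'   ([fit_conditional_earlystop()], [fit_conditional_l2()] or
#'   [fit_label_noise()]).
#' @return An object of class `hlr_model`.
#' @export
fit_hlr <- function(labels, features, tax, method = c("earlystop", "l2", "labelnoise"),
                    seed = 1, eta_holdout_trs = 30, min_samples = 10, min_pos = 3,
                    ...) {
  method <- match.arg(method)
  stopifnot(inherits(labels, "label_timecourse"), inherits(tax, "taxonomy"),
            inherits(features, "feature_matrix"))
  if (nrow(labels$values) != nrow(features$values)) {
    stop("labels (", nrow(labels$values), " TRs) and features (",
         nrow(features$values), " TRs) are misaligned")
  }
  missing <- setdiff(tax$nodes$id, labels$categories)
  if (length(missing) > 0) {
    stop("labels lack taxonomy column(s): ", paste(missing, collapse = ", "))
  }
  viol <- validate_closure(labels, tax)
  if (nrow(viol) > 0) {
    stop("labels are not hierarchy-closed (", nrow(viol),
         " violations); run propagate_labels() first")
  }
  Tn <- nrow(labels$values)
  holdout <- seq_len(Tn) > Tn - min(eta_holdout_trs, floor(Tn / 3))
  P0 <- vapply(tax$order, function(cat) {
    laplace_rate(sum(labels$values[, cat]), Tn)
  }, numeric(1))

  models <- list()
  for (cat in tax$order) {
    cmask <- conditioning_mask(labels, tax, cat)
    y <- labels$values[, cat]
    fit_mask <- cmask & !holdout
    m <- switch(method,
      earlystop = fit_conditional_earlystop(features, y, fit_mask,
        seed = seed + match(cat, tax$order), min_samples = min_samples,
        min_pos = min_pos, ...),
      l2 = fit_conditional_l2(features, y, fit_mask,
        seed = seed + match(cat, tax$order), min_samples = min_samples,
        min_pos = min_pos, ...),
      labelnoise = fit_label_noise(features, y, fit_mask,
        min_samples = min_samples, min_pos = min_pos, ...)$model
    )
    m$category <- cat
    names(m$weights) <- colnames(features$values)
    if (!m$degenerate) {
      m <- suppressWarnings(
        fit_smoothing_eta(m, features, y, mask = cmask & holdout)
      )
    }
    models[[cat]] <- m
  }
  structure(
    list(taxonomy = tax, voxel_ids = features$voxel_ids, delays = features$delays,
         models = models, P0 = P0, method = method, seed = seed),
    class = "hlr_model"
  )
}

#' @export
print.hlr_model <- function(x, ...) {
  ndeg <- sum(vapply(x$models, `[[`, logical(1), "degenerate"))
  cat("<hlr_model> ", length(x$models), " conditional models (", ndeg,
      " degenerate), ", length(x$voxel_ids), " voxels x delays ",
      paste(x$delays, collapse = ","), ", method = ", x$method, "\n", sep = "")
  invisible(x)
}

#' Decode category probabilities from voxel responses
#'
#' For every TR and category, the marginal probability that the category is
#' present is the product of the smoothed conditional probabilities of every
#' node in its ancestor closure (hypernyms and itself), computed
#' independently per TR. This enforces the hierarchy constraint: a
#' category's probability can never exceed any of its hypernyms'.
#'
#' @param model An [fit_hlr()] decoder.
#' @param features A `feature_matrix` with the model's voxels and delays.
#' @return An object of class `decoded_matrix`: list with `values`
#'   (time x category probabilities), `categories`, `valid`.
#' @export
decode <- function(model, features) {
  stopifnot(inherits(model, "hlr_model"), inherits(features, "feature_matrix"))
  cats <- model$taxonomy$order
  cond <- vapply(cats, function(cat) {
    predict_conditional(model$models[[cat]], features)
  }, numeric(nrow(features$values)))
  cond <- matrix(cond, nrow = nrow(features$values),
                 dimnames = list(NULL, cats))
  theta <- cond
  for (cat in cats) {
    closure <- ancestor_closure(model$taxonomy, cat)
    if (length(closure) > 1) {
      theta[, cat] <- apply(cond[, closure, drop = FALSE], 1, prod)
    }
  }
  structure(
    list(values = theta, categories = cats, valid = features$valid),
    class = "decoded_matrix"
  )
}

#' @export
print.decoded_matrix <- function(x, ...) {
  cat("<decoded_matrix> ", nrow(x$values), " TRs x ", ncol(x$values),
      " categories, ", sum(x$valid), " valid TRs\n", sep = "")
  invisible(x)
}

#' Read / write decoded probabilities as TSV
#'
#' Columns: `tr` (0-based), `valid` (0/1), then one probability column per
#' category.
#'
#' @param decoded A `decoded_matrix`.
#' @param path TSV path.
#' @export
write_decoded <- function(decoded, path) {
  stopifnot(inherits(decoded, "decoded_matrix"))
  df <- data.frame(tr = seq_len(nrow(decoded$values)) - 1L,
                   valid = as.integer(decoded$valid),
                   decoded$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decoded
#' @export
read_decoded <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("tr", "valid") %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), c("tr", "valid")), drop = FALSE])
  structure(
    list(values = m, categories = colnames(m), valid = df$valid == 1L),
    class = "decoded_matrix"
  )
}

#' Serialize / restore a fitted decoder as JSON
#'
#' The manifest holds the taxonomy, voxel ids, delays, and per-category
#' weights, bias, conditional prior, smoothing and flip matrix at full
#' numeric precision, so a round-trip reproduces decoded probabilities to
#' machine accuracy.
#'
#' @param model An `hlr_model`.
#' @param path JSON file path.
#' @export
write_hlr <- function(model, path) {
  stopifnot(inherits(model, "hlr_model"))
  doc <- list(
    taxonomy = list(
      nodes = model$taxonomy$nodes,
      edges = unname(apply(as.matrix(model$taxonomy$edges), 1, as.list))
    ),
    voxel_ids = model$voxel_ids,
    delays = model$delays,
    method = model$method,
    seed = model$seed,
    P0 = as.list(model$P0),
    models = lapply(model$models, function(m) {
      list(category = m$category, weights = unname(m$weights), bias = m$bias,
           p0 = m$p0, eta = m$eta, n_cond = m$n_cond, n_pos = m$n_pos,
           degenerate = m$degenerate,
           flip = if (is.null(m$flip)) NULL else as.vector(m$flip))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hlr
#' @export
read_hlr <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tax <- taxonomy(as.data.frame(doc$taxonomy$nodes),
                  if (is.list(doc$taxonomy$edges) && !is.data.frame(doc$taxonomy$edges))
                    do.call(rbind, doc$taxonomy$edges) else doc$taxonomy$edges)
  feat_names <- unlist(lapply(doc$delays, function(d) paste0(doc$voxel_ids, "+", d)))
  models <- lapply(doc$models, function(m) {
    w <- as.numeric(m$weights)
    names(w) <- feat_names
    new_conditional_model(m$category, w, m$bias, m$p0, eta = m$eta,
                          n_cond = m$n_cond, n_pos = m$n_pos,
                          degenerate = m$degenerate,
                          flip = if (is.null(m$flip)) NULL else matrix(unlist(m$flip), 2))
  })
  names(models) <- vapply(models, `[[`, character(1), "category")
  structure(
    list(taxonomy = tax, voxel_ids = as.character(doc$voxel_ids),
         delays = as.integer(doc$delays), models = models,
         P0 = unlist(doc$P0), method = doc$method, seed = doc$seed),
    class = "hlr_model"
  )
}

#' Tidy a fitted HLR decoder
#'
#' @param x An `hlr_model`.
#' @param ... Unused.
#' @method tidy hlr_model
#' @return One row per category: conditional sample size, positives,
#'   conditional prior, smoothing, bias, weight norm and degeneracy flag.
#' @export
tidy.hlr_model <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      category = m$category,
      n_cond = m$n_cond,
      n_pos = m$n_pos,
      p0 = m$p0,
      marginal_prior = unname(x$P0[m$category]),
      eta = m$eta,
      bias = m$bias,
      weight_norm = sqrt(sum(m$weights^2)),
      degenerate = m$degenerate
    )
  })
}

#' @rdname tidy.hlr_model
#' @method glance hlr_model
#' @export
glance.hlr_model <- function(x, ...) {
  tibble::tibble(
    n_categories = length(x$models),
    n_degenerate = sum(vapply(x$models, `[[`, logical(1), "degenerate")),
    n_voxels = length(x$voxel_ids),
    n_features = length(x$voxel_ids) * length(x$delays),
    method = x$method
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
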