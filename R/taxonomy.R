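#' Construct a category taxonomy
#'
#' A taxonomy is a directed acyclic graph of hypernym (parent) to hyponym
#' (child) relations between category ids, in the style of the WordNet noun
#' and verb hierarchies (ids such as `"vehicle.n.01"`). Every non-root node
#' must have at least one parent; the semantics of "hypernyms present" for a
#' multi-parent node is the conjunction of *all* its parents.
#'
#' @param nodes Character vector of unique node ids, or a data frame with
#'   columns `id` and `pos` (`"noun"` or `"verb"`).
#' @param edges Two-column matrix or data frame of (parent, child) id pairs.
#'   May have zero rows for a single-node taxonomy.
#' @param pos Optional character vector of part-of-speech tags, recycled to
#'   the number of nodes; ignored when `nodes` is a data frame.
#'
#' @return An object of class `taxonomy`: a list with `nodes` (tibble of
#'   `id`, `pos`), `edges` (tibble of `parent`, `child`), `roots`, and
#'   `order` (a deterministic topological order, parents before children,
#'   Kahn's algorithm with lexicographic tie-breaking).
#' @export
#' @examples
#' tax <- taxonomy(c("organism", "plant", "animal"),
#'                 rbind(c("organism", "plant"), c("organism", "animal")))
#' tax$roots
taxonomy <- function(nodes, edges, pos = "noun") {
  if (is.data.frame(nodes)) {
    ids <- as.character(nodes$id)
    pos <- if ("pos" %in% names(nodes)) as.character(nodes$pos) else rep("noun", length(ids))
  } else {
    ids <- as.character(nodes)
    pos <- rep_len(as.character(pos), length(ids))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate node id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(pos %in% c("noun", "verb"))) {
    stop("pos tags must be 'noun' or 'verb'")
  }
  edges <- as_edge_tbl(edges)
  unknown <- setdiff(c(edges$parent, edges$child), ids)
  if (length(unknown) > 0) {
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(paste(edges$parent, edges$child, sep = "\r"))) {
    edges <- dplyr::distinct(edges)
  }
  ord <- kahn_order(ids, edges)  # errors on cycles
  roots <- sort(setdiff(ids, edges$child))
  if (length(roots) == 0 && length(ids) > 0) stop("taxonomy has no root node")
  structure(
    list(
      nodes = tibble::tibble(id = ids, pos = pos),
      edges = edges,
      roots = roots,
      order = ord
    ),
    class = "taxonomy"
  )
}

as_edge_tbl <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      (is.matrix(edges) && nrow(edges) == 0) || length(edges) == 0) {
    return(tibble::tibble(parent = character(), child = character()))
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    stop("edges must be a two-column matrix or data frame of (parent, child)")
  }
  tibble::tibble(parent = as.character(edges[[1]]), child = as.character(edges[[2]]))
}

# Kahn's algorithm; lexicographic tie-breaking so the order is reproducible.
kahn_order <- function(ids, edges) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  children <- split(edges$child, edges$parent)
  frontier <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(frontier) > 0) {
    nxt <- frontier[1]
    frontier <- frontier[-1]
    out <- c(out, nxt)
    for (ch in children[[nxt]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) frontier <- sort(c(frontier, ch))
    }
  }
  if (length(out) != length(ids)) {
    stop("cycle detected in taxonomy involving node(s): ",
         paste(setdiff(ids, out), collapse = ", "))
  }
  out
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " categories, ", nrow(x$edges), " edges, ",
      length(x$roots), " root(s)\n", sep = "")
  cat("roots:", paste(utils::head(x$roots, 5), collapse = ", "),
      if (length(x$roots) > 5) "..." else "", "\n")
  invisible(x)
}

#' Read / write a taxonomy as JSON
#'
#' The on-disk format is a JSON document with a `"nodes"` array of
#' `{id, pos}` objects and an `"edges"` array of `[parent, child]` pairs.
#' Toy hierarchies are first-class: no WordNet installation is consulted.
#'
#' @param path Path to a JSON file.
#' @return `read_taxonomy()` returns a validated [taxonomy()];
#'   `write_taxonomy()` returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$nodes)) stop("taxonomy JSON lacks a 'nodes' array: ", path)
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  edges <- doc$edges
  if (is.list(edges) && !is.data.frame(edges)) edges <- do.call(rbind, edges)
  taxonomy(nodes, edges)
}

#' @rdname read_taxonomy
#' @param tax A [taxonomy()].
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  doc <- list(
    nodes = tax$nodes,
    edges = unname(apply(as.matrix(tax$edges), 1, as.list))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

parents_of <- function(tax, cat) tax$edges$parent[tax$edges$child == cat]

#' Ancestor closure of a category
#'
#' Returns the category together with all of its ancestors (hypernyms,
#' transitively), ordered topologically with parents before children. This
#' is the set over which the HLR factorizes the marginal probability of the
#' category: for the chain motor vehicle -> car -> station wagon the closure
#' of station wagon is all three categories.
#'
#' @param tax A [taxonomy()].
#' @param cat A category id present in `tax`.
#' @return Character vector of ids in deterministic topological order.
#' @export
ancestor_closure <- function(tax, cat) {
  stopifnot(inherits(tax, "taxonomy"))
  if (!cat %in% tax$nodes$id) stop("unknown category id: ", cat)
  seen <- cat
  frontier <- cat
  while (length(frontier) > 0) {
    ps <- unique(tax$edges$parent[tax$edges$child %in% frontier])
    frontier <- setdiff(ps, seen)
    seen <- union(seen, frontier)
  }
  tax$order[tax$order %in% seen]
}

#' Label time courses aligned to TRs
#'
#' A binary time x category matrix at the fMRI sampling rate (one row per
#' TR), with run boundaries so that no operation mixes runs. After
#' [propagate_labels()] the matrix is hierarchy-closed: whenever a category
#' is present all of its hypernyms are present too.
#'
#' @param values Binary matrix (rows = TRs, columns = categories) with
#'   column names, or a data frame.
#' @param runs Data frame / tibble with columns `start` (0-based TR) and
#'   `length`; defaults to a single run spanning the matrix.
#' @param tr_seconds Sampling interval in seconds (default 2).
#' @return An object of class `label_timecourse` with fields `values`
#'   (integer matrix), `categories`, `runs`, `tr_seconds`.
#' @export
label_timecourse <- function(values, runs = NULL, tr_seconds = 2) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("label matrix must have category column names")
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stop("label entries must be 0/1")
  if (is.null(runs)) runs <- data.frame(start = 0L, length = nrow(values))
  runs <- tibble::tibble(start = as.integer(runs$start), length = as.integer(runs$length))
  if (sum(runs$length) != nrow(values)) {
    stop("run lengths (", sum(runs$length), ") do not sum to the number of TRs (",
         nrow(values), ")")
  }
  stopifnot(tr_seconds > 0)
  structure(
    list(values = values, categories = colnames(values), runs = runs,
         tr_seconds = as.numeric(tr_seconds)),
    class = "label_timecourse"
  )
}

#' @export
print.label_timecourse <- function(x, ...) {
  cat("<label_timecourse> ", nrow(x$values), " TRs x ", ncol(x$values),
      " categories, ", nrow(x$runs), " run(s), TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Propagate hypernym entailment onto a label matrix
#'
#' Sets every ancestor of a present category to present at the same TR, and
#' adds all-zero columns for taxonomy categories absent from the input so the
#' output covers every node reachable upward. Idempotent and monotone (never
#' clears a 1).
#'
#' @param labels A [label_timecourse()] whose columns are all in `tax`.
#' @param tax A [taxonomy()].
#' @return A hierarchy-closed [label_timecourse()] with columns ordered as in
#'   `tax$order` (restricted to the closure of the input columns).
#' @export
propagate_labels <- function(labels, tax) {
  stopifnot(inherits(labels, "label_timecourse"), inherits(tax, "taxonomy"))
  missing_cols <- setdiff(labels$categories, tax$nodes$id)
  if (length(missing_cols) > 0) {
    stop("label column(s) not in taxonomy: ", paste(missing_cols, collapse = ", "))
  }
  keep <- unique(unlist(lapply(labels$categories, ancestor_closure, tax = tax)))
  cols <- tax$order[tax$order %in% keep]
  m <- matrix(0L, nrow(labels$values), length(cols), dimnames = list(NULL, cols))
  m[, labels$categories] <- labels$values
  # reverse topological order: each child ORs itself into its parents
  for (cat in rev(cols)) {
    for (p in intersect(parents_of(tax, cat), cols)) {
      m[, p] <- pmax(m[, p], m[, cat])
    }
  }
  label_timecourse(m, runs = labels$runs, tr_seconds = labels$tr_seconds)
}

#' List hypernym-entailment violations in a label matrix
#'
#' @param labels A [label_timecourse()].
#' @param tax A [taxonomy()].
#' @return A tibble with one row per violation: `tr` (0-based), `parent`,
#'   `child`, at every time point where the child is present but a parent is
#'   not. Zero rows iff the matrix is hierarchy-closed.
#' @export
validate_closure <- function(labels, tax) {
  stopifnot(inherits(labels, "label_timecourse"), inherits(tax, "taxonomy"))
  e <- dplyr::filter(tax$edges, .data$parent %in% labels$categories,
                     .data$child %in% labels$categories)
  out <- purrr::pmap_dfr(e, function(parent, child) {
    bad <- which(labels$values[, child] == 1L & labels$values[, parent] == 0L)
    tibble::tibble(tr = bad - 1L, parent = parent, child = child)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(tr = integer(), parent = character(), child = character())
  }
  dplyr::arrange(out, .data$tr, .data$parent, .data$child)
}

#' Read / write TR-aligned labels as TSV (+ JSON sidecar)
#'
#' The TSV has a first column `tr` (0-based integer) and one 0/1 column per
#' category; run boundaries and the TR duration live in a JSON sidecar
#' `{"runs":[{"start":..,"length":..}], "tr_seconds":..}` at `<path>.json`
#' (or a path given explicitly).
#'
#' @param path TSV file path.
#' @param sidecar Path to the JSON sidecar; default `paste0(path, ".json")`.
#'   When missing on read, a single run is assumed with TR = 2 s.
#' @return `read_labels()` returns a [label_timecourse()].
#' @export
read_labels <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "tr") stop("labels TSV must start with a 'tr' column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  runs <- NULL; tr_seconds <- 2
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    runs <- meta$runs
    if (!is.null(meta$tr_seconds)) tr_seconds <- meta$tr_seconds
  }
  label_timecourse(m, runs = runs, tr_seconds = tr_seconds)
}

#' @rdname read_labels
#' @param labels A [label_timecourse()].
#' @export
write_labels <- function(labels, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(labels, "label_timecourse"))
  df <- data.frame(tr = seq_len(nrow(labels$values)) - 1L, labels$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(runs = labels$runs, tr_seconds = labels$tr_seconds),
    sidecar, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
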