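#' Read disease-miRNA association pairs from a TSV file
#'
#' Reads a two-column tab-separated file of known disease-miRNA associations,
#' one pair per line, columns `disease_id` and `mirna_id`.
#'
#' @param path Path to the TSV file.
#' @param header Logical; does the file carry a header line? Header presence
#'   is an explicit flag, never guessed from the content.
#' @return A tibble with character columns `disease_id` and `mirna_id`.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("d1\tm1", "d2\tm2"), tf)
#' read_association_pairs(tf)
read_association_pairs <- function(path, header = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed association line %d (expected 2 tab-separated fields): %s",
      bad[1] + as.integer(header), lines[bad[1]]
    ), call. = FALSE)
  }
  tibble::tibble(
    disease_id = vapply(fields, `[`, character(1), 1L),
    mirna_id = vapply(fields, `[`, character(1), 2L)
  )
}

#' Build a binary association matrix from a pair table
#'
#' Converts a table of (disease, miRNA) pairs into a dense binary matrix with
#' diseases as rows and miRNAs as columns. Row/column order is the order of
#' first appearance in the table unless explicit label universes are supplied,
#' in which case those orders are used and every pair must fall inside them.
#' Duplicate pairs collapse to a single 1.
#'
#' @param pairs Data frame with columns `disease_id` and `mirna_id`.
#' @param diseases,mirnas Optional character vectors fixing the label universe
#'   and ordering of the rows/columns.
#' @return A numeric matrix in \{0,1\} with `dimnames` set to the labels.
#' @export
association_matrix <- function(pairs, diseases = NULL, mirnas = NULL) {
  stopifnot(is.data.frame(pairs))
  d <- as.character(pairs$disease_id)
  m <- as.character(pairs$mirna_id)
  if (any(!nzchar(d)) || any(!nzchar(m))) {
    stop("association pairs contain empty labels", call. = FALSE)
  }
  if (is.null(diseases)) diseases <- unique(d)
  if (is.null(mirnas)) mirnas <- unique(m)
  check_universe <- function(x, universe, what) {
    out <- setdiff(x, universe)
    if (length(out) > 0) {
      stop(sprintf(
        "%s label(s) outside the supplied universe: %s",
        what, paste(utils::head(out, 5), collapse = ", ")
      ), call. = FALSE)
    }
  }
  check_universe(d, diseases, "disease")
  check_universe(m, mirnas, "miRNA")
  A <- matrix(0, length(diseases), length(mirnas),
    dimnames = list(diseases, mirnas)
  )
  A[cbind(match(d, diseases), match(m, mirnas))] <- 1
  A
}

#' Read disease ontology DAGs from a child-parent edge list
#'
#' Reads a two-column TSV of `child_id` / `parent_id` edges describing the
#' ancestry graph of disease terms, and returns, for every term appearing
#' anywhere in the file, its DAG: the ancestor closure (the term itself plus
#' all terms reachable through parent edges) and the child-to-parent edges
#' induced within that closure.
#'
#' @param path Path to the edge-list TSV (no header).
#' @return A named list; each element is a `disease_dag` list with fields
#'   `term_id`, `ancestors` (character, includes the term itself) and `edges`
#'   (two-column character matrix, child then parent).
#' @export
read_dag_edges <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("malformed DAG edge line %d: %s", bad[1], lines[bad[1]]),
      call. = FALSE
    )
  }
  edges <- data.frame(
    child = vapply(fields, `[`, character(1), 1L),
    parent = vapply(fields, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  dags_from_edges(edges)
}

#' Build per-term DAGs from an in-memory edge table
#'
#' @param edges Data frame with character columns `child` and `parent`
#'   (child-to-parent ancestry edges).
#' @param terms Optional character vector of terms to return DAGs for;
#'   defaults to every term appearing in `edges`.
#' @return Named list of `disease_dag` objects (see [read_dag_edges()]).
#' @export
dags_from_edges <- function(edges, terms = NULL) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  vocab <- unique(c(child, parent))
  parents_of <- split(parent, factor(child, levels = vocab))
  # cycle detection: iterative DFS coloring over the parent relation
  color <- stats::setNames(rep(0L, length(vocab)), vocab) # 0 new, 1 open, 2 done
  for (v in vocab) {
    if (color[[v]] != 0L) next
    dfs <- function(node, path) {
      if (color[[node]] == 1L) {
        cyc <- c(path[which(path == node)[1]:length(path)], node)
        stop(sprintf("cycle detected in DAG edges: %s",
          paste(cyc, collapse = " -> ")
        ), call. = FALSE)
      }
      if (color[[node]] == 2L) return(invisible(NULL))
      color[[node]] <<- 1L
      for (p in parents_of[[node]]) dfs(p, c(path, node))
      color[[node]] <<- 2L
      invisible(NULL)
    }
    dfs(v, character(0))
  }
  if (is.null(terms)) terms <- vocab
  ancestors_of <- function(term) {
    seen <- character(0)
    frontier <- term
    while (length(frontier) > 0) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents_of[intersect(frontier, vocab)],
        use.names = FALSE
      )), seen)
    }
    seen
  }
  out <- lapply(terms, function(term) {
    anc <- ancestors_of(term)
    keep <- child %in% anc & parent %in% anc
    new_disease_dag(term, anc, cbind(child = child[keep], parent = parent[keep]))
  })
  stats::setNames(out, terms)
}

#' @rdname dags_from_edges
#' @param term_id Term label.
#' @param ancestors Character vector of ancestor labels (must include
#'   `term_id`).
#' @param edge_matrix Two-column character matrix of child-parent edges within
#'   the closure.
#' @export
new_disease_dag <- function(term_id, ancestors, edge_matrix) {
  stopifnot(term_id %in% ancestors)
  if (length(edge_matrix) > 0) {
    stopifnot(all(edge_matrix %in% ancestors))
  }
  structure(
    list(term_id = term_id, ancestors = ancestors, edges = edge_matrix),
    class = "disease_dag"
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf(
    "<disease_dag> term %s: %d ancestor term(s), %d edge(s)\n",
    x$term_id, length(x$ancestors), NROW(x$edges)
  ))
  invisible(x)
}

#' Write / read a labeled numeric matrix as TSV
#'
#' The on-disk dialect is a tab-separated table whose first row holds the
#' column labels and whose first column holds the row labels. Values are
#' serialized with 17 significant digits so a write-then-read round trip
#' reproduces labels exactly and values to within 1e-12 (in practice,
#' bit-exactly).
#'
#' @param m Labeled numeric matrix.
#' @param path Output/input path.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(row) {
    paste(format(row, digits = 17, scientific = FALSE, trim = TRUE),
      collapse = "\t"
    )
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop("empty matrix file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cols <- fields[[1]][-1]
  widths <- vapply(fields[-1], length, integer(1))
  if (length(widths) > 0 && any(widths != length(cols) + 1L)) {
    stop(sprintf(
      "ragged matrix row %d: expected %d fields, got %d",
      which(widths != length(cols) + 1L)[1] + 1L, length(cols) + 1L,
      widths[widths != length(cols) + 1L][1]
    ), call. = FALSE)
  }
  rows <- vapply(fields[-1], `[`, character(1), 1L)
  vals <- suppressWarnings(
    lapply(fields[-1], function(f) as.numeric(f[-1]))
  )
  for (i in seq_along(vals)) {
    j <- which(is.na(vals[[i]]))
    if (length(j) > 0) {
      stop(sprintf(
        "non-numeric matrix cell at row '%s', column '%s'",
        rows[i], cols[j[1]]
      ), call. = FALSE)
    }
  }
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(0), 0, length(cols))
  dimnames(m) <- list(rows, cols)
  m
}

#' Rank the predicted miRNAs for one disease
#'
#' Sorts all candidate miRNAs for a given disease by prediction score in
#' descending order (ties broken by miRNA label, ascending) and returns the
#' top of the list together with a flag marking the pairs that were already
#' known at training time.
#'
#' @param scores An `mda_scores` object (see [predict_mda()]) or a labeled
#'   numeric score matrix; in the latter case `known_mask` must be given.
#' @param disease Disease label to rank candidates for.
#' @param top_n Number of rows to return (default all miRNAs).
#' @param known_mask Binary matrix of training positives, same shape as the
#'   scores; ignored when `scores` is an `mda_scores` object.
#' @return A tibble with columns `rank`, `mirna_id`, `score`, `known_flag`.
#' @export
rank_predictions <- function(scores, disease, top_n = NULL, known_mask = NULL) {
  if (inherits(scores, "mda_scores")) {
    known_mask <- scores$known_mask
    scores <- scores$scores
  }
  stopifnot(is.matrix(scores))
  if (is.null(known_mask)) {
    known_mask <- matrix(0, nrow(scores), ncol(scores),
      dimnames = dimnames(scores)
    )
  }
  if (!disease %in% rownames(scores)) {
    stop(sprintf("unknown disease label '%s'", disease), call. = FALSE)
  }
  if (is.null(top_n)) top_n <- ncol(scores)
  stopifnot(top_n >= 1)
  s <- scores[disease, ]
  k <- known_mask[disease, ]
  ord <- order(-s, colnames(scores))
  n <- min(top_n, length(s))
  tibble::tibble(
    rank = seq_len(n),
    mirna_id = colnames(scores)[ord][seq_len(n)],
    score = unname(s[ord][seq_len(n)]),
    known_flag = as.integer(k[ord][seq_len(n)])
  )
}

#' Write ranked predictions for one disease to a TSV file
#'
#' @inheritParams rank_predictions
#' @param path Output path; columns `rank`, `mirna_id`, `score`, `known_flag`.
#' @return The ranked tibble, invisibly.
#' @export
write_ranked_predictions <- function(scores, path, disease, top_n = NULL,
                                     known_mask = NULL) {
  tab <- rank_predictions(scores, disease, top_n, known_mask)
  readr::write_tsv(tab, path)
  invisible(tab)
}
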