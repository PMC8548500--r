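#' K nearest known neighbors of each entity
#'
#' For every disease (or miRNA), returns the K most similar *other* entities
#' that have at least one known association in the training matrix ("known"
#' entities), sorted by similarity descending with ties broken by label
#' ascending. Fewer than K are returned when fewer known entities exist.
#'
#' @param sim Similarity matrix whose labels match the association matrix's
#'   rows (`space = "disease"`) or columns (`space = "mirna"`).
#' @param A Association matrix defining which entities are known.
#' @param space `"disease"` or `"mirna"`.
#' @param k Number of neighbors.
#' @return Named list; per entity a tibble with columns `neighbor` and
#'   `similarity` (possibly zero rows).
#' @export
knn_known <- function(sim, A, space = c("disease", "mirna"), k) {
  space <- match.arg(space)
  stopifnot(k >= 1)
  labels <- if (space == "disease") rownames(A) else colnames(A)
  if (!identical(rownames(sim), labels)) {
    stop("similarity labels do not match the association matrix", call. = FALSE)
  }
  known <- if (space == "disease") rowSums(A) > 0 else colSums(A) > 0
  out <- lapply(labels, function(ent) {
    cand <- labels[known & labels != ent]
    s <- sim[ent, cand]
    ord <- order(-s, cand)
    take <- utils::head(ord, k)
    tibble::tibble(neighbor = cand[take], similarity = unname(s[take]))
  })
  stats::setNames(out, labels)
}

#' Complete a sparse association matrix with weighted K nearest known
#' neighbors (WKNKN)
#'
#' Unknown entries (zeros) of the binary association matrix are replaced by an
#' interaction likelihood estimated from each entity's K nearest known
#' neighbors in both spaces. The disease-side estimate for disease `i` is the
#' decay-weighted average of its neighbors' association profiles,
#' `Yd(i, .) = sum_t r^(t-1) * sim(i, n_t) * A(n_t, .) / sum_t sim(i, n_t)`,
#' and the miRNA-side estimate is the analogue on columns; a zero entry
#' becomes `min(1, (Yd + Ym) / 2)` while known 1s are kept untouched.
#'
#' @param A Binary association matrix (diseases x miRNAs).
#' @param sim_d,sim_m Disease- and miRNA-space similarity matrices used for
#'   the neighbor search and weights (normally the integrated similarities
#'   ISD/ISM; pass the semantic/functional-only matrices to probe the
#'   alternative).
#' @param k Number of nearest known neighbors (default 5).
#' @param r Decay term in (0, 1\]; the t-th neighbor is weighted by
#'   `r^(t-1)` (default 0.7).
#' @return Completed association matrix in \[0, 1\], elementwise >= `A`.
#' @export
wknkn_complete <- function(A, sim_d, sim_m, k = 5, r = 0.7) {
  stopifnot(is.matrix(A))
  if (!(r > 0 && r <= 1)) stop("r must be in (0, 1]", call. = FALSE)
  stopifnot(k >= 1)
  side_estimate <- function(M, sim) {
    # M: entities in rows; returns the neighbor-weighted profile per row
    nn <- knn_known(sim, M, space = "disease", k = k)
    Y <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
    for (i in seq_len(nrow(M))) {
      nb <- nn[[rownames(M)[i]]]
      if (nrow(nb) == 0) next
      w <- r^(seq_len(nrow(nb)) - 1) * nb$similarity
      denom <- sum(nb$similarity)
      if (denom == 0) next
      Y[i, ] <- colSums(w * M[nb$neighbor, , drop = FALSE]) / denom
    }
    Y
  }
  Yd <- side_estimate(A, sim_d)
  Ym <- t(side_estimate(t(A), sim_m))
  est <- pmin(1, (Yd + Ym) / 2)
  out <- ifelse(A == 1, 1, est)
  dimnames(out) <- dimnames(A)
  out
}
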