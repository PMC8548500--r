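#' Semantic contribution of each ancestor term to a disease
#'
#' In the Wang-style ontology measure, a disease contributes 1 to itself and
#' every ancestor term `t` contributes `delta_sem` times the best contribution
#' among its children inside the disease's DAG, i.e. the contribution decays
#' by a fixed factor per generation along the best (shortest) path down to the
#' disease.
#'
#' @param dag A `disease_dag` (see [read_dag_edges()]).
#' @param delta_sem Semantic decay factor per generation, in (0, 1);
#'   default 0.5.
#' @return Named numeric vector over `dag$ancestors` with values in (0, 1];
#'   the disease itself maps to 1.
#' @export
semantic_contributions <- function(dag, delta_sem = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta_sem > 0, delta_sem < 1)
  anc <- dag$ancestors
  contrib <- stats::setNames(rep(NA_real_, length(anc)), anc)
  contrib[dag$term_id] <- 1
  if (length(anc) > 1) {
    edges <- dag$edges
    children_of <- split(edges[, "child"], factor(edges[, "parent"], levels = anc))
    # propagate upward: repeat until fixed point (closure is small and acyclic)
    repeat {
      changed <- FALSE
      for (t in anc) {
        kids <- children_of[[t]]
        if (length(kids) == 0) next
        vals <- contrib[kids]
        if (all(is.na(vals))) next
        cand <- delta_sem * max(vals, na.rm = TRUE)
        if (is.na(contrib[t]) || cand > contrib[t]) {
          if (t != dag$term_id) {
            contrib[t] <- cand
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  if (anyNA(contrib)) {
    stop(sprintf(
      "ancestor closure of '%s' contains term(s) with no path to it: %s",
      dag$term_id, paste(names(contrib)[is.na(contrib)], collapse = ", ")
    ), call. = FALSE)
  }
  contrib
}

#' Disease semantic similarity from ontology DAGs
#'
#' Two diseases sharing a larger, closer part of their ancestry are more
#' similar: the similarity is the sum of both diseases' semantic contributions
#' over the shared ancestor terms, normalized by the two total semantic
#' values, which puts it in \[0, 1\] with 1 on the diagonal.
#'
#' @param dags Named list of `disease_dag` objects, one per disease.
#' @param delta_sem Semantic decay factor per generation (default 0.5).
#' @param diseases Optional label universe; diseases without a DAG get
#'   all-zero rows (their similarity is later filled by the GIP kernel during
#'   integration).
#' @return Symmetric labeled similarity matrix in \[0, 1\].
#' @export
disease_semantic_similarity <- function(dags, delta_sem = 0.5, diseases = NULL) {
  if (length(dags) == 0) stop("empty DAG map", call. = FALSE)
  if (is.null(diseases)) diseases <- names(dags)
  contribs <- lapply(dags, semantic_contributions, delta_sem = delta_sem)
  totals <- vapply(contribs, sum, numeric(1))
  n <- length(diseases)
  dss <- matrix(0, n, n, dimnames = list(diseases, diseases))
  with_dag <- intersect(diseases, names(dags))
  for (a in seq_along(with_dag)) {
    di <- with_dag[a]
    ci <- contribs[[di]]
    for (b in a:length(with_dag)) {
      dj <- with_dag[b]
      cj <- contribs[[dj]]
      shared <- intersect(names(ci), names(cj))
      if (length(shared) == 0) next
      v <- sum(ci[shared] + cj[shared]) / (totals[[di]] + totals[[dj]])
      dss[di, dj] <- v
      dss[dj, di] <- v
    }
  }
  dss
}

#' miRNA functional similarity from disease-annotation sets
#'
#' Each miRNA is characterized by the set of diseases it is associated with
#' (its DTT set). The similarity of a disease to a set is its best semantic
#' similarity to any member; the functional similarity of two miRNAs is the
#' average, over both annotation sets, of each disease's similarity to the
#' other miRNA's set.
#'
#' @param dtt Named list: for each miRNA, a character vector of disease terms
#'   (all indexed by `dss`, all non-empty).
#' @param dss Disease semantic similarity matrix.
#' @return Symmetric labeled similarity matrix in \[0, 1\] over the miRNAs.
#' @export
mirna_functional_similarity <- function(dtt, dss) {
  if (length(dtt) == 0) stop("empty DTT map", call. = FALSE)
  sizes <- lengths(dtt)
  if (any(sizes == 0)) {
    stop(sprintf(
      "empty disease set for miRNA(s): %s",
      paste(names(dtt)[sizes == 0], collapse = ", ")
    ), call. = FALSE)
  }
  missing <- setdiff(unique(unlist(dtt, use.names = FALSE)), rownames(dss))
  if (length(missing) > 0) {
    stop(sprintf(
      "DTT disease term(s) not indexed by the semantic similarity matrix: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ), call. = FALSE)
  }
  mirnas <- names(dtt)
  n <- length(mirnas)
  mfs <- matrix(0, n, n, dimnames = list(mirnas, mirnas))
  # SS(d, DTT) = max over the set; column-wise max of the relevant submatrix
  set_sim <- function(ds, set) {
    # rows ds vs set: vector of max similarity of each d in ds to the set
    sub <- dss[ds, set, drop = FALSE]
    apply(sub, 1, max)
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      si <- dtt[[i]]
      sj <- dtt[[j]]
      v <- (sum(set_sim(si, sj)) + sum(set_sim(sj, si))) /
        (length(si) + length(sj))
      mfs[i, j] <- v
      mfs[j, i] <- v
    }
  }
  mfs
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Treats each disease (row) or miRNA (column) of the association matrix as a
#' binary interaction profile and applies a Gaussian kernel
#' `K(x, y) = exp(-gamma * ||x - y||^2)` with a data-driven bandwidth
#' `gamma = gamma_prime / mean(||profile||^2)`.
#'
#' @param A Binary (or WKNKN-completed) association matrix, diseases in rows.
#' @param space `"disease"` (profiles are rows) or `"mirna"` (columns).
#' @param gamma_prime Bandwidth adjustment parameter; default 1.
#' @return Symmetric labeled similarity matrix with entries in (0, 1] and unit
#'   diagonal.
#' @export
gip_similarity <- function(A, space = c("disease", "mirna"), gamma_prime = 1) {
  space <- match.arg(space)
  stopifnot(is.matrix(A), gamma_prime > 0)
  P <- if (space == "disease") A else t(A)
  msq <- mean(rowSums(P^2))
  if (msq == 0) {
    stop("all-zero association matrix: GIP bandwidth undefined", call. = FALSE)
  }
  gamma <- gamma_prime / msq
  d2 <- as.matrix(stats::dist(P))^2
  K <- exp(-gamma * d2)
  dimnames(K) <- list(rownames(P), rownames(P))
  K
}

#' Integrate a primary similarity with its GIP fallback
#'
#' Ontology-derived (disease) or annotation-derived (miRNA) similarity is
#' undefined for entities lacking the side information; for those pairs the
#' GIP kernel stands in. A pair "has" primary similarity when its primary
#' entry is positive, unless an explicit availability mask is supplied.
#'
#' @param primary_sim Disease semantic or miRNA functional similarity matrix.
#' @param gip_sim GIP kernel matrix on the same labels.
#' @param mask Optional logical matrix: `TRUE` where the primary similarity is
#'   available; default `primary_sim > 0`.
#' @return Symmetric labeled similarity matrix with unit diagonal.
#' @export
integrate_similarity <- function(primary_sim, gip_sim, mask = NULL) {
  if (!identical(dimnames(primary_sim), dimnames(gip_sim)) ||
    !identical(dim(primary_sim), dim(gip_sim))) {
    stop("label/shape mismatch between primary and GIP similarity matrices",
      call. = FALSE
    )
  }
  if (is.null(mask)) mask <- primary_sim > 0
  out <- ifelse(mask, primary_sim, gip_sim)
  diag(out) <- 1
  dimnames(out) <- dimnames(primary_sim)
  out
}
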