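#' Initial probability matrix of the heterogeneous walk
#'
#' Block-diagonal seed matrix: every disease seeds its own column with
#' `(1 - delta) / n_d` and every miRNA with `delta / n_m`, so all
#' disease-miRNA pairs are walked simultaneously and the two sub-networks are
#' weighted by `delta`. The trace is always 1.
#'
#' @param n_d,n_m Numbers of diseases and miRNAs.
#' @param delta Sub-network weight in (0, 1).
#' @param labels Optional character vector of `n_d + n_m` node labels.
#' @return An `(n_d + n_m)` square matrix.
#' @export
initial_probability <- function(n_d, n_m, delta, labels = NULL) {
  stopifnot(n_d >= 1, n_m >= 1, delta > 0, delta < 1)
  p0 <- diag(c(rep((1 - delta) / n_d, n_d), rep(delta / n_m, n_m)))
  if (!is.null(labels)) dimnames(p0) <- list(labels, labels)
  p0
}

#' Propagate a random walk with restart
#'
#' Iterates `P_{t+1} = (1 - gamma) * W %*% P_t + gamma * P0` from `P_0 = P0`
#' (the transition matrix left-multiplies the state). Stops after `t_max`
#' iterations, or earlier when the max-norm change drops below `tol`
#' (if `tol > 0`).
#'
#' @param W An `hetnet` object or the assembled transition matrix itself.
#' @param p0 Initial probability matrix (see [initial_probability()]).
#' @param gamma Restart probability in (0, 1).
#' @param t_max Iteration count (default 10).
#' @param tol Early-stop tolerance; 0 disables (default).
#' @return List with `P` (final state), `iterations` (steps actually run) and
#'   `delta_last` (final max-norm change).
#' @export
rwr_propagate <- function(W, p0, gamma, t_max = 10, tol = 0) {
  if (inherits(W, "hetnet")) W <- W$assembled
  stopifnot(gamma > 0, gamma < 1, t_max >= 1)
  if (!identical(dim(W), dim(p0))) {
    stop("transition matrix and initial probability shapes differ", call. = FALSE)
  }
  P <- p0
  delta_last <- Inf
  iterations <- 0L
  for (t in seq_len(t_max)) {
    P_next <- (1 - gamma) * (W %*% P) + gamma * p0
    if (any(!is.finite(P_next))) {
      stop(sprintf("non-finite values during propagation at iteration %d", t),
        call. = FALSE
      )
    }
    delta_last <- max(abs(P_next - P))
    P <- P_next
    iterations <- t
    if (tol > 0 && delta_last < tol) break
  }
  list(P = P, iterations = iterations, delta_last = delta_last)
}

#' Fuse the two walks and extract the disease-miRNA score block
#'
#' Combines the disease-based and miRNA-based stationary states as
#' `P = (1 - delta) * P1 + delta * P2` and reads the association scores off
#' the off-diagonal blocks: the top-right `n_d x n_m` block averaged with the
#' transpose of the bottom-left block (`symmetrize = FALSE` keeps the
#' top-right block only).
#'
#' @param p1,p2 Final states of the disease-based and miRNA-based walks
#'   (matrices or the lists returned by [rwr_propagate()]).
#' @param delta Fusion weight in (0, 1).
#' @param n_d,n_m Numbers of diseases and miRNAs.
#' @param disease_ids,mirna_ids Labels for the output block.
#' @param symmetrize Average the two off-diagonal blocks (default `TRUE`).
#' @return An `n_d x n_m` labeled score matrix.
#' @export
combine_and_extract <- function(p1, p2, delta, n_d, n_m,
                                disease_ids = NULL, mirna_ids = NULL,
                                symmetrize = TRUE) {
  if (is.list(p1) && !is.matrix(p1)) p1 <- p1$P
  if (is.list(p2) && !is.matrix(p2)) p2 <- p2$P
  stopifnot(identical(dim(p1), dim(p2)), delta > 0, delta < 1)
  if (nrow(p1) != n_d + n_m) stop("state shape mismatch", call. = FALSE)
  P <- (1 - delta) * p1 + delta * p2
  top_right <- P[seq_len(n_d), n_d + seq_len(n_m), drop = FALSE]
  if (symmetrize) {
    bottom_left <- P[n_d + seq_len(n_m), seq_len(n_d), drop = FALSE]
    top_right <- (top_right + t(bottom_left)) / 2
  }
  dimnames(top_right) <- list(disease_ids, mirna_ids)
  top_right
}

#' Predict miRNA-disease association scores
#'
#' Runs the full pipeline on a binary association matrix and the two
#' integrated similarity matrices: WKNKN completion, degree-weighted base
#' adjacencies, intra/inter transition blocks, assembly of the disease-based
#' and miRNA-based heterogeneous networks, random walk with restart on each,
#' and fusion into a final score for every disease-miRNA pair. The
#' computation is deterministic given its inputs.
#'
#' @param A Binary association matrix (diseases x miRNAs, labeled).
#' @param isd,ism Integrated disease / miRNA similarity matrices.
#' @param params An [mda_params()] object.
#' @param wknkn Apply the WKNKN completion step (default `TRUE`; `FALSE`
#'   runs the walk on the raw binary matrix, the no-completion ablation).
#' @param symmetrize Passed to [combine_and_extract()].
#' @return An `mda_scores` object: fields `scores` (n_d x n_m), `known_mask`
#'   (the training positives), `a_new` (completed matrix), `params`,
#'   `iterations`, `isolated`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' fx <- make_fixture(fixture_spec(n_d = 12, n_m = 16, n_blocks = 2, seed = 1))
#' fit <- predict_mda(fx$A, fx$isd, fx$ism, mda_params())
#' rank_predictions(fit, rownames(fx$A)[1], top_n = 5)
predict_mda <- function(A, isd, ism, params = mda_params(), wknkn = TRUE,
                        symmetrize = TRUE) {
  stopifnot(inherits(params, "mda_params"))
  a_new <- if (wknkn) {
    wknkn_complete(A, isd, ism, k = params$k, r = params$r)
  } else {
    A
  }
  nets <- build_hetnets(isd, a_new, ism, params$phi)
  n_d <- nrow(A)
  n_m <- ncol(A)
  p0 <- initial_probability(n_d, n_m, params$delta)
  run1 <- rwr_propagate(nets$disease_based, p0, params$gamma, params$t_max,
    params$tol
  )
  run2 <- rwr_propagate(nets$mirna_based, p0, params$gamma, params$t_max,
    params$tol
  )
  scores <- combine_and_extract(run1, run2, params$delta, n_d, n_m,
    disease_ids = rownames(A), mirna_ids = colnames(A),
    symmetrize = symmetrize
  )
  structure(
    list(
      scores = scores, known_mask = (A == 1) * 1, a_new = a_new,
      params = params,
      iterations = c(disease_based = run1$iterations,
        mirna_based = run2$iterations
      ),
      isolated = nets$isolated
    ),
    class = "mda_scores"
  )
}

#' @export
print.mda_scores <- function(x, ...) {
  cat(sprintf(
    "<mda_scores> %d diseases x %d miRNAs; %d known positives; K=%d r=%g phi=%g delta=%g gamma=%g\n",
    nrow(x$scores), ncol(x$scores), sum(x$known_mask), x$params$k, x$params$r,
    x$params$phi, x$params$delta, x$params$gamma
  ))
  invisible(x)
}

#' Tidy a fitted score table into one row per disease-miRNA pair
#'
#' @param x An `mda_scores` object.
#' @param ... Unused.
#' @return Tibble with columns `disease_id`, `mirna_id`, `score`, `known`.
#' @method tidy mda_scores
#' @export
tidy.mda_scores <- function(x, ...) {
  tibble::tibble(
    disease_id = rep(rownames(x$scores), times = ncol(x$scores)),
    mirna_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores),
    known = as.vector(x$known_mask) == 1
  )
}

#' One-row summary of a fitted score table
#'
#' @param x An `mda_scores` object.
#' @param ... Unused.
#' @return Tibble with pair counts, score range, and iteration counts.
#' @method glance mda_scores
#' @export
glance.mda_scores <- function(x, ...) {
  tibble::tibble(
    n_diseases = nrow(x$scores),
    n_mirnas = ncol(x$scores),
    n_known = sum(x$known_mask),
    min_score = min(x$scores),
    max_score = max(x$scores),
    iterations_disease_based = unname(x$iterations["disease_based"]),
    iterations_mirna_based = unname(x$iterations["mirna_based"])
  )
}

#' Plot the score distribution of known versus candidate pairs
#'
#' @param object An `mda_scores` object.
#' @param ... Unused.
#' @return A ggplot object: score densities for known positives and unknown
#'   candidate pairs.
#' @method autoplot mda_scores
#' @export
autoplot.mda_scores <- function(object, ...) {
  df <- tidy.mda_scores(object)
  df$status <- ifelse(df$known, "known positive", "candidate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$status)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(
      x = "prediction score", y = "density", fill = NULL,
      title = "Prediction score distribution"
    ) +
    ggplot2::theme_minimal()
}
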