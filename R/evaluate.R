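#' ROC and precision-recall evaluation of a score vector
#'
#' Computes the full ROC and PR curves by sweeping every distinct score
#' threshold (tied scores are grouped, which makes the trapezoidal ROC area
#' identical to the midrank Wilcoxon-Mann-Whitney statistic). AUPR uses the
#' conservative step-wise (rectangular, recall-increment) rule, with the curve
#' anchored at recall 0 at the first attainable precision.
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels Binary vector (0/1 or logical) of the same length; at least
#'   one positive and one negative are required for the ROC, at least one
#'   positive for the PR curve.
#' @return An `mda_eval` object with `auc`, `aupr`, `roc_points` (tibble of
#'   FPR/TPR), `pr_points` (tibble of recall/precision), `n_pos`, `n_neg`.
#' @export
eval_binary <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes are required to evaluate ROC/PR", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: cumulative TP/FP at the end of each tie group
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  # rectangular AUPR over recall increments; anchor at recall 0 with the
  # first attainable precision
  rec0 <- c(0, recall)
  prec_steps <- precision
  aupr <- sum(diff(rec0) * prec_steps)
  structure(
    list(
      auc = auc, aupr = aupr,
      roc_points = tibble::tibble(fpr = fpr, tpr = tpr),
      pr_points = tibble::tibble(
        recall = c(0, recall),
        precision = c(precision[1], precision)
      ),
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "mda_eval"
  )
}

#' @export
print.mda_eval <- function(x, ...) {
  cat(sprintf(
    "<mda_eval> AUC %.4f, AUPR %.4f (%d positives, %d negatives)\n",
    x$auc, x$aupr, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @rdname eval_binary
#' @param x An `mda_eval` object.
#' @param ... Unused.
#' @method tidy mda_eval
#' @export
tidy.mda_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$roc_points, x = "fpr", y = "tpr"),
      curve = "ROC"
    ),
    dplyr::mutate(dplyr::rename(x$pr_points, x = "recall", y = "precision"),
      curve = "PR"
    )
  )
}

#' @rdname eval_binary
#' @method glance mda_eval
#' @export
glance.mda_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, aupr = x$aupr, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname eval_binary
#' @param object An `mda_eval` object.
#' @method autoplot mda_eval
#' @export
autoplot.mda_eval <- function(object, ...) {
  df <- tidy.mda_eval(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(
      x = "FPR / recall", y = "TPR / precision",
      title = sprintf("AUC %.4f, AUPR %.4f", object$auc, object$aupr)
    ) +
    ggplot2::theme_minimal()
}

#' Degree-product baseline scores
#'
#' A naive link-prediction baseline: the score of pair (i, j) is the product
#' of disease i's and miRNA j's numbers of known associations in the training
#' matrix. Any propagation method should beat it on structured data.
#'
#' @param A Training association matrix.
#' @return Score matrix of the same shape.
#' @export
degree_product_baseline <- function(A) {
  outer(rowSums(A), colSums(A))
}

#' Five-fold cross-validation of the prediction pipeline
#'
#' All `n_d * n_m` disease-miRNA pairs (positives and negatives alike) are
#' randomly partitioned into five folds. Per fold, the test-fold positives are
#' zeroed in the training matrix; the GIP kernels, integrated similarities and
#' WKNKN completion are recomputed on the masked matrix (the semantic and
#' functional similarities are association-independent and enter unchanged);
#' the pipeline is re-run; and AUC/AUPR are computed over the test-fold pairs
#' with the held-out positives as the positive class.
#'
#' @param A Binary association matrix.
#' @param dss Disease semantic similarity matrix (association-independent).
#' @param mfs miRNA functional similarity matrix (association-independent).
#' @param params An [mda_params()] object.
#' @param folds Number of folds (default 5).
#' @param n_repeats Number of repeated partitions (default 1).
#' @param seed RNG seed for fold assignment; defaults to `params$seed`.
#' @param wknkn Apply WKNKN inside each fold (default `TRUE`; `FALSE` gives
#'   the no-completion ablation).
#' @param completed_eval Additionally report metrics against the WKNKN-completed
#'   training matrix binarized at > 0 (columns `auc_completed`,
#'   `aupr_completed`).
#' @param pipeline Scoring function `(A_train, isd, ism, params) -> score
#'   matrix`; defaults to the full pipeline. Supply
#'   `function(A, ...) degree_product_baseline(A)` for the baseline.
#' @return An `mda_cv` object: `folds` (per-fold tibble), `summary`
#'   (mean/sd), `seeds`.
#' @export
five_fold_cv <- function(A, dss, mfs, params = mda_params(), folds = 5,
                         n_repeats = 1, seed = NULL, wknkn = TRUE,
                         completed_eval = FALSE, pipeline = NULL) {
  stopifnot(sum(A) >= folds)
  if (is.null(seed)) seed <- params$seed
  if (is.null(pipeline)) {
    pipeline <- function(A_train, isd, ism, params) {
      predict_mda(A_train, isd, ism, params, wknkn = wknkn)
    }
  }
  n_pairs <- length(A)
  rows <- list()
  seeds <- seed + seq_len(n_repeats) - 1L
  for (rep_i in seq_len(n_repeats)) {
    assignment <- withr::with_seed(
      seeds[rep_i],
      sample(rep(seq_len(folds), length.out = n_pairs))
    )
    for (f in seq_len(folds)) {
      test_idx <- which(assignment == f)
      test_pos <- test_idx[A[test_idx] == 1]
      if (length(test_pos) == 0) {
        warning(sprintf("repeat %d fold %d has no positives; skipped", rep_i, f))
        next
      }
      A_train <- A
      A_train[test_pos] <- 0
      fold_fit <- cv_fold_scores(A_train, dss, mfs, params, pipeline)
      ev <- eval_binary(fold_fit$scores[test_idx], A[test_idx])
      row <- tibble::tibble(
        repeat_i = rep_i, fold = f, n_test_pos = length(test_pos),
        n_test = length(test_idx), auc = ev$auc, aupr = ev$aupr
      )
      if (completed_eval && !is.null(fold_fit$a_new)) {
        lab2 <- (fold_fit$a_new[test_idx] > 0) * 1
        if (any(lab2 == 1) && any(lab2 == 0)) {
          ev2 <- eval_binary(fold_fit$scores[test_idx], lab2)
          row$auc_completed <- ev2$auc
          row$aupr_completed <- ev2$aupr
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  fold_tab <- dplyr::bind_rows(rows)
  structure(
    list(
      folds = fold_tab,
      summary = tibble::tibble(
        mean_auc = mean(fold_tab$auc), sd_auc = stats::sd(fold_tab$auc),
        mean_aupr = mean(fold_tab$aupr), sd_aupr = stats::sd(fold_tab$aupr),
        n_folds = nrow(fold_tab)
      ),
      seeds = seeds
    ),
    class = "mda_cv"
  )
}

# one CV fold: recompute association-dependent similarities on the masked
# matrix, then score. Isolated (all-zero) rows/columns are tolerated by GIP as
# long as the matrix itself is nonzero.
cv_fold_scores <- function(A_train, dss, mfs, params, pipeline) {
  gip_d <- gip_similarity(A_train, "disease")
  gip_m <- gip_similarity(A_train, "mirna")
  isd <- integrate_similarity(dss, gip_d)
  ism <- integrate_similarity(mfs, gip_m)
  scores <- pipeline(A_train, isd, ism, params)
  a_new <- attr(scores, "a_new")
  if (is.null(a_new) && is.list(scores) && !is.matrix(scores)) {
    a_new <- scores$a_new
    scores <- scores$scores
  }
  list(scores = scores, a_new = a_new)
}

#' @export
print.mda_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mda_cv> %d fold runs: AUC %.4f +/- %.4f, AUPR %.4f +/- %.4f\n",
    s$n_folds, s$mean_auc, s$sd_auc, s$mean_aupr, s$sd_aupr
  ))
  invisible(x)
}

#' @rdname five_fold_cv
#' @param x An `mda_cv` object.
#' @param ... Unused.
#' @method tidy mda_cv
#' @export
tidy.mda_cv <- function(x, ...) x$folds

#' @rdname five_fold_cv
#' @method glance mda_cv
#' @export
glance.mda_cv <- function(x, ...) x$summary

#' @rdname five_fold_cv
#' @param object An `mda_cv` object.
#' @method autoplot mda_cv
#' @export
autoplot.mda_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("auc", "aupr"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Cross-validation fold metrics"
    ) +
    ggplot2::theme_minimal()
}

#' Global leave-one-out cross-validation
#'
#' Removes each known association in turn, re-runs the whole pipeline on the
#' masked matrix (recomputing the GIP kernels, integration and WKNKN), and
#' records the held-out pair's score. Negatives are all never-known pairs,
#' scored by the full-data model. AUC/AUPR are computed over the pooled
#' scores.
#'
#' @inheritParams five_fold_cv
#' @return An `mda_eval` object, with an extra field `n_reruns`.
#' @export
global_loocv <- function(A, dss, mfs, params = mda_params(), wknkn = TRUE,
                         pipeline = NULL) {
  pos <- which(A == 1)
  stopifnot(length(pos) >= 2)
  if (is.null(pipeline)) {
    pipeline <- function(A_train, isd, ism, params) {
      predict_mda(A_train, isd, ism, params, wknkn = wknkn)
    }
  }
  full <- cv_fold_scores(A, dss, mfs, params, pipeline)$scores
  pos_scores <- vapply(pos, function(idx) {
    A_train <- A
    A_train[idx] <- 0
    cv_fold_scores(A_train, dss, mfs, params, pipeline)$scores[idx]
  }, numeric(1))
  neg <- which(A == 0)
  ev <- eval_binary(
    c(pos_scores, full[neg]),
    c(rep(1L, length(pos)), rep(0L, length(neg)))
  )
  ev$n_reruns <- length(pos)
  ev
}
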