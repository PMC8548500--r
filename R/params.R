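#' Pipeline parameters
#'
#' Bundles the tunable parameters of the prediction pipeline with their
#' defaults. `k` and `r` govern the WKNKN completion; `phi`, `delta` and
#' `gamma` the heterogeneous-network walk; `delta_sem` the ontology decay;
#' `t_max`/`tol` the propagation length.
#'
#' @param k Number of nearest known neighbors for WKNKN (positive integer,
#'   default 5).
#' @param r WKNKN decay term in (0, 1\] (default 0.7).
#' @param phi Inter-network jump probability in (0, 1) (default 0.9).
#' @param delta Sub-network weight in (0, 1), used both to seed the initial
#'   probability and to fuse the two walks (default 0.7).
#' @param gamma Restart probability in (0, 1) (default 0.7).
#' @param delta_sem Semantic decay factor per DAG generation in (0, 1)
#'   (default 0.5).
#' @param t_max Number of propagation iterations (default 10).
#' @param tol Early-stop tolerance on the max-norm change per iteration;
#'   0 disables early stopping (default).
#' @param seed RNG seed; affects only cross-validation fold assignment and
#'   fixture generation, never the prediction itself.
#' @return A list of class `mda_params`.
#' @export
mda_params <- function(k = 5, r = 0.7, phi = 0.9, delta = 0.7, gamma = 0.7,
                       delta_sem = 0.5, t_max = 10, tol = 0, seed = 1L) {
  check_range <- function(x, lo, hi, name, lo_open = TRUE, hi_open = TRUE) {
    bad <- if (lo_open) x <= lo else x < lo
    bad <- bad || if (hi_open) x >= hi else x > hi
    if (bad) {
      stop(sprintf(
        "%s = %s out of range %s%s, %s%s", name, format(x),
        if (lo_open) "(" else "[", format(lo), format(hi),
        if (hi_open) ")" else "]"
      ), call. = FALSE)
    }
  }
  if (k < 1 || k != round(k)) stop("k must be a positive integer", call. = FALSE)
  check_range(r, 0, 1, "r", hi_open = FALSE)
  check_range(phi, 0, 1, "phi")
  check_range(delta, 0, 1, "delta")
  check_range(gamma, 0, 1, "gamma")
  check_range(delta_sem, 0, 1, "delta_sem")
  if (t_max < 1 || t_max != round(t_max)) {
    stop("t_max must be a positive integer", call. = FALSE)
  }
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  structure(
    list(
      k = as.integer(k), r = r, phi = phi, delta = delta, gamma = gamma,
      delta_sem = delta_sem, t_max = as.integer(t_max), tol = tol,
      seed = as.integer(seed)
    ),
    class = "mda_params"
  )
}

#' @export
print.mda_params <- function(x, ...) {
  cat("<mda_params>",
    sprintf("K=%d r=%g phi=%g delta=%g gamma=%g", x$k, x$r, x$phi, x$delta,
      x$gamma
    ),
    sprintf("delta_sem=%g t_max=%d tol=%g seed=%d", x$delta_sem, x$t_max,
      x$tol, x$seed
    ), "\n"
  )
  invisible(x)
}
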