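#' Degree-weighted base adjacency matrices
#'
#' Re-weights the (completed) association matrix by the integrated
#' similarities so that an edge to a hub that many similar entities also reach
#' carries more mass: the disease-based adjacency is `ISD %*% A_new` (each
#' entry pools the associations of all similar diseases) and the miRNA-based
#' adjacency is `A_new %*% ISM`.
#'
#' @param isd Integrated disease similarity matrix.
#' @param a_new Completed association matrix (diseases x miRNAs).
#' @param ism Integrated miRNA similarity matrix.
#' @return List with elements `disease_base` and `mirna_base`, both
#'   diseases x miRNAs.
#' @export
base_adjacencies <- function(isd, a_new, ism) {
  if (!identical(rownames(isd), rownames(a_new)) ||
    !identical(colnames(isd), rownames(a_new))) {
    stop("disease similarity labels do not align with the association matrix",
      call. = FALSE
    )
  }
  if (!identical(rownames(ism), colnames(a_new)) ||
    !identical(colnames(ism), colnames(a_new))) {
    stop("miRNA similarity labels do not align with the association matrix",
      call. = FALSE
    )
  }
  list(
    disease_base = isd %*% a_new,
    mirna_base = a_new %*% ism
  )
}

#' Inter-space transition block
#'
#' Transition probabilities between the disease and miRNA sub-networks. For
#' the disease-to-miRNA direction each disease row is normalized to sum to the
#' jump probability `phi`; for the miRNA-to-disease direction each miRNA
#' *column* is normalized to sum to `phi`. Rows/columns whose normalizer is
#' zero (no associations) are left all-zero.
#'
#' @param a_new Completed association matrix.
#' @param base The matching base adjacency: `mirna_base` for
#'   `direction = "dm"`, `disease_base` for `direction = "md"`.
#' @param phi Inter-network jump probability in (0, 1).
#' @param direction `"dm"` (disease to miRNA, row-normalized) or `"md"`
#'   (miRNA to disease, column-normalized).
#' @return A diseases x miRNAs transition block.
#' @export
inter_transition <- function(a_new, base, phi, direction = c("dm", "md")) {
  direction <- match.arg(direction)
  stopifnot(phi > 0, phi < 1, identical(dim(a_new), dim(base)))
  W <- a_new * base
  if (direction == "dm") {
    denom <- rowSums(W)
    scale <- ifelse(denom > 0, phi / denom, 0)
    out <- W * scale
  } else {
    denom <- colSums(W)
    scale <- ifelse(denom > 0, phi / denom, 0)
    out <- sweep(W, 2, scale, `*`)
  }
  dimnames(out) <- dimnames(a_new)
  out
}

#' Intra-space transition block
#'
#' Transition probabilities inside one sub-network: each entity's row is its
#' similarity row normalized to sum to 1 (the self-similarity diagonal is part
#' of the normalizer), scaled by `1 - phi` when the entity has at least one
#' association in `a_new` (a connected walker keeps probability `phi` for
#' jumping across) and left unscaled for isolated entities, whose walk stays
#' inside the sub-network.
#'
#' @param sim Intra-space similarity matrix (ISD or ISM).
#' @param a_new Completed association matrix, used only to decide which
#'   entities are connected.
#' @param phi Inter-network jump probability in (0, 1).
#' @param space `"disease"` (connectivity from row sums) or `"mirna"`
#'   (column sums).
#' @return List with `W` (the square transition block) and `isolated`
#'   (labels whose similarity row was all zero and is left all-zero).
#' @export
intra_transition <- function(sim, a_new, phi, space = c("disease", "mirna")) {
  space <- match.arg(space)
  stopifnot(phi > 0, phi < 1)
  connected <- if (space == "disease") rowSums(a_new) > 0 else colSums(a_new) > 0
  labels <- if (space == "disease") rownames(a_new) else colnames(a_new)
  if (!identical(rownames(sim), labels)) {
    stop("similarity labels do not match the association matrix", call. = FALSE)
  }
  denom <- rowSums(sim)
  zero <- denom == 0
  inv <- ifelse(zero, 0, 1 / denom)
  W <- sim * inv
  W[connected, ] <- (1 - phi) * W[connected, , drop = FALSE]
  dimnames(W) <- dimnames(sim)
  list(W = W, isolated = labels[zero])
}

#' Assemble a heterogeneous transition matrix
#'
#' Stacks the two intra-space blocks and one inter-space block into the
#' `(n_d + n_m)` square transition matrix `[[Wd, T], [t(T), Wm]]` of one
#' heterogeneous network (disease-based when `T` is the row-normalized
#' disease-to-miRNA block, miRNA-based when it is the column-normalized
#' miRNA-to-disease block).
#'
#' @param wd Disease intra-space block (n_d x n_d).
#' @param wm miRNA intra-space block (n_m x n_m).
#' @param t_block Inter-space block (n_d x n_m).
#' @param orientation `"disease_based"` or `"mirna_based"` (metadata only).
#' @return An `hetnet` list: `assembled`, the four blocks, `orientation`,
#'   `n_d`, `n_m`.
#' @export
assemble_hetnet <- function(wd, wm, t_block,
                            orientation = c("disease_based", "mirna_based")) {
  orientation <- match.arg(orientation)
  n_d <- nrow(wd)
  n_m <- nrow(wm)
  if (ncol(wd) != n_d || ncol(wm) != n_m ||
    nrow(t_block) != n_d || ncol(t_block) != n_m) {
    stop("block shapes do not conform", call. = FALSE)
  }
  assembled <- rbind(
    cbind(wd, t_block),
    cbind(t(t_block), wm)
  )
  structure(
    list(
      assembled = assembled, Wd = wd, Wm = wm, T = t_block,
      orientation = orientation, n_d = n_d, n_m = n_m
    ),
    class = "hetnet"
  )
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf(
    "<hetnet> %s: %d diseases + %d miRNAs (%d x %d assembled)\n",
    x$orientation, x$n_d, x$n_m, x$n_d + x$n_m, x$n_d + x$n_m
  ))
  invisible(x)
}

#' Build both heterogeneous networks from the pipeline inputs
#'
#' Convenience wrapper running [base_adjacencies()], [inter_transition()],
#' [intra_transition()] and [assemble_hetnet()] for the disease-based and
#' miRNA-based networks.
#'
#' @inheritParams base_adjacencies
#' @param phi Inter-network jump probability.
#' @return List with `disease_based` and `mirna_based` `hetnet` objects and
#'   the `isolated` diagnostic labels.
#' @export
build_hetnets <- function(isd, a_new, ism, phi) {
  base <- base_adjacencies(isd, a_new, ism)
  t_dm <- inter_transition(a_new, base$mirna_base, phi, "dm")
  t_md <- inter_transition(a_new, base$disease_base, phi, "md")
  wd <- intra_transition(isd, a_new, phi, "disease")
  wm <- intra_transition(ism, a_new, phi, "mirna")
  list(
    disease_based = assemble_hetnet(wd$W, wm$W, t_dm, "disease_based"),
    mirna_based = assemble_hetnet(wd$W, wm$W, t_md, "mirna_based"),
    isolated = list(disease = wd$isolated, mirna = wm$isolated)
  )
}
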