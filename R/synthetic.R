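#' Synthetic fixture specification
#'
#' Describes a self-contained synthetic study: a planted-block association
#' matrix between `n_d` diseases and `n_m` miRNAs, a disease ontology forest
#' whose trees follow the planted blocks (so the semantic similarity inherits
#' the block structure), and the annotation sets derived from the planted
#' associations.
#'
#' @param n_d,n_m Numbers of diseases and miRNAs (defaults 60 and 80).
#' @param n_blocks Number of planted disease-miRNA co-clusters (default 4).
#' @param within_block_density Probability of an association inside a block
#'   (default 0.3).
#' @param background_density Probability outside blocks (default 0.01); must
#'   be below the within-block density.
#' @param dag_depth Number of levels of the ontology trees (default 3).
#' @param seed Integer seed; one seed drives the whole fixture.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_d = 60, n_m = 80, n_blocks = 4,
                         within_block_density = 0.3,
                         background_density = 0.01,
                         dag_depth = 3, seed = 1L) {
  stopifnot(
    n_d >= 1, n_m >= 1, n_blocks >= 1, n_blocks <= min(n_d, n_m),
    within_block_density > 0, within_block_density <= 1,
    background_density >= 0, background_density < within_block_density,
    dag_depth >= 1
  )
  structure(
    list(
      n_d = as.integer(n_d), n_m = as.integer(n_m),
      n_blocks = as.integer(n_blocks),
      within_block_density = within_block_density,
      background_density = background_density,
      dag_depth = as.integer(dag_depth), seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Simulate a forest of disease ontology DAGs
#'
#' Builds `n_trees` rooted trees of at most `dag_depth` levels over an
#' internal vocabulary of synthetic ontology terms and hangs the `n_d` disease
#' leaves off them (round-robin across trees, random internal parent within
#' the tree). Diseases in one tree share ancestors, giving their semantic
#' similarity a block structure; diseases in different trees share nothing.
#'
#' @param n_d Number of diseases.
#' @param dag_depth Levels of each tree (1 means isolated singleton terms).
#' @param n_trees Number of trees in the forest (default 4, capped at `n_d`).
#' @param seed Integer seed.
#' @return Named list of `disease_dag` objects for diseases `d1 ... d<n_d>`,
#'   with attribute `"tree"` giving each disease's tree index.
#' @export
simulate_disease_dags <- function(n_d, dag_depth, n_trees = 4, seed = 1L) {
  stopifnot(n_d >= 1, dag_depth >= 1)
  n_trees <- min(n_trees, n_d)
  diseases <- paste0("d", seq_len(n_d))
  # contiguous near-equal groups, matching the planted-block partition rule
  tree_of <- sort(rep(seq_len(n_trees), length.out = n_d))
  if (dag_depth == 1) {
    dags <- lapply(diseases, function(d) {
      new_disease_dag(d, d, matrix(character(0), 0, 2,
        dimnames = list(NULL, c("child", "parent"))
      ))
    })
    dags <- stats::setNames(dags, diseases)
    attr(dags, "tree") <- stats::setNames(tree_of, diseases)
    return(dags)
  }
  edges <- withr::with_seed(seed, {
    ed <- list()
    for (b in seq_len(n_trees)) {
      # internal levels 1..dag_depth-1: level 1 is the root, each deeper
      # level has two terms per parent slot, linked to a random parent above
      level_nodes <- list(sprintf("t%d_L1_1", b))
      for (lev in seq(2, dag_depth - 1, length.out = max(0, dag_depth - 2))) {
        n_here <- min(4, 2^(lev - 1))
        nodes <- sprintf("t%d_L%d_%d", b, lev, seq_len(n_here))
        parents <- sample(level_nodes[[lev - 1]], n_here, replace = TRUE)
        ed[[length(ed) + 1]] <- data.frame(child = nodes, parent = parents)
        level_nodes[[lev]] <- nodes
      }
      leaves <- diseases[tree_of == b]
      internal <- unlist(level_nodes)
      ed[[length(ed) + 1]] <- data.frame(
        child = leaves,
        parent = sample(internal, length(leaves), replace = TRUE)
      )
    }
    do.call(rbind, ed)
  })
  dags <- dags_from_edges(edges, terms = diseases)
  attr(dags, "tree") <- stats::setNames(tree_of, diseases)
  dags
}

#' Simulate a planted-block association matrix
#'
#' Partitions the diseases and miRNAs into `n_blocks` co-clusters (contiguous,
#' near-equal groups) and draws each pair as an independent Bernoulli with the
#' within-block density inside a co-cluster and the background density
#' elsewhere. A generated all-zero row or column is repaired by forcing one
#' within-block positive, so every entity is "known".
#'
#' @param spec A [fixture_spec()].
#' @return List: `A` (binary matrix), `disease_block`, `mirna_block`
#'   (named integer vectors), `repaired` (labels that needed the repair).
#' @export
simulate_associations <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  diseases <- paste0("d", seq_len(spec$n_d))
  mirnas <- paste0("m", seq_len(spec$n_m))
  d_block <- stats::setNames(
    sort(rep(seq_len(spec$n_blocks), length.out = spec$n_d)), diseases
  )
  m_block <- stats::setNames(
    sort(rep(seq_len(spec$n_blocks), length.out = spec$n_m)), mirnas
  )
  within <- outer(d_block, m_block, `==`)
  prob <- ifelse(within, spec$within_block_density, spec$background_density)
  repaired <- character(0)
  A <- withr::with_seed(spec$seed, {
    A <- matrix(
      stats::rbinom(length(prob), 1, as.vector(prob)),
      spec$n_d, spec$n_m,
      dimnames = list(diseases, mirnas)
    )
    for (i in which(rowSums(A) == 0)) {
      j <- sample(which(m_block == d_block[i]), 1)
      A[i, j] <- 1
      repaired <- c(repaired, diseases[i])
    }
    for (j in which(colSums(A) == 0)) {
      i <- sample(which(d_block == m_block[j]), 1)
      A[i, j] <- 1
      repaired <- c(repaired, mirnas[j])
    }
    A
  })
  list(A = A, disease_block = d_block, mirna_block = m_block,
    repaired = repaired
  )
}

#' Generate a complete synthetic fixture
#'
#' Draws the planted-block association matrix and a matching ontology forest
#' (one tree per block), derives each miRNA's disease-annotation set from the
#' planted associations, computes all similarity matrices (semantic,
#' functional, GIP, integrated) with the similarity module, and optionally
#' serializes everything to a directory in the package's TSV dialects together
#' with a YAML manifest recording the spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory; created if needed.
#' @param delta_sem Semantic decay factor used for the bundled DSS
#'   (default 0.5).
#' @return List with `A`, `dags`, `dtt`, `dss`, `mfs`, `gip_d`, `gip_m`,
#'   `isd`, `ism`, `disease_block`, `mirna_block`, `spec`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = NULL, delta_sem = 0.5) {
  sim <- simulate_associations(spec)
  dags <- simulate_disease_dags(spec$n_d, spec$dag_depth,
    n_trees = spec$n_blocks, seed = spec$seed + 1L
  )
  # annotation sets from the planted associations; repair guarantees non-empty
  dtt <- apply(sim$A, 2, function(col) rownames(sim$A)[col == 1],
    simplify = FALSE
  )
  dss <- disease_semantic_similarity(dags, delta_sem = delta_sem)
  mfs <- mirna_functional_similarity(dtt, dss)
  gip_d <- gip_similarity(sim$A, "disease")
  gip_m <- gip_similarity(sim$A, "mirna")
  isd <- integrate_similarity(dss, gip_d)
  ism <- integrate_similarity(mfs, gip_m)
  out <- list(
    A = sim$A, dags = dags, dtt = dtt, dss = dss, mfs = mfs,
    gip_d = gip_d, gip_m = gip_m, isd = isd, ism = ism,
    disease_block = sim$disease_block, mirna_block = sim$mirna_block,
    spec = spec
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pairs <- which(sim$A == 1, arr.ind = TRUE)
    writeLines(
      paste(rownames(sim$A)[pairs[, 1]], colnames(sim$A)[pairs[, 2]],
        sep = "\t"
      ),
      file.path(dir, "associations.tsv")
    )
    dag_edges <- do.call(rbind, lapply(dags, `[[`, "edges"))
    dag_edges <- unique(dag_edges)
    writeLines(
      paste(dag_edges[, "child"], dag_edges[, "parent"], sep = "\t"),
      file.path(dir, "dag_edges.tsv")
    )
    for (nm in c("dss", "mfs", "gip_d", "gip_m", "isd", "ism")) {
      write_matrix_tsv(out[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
    write_matrix_tsv(sim$A, file.path(dir, "A.tsv"))
    yaml::write_yaml(unclass(spec), file.path(dir, "manifest.yaml"))
  }
  out
}
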