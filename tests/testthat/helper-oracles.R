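# Independent naive-loop reference implementations used as oracles.
# Deliberately written in the most literal way possible (double/triple loops,
# explicit path enumeration, explicit matrix powers) so they share no code
# path with the package.

# shortest child->parent path length from term to each ancestor, by BFS;
# contribution = delta^distance (the unrolled max-over-paths recursion)
oracle_semantic_contributions <- function(dag, delta_sem) {
  anc <- dag$ancestors
  dist <- stats::setNames(rep(Inf, length(anc)), anc)
  dist[dag$term_id] <- 0
  frontier <- dag$term_id
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (node in frontier) {
      if (NROW(dag$edges) == 0) next
      parents <- dag$edges[dag$edges[, "child"] == node, "parent"]
      for (p in parents) {
        if (dist[p] > dist[node] + 1) {
          dist[p] <- dist[node] + 1
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  delta_sem^dist
}

oracle_dss <- function(dags, delta_sem) {
  n <- length(dags)
  ids <- names(dags)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  contribs <- lapply(dags, oracle_semantic_contributions, delta_sem = delta_sem)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ci <- contribs[[i]]
      cj <- contribs[[j]]
      num <- 0
      for (t in names(ci)) {
        if (t %in% names(cj)) num <- num + ci[[t]] + cj[[t]]
      }
      out[i, j] <- num / (sum(ci) + sum(cj))
    }
  }
  out
}

oracle_mfs <- function(dtt, dss) {
  n <- length(dtt)
  ids <- names(dtt)
  ss <- function(d, set) {
    best <- -Inf
    for (x in set) best <- max(best, dss[d, x])
    best
  }
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tot <- 0
      for (d in dtt[[i]]) tot <- tot + ss(d, dtt[[j]])
      for (d in dtt[[j]]) tot <- tot + ss(d, dtt[[i]])
      out[i, j] <- tot / (length(dtt[[i]]) + length(dtt[[j]]))
    }
  }
  out
}

oracle_gip <- function(A, space, gamma_prime = 1) {
  P <- if (space == "disease") A else t(A)
  n <- nrow(P)
  tot <- 0
  for (i in seq_len(n)) tot <- tot + sum(P[i, ]^2)
  gamma <- gamma_prime / (tot / n)
  out <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
    }
  }
  out
}

oracle_integrate <- function(primary, gip) {
  n <- nrow(primary)
  out <- matrix(0, n, n, dimnames = dimnames(primary))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- if (i == j) 1 else if (primary[i, j] > 0) primary[i, j] else gip[i, j]
    }
  }
  out
}

# triple-loop WKNKN under the documented rules
oracle_wknkn <- function(A, sim_d, sim_m, k, r) {
  n_d <- nrow(A)
  n_m <- ncol(A)
  neighbors <- function(idx, labels, sim_row, known) {
    cand <- setdiff(labels[known], labels[idx])
    cand[order(-sim_row[cand], cand)][seq_len(min(k, length(cand)))]
  }
  Yd <- matrix(0, n_d, n_m)
  for (i in seq_len(n_d)) {
    nb <- neighbors(i, rownames(A), sim_d[i, ], rowSums(A) > 0)
    if (length(nb) == 0) next
    denom <- sum(sim_d[i, nb])
    if (denom == 0) next
    for (j in seq_len(n_m)) {
      acc <- 0
      for (t in seq_along(nb)) {
        acc <- acc + r^(t - 1) * sim_d[i, nb[t]] * A[nb[t], j]
      }
      Yd[i, j] <- acc / denom
    }
  }
  Ym <- matrix(0, n_d, n_m)
  for (j in seq_len(n_m)) {
    nb <- neighbors(j, colnames(A), sim_m[j, ], colSums(A) > 0)
    if (length(nb) == 0) next
    denom <- sum(sim_m[j, nb])
    if (denom == 0) next
    for (i in seq_len(n_d)) {
      acc <- 0
      for (t in seq_along(nb)) {
        acc <- acc + r^(t - 1) * sim_m[j, nb[t]] * A[i, nb[t]]
      }
      Ym[i, j] <- acc / denom
    }
  }
  out <- A
  for (i in seq_len(n_d)) {
    for (j in seq_len(n_m)) {
      if (A[i, j] != 1) out[i, j] <- min(1, (Yd[i, j] + Ym[i, j]) / 2)
    }
  }
  out
}

oracle_base_adjacencies <- function(isd, a_new, ism) {
  n_d <- nrow(a_new)
  n_m <- ncol(a_new)
  db <- matrix(0, n_d, n_m)
  mb <- matrix(0, n_d, n_m)
  for (i in seq_len(n_d)) {
    for (j in seq_len(n_m)) {
      for (kk in seq_len(n_d)) db[i, j] <- db[i, j] + isd[i, kk] * a_new[kk, j]
      for (kk in seq_len(n_m)) mb[i, j] <- mb[i, j] + a_new[i, kk] * ism[kk, j]
    }
  }
  dimnames(db) <- dimnames(a_new)
  dimnames(mb) <- dimnames(a_new)
  list(disease_base = db, mirna_base = mb)
}

oracle_inter <- function(a_new, base, phi, direction) {
  n_d <- nrow(a_new)
  n_m <- ncol(a_new)
  out <- matrix(0, n_d, n_m, dimnames = dimnames(a_new))
  if (direction == "dm") {
    for (i in seq_len(n_d)) {
      denom <- 0
      for (l in seq_len(n_m)) denom <- denom + a_new[i, l] * base[i, l]
      if (denom == 0) next
      for (j in seq_len(n_m)) out[i, j] <- phi * a_new[i, j] * base[i, j] / denom
    }
  } else {
    for (j in seq_len(n_m)) {
      denom <- 0
      for (l in seq_len(n_d)) denom <- denom + a_new[l, j] * base[l, j]
      if (denom == 0) next
      for (i in seq_len(n_d)) out[i, j] <- phi * a_new[i, j] * base[i, j] / denom
    }
  }
  out
}

oracle_intra <- function(sim, a_new, phi, space) {
  n <- nrow(sim)
  connected <- if (space == "disease") rowSums(a_new) > 0 else colSums(a_new) > 0
  out <- matrix(0, n, n, dimnames = dimnames(sim))
  for (i in seq_len(n)) {
    denom <- sum(sim[i, ])
    if (denom == 0) next
    for (j in seq_len(n)) {
      v <- sim[i, j] / denom
      out[i, j] <- if (connected[i]) (1 - phi) * v else v
    }
  }
  out
}

oracle_p0 <- function(n_d, n_m, delta) {
  n <- n_d + n_m
  out <- matrix(0, n, n)
  for (i in seq_len(n_d)) out[i, i] <- (1 - delta) / n_d
  for (j in seq_len(n_m)) out[n_d + j, n_d + j] <- delta / n_m
  out
}

# exact unrolled recurrence via explicit matrix powers:
# P_t = (1-g)^t W^t P0 + g * sum_{k=0..t-1} (1-g)^k W^k P0
oracle_propagate <- function(W, p0, gamma, t_max) {
  n <- nrow(W)
  Wk <- diag(n) # W^0
  acc <- matrix(0, n, n)
  for (k in 0:(t_max - 1)) {
    acc <- acc + (1 - gamma)^k * (Wk %*% p0)
    Wk <- Wk %*% W
  }
  (1 - gamma)^t_max * (Wk %*% p0) + gamma * acc
}

oracle_combine <- function(p1, p2, delta, n_d, n_m) {
  P <- (1 - delta) * p1 + delta * p2
  tr <- P[1:n_d, n_d + 1:n_m, drop = FALSE]
  bl <- P[n_d + 1:n_m, 1:n_d, drop = FALSE]
  (tr + t(bl)) / 2
}

# Mann-Whitney pair-counting AUC with half credit for ties
oracle_auc_mww <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# -- random instance generators for oracle sweeps ---------------------------

rand_sim <- function(n, ids, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    m
  })
}

rand_assoc <- function(n_d, n_m, seed, density = 0.3) {
  withr::with_seed(seed, {
    A <- matrix(stats::rbinom(n_d * n_m, 1, density), n_d, n_m)
    if (sum(A) == 0) A[1, 1] <- 1
    dimnames(A) <- list(paste0("d", seq_len(n_d)), paste0("m", seq_len(n_m)))
    A
  })
}

# random DAG over <= n nodes: nodes may only point to lower-numbered nodes,
# which guarantees acyclicity; returns the edge data frame
rand_dag_edges <- function(n, seed, p_edge = 0.4) {
  withr::with_seed(seed, {
    ids <- paste0("t", seq_len(n))
    edges <- NULL
    for (child in seq(2, n)) {
      parents <- which(stats::runif(child - 1) < p_edge)
      if (length(parents) == 0) parents <- sample(seq_len(child - 1), 1)
      edges <- rbind(edges, data.frame(
        child = ids[child], parent = ids[parents]
      ))
    }
    edges
  })
}
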