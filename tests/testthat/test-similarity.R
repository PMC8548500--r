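test_that("semantic contributions decay along the best path", {
  empty_edges <- matrix(character(0), 0, 2,
    dimnames = list(NULL, c("child", "parent"))
  )
  single <- new_disease_dag("d", "d", empty_edges)
  expect_equal(semantic_contributions(single), c(d = 1))

  chain <- dags_from_edges(
    data.frame(child = c("d", "p"), parent = c("p", "g"))
  )$d
  expect_equal(
    semantic_contributions(chain, 0.5)[c("d", "p", "g")],
    c(d = 1, p = 0.5, g = 0.25)
  )

  # diamond: two equal paths to the top, max picks 0.25
  diamond <- dags_from_edges(data.frame(
    child = c("d", "d", "p1", "p2"),
    parent = c("p1", "p2", "g", "g")
  ))$d
  expect_equal(
    semantic_contributions(diamond, 0.5)[c("d", "p1", "p2", "g")],
    c(d = 1, p1 = 0.5, p2 = 0.5, g = 0.25)
  )
})

test_that("semantic contributions match the max-over-paths oracle on random DAGs", {
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(3:12, 1))
    dags <- dags_from_edges(rand_dag_edges(n, seed))
    for (term in names(dags)) {
      got <- semantic_contributions(dags[[term]], 0.5)
      want <- oracle_semantic_contributions(dags[[term]], 0.5)
      expect_equal(got[names(want)], want, tolerance = 1e-12)
    }
  }
})

test_that("disease semantic similarity reproduces the hand-derived values", {
  # identical DAGs -> similarity 1
  dags <- dags_from_edges(data.frame(child = c("a", "b"), parent = c("r", "r")))
  dss <- disease_semantic_similarity(dags, 0.5)
  expect_equal(unname(diag(dss)), rep(1, 3))

  # child-parent pair: (0.5 + 1) / ((1 + 0.5) + 1) = 0.6
  dags <- dags_from_edges(data.frame(child = "d", parent = "p"))
  dss <- disease_semantic_similarity(dags, 0.5)
  expect_equal(dss["d", "p"], 0.6)

  # disjoint DAGs share nothing
  dags <- c(
    dags_from_edges(data.frame(child = "d1", parent = "p1")),
    dags_from_edges(data.frame(child = "d2", parent = "p2"))
  )
  dss <- disease_semantic_similarity(dags[c("d1", "d2")], 0.5)
  expect_equal(dss["d1", "d2"], 0)

  expect_error(disease_semantic_similarity(list()), "empty")
})

test_that("disease semantic similarity is permutation-equivariant", {
  dags <- dags_from_edges(rand_dag_edges(8, 42))
  dss <- disease_semantic_similarity(dags, 0.5)
  perm <- withr::with_seed(7, sample(names(dags)))
  dss_p <- disease_semantic_similarity(dags[perm], 0.5)
  expect_equal(dss_p, dss[perm, perm])
})

test_that("miRNA functional similarity matches examples and the loop oracle", {
  dss <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
    dimnames = list(c("d1", "d2"), c("d1", "d2"))
  )
  expect_equal(
    mirna_functional_similarity(list(m1 = "d1", m2 = "d1"), dss)["m1", "m2"], 1
  )
  expect_equal(
    mirna_functional_similarity(list(m1 = "d1", m2 = "d2"), dss)["m1", "m2"], 0.6
  )
  mfs <- mirna_functional_similarity(
    list(m1 = "d1", m2 = c("d1", "d2")), dss
  )
  expect_equal(mfs["m1", "m2"], (1 + (1 + 0.6)) / 3)

  expect_error(
    mirna_functional_similarity(list(m1 = character(0)), dss), "empty"
  )
  expect_error(
    mirna_functional_similarity(list(m1 = "dX"), dss), "not indexed"
  )

  # random DTT sets against the double-loop oracle
  for (seed in 1:10) {
    dags <- dags_from_edges(rand_dag_edges(7, seed))
    dssr <- disease_semantic_similarity(dags, 0.5)
    dtt <- withr::with_seed(seed, {
      lapply(stats::setNames(1:5, paste0("m", 1:5)), function(i) {
        sample(rownames(dssr), sample(1:3, 1))
      })
    })
    expect_equal(mirna_functional_similarity(dtt, dssr), oracle_mfs(dtt, dssr),
      tolerance = 1e-12
    )
  }
})

test_that("GIP kernel uses the mean-profile-norm bandwidth", {
  A <- diag(2)
  dimnames(A) <- list(c("d1", "d2"), c("m1", "m2"))
  gip <- gip_similarity(A, "disease")
  expect_equal(gip["d1", "d2"], exp(-2))
  expect_equal(unname(diag(gip)), c(1, 1))

  # identical profiles and all-ones matrix: similarity 1 everywhere
  A1 <- matrix(1, 2, 2, dimnames = list(c("d1", "d2"), c("m1", "m2")))
  expect_equal(unname(gip_similarity(A1, "disease")), matrix(1, 2, 2))
  expect_equal(unname(gip_similarity(A1, "mirna")), matrix(1, 2, 2))

  expect_error(gip_similarity(A1 * 0, "disease"), "all-zero")

  # scaling gamma_prime by c raises the off-diagonal to the c-th power
  A <- rand_assoc(6, 5, 3)
  g1 <- gip_similarity(A, "disease", gamma_prime = 1)
  g3 <- gip_similarity(A, "disease", gamma_prime = 3)
  expect_equal(g3, g1^3, tolerance = 1e-12)
  expect_true(all(g3 <= g1 + 1e-15))
})

test_that("integration falls back to GIP exactly where primary is zero", {
  ids <- paste0("d", 1:3)
  primary <- matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3, 3,
    dimnames = list(ids, ids)
  )
  gip <- matrix(0.4, 3, 3, dimnames = list(ids, ids))
  diag(gip) <- 1
  out <- integrate_similarity(primary, gip)
  expect_equal(out["d1", "d2"], 0.5) # primary branch
  expect_equal(out["d1", "d3"], 0.4) # fallback branch
  expect_equal(out["d3", "d1"], 0.4) # whole zero row falls back
  expect_equal(unname(diag(out)), rep(1, 3))

  # all-positive primary passes through
  p2 <- rand_sim(4, paste0("d", 1:4), 5)
  g2 <- rand_sim(4, paste0("d", 1:4), 6)
  expect_equal(integrate_similarity(p2, g2), p2)

  # explicit mask overrides the >0 heuristic
  mask <- matrix(FALSE, 3, 3)
  out2 <- integrate_similarity(primary, gip, mask = mask)
  expect_equal(out2["d1", "d2"], 0.4)

  expect_error(integrate_similarity(primary, gip[1:2, 1:2]), "mismatch")
})

test_that("all similarity kinds are symmetric, unit-diagonal and range-valid", {
  for (seed in 1:10) {
    A <- rand_assoc(7, 6, seed)
    dags <- dags_from_edges(rand_dag_edges(7, seed))
    dss <- disease_semantic_similarity(dags, 0.5)
    dtt <- withr::with_seed(seed + 100, {
      lapply(stats::setNames(1:6, paste0("m", 1:6)), function(i) {
        sample(names(dags), sample(1:3, 1))
      })
    })
    mfs <- mirna_functional_similarity(dtt, dss)
    gip_d <- gip_similarity(A, "disease")
    gip_m <- gip_similarity(A, "mirna")
    isd <- integrate_similarity(dss[1:7, 1:7], {
      g <- gip_d
      dimnames(g) <- dimnames(dss[1:7, 1:7])
      g
    })
    for (S in list(dss, mfs, gip_d, gip_m, isd)) {
      expect_equal(S, t(S), tolerance = 1e-12)
      expect_equal(unname(diag(S)), rep(1, nrow(S)))
      expect_true(all(S >= 0 & S <= 1 + 1e-12))
    }
    expect_true(all(gip_d > 0))
    expect_true(all(gip_m > 0))
  }
})
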