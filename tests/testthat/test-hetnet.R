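fixture_small <- function(seed, n_d = 7, n_m = 5) {
  A <- rand_assoc(n_d, n_m, seed, density = 0.3)
  list(
    A = A,
    isd = rand_sim(n_d, rownames(A), seed + 50),
    ism = rand_sim(n_m, colnames(A), seed + 60)
  )
}

test_that("base adjacencies are the similarity-weighted matrix products", {
  fx <- fixture_small(1)
  base <- base_adjacencies(fx$isd, fx$A, fx$ism)

  idn <- function(ids) {
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    m
  }
  # identity similarity passes the association matrix through
  expect_equal(
    unname(base_adjacencies(idn(rownames(fx$A)), fx$A, fx$ism)$disease_base),
    unname(fx$A)
  )
  expect_equal(
    unname(base_adjacencies(fx$isd, fx$A, idn(colnames(fx$A)))$mirna_base),
    unname(fx$A)
  )

  # 2x2 hand product
  isd2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
    dimnames = list(c("d1", "d2"), c("d1", "d2"))
  )
  a2 <- diag(2)
  dimnames(a2) <- list(c("d1", "d2"), c("m1", "m2"))
  expect_equal(
    unname(base_adjacencies(isd2, a2, {
      i <- diag(2)
      dimnames(i) <- list(c("m1", "m2"), c("m1", "m2"))
      i
    })$disease_base),
    matrix(c(1, 0.5, 0.5, 1), 2, 2)
  )

  expect_error(base_adjacencies(fx$isd[1:3, 1:3], fx$A, fx$ism), "align")
})

test_that("inter-space transitions normalize rows (dm) or columns (md) to phi", {
  phi <- 0.9
  # hand case: A row (1,1,0), base row (2,1,3) -> 0.9 * (2,1,0)/3
  a <- matrix(c(1, 1, 0), 1, 3, dimnames = list("d1", paste0("m", 1:3)))
  b <- matrix(c(2, 1, 3), 1, 3, dimnames = dimnames(a))
  expect_equal(
    unname(inter_transition(a, b, phi, "dm")),
    matrix(c(0.6, 0.3, 0), 1, 3)
  )

  for (seed in 1:10) {
    fx <- fixture_small(seed)
    base <- base_adjacencies(fx$isd, fx$A, fx$ism)
    t_dm <- inter_transition(fx$A, base$mirna_base, phi, "dm")
    t_md <- inter_transition(fx$A, base$disease_base, phi, "md")
    rs <- rowSums(t_dm)
    nz <- rowSums(fx$A * base$mirna_base) > 0
    expect_equal(unname(rs[nz]), rep(phi, sum(nz)), tolerance = 1e-10)
    expect_equal(unname(rs[!nz]), rep(0, sum(!nz)))
    cs <- colSums(t_md)
    nzc <- colSums(fx$A * base$disease_base) > 0
    expect_equal(unname(cs[nzc]), rep(phi, sum(nzc)), tolerance = 1e-10)

    expect_equal(t_dm, oracle_inter(fx$A, base$mirna_base, phi, "dm"),
      tolerance = 1e-12
    )
    expect_equal(t_md, oracle_inter(fx$A, base$disease_base, phi, "md"),
      tolerance = 1e-12
    )
  }

  # an all-zero association row propagates nothing
  a0 <- matrix(0, 1, 3, dimnames = list("d1", paste0("m", 1:3)))
  expect_equal(unname(inter_transition(a0, b, phi, "dm")), matrix(0, 1, 3))
})

test_that("intra-space transitions scale connected rows by 1 - phi", {
  ids <- paste0("d", 1:3)
  sim <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.5, 0.5, 0.5, 1), 3, 3,
    dimnames = list(ids, ids)
  )
  A <- matrix(c(1, 0, 0), 3, 1, dimnames = list(ids, "m1"))
  out <- intra_transition(sim, A, 0.9, "disease")
  # connected disease: (1 - 0.9) * (1, 0.5, 0.5) / 2
  expect_equal(unname(out$W["d1", ]), c(0.05, 0.025, 0.025))
  expect_equal(sum(out$W["d1", ]), 0.1)
  # isolated disease: unscaled, sums to 1
  expect_equal(sum(out$W["d2", ]), 1)

  # an all-zero similarity row is flagged and left all-zero
  sim0 <- sim
  sim0["d3", ] <- 0
  out0 <- intra_transition(sim0, A, 0.9, "disease")
  expect_equal(out0$isolated, "d3")
  expect_equal(unname(out0$W["d3", ]), rep(0, 3))

  for (seed in 1:10) {
    fx <- fixture_small(seed)
    expect_equal(
      intra_transition(fx$isd, fx$A, 0.9, "disease")$W,
      oracle_intra(fx$isd, fx$A, 0.9, "disease"),
      tolerance = 1e-12
    )
    expect_equal(
      intra_transition(fx$ism, fx$A, 0.9, "mirna")$W,
      oracle_intra(fx$ism, fx$A, 0.9, "mirna"),
      tolerance = 1e-12
    )
  }
})

test_that("assembly places the blocks and keeps the transpose exact", {
  fx <- fixture_small(2, n_d = 2, n_m = 3)
  nets <- build_hetnets(fx$isd, fx$A, fx$ism, 0.9)
  W <- nets$disease_based
  expect_equal(dim(W$assembled), c(5, 5))
  expect_equal(unname(W$assembled[1:2, 3:5]), unname(W$T))
  expect_equal(unname(W$assembled[3:5, 1:2]), unname(t(W$T)))
  expect_equal(unname(W$assembled[1:2, 1:2]), unname(W$Wd))
  expect_equal(unname(W$assembled[3:5, 3:5]), unname(W$Wm))
  expect_true(all(W$assembled >= 0))

  # zero inter block decouples the two sub-networks
  z <- matrix(0, 2, 3)
  dec <- assemble_hetnet(W$Wd, W$Wm, z)
  expect_equal(unname(dec$assembled[1:2, 3:5]), z)
  expect_equal(unname(dec$assembled[3:5, 1:2]), t(z))

  expect_error(assemble_hetnet(W$Wd, W$Wm, matrix(0, 3, 2)), "conform")
})

test_that("connected disease rows of the disease-based network sum to one", {
  for (seed in 1:10) {
    fx <- fixture_small(seed)
    phi <- 0.9
    base <- base_adjacencies(fx$isd, fx$A, fx$ism)
    nets <- build_hetnets(fx$isd, fx$A, fx$ism, phi)
    nz <- rowSums(fx$A * base$mirna_base) > 0
    rs <- rowSums(nets$disease_based$assembled)[seq_len(nrow(fx$A))]
    expect_equal(unname(rs[nz]), rep(1, sum(nz)), tolerance = 1e-10)
  }
})
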