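test_that("pair overlap matches the Gaussian product closed forms", {
  a <- single_atom(1L)
  b <- single_atom(2L)
  # identical atoms at identity: p^2 (pi / (2 kappa))^{3/2}
  expect_equal(pair_overlap(a, b), V_SELF_ATOM, tolerance = 1e-9)
  expect_equal(self_overlap(a), V_SELF_ATOM, tolerance = 1e-9)
  # separation d: V_AA * exp(-kappa d^2 / 2)
  b1 <- single_atom(2L, c(1, 0, 0))
  expect_equal(pair_overlap(a, b1),
               V_SELF_ATOM * exp(-KAPPA_SHAPE / 2), tolerance = 1e-9)
  # essentially infinite separation
  bfar <- single_atom(2L, c(1e6, 0, 0))
  expect_lt(pair_overlap(a, bfar), 1e-12)
})

test_that("two-atom self overlap equals the 4-term double sum", {
  conf <- atom_conf(c(0, 0, 0, 1.54, 0, 0))
  k <- KAPPA_SHAPE
  term0 <- 2.7^2 * (pi / (2 * k))^1.5
  term_d <- term0 * exp(-k / 2 * 1.54^2)
  expect_equal(self_overlap(conf), 2 * term0 + 2 * term_d, tolerance = 1e-9)
})

test_that("self overlap is rigid-motion invariant", {
  set.seed(31)
  conf <- random_conformer(1L, n_atoms = 8)
  v <- self_overlap(conf)
  for (i in 1:5)
    expect_equal(self_overlap(apply_transform(random_rigid(), conf)), v,
                 tolerance = 1e-9)
})

test_that("shape Tanimoto follows its closed form and bounds", {
  a <- single_atom(1L)
  st_at <- function(d) {
    e <- exp(-KAPPA_SHAPE * d^2 / 2)
    e / (2 - e)
  }
  expect_equal(shape_tanimoto(a, single_atom(2L)), 1.0, tolerance = 1e-12)
  expect_equal(shape_tanimoto(a, single_atom(2L, c(1, 0, 0))), st_at(1),
               tolerance = 1e-9)
  expect_equal(shape_tanimoto(a, single_atom(2L, c(2, 0, 0))), st_at(2),
               tolerance = 1e-9)
  expect_lt(shape_tanimoto(a, single_atom(2L, c(1e6, 0, 0))), 1e-12)
})

test_that("ST is symmetric, invariant under common motion, and in [0,1]", {
  set.seed(41)
  for (i in 1:25) {
    a <- random_conformer(1L, n_atoms = sample(2:10, 1))
    b <- random_conformer(2L, n_atoms = sample(2:10, 1))
    tf <- random_rigid()
    st <- shape_tanimoto(a, b, tf)
    expect_gte(st, 0)
    expect_lte(st, 1)
    expect_equal(st, shape_tanimoto(b, a, invert_transform(tf)),
                 tolerance = 1e-9)
    # move both conformers by g, conjugate the pose accordingly
    g <- random_rigid()
    st2 <- shape_tanimoto(apply_transform(g, a), apply_transform(g, b),
                          compose_transform(compose_transform(g, tf),
                                            invert_transform(g)))
    expect_equal(st, st2, tolerance = 1e-9)
  }
})

test_that("analytic overlap matches grid quadrature within 1%", {
  set.seed(51)
  for (i in 1:6) {
    a <- random_conformer(1L, n_atoms = sample(2:8, 1))
    b <- random_conformer(2L, n_atoms = sample(2:8, 1))
    v <- pair_overlap(a, b)
    vg <- grid_overlap_oracle(a, b, spacing = 0.1)
    expect_equal(v, vg, tolerance = 0.01)
  }
  # quadrature converges as spacing halves (errors are tiny below ~0.5 A,
  # so the comparison uses coarse spacings where they are measurable)
  a <- chain_conf(3, cid = 1L)
  b <- chain_conf(4, cid = 2L)
  v <- pair_overlap(a, b)
  e1 <- abs(grid_overlap_oracle(a, b, spacing = 1.2) - v)
  e2 <- abs(grid_overlap_oracle(a, b, spacing = 0.6) - v)
  expect_lt(e2, e1)
})

test_that("color overlap keeps feature types independent", {
  a <- with_features(single_atom(1L), "acceptor", 1)
  b <- with_features(single_atom(2L), "donor", 1)
  terms <- color_overlap(a, b)
  expect_true(all(terms$v_ab == 0))
  expect_gt(terms$v_aa[["acceptor"]], 0)
  expect_gt(terms$v_bb[["donor"]], 0)
  expect_equal(color_tanimoto(terms), 0)
})

test_that("color overlap matches its closed forms", {
  a <- with_features(single_atom(1L), "acceptor", 1)
  b <- with_features(single_atom(2L), "acceptor", 1)
  terms0 <- color_overlap(a, b)
  expect_equal(terms0$v_ab[["acceptor"]], V_SELF_COLOR, tolerance = 1e-9)
  expect_equal(color_tanimoto(terms0), 1.0, tolerance = 1e-12)
  # same single-color pair at distance d
  bshift <- apply_transform(rigid_transform(diag(3), c(1, 0, 0)), b)
  v_ab <- color_overlap(a, bshift)$v_ab[["acceptor"]]
  expect_equal(v_ab, V_SELF_COLOR * exp(-KAPPA_COLOR / 2), tolerance = 1e-9)
  # A = {1 acceptor}, B = {1 acceptor at d, 1 donor}: CT = v_ab/(3v - v_ab)
  b2 <- single_atom(2L, c(1, 0, 0))
  b2$features <- feature_points(c("acceptor", "donor"),
                                xyz = rbind(c(1, 0, 0), c(5, 5, 5)))
  ct <- color_tanimoto(color_overlap(a, b2))
  expect_equal(ct, v_ab / (3 * V_SELF_COLOR - v_ab), tolerance = 1e-6)
  # at d = 0 that reduces to 1/2
  b0 <- single_atom(2L)
  b0$features <- feature_points(c("acceptor", "donor"),
                                xyz = rbind(c(0, 0, 0), c(5, 5, 5)))
  expect_equal(color_tanimoto(color_overlap(a, b0)), 0.5, tolerance = 1e-6)
})

test_that("color overlap matches grid quadrature on small instances", {
  set.seed(61)
  a <- with_features(chain_conf(4, cid = 1L), c("acceptor", "acceptor"),
                     c(1, 3))
  b <- with_features(chain_conf(5, cid = 2L), "acceptor", 2)
  tf <- random_rigid()
  v <- color_overlap(a, b, tf)$v_ab[["acceptor"]]
  vg <- grid_overlap_oracle(a, b, tf, spacing = 0.05, color = "acceptor")
  expect_equal(v, vg, tolerance = 0.01)
})

test_that("both-empty feature sets give CT = 0 by convention", {
  terms <- color_overlap(chain_conf(2, cid = 1L), chain_conf(3, cid = 2L))
  expect_equal(color_tanimoto(terms), 0)
  # one-sided emptiness: denominator is the featured side's self overlap
  a <- with_features(single_atom(1L), "ring", 1)
  terms1 <- color_overlap(a, chain_conf(3, cid = 2L))
  expect_equal(color_tanimoto(terms1), 0)
  expect_equal(sum(terms1$v_aa), V_SELF_COLOR, tolerance = 1e-9)
  expect_equal(sum(terms1$v_bb), 0)
})

test_that("combo Tanimoto is plain addition with range checks", {
  expect_equal(combo_tanimoto(1, 1), 2)
  expect_equal(combo_tanimoto(0.73, 0.28), 1.01)
  expect_equal(combo_tanimoto(0.4, 0), 0.4)
  expect_error(combo_tanimoto(1.2, 0))
  expect_error(combo_tanimoto(0.5, -0.1))
})
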