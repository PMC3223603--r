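test_that("principal pose centres and is deterministic", {
  set.seed(71)
  conf <- random_conformer(1L, n_atoms = 10)
  tf <- principal_pose(conf)
  centred <- apply_transform(tf, conf)
  # already-canonical conformer maps to identity
  tf2 <- principal_pose(centred)
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-7)
  expect_equal(tf2$translation, c(0, 0, 0), tolerance = 1e-9)
  # translated copy recovers a pure translation
  moved <- apply_transform(rigid_transform(diag(3), c(5, -2, 1)), centred)
  tf3 <- principal_pose(moved)
  expect_equal(tf3$rotation, diag(3), tolerance = 1e-7)
  expect_equal(tf3$translation, -c(5, -2, 1), tolerance = 1e-7)
  # single atom: identity rotation by convention
  tf1 <- principal_pose(single_atom(1L, c(2, 2, 2)))
  expect_equal(tf1$rotation, diag(3))
})

test_that("shape optimization recovers self-superposition exactly", {
  set.seed(81)
  conf <- random_conformer(1L)
  copy <- conf
  copy$cid <- 2L
  fit <- optimize_shape(conf, copy)
  expect_equal(fit$st, 1.0, tolerance = 1e-6)
  aligned <- apply_transform(fit$transform, copy)
  rmsd <- sqrt(mean(rowSums((aligned$xyz - conf$xyz)^2)))
  expect_lt(rmsd, 0.01)
})

test_that("shape optimization undoes a known rigid motion", {
  set.seed(91)
  for (i in 1:5) {
    conf <- random_conformer(1L, n_atoms = sample(8:30, 1))
    moved <- apply_transform(random_rigid(), conf)
    moved$cid <- 2L
    fit <- optimize_shape(conf, moved)
    expect_gte(fit$st, 0.999)
    aligned <- apply_transform(fit$transform, moved)
    rmsd <- sqrt(mean(rowSums((aligned$xyz - conf$xyz)^2)))
    expect_lt(rmsd, 0.05)
  }
})

test_that("two single atoms superpose to coincidence", {
  a <- single_atom(1L, c(1, 2, 3))
  b <- single_atom(2L, c(-4, 0, 7))
  fit <- optimize_shape(a, b)
  expect_equal(fit$st, 1.0, tolerance = 1e-9)
  expect_equal(as.numeric(fit$transform$rotation %*% c(-4, 0, 7) +
                            fit$transform$translation),
               c(1, 2, 3), tolerance = 1e-5)
})

test_that("color optimization hits CT = 1 on identical featured conformers", {
  set.seed(101)
  conf <- random_conformer(1L)
  expect_gt(nrow(conf$features), 0)
  copy <- conf
  copy$cid <- 2L
  fit <- optimize_color(conf, copy)
  expect_equal(fit$ct, 1.0, tolerance = 1e-6)
})

test_that("featureless pairs fall back to the shape pose with CT = 0", {
  a <- chain_conf(5, cid = 1L)
  b <- chain_conf(6, cid = 2L)
  s <- optimize_shape(a, b)
  co <- optimize_color(a, b)
  expect_equal(co$ct, 0)
  expect_equal(co$st, s$st, tolerance = 1e-12)
  expect_equal(co$transform$rotation, s$transform$rotation)
  rec <- score_pair(a, b)
  expect_equal(rec$ct_stopt, 0)
  expect_equal(rec$ct_ctopt, 0)
  expect_equal(rec$st_ctopt, rec$st_stopt)
})

test_that("the two optima dominate each other's cross-evaluations", {
  set.seed(111)
  for (i in 1:15) {
    a <- random_conformer(1L, n_atoms = sample(5:25, 1))
    b <- random_conformer(2L, n_atoms = sample(5:25, 1))
    rec <- score_pair(a, b)
    expect_gte(rec$st_stopt + 1e-6, rec$st_ctopt)
    expect_gte(rec$ct_ctopt + 1e-6, rec$ct_stopt)
    expect_true(all(c(rec$st_stopt, rec$ct_stopt, rec$st_ctopt,
                      rec$ct_ctopt) >= 0))
    expect_true(all(c(rec$st_stopt, rec$ct_stopt, rec$st_ctopt,
                      rec$ct_ctopt) <= 1))
  }
})

test_that("records are symmetric in input order and combo is exact addition", {
  set.seed(121)
  a <- random_conformer(1L)
  b <- random_conformer(2L)
  r1 <- score_pair(a, b)
  r2 <- score_pair(b, a)
  expect_identical(r1, r2)  # canonical cid ordering makes this bitwise
  expect_identical(r1$combo_stopt, r1$st_stopt + r1$ct_stopt)
  expect_identical(r1$combo_ctopt, r1$st_ctopt + r1$ct_ctopt)
  expect_lt(r1$cid_a, r1$cid_b)
  expect_error(score_pair(a, a), "self-pair")
})

test_that("scoring is deterministic for identical inputs", {
  set.seed(131)
  a <- random_conformer(1L, n_atoms = 12)
  b <- random_conformer(2L, n_atoms = 14)
  expect_identical(score_pair(a, b), score_pair(a, b))
})

test_that("score_matrix enumerates each unordered pair exactly once", {
  set.seed(141)
  confs <- lapply(1:4, function(i) random_conformer(i, n_atoms = 6))
  m <- score_matrix(confs)
  expect_equal(nrow(m), 6)
  expect_true(all(m$cid_a < m$cid_b))
  expect_equal(nrow(unique(m[, c("cid_a", "cid_b")])), 6)
  expect_equal(nrow(score_matrix(confs[1])), 0)
  dup <- confs
  dup[[2]]$cid <- 1L
  expect_error(score_matrix(dup), "duplicate")
  # explicit pair subset, duplicates and order collapsed
  m2 <- score_matrix(confs, pairs = rbind(c(2, 1), c(1, 2), c(3, 4)))
  expect_equal(nrow(m2), 2)
  # pair count formula at larger n (count only)
  n <- 734486
  expect_identical(n * (n - 1) / 2, 269734474855)
})

test_that("stored poses reproduce the reported scores", {
  set.seed(151)
  a <- random_conformer(1L)
  b <- random_conformer(2L)
  rec <- score_pair(a, b)
  tf <- combotan:::unflatten_transform(rec, "stopt")
  expect_equal(shape_tanimoto(a, b, tf), rec$st_stopt, tolerance = 1e-9)
  tfc <- combotan:::unflatten_transform(rec, "ctopt")
  expect_equal(color_tanimoto(color_overlap(a, b, tfc)), rec$ct_ctopt,
               tolerance = 1e-9)
})
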