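test_that("outcome classification treats everything but inactive as active space", {
  expect_equal(classify_outcome("Inactive"), "inactive")
  expect_equal(classify_outcome("inactive"), "inactive")
  expect_equal(classify_outcome("Active"), "noninactive")
  expect_equal(classify_outcome("Inconclusive"), "noninactive")
  expect_equal(classify_outcome("Probe"), "noninactive")
  expect_equal(classify_outcome(c("Active", "INACTIVE")),
               c("noninactive", "inactive"))
  expect_error(classify_outcome(""), "empty")
})

test_that("conflicting outcomes for one CID resolve to noninactive", {
  expect_warning(
    a <- assay_table(1L, "screening", c(10, 10, 11),
                     c("Active", "Inactive", "Inactive")),
    "conflicting")
  expect_length(a$outcomes, 2)
  expect_equal(classify_outcome(a$outcomes[["10"]]), "noninactive")
})

test_that("pair enumeration follows the NN/NI combinatorics", {
  a <- assay_table(1L, "confirmatory", 1:5,
                   c("Active", "Active", "Active", "Inactive", "Inactive"))
  p <- enumerate_pairs(a)
  expect_equal(p$n_nn, 3)
  expect_equal(p$n_ni, 6)
  expect_true(all(p$nn[, 1] < p$nn[, 2]))
  expect_true(all(p$ni[, 1] < p$ni[, 2]))
  expect_equal(nrow(unique(rbind(p$nn, p$ni))), 9)

  b <- assay_table(2L, "screening", 1:6,
                   c("Active", rep("Inactive", 5)))
  pb <- enumerate_pairs(b)
  expect_equal(pb$n_nn, 0)
  expect_equal(pb$n_ni, 5)

  # compounds without a 3-D description drop out of both sets
  p3 <- enumerate_pairs(a, have_3d = c(1, 2, 4))
  expect_equal(p3$n_nn, 1)
  expect_equal(p3$n_ni, 2)
})

test_that("eligibility filter keeps assays at the 6/6 boundary", {
  mk <- function(n_nn, n_ni) list(n_nn = n_nn, n_ni = n_ni)
  sets <- list(`1` = mk(6, 6), `2` = mk(5, 100), `3` = mk(0, 50),
               `4` = mk(100, 5), `5` = mk(7, 6))
  expect_equal(filter_eligible(sets), c(1L, 5L))
  expect_equal(filter_eligible(sets, min_nn = 5L), c(1L, 2L, 5L))
})

test_that("per-assay statistics match hand-computed values", {
  a <- assay_table(7L, "confirmatory", 1:4,
                   c("Active", "Active", "Inactive", "Inactive"))
  p <- enumerate_pairs(a)  # NN: (1,2); NI: (1,3),(1,4),(2,3),(2,4)
  scores <- fake_scores(c(1, 1, 1, 2, 2), c(2, 3, 4, 3, 4),
                        c(0.8, 0.6, 0.6, 0.6, 0.6))
  st <- per_aid_statistics(a, p, scores)
  expect_equal(st$st_stopt_mu_nn, 0.8)
  expect_equal(st$st_stopt_mu_ni, 0.6)
  expect_equal(st$st_stopt_mu_diff, 0.2)
  expect_equal(st$st_stopt_sd_diff, 0)

  # NN {0.7, 0.9}, NI {0.5, 0.7}: population SDs 0.1, sd_diff 0.1 sqrt(2)
  a2 <- assay_table(8L, "screening", 1:4,
                    c("Active", "Active", "Active", "Inactive"))
  p2 <- enumerate_pairs(a2)
  p2$nn <- p2$nn[1:2, , drop = FALSE]  # (1,2), (1,3)
  p2$n_nn <- 2L
  p2$ni <- p2$ni[1:2, , drop = FALSE]  # (1,4), (2,4)
  p2$n_ni <- 2L
  sc2 <- fake_scores(c(1, 1, 1, 2), c(2, 3, 4, 4), c(0.7, 0.9, 0.5, 0.7))
  st2 <- per_aid_statistics(a2, p2, sc2)
  expect_equal(st2$ct_ctopt_mu_diff, 0.2)
  expect_equal(st2$ct_ctopt_sd_nn, 0.1)
  expect_equal(st2$ct_ctopt_sd_ni, 0.1)
  expect_equal(st2$ct_ctopt_sd_diff, 0.1 * sqrt(2))
  # pooled alternative
  st2p <- per_aid_statistics(a2, p2, sc2, sd_diff = "pooled")
  expect_equal(st2p$ct_ctopt_sd_diff, sqrt(0.01 / 2 + 0.01 / 2))

  # missing score rows are an error naming the pair
  expect_error(per_aid_statistics(a, p, scores[-2, ]), "\\(1, 3\\)")
})

test_that("difference of means equals the brute-force cross-difference mean", {
  set.seed(161)
  for (i in 1:50) {
    nn <- runif(sample(2:12, 1))
    ni <- runif(sample(2:12, 1))
    # oracle: enumerate every NN x NI difference
    cross <- outer(nn, ni, `-`)
    expect_lt(abs(mean(cross) - (mean(nn) - mean(ni))), 1e-12)
  }
})

test_that("aggregation reproduces simple across-assay moments", {
  a1 <- fake_stats_row(1L, "screening", mu_diff = 0.1)
  a2 <- fake_stats_row(2L, "confirmatory", mu_diff = 0.3)
  agg <- aggregate_assay_stats(rbind(a1, a2))
  all_diff <- agg[agg$grouping == "All" & agg$measure == "combo_stopt" &
                    agg$set == "diff", ]
  expect_equal(all_diff$mu_of_mu, 0.2)
  expect_equal(all_diff$sigma_of_mu, 0.1)
  # single-assay group: mean is the value, SD is zero
  scr <- agg[agg$grouping == "screening" & agg$measure == "combo_stopt" &
               agg$set == "diff", ]
  expect_equal(scr$mu_of_mu, 0.1)
  expect_equal(scr$sigma_of_mu, 0)
  expect_equal(unique(agg$n_aids[agg$grouping == "All"]), 2)
  expect_error(aggregate_assay_stats(a1[0, ]), "no per-assay")
})

test_that("outlier bounds follow the mean +/- k sd rule", {
  rows <- do.call(rbind, lapply(1:4, function(i)
    fake_stats_row(i, "screening", mu_diff = c(0, 0, 0, 1)[i])))
  out <- find_outliers(rows, "combo_stopt", k = 1)
  expect_equal(out$mu, 0.25)
  expect_equal(out$sigma, 0.433012701892, tolerance = 1e-10)
  expect_equal(out$upper, 4L)
  expect_length(out$lower, 0)

  flat <- do.call(rbind, lapply(1:3, function(i)
    fake_stats_row(i, "other", mu_diff = 0.2)))
  expect_warning(out0 <- find_outliers(flat, "combo_stopt"), "zero variance")
  expect_length(out0$upper, 0)
  expect_length(out0$lower, 0)
})

test_that("outlier report partitions and counts per category", {
  set.seed(171)
  rows <- do.call(rbind, lapply(1:20, function(i)
    fake_stats_row(i, if (i <= 10) "screening" else "confirmatory",
                   mu_diff = c(rnorm(18, 0, 0.02), 0.5, -0.5)[i])))
  rep <- outlier_report(rows)
  for (m in combotan:::MEASURES) {
    pm <- rep$per_measure[[m]]
    expect_length(intersect(pm$lower, pm$upper), 0)
  }
  cc <- rep$category_counts
  for (m in combotan:::MEASURES) for (side in c("lower", "upper")) {
    sub <- cc[cc$measure == m & cc$side == side, ]
    expect_equal(sub$n_outliers[sub$category == "All"],
                 sum(sub$n_outliers[sub$category != "All"]))
  }
  # identical mu_diff across measures here, so overlaps are complete
  expect_equal(unname(rep$combo_opt_overlap["upper"]),
               length(rep$per_measure$combo_stopt$upper))
})

test_that("outlier ranking averages the two optimization types", {
  rows <- rbind(
    fake_stats_row(1475L, "summary", stopt_diff = 0.68, ctopt_diff = 0.46),
    fake_stats_row(672L, "confirmatory", stopt_diff = 0.45, ctopt_diff = 0.50),
    fake_stats_row(9L, "other", stopt_diff = 0.3, ctopt_diff = 0.3))
  rk <- rank_outliers(rows)
  expect_equal(rk$average, c(0.57, 0.475, 0.3))
  expect_equal(rk$aid[1], 1475L)
  expect_equal(round(rk$average[2], 2), 0.48)
  rk2 <- rank_outliers(rows, aids = c(672L, 9L))
  expect_equal(nrow(rk2), 2)
})
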