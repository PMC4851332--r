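two_region_table <- function(n_per = 60, seed = 61,
                             shape = c("rise_fall", "rise_fall")) {
  tc <- toy_identity_curve(8000, 2000)
  set.seed(seed)
  a <- simulate_dates(demographic_curve(shape[1], c(7000, 3000)), n_per, tc,
                      sites = 8, set_label = "A")
  b <- simulate_dates(demographic_curve(shape[2], c(7000, 3000)), n_per, tc,
                      sites = 8, set_label = "B")
  bind_dates(a, b)
}

test_that("label permutations preserve per-set bin counts exactly", {
  labels <- rep(c("Kanto", "Aomori", "Hokkaido"), c(87, 128, 186))
  set.seed(62)
  for (i in 1:20)
    expect_equal(c(table(permute_labels(labels))), c(table(labels)))

  # two bins, two labels: both assignments equally likely
  set.seed(63)
  firsts <- replicate(4000, permute_labels(c("A", "B"))[1])
  expect_gt(stats::chisq.test(table(firsts))$p.value, 0.001)

  set.seed(64)
  p1 <- permute_labels(labels)
  set.seed(64)
  p2 <- permute_labels(labels)
  expect_identical(p1, p2)
  expect_error(permute_labels(rep("A", 5)), "two distinct")
})

test_that("the aggregate SPD is invariant and per-set results are exchangeable", {
  tab <- two_region_table()
  tc <- toy_identity_curve(8000, 2000)
  res <- perm_test(tab, tc, nsim = 30, seed = 65)

  # aggregate invariance: per-set observed SPDs sum to the total
  agg <- res$sets$A$obs_density + res$sets$B$obs_density
  expect_equal(agg, res$total_density, tolerance = 1e-12)

  # per-set bin counts match the observed binning
  bins <- make_bins(tab, 200)
  per_set <- table(bins$set_label[!duplicated(bins$bin_id)])
  expect_equal(res$sets$A$n_bins, unname(per_set["A"]))
  expect_equal(res$sets$B$n_bins, unname(per_set["B"]))

  # relabelling the sets permutes the results correspondingly
  swapped <- as.data.frame(tab)
  swapped$set_label <- ifelse(swapped$set_label == "A", "B", "A")
  res_sw <- perm_test(as_date_table(swapped), tc, nsim = 30, seed = 65)
  expect_equal(res_sw$sets$B$obs_density, res$sets$A$obs_density)
  expect_equal(res_sw$sets$A$n_bins, res$sets$B$n_bins)
})

test_that("with two sets the test is symmetric and intervals mirror", {
  tab <- two_region_table(80, seed = 66,
                          shape = c("rise_fall", "uniform"))
  tc <- toy_identity_curve(8000, 2000)
  res <- perm_test(tab, tc, nsim = 100, seed = 67)
  expect_equal(res$sets$A$global_stat, res$sets$B$global_stat,
               tolerance = 1e-9)
  expect_equal(res$sets$A$pvalue, res$sets$B$pvalue)
  expect_equal(res$sets$A$obs_z, -res$sets$B$obs_z, tolerance = 1e-9)
  expect_equal(res$sets$A$pos_intervals, res$sets$B$neg_intervals)
  expect_equal(res$sets$A$neg_intervals, res$sets$B$pos_intervals)
})

test_that("two literal copies of the same bins are never called divergent", {
  tc <- toy_identity_curve(8000, 2000)
  set.seed(68)
  a <- simulate_dates(demographic_curve("rise_fall", c(7000, 3000)), 50, tc,
                      sites = 5, set_label = "A")
  b <- as.data.frame(a)
  b$set_label <- "B"
  b$site_id <- paste0(b$site_id, "b") # same dates, distinct sites
  tab <- bind_dates(a, as_date_table(b))
  res <- perm_test(tab, tc, nsim = 200, seed = 69)
  expect_gt(res$sets$A$pvalue, 0.5)
  expect_gt(res$sets$B$pvalue, 0.5)
})

test_that("perm_test validates inputs and is seed-reproducible", {
  tc <- toy_identity_curve(8000, 2000)
  single <- site_table(c(5000, 5100, 5600))
  expect_error(perm_test(single, tc, nsim = 10), "two set labels")

  tab <- two_region_table(40, seed = 70)
  r1 <- perm_test(tab, tc, nsim = 50, seed = 71)
  r2 <- perm_test(tab, tc, nsim = 50, seed = 71)
  expect_identical(r1$sets$A$pvalue, r2$sets$A$pvalue)
  expect_identical(r1$sets$B$lo, r2$sets$B$lo)

  # restricting the range clips the grid the statistics are computed on
  r3 <- perm_test(tab, tc, nsim = 50, range = c(7000, 4420), seed = 71)
  expect_equal(length(r3$grid), 7000 - 4420 + 1)
  expect_true(all(r3$grid >= 4420 & r3$grid <= 7000))
})

test_that("three-set runs give genuinely per-set answers", {
  tc <- toy_identity_curve(8000, 2000)
  set.seed(72)
  a <- simulate_dates(demographic_curve("rise_fall", c(7000, 3000)), 50, tc,
                      sites = 5, set_label = "A")
  b <- simulate_dates(demographic_curve("rise_fall", c(7000, 3000)), 50, tc,
                      sites = 5, set_label = "B")
  cc <- simulate_dates(demographic_curve("uniform", c(7000, 3000)), 50, tc,
                       sites = 5, set_label = "C")
  res <- perm_test(bind_dates(a, b, cc), tc, nsim = 100, seed = 73)
  expect_named(res$sets, c("A", "B", "C"))
  stats <- vapply(res$sets, `[[`, numeric(1), "global_stat")
  expect_gt(length(unique(round(stats, 6))), 1L)
})
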