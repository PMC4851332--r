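test_that("complete-linkage binning matches hand-computed partitions", {
  # merge 5000/5100 at height 100; adding 5350 would need height 350 > 200
  tab <- site_table(c(5000, 5100, 5350))
  bins <- make_bins(tab, h = 200)
  expect_equal(length(unique(bins$bin_id)), 2L)
  expect_equal(bins$bin_id[1], bins$bin_id[2])
  expect_false(bins$bin_id[3] == bins$bin_id[1])

  expect_equal(length(unique(make_bins(site_table(4800), 200)$bin_id)), 1L)

  # h = 0: one bin per distinct CRA; h = Inf: one bin per site
  tab2 <- site_table(c(5000, 5000, 5200, 5400))
  expect_equal(length(unique(make_bins(tab2, 0)$bin_id)), 3L)
  expect_equal(length(unique(make_bins(tab2, Inf)$bin_id)), 1L)

  # sites never share bins
  two_sites <- bind_dates(site_table(c(5000, 5010), site = "s1"),
                          site_table(c(5000, 5010), site = "s2"))
  expect_equal(length(unique(make_bins(two_sites, 200)$bin_id)), 2L)
})

test_that("binning agrees with a naive agglomerative oracle and with hclust", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(1:7, 1)
    cras <- round(runif(n, 4000, 6000), 1)
    h <- sample(c(50, 100, 200, 400), 1)
    bins <- make_bins(site_table(cras), h)
    memb <- as.integer(factor(bins$bin_id))
    expect_true(same_partition(memb, oracle_complete_linkage(cras, h)))
    if (n >= 2) {
      hc <- stats::cutree(stats::hclust(stats::dist(cras), "complete"), h = h)
      expect_true(same_partition(memb, hc))
    }
  }
})

test_that("bin partitions and SPDs are invariant to row order", {
  set.seed(42)
  tab <- simulate_dates(demographic_curve("rise_fall", c(7000, 3000)), 60,
                        toy_identity_curve(8000, 2000), sites = 6,
                        set_label = "A")
  perm <- sample(nrow(tab))
  shuffled <- as_date_table(as.data.frame(tab)[perm, ])

  tc <- toy_identity_curve(8000, 2000)
  spd1 <- sum_spd(make_bins(tab, 200), calibrate_table(tab, tc))
  spd2 <- sum_spd(make_bins(shuffled, 200), calibrate_table(shuffled, tc))
  expect_equal(spd1$density, spd2$density, tolerance = 1e-12)
  expect_equal(spd1$n_bins, spd2$n_bins)
})

test_that("bin densities pool member masses arithmetically", {
  tc <- toy_identity_curve(8000, 2000)
  a <- calibrate(5000, 20, tc)
  expect_identical(bin_density(list(a)), a)
  two <- bin_density(list(a, a))
  expect_equal(sum(two$prob), 1, tolerance = 1e-9)
  expect_equal(max(two$prob), max(a$prob), tolerance = 1e-12)

  b <- calibrate(6000, 20, tc) # disjoint support
  mix <- bin_density(list(a, b))
  expect_equal(sum(mix$prob), 1, tolerance = 1e-9)
  near <- function(y) sum(mix$prob[abs(mix$calbp - y) <= 150])
  expect_equal(near(5000), 0.5, tolerance = 1e-9)
  expect_equal(near(6000), 0.5, tolerance = 1e-9)
  expect_error(bin_density(list()), "no member")
})

test_that("SPDs conserve one unit of mass per bin and add across sets", {
  tc <- toy_identity_curve(8000, 2000)
  # one bin of two identical dates equals the single calibrated density
  tab <- site_table(c(5000, 5000), errors = 25)
  spd <- sum_spd(make_bins(tab, 200), calibrate_table(tab, tc))
  single <- calibrate(5000, 25, tc)
  expect_equal(sum(spd$density), 1, tolerance = 1e-9)
  expect_equal(max(spd$density), max(single$prob), tolerance = 1e-12)

  # k single-date bins with interior supports: total density = k
  set.seed(43)
  cras <- round(runif(12, 4000, 6000))
  tabs <- lapply(seq_along(cras), function(i)
    site_table(cras[i], site = paste0("s", i)))
  tab_k <- do.call(bind_dates, tabs)
  spd_k <- sum_spd(make_bins(tab_k, 200), calibrate_table(tab_k, tc))
  expect_equal(sum(spd_k$density), 12, tolerance = 1e-6)
  expect_equal(spd_k$n_bins, 12L)

  # additivity: union SPD = sum of per-set SPDs
  a <- site_table(c(5000, 5600), site = "sa", set = "A")
  b <- site_table(c(4400, 6100), site = "sb", set = "B")
  u <- bind_dates(a, b)
  spd_u <- sum_spd(make_bins(u, 200), calibrate_table(u, tc))
  spd_a <- sum_spd(make_bins(a, 200), calibrate_table(a, tc))
  spd_b <- sum_spd(make_bins(b, 200), calibrate_table(b, tc))
  expect_equal(spd_u$density, spd_a$density + spd_b$density,
               tolerance = 1e-12)
})

test_that("rolling mean smooths as a truncated centred window", {
  tc <- toy_identity_curve(8000, 2000)
  tab <- site_table(c(5000, 5600))
  spd <- sum_spd(make_bins(tab, 200), calibrate_table(tab, tc))

  flat <- spd
  flat$density <- rep(0.25, length(spd$grid))
  expect_equal(rolling_mean(flat, 200)$density, flat$density)
  expect_equal(rolling_mean(spd, 1)$density, spd$density)

  spike <- spd
  spike$density <- numeric(length(spd$grid))
  spike$density[2000] <- 1
  sm <- rolling_mean(spike, 201)
  expect_equal(sm$density[1900:2100], rep(1 / 201, 201), tolerance = 1e-12)
  expect_equal(sm$density[1899], 0)
  expect_equal(sm$density[2101], 0)
  # even windows centre by rounding up to the next odd width
  expect_equal(rolling_mean(spike, 200)$density, sm$density)
  expect_error(rolling_mean(spd, 0), ">= 1")
})
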