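test_that("split time interpolates M against log-time", {
  # M = 0.4 at 30,000 and 0.6 at 40,000 generations
  grid <- c(10, 30000, 40000)
  tr <- im_trajectory(grid, m = c(1, 1), N1 = c(1, 1), N2 = c(1, 1))
  attr(tr, "M_boundaries") <- c(0, 0.4, 0.6)
  expect_equal(split_time(tr), 30000 * sqrt(4 / 3) * 2, tolerance = 1e-6)

  # never-merging pair
  g <- time_grid(20)
  none <- im_trajectory(g, m = rep(0, 19), N1 = rep(2e4, 19),
                        N2 = rep(2e4, 19))
  expect_true(is.na(split_time(none)))

  # constant migration: closed form within one grid interval
  const <- im_trajectory(g, m = rep(1e-5, 19), N1 = rep(2e4, 19),
                         N2 = rep(2e4, 19))
  cross_gen <- split_time(const) / 2
  closed <- log(2) / 2e-5
  expect_lte(abs(findInterval(cross_gen, g) - findInterval(closed, g)), 1)
})

test_that("initial divergence scans from the ancient end", {
  g <- time_grid(20)
  K <- 19
  # M capped below both thresholds
  low <- im_trajectory(g, m = rep(1e-7, K), N1 = rep(2e4, K),
                       N2 = rep(2e4, K))
  expect_true(max(low$M) < 0.95)
  res <- initial_divergence_times(low)
  expect_true(all(is.na(res$time_years)))

  # crossing at a known epoch: migration shut off at 175,000 generations
  grid2 <- time_grid(40)
  m2 <- ifelse(grid2[-40] >= 175000, 2e-4, 1e-6)
  div <- im_trajectory(grid2, m = m2, N1 = rep(2e4, 39), N2 = rep(2e4, 39))
  res2 <- initial_divergence_times(div, thresholds = 0.99)
  idx <- findInterval(res2$time_years / 2, grid2)
  expect_lte(abs(idx - findInterval(175000, grid2)), 1)

  # only reaching the threshold at the oldest boundary: flagged at-limit
  m3 <- c(rep(0, 38), 10)  # all migration mass in the last interval
  lim <- im_trajectory(grid2, m = m3, N1 = rep(2e4, 39), N2 = rep(2e4, 39))
  res3 <- initial_divergence_times(lim, thresholds = 0.999)
  expect_true(res3$at_limit)
})

test_that("isolation events are maximal merged runs below the threshold", {
  g <- time_grid(40)
  K <- 39
  s <- scaling_config()
  # sub-threshold across the intervals overlapping 190-130 ka
  m <- ifelse(g[-40] < 95000 & g[-1] > 65000, 1e-12, 1e-5)
  tr <- im_trajectory(g, m = m, N1 = rep(2e4, K), N2 = rep(2e4, K))
  ev <- isolation_events(tr, s)
  expect_equal(nrow(ev), 1)
  expect_true(ev$midpoint > 130000 && ev$midpoint < 190000)

  none <- im_trajectory(g, m = rep(1e-5, K), N1 = rep(2e4, K),
                        N2 = rep(2e4, K))
  expect_equal(nrow(isolation_events(none, s)), 0)

  m2 <- rep(1e-5, K); m2[c(5, 6, 20, 21)] <- 1e-12
  two <- isolation_events(im_trajectory(g, m2, rep(2e4, K), rep(2e4, K)), s)
  expect_equal(nrow(two), 2)
  expect_true(all(diff(two$midpoint) > 0))
  expect_true(all(two$start < two$end))
})

test_that("isolation frequency histogram counts midpoints per bin", {
  g <- time_grid(40)
  K <- 39
  m <- rep(1e-5, K); m[28:29] <- 1e-12  # one event around 160 ka
  tr <- im_trajectory(g, m, rep(2e4, K), rep(2e4, K))
  hist <- isolation_frequency_histogram(rep(list(tr), 10))
  expect_equal(sum(hist$count), 10)
  expect_equal(max(hist$frequency), 1)
  mid <- isolation_events(tr)$midpoint
  bin <- hist[hist$left <= mid & hist$right > mid, ]
  expect_equal(bin$frequency, 1)
  expect_error(isolation_frequency_histogram(list()), "empty")
})

test_that("pattern classification follows the core/peripheral rules", {
  g <- time_grid(64)
  core_tr <- history_to_trajectory(scenario("core")$history, g)
  expect_equal(classify_pattern(core_tr)$label, "CORE")

  pgp_tr <- history_to_trajectory(scenario("peripheral_pgp")$history, g)
  expect_equal(classify_pattern(pgp_tr)$label, "PERIPHERAL_STRONG_PGP")

  mis8_tr <- history_to_trajectory(scenario("peripheral_mis8")$history, g)
  expect_equal(classify_pattern(mis8_tr)$label, "PERIPHERAL_STRONG_MIS8")

  flat <- im_trajectory(g, m = rep(1e-5, 63), N1 = rep(15000, 63),
                        N2 = rep(15000, 63))
  expect_equal(classify_pattern(flat)$label, "UNCLASSIFIED")

  short <- im_trajectory(time_grid(10, 10, 1e4), m = rep(1e-5, 9),
                         N1 = rep(3e4, 9), N2 = rep(3e4, 9))
  expect_error(classify_pattern(short), "cover")
})

test_that("classification is invariant to grid refinement", {
  for (nm in c("core", "peripheral_pgp", "peripheral_mis8")) {
    h <- scenario(nm)$history
    l1 <- classify_pattern(history_to_trajectory(h, time_grid(64)))$label
    l2 <- classify_pattern(history_to_trajectory(h, time_grid(256)))$label
    expect_equal(l1, l2)
  }
})

test_that("envelopes follow the stated quantile conventions and nest", {
  g <- time_grid(30)
  K <- 29
  mk <- function(n) im_trajectory(g, m = rep(1e-5, K), N1 = rep(n, K),
                                  N2 = rep(n, K))
  same <- envelope(rep(list(mk(2e4)), 3))
  expect_equal(same$ne_median, same$ne_lo_outer)
  expect_equal(same$ne_median, same$ne_hi_outer)
  expect_equal(same$ne_median, rep(2e4, 80), tolerance = 1e-9)

  five <- envelope(lapply((1:5) * 1e3, mk))
  expect_equal(unique(round(five$ne_median)), 3000)
  qs <- quantile((1:5) * 1e3, c(0.125, 0.875), type = 7, names = FALSE)
  expect_equal(unique(round(five$ne_lo_inner, 6)), qs[1])
  expect_equal(unique(round(five$ne_hi_inner, 6)), qs[2])

  set.seed(42)
  rnd <- lapply(1:7, function(i) {
    im_trajectory(g, m = 10^runif(K, -8, -4), N1 = 10^runif(K, 3, 5),
                  N2 = 10^runif(K, 3, 5))
  })
  env <- envelope(rnd)
  for (v in c("m", "ne")) {
    expect_true(all(env[[paste0(v, "_lo_outer")]] <=
                      env[[paste0(v, "_lo_inner")]] + 1e-9))
    expect_true(all(env[[paste0(v, "_lo_inner")]] <=
                      env[[paste0(v, "_median")]] + 1e-9))
    expect_true(all(env[[paste0(v, "_median")]] <=
                      env[[paste0(v, "_hi_inner")]] + 1e-9))
    expect_true(all(env[[paste0(v, "_hi_inner")]] <=
                      env[[paste0(v, "_hi_outer")]] + 1e-9))
  }
  expect_error(envelope(list(mk(1e4))), "two")
})

test_that("time scaling converts between unit systems", {
  s <- scaling_config()
  expect_equal(scale_times(7.1e-5, s, "scaled", "generations"), 10000)
  expect_equal(scale_times(7.1e-5, s, "scaled", "years"), 20000)
  expect_equal(scale_times(4900, s, "generations", "years"), 9800)
  expect_equal(scale_times(9800, s, "years", "generations"), 4900)
  expect_equal(scaled_rate_to_size(1 / 2.84e-4, s), 20000)
})

test_that("group comparisons gate on normality and adjust within family", {
  set.seed(5)
  same <- data.frame(v = rep(c(2, 4, 6, 8, 10), 2),
                     grp = rep(c("a", "b"), each = 5))
  res <- compare_groups(same, "v", "grp", mode = "wilcoxon")
  expect_equal(res$p_value, 1)
  expect_equal(res$p_adjusted, 1)

  sep <- data.frame(v = c(1:10, 101:110),
                    grp = rep(c("a", "b"), each = 10))
  res2 <- compare_groups(sep, "v", "grp", mode = "wilcoxon")
  expect_equal(res2$p_value, 2 / choose(20, 10))

  # Shapiro gate: heavy-tailed samples fall back to the rank test
  set.seed(11)
  sk <- data.frame(v = c(rexp(30)^3, rexp(30)^3),
                   grp = rep(c("a", "b"), each = 30))
  expect_equal(compare_groups(sk, "v", "grp")$method, "wilcoxon")
  nm <- data.frame(v = rnorm(60), grp = rep(c("a", "b"), each = 30))
  expect_equal(compare_groups(nm, "v", "grp")$method, "t")

  # BH keeps a single true effect at q = 0.05 among null comparisons
  set.seed(21)
  dat <- data.frame(
    v = c(rnorm(50), rnorm(50), rnorm(50), rnorm(50, mean = 2)),
    grp = rep(c("a", "b", "c", "d"), each = 50))
  fam <- compare_groups(dat, "v", "grp")
  hit <- fam[(fam$group1 == "d" | fam$group2 == "d"), ]
  expect_true(all(hit$p_adjusted < 0.05))
})

test_that("divergence-time ordering follows monotone M", {
  g <- time_grid(40)
  K <- 39
  set.seed(9)
  for (i in 1:5) {
    tr <- im_trajectory(g, m = 10^runif(K, -6, -3.5), N1 = rep(2e4, K),
                        N2 = rep(2e4, K))
    st <- split_time(tr)
    idt <- initial_divergence_times(tr)
    vals <- c(st, idt$time_years[idt$threshold == 0.99],
              idt$time_years[idt$threshold == 0.999])
    vals <- vals[!is.na(vals)]
    expect_true(all(diff(vals) >= -1e-9))
  }
})
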