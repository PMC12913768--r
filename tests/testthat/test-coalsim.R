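test_that("coalescence-time sampling matches exponential theory", {
  h <- epoched_history(0, 10000, 10000, 0)
  draws <- sample_tmrca(h, "BOTH_IN_1", 1e6, seed = 42)
  expect_false(any(draws$censored))
  expect_lt(abs(mean(draws$time) / 20000 - 1), 0.01)

  split <- sample_tmrca(h, "SPLIT", 1000, horizon = 1e6, seed = 1)
  expect_true(all(split$censored))
  expect_true(all(split$time == 1e6))

  again <- sample_tmrca(h, "BOTH_IN_1", 1000, seed = 9)
  expect_identical(sample_tmrca(h, "BOTH_IN_1", 1000, seed = 9)$time,
                   again$time)
})

test_that("censoring fraction equals model survival at the horizon", {
  h <- epoched_history(c(0, 2000), N1 = c(5e3, 2e4), N2 = c(5e3, 2e4),
                       m = c(1e-5, 1e-4))
  draws <- sample_tmrca(h, "BOTH_IN_1", 5e4, horizon = 3e4, seed = 3)
  s_model <- model_survival(h, 3e4, "BOTH_IN_1")
  se <- sqrt(s_model * (1 - s_model) / 5e4)
  expect_lt(abs(mean(draws$censored) - s_model), 4 * se)
})

test_that("occurrence/exposure hazards are unbiased and flag empty bins", {
  h <- epoched_history(0, 10000, 10000, 0)  # rate 5e-5
  draws <- sample_tmrca(h, "BOTH_IN_1", 1e5, seed = 12)
  grid <- time_grid(20, from = 100, to = 1e5)
  eh <- empirical_hazard(draws, grid)
  early <- which(eh$left < 2e4 & eh$events > 10)
  se <- sqrt(eh$events[early]) / eh$exposure[early]
  expect_true(all(abs(eh$hazard[early] - 5e-5) < 3 * se))

  # zero events over positive exposure is hazard 0, not NA
  few <- structure(tibble::tibble(time = c(50, 60), censored = c(FALSE, FALSE),
                                  start = "BOTH_IN_1", block = 1L),
                   class = c("tmrca_sample", class(tibble::tibble())))
  eh2 <- empirical_hazard(few, c(0, 10, 100))
  expect_equal(eh2$hazard[1], 0)
  # no draw reaches a late bin: undefined, not zero
  eh3 <- empirical_hazard(few, c(0, 100, 1000))
  expect_true(is.na(eh3$hazard[2]))
})

test_that("block bootstrap reproduces the 30 x 100 design", {
  h <- epoched_history(0, 10000, 10000, 0)
  draws <- sample_tmrca(h, "BOTH_IN_1", 3000, n_blocks = 30, seed = 5)
  reps <- block_bootstrap(draws, seed = 17)
  expect_length(reps, 100)
  expect_true(all(vapply(reps, nrow, numeric(1)) > 0))

  # degenerate blocks: every replicate has the original hazard curve
  const <- draws
  const$time <- rep(1000, nrow(const))
  const$censored <- FALSE
  grid <- c(0, 500, 1500, 5000)
  h0 <- empirical_hazard(const, grid)$hazard
  for (r in block_bootstrap(const, n_reps = 5, seed = 2)) {
    expect_equal(empirical_hazard(r, grid)$hazard, h0)
  }

  # replicate-to-replicate spread shrinks with more blocks
  spread <- function(nb) {
    d <- sample_tmrca(h, "BOTH_IN_1", 5000, n_blocks = nb, seed = 8)
    reps <- block_bootstrap(d, n_blocks = nb, n_reps = 40, seed = 4)
    sd(vapply(reps, function(r) mean(r$time), numeric(1)))
  }
  expect_gt(spread(10), spread(100))
})

test_that("scenario presets encode the stated demographic regimes", {
  core <- scenario("core")
  expect_true(all(core$history$N1[core$history$start < 225000] >= 20000))
  pgp <- scenario("peripheral_pgp")
  ep <- pgp$history[pgp$history$start == 65000, ]
  expect_equal(ep$m, 0)
  expect_equal(ep$N1 / 25000, 0.05)  # 95% reduction
  expect_equal(c(ep$start, ep$end) * 2, c(130000, 190000))  # 190-130 ka
  arc <- scenario("lgm_arctic")
  expect_equal(min(arc$history$N1) / 30000, 1 - 0.983, tolerance = 1e-3)
  expect_match(paste(pgp$notes, collapse = " "), "synthetic")
})

test_that("genotype panels realize Balding-Nichols structure", {
  regions <- data.frame(region = c("a", "b"), n_samples = c(30, 30),
                        fst = c(0, 0), selfing_f = c(0, 1))
  panel <- simulate_genotype_panel(regions, n_sites = 500, seed = 21)
  expect_identical(panel$geno,
                   simulate_genotype_panel(regions, n_sites = 500,
                                           seed = 21)$geno)
  b_rows <- panel$samples$region == "b"
  expect_equal(sum(panel$geno[b_rows, ] == 1L), 0)  # selfing_f = 1
  expect_true(all(diff(panel$map$pos[panel$map$chrom == panel$map$chrom[1]]) > 0))

  # HWE at fst = 0, selfing 0: chi-square GoF passes on >= 99% of sites
  hw <- simulate_genotype_panel(
    data.frame(region = "x", n_samples = 100, fst = 0, selfing_f = 0),
    n_sites = 2000, seed = 22)
  pvals <- apply(hw$geno, 2, function(g) {
    p <- mean(g) / 2
    if (p == 0 || p == 1) return(1)
    expd <- 100 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 1L, 3)
    suppressWarnings(stats::chisq.test(obs, p = expd / 100)$p.value)
  })
  expect_gte(mean(pvals >= 0.01), 0.985)

  # expected heterozygosity decreases with fst
  het_at <- function(f) {
    p <- simulate_genotype_panel(
      data.frame(region = "x", n_samples = 50, fst = f, selfing_f = 0),
      n_sites = 3000, seed = 30)
    q <- colMeans(p$geno) / 2
    mean(2 * q * (1 - q))
  }
  hets <- c(het_at(0), het_at(0.1), het_at(0.3))
  expect_true(all(diff(hets) < 0))

  expect_error(simulate_genotype_panel(
    data.frame(region = "x", n_samples = 5, fst = 1.2, selfing_f = 0)),
    "fst")
})

test_that("planted ROH panels honour their truth segments", {
  segs <- data.frame(sample = "s1", chrom = "chr1",
                     start = 2e6, end = 2.5e6)
  p <- plant_roh_panel(segs, c(chr1 = 5e6), snp_spacing_bp = 1000,
                       het_prob = 0.5, error_rate = 0, seed = 13)
  inside <- p$map$pos >= 2e6 & p$map$pos <= 2.5e6
  expect_equal(sum(p$geno[1, inside] == 1L), 0)
  expect_gt(mean(p$geno[1, !inside] == 1L), 0.4)
  expect_identical(p$geno,
                   plant_roh_panel(segs, c(chr1 = 5e6), 1000, 0.5, 0,
                                   seed = 13)$geno)

  # high diversity, no segments: no 35-SNP window with <= 1 het
  p2 <- plant_roh_panel(data.frame(sample = "s1", chrom = "chr1",
                                   start = 1, end = 1),
                        c(chr1 = 2e6), snp_spacing_bp = 1000,
                        het_prob = 0.5, error_rate = 0.5, seed = 14)
  g <- p2$geno[1, ]
  win_hets <- vapply(seq_len(length(g) - 34), function(i) {
    sum(g[i:(i + 34)] == 1L)
  }, numeric(1))
  expect_true(all(win_hets > 1))
})
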