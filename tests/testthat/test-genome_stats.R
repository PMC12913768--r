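make_panel <- function(geno_rows, pos, chrom = "chr1", regions = NULL) {
  geno <- do.call(rbind, geno_rows)
  ids <- sprintf("s%d", seq_len(nrow(geno)))
  rownames(geno) <- ids
  if (is.null(regions)) regions <- rep("r1", nrow(geno))
  genotype_panel(geno, tibble::tibble(chrom = chrom, pos = pos),
                 tibble::tibble(sample = ids, region = regions))
}

test_that("ROH detection applies the scanning-window rules", {
  pos <- seq(1000, by = 2000, length.out = 40)  # 40 SNPs over ~80 kb
  clean <- make_panel(list(rep(0L, 40)), pos)
  seg <- detect_roh(clean)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(pos[1], pos[40]))
  expect_equal(seg$n_snps, 40L)

  # two hets in every window suppress all candidate SNPs
  g2 <- rep(0L, 40); g2[c(10, 15, 22, 29)] <- 1L
  expect_equal(nrow(detect_roh(make_panel(list(g2), pos))), 0)

  # a 600 kb gap splits the run; both halves fail the 35-SNP minimum
  pos3 <- c(seq(1000, by = 2000, length.out = 20),
            seq(700000, by = 2000, length.out = 20))
  expect_equal(nrow(detect_roh(make_panel(list(rep(0L, 40)), pos3))), 0)
  # with 40 SNPs per side the halves qualify separately
  pos4 <- c(seq(1000, by = 2000, length.out = 40),
            seq(800000, by = 2000, length.out = 40))
  segs4 <- detect_roh(make_panel(list(rep(0L, 80)), pos4))
  expect_equal(nrow(segs4), 2)

  # sparse SNPs violate the 100 kb/SNP density cap
  pos5 <- seq(1, by = 150000, length.out = 40)
  expect_equal(nrow(detect_roh(make_panel(list(rep(0L, 40)), pos5))), 0)
})

test_that("ROH detection equals the brute-force reference on random panels", {
  set.seed(33)
  for (i in 1:12) {
    n <- sample(40:400, 1)
    span <- sample(c(1e5, 1e6, 5e6), 1)
    pos <- sort(sample.int(span, n))
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.55, 0.15, 0.25, 0.05))
    # plant a homozygous stretch so segments actually occur
    if (n > 60) {
      a <- sample(1:(n - 50), 1)
      g[a:(a + 49)] <- sample(c(0L, 2L), 50, replace = TRUE)
    }
    mine <- detect_roh(make_panel(list(g), pos))
    ref <- brute_roh(g, pos)
    expect_equal(nrow(mine), nrow(ref))
    if (nrow(ref)) {
      expect_equal(mine$start, ref$start)
      expect_equal(mine$end, ref$end)
      expect_equal(mine$n_snps, ref$n_snps)
    }
  }
})

test_that("F_ROH is the genome fraction in runs of homozygosity", {
  segs <- tibble::tibble(sample = "s1", chrom = "chr1",
                         start = 1, end = 21929137)
  expect_equal(f_roh(segs)$f_roh, 0.1, tolerance = 1e-6)
  expect_equal(f_roh(segs[0, ], samples = "s2")$f_roh, 0)
  whole <- tibble::tibble(sample = "s1", chrom = "chr1",
                          start = 1, end = 219291370)
  expect_equal(f_roh(whole)$f_roh, 1)
})

test_that("F_IS matches its method-of-moments definition", {
  # every sample heterozygous at every site, p = 0.5
  pos <- seq(1000, by = 1000, length.out = 50)
  allhet <- make_panel(rep(list(rep(1L, 50)), 6), pos)
  res <- f_is(allhet, "r1")
  n_chr <- 12
  e_site <- 1 - 2 * 0.25 * n_chr / (n_chr - 1)
  expect_equal(res$per_sample$f,
               rep((0 - 50 * e_site) / (50 - 50 * e_site), 6))
  expect_lt(res$f_is, 0)

  # fully homozygous panel, every site polymorphic at p = 0.5: F = 1
  hom <- make_panel(c(rep(list(rep(0L, 50)), 3), rep(list(rep(2L, 50)), 3)),
                    pos)
  expect_equal(f_is(hom, "r1")$f_is, 1)

  expect_error(f_is(make_panel(rep(list(rep(1L, 50)), 3), pos), "r1"),
               "at least 4")

  # random-mating panel: regional median within 0.02 of zero
  pan <- simulate_genotype_panel(
    data.frame(region = "r", n_samples = 40, fst = 0, selfing_f = 0),
    n_sites = 10000, seed = 44)
  expect_lt(abs(f_is(pan, "r")$f_is), 0.02)
})

test_that("nucleotide diversity equals brute-force pairwise differences", {
  pos <- seq(1000, by = 1000, length.out = 3)
  # 5 diploids: one site at p = 0.5, one fixed, one low-frequency
  rows <- list(c(2L, 0L, 1L), c(2L, 0L, 0L), c(1L, 0L, 0L),
               c(0L, 0L, 0L), c(0L, 0L, 0L))
  panel <- make_panel(rows, pos)
  pi_pkg <- nucleotide_diversity(panel, callable_sites = 1000)$pi
  geno <- do.call(rbind, rows)
  brute <- 0
  for (j in 1:3) {
    haps <- unlist(lapply(geno[, j], function(g) {
      c(rep(1, g), rep(0, 2 - g))
    }))
    if (length(unique(haps)) > 1) brute <- brute + brute_pi_site(haps)
  }
  expect_equal(pi_pkg, brute / 1000, tolerance = 1e-12)

  # the single-site closed form: p = 0.5 in 10 haplotypes over 1000 sites
  one <- make_panel(list(2L, 2L, 1L, 0L, 0L), 1000)
  expect_equal(nucleotide_diversity(one, callable_sites = 1000)$pi,
               2 * 0.25 * 10 / 9 / 1000, tolerance = 1e-12)

  # estimator depends on allele frequencies only, not on het arrangement
  arr1 <- make_panel(list(c(1L), c(1L), c(1L), c(1L)), 1000)
  arr2 <- make_panel(list(c(2L), c(2L), c(0L), c(0L)), 1000)
  expect_equal(nucleotide_diversity(arr1)$pi, nucleotide_diversity(arr2)$pi)
})

test_that("Weir-Cockerham theta behaves at the boundaries and recovers truth", {
  pos <- seq(1000, by = 1000, length.out = 20)
  fixed <- make_panel(c(rep(list(rep(0L, 20)), 5), rep(list(rep(2L, 20)), 5)),
                      pos, regions = rep(c("a", "b"), each = 5))
  expect_equal(weighted_fst(fixed, "a", "b"), 1)

  set.seed(3)
  g <- matrix(rbinom(20 * 20, 2, 0.4), nrow = 20)
  same <- genotype_panel(
    g, tibble::tibble(chrom = "chr1", pos = pos),
    tibble::tibble(sample = sprintf("s%d", 1:20),
                   region = rep(c("a", "b"), each = 10)))
  expect_lt(abs(weighted_fst(same, "a", "b")), 0.05)

  # invariance to site order and allele-label swaps
  pan <- simulate_genotype_panel(
    data.frame(region = c("a", "b"), n_samples = c(15, 15),
               fst = c(0.2, 0.2), selfing_f = c(0, 0)),
    n_sites = 2000, seed = 55)
  theta <- weighted_fst(pan, "a", "b")
  expect_lt(abs(theta - 0.2), 0.03)
  # site order: the variance components are sums over exchangeable sites
  perm <- sample(ncol(pan$geno))
  expect_equal(sum(imcoal:::wc_components(pan$geno[1:15, ],
                                          pan$geno[16:30, ])$a),
               sum(imcoal:::wc_components(pan$geno[1:15, perm],
                                          pan$geno[16:30, perm])$a))
  swapped <- 2L - pan$geno
  expect_equal(
    weighted_fst(genotype_panel(swapped, pan$map, pan$samples), "a", "b"),
    theta)

  # seeded subsampling is reproducible and respects sample counts
  expect_equal(weighted_fst(pan, "a", "b", subsample_n = 5, seed = 1),
               weighted_fst(pan, "a", "b", subsample_n = 5, seed = 1))
  expect_error(weighted_fst(pan, "a", "b", subsample_n = 50), "fewer")
})

test_that("exact heterozygote-excess test matches enumeration oracles", {
  # config-sum oracle at every allele count for n <= 10
  for (n in c(3, 5, 7, 10)) {
    for (n_alt in 0:n) {
      for (h in seq(n_alt %% 2, min(n_alt, n), by = 2)) {
        n_aa <- (n_alt - h) / 2
        p_pkg <- hwe_exact_het_p(h, n - h - n_aa, n_aa)
        p_ref <- brute_hwe_het_p(h, n - h - n_aa, n_aa)
        expect_equal(p_pkg, p_ref, tolerance = 1e-12)
      }
    }
  }
  # fully independent arrangement enumeration at small n
  for (cfg in list(c(4, 0, 0), c(3, 1, 1), c(2, 2, 0), c(5, 0, 0))) {
    expect_equal(hwe_exact_het_p(cfg[1], cfg[2], cfg[3]),
                 enumerate_hwe_het_p(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-12)
  }
  expect_equal(hwe_exact_het_p(10, 0, 0), 1024 / 184756)
  expect_equal(hwe_exact_het_p(5, 0, 0), 32 / 252)
})

test_that("the HWE filter removes heterozygote excess only", {
  pos <- c(1000, 2000, 3000)
  # site 1: 10 diploids all het (excess, removed); site 2: all hom at
  # p = 0.5 (deficit, retained); site 3: ordinary
  rows <- lapply(1:10, function(i) {
    c(1L, if (i <= 5) 0L else 2L, rbinom(1, 2, 0.5))
  })
  set.seed(2)
  panel <- make_panel(rows, pos)
  res <- hwe_het_filter(panel, alpha = 0.01)
  expect_false(res$keep[1])
  expect_true(res$keep[2])
  expect_equal(res$sites$p_min[1], 1024 / 184756)
  expect_equal(res$sites$p_min[2], 1)
  expect_equal(ncol(res$panel$geno), sum(res$keep))

  # 5 all-het diploids: p = 0.127 > 0.01, retained
  small <- make_panel(lapply(1:5, function(i) c(1L)), 1000)
  expect_true(hwe_het_filter(small, alpha = 0.01)$keep[1])
})

test_that("per-sample heterozygosity counts het calls over callable calls", {
  pos <- seq(1000, by = 1000, length.out = 4)
  panel <- make_panel(list(c(1L, 1L, 1L, 1L), c(0L, 2L, 0L, 2L),
                           c(1L, NA, 0L, 1L)), pos)
  het <- sample_heterozygosity(panel)
  expect_equal(het$heterozygosity, c(1, 0, 2 / 3))

  pan <- simulate_genotype_panel(
    data.frame(region = "r", n_samples = 30, fst = 0, selfing_f = 0.5),
    n_sites = 5000, seed = 66)
  p <- pan$truth$ancestral_p
  expected <- mean(2 * p * (1 - p) * 0.5)
  expect_lt(abs(mean(sample_heterozygosity(pan)$heterozygosity) - expected),
            0.01)
})
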