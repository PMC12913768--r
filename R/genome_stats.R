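#' Parameters for runs-of-homozygosity detection
#'
#' Defaults mirror the PLINK scanning-window parameterization
#' `--homozyg-snp 35 --homozyg-kb 50 --homozyg-density 100 --homozyg-gap
#' 500 --homozyg-window-het 1`, with the tool's documented defaults for the
#' flags not set there (hit threshold 0.05, up to 5 missing calls per
#' window).
#'
#' @param window_snps SNPs per scanning window.
#' @param max_het_per_window Heterozygous calls tolerated per window.
#' @param max_missing_per_window Missing calls tolerated per window.
#' @param hit_threshold Minimum fraction of overlapping homozygous windows
#'   for a SNP to enter a candidate run.
#' @param min_snps Minimum SNPs per reported segment.
#' @param min_length_kb Minimum segment length (kb).
#' @param max_gap_kb Gap between consecutive SNPs that splits a run (kb).
#' @param max_inverse_density_kb_per_snp Maximum kb per SNP in a segment.
#' @return List of class `roh_params`.
#' @export
roh_params <- function(window_snps = 35, max_het_per_window = 1,
                       max_missing_per_window = 5, hit_threshold = 0.05,
                       min_snps = 35, min_length_kb = 50, max_gap_kb = 500,
                       max_inverse_density_kb_per_snp = 100) {
  p <- list(window_snps = window_snps,
            max_het_per_window = max_het_per_window,
            max_missing_per_window = max_missing_per_window,
            hit_threshold = hit_threshold, min_snps = min_snps,
            min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
            max_inverse_density_kb_per_snp = max_inverse_density_kb_per_snp)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' PLINK-style scanning-window detection: a window of `window_snps`
#' consecutive SNPs is homozygous if it contains at most
#' `max_het_per_window` heterozygous and `max_missing_per_window` missing
#' calls; each SNP's hit rate is the fraction of overlapping homozygous
#' windows; SNPs at or above `hit_threshold` form candidate runs, which are
#' split at gaps larger than `max_gap_kb` and reported if they satisfy the
#' length, SNP-count and density requirements.
#'
#' @param panel A `genotype_panel` (positions sorted within chromosome).
#' @param params A [roh_params()].
#' @return Tibble with `sample`, `chrom`, `start`, `end` (bp, 1-based
#'   inclusive), `length_bp` (`end - start + 1`), `n_snps`, `n_het`.
#' @export
detect_roh <- function(panel, params = roh_params()) {
  out <- list()
  for (s in seq_len(nrow(panel$geno))) {
    id <- panel$samples$sample[s]
    for (ch in unique(panel$map$chrom)) {
      sel <- panel$map$chrom == ch
      segs <- roh_one(panel$geno[s, sel], panel$map$pos[sel], params)
      if (nrow(segs)) {
        segs$sample <- id
        segs$chrom <- ch
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          length_bp = numeric(0), n_snps = integer(0),
                          n_het = integer(0)))
  }
  dplyr::bind_rows(out) |>
    dplyr::select("sample", "chrom", "start", "end", "length_bp",
                  "n_snps", "n_het") |>
    dplyr::arrange(.data$sample, .data$chrom, .data$start)
}

roh_one <- function(g, pos, p) {
  n <- length(g)
  empty <- tibble::tibble(start = numeric(0), end = numeric(0),
                          length_bp = numeric(0), n_snps = integer(0),
                          n_het = integer(0))
  if (n < p$window_snps) return(empty)
  if (is.unsorted(pos, strictly = TRUE)) stop("unsorted positions", call. = FALSE)
  w <- p$window_snps
  nw <- n - w + 1
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ch <- c(0, cumsum(het))
  cm <- c(0, cumsum(mis))
  win_ok <- (ch[(1:nw) + w] - ch[1:nw]) <= p$max_het_per_window &
    (cm[(1:nw) + w] - cm[1:nw]) <= p$max_missing_per_window
  cw <- c(0, cumsum(win_ok))
  j <- seq_len(n)
  first_w <- pmax(1L, j - w + 1L)
  last_w <- pmin(j, nw)
  hits <- cw[last_w + 1] - cw[first_w]
  denom <- last_w - first_w + 1L
  pass <- hits / denom >= p$hit_threshold

  if (!any(pass)) return(empty)
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- list()
  for (i in which(runs$values)) {
    idx_all <- starts[i]:ends[i]
    # split at large genotype gaps
    gap_after <- diff(pos[idx_all]) > p$max_gap_kb * 1000
    grp <- cumsum(c(0, gap_after))
    for (gset in split(idx_all, grp)) {
      len <- pos[gset[length(gset)]] - pos[gset[1]] + 1
      nsnp <- length(gset)
      if (len < p$min_length_kb * 1000) next
      if (nsnp < p$min_snps) next
      if (len / nsnp > p$max_inverse_density_kb_per_snp * 1000) next
      segs[[length(segs) + 1]] <- tibble::tibble(
        start = pos[gset[1]], end = pos[gset[length(gset)]],
        length_bp = len, n_snps = nsnp, n_het = sum(het[gset]))
    }
  }
  if (!length(segs)) empty else dplyr::bind_rows(segs)
}

#' Genomic inbreeding coefficient from runs of homozygosity
#'
#' F_ROH = total ROH length divided by the genome length (default
#' 219,291,370 bp, the reference assembly including centromeres).
#'
#' @param segments Output of [detect_roh()].
#' @param samples Optional character vector of samples to report (samples
#'   without segments get F_ROH = 0).
#' @param genome_length Denominator in bp.
#' @return Tibble with `sample`, `roh_bp`, `f_roh`.
#' @export
f_roh <- function(segments, samples = NULL, genome_length = genome_length_bp) {
  tot <- segments |>
    dplyr::group_by(sample = .data$sample) |>
    dplyr::summarise(roh_bp = sum(.data$end - .data$start + 1))
  if (!is.null(samples)) {
    tot <- dplyr::left_join(tibble::tibble(sample = samples), tot,
                            by = "sample")
    tot$roh_bp[is.na(tot$roh_bp)] <- 0
  }
  dplyr::mutate(tot, f_roh = .data$roh_bp / genome_length)
}

#' Method-of-moments inbreeding coefficients within a region
#'
#' Per sample, `F = (O_hom - E_hom) / (n_sites - E_hom)` where the expected
#' homozygosity per site is `1 - 2pq * 2n/(2n - 1)` with allele frequencies
#' estimated from the region's called genotypes (the vcftools-style
#' estimator). The regional value is the median over samples; at least
#' four samples are required.
#'
#' @param panel A `genotype_panel`.
#' @param region Region name.
#' @param min_samples Minimum samples per region.
#' @return List: `per_sample` (tibble `sample`, `o_hom`, `e_hom`,
#'   `n_sites`, `f`), and `f_is` (regional median).
#' @export
f_is <- function(panel, region, min_samples = 4) {
  sel <- panel$samples$region == region
  if (sum(sel) < min_samples) {
    stop(sprintf(
      "region '%s' has %d samples; F_IS requires at least %d samples per region",
      region, sum(sel), min_samples), call. = FALSE)
  }
  geno <- panel$geno[sel, , drop = FALSE]
  called <- !is.na(geno)
  n_chr <- 2 * colSums(called)
  ac <- colSums(geno, na.rm = TRUE)
  valid <- n_chr >= 2
  pfreq <- ifelse(valid, ac / n_chr, NA_real_)
  e_site <- 1 - 2 * pfreq * (1 - pfreq) * n_chr / pmax(n_chr - 1, 1)
  e_site[!valid] <- 0
  called[, !valid] <- FALSE
  o_hom <- unname(rowSums((geno == 0L | geno == 2L) & called, na.rm = TRUE))
  e_hom <- as.vector(called %*% e_site)
  n_sites <- unname(rowSums(called))
  f <- (o_hom - e_hom) / (n_sites - e_hom)
  per_sample <- tibble::tibble(sample = panel$samples$sample[sel],
                               o_hom = o_hom, e_hom = e_hom,
                               n_sites = n_sites, f = f)
  list(per_sample = per_sample, f_is = stats::median(f))
}

#' Regional nucleotide diversity
#'
#' Per region, the mean over sites of the unbiased pairwise-difference
#' estimator `2*p*q*n/(n - 1)` (n = called haplotypes), or the sum divided
#' by `callable_sites` when a denominator is supplied.
#'
#' @param panel A `genotype_panel`.
#' @param regions Regions to report (default: all in the panel).
#' @param callable_sites Optional denominator (total callable sites).
#' @return Tibble with `region`, `n_sites`, `pi`.
#' @export
nucleotide_diversity <- function(panel, regions = NULL, callable_sites = NULL) {
  if (is.null(regions)) regions <- unique(panel$samples$region)
  purrr::map_dfr(regions, function(r) {
    geno <- panel$geno[panel$samples$region == r, , drop = FALSE]
    called <- !is.na(geno)
    n <- 2 * colSums(called)
    ac <- colSums(geno, na.rm = TRUE)
    ok <- n >= 2
    pfreq <- ac[ok] / n[ok]
    site_pi <- 2 * pfreq * (1 - pfreq) * n[ok] / (n[ok] - 1)
    denom <- if (is.null(callable_sites)) sum(ok) else callable_sites
    tibble::tibble(region = r, n_sites = sum(ok), pi = sum(site_pi) / denom)
  })
}

#' Per-sample heterozygosity
#'
#' @param panel A `genotype_panel`.
#' @return Tibble with `sample`, `n_called`, `n_het`, `heterozygosity`.
#' @export
sample_heterozygosity <- function(panel) {
  called <- !is.na(panel$geno)
  n_het <- unname(rowSums(panel$geno == 1L, na.rm = TRUE))
  n_called <- unname(rowSums(called))
  tibble::tibble(sample = panel$samples$sample,
                 n_called = n_called, n_het = n_het,
                 heterozygosity = n_het / n_called)
}

#' Weir-Cockerham weighted F_ST between two regions
#'
#' The variance-components estimator, weighted across sites as the ratio of
#' the sums of the `a` and `a + b + c` components. An optional fixed-size
#' subsample per region (seeded) mirrors designs that equalize sample
#' sizes across regional pairs.
#'
#' @param panel A `genotype_panel`.
#' @param region_a,region_b Region names.
#' @param subsample_n Optional per-region subsample size.
#' @param seed Seed for the subsample.
#' @return Weighted theta (scalar).
#' @export
weighted_fst <- function(panel, region_a, region_b, subsample_n = NULL,
                         seed = NULL) {
  pick <- function(region) {
    idx <- which(panel$samples$region == region)
    if (!is.null(subsample_n)) {
      if (length(idx) < subsample_n) {
        stop("region '", region, "' has fewer than ", subsample_n,
             " samples", call. = FALSE)
      }
      idx <- sort(sample(idx, subsample_n))
    }
    idx
  }
  idx <- if (is.null(seed)) list(pick(region_a), pick(region_b)) else {
    withr::with_seed(seed, list(pick(region_a), pick(region_b)))
  }
  comp <- wc_components(panel$geno[idx[[1]], , drop = FALSE],
                        panel$geno[idx[[2]], , drop = FALSE])
  sum(comp$a, na.rm = TRUE) / sum(comp$a + comp$b + comp$c, na.rm = TRUE)
}

# Weir-Cockerham (1984) variance components for two populations, per site.
wc_components <- function(g1, g2) {
  stat <- function(g) {
    called <- !is.na(g)
    n <- colSums(called)
    p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  s1 <- stat(g1); s2 <- stat(g2)
  r <- 2
  n_bar <- (s1$n + s2$n) / r
  ok <- s1$n >= 1 & s2$n >= 1 & n_bar > 1
  n_c <- (r * n_bar - (s1$n^2 + s2$n^2) / (r * n_bar)) / (r - 1)
  p_bar <- (s1$n * s1$p + s2$n * s2$p) / (r * n_bar)
  s2v <- (s1$n * (s1$p - p_bar)^2 + s2$n * (s2$p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (s1$n * s1$h + s2$n * s2$h) / (r * n_bar)
  a <- n_bar / n_c *
    (s2v - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2v - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2v -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Pairwise weighted F_ST across all regional pairs
#'
#' @inheritParams weighted_fst
#' @return Tibble with `region1`, `region2`, `fst`.
#' @export
pairwise_fst <- function(panel, subsample_n = NULL, seed = NULL) {
  regions <- unique(panel$samples$region)
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  seeds <- if (is.null(seed)) rep(list(NULL), length(pairs)) else {
    as.list(seed + seq_along(pairs) - 1)
  }
  purrr::map2_dfr(pairs, seeds, function(pr, sd) {
    tibble::tibble(region1 = pr[1], region2 = pr[2],
                   fst = weighted_fst(panel, pr[1], pr[2], subsample_n, sd))
  })
}

#' Exact one-sided test for heterozygote excess
#'
#' Conditional on the allele counts, the number of heterozygotes among `n`
#' diploids takes values of matching parity with probability proportional
#' to `2^h * n! / (n_AA! h! n_aa!)`; the p-value is the probability of a
#' heterozygote count at least as large as observed (no mid-p).
#'
#' @param n_het,n_hom_ref,n_hom_alt Genotype counts at the site.
#' @return One-sided p-value; 1 for monomorphic sites.
#' @examples
#' hwe_exact_het_p(10, 0, 0)  # 1024/184756
#' hwe_exact_het_p(5, 0, 0)   # 32/252
#' @export
hwe_exact_het_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  n_a <- n_het + 2 * n_hom_alt
  if (n == 0 || n_a == 0 || n_a == 2 * n) return(1)
  hs <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- hs * log(2) + lgamma(n + 1) - lgamma((n_a - hs) / 2 + 1) -
    lgamma(hs + 1) - lgamma(n - hs - (n_a - hs) / 2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hs >= n_het])
}

#' Heterozygote-excess Hardy-Weinberg site filter
#'
#' Removes a site if it shows significant heterozygote excess
#' (one-sided exact test, `p < alpha`) in any regional sample set;
#' homozygote excess never triggers removal (the one-sided test gives
#' such sites p = 1). Monomorphic sites within a region are skipped
#' (p = 1 for that region).
#'
#' @param panel A `genotype_panel`.
#' @param alpha Per-region significance threshold.
#' @return List: `panel` (sites retained), `sites` (tibble `chrom`, `pos`,
#'   `p_min`, `removed`), `keep` (logical by site).
#' @export
hwe_het_filter <- function(panel, alpha = 0.01) {
  regions <- unique(panel$samples$region)
  n_sites <- ncol(panel$geno)
  p_min <- rep(1, n_sites)
  cache <- new.env(parent = emptyenv())
  for (r in regions) {
    geno <- panel$geno[panel$samples$region == r, , drop = FALSE]
    nh <- colSums(geno == 1L, na.rm = TRUE)
    n0 <- colSums(geno == 0L, na.rm = TRUE)
    n2 <- colSums(geno == 2L, na.rm = TRUE)
    for (s in seq_len(n_sites)) {
      key <- paste(nh[s], n0[s], n2[s], sep = "_")
      p <- cache[[key]]
      if (is.null(p)) {
        p <- hwe_exact_het_p(nh[s], n0[s], n2[s])
        cache[[key]] <- p
      }
      if (p < p_min[s]) p_min[s] <- p
    }
  }
  keep <- p_min >= alpha
  filtered <- genotype_panel(panel$geno[, keep, drop = FALSE],
                             panel$map[keep, ], panel$samples, panel$truth)
  list(panel = filtered,
       sites = tibble::tibble(chrom = panel$map$chrom, pos = panel$map$pos,
                              p_min = p_min, removed = !keep),
       keep = keep)
}
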