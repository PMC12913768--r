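#' Reference genome length and chromosomes
#'
#' Total assembly length (bp) used as the F_ROH denominator, split over
#' seven chromosomes for synthetic panels.
#' @keywords internal
genome_length_bp <- 219291370

default_chrom_lengths <- function() {
  n <- 7
  base <- genome_length_bp %/% n
  len <- rep(base, n)
  len[n] <- genome_length_bp - base * (n - 1)
  stats::setNames(len, paste0("chr", seq_len(n)))
}

#' Simulate pairwise coalescence times under an IM demography
#'
#' Exact structured-coalescent simulation of the two-lineage continuous-time
#' Markov chain under a piecewise-constant two-population history, with
#' epoch-boundary-aware competing-risk waiting times. This is the
#' Monte-Carlo oracle for [model_rate_curves()] and the input source for
#' end-to-end tests.
#'
#' @param history An [epoched_history()].
#' @param start Starting configuration: `"BOTH_IN_1"`, `"BOTH_IN_2"` or
#'   `"SPLIT"`.
#' @param n Number of independent lineage pairs to simulate (>= 1).
#' @param horizon Censoring horizon in generations; pairs not coalesced by
#'   `horizon` are recorded as censored.
#' @param n_blocks Number of exchangeable blocks the draws are assigned to
#'   (round-robin), for [block_bootstrap()].
#' @param seed Optional integer seed; same seed and inputs give identical
#'   draws.
#' @return A tibble of class `tmrca_sample` with columns `time` (generations;
#'   the censoring horizon for censored pairs), `censored`, `start`, `block`.
#' @export
sample_tmrca <- function(history, start = "BOTH_IN_1", n, horizon = Inf,
                         n_blocks = 1, seed = NULL) {
  start <- match.arg(start, lineage_states[1:3])
  stopifnot(n >= 1, n_blocks >= 1, horizon > 0)
  run <- function() sample_tmrca_impl(history, start, n, horizon, n_blocks)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "seed") <- seed
  class(out) <- c("tmrca_sample", class(out))
  out
}

sample_tmrca_impl <- function(history, start, n, horizon, n_blocks) {
  s0 <- match(start, lineage_states[1:3]) - 1L
  draws <- sample_tmrca_cpp(history$start, history$N1, history$N2,
                            history$m, s0, as.integer(n), horizon)
  tibble::tibble(
    time = draws$time, censored = draws$censored,
    start = rep.int(start, n),
    block = rep_len(seq_len(n_blocks), n)
  )
}

#' Occurrence/exposure hazard estimate from coalescence-time draws
#'
#' Per grid interval, hazard = events / total time at risk; censored draws
#' contribute exposure only. Intervals with zero exposure are `NA`
#' (undefined), not zero.
#'
#' @param samples A `tmrca_sample` tibble (one starting configuration).
#' @param grid Ascending grid boundaries in generations.
#' @return Tibble with `left`, `right`, `events`, `exposure`, `hazard`.
#' @export
empirical_hazard <- function(samples, grid) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0))
  tt <- samples$time
  ev_t <- tt[!samples$censored]
  left <- grid[-length(grid)]
  right <- grid[-1]
  g <- vapply(grid, function(b) sum(pmin(tt, b)), numeric(1))
  exposure <- diff(g)
  events <- as.numeric(
    table(cut(ev_t, breaks = grid, right = FALSE))
  )
  hazard <- ifelse(exposure > 0, events / exposure, NA_real_)
  tibble::tibble(left = left, right = right, events = events,
                 exposure = exposure, hazard = hazard)
}

#' Empirical rate curves from pooled coalescence-time draws
#'
#' Builds a `rate_curves` table from draws covering up to three starting
#' configurations (`BOTH_IN_1` -> `lambda_11`, `SPLIT` -> `lambda_12`,
#' `BOTH_IN_2` -> `lambda_22`). Configurations absent from `samples` yield
#' `NA` columns.
#'
#' @param samples A `tmrca_sample` tibble; draws from several calls can be
#'   pooled with `dplyr::bind_rows()`.
#' @inheritParams empirical_hazard
#' @return A [rate_curves()] tibble in per-generation units.
#' @export
empirical_rate_curves <- function(samples, grid) {
  K <- length(grid) - 1
  one <- function(cfg) {
    sub <- samples[samples$start == cfg, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(hazard = rep(NA_real_, K),
                            events = rep(NA_real_, K),
                            exposure = rep(NA_real_, K)))
    }
    empirical_hazard(sub, grid)[c("hazard", "events", "exposure")]
  }
  h11 <- one("BOTH_IN_1"); h12 <- one("SPLIT"); h22 <- one("BOTH_IN_2")
  out <- rate_curves(grid[-length(grid)], grid[-1],
                     lambda_11 = h11$hazard,
                     lambda_12 = h12$hazard,
                     lambda_22 = h22$hazard,
                     units = "generations")
  out$events_11 <- h11$events; out$exposure_11 <- h11$exposure
  out$events_12 <- h12$events; out$exposure_12 <- h12$exposure
  out$events_22 <- h22$events; out$exposure_22 <- h22$exposure
  out
}

#' Simulate a full set of coalescence-rate curves for a population pair
#'
#' Convenience wrapper: simulates `n_per_start` pairwise coalescence times
#' for each of the three starting configurations under one demographic
#' history and converts them to empirical rate curves on `grid`.
#'
#' @inheritParams sample_tmrca
#' @param grid Ascending grid boundaries in generations.
#' @param n_per_start Draws per starting configuration.
#' @return List with elements `samples` (pooled `tmrca_sample`) and `rates`
#'   (a [rate_curves()] tibble).
#' @export
simulate_pair_rates <- function(history, grid, n_per_start = 1e5,
                                n_blocks = 1, seed = NULL,
                                horizon = max(grid)) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  samples <- dplyr::bind_rows(
    sample_tmrca(history, "BOTH_IN_1", n_per_start, horizon, n_blocks, seeds[[1]]),
    sample_tmrca(history, "SPLIT", n_per_start, horizon, n_blocks, seeds[[2]]),
    sample_tmrca(history, "BOTH_IN_2", n_per_start, horizon, n_blocks, seeds[[3]])
  )
  class(samples) <- c("tmrca_sample", class(samples))
  list(samples = samples, rates = empirical_rate_curves(samples, grid))
}

#' Block bootstrap of coalescence-time draws
#'
#' Resamples exchangeable blocks of draws with replacement, mirroring the
#' 30-blocks-resampled-100-times design used for genomic block bootstraps
#' of demographic trajectories.
#'
#' @param samples A `tmrca_sample` tibble with a `block` column.
#' @param n_blocks Blocks drawn (with replacement) per replicate.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return List of `n_reps` `tmrca_sample` tibbles.
#' @export
block_bootstrap <- function(samples, n_blocks = 30, n_reps = 100, seed = NULL) {
  blocks <- sort(unique(samples$block))
  split_idx <- split(seq_len(nrow(samples)), samples$block)
  run <- function() {
    lapply(seq_len(n_reps), function(i) {
      picked <- sample(blocks, n_blocks, replace = TRUE)
      out <- samples[unlist(split_idx[as.character(picked)], use.names = FALSE), ]
      class(out) <- unique(c("tmrca_sample", class(out)))
      out
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Demographic scenario presets
#'
#' Named two-population histories encoding the demographic regimes the
#' model targets. Times are generations before present at a 2-year
#' generation time; glacial windows follow the standard chronology
#' ([period_catalog()]).
#'
#' * `"core"`: stable N1 = N2 = 25,000 with steady migration m = 2e-5 from
#'   the present back to 450 ka (225,000 generations), consistent with an
#'   effective size floor above 20,000 through glacial cycles; panmictic
#'   ancestor beyond.
#' * `"peripheral_pgp"`: as core, but migration ceases and sizes drop by
#'   95% during the Penultimate Glacial Period (190-130 ka).
#' * `"peripheral_mis8"`: the same bottleneck placed in MIS 8 (300-243 ka).
#' * `"lgm_arctic"`: an early-Holocene split followed by a transient 98.3%
#'   decline relative to the Holocene Thermal Maximum peak, emulating
#'   leading-edge Arctic colonization.
#' * `"holocene_split"`: migration shut off 5,000 generations ago (10 ka);
#'   the closed-form median split time is 5,000 + ln(2)/(2m) generations.
#'
#' @param name Preset name.
#' @return List of class `scenario_preset` with elements `name`, `history`
#'   (an [epoched_history()]) and `notes` (per-parameter provenance).
#' @export
scenario <- function(name = c("core", "peripheral_pgp", "peripheral_mis8",
                              "lgm_arctic", "holocene_split")) {
  name <- match.arg(name)
  h <- switch(name,
    core = epoched_history(
      c(0, 225000),
      N1 = c(25000, 15000), N2 = c(25000, 15000),
      m = c(2e-5, 2.5e-4)
    ),
    peripheral_pgp = epoched_history(
      c(0, 65000, 95000, 225000),
      N1 = c(25000, 1250, 25000, 15000),
      N2 = c(25000, 1250, 25000, 15000),
      m = c(5e-6, 0, 5e-6, 2.5e-4)
    ),
    peripheral_mis8 = epoched_history(
      c(0, 121500, 150000, 225000),
      N1 = c(25000, 1250, 25000, 15000),
      N2 = c(25000, 1250, 25000, 15000),
      m = c(5e-6, 0, 5e-6, 2.5e-4)
    ),
    lgm_arctic = epoched_history(
      c(0, 1000, 3000, 4500),
      N1 = c(10000, 510, 30000, 20000),
      N2 = c(10000, 30000, 30000, 20000),
      m = c(0, 0, 3e-4, 2.5e-4)
    ),
    holocene_split = epoched_history(
      c(0, 5000),
      N1 = c(20000, 20000), N2 = c(20000, 20000),
      m = c(0, 2e-4)
    )
  )
  notes <- switch(name,
    core = c(
      "N floor above 20,000 through glacial cycles: reported core-pattern property",
      "N = 25,000, m = 2e-5, panmictic ancestor at 450 ka: synthetic choices"),
    peripheral_pgp = c(
      "isolation window 190-130 ka: Penultimate Glacial Period chronology",
      "95% size reduction depth: synthetic choice"),
    peripheral_mis8 = c(
      "isolation window 300-243 ka: MIS 8 marine-isotope chronology",
      "95% size reduction depth: synthetic choice"),
    lgm_arctic = c(
      "98.3% transient decline relative to peak HTM size: reported Arctic decline",
      "split and recovery timings: synthetic choices"),
    holocene_split = c(
      "migration cessation at 5,000 generations (10 ka): synthetic benchmark",
      "m = 2e-4 before the split: synthetic choice")
  )
  structure(list(name = name, history = h, notes = notes),
            class = "scenario_preset")
}

#' Simulate a regionally structured genotype panel
#'
#' Draws ancestral allele frequencies uniformly on \[0.05, 0.95\], regional
#' frequencies from a Balding-Nichols (beta) distribution at each region's
#' F_ST, and genotypes with a within-region inbreeding coefficient
#' `selfing_f` (P(het) = 2pq(1 - F)). Truth (frequencies and parameters) is
#' stored for estimator-recovery tests.
#'
#' @param regions Data frame with columns `region`, `n_samples`, `fst`
#'   (in \[0, 1)) and `selfing_f` (in \[0, 1\]).
#' @param n_sites Number of biallelic sites.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Optional integer seed.
#' @return A `genotype_panel`: list with `geno` (samples x sites matrix of
#'   0/1/2/NA alt-allele counts), `map` (tibble `chrom`, `pos`), `samples`
#'   (tibble `sample`, `region`) and `truth`.
#' @export
simulate_genotype_panel <- function(regions, n_sites = 1000,
                                    chrom_lengths = default_chrom_lengths(),
                                    missing_rate = 0, seed = NULL) {
  stopifnot(all(c("region", "n_samples", "fst", "selfing_f") %in% names(regions)))
  if (any(regions$fst < 0 | regions$fst >= 1)) {
    stop("`fst` must be in [0, 1)", call. = FALSE)
  }
  if (any(regions$selfing_f < 0 | regions$selfing_f > 1)) {
    stop("`selfing_f` must be in [0, 1]", call. = FALSE)
  }
  run <- function() {
    map <- random_site_map(n_sites, chrom_lengths)
    p_anc <- stats::runif(n_sites, 0.05, 0.95)
    n_reg <- nrow(regions)
    p_reg <- matrix(NA_real_, n_reg, n_sites,
                    dimnames = list(regions$region, NULL))
    for (r in seq_len(n_reg)) {
      f <- regions$fst[r]
      p_reg[r, ] <- if (f == 0) p_anc else {
        stats::rbeta(n_sites, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      }
    }
    total_n <- sum(regions$n_samples)
    geno <- matrix(NA_integer_, total_n, n_sites)
    sample_region <- rep(regions$region, regions$n_samples)
    row0 <- 0
    for (r in seq_len(n_reg)) {
      ns <- regions$n_samples[r]
      p <- p_reg[r, ]
      q <- 1 - p
      fs <- regions$selfing_f[r]
      p2 <- p^2 + fs * p * q
      p1 <- 2 * p * q * (1 - fs)
      u <- matrix(stats::runif(ns * n_sites), ns, n_sites)
      g <- matrix(0L, ns, n_sites)
      g[u < rep(p2, each = ns)] <- 2L
      g[u >= rep(p2, each = ns) & u < rep(p2 + p1, each = ns)] <- 1L
      geno[row0 + seq_len(ns), ] <- g
      row0 <- row0 + ns
    }
    if (missing_rate > 0) {
      geno[matrix(stats::runif(length(geno)) < missing_rate,
                  nrow(geno), ncol(geno))] <- NA_integer_
    }
    ids <- sprintf("S%03d", seq_len(total_n))
    rownames(geno) <- ids
    genotype_panel(
      geno = geno, map = map,
      samples = tibble::tibble(sample = ids, region = sample_region),
      truth = list(ancestral_p = p_anc, region_p = p_reg, regions = regions)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

random_site_map <- function(n_sites, chrom_lengths) {
  stopifnot(n_sites >= 1, all(chrom_lengths > 0))
  probs <- chrom_lengths / sum(chrom_lengths)
  counts <- as.vector(stats::rmultinom(1, n_sites, probs))
  pieces <- lapply(seq_along(chrom_lengths), function(i) {
    if (counts[i] == 0) return(NULL)
    tibble::tibble(
      chrom = names(chrom_lengths)[i],
      pos = sort(sample.int(chrom_lengths[[i]], counts[i]))
    )
  })
  dplyr::bind_rows(pieces)
}

#' Construct a genotype panel
#'
#' @param geno Samples x sites integer matrix of alt-allele counts
#'   (0/1/2/NA), rows named by sample.
#' @param map Tibble with `chrom`, `pos` (strictly increasing within
#'   chromosome), one row per site.
#' @param samples Tibble with `sample` and `region`.
#' @param truth Optional list of generating truth.
#' @return List of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, map, samples, truth = NULL) {
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(map))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  ok <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = all(diff(.data$pos) > 0) || dplyr::n() == 1)
  if (!all(ok$sorted)) {
    stop("positions must be strictly increasing within chromosome",
         call. = FALSE)
  }
  structure(list(geno = geno, map = map, samples = samples, truth = truth),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d sites on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

#' Build a genotype panel with planted runs of homozygosity
#'
#' Generates SNPs at a controlled density and makes genotypes heterozygous
#' with probability `het_prob` outside the truth segments; inside segments
#' heterozygotes appear only at the genotyping `error_rate`. The planted
#' segments are retained in `truth` for recovery scoring.
#'
#' @param segments Data frame of truth ROH: `sample`, `chrom`, `start`,
#'   `end` (bp, 1-based inclusive).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param snp_spacing_bp Mean spacing between SNPs.
#' @param het_prob Probability a non-ROH genotype is heterozygous.
#' @param error_rate Probability a genotype inside a truth segment is
#'   (erroneously) heterozygous.
#' @param seed Optional integer seed.
#' @return A `genotype_panel` with `truth$roh = segments`.
#' @export
plant_roh_panel <- function(segments, chrom_lengths, snp_spacing_bp = 1000,
                            het_prob = 0.5, error_rate = 0, seed = NULL) {
  stopifnot(all(c("sample", "chrom", "start", "end") %in% names(segments)))
  run <- function() {
    n_sites <- max(1, round(sum(chrom_lengths) / snp_spacing_bp))
    map <- random_site_map(n_sites, chrom_lengths)
    ids <- sort(unique(segments$sample))
    geno <- matrix(NA_integer_, length(ids), nrow(map),
                   dimnames = list(ids, NULL))
    for (i in seq_along(ids)) {
      inside <- rep(FALSE, nrow(map))
      seg <- segments[segments$sample == ids[i], , drop = FALSE]
      for (j in seq_len(nrow(seg))) {
        inside <- inside | (map$chrom == seg$chrom[j] &
                              map$pos >= seg$start[j] & map$pos <= seg$end[j])
      }
      p_het <- ifelse(inside, error_rate, het_prob)
      is_het <- stats::runif(nrow(map)) < p_het
      hom <- sample(c(0L, 2L), nrow(map), replace = TRUE)
      geno[i, ] <- ifelse(is_het, 1L, hom)
    }
    genotype_panel(
      geno = geno, map = map,
      samples = tibble::tibble(sample = ids, region = "planted"),
      truth = list(roh = tibble::as_tibble(segments))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
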