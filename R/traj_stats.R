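#' Catalog of named geological periods
#'
#' Glacial and interglacial windows in years before present: the Last
#' Glacial Maximum (22-17 ka), Penultimate Glacial Period (190-130 ka),
#' MIS 3 interstadial (59-29 ka), MIS 2 glaciation (29-14 ka), Holocene
#' Thermal Maximum (9-4 ka), and configurable MIS 8 / MIS 10 windows from
#' the standard marine-isotope chronology.
#'
#' @param mis8,mis10 Length-2 numeric windows, years before present
#'   (young, old).
#' @return Tibble of class `period_catalog` with `period`, `young`, `old`.
#' @export
period_catalog <- function(mis8 = c(243000, 300000),
                           mis10 = c(337000, 374000)) {
  out <- tibble::tribble(
    ~period, ~young, ~old,
    "HTM",    4000,   9000,
    "MIS2",  14000,  29000,
    "LGM",   17000,  22000,
    "MIS3",  29000,  59000,
    "PGP",  130000, 190000,
    "MIS8",  mis8[1], mis8[2],
    "MIS10", mis10[1], mis10[2]
  )
  stopifnot(all(out$young < out$old), !anyDuplicated(out$period))
  class(out) <- c("period_catalog", class(out))
  out
}

period_window <- function(periods, name) {
  row <- periods[periods$period == name, ]
  if (nrow(row) != 1) stop("unknown period: ", name, call. = FALSE)
  c(row$young, row$old)
}

#' Convert times and rates between unit systems
#'
#' Mutation-scaled times divide by mu to give generations; generations
#' multiply by the generation time to give years. Mutation-scaled
#' coalescence rates map to diploid sizes via `N = (1/lambda) / (2 mu)`.
#'
#' @param x Numeric values.
#' @param scaling A [scaling_config()].
#' @param from,to Units among `"scaled"`, `"generations"`, `"years"`.
#' @return Converted numeric vector.
#' @examples
#' s <- scaling_config()
#' scale_times(7.1e-5, s, "scaled", "generations")  # 10,000
#' scale_times(10000, s, "generations", "years")    # 20,000
#' @export
scale_times <- function(x, scaling = scaling_config(),
                        from = c("generations", "scaled", "years"),
                        to = c("years", "generations", "scaled")) {
  from <- match.arg(from)
  to <- match.arg(to)
  gen <- switch(from,
                scaled = x / scaling$mu,
                generations = x,
                years = x / scaling$g)
  switch(to,
         scaled = gen * scaling$mu,
         generations = gen,
         years = gen * scaling$g)
}

#' Diploid size from a mutation-scaled coalescence rate
#'
#' @param lambda_scaled Mutation-scaled rate (> 0).
#' @param scaling A [scaling_config()].
#' @return Diploid effective size `1 / (2 * mu * lambda_scaled)`.
#' @export
scaled_rate_to_size <- function(lambda_scaled, scaling = scaling_config()) {
  1 / (2 * scaling$mu * lambda_scaled)
}

# Crossing of the non-decreasing M series at `threshold`, interpolated
# linearly in M against log-time between bracketing boundaries. Returns
# generations, or NA if M never reaches the threshold.
m_crossing_generations <- function(boundaries, M, threshold) {
  if (any(diff(M) < -1e-12)) stop("M must be non-decreasing", call. = FALSE)
  if (max(M) < threshold) return(NA_real_)
  if (M[1] >= threshold) return(boundaries[1])
  j <- which(M >= threshold)[1]
  lt0 <- log(boundaries[j - 1]); lt1 <- log(boundaries[j])
  frac <- (threshold - M[j - 1]) / (M[j] - M[j - 1])
  exp(lt0 + frac * (lt1 - lt0))
}

#' Median split time of a population pair
#'
#' The youngest time at which the cumulative migration probability reaches
#' `threshold` (default 0.5, the median split time), located by linear
#' interpolation of M against log-time and converted to years.
#'
#' @param traj An [im_trajectory()] (times in generations).
#' @param scaling A [scaling_config()].
#' @param threshold Crossing threshold on M.
#' @return Split time in years, or `NA` if M never reaches the threshold.
#' @export
split_time <- function(traj, scaling = scaling_config(), threshold = 0.5) {
  gen <- m_crossing_generations(traj_boundaries(traj), traj_M(traj), threshold)
  gen * scaling$g
}

#' Initial-divergence times of a population pair
#'
#' Scanning from the ancient end toward the present, the oldest times at
#' which M first drops below each threshold (defaults 0.999 and 0.99).
#' Because M is non-decreasing this is the same crossing located by
#' [split_time()]'s interpolation; a crossing in the oldest grid interval
#' (or M only reaching the threshold at the oldest boundary) is flagged as
#' at the resolution limit.
#'
#' @inheritParams split_time
#' @param thresholds Numeric thresholds on M.
#' @return Tibble with `threshold`, `time_years` (`NA` if M stays below the
#'   threshold everywhere) and `at_limit`.
#' @export
initial_divergence_times <- function(traj, scaling = scaling_config(),
                                     thresholds = c(0.999, 0.99)) {
  b <- traj_boundaries(traj)
  M <- traj_M(traj)
  purrr::map_dfr(thresholds, function(thr) {
    gen <- m_crossing_generations(b, M, thr)
    tibble::tibble(
      threshold = thr,
      time_years = gen * scaling$g,
      at_limit = !is.na(gen) && gen >= b[length(b) - 1]
    )
  })
}

#' Isolation events of a trajectory
#'
#' Maximal runs of consecutive grid intervals whose migration rate is below
#' `m_threshold` (default 1e-7 per generation), merged across adjacent
#' intervals and reported with start, end and midpoint in years.
#'
#' @inheritParams split_time
#' @param m_threshold Migration rate below which an interval counts as
#'   isolated.
#' @return Tibble with `start`, `end`, `midpoint` (years) and `min_m`;
#'   zero rows if migration never drops below the threshold.
#' @export
isolation_events <- function(traj, scaling = scaling_config(),
                             m_threshold = 1e-7) {
  below <- traj$m < m_threshold
  if (!any(below)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          midpoint = numeric(0), min_m = numeric(0)))
  }
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  purrr::map_dfr(keep, function(i) {
    idx <- starts[i]:ends[i]
    tibble::tibble(
      start = traj$left[idx[1]] * scaling$g,
      end = traj$right[idx[length(idx)]] * scaling$g,
      min_m = min(traj$m[idx])
    )
  }) |>
    dplyr::mutate(midpoint = (.data$start + .data$end) / 2) |>
    dplyr::select("start", "end", "midpoint", "min_m")
}

#' Frequency histogram of isolation-event midpoints
#'
#' Counts event midpoints per time bin across a collection of trajectories;
#' frequencies are counts divided by the number of trajectories.
#'
#' @param trajs Non-empty list of [im_trajectory()] objects.
#' @param bins Ascending bin boundaries in years (default: the 80-point
#'   summary grid converted to years).
#' @inheritParams isolation_events
#' @return Tibble with `left`, `right` (years), `count`, `frequency`.
#' @export
isolation_frequency_histogram <- function(trajs, scaling = scaling_config(),
                                          bins = NULL, m_threshold = 1e-7) {
  if (length(trajs) == 0) stop("empty trajectory collection", call. = FALSE)
  if (is.null(bins)) bins <- time_grid(80) * scaling$g
  mids <- unlist(lapply(trajs, function(tr) {
    isolation_events(tr, scaling, m_threshold)$midpoint
  }))
  counts <- if (length(mids)) {
    as.numeric(table(cut(mids, breaks = bins, right = FALSE)))
  } else rep(0, length(bins) - 1)
  tibble::tibble(left = bins[-length(bins)], right = bins[-1],
                 count = counts, frequency = counts / length(trajs))
}

#' Classify a trajectory as core or peripheral
#'
#' Core trajectories keep an effective size of at least `core_n_floor` and
#' show no isolation event over the glacial window spanning the onset of
#' the LGM to the young edge of MIS 10; peripheral trajectories show at
#' least one isolation event or a bottleneck (a drop of at least
#' `bottleneck_drop` relative to the running pre-decline maximum of
#' `im_N1`) in that window, with a STRONG sub-label when the bottleneck
#' minimum or event midpoint falls in the PGP or MIS 8. Trajectories
#' meeting neither definition are UNCLASSIFIED.
#'
#' @inheritParams split_time
#' @param periods A [period_catalog()].
#' @param core_n_floor Effective-size floor for the core pattern.
#' @param bottleneck_drop Relative size drop defining a bottleneck.
#' @param m_threshold Isolation-event migration threshold.
#' @return List of class `pattern_label`: `label` (one of `CORE`,
#'   `PERIPHERAL_STRONG_PGP`, `PERIPHERAL_STRONG_MIS8`, `PERIPHERAL_OTHER`,
#'   `UNCLASSIFIED`) and `evidence` (window, minimum size, events,
#'   bottleneck record).
#' @export
classify_pattern <- function(traj, scaling = scaling_config(),
                             periods = period_catalog(),
                             core_n_floor = 20000, bottleneck_drop = 0.9,
                             m_threshold = 1e-7) {
  window <- c(period_window(periods, "LGM")[2], period_window(periods, "MIS10")[1])
  b_years <- traj_boundaries(traj) * scaling$g
  if (b_years[1] > window[1] || b_years[length(b_years)] < window[2]) {
    stop("trajectory does not cover the classification window", call. = FALSE)
  }
  mid_years <- (traj$left + traj$right) / 2 * scaling$g
  in_win <- traj$right * scaling$g > window[1] & traj$left * scaling$g < window[2]

  events <- isolation_events(traj, scaling, m_threshold)
  ev_in <- events[events$midpoint >= window[1] & events$midpoint <= window[2], ]

  n <- traj$im_N1
  # pre-decline maximum: running max over in-window intervals at least as
  # old; estimates beyond the window (poorly resolved deep past) do not
  # define the reference level
  n_ref <- ifelse(in_win, n, -Inf)
  premax <- pmax(n, rev(cummax(rev(n_ref))))
  drop <- 1 - n / premax
  bn <- in_win & drop >= bottleneck_drop
  bn_idx <- if (any(bn)) which(bn)[which.min(n[bn])] else NA_integer_
  bn_span <- if (is.na(bn_idx)) c(NA_real_, NA_real_) else {
    c(traj$left[bn_idx], traj$right[bn_idx]) * scaling$g
  }

  min_n_window <- min(n[in_win])
  # STRONG attribution by overlap with the stage window: robust to the
  # grid smearing step changes across interval boundaries
  overlaps <- function(lo, hi, name) {
    w <- period_window(periods, name)
    !is.na(lo) & hi > w[1] & lo < w[2]
  }

  label <- if (nrow(ev_in) > 0 || any(bn)) {
    in_pgp <- any(overlaps(ev_in$start, ev_in$end, "PGP")) ||
      isTRUE(overlaps(bn_span[1], bn_span[2], "PGP"))
    in_mis8 <- any(overlaps(ev_in$start, ev_in$end, "MIS8")) ||
      isTRUE(overlaps(bn_span[1], bn_span[2], "MIS8"))
    if (in_pgp) "PERIPHERAL_STRONG_PGP"
    else if (in_mis8) "PERIPHERAL_STRONG_MIS8"
    else "PERIPHERAL_OTHER"
  } else if (min_n_window >= core_n_floor) {
    "CORE"
  } else "UNCLASSIFIED"

  structure(list(
    label = label,
    evidence = list(window_years = window, min_n_window = min_n_window,
                    events = ev_in, bottleneck_span_years = bn_span,
                    max_drop = max(drop[in_win]))
  ), class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("<pattern_label> %s (min N in window %.0f, %d event(s))\n",
              x$label, x$evidence$min_n_window, nrow(x$evidence$events)))
  invisible(x)
}

#' Percentile envelopes of trajectory collections
#'
#' Resamples each trajectory (a step function over its grid) onto a common
#' log-spaced grid of `n_points` time points spanning the overlap of all
#' trajectories, then computes per-point empirical percentiles (the linear
#' interpolation quantile convention): the median, the 12.5-87.5% inner
#' band and the 2.5-97.5% outer band. Migration percentiles are taken in
#' log space (zeros floored at 1e-12), size percentiles in linear scale;
#' the resulting series are passed through a monotone piecewise-cubic
#' (PCHIP) interpolant in log-log space with no extrapolation.
#'
#' @param trajs List of at least two [im_trajectory()] objects.
#' @param scaling A [scaling_config()].
#' @param n_points Number of grid points of the summary grid.
#' @return Tibble of class `envelope_summary`: `time_years`, and for each
#'   of `m` and `ne`, `median`, `lo_inner`, `hi_inner`, `lo_outer`,
#'   `hi_outer`.
#' @export
envelope <- function(trajs, scaling = scaling_config(), n_points = 80) {
  if (length(trajs) < 2) stop("need at least two trajectories", call. = FALSE)
  lo <- max(vapply(trajs, function(tr) traj_boundaries(tr)[1], numeric(1)))
  hi <- min(vapply(trajs, function(tr) max(traj_boundaries(tr)), numeric(1)))
  stopifnot(hi > lo)
  pts <- exp(seq(log(lo), log(hi), length.out = n_points))

  step_at <- function(tr, what) {
    b <- traj_boundaries(tr)
    idx <- pmin(pmax(findInterval(pts, b, rightmost.closed = TRUE), 1), nrow(tr))
    tr[[what]][idx]
  }
  m_mat <- vapply(trajs, step_at, numeric(n_points), what = "m")
  n_mat <- vapply(trajs, step_at, numeric(n_points), what = "im_N1")

  qs <- c(0.025, 0.125, 0.5, 0.875, 0.975)
  m_q <- t(apply(log(pmax(m_mat, 1e-12)), 1, stats::quantile, probs = qs,
                 type = 7, names = FALSE))
  m_q <- exp(m_q)
  n_q <- t(apply(n_mat, 1, stats::quantile, probs = qs, type = 7,
                 names = FALSE))

  smooth <- function(y) {
    pos <- y > 0
    if (!all(pos)) return(y)  # log-log smoothing needs positive values
    exp(pracma::pchip(log(pts), log(y), log(pts)))
  }
  out <- tibble::tibble(
    time_years = pts * scaling$g,
    m_lo_outer = smooth(m_q[, 1]), m_lo_inner = smooth(m_q[, 2]),
    m_median = smooth(m_q[, 3]),
    m_hi_inner = smooth(m_q[, 4]), m_hi_outer = smooth(m_q[, 5]),
    ne_lo_outer = smooth(n_q[, 1]), ne_lo_inner = smooth(n_q[, 2]),
    ne_median = smooth(n_q[, 3]),
    ne_hi_inner = smooth(n_q[, 4]), ne_hi_outer = smooth(n_q[, 5])
  )
  class(out) <- c("envelope_summary", class(out))
  out
}

#' Two-group comparisons with a normality gate and FDR correction
#'
#' For each requested pair of groups, a Shapiro-Wilk test (alpha = 0.05 in
#' both groups) selects between Welch's t-test and the Wilcoxon rank-sum
#' test; Benjamini-Hochberg adjustment is applied across the family of
#' comparisons. `mode` can force one test for all pairs.
#'
#' @param data Data frame with a value column and a group column.
#' @param value,group Column names (strings).
#' @param comparisons Optional list of length-2 group vectors; default all
#'   pairs of observed groups.
#' @param mode `"auto"` (Shapiro gate), `"t"` or `"wilcoxon"`.
#' @param adjust Multiple-testing method passed to [stats::p.adjust()].
#' @return Tibble with `group1`, `group2`, `method`, `statistic`,
#'   `p_value`, `p_adjusted`, `n1`, `n2`.
#' @export
compare_groups <- function(data, value, group, comparisons = NULL,
                           mode = c("auto", "t", "wilcoxon"),
                           adjust = "BH") {
  mode <- match.arg(mode)
  v <- data[[value]]
  g <- as.character(data[[group]])
  lv <- unique(g)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lv, 2, simplify = FALSE)
  }
  res <- purrr::map_dfr(comparisons, function(pair) {
    a <- v[g == pair[1]]
    b <- v[g == pair[2]]
    use_t <- switch(mode,
      t = TRUE,
      wilcoxon = FALSE,
      auto = length(a) >= 3 && length(b) >= 3 &&
        length(unique(a)) > 1 && length(unique(b)) > 1 &&
        stats::shapiro.test(a)$p.value > 0.05 &&
        stats::shapiro.test(b)$p.value > 0.05
    )
    ht <- if (use_t) stats::t.test(a, b) else {
      suppressWarnings(stats::wilcox.test(a, b))
    }
    tibble::tibble(group1 = pair[1], group2 = pair[2],
                   method = if (use_t) "t" else "wilcoxon",
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   n1 = length(a), n2 = length(b))
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res
}
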