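#' Lineage states of the two-population pairwise coalescent
#'
#' Internal constant: the state space of the continuous-time Markov chain
#' tracking two ancestral lineages under the two-population
#' isolation-migration (IM) model. `BOTH_IN_1` / `BOTH_IN_2`: both lineages
#' in population 1 / 2; `SPLIT`: one lineage in each; `COALESCED`: absorbing.
#'
#' @keywords internal
lineage_states <- c("BOTH_IN_1", "BOTH_IN_2", "SPLIT", "COALESCED")

#' Construct a piecewise-constant two-population demographic history
#'
#' An epoched history describes a two-population isolation-migration
#' demography as a sequence of epochs tiling `[0, Inf)` in generations before
#' present. Within each epoch the diploid effective sizes `N1`, `N2` and the
#' symmetric per-lineage migration probability `m` (per generation) are
#' constant.
#'
#' @param boundaries Strictly ascending epoch start times in generations
#'   before present; the first must be 0. The last epoch is unbounded.
#' @param N1,N2 Diploid effective population sizes per epoch (finite, > 0).
#' @param m Symmetric per-lineage migration probability per generation per
#'   epoch (finite, >= 0).
#'
#' @return A tibble of class `epoched_history` with columns `start`, `end`
#'   (in generations; `Inf` for the last epoch), `N1`, `N2`, `m`.
#' @examples
#' epoched_history(c(0, 5000), N1 = c(2e4, 2e4), N2 = c(2e4, 2e4),
#'                 m = c(0, 1e-4))
#' @export
epoched_history <- function(boundaries, N1, N2, m) {
  boundaries <- as.numeric(boundaries)
  k <- length(boundaries)
  if (k < 1 || boundaries[1] != 0) {
    stop("`boundaries` must start at 0", call. = FALSE)
  }
  if (k > 1 && any(diff(boundaries) <= 0)) {
    stop("`boundaries` must be strictly ascending", call. = FALSE)
  }
  N1 <- rep_len(as.numeric(N1), k)
  N2 <- rep_len(as.numeric(N2), k)
  m <- rep_len(as.numeric(m), k)
  if (!all(is.finite(N1)) || !all(is.finite(N2)) || any(N1 <= 0) || any(N2 <= 0)) {
    stop("population sizes must be finite and positive", call. = FALSE)
  }
  if (!all(is.finite(m)) || any(m < 0)) {
    stop("migration rates must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    start = boundaries,
    end = c(boundaries[-1], Inf),
    N1 = N1, N2 = N2, m = m
  )
  class(out) <- c("epoched_history", class(out))
  out
}

#' Time-scaling configuration
#'
#' Converts between mutation-scaled units, generations and years. Defaults
#' are the calibration used throughout: an experimentally determined
#' Arabidopsis-type mutation rate of 7.1e-9 per bp per generation and a
#' 2-year generation time suitable for perennial herbs.
#'
#' @param mu Mutation rate per bp per generation (> 0).
#' @param g Generation time in years (> 0).
#' @return A list of class `scaling_config`.
#' @export
scaling_config <- function(mu = 7.1e-9, g = 2) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu), mu > 0,
            is.numeric(g), length(g) == 1, is.finite(g), g > 0)
  structure(list(mu = mu, g = g), class = "scaling_config")
}

#' Logarithmic time grid
#'
#' Ascending interval boundaries in generations before present, log-spaced.
#' The 40-boundary default spans the resolvable range of coalescence-rate
#' inference; summaries across replicates use a finer 80-point grid.
#'
#' @param n Number of boundaries (intervals = `n - 1`).
#' @param from,to First and last boundary, generations (> 0 for log spacing).
#' @return Numeric vector of ascending boundaries.
#' @export
time_grid <- function(n = 40, from = 10, to = 2e6) {
  stopifnot(n >= 2, from > 0, to > from)
  exp(seq(log(from), log(to), length.out = n))
}

#' Transition-rate matrix of the pairwise lineage chain
#'
#' Builds the 4x4 generator of the CTMC over [lineage_states] for one epoch
#' of an IM demography. Two lineages in the same population coalesce at rate
#' `1/(2N)` (diploid scaling); each lineage independently migrates at rate
#' `m`, so a same-population pair separates at rate `2m` and a split pair
#' rejoins either population at rate `m`.
#'
#' @param N1,N2 Diploid effective sizes (> 0).
#' @param m Symmetric per-lineage migration rate (>= 0).
#' @return 4x4 rate matrix with rows summing to zero; `COALESCED` absorbing.
#' @examples
#' lineage_generator(10000, 10000, 0)
#' @export
lineage_generator <- function(N1, N2, m) {
  if (!is.finite(N1) || !is.finite(N2) || N1 <= 0 || N2 <= 0) {
    stop("population sizes must be finite and positive", call. = FALSE)
  }
  if (!is.finite(m) || m < 0) {
    stop("migration rate must be finite and non-negative", call. = FALSE)
  }
  c1 <- 1 / (2 * N1)
  c2 <- 1 / (2 * N2)
  Q <- matrix(0, 4, 4, dimnames = list(lineage_states, lineage_states))
  Q["BOTH_IN_1", "SPLIT"] <- 2 * m
  Q["BOTH_IN_1", "COALESCED"] <- c1
  Q["BOTH_IN_2", "SPLIT"] <- 2 * m
  Q["BOTH_IN_2", "COALESCED"] <- c2
  Q["SPLIT", "BOTH_IN_1"] <- m
  Q["SPLIT", "BOTH_IN_2"] <- m
  diag(Q) <- -rowSums(Q)
  Q
}

# 3x3 generator restricted to the transient states (BOTH_IN_1, BOTH_IN_2,
# SPLIT); survival = total transient mass.
transient_rates <- function(N1, N2, m) {
  lineage_generator(N1, N2, m)[1:3, 1:3]
}

# Cumulative transient propagators of an epoched history at the requested
# ascending times (>= 0). Returns a list of 3x3 matrices P(0 -> t): row s =
# start state, col = transient state occupied at t. Per-segment matrix
# exponentials are computed in compiled code.
history_propagators <- function(history, times) {
  stopifnot(all(diff(times) >= 0), times[1] >= 0)
  cuts <- sort(unique(c(history$start, times)))
  cuts <- cuts[cuts >= 0 & is.finite(cuts)]
  P <- diag(3)
  out <- vector("list", length(times))
  ti <- 1
  while (ti <= length(times) && times[ti] <= cuts[1]) {
    out[[ti]] <- P
    ti <- ti + 1
  }
  if (length(cuts) > 1) {
    for (j in seq_len(length(cuts) - 1)) {
      t0 <- cuts[j]; t1 <- cuts[j + 1]
      ep <- findInterval(t0, history$start)
      P <- P %*% transient_propagator_cpp(history$N1[ep], history$N2[ep],
                                          history$m[ep], t1 - t0)
      while (ti <= length(times) && times[ti] <= t1) {
        out[[ti]] <- P
        ti <- ti + 1
      }
    }
  }
  out
}

#' Model survival probabilities of a lineage pair
#'
#' Probability that a pair of lineages with the given starting configuration
#' has not coalesced by each time, obtained by chaining per-epoch matrix
#' exponentials of the lineage generator.
#'
#' @param history An [epoched_history()].
#' @param times Ascending times in generations (>= 0).
#' @param start One of `"BOTH_IN_1"`, `"BOTH_IN_2"`, `"SPLIT"`.
#' @return Numeric vector of survival probabilities.
#' @export
model_survival <- function(history, times, start = "BOTH_IN_1") {
  start <- match.arg(start, lineage_states[1:3])
  s <- match(start, lineage_states[1:3])
  props <- history_propagators(history, times)
  vapply(props, function(P) sum(P[s, ]), numeric(1))
}

#' Model-implied coalescence-rate curves
#'
#' The forward map of the IM model: per-interval coalescence hazards for the
#' three starting configurations (both lineages in population 1, one in
#' each, both in population 2) on a time grid, computed exactly from
#' per-epoch matrix exponentials as `-diff(log S) / diff(t)`.
#'
#' Where survival underflows (deep bottlenecks) hazards are `NA`, not zero.
#'
#' @param history An [epoched_history()].
#' @param grid Ascending grid boundaries in generations (see [time_grid()]).
#' @return A `rate_curves` tibble with columns `left`, `right`, `lambda_11`,
#'   `lambda_12`, `lambda_22`; attribute `units = "generations"`.
#' @export
model_rate_curves <- function(history, grid) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0), grid[1] >= 0)
  props <- history_propagators(history, grid)
  surv <- t(vapply(props, rowSums, numeric(3)))  # time x start-state
  surv[surv < 1e-300] <- NA_real_
  dt <- diff(grid)
  haz <- -apply(log(surv), 2, diff) / dt
  haz[haz < 0 & !is.na(haz)] <- 0  # numerical noise near machine precision
  rate_curves(
    left = grid[-length(grid)], right = grid[-1],
    lambda_11 = haz[, 1], lambda_12 = haz[, 3], lambda_22 = haz[, 2],
    units = "generations"
  )
}

#' Construct a rate-curves table
#'
#' Container for time-binned within- and cross-population coalescence
#' hazards: `lambda_11` (pair starting in population 1), `lambda_12` (one
#' lineage in each), `lambda_22` (pair in population 2). `NA` marks
#' intervals where the hazard is undefined (no exposure / underflow).
#'
#' @param left,right Interval boundaries (ascending, `right > left`).
#' @param lambda_11,lambda_12,lambda_22 Per-interval hazards (>= 0 or `NA`).
#' @param units `"generations"` or `"scaled"` (mutation-scaled).
#' @return A tibble of class `rate_curves`.
#' @export
rate_curves <- function(left, right, lambda_11, lambda_12, lambda_22,
                        units = c("generations", "scaled")) {
  units <- match.arg(units)
  stopifnot(length(left) == length(right),
            all(right > left), all(diff(left) > 0))
  for (lam in list(lambda_11, lambda_12, lambda_22)) {
    stopifnot(length(lam) == length(left))
    if (any(lam < 0, na.rm = TRUE)) {
      stop("hazards must be non-negative", call. = FALSE)
    }
  }
  out <- tibble::tibble(left = as.numeric(left), right = as.numeric(right),
                        lambda_11 = as.numeric(lambda_11),
                        lambda_12 = as.numeric(lambda_12),
                        lambda_22 = as.numeric(lambda_22))
  attr(out, "units") <- units
  class(out) <- c("rate_curves", class(out))
  out
}

#' Cumulative migration probability M(t)
#'
#' Probability that at least one lineage of a cross-population pair has
#' switched demes by time t, under per-lineage migration rate `m(t)`:
#' `M(t) = 1 - exp(-2 * integral of m)`. `M` is evaluated at grid
#' boundaries, with `M = 0` at the first boundary; it is non-decreasing and
#' bounded by 1. Thresholds on `M` define divergence statistics: the median
#' split time is where `M` falls below 0.5 scanning into the past;
#' initial divergence where it falls below 0.999 / 0.99.
#'
#' @param m Per-interval migration rates (length `length(grid) - 1`, >= 0).
#' @param grid Ascending grid boundaries in generations.
#' @return Numeric vector of `M` at each boundary (length `length(grid)`).
#' @examples
#' g <- c(0, 10^(1:6))
#' cumulative_migration(rep(1e-5, 6), g)
#' @export
cumulative_migration <- function(m, grid) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0))
  m <- as.numeric(m)
  if (length(m) != length(grid) - 1) {
    stop("`m` must have one rate per grid interval", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("migration rates must be finite and non-negative", call. = FALSE)
  }
  c(0, 1 - exp(-2 * cumsum(m * diff(grid))))
}
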