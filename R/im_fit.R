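#' Configuration for isolation-migration model fitting
#'
#' @param beta_m Ridge regularization weight on migration rates.
#' @param beta_N Smoothness regularization weight on relative changes of
#'   population sizes between adjacent intervals.
#' @param N_ancestral Diploid size pinned beyond the oldest grid boundary.
#' @param N_bounds Length-2 lower/upper bounds on fitted sizes.
#' @param m_bounds Length-2 lower/upper bounds on fitted migration rates;
#'   the working lower bound is `m_floor` (rates at the floor are
#'   effectively zero, five orders of magnitude below the isolation-event
#'   threshold of 1e-7).
#' @param m_floor Numerical floor standing in for m = 0 on the log scale.
#' @param seed Seed for multistart jitter (fits are deterministic given it).
#' @param multistart Number of jittered starts; the best final objective
#'   wins.
#' @param max_sweeps Maximum number of forward refinement sweeps; sweeps
#'   are only accepted while the global objective decreases.
#' @param eps Log-hazard floor in the residuals (hazard-only inputs).
#' @param beta_N_smooth Symmetric smoothness penalty on log sizes between
#'   adjacent intervals, in deviance units per squared log unit (count-mode
#'   inputs only); guards sparsely informed intervals against collapse
#'   toward the bounds, which the relative-change penalty prices
#'   asymmetrically.
#' @param beta_m_smooth Smoothness penalty on log10 migration between
#'   adjacent intervals, in deviance units per squared decade (count-mode
#'   inputs only). Deliberately not scaled with data size: chance
#'   fluctuations of the deviance are size-invariant, while genuine
#'   isolation signals grow with the number of draws.
#' @param smooth_tol Parsimony threshold of the migration-smoothing pass:
#'   an interval keeps a migration rate different from its older
#'   neighbour's only if that worsens the interval's data objective by at
#'   least this much. `NULL` selects 6 deviance units for count-bearing
#'   inputs (a strong-evidence threshold, robust to testing across ~40
#'   intervals) and 1e-3 for hazard-only inputs.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(beta_m = 1e-8, beta_N = 1e-6, N_ancestral = 15000,
                       N_bounds = c(10, 1e7), m_bounds = c(0, 0.5),
                       m_floor = 1e-12, seed = 1, multistart = 1,
                       max_sweeps = 3, eps = 1e-12, beta_m_smooth = 0.5,
                       beta_N_smooth = 6, smooth_tol = NULL) {
  stopifnot(beta_m >= 0, beta_N >= 0,
            length(N_bounds) == 2, N_bounds[1] < N_bounds[2],
            length(m_bounds) == 2, m_bounds[1] <= m_bounds[2],
            N_ancestral >= N_bounds[1], N_ancestral <= N_bounds[2],
            m_floor > 0, multistart >= 1, max_sweeps >= 1)
  structure(list(beta_m = beta_m, beta_N = beta_N,
                 N_ancestral = N_ancestral, N_bounds = N_bounds,
                 m_bounds = m_bounds, m_floor = m_floor, seed = seed,
                 multistart = multistart, max_sweeps = max_sweeps,
                 eps = eps, beta_m_smooth = beta_m_smooth,
                 beta_N_smooth = beta_N_smooth, smooth_tol = smooth_tol),
            class = "fit_config")
}

#' Construct an isolation-migration trajectory
#'
#' @param grid Ascending grid boundaries in generations.
#' @param m Per-interval migration rates.
#' @param N1,N2 Per-interval diploid sizes (`im_N1`, `im_N2`).
#' @return A tibble of class `im_trajectory`: one row per interval with
#'   `left`, `right`, `m`, `im_N1`, `im_N2` and `M` (cumulative migration
#'   probability at the interval's right boundary); the full boundary
#'   vector and M series are kept as attributes.
#' @export
im_trajectory <- function(grid, m, N1, N2) {
  K <- length(grid) - 1
  stopifnot(length(m) == K, length(N1) == K, length(N2) == K)
  M <- cumulative_migration(m, grid)
  out <- tibble::tibble(left = grid[-length(grid)], right = grid[-1],
                        m = as.numeric(m), im_N1 = as.numeric(N1),
                        im_N2 = as.numeric(N2), M = M[-1])
  attr(out, "boundaries") <- grid
  attr(out, "M_boundaries") <- M
  class(out) <- c("im_trajectory", class(out))
  out
}

traj_boundaries <- function(traj) {
  b <- attr(traj, "boundaries")
  if (is.null(b)) b <- c(traj$left, traj$right[nrow(traj)])
  b
}

traj_M <- function(traj) {
  M <- attr(traj, "M_boundaries")
  if (is.null(M)) M <- cumulative_migration(traj$m, traj_boundaries(traj))
  M
}

#' Warm start for the IM fit from observed rate curves
#'
#' Inverts the diploid dictionary N = 1/(2 lambda) on the within-population
#' curves and maps the relative cross-coalescence rate
#' `2 lambda_12 / (lambda_11 + lambda_22)` monotonically into the migration
#' bounds. Deterministic; intervals with missing or zero within-population
#' hazard are clipped to the bounds and carried forward.
#'
#' @param rates A [rate_curves()] tibble in per-generation units.
#' @param config A [fit_config()].
#' @return An [epoched_history()] whose epochs are the grid intervals, with
#'   one ancestral epoch pinned to `N_ancestral` beyond the oldest boundary.
#' @export
initialize_from_rates <- function(rates, config = fit_config()) {
  stopifnot(identical(attr(rates, "units"), "generations"))
  grid <- c(rates$left, rates$right[nrow(rates)])
  inv <- function(lam) {
    N <- 1 / (2 * lam)
    N[!is.finite(N)] <- NA_real_
    N <- pmin(pmax(N, config$N_bounds[1]), config$N_bounds[2])
    fill_forward(N, config$N_ancestral)
  }
  N1 <- inv(rates$lambda_11)
  N2 <- inv(rates$lambda_22)
  rccr <- 2 * rates$lambda_12 / (rates$lambda_11 + rates$lambda_22)
  rccr <- pmin(pmax(rccr, 0), 1)
  m0 <- fill_forward(rccr * 1e-4, config$m_floor)
  m0 <- pmin(pmax(m0, 0), config$m_bounds[2])
  epoched_history(c(0, grid[-c(1, length(grid))], grid[length(grid)]),
                  N1 = c(N1, config$N_ancestral),
                  N2 = c(N2, config$N_ancestral),
                  m = c(m0, m0[length(m0)]))
}

fill_forward <- function(x, default) {
  if (all(is.na(x))) return(rep(default, length(x)))
  first <- which(!is.na(x))[1]
  if (first > 1) x[seq_len(first - 1)] <- x[first]
  for (i in seq_along(x)) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}

#' Fit the piecewise isolation-migration model to rate curves
#'
#' Fits per-interval sizes and migration rates by regularized maximum
#' goodness of fit to the three coalescence-rate curves, plus a ridge
#' penalty `beta_m * m^2` and a size-smoothness penalty
#' `beta_N * ((N_k - N_{k-1}) / N_{k-1})^2`, subject to box bounds. When
#' the curves carry event counts and exposures (simulated rates from
#' [empirical_rate_curves()]), the data term is the Poisson deviance of
#' observed versus model-expected coalescences per interval, which makes
#' zero-event bins exactly as informative as their exposure warrants; for
#' hazard-only inputs (e.g. MSMC2 tables) it is the squared log-hazard
#' residual `(log(model + eps) - log(observed + eps))^2`.
#'
#' The optimizer sweeps intervals forward in time, solving each interval's
#' three parameters by bounded quasi-Newton steps given the propagated
#' lineage-state distribution, then applies two parsimony passes: sizes
#' revert to the younger neighbour's values unless the data reject them
#' after re-fitting migration under the candidate (young to old), and
#' migration reverts to the older neighbour's rate unless the data demand
#' otherwise (old to young), both at the `smooth_tol` threshold. Cycles
#' repeat while the global objective decreases. Epochs older than the
#' oldest grid boundary are pinned to `N_ancestral`. Intervals with no
#' usable data (zero exposure everywhere, or survival underflow) inherit
#' the previous interval's parameters and are flagged.
#'
#' @param rates A [rate_curves()] tibble in per-generation units with at
#'   least 8 intervals. `NA` hazards are treated as missing; `NaN` is an
#'   error.
#' @param config A [fit_config()].
#' @return Object of class `im_fit`: list with `trajectory`
#'   (an [im_trajectory()]), `diagnostics` (objective, trace, convergence,
#'   per-interval flags, failure count, oscillation flag), `config`, and
#'   the input `rates`.
#' @export
fit_im <- function(rates, config = fit_config()) {
  stopifnot(inherits(rates, "rate_curves"))
  if (!identical(attr(rates, "units"), "generations")) {
    stop("`rates` must be in per-generation units", call. = FALSE)
  }
  if (nrow(rates) < 8) stop("grid must have at least 8 intervals", call. = FALSE)
  obs <- as.matrix(rates[, c("lambda_11", "lambda_22", "lambda_12")])
  if (any(is.nan(obs))) stop("NaN hazards in input", call. = FALSE)
  cnt <- NULL
  if (all(c("events_11", "exposure_11") %in% names(rates))) {
    cnt <- list(
      events = as.matrix(rates[, c("events_11", "events_22", "events_12")]),
      exposure = as.matrix(rates[, c("exposure_11", "exposure_22",
                                     "exposure_12")])
    )
  }

  grid <- c(rates$left, rates$right[nrow(rates)])
  # regularization weights are defined against unit-scale log residuals;
  # the deviance data term scales with event counts, so translate the
  # penalty strength accordingly
  config$reg_scale <- if (is.null(cnt)) 1 else {
    max(1, sum(cnt$events, na.rm = TRUE) / nrow(rates))
  }
  init <- initialize_from_rates(rates, config)
  K <- nrow(rates)
  par0 <- cbind(log(init$N1[1:K]), log(init$N2[1:K]),
                log10(pmax(init$m[1:K], config$m_floor)))

  starts <- list(par0)
  if (config$multistart > 1) {
    starts <- c(starts, withr::with_seed(config$seed, {
      lapply(seq_len(config$multistart - 1), function(i) {
        par0 + cbind(stats::rnorm(K, 0, 0.3), stats::rnorm(K, 0, 0.3),
                     stats::rnorm(K, 0, 0.5))
      })
    }))
  }

  best <- NULL
  for (p0 in starts) {
    cand <- fit_im_sweeps(p0, obs, cnt, grid, config)
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }

  traj <- im_trajectory(grid, m = 10^best$par[, 3],
                        N1 = exp(best$par[, 1]), N2 = exp(best$par[, 2]))
  diag <- fit_diagnostics(best, grid, config)
  structure(list(trajectory = traj, diagnostics = diag,
                 config = config, rates = rates),
            class = "im_fit")
}

# Repeated (sweep + parsimony passes) cycles; a cycle is kept only if it
# lowers the global objective, so the recorded trace is non-increasing.
fit_im_sweeps <- function(par, obs, cnt, grid, config) {
  cycle <- function(p) {
    st <- fit_forward_sweep(p, obs, cnt, grid, config)
    st <- adopt_N_pass(st, obs, cnt, grid, config)
    smooth_m_pass(st, obs, cnt, grid, config)
  }
  state <- cycle(par)
  trace <- state$objective
  for (s in seq_len(config$max_sweeps - 1)) {
    cand <- cycle(state$par)
    if (cand$objective < state$objective - 1e-12) {
      state <- cand
      trace <- c(trace, cand$objective)
    } else break
  }
  state$trace <- trace
  state
}

# Parsimony pass on sizes, young to old: interval k keeps sizes different
# from interval k-1's only if the data reject them even after re-fitting
# the interval's migration rate under the candidate sizes. This pins the
# directions left free by the quasi-stationary ridge (deep intervals where
# the three curves share a single decay rate) to the last identified
# values instead of letting them random-walk. Propagators are updated
# incrementally so each decision uses the adopted upstream parameters.
adopt_N_pass <- function(state, obs, cnt, grid, config) {
  tol <- config$smooth_tol
  if (is.null(tol)) tol <- if (is.null(cnt)) 1e-3 else 6
  par <- state$par
  K <- nrow(par)
  wlo <- log10(config$m_floor)
  whi <- log10(max(config$m_bounds[2], config$m_floor))
  P <- diag(3)
  P_in <- vector("list", K)
  for (k in seq_len(K)) {
    P_in[[k]] <- P
    dt <- grid[k + 1] - grid[k]
    head_dt <- if (k == 1) grid[1] else 0
    S_in <- rowSums(P)
    y <- obs[k, ]
    use <- !is.na(y) & S_in > 1e-14
    if (!is.null(cnt)) use <- use & cnt$exposure[k, ] > 0

    dat <- function(p) {
      sv <- interval_survival_cpp(P, exp(p[1]), exp(p[2]), 10^p[3], dt,
                                  head_dt)
      h <- pmax(as.vector((log(pmax(sv$S0, 1e-300)) -
                             log(pmax(sv$S_out, 1e-300))) / dt), 0)
      interval_data_obj(h, y, use, k, cnt, config$eps)
    }

    if (k > 1 && !identical(par[k, 1:2], par[k - 1, 1:2])) {
      if (!any(use)) {
        par[k, 1:2] <- par[k - 1, 1:2]
      } else {
        cur <- dat(par[k, ])
        rs <- if (is.null(config$reg_scale)) 1 else config$reg_scale
        pen <- function(w) {
          val <- rs * config$beta_m * (10^w)^2
          if (!is.null(cnt)) {
            val <- val + config$beta_m_smooth * (w - par[k - 1, 3])^2
          }
          val
        }
        refit <- stats::optim(par[k, 3],
                              function(w) dat(c(par[k - 1, 1:2], w)) + pen(w),
                              method = "L-BFGS-B", lower = wlo, upper = whi,
                              control = list(maxit = 50, factr = 1e7))
        if (dat(c(par[k - 1, 1:2], refit$par)) - cur < tol) {
          par[k, ] <- c(par[k - 1, 1:2], refit$par)
        }
      }
    }
    P <- interval_survival_cpp(P, exp(par[k, 1]), exp(par[k, 2]),
                               10^par[k, 3], dt, head_dt)$P_out
  }
  state$par <- par
  state$P_in <- P_in
  state$objective <- global_objective(par, obs, cnt, grid, config)
  state
}

# Data misfit of one interval for the three curves: Poisson deviance of
# events against model-expected events when counts are available,
# otherwise squared log-hazard residuals.
interval_data_obj <- function(h, y, use, k, cnt, eps) {
  if (is.null(cnt)) {
    return(sum((log(h[use] + eps) - log(y[use] + eps))^2))
  }
  D <- cnt$events[k, use]
  E <- h[use] * cnt$exposure[k, use]
  dev <- 2 * (E - D)
  pos <- D > 0
  dev[pos] <- dev[pos] + 2 * D[pos] * log(D[pos] / pmax(E[pos], 1e-300))
  sum(dev)
}

fit_forward_sweep <- function(par, obs, cnt, grid, config) {
  K <- nrow(par)
  eps <- config$eps
  lN <- log(config$N_bounds)
  wlo <- log10(config$m_floor)
  whi <- log10(max(config$m_bounds[2], config$m_floor))
  P <- diag(3)
  objective <- 0
  conv <- logical(K)
  data_free <- logical(K)
  P_in <- vector("list", K)

  for (k in seq_len(K)) {
    dt <- grid[k + 1] - grid[k]
    head_dt <- if (k == 1) grid[1] else 0
    P_in[[k]] <- P
    S_in <- rowSums(P)
    y <- obs[k, ]                       # order: l11 (B1), l22 (B2), l12 (SPLIT)
    use <- !is.na(y) & S_in > 1e-14
    if (!is.null(cnt)) use <- use & cnt$exposure[k, ] > 0

    local <- function(p, data_only = FALSE) {
      sv <- interval_survival_cpp(P, exp(p[1]), exp(p[2]), 10^p[3], dt,
                                  head_dt)
      h <- (log(pmax(sv$S0, 1e-300)) - log(pmax(sv$S_out, 1e-300))) / dt
      h <- pmax(as.vector(h), 0)
      val <- interval_data_obj(h, y, use, k, cnt, eps)
      if (!data_only) {
        rs <- if (is.null(config$reg_scale)) 1 else config$reg_scale
        val <- val + rs * config$beta_m * (10^p[3])^2
        if (k > 1) {
          val <- val + rs *
            (config$beta_N * ((exp(p[1]) - exp(par[k - 1, 1])) / exp(par[k - 1, 1]))^2 +
               config$beta_N * ((exp(p[2]) - exp(par[k - 1, 2])) / exp(par[k - 1, 2]))^2)
          if (!is.null(cnt)) {
            val <- val + config$beta_m_smooth * (p[3] - par[k - 1, 3])^2 +
              config$beta_N_smooth * ((p[1] - par[k - 1, 1])^2 +
                                        (p[2] - par[k - 1, 2])^2)
          }
        }
      }
      val
    }

    if (!any(use)) {
      data_free[k] <- TRUE
      if (k > 1) par[k, ] <- par[k - 1, ]
      conv[k] <- TRUE
    } else {
      p0 <- pmin(pmax(par[k, ], c(lN[1], lN[1], wlo)), c(lN[2], lN[2], whi))
      opt <- stats::optim(p0, local, method = "L-BFGS-B",
                          lower = c(lN[1], lN[1], wlo),
                          upper = c(lN[2], lN[2], whi),
                          control = list(maxit = 200, factr = 1e7))
      par[k, ] <- opt$par
      conv[k] <- opt$convergence == 0
    }

    objective <- objective + local(par[k, ])
    P <- interval_survival_cpp(P, exp(par[k, 1]), exp(par[k, 2]),
                               10^par[k, 3], dt, head_dt)$P_out
  }

  list(par = par, objective = objective, converged = conv,
       data_free = data_free, m_held = data_free, P_in = P_in)
}

# Parsimony pass on migration, old to young: interval k keeps a migration
# rate different from interval k+1's only if replacing it worsens k's data
# objective by at least smooth_tol. Prevents intervals that carry no
# information about m (e.g. fully mixed lineages, or empty young bins)
# from drifting to the regularization floor and creating artefactual
# isolation events. The global objective is recomputed exactly afterwards.
smooth_m_pass <- function(state, obs, cnt, grid, config) {
  tol <- config$smooth_tol
  if (is.null(tol)) tol <- if (is.null(cnt)) 1e-3 else 6
  par <- state$par
  K <- nrow(par)
  m_held <- state$m_held

  data_obj_k <- function(k, p) {
    P <- state$P_in[[k]]
    dt <- grid[k + 1] - grid[k]
    head_dt <- if (k == 1) grid[1] else 0
    S_in <- rowSums(P)
    y <- obs[k, ]
    use <- !is.na(y) & S_in > 1e-14
    if (!is.null(cnt)) use <- use & cnt$exposure[k, ] > 0
    if (!any(use)) return(0)
    sv <- interval_survival_cpp(P, exp(p[1]), exp(p[2]), 10^p[3], dt,
                                head_dt)
    h <- pmax(as.vector((log(pmax(sv$S0, 1e-300)) -
                           log(pmax(sv$S_out, 1e-300))) / dt), 0)
    interval_data_obj(h, y, use, k, cnt, config$eps)
  }

  for (k in (K - 1):1) {
    if (par[k, 3] == par[k + 1, 3]) next
    cur <- data_obj_k(k, par[k, ])
    alt <- data_obj_k(k, c(par[k, 1:2], par[k + 1, 3]))
    if (alt - cur < tol) {
      par[k, 3] <- par[k + 1, 3]
      m_held[k] <- TRUE
    }
  }
  state$par <- par
  state$m_held <- m_held
  state$objective <- global_objective(par, obs, cnt, grid, config)
  state
}

global_objective <- function(par, obs, cnt, grid, config) {
  K <- nrow(par)
  P <- diag(3)
  total <- 0
  for (k in seq_len(K)) {
    dt <- grid[k + 1] - grid[k]
    head_dt <- if (k == 1) grid[1] else 0
    S_in <- rowSums(P)
    y <- obs[k, ]
    use <- !is.na(y) & S_in > 1e-14
    if (!is.null(cnt)) use <- use & cnt$exposure[k, ] > 0
    sv <- interval_survival_cpp(P, exp(par[k, 1]), exp(par[k, 2]),
                                10^par[k, 3], dt, head_dt)
    Pk <- sv$P_out
    if (any(use)) {
      h <- pmax(as.vector((log(pmax(sv$S0, 1e-300)) -
                             log(pmax(sv$S_out, 1e-300))) / dt), 0)
      total <- total + interval_data_obj(h, y, use, k, cnt, config$eps)
    }
    rs <- if (is.null(config$reg_scale)) 1 else config$reg_scale
    total <- total + rs * config$beta_m * (10^par[k, 3])^2
    if (k > 1) {
      total <- total + rs *
        (config$beta_N * ((exp(par[k, 1]) - exp(par[k - 1, 1])) / exp(par[k - 1, 1]))^2 +
           config$beta_N * ((exp(par[k, 2]) - exp(par[k - 1, 2])) / exp(par[k - 1, 2]))^2)
      if (!is.null(cnt)) {
        total <- total +
          config$beta_m_smooth * (par[k, 3] - par[k - 1, 3])^2 +
          config$beta_N_smooth * ((par[k, 1] - par[k - 1, 1])^2 +
                                    (par[k, 2] - par[k - 1, 2])^2)
      }
    }
    P <- Pk
  }
  total
}

fit_diagnostics <- function(state, grid, config) {
  K <- nrow(state$par)
  lN <- log(config$N_bounds)
  tol <- 1e-6
  at_lower <- state$par[, 1] < lN[1] + tol | state$par[, 2] < lN[1] + tol
  at_upper <- state$par[, 1] > lN[2] - tol | state$par[, 2] > lN[2] - tol
  failure <- (at_lower | at_upper) & !state$data_free
  runs <- rle(failure)
  n_failure_events <- sum(runs$values)
  oscillation <- any(at_lower & failure) && any(at_upper & failure)
  intervals <- tibble::tibble(
    left = grid[-length(grid)], right = grid[-1],
    failure = failure, at_lower_bound = at_lower & failure,
    at_upper_bound = at_upper & failure,
    data_free = state$data_free, m_held = state$m_held
  )
  list(objective = state$objective, trace = state$trace,
       converged = all(state$converged),
       n_unconverged = sum(!state$converged), intervals = intervals,
       n_failures = n_failure_events, oscillation = oscillation)
}

#' Run-acceptance rules for a fitted IM trajectory
#'
#' Applies the acceptance policy for fitted runs: runs with two or more
#' failure events whose sizes oscillate between the bounds are discarded;
#' any failure disqualifies the run for initial-divergence estimation; a
#' failure within the Holocene (more recent than 11,700 years) disqualifies
#' it for split-time estimation; current effective sizes are always
#' accepted (most-recent coalescence rates are unaffected by older
#' epochs, by the Markov property of the lineage chain).
#'
#' @param fit An `im_fit` object.
#' @param scaling A [scaling_config()].
#' @param holocene_years Recency bound of the Holocene in years.
#' @return One-row tibble of class `run_acceptance` with logical columns
#'   `accepted_initial_divergence`, `accepted_split_time`,
#'   `accepted_current_ne`, `discarded`, and a `reason` string.
#' @export
qc_run <- function(fit, scaling = scaling_config(), holocene_years = 11700) {
  d <- fit$diagnostics
  fail <- d$intervals$failure
  mid_years <- (d$intervals$left + d$intervals$right) / 2 * scaling$g
  holocene_fail <- any(fail & mid_years < holocene_years)
  discarded <- d$n_failures >= 2 && d$oscillation
  reasons <- character(0)
  if (discarded) {
    reasons <- "repeated failures with sizes oscillating between bounds"
  } else {
    if (any(fail)) reasons <- c(reasons, "failure epoch: initial divergence not accepted")
    if (holocene_fail) reasons <- c(reasons, "Holocene failure: split time not accepted")
  }
  out <- tibble::tibble(
    accepted_initial_divergence = !discarded && !any(fail),
    accepted_split_time = !discarded && !holocene_fail,
    accepted_current_ne = TRUE,
    discarded = discarded,
    reason = if (length(reasons)) paste(reasons, collapse = "; ") else "accepted"
  )
  class(out) <- c("run_acceptance", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an IM fit into its trajectory table
#'
#' @param x An `im_fit` object.
#' @param scaling Optional [scaling_config()]; when given, `time_years`
#'   columns are added.
#' @param ... Unused.
#' @return The trajectory tibble (one row per grid interval).
#' @export
tidy.im_fit <- function(x, scaling = NULL, ...) {
  out <- tibble::as_tibble(x$trajectory)
  if (!is.null(scaling)) {
    out$left_years <- out$left * scaling$g
    out$right_years <- out$right * scaling$g
  }
  out
}

#' One-row fit summary
#'
#' @param x An `im_fit` object.
#' @param ... Unused.
#' @export
glance.im_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(objective = d$objective, converged = d$converged,
                 n_failures = d$n_failures, oscillation = d$oscillation,
                 n_intervals = nrow(x$trajectory))
}

#' @export
print.im_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<im_fit> %d intervals | objective %.4g | %d interval(s) unconverged | failures: %d%s\n",
    nrow(x$trajectory), d$objective, d$n_unconverged,
    d$n_failures, if (d$oscillation) " (oscillating)" else ""))
  invisible(x)
}
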