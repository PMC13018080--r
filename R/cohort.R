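#' Cohort state-trajectory model
#'
#' Three-state (functionally independent mRS 0-2 / functionally dependent
#' mRS 3-5 / dead) cohort dynamics on the evaluation grid
#' \{0.25, 1, 2, 3, 5\} years, then annually to 30 years. The 3-month point
#' seeds both the disability track and the nursing-home occupancy track.
#' Between 1 and 5 years per-interval transition matrices act; after 5 years
#' the independent:dependent mix of survivors is frozen (outcome plateau) and
#' only mortality acts, applied annually, with dead absorbing.
#'
#' @name cohort_model
NULL

STATES <- c("independent", "dependent", "dead")

#' Construct and validate a state distribution
#'
#' @param independent,dependent,dead fractions of the cohort in each band.
#' @return Named numeric vector of length 3 summing to 1.
#' @export
#' @examples
#' state_distribution(0.5, 0.3, 0.2)
state_distribution <- function(independent, dependent, dead) {
  validate_state_distribution(
    c(independent = independent, dependent = dependent, dead = dead))
}

validate_state_distribution <- function(d, what = "state distribution",
                                        tol = 1e-9) {
  if (!is.numeric(d) || length(d) != 3)
    fail("%s: need 3 numeric fractions", what)
  if (is.null(names(d))) names(d) <- STATES
  d <- d[STATES]
  if (anyNA(d)) fail("%s: fields must be named %s", what,
                     paste(STATES, collapse = "/"))
  if (any(d < -tol) || any(d > 1 + tol))
    fail("%s: fractions must lie in [0, 1]", what)
  if (abs(sum(d) - 1) > tol)
    fail("%s: fractions must sum to 1 (got %.12f)", what, sum(d))
  d
}

#' Evolve a state distribution through a sequence of transition matrices
#'
#' Row-stochastic left multiplication: `d[k] = d[k-1] %*% M[[k]]`. This is the
#' single primitive all trajectory code goes through, so that any trajectory
#' equals explicit matrix-power evolution by construction.
#'
#' @param dist0 starting distribution (named numeric, independent/dependent/dead).
#' @param matrices list of 3x3 row-stochastic transition matrices, one per
#'   interval, rows = from-state, columns = to-state.
#' @return Matrix with one row per time point (including the start), columns
#'   `independent`, `dependent`, `dead`.
#' @export
evolve_states <- function(dist0, matrices) {
  d <- validate_state_distribution(dist0)
  out <- matrix(NA_real_, nrow = length(matrices) + 1L, ncol = 3,
                dimnames = list(NULL, STATES))
  out[1L, ] <- d
  for (k in seq_along(matrices)) {
    M <- validate_transition_matrix(matrices[[k]])
    d <- as.numeric(d %*% M)
    out[k + 1L, ] <- d
  }
  out
}

validate_transition_matrix <- function(M, tol = 1e-9) {
  if (!is.matrix(M) || any(dim(M) != 3))
    fail("transition matrix must be 3x3")
  dimnames(M) <- list(STATES, STATES)
  if (any(M < -tol)) fail("transition matrix: negative rate")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-8))
    fail("transition matrix: outflow of a row differs from 1 (sums: %s)",
         paste(signif(rs, 10), collapse = ", "))
  if (abs(M["dead", "dead"] - 1) > tol)
    fail("transition matrix: dead must be absorbing")
  M
}

#' Transition matrix realizing the move between two state distributions
#'
#' Builds a valid row-stochastic matrix taking `from` to `to`: deaths are
#' drawn from the two alive states proportionally to their size, then the
#' minimal net transfer between independent and dependent closes the balance.
#' Dead is absorbing. Requires the dead fraction not to decrease.
#'
#' @param from,to state distributions (named numeric).
#' @return A 3x3 row-stochastic matrix `M` with `from %*% M == to`.
#' @export
transition_from_dists <- function(from, to) {
  from <- validate_state_distribution(from)
  to <- validate_state_distribution(to)
  dm <- to[["dead"]] - from[["dead"]]
  if (dm < -1e-9) fail("transition_from_dists: dead fraction cannot decrease")
  dm <- max(dm, 0)
  alive <- from[["independent"]] + from[["dependent"]]
  M <- diag(3); dimnames(M) <- list(STATES, STATES)
  if (alive <= 1e-15) return(M) # everyone dead already; identity is valid
  p_die <- min(dm / alive, 1)
  i_surv <- from[["independent"]] * (1 - p_die)
  d_surv <- from[["dependent"]] * (1 - p_die)
  x <- i_surv - to[["independent"]] # net flow independent -> dependent
  M["dead", ] <- c(0, 0, 1)
  if (x >= 0) {
    p_id <- if (i_surv > 1e-15) min(x / from[["independent"]], 1) else 0
    M["independent", ] <- c((1 - p_die) - p_id, p_id, p_die)
    M["dependent", ] <- c(0, 1 - p_die, p_die)
  } else {
    p_di <- if (d_surv > 1e-15) min(-x / from[["dependent"]], 1) else 0
    M["independent", ] <- c(1 - p_die, 0, p_die)
    M["dependent", ] <- c(p_di, (1 - p_die) - p_di, p_die)
  }
  validate_transition_matrix(M)
}

#' Evaluation time grid
#'
#' @param horizon final year (positive, at most 30).
#' @return Numeric vector of evaluation times in years since admission:
#'   0.25 (the 3-month point), 1, 2, 3, 5, then annually to `horizon`.
#' @export
time_grid <- function(horizon = 30) {
  if (!is.numeric(horizon) || horizon <= 0 || horizon > 30)
    fail("horizon must be a positive number of years <= 30")
  pts <- c(0.25, 1, 2, 3, 5, if (horizon > 5) 6:horizon)
  pts[pts <= horizon + 1e-12]
}

#' Simulate the cohort state trajectory per stratum
#'
#' Starts each stratum from its 3-month distribution, applies the schedule's
#' per-interval transitions through year 5 (intervals 0.25-1, 1-2, 2-3, 3-5),
#' then applies the post-5-year annual mortality to both alive states, which
#' keeps the independent:dependent mix of survivors constant (plateau).
#' Nursing-home occupancy is tracked on the same grid via
#' [nursing_home_occupancy()].
#'
#' @param config a validated config list ([default_config()]).
#' @param horizon last year simulated (default 30).
#' @param strata which strata to simulate (`"ci"`, `"no_ci"`).
#' @return A data.frame with columns `stratum`, `time_years`,
#'   `f_independent`, `f_dependent`, `f_dead`, `nh_occupancy`.
#' @export
#' @examples
#' traj <- simulate_cohort(default_config(), horizon = 5)
#' subset(traj, stratum == "ci")
simulate_cohort <- function(config, horizon = 30,
                            strata = c("ci", "no_ci")) {
  grid <- time_grid(horizon)
  out <- lapply(strata, function(s) {
    sch <- config$schedule[[s]]
    if (is.null(sch)) fail("unknown stratum '%s'", s)
    key_dists <- list(sch$dist_3mo, sch$dist_1y, sch$dist_2y,
                      sch$dist_3y, sch$dist_5y)
    key_times <- c(0.25, 1, 2, 3, 5)
    keep <- key_times <= horizon + 1e-12
    mats <- list()
    n_key <- sum(keep)
    if (n_key > 1)
      for (k in 2:n_key)
        mats[[k - 1L]] <- transition_from_dists(key_dists[[k - 1L]],
                                                key_dists[[k]])
    # annual mortality after year 5, equal for both alive states
    if (horizon > 5) {
      q <- sch$mortality_post5y
      Mq <- matrix(c(1 - q, 0, q,
                     0, 1 - q, q,
                     0, 0, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(STATES, STATES))
      mats <- c(mats, rep(list(Mq), horizon - 5L))
    }
    dists <- evolve_states(key_dists[[1L]], mats)
    alive <- 1 - dists[, "dead"]
    occ <- nursing_home_occupancy(sch$nh_3mo, config$nursing_home, grid,
                                  alive = alive)
    data.frame(stratum = s, time_years = grid,
               f_independent = dists[, "independent"],
               f_dependent = dists[, "dependent"],
               f_dead = dists[, "dead"],
               nh_occupancy = occ,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Nursing-home occupancy on the evaluation grid
#'
#' Occupancy starts from the 3-month utilization, retains 70% to 1 year, 61%
#' of the 1-year residents to 2 years and 36% to 5 years; the unprinted
#' 3-year retention is interpolated geometrically between the 2- and 5-year
#' anchors. After 5 years one of three rules applies (see
#' `nursing_home$post5y_mode`): `share_of_alive` sets occupancy to 13% of
#' survivors, `retain_all` carries the 5-year occupancy forward with deaths
#' removed in proportion to cohort mortality, `retain_13pct` decays occupancy
#' by the factor 0.13 per year. Occupancy is capped at the alive fraction.
#'
#' @param initial_3mo occupancy fraction at 3 months, in \[0, 1\].
#' @param nhs nursing-home schedule (the `nursing_home` config component).
#' @param times evaluation grid, as from [time_grid()].
#' @param alive optional alive fraction at each grid point (needed by the
#'   `share_of_alive` and `retain_all` rules and for capping).
#' @return Numeric occupancy series aligned with `times`.
#' @export
#' @examples
#' nhs <- default_config()$nursing_home
#' nursing_home_occupancy(0.10, nhs, c(0.25, 1, 2, 3, 5))
nursing_home_occupancy <- function(initial_3mo, nhs, times, alive = NULL) {
  if (!is.numeric(initial_3mo) || initial_3mo < 0 || initial_3mo > 1)
    fail("nursing_home_occupancy: initial_3mo must be a fraction in [0, 1]")
  r1 <- nhs$retention_3mo_to_1y
  r2 <- nhs$retention_1y_to_2y
  r5 <- nhs$retention_1y_to_5y
  # geometric interpolation of the unprinted 3-year retention between the
  # printed 2- and 5-year retention anchors
  r3 <- r2 * (r5 / r2)^((3 - 2) / (5 - 2))
  occ1 <- initial_3mo * r1
  base <- function(t) {
    if (t <= 0.25 + 1e-12) initial_3mo
    else if (t <= 1) occ1
    else if (t <= 2) occ1 * r2
    else if (t <= 3) occ1 * r3
    else if (t <= 5) occ1 * r5
    else NA_real_
  }
  occ <- vapply(times, base, numeric(1))
  post <- which(times > 5 + 1e-12)
  if (length(post)) {
    if (nhs$post5y_mode %in% c("share_of_alive", "retain_all") &&
        is.null(alive))
      fail("nursing_home_occupancy: post5y_mode '%s' needs the alive series",
           nhs$post5y_mode)
    i5 <- which(abs(times - 5) < 1e-9)
    occ5 <- occ1 * r5
    occ[post] <- switch(nhs$post5y_mode,
      share_of_alive = nhs$annual_rate_post5y * alive[post],
      retain_all = if (length(i5)) occ5 * alive[post] / alive[i5]
                   else occ5 * alive[post] / max(alive[1L], 1e-15),
      retain_13pct = occ5 * nhs$annual_rate_post5y^(times[post] - 5)
    )
  }
  if (!is.null(alive)) occ <- pmin(occ, alive)
  occ
}
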